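# Marker ordering within a linkage group. A seed order is grown by greedy
# insertion from the most informative loci; alternative orders are then
# compared with a ripple (sliding window, all permutations) under the
# strictly lexicographic objective (fewest crossovers, highest likelihood,
# shortest map).

#' Build a pairwise lookup cache from two-point results
#'
#' Dense matrices over the given loci for fast ordering; pairs that were
#' not estimable are penalized as unlinked (rf just under 0.5, LOD 0).
#'
#' @param tp data.frame from [two_point_all()].
#' @param loci locus ids to index.
#' @return list of matrices `rf`, `lod`, `n`, `xo` (expected crossovers
#'   per meiosis, i.e. the adjacent rf, with unestimable pairs penalized
#'   at the free-recombination value) and `gap` (phase-gap LOD), each
#'   `loci x loci`.
#' @export
tp_cache <- function(tp, loci) {
  m <- length(loci)
  mk <- function(fill) matrix(fill, m, m, dimnames = list(loci, loci))
  rf <- mk(0.4999); lod <- mk(0); nn <- mk(0); gap <- mk(Inf)
  keep <- tp$a %in% loci & tp$b %in% loci
  tp <- tp[keep, , drop = FALSE]
  ia <- match(tp$a, loci); ib <- match(tp$b, loci)
  idx <- cbind(ia, ib); idx2 <- cbind(ib, ia)
  rf[idx] <- tp$rf; rf[idx2] <- tp$rf
  lod[idx] <- tp$lod; lod[idx2] <- tp$lod
  nn[idx] <- tp$n_informative; nn[idx2] <- tp$n_informative
  gap[idx] <- tp$phase_gap_lod; gap[idx2] <- tp$phase_gap_lod
  # crossover term on the per-meiosis scale so that pairs informative in
  # one or two parents are weighted comparably (sum of adjacent rf)
  xo <- pmin(rf, 0.5)
  diag(rf) <- 0; diag(lod) <- 0; diag(xo) <- 0
  list(rf = rf, lod = lod, n = nn, xo = xo, gap = gap)
}

# lexicographic objective of an order: (total expected crossovers,
# -sum of adjacent LODs, map length). Smaller is better.
order_objective <- function(ord, cache, mapping_function = "kosambi") {
  if (length(ord) < 2) return(c(0, 0, 0))
  i <- ord[-length(ord)]; j <- ord[-1L]
  idx <- cbind(match(i, rownames(cache$rf)), match(j, rownames(cache$rf)))
  rfs <- pmin(cache$rf[idx], 0.4999)
  c(sum(cache$xo[idx]), -sum(cache$lod[idx]),
    sum(map_distance(rfs, mapping_function)))
}

# edge-wise objective matrices for fast incremental evaluation
obj_mats <- function(cache, mapping_function) {
  D <- map_distance(pmin(cache$rf, 0.4999), mapping_function)
  diag(D) <- 0
  list(xo = cache$xo, nl = -cache$lod, dd = D)
}

# objective of an integer-coded order as a 3-vector
obj_of <- function(ord_i, M) {
  if (length(ord_i) < 2) return(c(0, 0, 0))
  idx <- cbind(ord_i[-length(ord_i)], ord_i[-1L])
  c(sum(M$xo[idx]), sum(M$nl[idx]), sum(M$dd[idx]))
}

lex_less <- function(a, b, eps = 1e-9) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - eps) return(TRUE)
    if (a[k] > b[k] + eps) return(FALSE)
  }
  FALSE
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Order the loci of one linkage group
#'
#' Seed loci (by default those informative in both parents) are ordered by
#' greedy insertion: start from the highest-LOD seed pair, then insert
#' each remaining locus at the position minimizing the objective. The
#' order is then polished by a ripple: every sliding window of
#' `ripple_window` loci is permuted and an alternative accepted only if it
#' is strictly better lexicographically on (crossovers, likelihood,
#' length); passes repeat until none is accepted. Orientation is fixed by
#' placing the smaller terminal locus id first.
#'
#' @param group character vector of locus ids.
#' @param cache a [tp_cache()] over (at least) these loci.
#' @param seed_loci loci allowed to seed the order (default: all in
#'   `group`). Pairs whose two phases are nearly equally likely
#'   (`phase_gap_lod < 0.1`) are never used as the starting pair.
#' @param ripple_window sliding-window size (default 4).
#' @param mapping_function passed to the length term of the objective.
#' @param max_passes safety bound on ripple passes.
#' @return character vector: the ordered locus ids.
#' @export
order_group <- function(group, cache, seed_loci = NULL, ripple_window = 4L,
                        mapping_function = "kosambi", max_passes = 25L) {
  group <- sort(group)
  if (length(group) < 2) return(group)
  seed_loci <- if (is.null(seed_loci)) group else sort(intersect(seed_loci, group))
  if (length(seed_loci) < 2) seed_loci <- group
  all_ids <- rownames(cache$rf)
  M <- obj_mats(cache, mapping_function)

  lodm <- cache$lod[seed_loci, seed_loci, drop = FALSE]
  gapm <- cache$gap[seed_loci, seed_loci, drop = FALSE]
  cand <- lodm
  cand[gapm < 0.1] <- -Inf  # phase-ambiguous pairs cannot seed
  diag(cand) <- -Inf
  best <- which(cand == max(cand), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  start <- sort(c(seed_loci[best[1]], seed_loci[best[2]]))
  ord_i <- match(start, all_ids)

  # greedy insertion with O(1) delta per candidate position
  insert_best <- function(ord_i, li) {
    k <- length(ord_i)
    d_xo <- d_nl <- d_dd <- numeric(k + 1L)
    d_xo[1] <- M$xo[li, ord_i[1]]; d_nl[1] <- M$nl[li, ord_i[1]]
    d_dd[1] <- M$dd[li, ord_i[1]]
    d_xo[k + 1L] <- M$xo[ord_i[k], li]; d_nl[k + 1L] <- M$nl[ord_i[k], li]
    d_dd[k + 1L] <- M$dd[ord_i[k], li]
    if (k > 1) for (p in 2:k) {
      a <- ord_i[p - 1L]; b <- ord_i[p]
      d_xo[p] <- M$xo[a, li] + M$xo[li, b] - M$xo[a, b]
      d_nl[p] <- M$nl[a, li] + M$nl[li, b] - M$nl[a, b]
      d_dd[p] <- M$dd[a, li] + M$dd[li, b] - M$dd[a, b]
    }
    best_p <- 1L
    for (p in seq_len(k + 1L)[-1]) {
      if (lex_less(c(d_xo[p], d_nl[p], d_dd[p]),
                   c(d_xo[best_p], d_nl[best_p], d_dd[best_p]))) best_p <- p
    }
    append(ord_i, li, after = best_p - 1L)
  }

  remaining <- setdiff(seed_loci, start)
  while (length(remaining)) {
    # most strongly linked to the placed set first; ties by id
    link <- vapply(remaining, function(l) max(cache$lod[l, all_ids[ord_i]]), 0)
    nxt <- remaining[order(-link, remaining)][1]
    ord_i <- insert_best(ord_i, match(nxt, all_ids))
    remaining <- setdiff(remaining, nxt)
  }
  rest <- setdiff(group, all_ids[ord_i])
  while (length(rest)) {
    link <- vapply(rest, function(l) max(cache$lod[l, all_ids[ord_i]]), 0)
    nxt <- rest[order(-link, rest)][1]
    ord_i <- insert_best(ord_i, match(nxt, all_ids))
    rest <- setdiff(rest, nxt)
  }

  # polish: alternate window ripples with single-locus relocation until
  # neither moves anything (relocation fixes displacements beyond the
  # ripple window's reach)
  ord <- all_ids[ord_i]
  for (round in seq_len(5L)) {
    ord <- ripple_order(ord, cache, ripple_window, mapping_function, max_passes)
    rel <- relocate_pass(ord, cache, mapping_function)
    ord <- rel$ord
    if (!rel$moved) break
  }
  if (ord[length(ord)] < ord[1]) ord <- rev(ord)
  ord
}

# one sweep of single-locus relocation: each locus in turn is removed and
# re-inserted at its objective-optimal position; strict improvements only
relocate_pass <- function(ord, cache, mapping_function = "kosambi") {
  all_ids <- rownames(cache$rf)
  M <- obj_mats(cache, mapping_function)
  ord_i <- match(ord, all_ids)
  n <- length(ord_i)
  if (n < 3) return(list(ord = ord, moved = FALSE))
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (p in seq_len(n)) {
      li <- ord_i[p]
      rest <- ord_i[-p]
      # removal delta
      rem <- c(0, 0, 0)
      if (p > 1) rem <- rem + c(M$xo[ord_i[p - 1L], li], M$nl[ord_i[p - 1L], li],
                                M$dd[ord_i[p - 1L], li])
      if (p < n) rem <- rem + c(M$xo[li, ord_i[p + 1L]], M$nl[li, ord_i[p + 1L]],
                                M$dd[li, ord_i[p + 1L]])
      if (p > 1 && p < n)
        rem <- rem - c(M$xo[ord_i[p - 1L], ord_i[p + 1L]],
                       M$nl[ord_i[p - 1L], ord_i[p + 1L]],
                       M$dd[ord_i[p - 1L], ord_i[p + 1L]])
      # insertion deltas along the reduced order
      k <- n - 1L
      best_obj <- NULL; best_pos <- NULL
      for (q in 0:k) {
        ins <- c(0, 0, 0)
        if (q > 0) ins <- ins + c(M$xo[rest[q], li], M$nl[rest[q], li],
                                  M$dd[rest[q], li])
        if (q < k) ins <- ins + c(M$xo[li, rest[q + 1L]], M$nl[li, rest[q + 1L]],
                                  M$dd[li, rest[q + 1L]])
        if (q > 0 && q < k)
          ins <- ins - c(M$xo[rest[q], rest[q + 1L]], M$nl[rest[q], rest[q + 1L]],
                         M$dd[rest[q], rest[q + 1L]])
        if (is.null(best_obj) || lex_less(ins, best_obj)) {
          best_obj <- ins; best_pos <- q
        }
      }
      if (lex_less(best_obj, rem)) {
        ord_i <- append(rest, li, after = best_pos)
        moved <- TRUE; moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(ord = all_ids[ord_i], moved = moved_any)
}

#' Ripple polishing of a locus order
#'
#' @param ord current order (locus ids).
#' @inheritParams order_group
#' @return improved order.
#' @export
ripple_order <- function(ord, cache, ripple_window = 4L,
                         mapping_function = "kosambi", max_passes = 25L) {
  n <- length(ord)
  w <- min(ripple_window, n)
  if (w < 2) return(ord)
  M <- obj_mats(cache, mapping_function)
  all_ids <- rownames(cache$rf)
  ord_i <- match(ord, all_ids)
  pset <- perms(seq_len(w))[-1]
  # objective of the segment touched by a window permutation: edges from
  # s-1 to s+w (clipped); outside edges are unaffected
  seg_obj <- function(ord_i, s) {
    lo <- max(1L, s - 1L); hi <- min(n, s + w)
    obj_of(ord_i[lo:hi], M)
  }
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (s in seq_len(n - w + 1L)) {
      cur <- seg_obj(ord_i, s)
      for (p in pset) {
        cand <- ord_i
        cand[s:(s + w - 1L)] <- ord_i[s:(s + w - 1L)][p]
        obj <- seg_obj(cand, s)
        if (lex_less(obj, cur)) {
          ord_i <- cand; cur <- obj
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  all_ids[ord_i]
}

#' Compute cM positions along an ordered linkage group
#'
#' Positions accumulate the mapping-function distances of the adjacent
#' recombination fractions, starting at 0.
#'
#' @param ord ordered locus ids.
#' @param cache a [tp_cache()] (adjacent rf are read from it), or a
#'   numeric vector of adjacent rf of length `length(ord) - 1`.
#' @param mapping_function `"kosambi"` or `"haldane"`.
#' @return numeric vector of positions (first = 0). An adjacent rf of 0.5
#'   means infinite distance and signals an ordering failure (error).
#' @export
compute_positions <- function(ord, cache, mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  if (length(ord) == 1) return(0)
  rfs <- if (is.numeric(cache)) cache else {
    idx <- cbind(match(ord[-length(ord)], rownames(cache$rf)),
                 match(ord[-1L], rownames(cache$rf)))
    cache$rf[idx]
  }
  if (any(rfs >= 0.5))
    stop("adjacent recombination fraction of 0.5: ordering failure between ",
         paste(ord[which(rfs >= 0.5)[1] + 0:1], collapse = " and "))
  cumsum(c(0, map_distance(rfs, mapping_function)))
}

#' Multipoint-style positions by windowed weighted least squares
#'
#' Regression mapping: every estimable pair within `window` order
#' positions contributes the observation `x_j - x_i = d(rf_ij)`, weighted
#' by its LOD, and the inter-locus gaps are the non-negative weighted
#' least-squares solution. Using distances that span several intervals
#' makes the total length robust to noise in individual adjacent
#' estimates, which accumulate when intervals are summed one by one.
#'
#' @param ord ordered locus ids.
#' @param cache a [tp_cache()] over the loci.
#' @param mapping_function `"kosambi"` or `"haldane"`.
#' @param window maximum order distance of contributing pairs (default 6).
#' @param rf_max pairs at or above this rf carry no distance information
#'   and are excluded (default 0.49).
#' @return numeric positions (first = 0, non-decreasing).
#' @export
wls_positions <- function(ord, cache, mapping_function = "kosambi",
                          window = 6L, rf_max = 0.49) {
  n <- length(ord)
  if (n == 1) return(0)
  M <- obj_mats(cache, mapping_function)
  Dm <- M$dd[ord, ord, drop = FALSE]
  W <- cache$lod[ord, ord, drop = FALSE]
  NN <- cache$n[ord, ord, drop = FALSE]
  RF <- cache$rf[ord, ord, drop = FALSE]
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):min(n, i + window)) {
      if (NN[i, j] > 0 && RF[i, j] < rf_max) { ii <- c(ii, i); jj <- c(jj, j) }
    }
  }
  adj <- vapply(seq_len(n - 1L), function(k)
    if (NN[k, k + 1L] > 0 && RF[k, k + 1L] < rf_max) Dm[k, k + 1L] else NA_real_,
    0)
  if (length(ii) == 0) {
    g <- ifelse(is.na(adj), 0, adj)
    return(cumsum(c(0, g)))
  }
  A <- matrix(0, length(ii), n - 1L)
  for (r in seq_along(ii)) A[r, ii[r]:(jj[r] - 1L)] <- 1
  w <- pmax(W[cbind(ii, jj)], 0.1)
  g <- tryCatch({
    fit <- stats::lm.wfit(A, Dm[cbind(ii, jj)], w)
    fit$coefficients
  }, error = function(e) adj)
  # gaps without support fall back to the adjacent estimate; negative
  # gaps are clipped (the order already fixed which side they sit on)
  g[is.na(g)] <- adj[is.na(g)]
  g[is.na(g)] <- 0
  cumsum(c(0, pmax(g, 0)))
}

# Impute, per modeled parent, the founder-strand indicator (1/2/NA) of
# every offspring at every locus of an ordered group, chaining the
# pairwise phases of adjacent informative loci.
impute_strands <- function(geno, ord, scope, cache_phase = NULL) {
  info <- locus_info(geno)
  names(info) <- geno$loci$locus_id
  parents <- if (scope == "both") c("mother", "father") else
    if (scope == "female") "mother" else "father"
  out <- list()
  for (p in parents) {
    het <- vapply(ord, function(l) {
      al <- if (p == "mother") info[[l]]$mother_alleles else info[[l]]$father_alleles
      !is.na(al[1]) && al[1] != al[2]
    }, TRUE)
    loci_p <- ord[het]
    if (length(loci_p) == 0) next
    strand <- matrix(NA_integer_, length(loci_p), ncol(geno$calls),
                     dimnames = list(loci_p, colnames(geno$calls)))
    for (l in loci_p) {
      tr <- info[[l]]$trans
      key <- if (p == "mother") "mi" else "fi"
      # transmission is imputable only when unambiguous for this class
      trans_of <- vapply(info[[l]]$classes, function(cl) {
        v <- unique(tr[[cl]][, key])
        if (length(v) == 1) v else NA_integer_
      }, integer(1))
      i <- match(l, geno$loci$locus_id)
      cls <- match(geno$calls[i, ], info[[l]]$classes)
      strand[l, ] <- trans_of[cls]
    }
    # chain phases: flip locus k's strand when the best phase of the pair
    # (k-1, k) is repulsion
    if (length(loci_p) > 1 && !is.null(cache_phase)) {
      flip <- FALSE
      for (k in 2:length(loci_p)) {
        ph <- cache_phase(loci_p[k - 1L], loci_p[k], p)
        if (identical(ph, "repulsion")) flip <- !flip
        if (flip) strand[loci_p[k], ] <- 3L - strand[loci_p[k], ]
      }
    }
    out[[p]] <- strand
  }
  out
}

#' Post-ordering quality control of a linkage group
#'
#' Flags and removes offspring whose total crossover count exceeds
#' `mean + xo_z * SD`; masks genotype calls that create a tight double
#' crossover (a single locus disagreeing with identical flanking strands
#' within `tight_cM`); removes terminal loci separated from the group by
#' more than `gap_cM`, and interior loci sitting more than `gap_cM` from
#' both neighbours while the neighbours themselves are close. The caller
#' should re-estimate and re-order after cleaning.
#'
#' @param geno an [fs_geno()].
#' @param ord ordered locus ids of the group.
#' @param tp two-point results data.frame (for phases).
#' @param cache [tp_cache()] over the group.
#' @param scope as in [estimate_two_point()].
#' @param gap_cM gap threshold in cM (default 20).
#' @param xo_z SD multiplier for excess crossovers (default 3).
#' @param tight_cM window (cM) within which a lone double crossover is
#'   treated as a genotyping error (default 5).
#' @param mapping_function mapping function for provisional positions.
#' @return list with `geno` (calls possibly masked, individuals removed),
#'   `ord` (loci possibly removed), `removed_loci`,
#'   `removed_individuals`, `masked` (count of masked calls) and
#'   `diagnostics` (per-individual crossover counts).
#' @export
clean_order <- function(geno, ord, tp, cache, scope = "both", gap_cM = 20,
                        xo_z = 3, tight_cM = 5,
                        mapping_function = "kosambi") {
  phase_of <- function(a, b, parent) {
    hit <- tp[(tp$a == a & tp$b == b) | (tp$a == b & tp$b == a), , drop = FALSE]
    if (nrow(hit) == 0) return(NA_character_)
    if (parent == "mother") hit$phase_m[1] else hit$phase_f[1]
  }
  strands <- impute_strands(geno, ord, scope, phase_of)
  pos <- compute_positions(ord, cache, mapping_function)
  names(pos) <- ord

  # per-individual crossover counts over all modeled parents
  xo_counts <- stats::setNames(numeric(ncol(geno$calls)), colnames(geno$calls))
  masked <- 0L
  calls <- geno$calls
  for (p in names(strands)) {
    st <- strands[[p]]
    lp <- rownames(st)
    for (o in seq_len(ncol(st))) {
      v <- st[, o]
      nz <- which(!is.na(v))
      if (length(nz) < 2) next
      ch <- which(v[nz[-1]] != v[nz[-length(nz)]])
      xo_counts[o] <- xo_counts[o] + length(ch)
      # tight double crossovers: isolated disagreements
      if (length(nz) >= 3) {
        for (k in 2:(length(nz) - 1L)) {
          a <- nz[k - 1L]; m <- nz[k]; b <- nz[k + 1L]
          if (v[a] == v[b] && v[m] != v[a] &&
              (pos[lp[b]] - pos[lp[a]]) <= tight_cM) {
            calls[lp[m], colnames(st)[o]] <- NA_character_
            masked <- masked + 1L
          }
        }
      }
    }
  }

  mu <- mean(xo_counts); sdev <- stats::sd(xo_counts)
  bad_ind <- names(xo_counts)[xo_counts > mu + xo_z * max(sdev, 1e-9)]

  # gap rule on provisional positions
  removed <- character(0)
  ord2 <- ord
  repeat {
    if (length(ord2) < 3) break
    p2 <- pos[ord2]
    gaps <- diff(p2)
    drop_l <- NULL
    if (gaps[1] > gap_cM) drop_l <- ord2[1]
    else if (gaps[length(gaps)] > gap_cM) drop_l <- ord2[length(ord2)]
    else {
      for (k in 2:(length(ord2) - 1L)) {
        if (gaps[k - 1L] > gap_cM && gaps[k] > gap_cM) {
          d_direct <- map_distance(min(cache$rf[ord2[k - 1L], ord2[k + 1L]], 0.4999),
                                   mapping_function)
          if (d_direct <= gap_cM) { drop_l <- ord2[k]; break }
        }
      }
    }
    if (is.null(drop_l)) break
    removed <- c(removed, drop_l)
    ord2 <- setdiff(ord2, drop_l)
  }

  keep_ind <- setdiff(colnames(calls), bad_ind)
  geno2 <- fs_geno(geno$loci, calls, geno$family_id)
  geno2 <- subset_geno(geno2, offspring = keep_ind)
  list(geno = geno2, ord = ord2, removed_loci = removed,
       removed_individuals = bad_ind, masked = masked,
       diagnostics = data.frame(individual = names(xo_counts),
                                crossovers = as.numeric(xo_counts)))
}
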
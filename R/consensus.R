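# Consensus merging of two family maps: conflict detection on shared
# loci, iterative removal from the map with the larger zero-recombination
# cluster, and a per-LG linear program that minimizes the mean absolute
# error between the consensus positions and the component maps subject to
# both maps' order constraints.

#' Match linkage groups between two maps by shared loci
#'
#' Each LG of map A is paired with the LG of map B holding the largest
#' number of its loci (and vice versa; only mutual best pairs are kept).
#' A tie for the best partner is an error, not a guess.
#'
#' @param map_a,map_b `genetic_map` objects.
#' @return data.frame with `lg_a`, `lg_b`, `n_shared`.
#' @export
match_linkage_groups <- function(map_a, map_b) {
  shared <- intersect(map_a$locus_id, map_b$locus_id)
  if (length(shared) == 0) stop("maps share no loci")
  la <- map_a$lg[match(shared, map_a$locus_id)]
  lb <- map_b$lg[match(shared, map_b$locus_id)]
  tab <- unclass(table(la, lb))
  pairs <- list()
  for (g in rownames(tab)) {
    counts <- tab[g, , drop = TRUE]
    top <- max(counts)
    if (top == 0) next
    best <- colnames(tab)[counts == top]
    if (length(best) > 1)
      stop("ambiguous linkage-group correspondence: ", g, " of map A ties between ",
           paste(best, collapse = ", "), " of map B")
    # mutual best check
    colc <- tab[, best, drop = TRUE]
    if (sum(colc == max(colc)) > 1)
      stop("ambiguous linkage-group correspondence: ", best,
           " of map B ties between ",
           paste(rownames(tab)[colc == max(colc)], collapse = ", "),
           " of map A")
    if (rownames(tab)[which.max(colc)] == g)
      pairs[[length(pairs) + 1L]] <- data.frame(lg_a = g, lg_b = best,
                                                n_shared = top)
  }
  do.call(rbind, pairs)
}

# zero-recombination cluster sizes: loci at identical positions on one LG
zero_rec_cluster <- function(map, tol = 1e-9) {
  key <- paste(map$lg, round(map$position_cM / tol) * tol)
  sz <- table(key)
  as.integer(sz[key])
}

#' Detect ordering conflicts between two family maps
#'
#' For every pair of shared loci on corresponding LGs, an opposite strict
#' order in the two maps is a conflict. Each conflicting locus is
#' annotated with the size of its zero-recombination (co-positioned)
#' cluster in each map.
#'
#' @param map_a,map_b `genetic_map` objects.
#' @return data.frame with one row per conflicted locus: `locus_id`,
#'   `lg_a`, `lg_b`, `n_conflicts`, `cluster_a`, `cluster_b`; attribute
#'   `pairs` holds the conflicting pairs.
#' @export
detect_conflicts <- function(map_a, map_b) {
  lgm <- match_linkage_groups(map_a, map_b)
  ca <- zero_rec_cluster(map_a); cb <- zero_rec_cluster(map_b)
  rows <- list(); prs <- list()
  for (r in seq_len(nrow(lgm))) {
    sa <- map_a[map_a$lg == lgm$lg_a[r], , drop = FALSE]
    sb <- map_b[map_b$lg == lgm$lg_b[r], , drop = FALSE]
    shared <- intersect(sa$locus_id, sb$locus_id)
    if (length(shared) < 2) next
    pa <- sa$position_cM[match(shared, sa$locus_id)]
    pb <- sb$position_cM[match(shared, sb$locus_id)]
    n <- length(shared)
    conflict_count <- stats::setNames(integer(n), shared)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      da <- pa[i] - pa[j]; db <- pb[i] - pb[j]
      if (da * db < 0) {  # strictly opposite order
        conflict_count[i] <- conflict_count[i] + 1L
        conflict_count[j] <- conflict_count[j] + 1L
        prs[[length(prs) + 1L]] <- data.frame(locus_1 = shared[i],
                                              locus_2 = shared[j],
                                              lg_a = lgm$lg_a[r])
      }
    }
    bad <- names(conflict_count)[conflict_count > 0]
    if (length(bad))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = bad, lg_a = lgm$lg_a[r], lg_b = lgm$lg_b[r],
        n_conflicts = as.integer(conflict_count[bad]),
        cluster_a = ca[match(bad, map_a$locus_id)],
        cluster_b = cb[match(bad, map_b$locus_id)])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), lg_a = character(0),
               lg_b = character(0), n_conflicts = integer(0),
               cluster_a = integer(0), cluster_b = integer(0))
  rownames(out) <- NULL
  attr(out, "pairs") <- if (length(prs)) do.call(rbind, prs) else NULL
  out
}

#' Resolve ordering conflicts between two family maps
#'
#' Runs up to `max_rounds` rounds. In each round conflicted loci are
#' visited in order of decreasing conflict count (ties by id); a locus
#' still in conflict is removed from the map in which it sits in a
#' zero-recombination cluster — from that map if clustered in only one,
#' from the map with the larger cluster if clustered in both, and from
#' map B on a tie (logged). Conflicts are re-detected after each round;
#' conflicts persisting after the last round are reported in the result,
#' never silently dropped.
#'
#' @param map_a,map_b `genetic_map` objects.
#' @param max_rounds maximum rounds (default 3).
#' @return list with `map_a`, `map_b` (loci removed), `log` (data.frame
#'   `round`, `locus_id`, `cluster_a`, `cluster_b`, `removed_from`,
#'   `cluster_rep`: a retained co-cluster member in the map the locus was
#'   removed from, used later to restore it), and `unresolved`
#'   (conflicts remaining after the final round).
#' @export
resolve_conflicts <- function(map_a, map_b, max_rounds = 3L) {
  log <- list()
  for (round in seq_len(max_rounds)) {
    conf <- detect_conflicts(map_a, map_b)
    if (nrow(conf) == 0) break
    conf <- conf[order(-conf$n_conflicts, conf$locus_id), , drop = FALSE]
    pair_df <- attr(conf, "pairs")
    removed_this_round <- character(0)
    for (k in seq_len(nrow(conf))) {
      l <- conf$locus_id[k]
      # still conflicted given removals made earlier this round?
      live <- pair_df[!(pair_df$locus_1 %in% removed_this_round) &
                        !(pair_df$locus_2 %in% removed_this_round), , drop = FALSE]
      if (!(l %in% c(live$locus_1, live$locus_2))) next
      ca <- conf$cluster_a[k]; cb <- conf$cluster_b[k]
      from <- if (ca > 1 && cb <= 1) "A"
      else if (cb > 1 && ca <= 1) "B"
      else if (ca > cb) "A"
      else "B"   # larger cluster in B, or tie -> B
      src <- if (from == "A") map_a else map_b
      pos_l <- src$position_cM[src$locus_id == l]
      lg_l <- src$lg[src$locus_id == l]
      mates <- src$locus_id[src$lg == lg_l &
                              abs(src$position_cM - pos_l) < 1e-9 &
                              src$locus_id != l]
      if (from == "A") map_a <- map_a[map_a$locus_id != l, , drop = FALSE]
      else map_b <- map_b[map_b$locus_id != l, , drop = FALSE]
      removed_this_round <- c(removed_this_round, l)
      log[[length(log) + 1L]] <- data.frame(
        round = round, locus_id = l, cluster_a = ca, cluster_b = cb,
        removed_from = from,
        cluster_rep = if (length(mates)) min(mates) else NA_character_)
    }
    if (length(removed_this_round) == 0) break
  }
  unresolved <- detect_conflicts(map_a, map_b)
  if (nrow(unresolved) > 0)
    warning(nrow(unresolved), " conflicts remain after ", max_rounds, " rounds")
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(round = integer(0), locus_id = character(0),
               cluster_a = integer(0), cluster_b = integer(0),
               removed_from = character(0), cluster_rep = character(0))
  list(map_a = map_a, map_b = map_b, log = log_df, unresolved = unresolved)
}

# L1 merge of one LG: LP over group positions + per-incidence error vars.
# Equal positions within one map define position groups (merged across
# maps by union-find) unless the other map strictly orders the pair.
merge_lg <- function(pos_list, epsilon = 0.01) {
  # pos_list: named list per map of named numeric vectors (positions)
  loci <- sort(unique(unlist(lapply(pos_list, names))))
  n <- length(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  strictly_ordered <- function(l1, l2) {
    for (pv in pos_list) {
      if (l1 %in% names(pv) && l2 %in% names(pv) &&
          abs(pv[l1] - pv[l2]) > 1e-9) return(TRUE)
    }
    FALSE
  }
  # equality: co-positioned in some map and not strictly ordered in any
  for (pv in pos_list) {
    ids <- names(pv)
    for (grp in split(ids, round(pv / 1e-9))) {
      if (length(grp) < 2) next
      for (k in 2:length(grp)) {
        if (!strictly_ordered(grp[1], grp[k]))
          union_(match(grp[1], loci), match(grp[k], loci))
      }
    }
  }
  grp_of <- vapply(seq_len(n), find, 0L)
  grp_ids <- sort(unique(grp_of))
  g <- match(grp_of, grp_ids)          # group index per locus
  ng <- length(grp_ids)

  # order constraints between groups from each map's consecutive
  # distinct-position pairs; detect direct contradictions
  ords <- list()
  for (mi in seq_along(pos_list)) {
    pv <- sort(pos_list[[mi]])
    ids <- names(pv)
    for (k in seq_len(length(ids) - 1L)) {
      # next locus at a strictly larger position
      later <- which(pv > pv[k] + 1e-9)
      if (!length(later)) break
      j <- later[1]
      g1 <- g[match(ids[k], loci)]; g2 <- g[match(ids[j], loci)]
      if (g1 == g2)
        stop("infeasible constraints: ", ids[k], " and ", ids[j],
             " are order-constrained inside one co-position group")
      ords[[length(ords) + 1L]] <- c(g1, g2)
    }
  }
  ords <- unique(do.call(rbind, c(ords, list(matrix(0L, 0, 2)))))
  if (nrow(ords)) {
    rev_hit <- paste(ords[, 2], ords[, 1]) %in% paste(ords[, 1], ords[, 2])
    both <- ords[rev_hit & ords[, 1] < ords[, 2], , drop = FALSE]
    if (nrow(both))
      stop("infeasible constraints: opposite orders between groups holding ",
           paste(apply(both, 1, function(r)
             paste(loci[g == r[1]][1], "vs", loci[g == r[2]][1])),
             collapse = "; "))
  }

  # incidences
  inc <- do.call(rbind, lapply(seq_along(pos_list), function(mi) {
    pv <- pos_list[[mi]]
    data.frame(map = mi, g = g[match(names(pv), loci)], y = unname(pv))
  }))
  m <- nrow(inc)
  nv <- ng + m
  a_obj <- c(rep(0, ng), rep(1 / m, m))
  # A1 x <= b1: x_g - e_k <= y_k
  A1 <- matrix(0, m, nv); b1 <- numeric(m)
  for (k in seq_len(m)) {
    A1[k, inc$g[k]] <- 1; A1[k, ng + k] <- -1; b1[k] <- inc$y[k]
  }
  # A2 x >= b2: x_g + e_k >= y_k, and order x_h - x_g >= eps
  no <- nrow(ords)
  A2 <- matrix(0, m + no, nv); b2 <- numeric(m + no)
  for (k in seq_len(m)) {
    A2[k, inc$g[k]] <- 1; A2[k, ng + k] <- 1; b2[k] <- inc$y[k]
  }
  if (no) for (k in seq_len(no)) {
    A2[m + k, ords[k, 2]] <- 1; A2[m + k, ords[k, 1]] <- -1
    b2[m + k] <- epsilon
  }
  sol <- boot::simplex(a = a_obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = FALSE)
  if (sol$solved != 1) stop("LP merge did not solve (status ", sol$solved, ")")
  x <- sol$soln[seq_len(ng)]
  pos <- x[g]
  names(pos) <- loci
  err <- abs(x[inc$g] - inc$y)
  list(positions = sort(pos), mae = mean(err),
       mae_per_map = tapply(err, inc$map, mean))
}

#' Merge two conflict-resolved family maps into a consensus map
#'
#' Per corresponding linkage group, consensus positions for the union of
#' loci are found by linear programming: the mean absolute difference
#' between consensus and component-map positions is minimized (standard
#' absolute-value linearization) subject to every component map's order —
#' a gap of at least `epsilon` cM for strictly ordered pairs and equality
#' for co-positioned ones (unless the other map strictly orders the
#' pair). The LP is solved with [boot::simplex()].
#'
#' @param map_a,map_b `genetic_map` objects (post conflict resolution).
#' @param epsilon minimum gap for strict order constraints, in cM
#'   (default 0.01).
#' @return a `genetic_map` of provenance `consensus`, with attributes
#'   `mae` (overall achieved mean absolute error), `mae_per_lg` and
#'   `mae_per_map`.
#' @export
merge_maps <- function(map_a, map_b, epsilon = 0.01) {
  lgm <- match_linkage_groups(map_a, map_b)
  out <- list(); maes <- numeric(0); per_map <- c(A = 0, B = 0); wts <- c(0, 0)
  for (r in seq_len(nrow(lgm))) {
    sa <- map_a[map_a$lg == lgm$lg_a[r], , drop = FALSE]
    sb <- map_b[map_b$lg == lgm$lg_b[r], , drop = FALSE]
    pos_list <- list(A = stats::setNames(sa$position_cM, sa$locus_id),
                     B = stats::setNames(sb$position_cM, sb$locus_id))
    mrg <- merge_lg(pos_list, epsilon = epsilon)
    out[[r]] <- data.frame(locus_id = names(mrg$positions),
                           lg = lgm$lg_a[r],
                           position_cM = unname(mrg$positions),
                           is_passenger = FALSE)
    maes <- c(maes, stats::setNames(mrg$mae, lgm$lg_a[r]))
    for (mi in 1:2) {
      nm <- c("A", "B")[mi]
      if (!is.na(mrg$mae_per_map[as.character(mi)])) {
        nk <- c(nrow(sa), nrow(sb))[mi]
        per_map[nm] <- per_map[nm] + mrg$mae_per_map[as.character(mi)] * nk
        wts[mi] <- wts[mi] + nk
      }
    }
  }
  df <- do.call(rbind, out)
  cons <- as_genetic_map(df, provenance = list(family = "consensus",
                                               scope = "both"),
                         mapping_function = attr(map_a, "mapping_function"))
  attr(cons, "mae") <- stats::weighted.mean(maes, vapply(out, nrow, 0L))
  attr(cons, "mae_per_lg") <- maes
  attr(cons, "mae_per_map") <- per_map / pmax(wts, 1)
  cons
}

#' Full consensus pipeline: detect, resolve, merge, restore
#'
#' Convenience wrapper running [resolve_conflicts()] then [merge_maps()],
#' and finally restoring every conflict-removed locus into the consensus
#' at the consensus position of its zero-recombination cluster
#' representative (the co-positioned locus retained in the map it was
#' removed from), so that removal for conflict never removes a locus from
#' the final consensus map.
#'
#' @inheritParams resolve_conflicts
#' @inheritParams merge_maps
#' @return list with `consensus` (a `genetic_map`), `map_a`, `map_b`
#'   (resolved maps), `log` (removal log with a `restored_at` column) and
#'   `unresolved`.
#' @export
consensus_map <- function(map_a, map_b, max_rounds = 3L, epsilon = 0.01) {
  res <- resolve_conflicts(map_a, map_b, max_rounds = max_rounds)
  cons <- merge_maps(res$map_a, res$map_b, epsilon = epsilon)
  log <- res$log
  log$restored_at <- NA_real_
  if (nrow(log)) {
    add <- list()
    for (k in seq_len(nrow(log))) {
      l <- log$locus_id[k]
      if (l %in% cons$locus_id) next  # still present via the other map
      anchor <- log$cluster_rep[k]
      if (is.na(anchor) || !(anchor %in% cons$locus_id)) {
        # cluster fully removed: fall back to the other map's position
        other <- if (log$removed_from[k] == "A") map_b else map_a
        if (l %in% other$locus_id) {
          anchor_pos <- other$position_cM[other$locus_id == l]
          anchor_lg <- other$lg[other$locus_id == l]
        } else next
      } else {
        anchor_pos <- cons$position_cM[cons$locus_id == anchor]
        anchor_lg <- cons$lg[cons$locus_id == anchor]
      }
      log$restored_at[k] <- anchor_pos
      add[[length(add) + 1L]] <- data.frame(
        locus_id = l, lg = anchor_lg, position_cM = anchor_pos,
        is_passenger = TRUE)
    }
    if (length(add)) {
      df <- rbind(as.data.frame(cons), do.call(rbind, add))
      at <- attributes(cons)
      cons <- as_genetic_map(df, provenance = at$provenance,
                             mapping_function = at$mapping_function)
      attr(cons, "mae") <- at$mae
      attr(cons, "mae_per_lg") <- at$mae_per_lg
      attr(cons, "mae_per_map") <- at$mae_per_map
    }
  }
  list(consensus = cons, map_a = res$map_a, map_b = res$map_b,
       log = log, unresolved = res$unresolved)
}
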
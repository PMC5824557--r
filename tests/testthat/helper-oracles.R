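# Independent oracles and fixture builders used across the test files.
# The likelihood oracle enumerates gametes at the allele level, written
# separately from the package's EM machinery on purpose.

# Build an fs_geno for given segregation types directly from parental
# transmission matrices (1/2 = transmitted allele index; phase is
# "allele 1 on haplotype 1" throughout, i.e. coupling).
geno_from_transmissions <- function(types, tm, tf, family_id = "FamT") {
  parents <- list(
    ABxCD = list(m = c("a", "b"), f = c("c", "d")),
    EFxEG = list(m = c("e", "f"), f = c("e", "g")),
    HKxHK = list(m = c("h", "k"), f = c("h", "k")),
    LMxLL = list(m = c("l", "m"), f = c("l", "l")),
    NNxNP = list(m = c("n", "n"), f = c("n", "p")))
  n_loci <- length(types); n_off <- ncol(tm)
  ids <- sprintf("T%03d", seq_len(n_loci))
  calls <- matrix(NA_character_, n_loci, n_off,
                  dimnames = list(ids, sprintf("O%03d", seq_len(n_off))))
  mo <- fa <- character(n_loci)
  for (i in seq_len(n_loci)) {
    p <- parents[[types[i]]]
    calls[i, ] <- geno_str(p$m[tm[i, ]], p$f[tf[i, ]])
    mo[i] <- geno_str(p$m[1], p$m[2])
    fa[i] <- geno_str(p$f[1], p$f[2])
  }
  fs_geno(data.frame(locus_id = ids, contig_id = ids, seg_type = types,
                     mother = mo, father = fa),
          calls, family_id)
}

# Allele-level two-point log-likelihood on an rf grid, maximized over all
# phase configurations: the brute-force oracle for the EM estimates.
oracle_two_point_grid <- function(geno, a, b, scope = "both", step = 1e-4) {
  ia <- match(a, geno$loci$locus_id); ib <- match(b, geno$loci$locus_id)
  pg <- function(s) strsplit(s, "/", fixed = TRUE)[[1]]
  ma <- pg(geno$loci$mother[ia]); mb <- pg(geno$loci$mother[ib])
  fa <- pg(geno$loci$father[ia]); fb <- pg(geno$loci$father[ib])
  mod_m <- ma[1] != ma[2] && mb[1] != mb[2] && scope %in% c("both", "female")
  mod_f <- fa[1] != fa[2] && fb[1] != fb[2] && scope %in% c("both", "male")
  ca <- geno$calls[ia, ]; cb <- geno$calls[ib, ]
  ok <- !is.na(ca) & !is.na(cb)
  ca <- ca[ok]; cb <- cb[ok]
  key <- paste(ca, cb)
  counts <- table(key)
  r <- seq(0, 0.5, by = step)
  gam <- function(alleles_1, alleles_2, phase, modeled) {
    # list of gametes: (allele at locus1, allele at locus2, prob(r))
    h <- if (phase == 0) list(c(1, 1), c(2, 2), c(1, 2), c(2, 1))
    else list(c(1, 2), c(2, 1), c(1, 1), c(2, 2))
    lapply(seq_along(h), function(k) {
      pr <- if (!modeled) rep(0.25, length(r))
      else if (k <= 2) (1 - r) / 2 else r / 2
      list(a1 = alleles_1[h[[k]][1]], a2 = alleles_2[h[[k]][2]], pr = pr)
    })
  }
  gs <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "/")
  best <- list(ll = -Inf, rf = NA)
  for (pm in (if (mod_m) 0:1 else 0)) for (pf in (if (mod_f) 0:1 else 0)) {
    gm <- gam(ma, mb, pm, mod_m); gf <- gam(fa, fb, pf, mod_f)
    ll <- rep(0, length(r))
    for (k in seq_along(counts)) {
      obs <- strsplit(names(counts)[k], " ", fixed = TRUE)[[1]]
      P <- rep(0, length(r))
      for (g1 in gm) for (g2 in gf) {
        if (gs(g1$a1, g2$a1) == obs[1] && gs(g1$a2, g2$a2) == obs[2])
          P <- P + g1$pr * g2$pr
      }
      ll <- ll + as.numeric(counts[k]) * log(P)
    }
    i <- which.max(ll)
    if (ll[i] > best$ll) best <- list(ll = ll[i], rf = r[i])
  }
  best
}

# Brute-force consensus merge on a small grid: minimal MAE over feasible
# position assignments. For L1 objectives the optimum sits at (or within
# epsilon-multiples of) the observed positions, so the grid is those
# values plus small epsilon offsets.
oracle_merge_grid <- function(pos_list, epsilon = 0.01) {
  loci <- sort(unique(unlist(lapply(pos_list, names))))
  ys <- sort(unique(unlist(pos_list)))
  grid <- sort(unique(c(ys, ys + epsilon, ys - epsilon)))
  combos <- do.call(expand.grid, rep(list(grid), length(loci)))
  names(combos) <- loci
  feasible <- rep(TRUE, nrow(combos))
  for (pv in pos_list) {
    ids <- names(sort(pv))
    pv <- sort(pv)
    for (k in seq_len(length(ids) - 1L)) {
      for (j in (k + 1L):length(ids)) {
        if (pv[j] > pv[k] + 1e-9) {
          feasible <- feasible & (combos[[ids[j]]] >= combos[[ids[k]]] + epsilon - 1e-12)
        } else {
          feasible <- feasible & (abs(combos[[ids[j]]] - combos[[ids[k]]]) < 1e-12)
        }
      }
    }
  }
  combos <- combos[feasible, , drop = FALSE]
  err <- rep(0, nrow(combos)); m <- 0L
  for (pv in pos_list) {
    for (l in names(pv)) {
      err <- err + abs(combos[[l]] - pv[[l]])
      m <- m + 1L
    }
  }
  min(err / m)
}

# quick perfect map from a true_map object
map_from_truth <- function(tm) {
  as_genetic_map(data.frame(locus_id = tm$locus_id,
                            lg = sprintf("LG%02d", tm$lg),
                            position_cM = tm$cM))
}

# Kendall tau between true and estimated positions of mapped loci
order_tau <- function(map, tm) {
  truth <- stats::setNames(tm$cM, tm$locus_id)
  sub <- map[!map$is_passenger, , drop = FALSE]
  abs(stats::cor(truth[sub$locus_id], sub$position_cM, method = "kendall"))
}
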
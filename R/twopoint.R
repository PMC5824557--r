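# Two-point linkage estimation for full-sib (CP) data: simultaneous
# maximum-likelihood estimation of the recombination fraction and the
# parental linkage phases. For each admissible phase configuration the rf
# is maximized by EM over the offspring whose parental transmissions are
# ambiguous (e.g. the h/k class of an HKxHK marker); the phase with the
# highest likelihood is returned. A parent contributes meioses only when
# heterozygous at both loci and included in `scope`; the gametes of all
# other parents enter the likelihood with free recombination (rf = 1/2),
# which is what makes single-parent (sex-specific) estimation exact.

# Build the cell structure for one locus pair: one "cell" per compatible
# joint transmission configuration of an observed genotype-class pair.
pair_model <- function(calls_a, calls_b, info_a, info_b, scope = "both") {
  model_m <- info_a$mother_alleles[1] != info_a$mother_alleles[2] &&
    info_b$mother_alleles[1] != info_b$mother_alleles[2] &&
    scope %in% c("both", "female")
  model_f <- info_a$father_alleles[1] != info_a$father_alleles[2] &&
    info_b$father_alleles[1] != info_b$father_alleles[2] &&
    scope %in% c("both", "male")
  ca <- match(calls_a, info_a$classes)
  cb <- match(calls_b, info_b$classes)
  ok <- !is.na(ca) & !is.na(cb)
  n_shared <- sum(ok)
  if (n_shared == 0 || (!model_m && !model_f))
    return(list(n_shared = n_shared, model_m = model_m, model_f = model_f,
                usable = FALSE))
  pid <- (ca[ok] - 1L) * length(info_b$classes) + cb[ok]
  counts <- table(pid)
  pairs <- as.integer(names(counts))
  n <- as.numeric(counts)

  cell_pair <- integer(0); bm <- integer(0); bf <- integer(0)
  for (k in seq_along(pairs)) {
    ia <- (pairs[k] - 1L) %/% length(info_b$classes) + 1L
    ib <- pairs[k] - (ia - 1L) * length(info_b$classes)
    ta <- info_a$trans[[ia]]; tb <- info_b$trans[[ib]]
    for (ra in seq_len(nrow(ta))) for (rb in seq_len(nrow(tb))) {
      cell_pair <- c(cell_pair, k)
      bm <- c(bm, as.integer(ta[ra, "mi"] != tb[rb, "mi"]))
      bf <- c(bf, as.integer(ta[ra, "fi"] != tb[rb, "fi"]))
    }
  }
  list(n_shared = n_shared, model_m = model_m, model_f = model_f,
       usable = TRUE, n = n, cell_pair = cell_pair, bm = bm, bf = bf,
       n_pairs = length(pairs))
}

# per-cell joint probability at given rf and phases (pm, pf in {0,1};
# 0 = coupling). Unmodeled parents contribute the constant 1/4.
pm_cell_prob <- function(mod, rf, pm, pf) {
  cm <- if (mod$model_m) {
    r <- xor(mod$bm == 1L, pm == 1L)
    0.5 * ifelse(r, rf, 1 - rf)
  } else 0.25
  cf <- if (mod$model_f) {
    r <- xor(mod$bf == 1L, pf == 1L)
    0.5 * ifelse(r, rf, 1 - rf)
  } else 0.25
  cm * cf
}

pm_loglik <- function(mod, rf, pm, pf) {
  p <- pm_cell_prob(mod, rf, pm, pf)
  P <- as.vector(rowsum(p, mod$cell_pair))
  if (any(P <= 0)) return(-Inf)
  sum(mod$n * log(P))
}

# EM for one phase configuration; returns rf-hat and its log-likelihood
pm_em <- function(mod, pm, pf, rf_init = 0.25, tol = 1e-6, max_iter = 100L) {
  n_parents <- mod$model_m + mod$model_f
  N <- sum(mod$n) * n_parents
  rf <- rf_init
  ll_old <- -Inf
  rm_eff <- if (mod$model_m) xor(mod$bm == 1L, pm == 1L) else NULL
  rf_eff <- if (mod$model_f) xor(mod$bf == 1L, pf == 1L) else NULL
  for (it in seq_len(max_iter)) {
    p <- pm_cell_prob(mod, rf, pm, pf)
    P <- as.vector(rowsum(p, mod$cell_pair))
    ll <- if (any(P <= 0)) -Inf else sum(mod$n * log(P))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- mod$n[mod$cell_pair] * p / P[mod$cell_pair]
    ER <- 0
    if (mod$model_m) ER <- ER + sum(w * rm_eff)
    if (mod$model_f) ER <- ER + sum(w * rf_eff)
    rf <- min(max(ER / N, 0), 0.5)
  }
  list(rf = rf, loglik = pm_loglik(mod, rf, pm, pf))
}

#' Two-point recombination fraction, LOD and phase for a locus pair
#'
#' @param geno an [fs_geno()] object.
#' @param a,b locus ids (or row indices) of the pair.
#' @param scope which parent's meioses carry the recombination signal:
#'   `"both"`, `"female"` (mother only) or `"male"`.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return list of class `two_point` with `locus_a`, `locus_b`, `rf`
#'   (in `[0, 0.5]`), `lod` (log10 likelihood ratio vs rf = 0.5, >= 0),
#'   `phase` (named `"coupling"`/`"repulsion"` per modeled parent),
#'   `n_informative` (shared offspring times modeled parents), `n_shared`,
#'   `loglik` and `phase_gap_lod` (LOD gap to the runner-up phase; small
#'   values mean the phase, hence rf, is poorly determined). `NULL` when
#'   the pair is undefined (no shared offspring or no jointly informative
#'   parent).
#' @examples
#' # a fully informative pair with no recombinants: rf = 0, LOD = N*log10(2)
#' @export
estimate_two_point <- function(geno, a, b, scope = c("both", "female", "male"),
                               tol = 1e-6, max_iter = 100L) {
  scope <- match.arg(scope)
  ids <- geno$loci$locus_id
  ia <- if (is.character(a)) match(a, ids) else a
  ib <- if (is.character(b)) match(b, ids) else b
  info_a <- classify_segregation(geno$loci$mother[ia], geno$loci$father[ia])
  info_b <- classify_segregation(geno$loci$mother[ib], geno$loci$father[ib])
  if (!info_a$informative || !info_b$informative)
    stop("both loci must be informative")
  mod <- pair_model(geno$calls[ia, ], geno$calls[ib, ], info_a, info_b, scope)
  tp_from_model(mod, ids[ia], ids[ib], tol, max_iter)
}

tp_from_model <- function(mod, id_a, id_b, tol = 1e-6, max_iter = 100L) {
  if (!isTRUE(mod$usable)) return(NULL)
  # phase grid, coupling-first so ties break toward coupling
  pms <- if (mod$model_m) 0:1 else 0L
  pfs <- if (mod$model_f) 0:1 else 0L
  best <- NULL; lls <- numeric(0)
  for (pm in pms) for (pf in pfs) {
    fit <- pm_em(mod, pm, pf, tol = tol, max_iter = max_iter)
    lls <- c(lls, fit$loglik)
    if (is.null(best) || fit$loglik > best$loglik + 1e-12)
      best <- list(rf = fit$rf, loglik = fit$loglik, pm = pm, pf = pf)
  }
  ll_half <- pm_loglik(mod, 0.5, 0L, 0L)
  lod <- max(0, (best$loglik - ll_half) / log(10))
  gap <- if (length(lls) > 1) {
    srt <- sort(lls, decreasing = TRUE)
    (srt[1] - srt[2]) / log(10)
  } else Inf
  phase <- c(mother = if (mod$model_m) c("coupling", "repulsion")[best$pm + 1L] else NA_character_,
             father = if (mod$model_f) c("coupling", "repulsion")[best$pf + 1L] else NA_character_)
  structure(list(locus_a = id_a, locus_b = id_b, rf = best$rf, lod = lod,
                 phase = phase,
                 n_informative = mod$n_shared * (mod$model_m + mod$model_f),
                 n_shared = mod$n_shared, loglik = best$loglik,
                 phase_gap_lod = gap),
            class = "two_point")
}

#' All pairwise two-point estimates within a family
#'
#' @inheritParams estimate_two_point
#' @param min_shared minimum shared non-missing offspring for a pair to be
#'   estimated (default 1).
#' @param progress print a dot every 500 pairs.
#' @return data.frame with one row per estimable pair: `a`, `b`, `rf`,
#'   `lod`, `phase_m`, `phase_f`, `n_informative`, `n_shared`,
#'   `phase_gap_lod`.
#' @export
two_point_all <- function(geno, scope = c("both", "female", "male"),
                          min_shared = 1L, tol = 1e-6, max_iter = 100L,
                          progress = FALSE) {
  scope <- match.arg(scope)
  ids <- geno$loci$locus_id
  info <- locus_info(geno)
  n <- length(ids)
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0L; done <- 0L
  for (i in seq_len(n - 1L)) {
    if (!info[[i]]$informative) next
    for (j in (i + 1L):n) {
      if (!info[[j]]$informative) next
      done <- done + 1L
      if (progress && done %% 500L == 0L) cat(".")
      mod <- pair_model(geno$calls[i, ], geno$calls[j, ], info[[i]], info[[j]], scope)
      if (!isTRUE(mod$usable) || mod$n_shared < min_shared) next
      tp <- tp_from_model(mod, ids[i], ids[j], tol, max_iter)
      k <- k + 1L
      rows[[k]] <- data.frame(
        a = ids[i], b = ids[j], rf = tp$rf, lod = tp$lod,
        phase_m = tp$phase[["mother"]], phase_f = tp$phase[["father"]],
        n_informative = tp$n_informative, n_shared = tp$n_shared,
        phase_gap_lod = tp$phase_gap_lod)
    }
  }
  if (progress) cat("\n")
  if (k == 0L) return(data.frame(a = character(0), b = character(0),
                                 rf = numeric(0), lod = numeric(0)))
  do.call(rbind, rows[seq_len(k)])
}

#' Map distance from a recombination fraction
#'
#' Kosambi: `25 * log((1 + 2r) / (1 - 2r))`; Haldane:
#' `-50 * log(1 - 2r)`. Both are in centiMorgans and infinite at r = 0.5.
#'
#' @param rf recombination fraction(s) in `[0, 0.5]`.
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @return distance(s) in cM.
#' @export
map_distance <- function(rf, mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  if (mapping_function == "kosambi") 25 * log((1 + 2 * rf) / (1 - 2 * rf))
  else -50 * log(1 - 2 * rf)
}

#' Recombination fraction from a map distance (inverse mapping function)
#'
#' @param d distance(s) in cM.
#' @inheritParams map_distance
#' @return recombination fraction(s).
#' @export
rf_from_distance <- function(d, mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  if (mapping_function == "kosambi") 0.5 * tanh(d / 50)
  else 0.5 * (1 - exp(-d / 50))
}
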
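# Marker QC: segregation-distortion testing, genotype-level filters and
# co-segregation binning, applied per family before map construction.

#' Test one locus for segregation distortion
#'
#' Pearson chi-square goodness-of-fit of the observed offspring
#' genotype-class counts against the Mendelian ratio expected for the
#' locus's segregation type (1:1:1:1, 1:2:1 or 1:1). The p-value is the
#' upper tail of the chi-square distribution with (classes - 1) degrees of
#' freedom; no continuity correction is applied. For `HKxHK` loci the test
#' uses the three genotype classes (1:2:1), not allele counts.
#'
#' @param calls character vector of offspring genotype calls (`"x/y"`,
#'   `NA` = missing) for one locus.
#' @param info classification as returned by [classify_segregation()].
#' @param locus_id optional label carried into the result.
#' @return list with `locus_id`, `observed` (named counts), `expected`,
#'   `chi2`, `df`, `p`, `n` (non-missing offspring).
#' @examples
#' info <- classify_segregation("l/m", "l/l")
#' test_segregation_distortion(c(rep("l/l", 70), rep("l/m", 30)), info)$chi2  # 16
#' @export
test_segregation_distortion <- function(calls, info, locus_id = NA_character_) {
  if (!isTRUE(info$informative))
    stop("locus is not informative; distortion test undefined")
  obs <- table(factor(calls[!is.na(calls)], levels = info$classes))
  n <- sum(obs)
  if (n == 0) stop("all offspring missing; distortion test undefined")
  exp_n <- info$expected * n
  chi2 <- sum((as.numeric(obs) - exp_n)^2 / exp_n)
  df <- length(info$classes) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  list(locus_id = locus_id, observed = obs, expected = exp_n,
       chi2 = chi2, df = df, p = p, n = n)
}

#' Filter a family genotype matrix before mapping
#'
#' Applies, in order: (1) removal of offspring with more than
#' `max_indiv_missing` missing calls; (2) removal of loci with genotype
#' call rate below `min_call_rate`; (3) removal of loci with within-family
#' minor allele frequency below `min_maf` (computed over parental plus
#' offspring alleles); (4) removal of loci with significantly distorted
#' segregation at level `alpha` after Bonferroni correction, where the
#' correction denominator is the number of informative loci tested in this
#' build. Uninformative or unclassifiable loci are removed first with their
#' own reason. Every removal is logged.
#'
#' @param geno an [fs_geno()] object.
#' @param min_call_rate minimum per-locus call rate (default 0.90).
#' @param max_indiv_missing maximum per-offspring missing fraction
#'   (default 0.50).
#' @param min_maf minimum within-family minor allele frequency
#'   (default 0.05).
#' @param alpha distortion significance level before Bonferroni
#'   (default 0.05).
#' @return list with `geno` (filtered [fs_geno()]), `log` (data.frame
#'   `item`, `type`, `reason`, `value`) and `n_tests` (Bonferroni
#'   denominator used).
#' @export
filter_markers <- function(geno, min_call_rate = 0.90, max_indiv_missing = 0.50,
                           min_maf = 0.05, alpha = 0.05) {
  stopifnot(inherits(geno, "fs_geno"))
  log <- list()
  note <- function(item, type, reason, value = NA_real_) {
    log[[length(log) + 1L]] <<- data.frame(item = item, type = type,
                                           reason = reason, value = value)
  }

  # 1. offspring missingness
  miss_frac <- colMeans(is.na(geno$calls))
  drop_ind <- names(miss_frac)[miss_frac > max_indiv_missing]
  for (i in drop_ind) note(i, "individual", "indiv_missing", miss_frac[i])
  calls <- geno$calls[, setdiff(colnames(geno$calls), drop_ind), drop = FALSE]
  if (ncol(calls) == 0) stop("no individuals survive filtering")

  info <- locus_info(geno)
  names(info) <- geno$loci$locus_id
  keep <- rep(TRUE, nrow(geno$loci))
  ids <- geno$loci$locus_id

  # uninformative / unclassifiable loci
  for (i in seq_along(ids)) {
    if (!info[[i]]$informative) {
      keep[i] <- FALSE
      note(ids[i], "locus", info[[i]]$reason)
    }
  }

  # 2. per-locus call rate
  cr <- rowMeans(!is.na(calls))
  for (i in which(keep & cr < min_call_rate)) {
    keep[i] <- FALSE
    note(ids[i], "locus", "call_rate", cr[i])
  }

  # 3. within-family MAF over parental + offspring alleles
  for (i in which(keep)) {
    al <- c(unlist(lapply(calls[i, !is.na(calls[i, ])], parse_geno)),
            info[[i]]$mother_alleles, info[[i]]$father_alleles)
    fr <- table(al) / length(al)
    maf <- min(fr)
    if (maf < min_maf) {
      keep[i] <- FALSE
      note(ids[i], "locus", "maf", maf)
    }
  }

  # 4. segregation distortion, Bonferroni over the loci actually tested
  test_idx <- which(keep)
  n_tests <- length(test_idx)
  thr <- alpha / max(n_tests, 1L)
  for (i in test_idx) {
    non_missing <- calls[i, !is.na(calls[i, ])]
    if (length(non_missing) == 0) {
      keep[i] <- FALSE
      note(ids[i], "locus", "all_missing")
      next
    }
    tst <- test_segregation_distortion(calls[i, ], info[[i]], ids[i])
    if (tst$p < thr) {
      keep[i] <- FALSE
      note(ids[i], "locus", "distortion", tst$p)
    }
  }

  if (!any(keep)) stop("no markers survive filtering")
  out <- fs_geno(geno$loci[keep, , drop = FALSE],
                 calls[keep, , drop = FALSE], geno$family_id)
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(item = character(0), type = character(0),
               reason = character(0), value = numeric(0))
  list(geno = out, log = log_df, n_tests = n_tests)
}

#' Bin co-segregating loci
#'
#' Groups loci whose offspring call vectors are identical (including the
#' positions of missing calls, which is the conservative reading of
#' "identical segregation pattern": loci differing only at missing entries
#' are kept apart because their identity there is untestable). Within each
#' bin the lexicographically smallest locus id is the representative that
#' enters mapping; the remaining members are passengers, re-attached at the
#' representative's final map position.
#'
#' @param geno an [fs_geno()] object (already filtered).
#' @return data.frame with columns `locus_id`, `representative`,
#'   `is_passenger`, plus attribute `bins`: a list of member-id vectors
#'   named by representative.
#' @export
bin_cosegregating <- function(geno) {
  stopifnot(inherits(geno, "fs_geno"))
  sig <- apply(geno$calls, 1L, function(r) paste(ifelse(is.na(r), ".", r), collapse = ";"))
  # the signature must also encode the segregation structure: two loci of
  # different types cannot co-segregate even if call strings coincide
  sig <- paste(geno$loci$seg_type, geno$loci$mother, geno$loci$father, sig)
  ids <- geno$loci$locus_id
  reps <- tapply(ids, sig, function(v) min(v))
  rep_of <- unname(reps[sig])
  bins <- split(ids, rep_of)
  out <- data.frame(locus_id = ids, representative = rep_of,
                    is_passenger = ids != rep_of)
  attr(out, "bins") <- bins
  out
}
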
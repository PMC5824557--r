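#' @keywords internal
"_PACKAGE"

# Segregation types of a full-sib (CP) outcross. Offspring genotypes are
# written as sorted allele pairs "x/y"; missing calls are NA.

#' Cross-pollinator segregation types
#'
#' The five marker configurations of a full-sib outcross: both parents
#' heterozygous with four (`ABxCD`), three (`EFxEG`) or two (`HKxHK`)
#' distinct alleles, or only the mother (`LMxLL`) or father (`NNxNP`)
#' heterozygous.
#'
#' @format Character vector of length 5.
#' @export
CP_SEG_TYPES <- c("ABxCD", "EFxEG", "HKxHK", "LMxLL", "NNxNP")

#' Canonical genotype string
#'
#' @param a1,a2 single-character allele labels.
#' @return `"x/y"` with alleles sorted, so that `geno_str("b","a")` and
#'   `geno_str("a","b")` are the same genotype.
#' @export
geno_str <- function(a1, a2) {
  ifelse(a1 <= a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
}

#' Split a genotype string into its two alleles
#'
#' @param g genotype string `"x/y"` or `NA`.
#' @return character vector of length 2, or `c(NA, NA)`.
#' @export
parse_geno <- function(g) {
  if (is.na(g)) return(c(NA_character_, NA_character_))
  strsplit(g, "/", fixed = TRUE)[[1]]
}

#' Classify the segregation type of a locus from its parental genotypes
#'
#' Determines which CP configuration the parents form and the Mendelian
#' expected offspring genotype-class ratio. Loci with both parents
#' homozygous carry no linkage information and are flagged uninformative;
#' a missing parent genotype makes the locus unclassifiable.
#'
#' @param mother,father parental genotypes as `"x/y"` strings.
#' @return a list with elements `seg_type` (one of [CP_SEG_TYPES] or `NA`),
#'   `informative` (logical), `reason` (why not, if not), `classes`
#'   (offspring genotype classes), `expected` (expected proportions per
#'   class), `mother_alleles`, `father_alleles`, and `trans`, a list (one
#'   entry per class) of two-column matrices enumerating the compatible
#'   parental transmissions (`mi`, `fi` = index of the transmitted allele
#'   in each parent, 1 or 2).
#' @examples
#' classify_segregation("a/b", "c/d")$seg_type   # "ABxCD"
#' classify_segregation("l/m", "l/l")$expected   # 1:1 over l/l, l/m
#' @export
classify_segregation <- function(mother, father) {
  out <- list(seg_type = NA_character_, informative = FALSE, reason = NA_character_,
              classes = character(0), expected = numeric(0),
              mother_alleles = c(NA_character_, NA_character_),
              father_alleles = c(NA_character_, NA_character_), trans = list())
  if (is.na(mother) || is.na(father)) {
    out$reason <- "missing_parent"
    return(out)
  }
  m <- parse_geno(mother); f <- parse_geno(father)
  out$mother_alleles <- m; out$father_alleles <- f
  mhet <- m[1] != m[2]; fhet <- f[1] != f[2]
  if (!mhet && !fhet) {
    out$reason <- "uninformative"
    return(out)
  }
  if (mhet && fhet) {
    n_all <- length(unique(c(m, f)))
    out$seg_type <- if (n_all == 4) "ABxCD" else if (n_all == 3) "EFxEG" else "HKxHK"
  } else if (mhet) {
    out$seg_type <- "LMxLL"
  } else {
    out$seg_type <- "NNxNP"
  }
  # cross the parental alleles to get classes, expected ratio and the
  # transmission-compatibility sets
  combos <- expand.grid(mi = 1:2, fi = 1:2)
  g <- geno_str(m[combos$mi], f[combos$fi])
  classes <- sort(unique(g))
  expected <- as.numeric(table(factor(g, levels = classes))) / 4
  trans <- lapply(classes, function(cl) {
    as.matrix(combos[g == cl, , drop = FALSE])
  })
  names(trans) <- classes
  out$informative <- TRUE
  out$classes <- classes
  out$expected <- expected
  out$trans <- trans
  out
}

# classification for every locus of an fs_geno, cached on first use
locus_info <- function(geno) {
  lapply(seq_len(nrow(geno$loci)), function(i) {
    classify_segregation(geno$loci$mother[i], geno$loci$father[i])
  })
}

#' Family genotype container
#'
#' Bundles the per-locus parental genotypes with the offspring call matrix
#' for one full-sib family.
#'
#' @param loci data.frame with columns `locus_id`, `contig_id`, `seg_type`,
#'   `mother`, `father` (genotypes as `"x/y"`).
#' @param calls character matrix (loci x offspring) of `"x/y"` genotype
#'   calls, `NA` for missing; rownames must equal `loci$locus_id`.
#' @param family_id family label.
#' @return an object of class `fs_geno`.
#' @export
fs_geno <- function(loci, calls, family_id = "FamA") {
  stopifnot(is.data.frame(loci), is.matrix(calls))
  if (anyDuplicated(loci$locus_id))
    stop("duplicated locus id: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  if (!identical(rownames(calls), loci$locus_id))
    stop("rownames(calls) must equal loci$locus_id")
  loci$locus_id <- as.character(loci$locus_id)
  if (is.null(loci$contig_id)) loci$contig_id <- loci$locus_id
  structure(list(loci = loci, calls = calls, family_id = family_id),
            class = "fs_geno")
}

#' @export
print.fs_geno <- function(x, ...) {
  cat(sprintf("fs_geno family %s: %d loci x %d offspring\n",
              x$family_id, nrow(x$calls), ncol(x$calls)))
  print(table(x$loci$seg_type, useNA = "ifany"))
  invisible(x)
}

# subset an fs_geno by locus ids and/or offspring ids
subset_geno <- function(geno, loci = NULL, offspring = NULL) {
  keep_l <- if (is.null(loci)) rep(TRUE, nrow(geno$loci)) else geno$loci$locus_id %in% loci
  keep_o <- if (is.null(offspring)) rep(TRUE, ncol(geno$calls)) else colnames(geno$calls) %in% offspring
  fs_geno(geno$loci[keep_l, , drop = FALSE],
          geno$calls[keep_l, keep_o, drop = FALSE],
          geno$family_id)
}
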
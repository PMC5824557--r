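# Readers and writers for the package's plain-text interchange formats:
# genotype tables (TSV or minimal VCF), map tables, 12-column similarity
# hits, and the YAML pipeline configuration.

#' Write a family genotype table to TSV
#'
#' Columns: `locus_id`, `contig_id`, `seg_type`, `mother`, `father`, then
#' one column per offspring; missing calls written as `-`.
#'
#' @param geno an [fs_geno()].
#' @param path output file.
#' @export
write_genotypes <- function(geno, path) {
  m <- geno$calls
  m[is.na(m)] <- "-"
  df <- cbind(geno$loci[, c("locus_id", "contig_id", "seg_type",
                            "mother", "father")], as.data.frame(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a family genotype table
#'
#' @param path input file.
#' @param format `"tsv"` (the [write_genotypes()] layout) or `"vcf"` (a
#'   VCF with parents among the samples; requires the vcfR package).
#' @param mother,father parent sample names (VCF only).
#' @param family_id family label.
#' @return an [fs_geno()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           mother = NULL, father = NULL,
                           family_id = "FamA") {
  format <- match.arg(format)
  if (format == "vcf")
    return(read_genotypes_vcf(path, mother, father, family_id))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  meta_cols <- c("locus_id", "contig_id", "seg_type", "mother", "father")
  stopifnot(all(meta_cols %in% names(df)))
  off <- setdiff(names(df), meta_cols)
  calls <- as.matrix(df[, off, drop = FALSE])
  calls[calls == "-"] <- NA_character_
  rownames(calls) <- df$locus_id
  fs_geno(df[, meta_cols], calls, family_id)
}

#' Write a family genotype table as a minimal VCF
#'
#' Allele letters are mapped per locus to bases (first allele = REF); the
#' samples are the two parents followed by the offspring. The file
#' round-trips through [read_genotypes()] with `format = "vcf"`.
#'
#' @param geno an [fs_geno()].
#' @param path output file.
#' @param mother,father sample names for the parents.
#' @export
write_genotypes_vcf <- function(geno, path, mother = "MOTHER", father = "FATHER") {
  bases <- c("A", "C", "G", "T", "AA", "CC", "GG", "TT")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", mother, father,
                       colnames(geno$calls)), collapse = "\t")), con)
  for (i in seq_len(nrow(geno$loci))) {
    als <- sort(unique(unlist(lapply(
      c(geno$loci$mother[i], geno$loci$father[i],
        geno$calls[i, !is.na(geno$calls[i, ])]), parse_geno))))
    base_of <- stats::setNames(bases[seq_along(als)], als)
    gt <- function(g) {
      if (is.na(g)) return("./.")
      al <- parse_geno(g)
      paste(match(al, als) - 1L, collapse = "/")
    }
    fields <- c(geno$loci$contig_id[i], as.character(i), geno$loci$locus_id[i],
                base_of[als[1]],
                if (length(als) > 1) paste(base_of[als[-1]], collapse = ",") else ".",
                ".", "PASS", ".", "GT",
                gt(geno$loci$mother[i]), gt(geno$loci$father[i]),
                vapply(geno$calls[i, ], gt, ""))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

read_genotypes_vcf <- function(path, mother, father, family_id = "FamA") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  if (is.null(mother) || is.null(father))
    stop("VCF input needs `mother` and `father` sample names")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!all(c(mother, father) %in% samples))
    stop("unknown sample name(s): ",
         paste(setdiff(c(mother, father), samples), collapse = ", "))
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), fix[, "ID"])
  if (anyDuplicated(ids))
    stop("duplicated locus id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- nrow(gt)
  to_call <- function(code, alleles) {
    if (is.na(code)) return(NA_character_)
    idx <- suppressWarnings(as.integer(strsplit(code, "[/|]")[[1]]))
    if (length(idx) != 2 || anyNA(idx)) return(NA_character_)
    geno_str(alleles[idx[1] + 1L], alleles[idx[2] + 1L])
  }
  off <- setdiff(samples, c(mother, father))
  calls <- matrix(NA_character_, n, length(off), dimnames = list(ids, off))
  mo <- fa <- character(n)
  n_bad <- 0L
  for (i in seq_len(n)) {
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    mo[i] <- to_call(gt[i, mother], alleles)
    fa[i] <- to_call(gt[i, father], alleles)
    calls[i, ] <- vapply(gt[i, off], to_call, "", alleles = alleles)
    info <- classify_segregation(mo[i], fa[i])
    if (info$informative) {
      bad <- !is.na(calls[i, ]) & !(calls[i, ] %in% info$classes)
      n_bad <- n_bad + sum(bad)
      calls[i, bad] <- NA_character_
    }
  }
  if (n_bad > 0)
    warning(n_bad, " offspring calls incompatible with the parents set to missing")
  seg <- vapply(seq_len(n), function(i)
    classify_segregation(mo[i], fa[i])$seg_type, "")
  loci <- data.frame(locus_id = ids, contig_id = unname(fix[, "CHROM"]),
                     seg_type = seg, mother = mo, father = fa)
  fs_geno(loci, calls, family_id)
}

#' Read a 12-column tabular similarity-hit file
#'
#' The classic tab-separated dialect: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`. Rows with a
#' different number of columns are skipped with a warning. Hits with
#' `sstart > send` are on the minus strand; their coordinates are
#' normalized to `sstart <= send` and recorded in the added `strand`
#' column.
#'
#' @param path input file.
#' @return data.frame with the 12 columns plus `strand`; attribute
#'   `n_malformed` counts skipped rows.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 12L
  if (any(!ok))
    warning(sum(!ok), " malformed hit rows skipped")
  if (!any(ok)) {
    warning("no valid hit rows in ", path)
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    out$strand <- character(0)
    attr(out, "n_malformed") <- sum(!ok)
    return(out)
  }
  m <- do.call(rbind, parts[ok])
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.numeric(m[, 9]), send = as.numeric(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
  out$strand <- ifelse(out$sstart <= out$send, "+", "-")
  flip <- out$sstart > out$send
  tmp <- out$sstart[flip]
  out$sstart[flip] <- out$send[flip]
  out$send[flip] <- tmp
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Write a hit table in the 12-column dialect
#' @param hits data.frame with the 12 standard columns.
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a genetic map to TSV
#' @param map a `genetic_map`.
#' @param path output file.
#' @export
write_map <- function(map, path) {
  prov <- attr(map, "provenance")
  df <- as.data.frame(map)
  df$provenance <- paste(if (!is.null(prov$family)) prov$family else "?",
                         if (!is.null(prov$scope)) prov$scope else "?",
                         sep = ":")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genetic map from TSV
#' @param path file written by [write_map()].
#' @return a `genetic_map`.
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  prov <- if ("provenance" %in% names(df) && nrow(df)) {
    parts <- strsplit(df$provenance[1], ":", fixed = TRUE)[[1]]
    list(family = parts[1], scope = parts[2])
  } else list()
  as_genetic_map(df[, c("locus_id", "lg", "position_cM", "is_passenger")],
                 provenance = prov)
}

#' Pipeline configuration with the study's thresholds as defaults
#'
#' @param min_lod minimum LOD for grouping (6).
#' @param max_rf maximum rf for grouping (0.35).
#' @param call_rate minimum per-locus call rate (0.90).
#' @param maf minimum minor allele frequency (0.05).
#' @param alpha distortion significance level before Bonferroni (0.05).
#' @param ripple_window ripple window size (4).
#' @param tolerance_frac synteny order-mismatch tolerance (0.05).
#' @param gap_cM map-gap threshold (20).
#' @param rounds conflict-resolution rounds (3).
#' @param mapping_function `"kosambi"` or `"haldane"`.
#' @param epsilon consensus LP minimum order gap in cM (0.01).
#' @param max_indiv_missing maximum per-offspring missing fraction (0.50).
#' @param min_evalue,min_bitscore_margin anchor-filter settings.
#' @param max_gap_cM placement clustering distance (1).
#' @param seed master seed for any simulation driven by the config.
#' @return validated list of class `sibmap_config`.
#' @export
pipeline_config <- function(min_lod = 6, max_rf = 0.35, call_rate = 0.90,
                            maf = 0.05, alpha = 0.05, ripple_window = 4L,
                            tolerance_frac = 0.05, gap_cM = 20, rounds = 3L,
                            mapping_function = "kosambi", epsilon = 0.01,
                            max_indiv_missing = 0.50, min_evalue = 1e-10,
                            min_bitscore_margin = 0.1, max_gap_cM = 1,
                            seed = 1L) {
  cfg <- list(min_lod = min_lod, max_rf = max_rf, call_rate = call_rate,
              maf = maf, alpha = alpha, ripple_window = as.integer(ripple_window),
              tolerance_frac = tolerance_frac, gap_cM = gap_cM,
              rounds = as.integer(rounds), mapping_function = mapping_function,
              epsilon = epsilon, max_indiv_missing = max_indiv_missing,
              min_evalue = min_evalue,
              min_bitscore_margin = min_bitscore_margin,
              max_gap_cM = max_gap_cM, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "sibmap_config")
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && x >= 0 && x <= 1
  if (!(is.numeric(cfg$min_lod) && cfg$min_lod >= 0))
    stop("min_lod must be non-negative")
  if (!(is.numeric(cfg$max_rf) && cfg$max_rf > 0 && cfg$max_rf <= 0.5))
    stop("max_rf must be in (0, 0.5]")
  for (k in c("call_rate", "maf", "alpha", "tolerance_frac",
              "max_indiv_missing", "min_bitscore_margin"))
    if (!in01(cfg[[k]])) stop(k, " must be in [0, 1]")
  if (cfg$ripple_window < 2) stop("ripple_window must be >= 2")
  if (cfg$gap_cM <= 0) stop("gap_cM must be positive")
  if (cfg$rounds < 1) stop("rounds must be >= 1")
  if (!cfg$mapping_function %in% c("kosambi", "haldane"))
    stop("mapping_function must be kosambi or haldane")
  if (cfg$epsilon <= 0) stop("epsilon must be positive")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return [pipeline_config()] object.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a `sibmap_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
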
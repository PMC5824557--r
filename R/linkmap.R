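# Assembly of a genetic map for one family: co-segregation binning,
# two-point estimation, LOD/rf grouping, ordering, QC, positions, and
# passenger re-attachment.

#' Group loci into linkage groups
#'
#' Builds a graph with an edge for every pair passing `lod >= min_lod`
#' and `rf <= max_rf` and returns its connected components (transitive
#' grouping). Groups are numbered deterministically by their smallest
#' member locus id.
#'
#' @param tp data.frame from [two_point_all()].
#' @param loci all locus ids to partition (singletons kept).
#' @param min_lod minimum LOD for direct linkage (default 6).
#' @param max_rf maximum recombination fraction (default 0.35).
#' @return list of character vectors (sorted within group), ordered by
#'   smallest member id.
#' @export
group_loci <- function(tp, loci, min_lod = 6, max_rf = 0.35) {
  edges <- tp[tp$lod >= min_lod & tp$rf <= max_rf, c("a", "b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = loci))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, "", 1L))]
}

#' Build a genetic map for one family
#'
#' The full pipeline: bin co-segregating loci, estimate all two-point
#' pairs under the requested parental scope, group at the LOD/rf
#' thresholds, order each group (seeding from loci informative in both
#' parents), clean (excess crossovers, tight double crossovers, gaps),
#' re-estimate and re-order, compute cM positions, and re-attach
#' passenger loci at their representatives' positions. Linkage groups are
#' labelled `LG01`, `LG02`, ... by decreasing locus count. Loci that end
#' up in single-locus groups (unlinked) are left off the map.
#'
#' @param geno a filtered [fs_geno()].
#' @param scope `"both"` (family map), `"female"` or `"male"`
#'   (sex-specific map: only that parent's meioses carry linkage signal,
#'   and only loci heterozygous in that parent are mapped).
#' @param min_lod,max_rf grouping thresholds (defaults 6 and 0.35).
#' @param ripple_window ripple window size (default 4).
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param gap_cM,xo_z,tight_cM QC parameters, see [clean_order()].
#' @param clean run the QC/cleaning stage (default TRUE).
#' @param positions `"wls"` (default): final cM positions by windowed
#'   weighted least squares over all estimable pairs ([wls_positions()]);
#'   `"adjacent"`: plain accumulation of adjacent-pair distances
#'   ([compute_positions()]).
#' @param clean_passes re-assess the cleaned, re-ordered group and clean
#'   again, up to this many passes or until nothing changes (default 3).
#'   Iteration matters because masking an error call moves its
#'   neighbours' provisional positions, exposing further tight double
#'   crossovers.
#' @param min_group smallest group retained as a linkage group (default 2).
#' @return an object of class `genetic_map`: a data.frame with columns
#'   `locus_id`, `lg`, `position_cM`, `is_passenger`, plus attributes
#'   `provenance` (family, scope), `mapping_function`, `removed`
#'   (QC-removed loci), `unlinked` (single-locus groups).
#' @export
build_map <- function(geno, scope = c("both", "female", "male"),
                      min_lod = 6, max_rf = 0.35, ripple_window = 4L,
                      mapping_function = c("kosambi", "haldane"),
                      gap_cM = 20, xo_z = 3, tight_cM = 5,
                      clean = TRUE, clean_passes = 3L, min_group = 2L,
                      positions = c("wls", "adjacent")) {
  scope <- match.arg(scope)
  positions <- match.arg(positions)
  mapping_function <- match.arg(mapping_function)
  info <- locus_info(geno)
  names(info) <- geno$loci$locus_id

  # scope restriction: a sex-specific map uses loci het in that parent
  het_in <- function(l, p) {
    al <- if (p == "mother") info[[l]]$mother_alleles else info[[l]]$father_alleles
    !is.na(al[1]) && al[1] != al[2]
  }
  ids <- geno$loci$locus_id
  usable <- vapply(ids, function(l) isTRUE(info[[l]]$informative), TRUE)
  if (scope == "female") usable <- usable & vapply(ids, het_in, TRUE, p = "mother")
  if (scope == "male") usable <- usable & vapply(ids, het_in, TRUE, p = "father")
  geno <- subset_geno(geno, loci = ids[usable])

  bins <- bin_cosegregating(geno)
  reps <- unique(bins$representative)
  geno_r <- subset_geno(geno, loci = reps)

  tp <- two_point_all(geno_r, scope = scope)
  groups <- group_loci(tp, reps, min_lod = min_lod, max_rf = max_rf)
  unlinked <- unlist(groups[lengths(groups) < min_group])
  groups <- groups[lengths(groups) >= min_group]

  seed_set <- reps[vapply(reps, function(l)
    het_in(l, "mother") && het_in(l, "father"), TRUE)]

  removed_all <- character(0)
  lg_list <- list()
  for (grp in groups) {
    cache <- tp_cache(tp, grp)
    ord <- order_group(grp, cache, seed_loci = seed_set,
                       ripple_window = ripple_window,
                       mapping_function = mapping_function)
    g_geno <- subset_geno(geno_r, loci = grp)
    if (clean) {
      tp_g <- tp
      for (pass in seq_len(clean_passes)) {
        cl <- clean_order(g_geno, ord, tp_g, cache, scope = scope,
                          gap_cM = gap_cM, xo_z = xo_z, tight_cM = tight_cM,
                          mapping_function = mapping_function)
        removed_all <- c(removed_all, cl$removed_loci)
        changed <- length(cl$removed_loci) > 0 ||
          length(cl$removed_individuals) > 0 || cl$masked > 0
        if (!changed) { ord <- cl$ord; break }
        g_geno <- subset_geno(cl$geno, loci = cl$ord)
        tp_g <- two_point_all(g_geno, scope = scope)
        cache <- tp_cache(tp_g, cl$ord)
        ord <- order_group(cl$ord, cache, seed_loci = seed_set,
                           ripple_window = ripple_window,
                           mapping_function = mapping_function)
      }
    }
    if (length(ord) < min_group) { unlinked <- c(unlinked, ord); next }
    pos <- if (positions == "wls")
      wls_positions(ord, cache, mapping_function)
    else compute_positions(ord, cache, mapping_function)
    lg_list[[length(lg_list) + 1L]] <- data.frame(
      locus_id = ord, position_cM = pos, is_passenger = FALSE)
  }

  if (length(lg_list) == 0) stop("no linkage groups formed")
  # attach passengers at their representative's position
  pass <- bins[bins$is_passenger, , drop = FALSE]
  for (k in seq_along(lg_list)) {
    df <- lg_list[[k]]
    extra <- pass[pass$representative %in% df$locus_id, , drop = FALSE]
    if (nrow(extra)) {
      add <- data.frame(locus_id = extra$locus_id,
                        position_cM = df$position_cM[match(extra$representative,
                                                           df$locus_id)],
                        is_passenger = TRUE)
      df <- rbind(df, add)
    }
    df <- df[order(df$position_cM, df$is_passenger, df$locus_id), , drop = FALSE]
    lg_list[[k]] <- df
  }

  # number LGs by decreasing size, ties by smallest locus id
  sizes <- vapply(lg_list, nrow, 0L)
  first_id <- vapply(lg_list, function(d) min(d$locus_id), "")
  o <- order(-sizes, first_id)
  out <- do.call(rbind, lapply(seq_along(o), function(k) {
    df <- lg_list[[o[k]]]
    df$lg <- sprintf("LG%02d", k)
    df[, c("locus_id", "lg", "position_cM", "is_passenger")]
  }))
  rownames(out) <- NULL
  structure(out,
            class = c("genetic_map", "data.frame"),
            provenance = list(family = geno$family_id, scope = scope),
            mapping_function = mapping_function,
            removed = removed_all, unlinked = unlinked)
}

#' Construct a genetic_map from a plain position table
#'
#' @param df data.frame with columns `locus_id`, `lg`, `position_cM` and
#'   optionally `is_passenger`.
#' @param provenance free-form provenance list.
#' @param mapping_function label only.
#' @return a `genetic_map`.
#' @export
as_genetic_map <- function(df, provenance = list(), mapping_function = "kosambi") {
  stopifnot(all(c("locus_id", "lg", "position_cM") %in% names(df)))
  if (is.null(df$is_passenger)) df$is_passenger <- FALSE
  if (anyDuplicated(df$locus_id))
    stop("locus appears on more than one position: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  df <- df[order(df$lg, df$position_cM, df$locus_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df[, c("locus_id", "lg", "position_cM", "is_passenger")],
            class = c("genetic_map", "data.frame"),
            provenance = provenance, mapping_function = mapping_function)
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  prov <- attr(x, "provenance")
  cat(sprintf("genetic_map (%s, scope %s): %d loci on %d LGs, %.1f cM\n",
              if (!is.null(prov$family)) prov$family else "?",
              if (!is.null(prov$scope)) prov$scope else "?",
              s$n_loci, s$n_lg, s$total_length_cM))
  invisible(x)
}

#' Summary statistics of a genetic map
#'
#' Total loci (passengers included), number of LGs, total length, mean and
#' SD of loci per LG and of LG length, and the mean locus interval under
#' both conventions: total length divided by the number of loci, and by
#' the number of adjacent intervals (loci minus LGs).
#'
#' @param map a `genetic_map`.
#' @return list of summary statistics.
#' @export
map_summary <- function(map) {
  per_lg <- split(map$position_cM, map$lg)
  lens <- vapply(per_lg, max, 0)
  nl <- vapply(per_lg, length, 0L)
  list(n_loci = nrow(map), n_lg = length(per_lg),
       total_length_cM = sum(lens),
       mean_loci_per_lg = mean(nl), sd_loci_per_lg = stats::sd(nl),
       mean_lg_length_cM = mean(lens), sd_lg_length_cM = stats::sd(lens),
       mean_interval_per_locus = sum(lens) / nrow(map),
       mean_interval_adjacent = sum(lens) / max(nrow(map) - length(per_lg), 1L))
}

#' Map summary statistics from printed totals
#'
#' The same arithmetic as [map_summary()] applied to already-summarized
#' totals, for checking published tables.
#'
#' @param n_loci total mapped loci.
#' @param n_lg number of linkage groups.
#' @param total_length_cM total map length.
#' @return list with `mean_loci_per_lg`, `mean_lg_length_cM`,
#'   `mean_interval_per_locus`, `mean_interval_adjacent`.
#' @export
map_summary_from_totals <- function(n_loci, n_lg, total_length_cM) {
  list(mean_loci_per_lg = n_loci / n_lg,
       mean_lg_length_cM = total_length_cM / n_lg,
       mean_interval_per_locus = total_length_cM / n_loci,
       mean_interval_adjacent = total_length_cM / (n_loci - n_lg))
}
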
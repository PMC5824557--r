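# End-to-end pipeline: QC both families, build family maps, resolve
# conflicts and merge into a consensus, then call syntenic blocks and
# place external features against each comparison genome.

#' Run the full mapping and synteny pipeline
#'
#' Stages, in order: marker filtering per family; family map construction
#' (scope `"both"`); conflict resolution and LP consensus merging;
#' per-genome anchor assignment, block detection and statistics; feature
#' placement and clustering when feature hits are supplied. Each stage
#' logs its locus counts; any stage error halts with the stage name. The
#' run is deterministic for fixed inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @param geno_a,geno_b [fs_geno()] objects for the two families.
#' @param hit_tables named list (by genome id) of 12-column hit tables of
#'   mapped-locus sequences against each comparison genome.
#' @param feature_hits optional named list (by genome id) of feature hit
#'   tables.
#' @param out_dir optional directory; when given, every intermediate is
#'   written (maps and logs as TSV, summaries as JSON).
#' @param sex_maps also build the four sex-specific maps (default FALSE).
#' @param verbose print per-stage progress (default TRUE).
#' @return list with `qc_a`, `qc_b`, `map_a`, `map_b`, optional
#'   `sex_maps`, `consensus` (the [consensus_map()] result), `anchors`,
#'   `blocks`, `stats` (per genome), `placements`, `clusters`,
#'   `summary`.
#' @export
run_pipeline <- function(config, geno_a, geno_b, hit_tables = list(),
                         feature_hits = NULL, out_dir = NULL,
                         sex_maps = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "sibmap_config"))
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("qc: family A %d loci, family B %d loci",
      nrow(geno_a$loci), nrow(geno_b$loci))
  qc_a <- stage("qc_a", filter_markers(
    geno_a, min_call_rate = config$call_rate,
    max_indiv_missing = config$max_indiv_missing,
    min_maf = config$maf, alpha = config$alpha))
  qc_b <- stage("qc_b", filter_markers(
    geno_b, min_call_rate = config$call_rate,
    max_indiv_missing = config$max_indiv_missing,
    min_maf = config$maf, alpha = config$alpha))
  say("qc kept: A %d, B %d", nrow(qc_a$geno$loci), nrow(qc_b$geno$loci))

  bm <- function(g, scope) build_map(
    g, scope = scope, min_lod = config$min_lod, max_rf = config$max_rf,
    ripple_window = config$ripple_window,
    mapping_function = config$mapping_function, gap_cM = config$gap_cM)
  map_a <- stage("map_a", bm(qc_a$geno, "both"))
  map_b <- stage("map_b", bm(qc_b$geno, "both"))
  say("family maps: A %d loci / %d LGs, B %d loci / %d LGs",
      nrow(map_a), length(unique(map_a$lg)),
      nrow(map_b), length(unique(map_b$lg)))

  sex <- NULL
  if (sex_maps)
    sex <- stage("sex_maps", list(
      a_female = bm(qc_a$geno, "female"), a_male = bm(qc_a$geno, "male"),
      b_female = bm(qc_b$geno, "female"), b_male = bm(qc_b$geno, "male")))

  cons <- stage("consensus", consensus_map(
    map_a, map_b, max_rounds = config$rounds, epsilon = config$epsilon))
  say("consensus: %d loci, MAE %.3f cM",
      nrow(cons$consensus), attr(cons$consensus, "mae"))

  anchors <- list(); blocks <- list(); stats <- list()
  for (gid in names(hit_tables)) {
    anchors[[gid]] <- stage(paste0("anchors_", gid), assign_anchors(
      hit_tables[[gid]], cons$consensus, genome_id = gid,
      min_evalue = config$min_evalue,
      min_bitscore_margin = config$min_bitscore_margin))
    blocks[[gid]] <- stage(paste0("blocks_", gid), find_blocks(
      cons$consensus, anchors[[gid]],
      tolerance_frac = config$tolerance_frac))
    stats[[gid]] <- block_stats(blocks[[gid]]$blocks, cons$consensus)
    say("genome %s: %d anchors, %d blocks, %.1f%% of map covered",
        gid, nrow(anchors[[gid]]), stats[[gid]]$n_blocks,
        stats[[gid]]$prop_covered_pct)
  }

  placements <- NULL; clusters <- NULL
  if (!is.null(feature_hits)) {
    pl <- list()
    for (gid in names(feature_hits)) {
      if (is.null(blocks[[gid]])) next
      pl[[gid]] <- stage(paste0("place_", gid), place_features(
        feature_hits[[gid]], blocks[[gid]], cons$consensus, genome_id = gid,
        min_evalue = config$min_evalue,
        min_bitscore_margin = config$min_bitscore_margin))
    }
    placements <- combine_placements(pl)
    clusters <- cluster_placements(placements, max_gap_cM = config$max_gap_cM)
    say("placed %d / %d features",
        sum(placements$primary), length(unique(placements$feature_id)))
  }

  summary <- list(
    consensus = map_summary(cons$consensus),
    family_a = map_summary(map_a), family_b = map_summary(map_b),
    consensus_mae = attr(cons$consensus, "mae"),
    block_stats = stats)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_map(map_a, file.path(out_dir, "map_famA.tsv"))
    write_map(map_b, file.path(out_dir, "map_famB.tsv"))
    write_map(cons$consensus, file.path(out_dir, "map_consensus.tsv"))
    utils::write.table(cons$log, file.path(out_dir, "conflict_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rbind(qc_a$log, qc_b$log),
                       file.path(out_dir, "qc_removals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (gid in names(blocks))
      utils::write.table(blocks[[gid]]$blocks,
                         file.path(out_dir, sprintf("blocks_%s.tsv", gid)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(placements))
      utils::write.table(placements, file.path(out_dir, "placements.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(qc_a = qc_a, qc_b = qc_b, map_a = map_a, map_b = map_b,
       sex_maps = sex, consensus = cons, anchors = anchors, blocks = blocks,
       stats = stats, placements = placements, clusters = clusters,
       summary = summary)
}
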
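# Comparative mapping: anchor assignment from similarity hits, syntenic
# block detection on the linkage map, block statistics, and placement of
# external features by interpolation between syntenic flanking loci.

#' Assign unique genome anchors to mapped loci from similarity hits
#'
#' Per (locus, genome) the best hit by bitscore is retained only if its
#' e-value passes `min_evalue` and its bitscore exceeds the best hit on a
#' *different* chromosome by at least the fraction
#' `min_bitscore_margin`; otherwise the locus stays unanchored for that
#' genome (ambiguous placement). The anchor coordinate is the hit's
#' subject midpoint (1-based).
#'
#' @param hits 12-column hit table (see [read_hits()]) for one genome.
#' @param map a `genetic_map`; hits whose query is not on the map are
#'   dropped.
#' @param genome_id label attached to the anchors.
#' @param min_evalue e-value ceiling (default 1e-10).
#' @param min_bitscore_margin required fractional margin of the best over
#'   the runner-up on another chromosome (default 0.1).
#' @return data.frame `locus_id`, `genome_id`, `chrom`, `bp`, `strand`,
#'   `evalue`, `bitscore`, one row per anchored locus.
#' @export
assign_anchors <- function(hits, map, genome_id = "genome",
                           min_evalue = 1e-10, min_bitscore_margin = 0.1) {
  h <- hits[hits$qseqid %in% map$locus_id, , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(locus_id = character(0), genome_id = character(0),
                      chrom = character(0), bp = numeric(0),
                      strand = character(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  strand <- ifelse(h$sstart <= h$send, "+", "-")
  bp <- floor((h$sstart + h$send) / 2)
  rows <- list()
  for (q in unique(h$qseqid)) {
    sub <- which(h$qseqid == q)
    o <- sub[order(-h$bitscore[sub], h$evalue[sub])]
    best <- o[1]
    if (h$evalue[best] > min_evalue) next
    other <- o[h$sseqid[o] != h$sseqid[best]]
    if (length(other)) {
      margin <- (h$bitscore[best] - h$bitscore[other[1]]) / h$bitscore[best]
      if (margin < min_bitscore_margin) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = q, genome_id = genome_id, chrom = h$sseqid[best],
      bp = bp[best], strand = strand[best], evalue = h$evalue[best],
      bitscore = h$bitscore[best])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), genome_id = character(0),
               chrom = character(0), bp = numeric(0), strand = character(0),
               evalue = numeric(0), bitscore = numeric(0))
  rownames(out) <- NULL
  out
}

#' Find syntenic blocks between a linkage map and one comparison genome
#'
#' Within each LG, the anchored loci are scanned in cM order. A block is
#' a maximal run on a single chromosome with monotone bp (either
#' direction), uninterrupted by any anchored locus of a different run. A
#' locus breaking monotonicity whose cM distance to the offending
#' neighbour is below `tolerance_frac` of the LG length is treated as a
#' local rearrangement or ordering error: it stays in the block but is
#' ignored for direction (logged in the `ignored` column). Runs shorter
#' than `min_block` are discarded.
#'
#' @param map a `genetic_map`.
#' @param anchors output of [assign_anchors()] for one genome.
#' @param tolerance_frac order-mismatch tolerance as a fraction of LG
#'   length (default 0.05).
#' @param min_block minimum loci per block (default 2).
#' @return list with `blocks` (data.frame `block_id`, `genome_id`, `lg`,
#'   `chrom`, `n_loci`, `cm_start`, `cm_end`, `bp_start`, `bp_end`,
#'   `orientation`) and `members` (data.frame `block_id`, `locus_id`,
#'   `cM`, `bp`, `ignored`).
#' @export
find_blocks <- function(map, anchors, tolerance_frac = 0.05, min_block = 2L) {
  genome_id <- if (nrow(anchors)) anchors$genome_id[1] else "genome"
  blocks <- list(); members <- list()
  bid <- 0L
  for (g in unique(map$lg)) {
    sub <- map[map$lg == g, , drop = FALSE]
    lg_len <- max(sub$position_cM)
    a <- anchors[anchors$locus_id %in% sub$locus_id, , drop = FALSE]
    if (nrow(a) == 0) next
    a$cM <- sub$position_cM[match(a$locus_id, sub$locus_id)]
    a <- a[order(a$cM, a$locus_id), , drop = FALSE]
    tol_cm <- tolerance_frac * lg_len

    run <- list()   # list of row indices, with ignored flags
    dir <- 0L; last_bp <- NA_real_; last_cm <- NA_real_
    flush <- function(run) {
      core <- run[!vapply(run, `[[`, TRUE, "ignored")]
      if (length(run) >= min_block && length(core) >= 1) {
        idx <- vapply(run, `[[`, 0L, "i")
        bid <<- bid + 1L
        bps <- a$bp[idx]; cms <- a$cM[idx]
        core_bp <- a$bp[vapply(core, `[[`, 0L, "i")]
        ori <- if (length(core_bp) > 1 && core_bp[length(core_bp)] < core_bp[1]) "-" else "+"
        blocks[[length(blocks) + 1L]] <<- data.frame(
          block_id = bid, genome_id = genome_id, lg = g,
          chrom = a$chrom[idx[1]], n_loci = length(idx),
          cm_start = min(cms), cm_end = max(cms),
          bp_start = min(bps), bp_end = max(bps), orientation = ori)
        members[[length(members) + 1L]] <<- data.frame(
          block_id = bid, locus_id = a$locus_id[idx], cM = cms, bp = bps,
          ignored = vapply(run, `[[`, TRUE, "ignored"))
      }
    }
    for (i in seq_len(nrow(a))) {
      if (length(run) == 0) {
        run <- list(list(i = i, ignored = FALSE))
        dir <- 0L; last_bp <- a$bp[i]; last_cm <- a$cM[i]
        next
      }
      new_run <- FALSE; ignored <- FALSE
      if (a$chrom[i] != a$chrom[run[[1]]$i]) {
        new_run <- TRUE
      } else {
        d <- sign(a$bp[i] - last_bp)
        if (dir == 0L) {
          dir <- d
        } else if (d != 0L && d != dir) {
          # order mismatch: tolerated if close to the offending neighbour
          if (a$cM[i] - last_cm < tol_cm) ignored <- TRUE else new_run <- TRUE
        }
      }
      if (new_run) {
        flush(run)
        run <- list(list(i = i, ignored = FALSE))
        dir <- 0L; last_bp <- a$bp[i]; last_cm <- a$cM[i]
      } else {
        run[[length(run) + 1L]] <- list(i = i, ignored = ignored)
        if (!ignored) { last_bp <- a$bp[i]; last_cm <- a$cM[i] }
      }
    }
    flush(run)
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(0), genome_id = character(0),
               lg = character(0), chrom = character(0), n_loci = integer(0),
               cm_start = numeric(0), cm_end = numeric(0),
               bp_start = numeric(0), bp_end = numeric(0),
               orientation = character(0)),
    members = if (length(members)) do.call(rbind, members) else
      data.frame(block_id = integer(0), locus_id = character(0),
                 cM = numeric(0), bp = numeric(0), ignored = logical(0)))
}

# merge overlapping [start, end] intervals and return their total length
merge_interval_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (k in seq_along(start)[-1]) {
    if (start[k] <= ce) ce <- max(ce, end[k])
    else { tot <- tot + (ce - cs); cs <- start[k]; ce <- end[k] }
  }
  tot + (ce - cs)
}

#' Summary statistics of syntenic blocks for one genome
#'
#' Counts, averages, physical (Mb) and genetic (cM) spans, and the
#' proportion of the linkage map covered: overlapping block cM intervals
#' are merged per LG before summation, and the merged total is divided by
#' the map's total length.
#'
#' @param blocks `blocks` data.frame from [find_blocks()].
#' @param map the `genetic_map` the blocks were called on.
#' @return list: `genome_id`, `n_blocks`, `n_loci`, `avg_loci_per_block`,
#'   `total_mb`, `avg_mb`, `total_cm`, `avg_cm`, `prop_covered_pct`.
#' @export
block_stats <- function(blocks, map) {
  map_len <- map_summary(map)$total_length_cM
  if (nrow(blocks) == 0)
    return(list(genome_id = NA_character_, n_blocks = 0L, n_loci = 0L,
                avg_loci_per_block = 0, total_mb = 0, avg_mb = 0,
                total_cm = 0, avg_cm = 0, prop_covered_pct = 0))
  total_mb <- sum(blocks$bp_end - blocks$bp_start + 1) / 1e6
  total_cm <- sum(blocks$cm_end - blocks$cm_start)
  covered <- sum(vapply(split(blocks, blocks$lg), function(b)
    merge_interval_length(b$cm_start, b$cm_end), 0))
  list(genome_id = blocks$genome_id[1],
       n_blocks = nrow(blocks), n_loci = sum(blocks$n_loci),
       avg_loci_per_block = sum(blocks$n_loci) / nrow(blocks),
       total_mb = total_mb, avg_mb = total_mb / nrow(blocks),
       total_cm = total_cm, avg_cm = total_cm / nrow(blocks),
       prop_covered_pct = 100 * covered / map_len)
}

#' Block summary statistics from printed totals
#'
#' The arithmetic of [block_stats()] applied to already-summarized
#' totals, for checking published tables: average loci per block, average
#' block sizes, and proportion of map covered.
#'
#' @param n_blocks,n_loci block and locus counts.
#' @param total_mb,total_cm total block spans.
#' @param map_length_cM total linkage-map length.
#' @return list with `avg_loci_per_block`, `avg_mb`, `avg_cm`,
#'   `prop_covered_pct` (treats the blocks as non-overlapping, as summary
#'   totals cannot be re-merged).
#' @export
block_stats_from_totals <- function(n_blocks, n_loci, total_mb, total_cm,
                                    map_length_cM) {
  list(avg_loci_per_block = n_loci / n_blocks,
       avg_mb = total_mb / n_blocks,
       avg_cm = total_cm / n_blocks,
       prop_covered_pct = 100 * total_cm / map_length_cM)
}

#' Place external features onto the map via syntenic flanking loci
#'
#' Each feature is anchored per genome by the [assign_anchors()] rule; a
#' feature whose anchor bp falls within a block's bp span is placed at
#' the cM position linearly interpolated (by bp fraction) between the two
#' block members flanking it in bp. A feature hitting a member locus's
#' exact bp takes that locus's cM. Features supported by several genomes
#' report all placements; the placement with the smallest anchor e-value
#' is primary.
#'
#' @param feature_hits 12-column hit table of the external sequences
#'   against one genome.
#' @param blocks result of [find_blocks()] for that genome.
#' @param map the `genetic_map`.
#' @param genome_id genome label.
#' @param min_evalue,min_bitscore_margin anchor-filter settings.
#' @return data.frame `feature_id`, `genome_id`, `block_id`, `lg`,
#'   `cM`, `flank_lo`, `flank_hi`, `evalue`, `placed`, `reason`.
#' @export
place_features <- function(feature_hits, blocks, map, genome_id = "genome",
                           min_evalue = 1e-10, min_bitscore_margin = 0.1) {
  fake_map <- data.frame(locus_id = unique(feature_hits$qseqid))
  anch <- assign_anchors(feature_hits, fake_map, genome_id,
                         min_evalue, min_bitscore_margin)
  bl <- blocks$blocks; mem <- blocks$members
  rows <- list()
  for (k in seq_len(nrow(anch))) {
    fid <- anch$locus_id[k]; chrom <- anch$chrom[k]; fbp <- anch$bp[k]
    cand <- bl[bl$chrom == chrom & bl$bp_start <= fbp & bl$bp_end >= fbp, ,
               drop = FALSE]
    if (nrow(cand) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, genome_id = genome_id, block_id = NA_integer_,
        lg = NA_character_, cM = NA_real_, flank_lo = NA_character_,
        flank_hi = NA_character_, evalue = anch$evalue[k], placed = FALSE,
        reason = "outside_blocks")
      next
    }
    b <- cand[1, ]
    mm <- mem[mem$block_id == b$block_id, , drop = FALSE]
    mm <- mm[order(mm$bp), , drop = FALSE]
    exact <- which(mm$bp == fbp)
    if (length(exact)) {
      cm <- mm$cM[exact[1]]
      lo <- hi <- mm$locus_id[exact[1]]
    } else {
      below <- max(which(mm$bp < fbp)); above <- min(which(mm$bp > fbp))
      frac <- (fbp - mm$bp[below]) / (mm$bp[above] - mm$bp[below])
      cm <- mm$cM[below] + frac * (mm$cM[above] - mm$cM[below])
      lo <- mm$locus_id[below]; hi <- mm$locus_id[above]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = fid, genome_id = genome_id, block_id = b$block_id,
      lg = b$lg, cM = cm, flank_lo = lo, flank_hi = hi,
      evalue = anch$evalue[k], placed = TRUE, reason = NA_character_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), genome_id = character(0),
               block_id = integer(0), lg = character(0), cM = numeric(0),
               flank_lo = character(0), flank_hi = character(0),
               evalue = numeric(0), placed = logical(0), reason = character(0))
  rownames(out) <- NULL
  out
}

#' Combine per-genome placements, marking a primary placement per feature
#'
#' @param placements list (or rbind) of [place_features()] results across
#'   genomes.
#' @return data.frame with an added logical `primary` column: the placed
#'   row with the smallest e-value per feature.
#' @export
combine_placements <- function(placements) {
  df <- if (is.data.frame(placements)) placements else do.call(rbind, placements)
  df$primary <- FALSE
  for (f in unique(df$feature_id[df$placed])) {
    idx <- which(df$feature_id == f & df$placed)
    df$primary[idx[which.min(df$evalue[idx])]] <- TRUE
  }
  df
}

#' Cluster placed features along each linkage group
#'
#' Single-linkage clustering by cM position: features closer than
#' `max_gap_cM` to their neighbour join the same cluster.
#'
#' @param placements placed features (rows with `placed = TRUE` and a
#'   `lg`/`cM`; the primary placement is used when a `primary` column is
#'   present).
#' @param max_gap_cM linking distance (default 1 cM).
#' @return data.frame `feature_id`, `lg`, `cM`, `cluster`, plus attribute
#'   `sizes` (table of cluster sizes).
#' @export
cluster_placements <- function(placements, max_gap_cM = 1) {
  df <- placements[placements$placed, , drop = FALSE]
  if ("primary" %in% names(df)) df <- df[df$primary, , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(feature_id = character(0), lg = character(0),
                      cM = numeric(0), cluster = character(0)))
  out <- list()
  for (g in unique(df$lg)) {
    sub <- df[df$lg == g, , drop = FALSE]
    sub <- sub[order(sub$cM, sub$feature_id), , drop = FALSE]
    brk <- c(0, cumsum(diff(sub$cM) > max_gap_cM))
    sub$cluster <- sprintf("%s_c%02d", g, brk + 1L)
    out[[length(out) + 1L]] <- sub[, c("feature_id", "lg", "cM", "cluster")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sizes") <- table(res$cluster)
  res
}
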
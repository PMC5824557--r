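# Simulation of full-sib crosses and rearranged comparison genomes with
# known ground truth. The crossover process is Poisson along the map
# (Haldane, no interference) so that observed recombination fractions are
# analytically checkable against the mapping-function inverse.

default_seg_mix <- c(ABxCD = 0.10, EFxEG = 0.15, HKxHK = 0.25,
                     LMxLL = 0.25, NNxNP = 0.25)

# canonical parental genotypes per segregation type
seg_type_parents <- list(
  ABxCD = list(mother = c("a", "b"), father = c("c", "d")),
  EFxEG = list(mother = c("e", "f"), father = c("e", "g")),
  HKxHK = list(mother = c("h", "k"), father = c("h", "k")),
  LMxLL = list(mother = c("l", "m"), father = c("l", "l")),
  NNxNP = list(mother = c("n", "n"), father = c("n", "p"))
)

#' Simulate a true genetic map
#'
#' Places `loci_per_lg` loci uniformly at random on each linkage group and
#' shifts each group so its first locus sits at 0 cM.
#'
#' @param n_lg number of linkage groups (>= 1).
#' @param lengths_cM linkage-group lengths in cM (recycled to `n_lg`);
#'   must be positive.
#' @param loci_per_lg number of loci per linkage group.
#' @param seed integer seed; the same seed reproduces the same map.
#' @return a data.frame of class `true_map` with columns `locus_id`, `lg`
#'   (integer), `cM` (non-decreasing within each LG, starting at 0), and
#'   attribute `lengths_cM`.
#' @export
simulate_true_map <- function(n_lg, lengths_cM, loci_per_lg, seed = 1L) {
  stopifnot(n_lg >= 1, loci_per_lg >= 1)
  lengths_cM <- rep_len(lengths_cM, n_lg)
  if (any(lengths_cM <= 0)) stop("linkage-group lengths must be positive")
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_lg), function(g) {
    pos <- sort(stats::runif(loci_per_lg, 0, lengths_cM[g]))
    pos <- pos - pos[1]
    data.frame(locus_id = sprintf("L%02d_%03d", g, seq_len(loci_per_lg)),
               lg = g, cM = pos)
  }))
  rownames(out) <- NULL
  attr(out, "lengths_cM") <- lengths_cM
  class(out) <- c("true_map", "data.frame")
  out
}

# one gamete per LG: crossover count ~ Poisson(length/100), breakpoints
# uniform, strand alternates from a random start. Returns the transmitted
# haplotype index (1/2) at each locus position.
sim_gamete <- function(pos_cM, length_cM) {
  k <- stats::rpois(1L, length_cM / 100)
  start <- sample(1:2, 1L)
  if (k == 0) return(list(strand = rep(start, length(pos_cM)), breakpoints = numeric(0)))
  bp <- sort(stats::runif(k, 0, length_cM))
  flips <- vapply(pos_cM, function(p) sum(bp < p), integer(1))
  list(strand = 1L + (start - 1L + flips) %% 2L, breakpoints = bp)
}

#' Simulate a full-sib family from a true map
#'
#' Each offspring receives one recombinant gamete per parent and linkage
#' group; crossovers per meiosis follow a Poisson process with mean equal
#' to the LG length in Morgans (no interference). Each locus is assigned a
#' CP segregation type from `seg_type_mix`; the parental linkage phase
#' (which allele sits on which haplotype) is randomized per locus.
#' Genotyping errors re-draw the call uniformly among the *other* genotype
#' classes possible for that segregation type; missingness is applied
#' independently per call. The pre-noise truth is returned alongside.
#'
#' @param truth a [simulate_true_map()] result.
#' @param n_offspring number of offspring (> 0).
#' @param seg_type_mix named proportions over [CP_SEG_TYPES] (sum to 1).
#' @param error_rate per-call probability of a genotyping error.
#' @param missing_rate per-call probability of a missing call.
#' @param seed integer seed.
#' @param family_id family label.
#' @return list with `geno` (an [fs_geno()]) and `truth`: a list holding
#'   `true_map`, `seg_type`, `phase` (per parent, the allele carried on
#'   each haplotype per locus), `transmission` (per parent, loci x
#'   offspring matrix of transmitted haplotype index), `breakpoints`
#'   (per parent, per offspring, per LG crossover positions in cM), and
#'   `true_calls` (pre-error, pre-missingness call matrix).
#' @export
simulate_family <- function(truth, n_offspring, seg_type_mix = default_seg_mix,
                            error_rate = 0.005, missing_rate = 0.05,
                            seed = 1L, family_id = "FamA") {
  stopifnot(inherits(truth, "true_map"))
  if (n_offspring <= 0) stop("n_offspring must be positive")
  seg_type_mix <- seg_type_mix[CP_SEG_TYPES]
  seg_type_mix[is.na(seg_type_mix)] <- 0
  names(seg_type_mix) <- CP_SEG_TYPES
  if (abs(sum(seg_type_mix) - 1) > 1e-8) stop("seg_type_mix must sum to 1")
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must be in [0, 1]")
  set.seed(seed)

  n_loci <- nrow(truth)
  lengths <- attr(truth, "lengths_cM")
  seg_type <- sample(CP_SEG_TYPES, n_loci, replace = TRUE, prob = seg_type_mix)
  off_ids <- sprintf("%s_O%03d", family_id, seq_len(n_offspring))

  # phase: row i gives the allele carried on haplotype 1 and 2 at locus i
  phase <- list(mother = matrix(NA_character_, n_loci, 2),
                father = matrix(NA_character_, n_loci, 2))
  for (i in seq_len(n_loci)) {
    par <- seg_type_parents[[seg_type[i]]]
    phase$mother[i, ] <- sample(par$mother)
    phase$father[i, ] <- sample(par$father)
  }

  transmission <- list(
    mother = matrix(NA_integer_, n_loci, n_offspring,
                    dimnames = list(truth$locus_id, off_ids)),
    father = matrix(NA_integer_, n_loci, n_offspring,
                    dimnames = list(truth$locus_id, off_ids)))
  breakpoints <- list(mother = vector("list", n_offspring),
                      father = vector("list", n_offspring))
  lgs <- unique(truth$lg)
  for (o in seq_len(n_offspring)) {
    for (p in c("mother", "father")) {
      bps <- vector("list", length(lgs))
      for (gi in seq_along(lgs)) {
        idx <- which(truth$lg == lgs[gi])
        gam <- sim_gamete(truth$cM[idx], lengths[lgs[gi]])
        transmission[[p]][idx, o] <- gam$strand
        bps[[gi]] <- gam$breakpoints
      }
      names(bps) <- as.character(lgs)
      breakpoints[[p]][[o]] <- bps
    }
  }

  # true calls from transmitted alleles
  true_calls <- matrix(NA_character_, n_loci, n_offspring,
                       dimnames = list(truth$locus_id, off_ids))
  for (i in seq_len(n_loci)) {
    am <- phase$mother[i, transmission$mother[i, ]]
    af <- phase$father[i, transmission$father[i, ]]
    true_calls[i, ] <- geno_str(am, af)
  }

  # noise: error re-draw among the other possible classes, then missingness
  calls <- true_calls
  class_sets <- lapply(CP_SEG_TYPES, function(tp) {
    par <- seg_type_parents[[tp]]
    sort(unique(geno_str(rep(par$mother, each = 2), rep(par$father, 2))))
  })
  names(class_sets) <- CP_SEG_TYPES
  err <- matrix(stats::runif(n_loci * n_offspring) < error_rate, n_loci, n_offspring)
  for (i in seq_len(n_loci)) {
    cls <- class_sets[[seg_type[i]]]
    for (o in which(err[i, ])) {
      others <- setdiff(cls, calls[i, o])
      calls[i, o] <- if (length(others) == 1) others else sample(others, 1L)
    }
  }
  calls[matrix(stats::runif(n_loci * n_offspring) < missing_rate,
               n_loci, n_offspring)] <- NA_character_

  loci <- data.frame(
    locus_id = truth$locus_id,
    contig_id = truth$locus_id,
    seg_type = seg_type,
    mother = geno_str(seg_type_parents_m1(seg_type), seg_type_parents_m2(seg_type)),
    father = geno_str(seg_type_parents_f1(seg_type), seg_type_parents_f2(seg_type)))
  geno <- fs_geno(loci, calls, family_id)
  list(geno = geno,
       truth = list(true_map = truth, seg_type = seg_type, phase = phase,
                    transmission = transmission, breakpoints = breakpoints,
                    true_calls = true_calls, n_errors = sum(err)))
}

seg_type_parents_m1 <- function(tp) vapply(tp, function(t) seg_type_parents[[t]]$mother[1], "")
seg_type_parents_m2 <- function(tp) vapply(tp, function(t) seg_type_parents[[t]]$mother[2], "")
seg_type_parents_f1 <- function(tp) vapply(tp, function(t) seg_type_parents[[t]]$father[1], "")
seg_type_parents_f2 <- function(tp) vapply(tp, function(t) seg_type_parents[[t]]$father[2], "")

# decompose a cM-sorted anchor table into maximal monotone runs:
# a run extends while the chromosome is unchanged and the bp difference
# keeps the run's sign; a boundary locus that still continues the previous
# trend stays with the earlier run. Used both to derive truth here and,
# with the tolerance rule added, by the synteny block finder.
monotone_runs <- function(chrom, bp) {
  n <- length(chrom)
  run_id <- integer(n)
  cur <- 1L; dir <- 0L
  run_id[1] <- 1L
  if (n > 1) for (i in 2:n) {
    new_run <- FALSE
    if (chrom[i] != chrom[i - 1L]) {
      new_run <- TRUE
    } else {
      d <- sign(bp[i] - bp[i - 1L])
      if (dir == 0L) dir <- d
      else if (d != 0L && d != dir) new_run <- TRUE
    }
    if (new_run) { cur <- cur + 1L; dir <- 0L }
    run_id[i] <- cur
  }
  run_id
}

#' Simulate comparison-genome anchors for a true map
#'
#' Gives every locus a chromosome and bp position collinear with its cM
#' position (1-based, `bp_per_cM` scale), then applies the requested
#' rearrangement events: an inversion reverses bp order within a cM
#' interval of one LG; a translocation moves the loci of an interval onto
#' another chromosome, beyond that chromosome's native span. The true
#' syntenic blocks implied by the construction (maximal monotone runs of
#' at least `min_block` loci) are returned together with a
#' similarity-hit table in the 12-column tabular dialect.
#'
#' @param truth a [simulate_true_map()] result.
#' @param events list of events, each a list with `type`
#'   (`"inversion"`/`"translocation"`), `lg`, `start`, `end` (cM interval,
#'   inside the LG) and for translocations `target_chrom` (LG index whose
#'   chromosome receives the interval). Intervals on the same LG must not
#'   overlap.
#' @param bp_per_cM physical scale (bp per cM, > 0; default 3e5, a typical
#'   teleost ratio).
#' @param genome_id label used in the returned tables.
#' @param min_block minimum run size counted as a true block (default 2).
#' @return list with `hits` (12-column data.frame: `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`), `anchors` (truth:
#'   `locus_id`, `chrom`, `bp`), and `true_blocks` (data.frame
#'   `block_id`, `lg`, `chrom`, `n_loci`, `members` list-column).
#' @export
simulate_genome_anchors <- function(truth, events = list(), bp_per_cM = 3e5,
                                    genome_id = "genomeA", min_block = 2L) {
  stopifnot(inherits(truth, "true_map"))
  if (bp_per_cM <= 0) stop("bp_per_cM must be positive")
  lengths <- attr(truth, "lengths_cM")
  # validate events
  if (length(events)) {
    ev_lg <- vapply(events, `[[`, 0, "lg")
    for (g in unique(ev_lg)) {
      iv <- do.call(rbind, lapply(events[ev_lg == g], function(e) {
        if (e$start >= e$end) stop("event interval must have start < end")
        if (e$start < 0 || e$end > lengths[g])
          stop("event interval outside its linkage group")
        c(e$start, e$end)
      }))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("overlapping rearrangement events on LG ", g)
    }
  }

  chrom_of <- function(lg) sprintf("chr%02d", lg)
  chrom <- chrom_of(truth$lg)
  bp <- 1 + round(truth$cM * bp_per_cM)
  for (e in events) {
    in_ev <- truth$lg == e$lg & truth$cM >= e$start & truth$cM <= e$end
    lo <- 1 + round(e$start * bp_per_cM); hi <- 1 + round(e$end * bp_per_cM)
    if (e$type == "inversion") {
      bp[in_ev] <- lo + hi - bp[in_ev]
    } else if (e$type == "translocation") {
      tgt <- e$target_chrom
      offset <- 1 + round(lengths[tgt] * bp_per_cM) + 1e6
      chrom[in_ev] <- chrom_of(tgt)
      bp[in_ev] <- offset + (bp[in_ev] - lo)
    } else stop("unknown event type: ", e$type)
  }
  anchors <- data.frame(locus_id = truth$locus_id, chrom = chrom, bp = bp)

  # true blocks by construction: per LG in cM order, maximal monotone runs
  tb <- list()
  for (g in unique(truth$lg)) {
    idx <- which(truth$lg == g)
    idx <- idx[order(truth$cM[idx])]
    runs <- monotone_runs(chrom[idx], bp[idx])
    for (r in unique(runs)) {
      mem <- truth$locus_id[idx[runs == r]]
      if (length(mem) >= min_block)
        tb[[length(tb) + 1L]] <- data.frame(
          lg = g, chrom = chrom[idx[runs == r][1]], n_loci = length(mem),
          members = I(list(mem)))
    }
  }
  true_blocks <- if (length(tb)) do.call(rbind, tb) else
    data.frame(lg = integer(0), chrom = character(0), n_loci = integer(0),
               members = I(list()))
  if (nrow(true_blocks)) true_blocks$block_id <- seq_len(nrow(true_blocks))

  hits <- data.frame(
    qseqid = truth$locus_id, sseqid = chrom, pident = 100, length = 1L,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
    sstart = bp, send = bp, evalue = 1e-180, bitscore = 300)
  list(hits = hits, anchors = anchors, true_blocks = true_blocks,
       genome_id = genome_id)
}

#' Simulate external features with known placements
#'
#' Inside-features are dropped strictly between two adjacent anchored loci
#' of a true block; their true map position is the linear interpolation of
#' the flanks' cM by bp fraction. Outside-features are placed on
#' chromosome regions far beyond any anchored locus, so they cannot fall
#' into a block.
#'
#' @param sim a [simulate_genome_anchors()] result.
#' @param truth the [simulate_true_map()] used to build `sim`.
#' @param n_inside,n_outside feature counts.
#' @param seed integer seed.
#' @return list with `hits` (12-column feature hit table) and
#'   `placements` (truth: `feature_id`, `lg`, `cM`; inside features only).
#' @export
simulate_external_features <- function(sim, truth, n_inside, n_outside,
                                       seed = 1L) {
  set.seed(seed)
  blocks <- sim$true_blocks
  if (n_inside > 0 && nrow(blocks) == 0)
    stop("need at least one true block to place inside-features")
  anchors <- sim$anchors
  rownames(anchors) <- anchors$locus_id
  pos <- stats::setNames(truth$cM, truth$locus_id)
  lg_of <- stats::setNames(truth$lg, truth$locus_id)

  rows <- list(); tru <- list()
  if (n_inside > 0) {
    bi <- sample(seq_len(nrow(blocks)), n_inside, replace = TRUE)
    for (k in seq_len(n_inside)) {
      mem <- blocks$members[[bi[k]]]
      mem <- mem[order(pos[mem])]
      j <- if (length(mem) == 2) 1L else sample(length(mem) - 1L, 1L)
      a <- mem[j]; b <- mem[j + 1L]
      b1 <- anchors[a, "bp"]; b2 <- anchors[b, "bp"]
      lo <- min(b1, b2); hi <- max(b1, b2)
      if (hi - lo < 2) { fb <- lo } else fb <- lo + sample(hi - lo - 1L, 1L)
      frac <- if (b2 == b1) 0 else (fb - b1) / (b2 - b1)
      cm <- pos[a] + frac * (pos[b] - pos[a])
      id <- sprintf("FTI%03d", k)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = id, sseqid = anchors[a, "chrom"], pident = 100, length = 1L,
        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
        sstart = fb, send = fb, evalue = 1e-150, bitscore = 280)
      tru[[length(tru) + 1L]] <- data.frame(feature_id = id,
                                            lg = unname(lg_of[a]), cM = unname(cm))
    }
  }
  if (n_outside > 0) {
    chroms <- unique(anchors$chrom)
    far <- max(anchors$bp) + 5e7
    for (k in seq_len(n_outside)) {
      id <- sprintf("FTO%03d", k)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = id, sseqid = sample(chroms, 1L), pident = 100, length = 1L,
        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
        sstart = far + k * 1000L, send = far + k * 1000L,
        evalue = 1e-150, bitscore = 280)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qseqid = character(0))
  placements <- if (length(tru)) do.call(rbind, tru) else
    data.frame(feature_id = character(0), lg = integer(0), cM = numeric(0))
  list(hits = hits, placements = placements)
}
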
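mk_hit <- function(q, s, sstart, send = sstart, bits = 200, ev = 1e-30) {
  data.frame(qseqid = q, sseqid = s, pident = 100, length = 150, mismatch = 0,
             gapopen = 0, qstart = 1, qend = 150, sstart = sstart, send = send,
             evalue = ev, bitscore = bits)
}

simple_map <- function(n = 6, lg = "LG01", step = 10) {
  as_genetic_map(data.frame(locus_id = sprintf("%s_L%02d", lg, 1:n), lg = lg,
                            position_cM = step * (0:(n - 1))))
}

test_that("anchor assignment enforces uniqueness and the bitscore margin", {
  map <- simple_map()
  h1 <- mk_hit(map$locus_id[1], "chr1", 100)
  expect_equal(nrow(assign_anchors(h1, map)), 1)

  # two equal-bitscore hits on different chromosomes: ambiguous
  h2 <- rbind(mk_hit(map$locus_id[2], "chr1", 500, bits = 200),
              mk_hit(map$locus_id[2], "chr2", 900, bits = 200))
  expect_equal(nrow(assign_anchors(h2, map)), 0)

  # 200 vs 150 bits: margin 0.25 > 0.1, anchored to the best
  h3 <- rbind(mk_hit(map$locus_id[3], "chr1", 500, bits = 200),
              mk_hit(map$locus_id[3], "chr2", 900, bits = 150))
  a3 <- assign_anchors(h3, map)
  expect_equal(a3$chrom, "chr1")

  # weak e-value rejected
  h4 <- mk_hit(map$locus_id[4], "chr1", 100, ev = 1e-5)
  expect_equal(nrow(assign_anchors(h4, map)), 0)
})

test_that("block detection handles collinearity, interruptions and tolerance", {
  map <- simple_map(5)
  # 5 collinear loci: one block of 5
  anch <- assign_anchors(do.call(rbind, lapply(1:5, function(i)
    mk_hit(map$locus_id[i], "chr1", i * 1e5))), map)
  fb <- find_blocks(map, anch, tolerance_frac = 0)
  expect_equal(nrow(fb$blocks), 1)
  expect_equal(fb$blocks$n_loci, 5)
  expect_equal(fb$blocks$orientation, "+")

  # middle locus on another chromosome: two blocks of 2 around it
  hits2 <- do.call(rbind, lapply(1:5, function(i)
    mk_hit(map$locus_id[i], if (i == 3) "chr9" else "chr1", i * 1e5)))
  fb2 <- find_blocks(map, assign_anchors(hits2, map), tolerance_frac = 0)
  expect_equal(fb2$blocks$n_loci, c(2, 2))

  # adjacent pair swapped in bp, 2% of LG length apart: block survives at
  # the 5% tolerance and splits at tolerance 0
  map3 <- as_genetic_map(data.frame(locus_id = sprintf("L%d", 1:5), lg = "LG01",
                                    position_cM = c(0, 30, 50, 52, 100)))
  bp <- c(1e5, 2e5, 3.1e5, 3.0e5, 4e5)  # loci 3 and 4 swapped
  hits3 <- do.call(rbind, lapply(1:5, function(i)
    mk_hit(map3$locus_id[i], "chr1", bp[i])))
  an3 <- assign_anchors(hits3, map3)
  expect_equal(nrow(find_blocks(map3, an3, tolerance_frac = 0.05)$blocks), 1)
  expect_gt(nrow(find_blocks(map3, an3, tolerance_frac = 0)$blocks), 1)

  # reversed run is a minus-orientation block
  hits4 <- do.call(rbind, lapply(1:5, function(i)
    mk_hit(map$locus_id[i], "chr1", (6 - i) * 1e5)))
  fb4 <- find_blocks(map, assign_anchors(hits4, map), tolerance_frac = 0)
  expect_equal(fb4$blocks$orientation, "-")
})

test_that("simulated rearrangements are recovered exactly at tolerance zero", {
  tm <- simulate_true_map(3, c(90, 80, 100), 15, seed = 101)
  ev <- list(list(type = "inversion", lg = 1, start = 30, end = 60),
             list(type = "translocation", lg = 3, start = 10, end = 45,
                  target_chrom = 2))
  sim <- simulate_genome_anchors(tm, ev, genome_id = "gX")
  map <- map_from_truth(tm)
  anch <- assign_anchors(sim$hits, map, "gX")
  fb <- find_blocks(map, anch, tolerance_frac = 0)
  truth_sets <- sort(vapply(sim$true_blocks$members,
                            function(m) paste(sort(m), collapse = ","), ""))
  found_sets <- sort(vapply(split(fb$members$locus_id, fb$members$block_id),
                            function(m) paste(sort(m), collapse = ","), ""))
  expect_identical(unname(found_sets), unname(truth_sets))  # precision = recall = 1
})

test_that("block statistics implement the stated arithmetic", {
  map <- simple_map(6)
  blocks <- data.frame(block_id = 1:2, genome_id = "g", lg = "LG01",
                       chrom = "chr1", n_loci = c(3, 2),
                       cm_start = c(0, 30), cm_end = c(20, 40),
                       bp_start = c(1, 2e6), bp_end = c(1e6, 3e6),
                       orientation = "+")
  st <- block_stats(blocks, map)
  expect_equal(st$n_blocks, 2)
  expect_equal(st$n_loci, 5)
  expect_equal(st$avg_loci_per_block, 2.5)
  expect_equal(st$total_cm, 30)
  expect_equal(st$prop_covered_pct, 100 * 30 / 50)

  # overlap merging: two overlapping blocks only count their union
  blocks2 <- blocks
  blocks2$cm_start <- c(0, 10); blocks2$cm_end <- c(20, 30)
  expect_equal(block_stats(blocks2, map)$prop_covered_pct, 100 * 30 / 50)
  expect_equal(block_stats(blocks[0, ], map)$n_blocks, 0)

  # published-table arithmetic from totals
  t2 <- block_stats_from_totals(511, 1900, 287.52, 750.5, 1605.43)
  expect_equal(round(t2$avg_loci_per_block, 1), 3.7)
  expect_equal(round(t2$prop_covered_pct, 1), 46.7)
})

test_that("features place by interpolation, with degenerate and outside cases", {
  map <- as_genetic_map(data.frame(locus_id = c("A", "B"), lg = "LG01",
                                   position_cM = c(10, 20)))
  hits <- rbind(mk_hit("A", "chr1", 1000), mk_hit("B", "chr1", 3000))
  anch <- assign_anchors(hits, map)
  fb <- find_blocks(map, anch, tolerance_frac = 0)
  # midway in bp between flanks at 10 and 20 cM -> 15 cM
  pl <- place_features(mk_hit("F1", "chr1", 2000), fb, map)
  expect_true(pl$placed)
  expect_equal(pl$cM, 15)
  # at a member locus's exact bp -> that locus's cM
  pl2 <- place_features(mk_hit("F2", "chr1", 1000), fb, map)
  expect_equal(pl2$cM, 10)
  # outside every block -> unplaced with a reason
  pl3 <- place_features(mk_hit("F3", "chr1", 9e6), fb, map)
  expect_false(pl3$placed)
  expect_equal(pl3$reason, "outside_blocks")
})

test_that("placement clustering groups by gap threshold", {
  pl <- data.frame(feature_id = sprintf("F%d", 1:6), genome_id = "g",
                   block_id = 1, lg = "LG01",
                   cM = c(5, 5, 5, 40, 90, 90.5),
                   flank_lo = "A", flank_hi = "B", evalue = 1e-30,
                   placed = TRUE, reason = NA)
  cl <- cluster_placements(pl, max_gap_cM = 1)
  sizes <- sort(as.integer(table(cl$cluster)))
  expect_equal(sizes, c(1, 2, 3))
  # far apart under a tight threshold: all separate
  cl2 <- cluster_placements(pl[4:5, ], max_gap_cM = 1)
  expect_equal(length(unique(cl2$cluster)), 2)
})
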
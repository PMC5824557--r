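test_that("simulated true maps are sorted, start at zero and are seed-deterministic", {
  tm <- simulate_true_map(1, 100, 11, seed = 1)
  expect_equal(nrow(tm), 11)
  expect_true(all(diff(tm$cM) >= 0))
  expect_identical(tm$cM[1], 0)
  expect_true(all(tm$cM <= 100))

  big <- simulate_true_map(24, 66.9, 119, seed = 2)
  expect_equal(nrow(big), 24 * 119)
  expect_equal(sum(attr(big, "lengths_cM")), 1605.6)
  expect_false(anyDuplicated(big$locus_id) > 0)

  expect_identical(simulate_true_map(4, c(50, 60, 70, 80), 9, seed = 7),
                   simulate_true_map(4, c(50, 60, 70, 80), 9, seed = 7))
  expect_error(simulate_true_map(2, c(100, -5), 10), "positive")
})

test_that("co-located loci never recombine and rates validate", {
  tm <- simulate_true_map(1, 100, 2, seed = 3)
  tm$cM <- c(20, 20)  # identical position
  fam <- simulate_family(tm, 200, error_rate = 0, missing_rate = 0, seed = 4)
  tr <- fam$truth$transmission
  expect_true(all(tr$mother[1, ] == tr$mother[2, ]))
  expect_true(all(tr$father[1, ] == tr$father[2, ]))
  expect_error(simulate_family(tm, 0), "positive")
  expect_error(simulate_family(tm, 10, error_rate = 1.5), "rates")
})

test_that("crossover process matches the Haldane inverse at 50 cM", {
  tm <- simulate_true_map(1, 100, 2, seed = 5)
  tm$cM <- c(10, 60)  # 50 cM apart
  fam <- simulate_family(tm, 5000, error_rate = 0, missing_rate = 0, seed = 6)
  tr <- fam$truth$transmission
  rec <- c(tr$mother[1, ] != tr$mother[2, ], tr$father[1, ] != tr$father[2, ])
  expect_equal(length(rec), 10000)
  expect_equal(mean(rec), (1 - exp(-1)) / 2, tolerance = 0.01 / 0.316)
})

test_that("genotyping errors follow the per-call binomial model", {
  tm <- simulate_true_map(1, 50, 10, seed = 7)
  fam <- simulate_family(tm, 100, error_rate = 0.01, missing_rate = 0, seed = 8)
  n_calls <- length(fam$truth$true_calls)
  flips <- sum(fam$geno$calls != fam$truth$true_calls)
  expect_equal(flips, fam$truth$n_errors)
  interval <- qbinom(c(0.005, 0.995), n_calls, 0.01)
  expect_gte(flips, interval[1])
  expect_lte(flips, interval[2])
})

test_that("fixed seeds reproduce families exactly", {
  tm <- simulate_true_map(2, c(60, 70), 8, seed = 9)
  f1 <- simulate_family(tm, 30, seed = 10)
  f2 <- simulate_family(tm, 30, seed = 10)
  expect_identical(f1$geno$calls, f2$geno$calls)
  expect_identical(f1$truth$transmission, f2$truth$transmission)
})

test_that("anchor simulation yields one block per LG without events", {
  tm <- simulate_true_map(3, c(60, 70, 80), 10, seed = 11)
  sim <- simulate_genome_anchors(tm)
  expect_equal(nrow(sim$true_blocks), 3)
  expect_equal(sim$true_blocks$n_loci, c(10, 10, 10))
  expect_equal(nrow(sim$hits), 30)
})

test_that("an interior inversion yields prefix, inverted run and suffix", {
  tm <- simulate_true_map(1, 100, 11, seed = 12)
  tm$cM <- seq(0, 100, by = 10)  # deterministic spacing
  ev <- list(list(type = "inversion", lg = 1, start = 25, end = 65))  # 5 loci
  sim <- simulate_genome_anchors(tm, ev)
  expect_equal(nrow(sim$true_blocks), 3)
  expect_equal(sum(sim$true_blocks$n_loci), 11)
})

test_that("translocated loci move off-chromosome; the rest stay collinear", {
  tm <- simulate_true_map(2, c(100, 100), 20, seed = 13)
  tm$cM <- rep(seq(0, 95, by = 5), 2)
  ev <- list(list(type = "translocation", lg = 1, start = 22, end = 68,
                  target_chrom = 2))  # 9 loci at 25, 30, ..., 65
  sim <- simulate_genome_anchors(tm, ev)
  moved <- sim$anchors$chrom[match(tm$locus_id[tm$lg == 1 & tm$cM >= 22 &
                                                 tm$cM <= 68], sim$anchors$locus_id)]
  expect_true(all(moved == "chr02"))
  expect_equal(sum(moved == "chr02"), 9)
  rest <- sim$anchors[sim$anchors$locus_id %in%
                        tm$locus_id[tm$lg == 1 & (tm$cM < 22 | tm$cM > 68)], ]
  expect_true(all(diff(rest$bp[order(rest$bp)]) > 0))
  expect_error(
    simulate_genome_anchors(tm, list(
      list(type = "inversion", lg = 1, start = 10, end = 40),
      list(type = "inversion", lg = 1, start = 30, end = 60))),
    "overlapping")
})

test_that("external features interpolate linearly between their flanks", {
  tm <- simulate_true_map(1, 100, 6, seed = 14)
  tm$cM <- c(0, 10, 20, 30, 40, 50)
  sim <- simulate_genome_anchors(tm)
  ft <- simulate_external_features(sim, tm, n_inside = 5, n_outside = 0, seed = 15)
  expect_equal(nrow(ft$placements), 5)
  expect_true(all(!is.na(ft$placements$cM)))
  # hand check: a feature at the bp midpoint of flanks at 10 and 20 cM
  a <- sim$anchors$bp[2]; b <- sim$anchors$bp[3]
  mid <- (a + b) / 2
  frac <- (mid - a) / (b - a)
  expect_equal(10 + frac * 10, 15)
  ft0 <- simulate_external_features(sim, tm, n_inside = 0, n_outside = 5, seed = 16)
  expect_equal(nrow(ft0$placements), 0)
  expect_equal(nrow(ft0$hits), 5)
})
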
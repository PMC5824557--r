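test_that("grouping applies the LOD/rf thresholds with transitive closure", {
  tp <- data.frame(a = c("A", "B", "A", "D"), b = c("B", "C", "C", "E"),
                   rf = c(0.20, 0.10, 0.45, 0.36), lod = c(10, 8, 1, 20))
  gr <- group_loci(tp, c("A", "B", "C", "D", "E", "F"),
                   min_lod = 6, max_rf = 0.35)
  # A-B and B-C pass; A-C fails directly but joins transitively;
  # D-E fails on rf; F is a singleton
  expect_equal(gr[[1]], c("A", "B", "C"))
  expect_equal(lengths(gr[-1]), c(1, 1, 1), ignore_attr = TRUE)
})

test_that("three well-spaced loci are ordered correctly", {
  set.seed(61)
  tm <- simulate_true_map(1, 20, 3, seed = 61)
  tm$cM <- c(0, 10, 20)
  fam <- simulate_family(tm, 200, error_rate = 0, missing_rate = 0, seed = 62,
                         seg_type_mix = c(ABxCD = 1, EFxEG = 0, HKxHK = 0,
                                          LMxLL = 0, NNxNP = 0))
  tp <- two_point_all(fam$geno)
  cache <- tp_cache(tp, tm$locus_id)
  ord <- order_group(tm$locus_id, cache)
  expect_true(identical(ord, tm$locus_id) || identical(ord, rev(tm$locus_id)))
})

test_that("the objective is reversal-symmetric and orientation is fixed by id", {
  tm <- simulate_true_map(1, 50, 8, seed = 63)
  fam <- simulate_family(tm, 100, error_rate = 0, missing_rate = 0, seed = 64)
  tp <- two_point_all(fam$geno)
  cache <- tp_cache(tp, tm$locus_id)
  ord <- order_group(tm$locus_id, cache)
  o1 <- sibmap:::order_objective(ord, cache)
  o2 <- sibmap:::order_objective(rev(ord), cache)
  expect_equal(o1, o2)
  expect_true(ord[1] < ord[length(ord)])
})

test_that("ripple leaves a locally optimal order unchanged", {
  tm <- simulate_true_map(1, 60, 6, seed = 65)
  fam <- simulate_family(tm, 150, error_rate = 0, missing_rate = 0, seed = 66,
                         seg_type_mix = c(ABxCD = 1, EFxEG = 0, HKxHK = 0,
                                          LMxLL = 0, NNxNP = 0))
  tp <- two_point_all(fam$geno)
  cache <- tp_cache(tp, tm$locus_id)
  ord <- order_group(tm$locus_id, cache)
  expect_identical(ripple_order(ord, cache), ord)
})

test_that("positions accumulate mapping-function distances from zero", {
  expect_equal(compute_positions(c("A", "B"), 0, "kosambi"), c(0, 0))
  expect_equal(compute_positions(c("A", "B", "C"), c(0.25, 0.25), "kosambi"),
               c(0, 25 * log(3), 50 * log(3)))
  expect_equal(compute_positions(c("A", "B"), 0.25, "haldane"),
               c(0, -50 * log(0.5)))
  expect_error(compute_positions(c("A", "B"), 0.5), "ordering failure")
})

test_that("excess-crossover individuals are flagged and tight doubles masked", {
  tm <- simulate_true_map(1, 60, 15, seed = 67)
  tm$cM <- seq(0, 14, by = 1)
  fam <- simulate_family(tm, 80, error_rate = 0, missing_rate = 0, seed = 68,
                         seg_type_mix = c(ABxCD = 1, EFxEG = 0, HKxHK = 0,
                                          LMxLL = 0, NNxNP = 0))
  g <- fam$geno
  # corrupt one individual: random calls at every locus (many crossovers)
  set.seed(69)
  info <- classify_segregation("a/b", "c/d")
  g$calls[, 5] <- sample(info$classes, 15, replace = TRUE)
  # plant one isolated flipped call in a tight window (double crossover)
  true_call <- g$calls[8, 10]
  g$calls[8, 10] <- setdiff(info$classes, true_call)[1]
  tp <- two_point_all(g)
  cache <- tp_cache(tp, tm$locus_id)
  ord <- order_group(tm$locus_id, cache)
  cl <- clean_order(g, ord, tp, cache, tight_cM = 8)
  expect_true(colnames(g$calls)[5] %in% cl$removed_individuals)
  expect_gte(cl$masked, 1)
  expect_true(is.na(cl$geno$calls[g$loci$locus_id[8], colnames(g$calls)[10]]))
})

test_that("clean simulated data pass cleaning untouched", {
  tm <- simulate_true_map(1, 30, 8, seed = 70)
  tm$cM <- seq(0, 28, by = 4)
  fam <- simulate_family(tm, 100, error_rate = 0, missing_rate = 0, seed = 71,
                         seg_type_mix = c(ABxCD = 1, EFxEG = 0, HKxHK = 0,
                                          LMxLL = 0, NNxNP = 0))
  tp <- two_point_all(fam$geno)
  cache <- tp_cache(tp, tm$locus_id)
  ord <- order_group(tm$locus_id, cache)
  cl <- clean_order(fam$geno, ord, tp, cache)
  expect_length(cl$removed_loci, 0)
  expect_length(cl$removed_individuals, 0)
})
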
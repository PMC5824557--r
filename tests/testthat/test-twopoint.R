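# closed-form checks, EM invariants, and agreement with the allele-level
# grid-search oracle

test_that("phase-known fully informative pairs hit the closed forms", {
  # 50 offspring x 2 parents = 100 meioses, no recombinants
  tm0 <- matrix(rep(sample(1:2, 50, replace = TRUE), 2), 2, 50, byrow = TRUE)
  tf0 <- matrix(rep(sample(1:2, 50, replace = TRUE), 2), 2, 50, byrow = TRUE)
  g <- geno_from_transmissions(c("ABxCD", "ABxCD"), tm0, tf0)
  tp <- estimate_two_point(g, 1, 2)
  expect_equal(tp$rf, 0)
  expect_equal(tp$lod, 100 * log10(2), tolerance = 1e-6)
  expect_equal(tp$n_informative, 100)
  expect_equal(unname(tp$phase["mother"]), "coupling")

  # mother-only pair, 100 meioses, 25 recombinants: rf = 0.25 exactly
  set.seed(1)
  t1 <- sample(1:2, 100, replace = TRUE)
  t2 <- t1
  flip <- sample(100, 25)
  t2[flip] <- 3L - t2[flip]
  g2 <- geno_from_transmissions(c("LMxLL", "LMxLL"),
                                rbind(t1, t2),
                                matrix(1L, 2, 100))
  tp2 <- estimate_two_point(g2, 1, 2)
  expect_equal(tp2$rf, 0.25, tolerance = 1e-9)
  expect_equal(tp2$lod, 25 * log10(0.25) + 75 * log10(0.75) + 100 * log10(2),
               tolerance = 1e-6)
  expect_equal(tp2$n_informative, 100)
})

test_that("independent loci give rf near 0.5 and LOD near 0", {
  set.seed(2)
  t1 <- sample(1:2, 400, replace = TRUE)
  t2 <- sample(1:2, 400, replace = TRUE)
  f1 <- sample(1:2, 400, replace = TRUE)
  f2 <- sample(1:2, 400, replace = TRUE)
  g <- geno_from_transmissions(c("ABxCD", "ABxCD"), rbind(t1, t2), rbind(f1, f2))
  tp <- estimate_two_point(g, 1, 2)
  expect_gt(tp$rf, 0.45)
  expect_lt(tp$lod, 1)
})

test_that("rf stays in [0, 0.5] and LOD is never negative", {
  tm <- simulate_true_map(1, 80, 12, seed = 51)
  fam <- simulate_family(tm, 60, error_rate = 0.01, missing_rate = 0.1, seed = 52)
  tp <- two_point_all(fam$geno)
  expect_true(all(tp$rf >= 0 & tp$rf <= 0.5))
  expect_true(all(tp$lod >= 0))
})

test_that("phase is recovered for a repulsion-linked pair", {
  set.seed(3)
  t1 <- sample(1:2, 200, replace = TRUE)
  t2 <- 3L - t1                      # perfect repulsion in the mother
  flip <- sample(200, 10)            # 5% recombination
  t2[flip] <- 3L - t2[flip]
  g <- geno_from_transmissions(c("LMxLL", "LMxLL"), rbind(t1, t2),
                               matrix(1L, 2, 200))
  tp <- estimate_two_point(g, 1, 2)
  expect_equal(unname(tp$phase["mother"]), "repulsion")
  expect_equal(tp$rf, 0.05, tolerance = 1e-6)
})

test_that("pairs with no jointly informative parent are undefined", {
  g <- geno_from_transmissions(c("LMxLL", "NNxNP"),
                               rbind(sample(1:2, 30, TRUE), rep(1L, 30)),
                               rbind(rep(1L, 30), sample(1:2, 30, TRUE)))
  expect_null(estimate_two_point(g, 1, 2))
})

test_that("EM agrees with the allele-level grid oracle on random pairs", {
  # a smaller batch here; the full 200-pair sweep lives in test-acceptance.R
  tm <- simulate_true_map(1, 100, 12, seed = 53)
  fam <- simulate_family(tm, 80, error_rate = 0.01, missing_rate = 0.05, seed = 54)
  g <- fam$geno
  info <- lapply(seq_len(12), function(i)
    classify_segregation(g$loci$mother[i], g$loci$father[i]))
  set.seed(55)
  pairs <- t(replicate(25, sample(12, 2)))
  checked <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!info[[i]]$informative || !info[[j]]$informative) next
    tp <- tryCatch(estimate_two_point(g, i, j), error = function(e) NULL)
    if (is.null(tp)) next
    ora <- oracle_two_point_grid(g, g$loci$locus_id[i], g$loci$locus_id[j])
    expect_lte(abs(tp$rf - ora$rf), 1e-3)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("mapping functions match their closed forms and invert", {
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0.25, "kosambi"), 25 * log(3))
  expect_equal(map_distance(0.25, "haldane"), -50 * log(0.5))
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(rf_from_distance(map_distance(r, "kosambi"), "kosambi"), r)
  expect_equal(rf_from_distance(map_distance(r, "haldane"), "haldane"), r)
})
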
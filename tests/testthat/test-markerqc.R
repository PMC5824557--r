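test_that("parental genotypes classify into the five CP types", {
  ab <- classify_segregation("a/b", "c/d")
  expect_equal(ab$seg_type, "ABxCD")
  expect_equal(ab$classes, c("a/c", "a/d", "b/c", "b/d"))
  expect_equal(ab$expected, rep(0.25, 4))

  lm <- classify_segregation("l/m", "l/l")
  expect_equal(lm$seg_type, "LMxLL")
  expect_equal(lm$classes, c("l/l", "l/m"))
  expect_equal(lm$expected, c(0.5, 0.5))

  hk <- classify_segregation("h/k", "h/k")
  expect_equal(hk$seg_type, "HKxHK")
  expect_equal(hk$expected, c(0.25, 0.5, 0.25))

  expect_equal(classify_segregation("e/f", "e/g")$seg_type, "EFxEG")
  expect_equal(classify_segregation("n/n", "n/p")$seg_type, "NNxNP")

  un <- classify_segregation("a/a", "a/a")
  expect_false(un$informative)
  expect_equal(un$reason, "uninformative")
  miss <- classify_segregation(NA, "a/b")
  expect_equal(miss$reason, "missing_parent")
})

test_that("segregation distortion test matches the closed-form chi-square", {
  info <- classify_segregation("l/m", "l/l")
  t0 <- test_segregation_distortion(c(rep("l/l", 50), rep("l/m", 50)), info)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)

  t1 <- test_segregation_distortion(c(rep("l/l", 70), rep("l/m", 30)), info)
  expect_equal(t1$chi2, 16)
  expect_equal(t1$p, 6.334248e-05, tolerance = 1e-6)

  info4 <- classify_segregation("a/b", "c/d")
  t2 <- test_segregation_distortion(rep(c("a/c", "a/d", "b/c", "b/d"), 25), info4)
  expect_equal(t2$chi2, 0)
  expect_equal(t2$p, 1)

  expect_error(test_segregation_distortion(rep(NA_character_, 10), info),
               "missing")
})

make_qc_geno <- function() {
  tm <- simulate_true_map(1, 60, 12, seed = 41)
  simulate_family(tm, 60, error_rate = 0, missing_rate = 0, seed = 42)$geno
}

test_that("filters remove by call rate, individual missingness and distortion", {
  g <- make_qc_geno()
  # degrade locus 1 below 90% call rate, individual 1 above 50% missing
  g$calls[1, 1:8] <- NA
  g$calls[2:9, 1] <- NA
  res <- filter_markers(g)
  expect_true(any(res$log$reason == "call_rate" &
                    res$log$item == g$loci$locus_id[1]))
  expect_true(any(res$log$reason == "indiv_missing" &
                    res$log$item == colnames(g$calls)[1]))
  expect_false(g$loci$locus_id[1] %in% res$geno$loci$locus_id)
  expect_false(colnames(g$calls)[1] %in% colnames(res$geno$calls))

  # a clearly distorted locus (45:15 against 1:1, chi2 = 15) is removed
  # after Bonferroni while still passing the MAF filter
  g2 <- make_qc_geno()
  i <- which(g2$loci$seg_type == "LMxLL")[1]
  skip_if(is.na(i))
  g2$calls[i, ] <- rep(c("l/l", "l/m"), c(45, 15))
  res2 <- filter_markers(g2)
  expect_true(any(res2$log$reason == "distortion" &
                    res2$log$item == g2$loci$locus_id[i]))
})

test_that("a clean matrix passes unchanged and filtering is idempotent", {
  g <- make_qc_geno()
  r1 <- filter_markers(g)
  informative <- vapply(seq_len(nrow(g$loci)), function(i)
    classify_segregation(g$loci$mother[i], g$loci$father[i])$informative, TRUE)
  expect_equal(nrow(r1$geno$loci), sum(informative))
  r2 <- filter_markers(r1$geno)
  expect_identical(r1$geno$calls, r2$geno$calls)
  expect_identical(r1$geno$loci$locus_id, r2$geno$loci$locus_id)
})

test_that("co-segregation binning is an exact-signature partition", {
  tm <- simulate_true_map(1, 40, 6, seed = 43)
  fam <- simulate_family(tm, 40, error_rate = 0, missing_rate = 0, seed = 44)
  g <- fam$geno
  # duplicate locus 1's calls into locus 2 (same seg structure forced)
  g$loci$seg_type[2] <- g$loci$seg_type[1]
  g$loci$mother[2] <- g$loci$mother[1]
  g$loci$father[2] <- g$loci$father[1]
  g$calls[2, ] <- g$calls[1, ]
  bins <- bin_cosegregating(g)
  expect_equal(bins$representative[2], g$loci$locus_id[1])
  expect_true(bins$is_passenger[2])
  # partition: every locus in exactly one bin, representatives minimal
  bl <- attr(bins, "bins")
  expect_setequal(unlist(bl), g$loci$locus_id)
  expect_true(all(vapply(names(bl), function(r) r == min(bl[[r]]), TRUE)))

  # one missing call breaks the signature (conservative rule)
  g$calls[2, 1] <- NA
  bins2 <- bin_cosegregating(g)
  expect_false(bins2$is_passenger[2])
})
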
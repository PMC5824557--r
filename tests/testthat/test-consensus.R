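mk_map <- function(ids, pos, lg = "LG01") {
  as_genetic_map(data.frame(locus_id = ids, lg = lg, position_cM = pos))
}

test_that("identical maps yield no conflicts and merge with zero MAE", {
  m <- mk_map(c("A", "B", "C"), c(0, 5, 12))
  expect_equal(nrow(detect_conflicts(m, m)), 0)
  cons <- merge_maps(m, m)
  expect_equal(attr(cons, "mae"), 0, tolerance = 1e-9)
  expect_equal(cons$position_cM, m$position_cM, tolerance = 1e-9)
})

test_that("oppositely ordered shared loci are flagged with cluster sizes", {
  ma <- mk_map(c("X", "P1", "P2", "Y", "Z"), c(0, 0, 0, 5, 9))
  mb <- mk_map(c("Y", "X", "Q1", "Q2", "Q3", "Q4", "Z"), c(0, 3, 3, 3, 3, 3, 8))
  conf <- detect_conflicts(ma, mb)
  expect_setequal(conf$locus_id, c("X", "Y"))
  x <- conf[conf$locus_id == "X", ]
  expect_equal(x$cluster_a, 3)  # X co-positioned with P1, P2 in A
  expect_equal(x$cluster_b, 5)  # X co-positioned with Q1..Q4 in B
})

test_that("resolution removes from the map with the larger cluster", {
  ma <- mk_map(c("X", "P1", "P2", "Y", "Z"), c(0, 0, 0, 5, 9))
  mb <- mk_map(c("Y", "X", "Q1", "Q2", "Q3", "Q4", "Z"), c(0, 3, 3, 3, 3, 3, 8))
  res <- resolve_conflicts(ma, mb)
  expect_equal(res$log$locus_id, "X")
  expect_equal(res$log$removed_from, "B")   # cluster 5 > 3
  expect_false("X" %in% res$map_b$locus_id)
  expect_true("X" %in% res$map_a$locus_id)
  expect_equal(nrow(res$unresolved), 0)

  # clustered only in A: removed from A
  ma2 <- mk_map(c("X", "P1", "Y"), c(2, 2, 5))
  mb2 <- mk_map(c("Y", "X", "Z"), c(0, 3, 8))
  res2 <- resolve_conflicts(ma2, mb2)
  expect_equal(res2$log$removed_from, "A")
  expect_false("X" %in% res2$map_a$locus_id)

  # no conflicts: untouched
  m <- mk_map(c("A", "B"), c(0, 4))
  res3 <- resolve_conflicts(m, m)
  expect_equal(nrow(res3$log), 0)
  expect_equal(as.data.frame(res3$map_a), as.data.frame(m))
})

test_that("merging respects both component orders and matches the grid oracle", {
  # loci {A,B} only in A at 0/10, {B,C} only in B at 0/10
  ma <- mk_map(c("A", "B"), c(0, 10))
  mb <- mk_map(c("B", "C"), c(0, 10))
  cons <- merge_maps(ma, mb)
  pos <- stats::setNames(cons$position_cM, cons$locus_id)
  expect_lt(pos["A"], pos["B"])
  expect_lt(pos["B"], pos["C"])
  oracle <- oracle_merge_grid(list(A = c(A = 0, B = 10), B = c(B = 0, C = 10)))
  expect_equal(attr(cons, "mae"), oracle, tolerance = 0.02)

  # disagreeing positions for the same loci
  ma2 <- mk_map(c("A", "B", "C"), c(0, 4, 10))
  mb2 <- mk_map(c("A", "B", "C"), c(0, 8, 12))
  cons2 <- merge_maps(ma2, mb2)
  oracle2 <- oracle_merge_grid(list(A = c(A = 0, B = 4, C = 10),
                                    B = c(A = 0, B = 8, C = 12)))
  expect_equal(attr(cons2, "mae"), oracle2, tolerance = 0.02)
  expect_true(all(diff(cons2$position_cM) >= 0))
})

test_that("a consensus never contradicts an order shared by both inputs", {
  set.seed(91)
  for (rep in 1:5) {
    ids <- sprintf("L%02d", 1:8)
    pa <- sort(runif(8, 0, 50)); pb <- pmax(0, pa + rnorm(8, 0, 0.5))
    # keep B order-compatible with A to avoid conflicts
    pb <- sort(pb)
    ma <- mk_map(ids, pa); mb <- mk_map(ids, pb)
    cons <- merge_maps(ma, mb)
    pos <- stats::setNames(cons$position_cM, cons$locus_id)
    for (k in 1:7) expect_lte(pos[ids[k]], pos[ids[k + 1]] + 1e-9)
  }
})

test_that("conflict removal never drops a locus from the consensus", {
  # a conflicted locus is by construction shared, so after removal from
  # one family map it persists in the other and hence in the consensus:
  # the consensus is always the union of the input loci
  ma <- mk_map(c("X", "P1", "P2", "Y", "Z"), c(0, 0, 0, 5, 9))
  mb <- mk_map(c("Y", "X", "Q1", "Q2", "Q3", "Q4", "Z"), c(0, 3, 3, 3, 3, 3, 8))
  full <- consensus_map(ma, mb)
  expect_setequal(full$consensus$locus_id, union(ma$locus_id, mb$locus_id))
  expect_equal(full$log$locus_id, "X")
  expect_true("X" %in% full$consensus$locus_id)

  ma2 <- mk_map(c("W", "P1", "Y"), c(2, 2, 5))
  mb2 <- mk_map(c("Y", "P1", "Z"), c(0, 3, 8))
  full2 <- consensus_map(ma2, mb2)
  expect_setequal(full2$consensus$locus_id,
                  union(ma2$locus_id, mb2$locus_id))
})

test_that("beating the naive mean-position consensus on simulated pairs", {
  set.seed(92)
  worse <- 0
  for (rep in 1:20) {
    ids <- sprintf("L%02d", 1:10)
    pa <- sort(runif(10, 0, 60))
    pb <- sort(pa + rnorm(10, 0, 2)); pb <- pb - pb[1]
    ma <- mk_map(ids, pa); mb <- mk_map(ids, pb)
    cons <- merge_maps(ma, mb)
    # naive consensus: per-locus mean, projected to feasibility by sorting
    naive <- sort((pa + pb) / 2)
    naive_mae <- mean(c(abs(naive - pa), abs(naive - pb)))
    if (attr(cons, "mae") > naive_mae + 1e-6) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
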
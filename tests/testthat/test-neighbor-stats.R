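collinear <- function(xs, labs) {
  make_specimen(cbind(xs, 0, 0), labs)
}

test_that("same-morphotype NN counts match hand cases and brute force", {
  s <- nnSameSummary(collinear(c(0, 1, 10, 11), c("G1", "G1", "G2", "G2")))
  expect_equal(s$observed[s$morphotype_i == "G1"], 2L)
  expect_equal(s$observed[s$morphotype_i == "G2"], 2L)

  s <- nnSameSummary(collinear(0:3, c("G1", "G2", "G1", "G2")))
  expect_equal(s$observed, c(0L, 0L))

  set.seed(7)
  for (rep in 1:8) {
    n <- sample(10:60, 1)
    pts <- rand_points(n)
    labs <- sample(c("G1", "G2", "G5"), n, replace = TRUE)
    got <- nnSameSummary(make_specimen(pts, labs))
    want <- brute_nn_same(pts, labs)
    expect_equal(
      stats::setNames(got$observed, got$morphotype_i),
      want[got$morphotype_i]
    )
  }
})

test_that("conservation: every hook has exactly one nearest neighbour", {
  set.seed(21)
  pts <- rand_points(40)
  labs <- sample(c("G1", "G2", "G3", "G4"), 40, replace = TRUE)
  sp <- make_specimen(pts, labs)
  same <- nnSameSummary(sp)
  cross <- nnCrossSummary(sp, applyExclusion = FALSE)
  # same-NN hooks plus hooks whose NN is of another morphotype... cross
  # counts use nearest-other-morphotype, so recompute the plain partition
  D <- pairwiseDistances(sp)
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  expect_equal(sum(labs == labs[nn]) + sum(labs != labs[nn]), 40L)
  expect_equal(sum(same$observed), sum(labs == labs[nn]))
})

test_that("analytic expectations evaluate the null formulas exactly", {
  expect_equal(expectedSame(10, 10), 10)
  expect_equal(expectedSame(1, 10), 0)
  expect_equal(expectedSame(4, 10), 4 / 3)
  expect_error(expectedSame(1, 1), "N_tot")

  expect_equal(expectedCross(5, 3, 20), 1)
  expect_equal(expectedCross(4, 6, 10), 4) # two morphotypes: all cross = j
  expect_error(expectedCross(5, 3, 5), "no cross-neighbours")

  # conservation identity over random count vectors
  set.seed(3)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    counts <- sample(1:30, k, replace = TRUE)
    tot <- sum(counts)
    for (i in seq_len(k)) {
      e <- sum(vapply(
        seq_len(k)[-i],
        function(j) expectedCross(counts[i], counts[j], tot), numeric(1)
      ))
      expect_equal(e, counts[i])
    }
  }
})

test_that("Tukey-fence outlier exclusion uses the upper fence only", {
  sp <- collinear(c(0, 1, 2, 3, 100), rep("G1", 5))
  rep_ <- excludeOutliers(sp)
  # oracle: direct quantile arithmetic on the per-hook mean distances
  D <- as.matrix(stats::dist(cbind(c(0, 1, 2, 3, 100), 0, 0)))
  diag(D) <- NA
  s <- rowMeans(D, na.rm = TRUE)
  q <- stats::quantile(s, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  expect_equal(rep_$excluded, unname(s > fence))
  expect_identical(rep_$hook_id[rep_$excluded], 5L)

  # unit square: all statistics equal, nothing excluded
  sq <- make_specimen(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), rep("G2", 4)
  )
  rep_ <- excludeOutliers(sq)
  expect_false(any(rep_$excluded))
  expect_true(all(rep_$rule_applied))

  # below 4 hooks the rule is skipped
  rep_ <- excludeOutliers(collinear(c(0, 1, 50), rep("G3", 3)))
  expect_false(any(rep_$rule_applied))
  expect_false(any(rep_$excluded))

  # nearest-distance variant is exposed
  rep_n <- excludeOutliers(sp, stat = "nearest")
  expect_equal(rep_n$stat[1:4], c(1, 1, 1, 1))
})

test_that("cross-morphotype NN counts match hand cases and brute force", {
  sp <- collinear(c(0, 1, 10, 11), c("G1", "G2", "G3", "G3"))
  cr <- nnCrossSummary(sp, applyExclusion = FALSE)
  get <- function(i, j) cr$observed[cr$morphotype_i == i & cr$morphotype_j == j]
  expect_equal(get("G1", "G2"), 1L)
  expect_equal(get("G2", "G1"), 1L)
  # both G3 hooks are nearer to G2 (x=1) than to G1 (x=0)
  expect_equal(get("G3", "G2"), 2L)
  expect_equal(get("G3", "G1"), 0L)

  # two morphotypes only: every cross-neighbour is the other one
  sp2 <- make_specimen(rand_points(12), rep(c("G1", "G4"), each = 6))
  cr2 <- nnCrossSummary(sp2, applyExclusion = FALSE)
  expect_equal(cr2$observed[cr2$morphotype_i == "G1"], 6L)

  set.seed(13)
  for (rep in 1:6) {
    n <- sample(20:40, 1)
    pts <- rand_points(n)
    labs <- sample(c("G1", "G2", "G3", "G4", "G5"), n, replace = TRUE)
    got <- nnCrossSummary(make_specimen(pts, labs), applyExclusion = FALSE)
    want <- brute_nn_cross(pts, labs)
    for (r in seq_len(nrow(got))) {
      key <- paste(got$morphotype_i[r], got$morphotype_j[r], sep = "->")
      expect_equal(got$observed[r], want[[key]] %||% 0L,
        info = paste("pair", key)
      )
    }
  }
})

test_that("cross summary excludes outliers before counting", {
  # a G1 straggler sits next to the G2 cluster; exclusion removes it so the
  # G2 hooks' nearest other-morphotype hook becomes G4
  xs <- c(0, 1, 2, 3, 20, 21, 22, 23, 19.5, 30, 31, 32, 33)
  labs <- c(rep("G1", 4), rep("G2", 4), "G1", rep("G4", 4))
  sp <- collinear(xs, labs)
  cr_raw <- nnCrossSummary(sp, applyExclusion = FALSE)
  cr_ex <- nnCrossSummary(sp)
  g2g1_raw <- cr_raw$observed[cr_raw$morphotype_i == "G2" & cr_raw$morphotype_j == "G1"]
  g2g1_ex <- cr_ex$observed[cr_ex$morphotype_i == "G2" & cr_ex$morphotype_j == "G1"]
  expect_gt(g2g1_raw, g2g1_ex)
  expect_equal(cr_ex$n_i[cr_ex$morphotype_i == "G1"][1], 4L) # straggler gone
})

test_that("label-permutation means converge on the analytic expectations", {
  set.seed(5)
  pts <- rand_points(30)
  labs <- sample(c("G1", "G2", "G4"), 30, replace = TRUE)
  sp <- make_specimen(pts, labs)
  pn <- permutationNull(sp, nPerm = 4000L, seed = 2L)
  se <- pn$same$sd / sqrt(pn$nPerm)
  expect_true(all(abs(pn$same$mean - pn$same$expected) <= 3 * se + 1e-9))
  se <- pn$cross$sd / sqrt(pn$nPerm)
  expect_true(all(abs(pn$cross$mean - pn$cross$expected) <= 3 * se + 1e-9))

  # determinism of a single shuffle
  a <- permutationNull(sp, nPerm = 1L, seed = 7L)
  b <- permutationNull(sp, nPerm = 1L, seed = 7L)
  expect_identical(a, b)

  # single-morphotype specimen: counts are constant = N
  mono <- make_specimen(rand_points(8), rep("G5", 8))
  pn <- permutationNull(mono, nPerm = 5L, seed = 1L)
  expect_equal(pn$same$mean, 8)
  expect_equal(pn$same$sd, 0)
})
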
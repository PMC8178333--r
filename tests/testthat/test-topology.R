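test_that("known small complexes give the textbook diagrams", {
  # equilateral triangle: two components die at 1, one essential, no loop
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  b <- diagramBars(ripsPersistence(tri))
  expect_equal(sum(b$dimension == 0L), 3L)
  expect_equal(sort(b$death[b$dimension == 0L]), c(1, 1, Inf))
  expect_equal(sum(b$dimension == 1L), 0L)

  # unit square: one loop born at 1, filled at sqrt(2)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  b <- diagramBars(ripsPersistence(sq))
  h1 <- b[b$dimension == 1L, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))

  # truncation below the minimum distance: every point is essential
  far <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 5))
  b <- diagramBars(ripsPersistence(far, maxScale = 1))
  expect_equal(sum(b$dimension == 0L & is.infinite(b$death)), 4L)
  expect_equal(sum(b$dimension == 1L), 0L)

  expect_error(ripsPersistence(matrix(0, 0, 3)), "empty")
  expect_error(ripsPersistence(sq, maxDim = 2L), "dimensions 0 and 1")
})

test_that("dimension-0 persistence equals single-linkage merge heights", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:60, 1)
    pts <- rand_points(n)
    b <- diagramBars(ripsPersistence(pts, maxDim = 0L))
    deaths <- sort(b$death[b$dimension == 0L & is.finite(b$death)])
    hc <- stats::hclust(stats::dist(pts), method = "single")
    expect_equal(deaths, sort(hc$height), tolerance = 1e-12)
  }
})

test_that("dimension-1 bars agree with an independent boundary reduction", {
  set.seed(57)
  for (rep in 1:8) {
    n <- sample(8:22, 1)
    pts <- rand_points(n)
    got <- ripsPersistence(pts)
    oracle <- r_reduce_h1(pts)
    gb <- diagramBars(got)
    gb <- gb[gb$dimension == 1L, , drop = FALSE]
    expect_equal(nrow(gb), nrow(oracle))
    if (nrow(oracle)) {
      o1 <- oracle[order(oracle$birth, oracle$death), ]
      g1 <- gb[order(gb$birth, gb$death), ]
      expect_equal(g1$birth, o1$birth, tolerance = 1e-12)
      expect_equal(g1$death, o1$death, tolerance = 1e-12)
    }
  }
})

test_that("alive dimension-1 bar counts match rank-based Betti numbers", {
  set.seed(99)
  for (rep in 1:4) {
    pts <- rand_points(11, scale = 4)
    d <- ripsPersistence(pts)
    crit <- diagramBars(d)
    crit <- crit$birth[crit$dimension == 1L]
    D <- stats::dist(pts)
    probes <- unique(c(stats::quantile(D, c(0.3, 0.5, 0.7)), crit + 1e-7))
    for (s in probes) {
      expect_equal(bars_alive_at(d, s), betti1_at(pts, s),
        info = paste("scale", s)
      )
    }
  }
})

test_that("diagrams are invariant under rigid motion and point order", {
  set.seed(17)
  pts <- rand_points(20)
  d0 <- ripsPersistence(pts)
  dR <- ripsPersistence(rigid_motion(pts))
  dP <- ripsPersistence(pts[sample(20), ])
  expect_lt(diagramDistance(d0, dR, 0), 1e-9)
  expect_lt(diagramDistance(d0, dR, 1), 1e-9)
  expect_lt(diagramDistance(d0, dP, 0), 1e-12)
  expect_lt(diagramDistance(d0, dP, 1), 1e-12)
})

test_that("small point perturbations move bars proportionally (stability)", {
  # moving every point by <= eps changes any pairwise distance, hence any
  # Rips bar endpoint, by at most 2 eps
  set.seed(23)
  pts <- rand_points(18)
  d0 <- ripsPersistence(pts)
  for (eps in c(0.01, 0.05)) {
    shift <- matrix(stats::runif(54, -eps / sqrt(3), eps / sqrt(3)), 18, 3)
    d1 <- ripsPersistence(pts + shift)
    expect_lte(diagramDistance(d0, d1, 0), 2 * eps + 1e-12)
    expect_lte(diagramDistance(d0, d1, 1), 2 * eps + 1e-12)
  }
})

test_that("a noisy circle shows exactly one dominant loop", {
  set.seed(8)
  r <- 5
  th <- stats::runif(40, 0, 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th), 0) +
    matrix(stats::runif(120, -0.05 * r / sqrt(3), 0.05 * r / sqrt(3)), 40, 3)
  b <- diagramBars(ripsPersistence(pts))
  pers <- sort(b$death[b$dimension == 1L] - b$birth[b$dimension == 1L],
    decreasing = TRUE
  )
  expect_gt(pers[1], 5 * max(pers[-1], 0, na.rm = TRUE))
})

test_that("morphotype links are the MST with a Tukey retention fence", {
  sp <- make_specimen(cbind(c(0, 1, 2), 0, 0), rep("G1", 3))
  lg <- morphotypeLinks(sp, "G1")
  e <- linkEdges(lg)
  expect_equal(nrow(e), 2L)
  expect_equal(e$strength, c(1, 1))
  expect_true(all(e$retained))

  # oracle: fence recomputed from the strengths (Tukey upper fence with the
  # 2x-median floor guarding the degenerate near-constant case)
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(5:40, 1)
    pts <- rand_points(n)
    sp <- make_specimen(pts, rep("G2", n))
    lg <- morphotypeLinks(sp, "G2")
    e <- linkEdges(lg)
    expect_equal(nrow(e), n - 1L) # retained + dropped = n - 1
    expect_equal(sum(e$strength), igraph_mst_weight(pts), tolerance = 1e-12)
    got <- cbind(pmin(e$from, e$to), pmax(e$from, e$to))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(got, igraph_mst_edges(pts), ignore_attr = TRUE)
    q <- stats::quantile(e$strength, c(0.25, 0.75), names = FALSE)
    fence <- max(q[2] + 1.5 * (q[2] - q[1]), 2 * stats::median(e$strength))
    expect_equal(lg@fence, fence)
    expect_equal(e$retained, e$strength <= fence)
  }

  # a far outlier's link is dropped on a long chain
  sp <- make_specimen(cbind(c(0:9, 60), 0, 0), rep("G4", 11))
  e <- linkEdges(morphotypeLinks(sp, "G4"))
  expect_false(e$retained[e$strength > 10])
  expect_true(all(e$retained[e$strength <= 1]))

  expect_warning(
    morphotypeLinks(make_specimen(matrix(0, 1, 3), "G1"), "G1"),
    "fewer than 2"
  )
})

test_that("bottleneck distance matches hand values and exhaustive matching", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  d <- ripsPersistence(sq)
  expect_equal(diagramDistance(d, d, 0), 0)
  expect_equal(diagramDistance(d, d, 1), 0)

  mk <- function(bars, np = 2L) {
    methods::new("PersistenceDiagram",
      bars = rbind(
        data.frame(dimension = 0L, birth = 0, death = rep(Inf, np)),
        bars
      ),
      nPoints = np, maxScale = 100
    )
  }
  a <- mk(data.frame(dimension = 1L, birth = 0, death = 2))
  b <- mk(data.frame(dimension = 1L, birth = 0, death = 3))
  expect_equal(diagramDistance(a, b, 1), 1)
  empty <- mk(data.frame(dimension = integer(0), birth = numeric(0), death = numeric(0)))
  expect_equal(diagramDistance(empty, b, 1), 1.5) # (3 - 0) / 2

  set.seed(41)
  for (rep in 1:10) {
    n1 <- sample(0:3, 1)
    n2 <- sample(0:3, 1)
    bars1 <- data.frame(
      dimension = rep(1L, n1), birth = stats::runif(n1, 0, 3)
    )
    bars1$death <- bars1$birth + stats::runif(n1, 0.1, 3)
    bars2 <- data.frame(
      dimension = rep(1L, n2), birth = stats::runif(n2, 0, 3)
    )
    bars2$death <- bars2$birth + stats::runif(n2, 0.1, 3)
    got <- diagramDistance(mk(bars1), mk(bars2), 1)
    want <- exhaustive_bottleneck(
      as.matrix(bars1[, c("birth", "death")]),
      as.matrix(bars2[, c("birth", "death")])
    )
    expect_equal(got, want, tolerance = 1e-12)
  }
})
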
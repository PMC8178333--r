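test_that("two straight paired axes are recovered from the default world", {
  sp <- generateClustered(syntheticConfig(seed = 1))
  axes <- inferAxes(sp)
  expect_length(axes, 2L)
  pairs <- lapply(axes, function(a) sort(a@pair))
  expect_true(any(vapply(pairs, identical, logical(1), c("G1", "G4"))))
  expect_true(any(vapply(pairs, identical, logical(1), c("G2", "G5"))))
  for (a in axes) {
    expect_gte(a@coverage, 0.9)
    expect_false(anyDuplicated(axisHooks(a)) > 0)
    # arc length is the running sum of consecutive centroid distances
    cc <- centroids(sp)
    rownames(cc) <- hookIDs(sp)
    xyz <- cc[as.character(axisHooks(a)), ]
    seg <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_equal(a@totalLength, sum(seg), tolerance = 1e-9)
    expect_equal(a@arcLength, c(0, cumsum(seg)), ignore_attr = TRUE)
    expect_true(a@straightness > 0 && a@straightness <= 1)
  }
})

test_that("a single arc pair yields one curved axis", {
  cfg <- syntheticConfig(
    seed = 4, nAxes = 1, hooksPerAxis = 20,
    axisGeometry = "arc", basalGroupSize = 0,
    rareCounts = c(TRI = 0L, UNI = 0L, RND = 0L)
  )
  sp <- generateClustered(cfg)
  axes <- inferAxes(sp)
  expect_length(axes, 1L)
  expect_lt(axes[[1]]@straightness, 1)
  expect_gte(axes[[1]]@coverage, 0.9)
})

test_that("axis inference degrades gracefully below 4 retained hooks", {
  sp <- make_specimen(
    rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 0)),
    c("G1", "G4", "G2")
  )
  expect_message(axes <- inferAxes(sp), "no axes")
  expect_length(axes, 0L)
})

test_that("axes are rigid-motion invariant as hook-id paths", {
  sp <- generateClustered(syntheticConfig(seed = 6))
  set.seed(2)
  moved <- make_specimen(
    rigid_motion(centroids(sp)), as.character(morphotypes(sp)),
    id = "moved", ids = hookIDs(sp)
  )
  a1 <- inferAxes(sp)
  a2 <- inferAxes(moved)
  expect_equal(lapply(a1, axisHooks), lapply(a2, axisHooks))
})

test_that("tree diameter paths agree with all-pairs shortest paths", {
  set.seed(19)
  for (rep in 1:6) {
    n <- sample(10:200, 1)
    pts <- rand_points(n, scale = 20)
    sp <- make_specimen(pts, rep("G1", n))
    e <- linkEdges(morphotypeLinks(sp, "G1"))
    path <- crownmap:::tree_diameter_path(hookIDs(sp), e)
    oracle <- igraph_diameter(hookIDs(sp), e)
    # path length equals the graph's weighted diameter
    idx <- match(path, hookIDs(sp))
    w <- 0
    for (k in seq_len(length(path) - 1)) {
      ee <- e[(e$from == path[k] & e$to == path[k + 1]) |
        (e$to == path[k] & e$from == path[k + 1]), ]
      w <- w + ee$strength[1]
    }
    expect_equal(w, oracle$length, tolerance = 1e-9)
    expect_equal(
      oracle$dm[as.character(path[1]), as.character(path[length(path)])],
      oracle$length,
      tolerance = 1e-9
    )
  }
})

test_that("basal hooks score high when at the axis base, ~both-ends otherwise", {
  sp <- generateClustered(syntheticConfig(seed = 1))
  axes <- inferAxes(sp)
  sc <- basalPositionScore(sp, axes)
  expect_gte(sc$score, 0.75)
  expect_length(sc$allScores, 4L) # two axes, both orientations each

  # single basal hook adjacent to one end of a synthetic straight axis
  pts <- cbind(seq(0, 10, length.out = 11), 0, 0)
  labs <- c(rep(c("G1", "G4"), length.out = 10), "G3")
  pts[11, ] <- c(-1, 0, 0)
  sp2 <- make_specimen(pts, labs)
  ax2 <- inferAxes(sp2)
  expect_equal(basalPositionScore(sp2, ax2)$score, 1)

  # no basal hooks: undefined, reported as NA
  sp3 <- sp2[as.character(morphotypes(sp2)) != "G3"]
  expect_true(is.na(basalPositionScore(sp3, inferAxes(sp3))$score))

  expect_error(basalPositionScore(sp, list()), "at least one axis")
})

test_that("axis sizes stay in the observed regime on default worlds", {
  for (s in c(3, 9)) {
    axes <- inferAxes(generateClustered(syntheticConfig(seed = s)))
    for (a in axes) expect_lte(length(axisHooks(a)), 70L)
  }
})
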
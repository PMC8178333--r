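# Synthetic specimens with the spatial structure the analysis assumes
# (clustered alternative) and without it (random null). The clustered world
# emulates the arrangements described for well-preserved body chambers:
# imbricated same-morphotype files, mirror pairs running side by side along
# up to two axes, the small morphotypes grouped at the axis base, a few
# scattered rare hooks, and an optional taphonomic scrambling that relocates
# a fraction of hooks uniformly in a body-chamber-like ellipsoid.

#' Construct a synthetic-specimen configuration
#'
#' Defaults describe a well-preserved adult specimen: two straight axes of
#' 50 hooks each (files of 25 G1+G4 and 25 G2+G5, imbrication step 1.5 mm,
#' files 2 mm apart), a basal group of 14 small hooks (G3 and VSB), two
#' hooks each of the rare tricuspid/unicuspid/rounded classes (about 2% of
#' hooks), 0.3 mm isotropic jitter, no scrambling, and a 90 x 50 x 40 mm
#' body-chamber ellipsoid — 120 hooks in total, inside the observed range of
#' 40--168 per specimen.
#'
#' @param seed RNG seed.
#' @param nAxes number of axes (1 or 2).
#' @param hooksPerAxis even hook count per axis (half per morphotype file).
#' @param pairAssignment list of morphotype pairs per axis.
#' @param axisGeometry `"straight"` or `"arc"`.
#' @param arcRadius,arcSpanDeg arc radius (mm) and span (degrees).
#' @param spacing along-file imbrication step (mm).
#' @param lateralOffset distance between the paired files (mm).
#' @param basalGroupSize basal-group hook count (G3/VSB split evenly).
#' @param rareCounts named counts for TRI, UNI, RND.
#' @param jitterSD isotropic Gaussian noise SD (mm).
#' @param scrambleFraction fraction of hooks relocated uniformly.
#' @param chamber ellipsoid semi-axes (mm).
#' @return a validated [SyntheticConfig-class].
#' @export
#' @examples
#' syntheticConfig(seed = 1)
syntheticConfig <- function(seed = 1L, nAxes = 2L, hooksPerAxis = 50L,
                            pairAssignment = list(c("G1", "G4"), c("G2", "G5")),
                            axisGeometry = "straight",
                            arcRadius = 25, arcSpanDeg = 120,
                            spacing = 1.5, lateralOffset = 2,
                            basalGroupSize = 14L,
                            rareCounts = c(TRI = 2L, UNI = 2L, RND = 2L),
                            jitterSD = 0.3, scrambleFraction = 0,
                            chamber = c(45, 25, 20)) {
  if (length(seed) != 1L || is.na(suppressWarnings(as.integer(seed)))) {
    stop("seed must be a single integer")
  }
  if (hooksPerAxis < 0) stop("n_hooks must be non-negative")
  if (jitterSD < 0) stop("jitter must be non-negative")
  rc <- as.integer(rareCounts)
  names(rc) <- names(rareCounts)
  methods::new("SyntheticConfig",
    seed = as.integer(seed), nAxes = as.integer(nAxes),
    hooksPerAxis = as.integer(hooksPerAxis),
    pairAssignment = lapply(pairAssignment, as.character),
    axisGeometry = axisGeometry,
    arcRadius = as.numeric(arcRadius), arcSpanDeg = as.numeric(arcSpanDeg),
    spacing = as.numeric(spacing), lateralOffset = as.numeric(lateralOffset),
    basalGroupSize = as.integer(basalGroupSize), rareCounts = rc,
    jitterSD = as.numeric(jitterSD),
    scrambleFraction = as.numeric(scrambleFraction),
    chamber = as.numeric(chamber)
  )
}

# Morphotype label sequence in deterministic generation order.
config_labels <- function(config) {
  lab <- character(0)
  nPairs <- config@hooksPerAxis %/% 2L
  for (a in seq_len(config@nAxes)) {
    pair <- config@pairAssignment[[a]]
    lab <- c(lab, rep(pair[1], nPairs), rep(pair[2], nPairs))
  }
  nb <- config@basalGroupSize
  lab <- c(lab, rep("G3", ceiling(nb / 2)), rep("VSB", floor(nb / 2)))
  for (m in c("TRI", "UNI", "RND")) lab <- c(lab, rep(m, config@rareCounts[[m]]))
  lab
}

# i.i.d. uniform points in the chamber ellipsoid (rejection from the cube).
runif_ellipsoid <- function(n, semi) {
  out <- matrix(NA_real_, n, 3L)
  got <- 0L
  while (got < n) {
    cand <- matrix(stats::runif(3L * (n - got) * 2L + 6L, -1, 1), ncol = 3L)
    keep <- rowSums(cand^2) <= 1
    take <- cand[keep, , drop = FALSE]
    k <- min(nrow(take), n - got)
    if (k > 0L) {
      out[(got + 1L):(got + k), ] <- take[seq_len(k), , drop = FALSE]
      got <- got + k
    }
  }
  sweep(out, 2L, semi, `*`)
}

# Ideal (noise-free) file positions along one axis. Returns a list with the
# two files' coordinate matrices and the unit tangent at the base.
axis_positions <- function(config, a) {
  nPairs <- config@hooksPerAxis %/% 2L
  lat <- config@lateralOffset / 2
  y0 <- if (config@nAxes == 2L) c(-5, 5)[a] else 0
  z0 <- if (config@nAxes == 2L) c(-3, 3)[a] else 0
  if (config@axisGeometry == "straight") {
    L <- (nPairs - 1L) * config@spacing
    t1 <- (seq_len(nPairs) - 1L) * config@spacing - L / 2
    t2 <- t1 + config@spacing / 2 # staggered imbrication
    f1 <- cbind(t1, y0 - lat, z0)
    f2 <- cbind(t2, y0 + lat, z0)
    tangent <- c(1, 0, 0)
  } else {
    R <- config@arcRadius
    dTheta <- config@spacing / R
    span <- config@arcSpanDeg * pi / 180
    th1 <- -span / 2 + (seq_len(nPairs) - 1L) * dTheta
    th2 <- th1 + dTheta / 2
    ctr <- c(0, y0 - R, z0)
    f1 <- cbind(ctr[1] + (R - lat) * sin(th1), ctr[2] + (R - lat) * cos(th1), z0)
    f2 <- cbind(ctr[1] + (R + lat) * sin(th2), ctr[2] + (R + lat) * cos(th2), z0)
    tangent <- c(cos(th1[1]), -sin(th1[1]), 0)
  }
  list(file1 = f1, file2 = f2, base = f1[1, ], tangent = tangent)
}

# Landmark squares (4 opening landmarks, 1 mm half-side) centred on each
# position, so that the centroid recovers the position exactly.
positions_to_landmarks <- function(pos) {
  n <- nrow(pos)
  off <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  lm <- array(NA_real_, dim = c(n, 4L, 3L))
  for (l in 1:4) lm[, l, ] <- pos + matrix(off[l, ], n, 3L, byrow = TRUE)
  lm
}

#' Generate a clustered synthetic specimen
#'
#' Deterministic for a fixed seed. Hooks are laid pairwise along each axis
#' (one morphotype file per side at half the lateral offset, the second file
#' staggered by half an imbrication step), the basal group is a compact blob
#' just proximal of the axis bases, rare morphotypes are scattered uniformly
#' in the chamber, isotropic Gaussian jitter is applied, and a fraction of
#' hooks is finally relocated uniformly (taphonomic disturbance). Opening
#' landmarks are synthesised as small squares centred on each hook position.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [HookSpecimen-class] with id `synthetic_seed<seed>`.
#' @export
#' @examples
#' sp <- generateClustered(syntheticConfig(seed = 1))
#' morphotypeCounts(sp)
generateClustered <- function(config) {
  methods::validObject(config)
  lab <- config_labels(config)
  n <- length(lab)
  withSeed(config@seed, {
    pos <- matrix(NA_real_, 0L, 3L)
    bases <- matrix(NA_real_, 0L, 3L)
    tangents <- matrix(NA_real_, 0L, 3L)
    for (a in seq_len(config@nAxes)) {
      ap <- axis_positions(config, a)
      pos <- rbind(pos, ap$file1, ap$file2)
      bases <- rbind(bases, ap$base)
      tangents <- rbind(tangents, ap$tangent)
    }
    nb <- config@basalGroupSize
    if (nb > 0L) {
      # two adjacent same-morphotype sub-blobs (G3 then VSB): the basal
      # hooks occur together at the axis base but, like every morphotype,
      # cluster among themselves
      ctr <- colMeans(bases) - 2.5 * colMeans(tangents)
      n3 <- ceiling(nb / 2)
      ctrs <- rbind(
        matrix(ctr + c(0, -1.5, 0), n3, 3L, byrow = TRUE),
        matrix(ctr + c(0, 1.5, 0), nb - n3, 3L, byrow = TRUE)
      )
      blob <- ctrs + matrix(stats::rnorm(3L * nb, sd = 1.0), nb, 3L)
      pos <- rbind(pos, blob)
    }
    nr <- sum(config@rareCounts)
    if (nr > 0L) pos <- rbind(pos, runif_ellipsoid(nr, config@chamber))
    nAxisBasal <- n - nr
    if (config@jitterSD > 0 && nAxisBasal > 0L) {
      pos[seq_len(nAxisBasal), ] <- pos[seq_len(nAxisBasal), ] +
        matrix(stats::rnorm(3L * nAxisBasal, sd = config@jitterSD), nAxisBasal, 3L)
    }
    nScr <- round(config@scrambleFraction * n)
    if (nScr > 0L) {
      idx <- sample.int(n, nScr)
      pos[idx, ] <- runif_ellipsoid(nScr, config@chamber)
    }
    HookSpecimen(
      paste0("synthetic_seed", config@seed), seq_len(n), lab,
      landmarks = positions_to_landmarks(pos)
    )
  })
}

#' Generate a matched random-null specimen
#'
#' Identical morphotype counts to the clustered twin for the same config,
#' with all positions i.i.d. uniform in the chamber ellipsoid — the random
#' distribution scenario of the null hypothesis.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [HookSpecimen-class] with id `null_seed<seed>`.
#' @export
generateNull <- function(config) {
  methods::validObject(config)
  lab <- config_labels(config)
  n <- length(lab)
  withSeed(config@seed, {
    pos <- runif_ellipsoid(n, config@chamber)
    HookSpecimen(
      paste0("null_seed", config@seed), seq_len(n), lab,
      landmarks = positions_to_landmarks(pos)
    )
  })
}

#' Generate a suite of varied synthetic specimens
#'
#' Emulates a multi-specimen study: per-specimen totals are drawn in the
#' observed range of 40--168 hooks by varying the per-axis hook count, with
#' one recorded seed and configuration per specimen.
#'
#' @param baseConfig a [SyntheticConfig-class] supplying all other settings.
#' @param nSpecimens number of specimens (>= 1).
#' @param seeds optional integer vector of per-specimen seeds (defaults to
#'   `baseConfig` seed + 17 * 1..n).
#' @param null generate null twins instead of clustered specimens.
#' @return named list of [HookSpecimen-class]; the per-specimen
#'   [SyntheticConfig-class] objects are attached as attribute `configs`.
#' @export
generateSuite <- function(baseConfig = syntheticConfig(), nSpecimens = 7L,
                          seeds = NULL, null = FALSE) {
  if (nSpecimens < 1L) stop("nSpecimens must be >= 1")
  if (is.null(seeds)) seeds <- baseConfig@seed + 17L * seq_len(nSpecimens)
  stopifnot(length(seeds) == nSpecimens)
  configs <- list()
  out <- list()
  for (k in seq_len(nSpecimens)) {
    hpa <- withSeed(seeds[k], 2L * sample(7:30, 1L))
    cfg <- baseConfig
    cfg@seed <- as.integer(seeds[k])
    cfg@hooksPerAxis <- hpa
    sp <- if (null) generateNull(cfg) else generateClustered(cfg)
    configs[[specimenID(sp)]] <- cfg
    out[[specimenID(sp)]] <- sp
  }
  attr(out, "configs") <- configs
  out
}
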
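#' Admissible morphotype codes
#'
#' The nine hook morphotype classes recognised in scaphitid ammonite
#' assemblages: five major bicuspid classes `G1`--`G5` (`G1`/`G5` and
#' `G2`/`G4` are mirror pairs), the very small bicuspid class `VSB`, and the
#' rare tricuspid (`TRI`), unicuspid (`UNI`) and rounded (`RND`) classes.
#'
#' @return Character vector of the nine admissible codes, in canonical order.
#' @export
#' @examples
#' morphotypeCodes()
morphotypeCodes <- function() {
  c("G1", "G2", "G3", "G4", "G5", "VSB", "TRI", "UNI", "RND")
}

#' HookSpecimen: a labelled 3D hook assemblage
#'
#' An S4 container for one specimen (one body chamber): every hook carries a
#' unique integer id, a morphotype label, optionally the four landmarks
#' digitised on its basal opening, and the derived centroid (the arithmetic
#' mean of the four landmarks) used by all downstream spatial statistics.
#' Coordinates are millimetres in an arbitrary specimen-fixed frame; no
#' registration between specimens is attempted.
#'
#' @slot specimenID single character identifier.
#' @slot hookID integer vector, unique within the specimen.
#' @slot morphotype factor with levels exactly [morphotypeCodes()].
#' @slot landmarks numeric array `n x 4 x 3` of opening landmarks (mm), or a
#'   zero-length array when only centroids are available ("centroid mode").
#' @slot centroids numeric matrix `n x 3` (mm).
#' @slot provenance `"landmarks"` or `"centroids"`, recording the input mode.
#'
#' @seealso [HookSpecimen()] for the validating constructor,
#'   [readSpecimens()] for file input.
#' @export
setClass("HookSpecimen",
  representation(
    specimenID = "character",
    hookID = "integer",
    morphotype = "factor",
    landmarks = "array",
    centroids = "matrix",
    provenance = "character"
  )
)

setValidity("HookSpecimen", function(object) {
  n <- length(object@hookID)
  msgs <- character(0)
  if (length(object@specimenID) != 1L || is.na(object@specimenID)) {
    msgs <- c(msgs, "specimenID must be a single non-missing string")
  }
  if (anyDuplicated(object@hookID)) {
    msgs <- c(msgs, "hook ids must be unique within a specimen")
  }
  if (length(object@morphotype) != n) {
    msgs <- c(msgs, "morphotype length must match number of hooks")
  }
  if (!identical(levels(object@morphotype), morphotypeCodes())) {
    msgs <- c(msgs, "morphotype levels must be exactly the 9 admissible codes")
  }
  if (anyNA(object@morphotype)) {
    msgs <- c(msgs, "morphotype labels must not be missing")
  }
  if (!is.numeric(object@centroids) || !identical(dim(object@centroids), c(n, 3L))) {
    msgs <- c(msgs, "centroids must be a numeric n x 3 matrix")
  } else if (n > 0 && !all(is.finite(object@centroids))) {
    msgs <- c(msgs, "centroid coordinates must be finite")
  }
  if (length(object@landmarks) > 0) {
    if (!identical(dim(object@landmarks), c(n, 4L, 3L))) {
      msgs <- c(msgs, "landmarks must be an n x 4 x 3 array")
    } else if (n > 0) {
      if (!all(is.finite(object@landmarks))) {
        msgs <- c(msgs, "landmark coordinates must be finite")
      } else {
        derived <- apply(object@landmarks, c(1L, 3L), mean)
        if (max(abs(derived - object@centroids)) > 1e-8) {
          msgs <- c(msgs, "centroids must equal the mean of the 4 opening landmarks")
        }
      }
    }
  }
  if (!object@provenance %in% c("landmarks", "centroids")) {
    msgs <- c(msgs, "provenance must be 'landmarks' or 'centroids'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HookSpecimen
#'
#' @param specimenID single character identifier.
#' @param hookID integer vector of unique hook ids.
#' @param morphotype character or factor of morphotype codes (see
#'   [morphotypeCodes()]); unknown codes are rejected.
#' @param landmarks optional `n x 4 x 3` array of opening landmarks (mm).
#'   When given, centroids are derived from it.
#' @param centroids optional `n x 3` matrix of hook centroids (mm); required
#'   when `landmarks` is absent.
#' @return A validated [HookSpecimen-class] object with hooks ordered by id.
#' @export
#' @examples
#' sp <- HookSpecimen("demo", 1:2, c("G1", "G4"),
#'   centroids = rbind(c(0, 0, 0), c(3, 4, 0))
#' )
#' nHooks(sp)
HookSpecimen <- function(specimenID, hookID, morphotype,
                         landmarks = NULL, centroids = NULL) {
  hookID <- as.integer(hookID)
  n <- length(hookID)
  bad <- setdiff(as.character(morphotype), morphotypeCodes())
  if (length(bad)) {
    stop("unknown morphotype code(s): ", paste(unique(bad), collapse = ", "))
  }
  morphotype <- factor(as.character(morphotype), levels = morphotypeCodes())
  if (is.null(landmarks) && is.null(centroids)) {
    stop("supply landmarks or centroids")
  }
  if (!is.null(landmarks)) {
    landmarks <- array(as.numeric(landmarks), dim = c(n, 4L, 3L))
    centroids <- apply(landmarks, c(1L, 3L), mean)
    if (n == 1L) centroids <- matrix(centroids, 1L, 3L)
    provenance <- "landmarks"
  } else {
    landmarks <- array(numeric(0), dim = c(0L, 4L, 3L))
    centroids <- matrix(as.numeric(centroids), n, 3L)
    provenance <- "centroids"
  }
  dimnames(centroids) <- list(NULL, c("x", "y", "z"))
  ord <- order(hookID)
  if (length(landmarks) > 0) landmarks <- landmarks[ord, , , drop = FALSE]
  methods::new("HookSpecimen",
    specimenID = as.character(specimenID),
    hookID = hookID[ord],
    morphotype = morphotype[ord],
    landmarks = landmarks,
    centroids = centroids[ord, , drop = FALSE],
    provenance = provenance
  )
}

#' PersistenceDiagram: Vietoris-Rips persistence bars
#'
#' Bars of the Rips filtration on a centroid cloud. Dimension-0 bars all have
#' birth 0 and record component merge scales (one bar per point; components
#' alive past `maxScale` carry death `Inf`). Dimension-1 bars record the
#' birth and death scales of loops.
#'
#' @slot bars data.frame with columns `dimension` (0 or 1), `birth`, `death`
#'   (mm; `Inf` for essential classes).
#' @slot nPoints number of input points.
#' @slot maxScale truncation scale of the filtration (mm).
#' @export
setClass("PersistenceDiagram",
  representation(bars = "data.frame", nPoints = "integer", maxScale = "numeric")
)

setValidity("PersistenceDiagram", function(object) {
  b <- object@bars
  msgs <- character(0)
  if (!all(c("dimension", "birth", "death") %in% names(b))) {
    msgs <- c(msgs, "bars must have columns dimension, birth, death")
  } else {
    if (nrow(b) && !all(b$dimension %in% c(0L, 1L))) {
      msgs <- c(msgs, "only dimensions 0 and 1 are supported")
    }
    if (nrow(b) && any(b$death < b$birth)) {
      msgs <- c(msgs, "bars must satisfy birth <= death")
    }
    if (sum(b$dimension == 0L) != object@nPoints) {
      msgs <- c(msgs, "number of dimension-0 bars must equal number of points")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LinkGraph: component-merge links of one morphotype subset
#'
#' The `n - 1` component-merging edges of the dimension-0 Rips filtration on
#' a set of hook centroids (equivalently the Euclidean minimum spanning
#' tree). Edge strength is the merge scale; edges with strength at or below
#' the Tukey upper fence of all strengths are flagged `retained` (the
#' "strongest and best integrated" links).
#'
#' @slot hookIDs integer ids of the member hooks.
#' @slot morphotype character label of the subset (possibly several codes).
#' @slot edges data.frame with columns `from`, `to` (hook ids), `strength`
#'   (mm) and `retained` (logical).
#' @slot fence numeric Tukey upper fence applied to strengths (mm).
#' @export
setClass("LinkGraph",
  representation(
    hookIDs = "integer", morphotype = "character",
    edges = "data.frame", fence = "numeric"
  )
)

setValidity("LinkGraph", function(object) {
  e <- object@edges
  msgs <- character(0)
  if (!all(c("from", "to", "strength", "retained") %in% names(e))) {
    msgs <- c(msgs, "edges must have columns from, to, strength, retained")
  } else {
    n <- length(object@hookIDs)
    if (n >= 2 && nrow(e) != n - 1L) {
      msgs <- c(msgs, "a merge-link graph on n hooks must have n - 1 edges")
    }
    if (nrow(e) && !all(c(e$from, e$to) %in% object@hookIDs)) {
      msgs <- c(msgs, "edge endpoints must be member hook ids")
    }
    if (nrow(e) && is.unsorted(e$strength)) {
      msgs <- c(msgs, "edge strengths must be non-decreasing in merge order")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' HookAxis: one reconstructed armature axis
#'
#' An ordered sequence of hooks tracing a candidate arm/tentacle axis,
#' produced by [inferAxes()]. The ordering merges the diameter paths of the
#' paired morphotypes' retained link graphs.
#'
#' @slot hookIDs integer ids in axis order (a simple path; no repeats).
#' @slot morphotype character morphotype per member hook.
#' @slot arcLength numeric cumulative distance along the ordered sequence (mm).
#' @slot pair character vector of the morphotype codes defining the axis.
#' @slot totalLength numeric sum of consecutive centroid distances (mm).
#' @slot straightness numeric in (0, 1]: end-to-end distance / total length.
#' @slot coverage numeric fraction of the pair's retained hooks on the axis.
#' @export
setClass("HookAxis",
  representation(
    hookIDs = "integer", morphotype = "character", arcLength = "numeric",
    pair = "character", totalLength = "numeric", straightness = "numeric",
    coverage = "numeric"
  )
)

setValidity("HookAxis", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@hookIDs)) {
    msgs <- c(msgs, "an axis path must not repeat hooks")
  }
  if (length(object@arcLength) != length(object@hookIDs)) {
    msgs <- c(msgs, "arcLength must have one entry per hook")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: generative parameters for synthetic specimens
#'
#' Describes the world the synthetic generator emulates: up to two armature
#' axes of imbricated, side-by-side morphotype files (mirror pairs G1-G4 and
#' G2-G5), a basal group of small morphotypes (G3 and VSB) at the axis base,
#' a few scattered rare hooks, isotropic landmarking/taphonomic jitter, an
#' optional uniform relocation of a fraction of hooks (taphonomic
#' scrambling), and an ellipsoidal body-chamber-like support for the random
#' null. All lengths are millimetres.
#'
#' @slot seed integer RNG seed.
#' @slot nAxes 1 or 2 axes.
#' @slot hooksPerAxis even count of hooks per axis (half per morphotype file).
#' @slot pairAssignment list of character pairs populating each axis.
#' @slot axisGeometry `"straight"` or `"arc"`.
#' @slot arcRadius arc radius (mm), used when `axisGeometry == "arc"`.
#' @slot arcSpanDeg angular span of the arc (degrees).
#' @slot spacing along-axis imbrication step between consecutive same-file
#'   hooks (mm).
#' @slot lateralOffset distance between the two files of a pair (mm).
#' @slot basalGroupSize count of basal-group hooks (split between G3 and VSB).
#' @slot rareCounts named integer counts for TRI, UNI, RND.
#' @slot jitterSD isotropic Gaussian noise SD (mm).
#' @slot scrambleFraction fraction of hooks relocated uniformly in the chamber.
#' @slot chamber ellipsoid semi-axes (mm) of the body-chamber-like volume.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer", nAxes = "integer", hooksPerAxis = "integer",
    pairAssignment = "list", axisGeometry = "character",
    arcRadius = "numeric", arcSpanDeg = "numeric",
    spacing = "numeric", lateralOffset = "numeric",
    basalGroupSize = "integer", rareCounts = "integer",
    jitterSD = "numeric", scrambleFraction = "numeric", chamber = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  chk <- function(cond, msg) if (!cond) msgs <<- c(msgs, msg)
  chk(length(object@seed) == 1L && is.finite(object@seed), "seed must be a single integer")
  chk(object@nAxes %in% 1:2, "nAxes must be 1 or 2")
  chk(object@hooksPerAxis >= 2L && object@hooksPerAxis %% 2L == 0L,
      "hooksPerAxis must be an even count >= 2")
  chk(length(object@pairAssignment) >= object@nAxes,
      "pairAssignment must name a morphotype pair per axis")
  for (p in object@pairAssignment) {
    chk(length(p) == 2L && all(p %in% morphotypeCodes()) && p[1] != p[2],
        "each pair must be two distinct morphotype codes")
  }
  chk(object@axisGeometry %in% c("straight", "arc"),
      "axisGeometry must be 'straight' or 'arc'")
  chk(object@arcRadius > 0, "arcRadius must be positive")
  chk(object@arcSpanDeg > 0 && object@arcSpanDeg <= 360, "arcSpanDeg in (0, 360]")
  chk(object@spacing > 0, "spacing must be positive")
  chk(object@lateralOffset >= 0, "lateralOffset must be non-negative")
  chk(object@basalGroupSize >= 0L, "basalGroupSize must be >= 0")
  chk(all(object@rareCounts >= 0L) &&
        identical(sort(names(object@rareCounts)), sort(c("TRI", "UNI", "RND"))),
      "rareCounts must be non-negative, named TRI, UNI, RND")
  chk(object@jitterSD >= 0, "jitterSD must be >= 0")
  chk(object@scrambleFraction >= 0 && object@scrambleFraction <= 1,
      "scrambleFraction must be in [0, 1]")
  chk(length(object@chamber) == 3L && all(object@chamber > 0),
      "chamber must be three positive semi-axes")
  if (length(msgs)) msgs else TRUE
})
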
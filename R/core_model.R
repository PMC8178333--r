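#' Centroid of the four opening landmarks
#'
#' The centroid of a hook's basal opening — the coordinate-wise arithmetic
#' mean of its four landmarks — is the proxy for the hook's soft-tissue
#' attachment point and the only geometry used downstream.
#'
#' @param landmarks numeric `4 x 3` matrix (rows = landmarks, columns =
#'   x, y, z in mm).
#' @param hookID optional id used in error messages.
#' @return numeric length-3 centroid.
#' @export
#' @examples
#' computeCentroid(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0)))
computeCentroid <- function(landmarks, hookID = NULL) {
  landmarks <- as.matrix(landmarks)
  who <- if (is.null(hookID)) "" else paste0(" for hook ", hookID)
  if (!identical(dim(landmarks), c(4L, 3L))) {
    stop("exactly 4 opening landmarks (4 x 3 matrix) are required", who)
  }
  if (!all(is.finite(landmarks))) {
    stop("landmark coordinates must be finite", who)
  }
  colMeans(landmarks)
}

#' @rdname crownmap-accessors
#' @export
setMethod("specimenID", "HookSpecimen", function(x) x@specimenID)

#' @rdname crownmap-accessors
#' @export
setMethod("hookIDs", "HookSpecimen", function(x) x@hookID)

#' @rdname crownmap-accessors
#' @export
setMethod("morphotypes", "HookSpecimen", function(x) x@morphotype)

#' @rdname crownmap-accessors
#' @export
setMethod("centroids", "HookSpecimen", function(x) x@centroids)

#' @rdname crownmap-accessors
#' @export
setMethod("nHooks", "HookSpecimen", function(x) length(x@hookID))

#' @rdname crownmap-accessors
#' @export
setMethod("morphotypeCounts", "HookSpecimen", function(x) {
  tab <- table(x@morphotype)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[cnt > 0]
})

#' @rdname crownmap-accessors
#' @export
setMethod("linkEdges", "LinkGraph", function(x) x@edges)

#' @rdname crownmap-accessors
#' @export
setMethod("diagramBars", "PersistenceDiagram", function(x) x@bars)

#' @rdname crownmap-accessors
#' @export
setMethod("axisHooks", "HookAxis", function(x) x@hookIDs)

#' Subset a specimen by hook
#'
#' @param x a [HookSpecimen-class].
#' @param i logical or integer index over hooks (in id order).
#' @param j,...,drop ignored.
#' @return a [HookSpecimen-class] with the selected hooks.
#' @export
setMethod("[", "HookSpecimen", function(x, i, j, ..., drop = FALSE) {
  keep <- seq_along(x@hookID)[i]
  lm <- if (length(x@landmarks) > 0) x@landmarks[keep, , , drop = FALSE] else x@landmarks
  methods::new("HookSpecimen",
    specimenID = x@specimenID,
    hookID = x@hookID[keep],
    morphotype = x@morphotype[keep],
    landmarks = lm,
    centroids = x@centroids[keep, , drop = FALSE],
    provenance = x@provenance
  )
})

#' @export
#' @describeIn HookSpecimen compact display of hook and morphotype counts.
#' @param object a `HookSpecimen`.
setMethod("show", "HookSpecimen", function(object) {
  cnt <- morphotypeCounts(object)
  cat("HookSpecimen '", object@specimenID, "': ", nHooks(object),
    " hooks (", object@provenance, " mode)\n",
    sep = ""
  )
  if (length(cnt)) {
    cat("  ", paste(names(cnt), cnt, sep = "=", collapse = " "), "\n", sep = "")
  }
})

setMethod("show", "PersistenceDiagram", function(object) {
  b <- object@bars
  cat("PersistenceDiagram: ", object@nPoints, " points, maxScale ",
    format(object@maxScale, digits = 4), " mm\n",
    "  dim0: ", sum(b$dimension == 0L), " bars (",
    sum(b$dimension == 0L & is.infinite(b$death)), " essential); dim1: ",
    sum(b$dimension == 1L), " bars\n",
    sep = ""
  )
})

setMethod("show", "LinkGraph", function(object) {
  cat("LinkGraph [", paste(object@morphotype, collapse = "+"), "]: ",
    length(object@hookIDs), " hooks, ", nrow(object@edges), " links (",
    sum(object@edges$retained), " retained, fence ",
    format(object@fence, digits = 4), " mm)\n",
    sep = ""
  )
})

setMethod("show", "HookAxis", function(object) {
  cat("HookAxis [", paste(object@pair, collapse = "-"), "]: ",
    length(object@hookIDs), " hooks, length ",
    format(object@totalLength, digits = 4), " mm, straightness ",
    format(object@straightness, digits = 3), ", coverage ",
    format(object@coverage, digits = 3), "\n",
    sep = ""
  )
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: seed ", object@seed, ", ", object@nAxes, " ",
    object@axisGeometry, " axis(es) x ", object@hooksPerAxis,
    " hooks, basal ", object@basalGroupSize, ", jitter ",
    object@jitterSD, " mm, scramble ", object@scrambleFraction, "\n",
    sep = ""
  )
})

#' @rdname pairwiseDistances
#' @export
setMethod("pairwiseDistances", "HookSpecimen", function(x) {
  if (nHooks(x) < 2L) stop("specimen too small for distance analysis")
  D <- as.matrix(stats::dist(x@centroids))
  dimnames(D) <- list(x@hookID, x@hookID)
  D
})

#' @rdname pairwiseDistances
#' @export
setMethod("pairwiseDistances", "matrix", function(x) {
  if (nrow(x) < 2L) stop("specimen too small for distance analysis")
  as.matrix(stats::dist(x))
})
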
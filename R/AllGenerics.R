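#' @name crownmap-accessors
#' @title Accessors for crownmap objects
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than reaching into slots.
#' @param x a crownmap object.
#' @param object a crownmap object (for `show`).
#' @return `specimenID`: character; `hookIDs`: integer vector; `morphotypes`:
#'   factor; `centroids`: numeric matrix (mm); `nHooks`: integer;
#'   `morphotypeCounts`: named integer vector over the codes present;
#'   `linkEdges`: data.frame of merge edges; `diagramBars`: data.frame of
#'   persistence bars; `axisHooks`: integer vector in path order.
NULL

#' @rdname crownmap-accessors
#' @export
setGeneric("specimenID", function(x) standardGeneric("specimenID"))

#' @rdname crownmap-accessors
#' @export
setGeneric("hookIDs", function(x) standardGeneric("hookIDs"))

#' @rdname crownmap-accessors
#' @export
setGeneric("morphotypes", function(x) standardGeneric("morphotypes"))

#' @rdname crownmap-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname crownmap-accessors
#' @export
setGeneric("nHooks", function(x) standardGeneric("nHooks"))

#' @rdname crownmap-accessors
#' @export
setGeneric("morphotypeCounts", function(x) standardGeneric("morphotypeCounts"))

#' @rdname crownmap-accessors
#' @export
setGeneric("linkEdges", function(x) standardGeneric("linkEdges"))

#' @rdname crownmap-accessors
#' @export
setGeneric("diagramBars", function(x) standardGeneric("diagramBars"))

#' @rdname crownmap-accessors
#' @export
setGeneric("axisHooks", function(x) standardGeneric("axisHooks"))

#' Pairwise centroid distances
#'
#' Symmetric Euclidean distance matrix between the hook centroids of a
#' specimen (mm), the input to every nearest-neighbour and topological
#' analysis.
#'
#' @param x a [HookSpecimen-class] (or numeric matrix of points).
#' @return symmetric numeric matrix with zero diagonal, dimnames = hook ids.
#' @export
setGeneric("pairwiseDistances", function(x) standardGeneric("pairwiseDistances"))
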
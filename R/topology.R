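# Self-contained Vietoris-Rips persistent homology (dimensions 0 and 1) on
# centroid clouds, and extraction of the component-merge "links" drawn
# between hooks of a morphotype. The heavy lifting (edge/triangle
# enumeration and GF(2) boundary reduction) is compiled; see src/rips.cpp.

#' Vietoris-Rips persistence of a point cloud
#'
#' Computes the persistence diagram of the Rips filtration on 3D points (or
#' on a specimen's centroids). Dimension 0 comes from union-find over edges
#' sorted by length (elder rule; ties towards the smaller point index);
#' dimension 1 from GF(2) boundary-matrix reduction with edges and triangles
#' entering at their longest-edge scale. The filtration is truncated at
#' `maxScale` (default: the cloud diameter, so it completes).
#'
#' @param x numeric `n x 3` matrix of points (mm) or a [HookSpecimen-class].
#' @param maxDim 0 or 1.
#' @param maxScale truncation scale (mm); `NULL` for the cloud diameter.
#' @return a [PersistenceDiagram-class]. There are exactly `n` dimension-0
#'   bars, one per point; components never merging below `maxScale` carry
#'   death `Inf`.
#' @export
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' diagramBars(ripsPersistence(sq)) # one loop born at 1, dying at sqrt(2)
ripsPersistence <- function(x, maxDim = 1L, maxScale = NULL) {
  if (methods::is(x, "HookSpecimen")) x <- centroids(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1L) stop("empty point set")
  if (maxDim > 1L) stop("only dimensions 0 and 1 are supported")
  if (maxDim < 0L) stop("maxDim must be 0 or 1")
  if (n == 1L) {
    bars <- data.frame(dimension = 0L, birth = 0, death = Inf)
    return(methods::new("PersistenceDiagram",
      bars = bars, nPoints = 1L,
      maxScale = if (is.null(maxScale)) 0 else maxScale
    ))
  }
  D <- as.matrix(stats::dist(x))
  if (is.null(maxScale)) maxScale <- max(D)
  if (maxScale <= 0) stop("maxScale must be positive")
  res <- rips_cpp(D, maxScale, as.integer(maxDim))
  nInf <- n - length(res$h0death)
  bars <- data.frame(
    dimension = 0L,
    birth = 0,
    death = c(res$h0death, rep(Inf, nInf))
  )
  if (maxDim >= 1L) {
    if (length(res$h1birth)) {
      bars <- rbind(bars, data.frame(
        dimension = 1L, birth = res$h1birth, death = res$h1death
      ))
    }
    if (length(res$h1infbirth)) {
      bars <- rbind(bars, data.frame(
        dimension = 1L, birth = res$h1infbirth, death = Inf
      ))
    }
  }
  rownames(bars) <- NULL
  methods::new("PersistenceDiagram",
    bars = bars, nPoints = n, maxScale = maxScale
  )
}

# Merge (MST) edges of the dimension-0 filtration on a point matrix:
# data.frame(from, to, strength) with from/to as row indices, in merge order.
merge_links <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  res <- rips_cpp(D, max(D), 0L)
  data.frame(from = res$mst_i, to = res$mst_j, strength = res$mst_w)
}

#' Morphotype link graph (strongest and best integrated links)
#'
#' The `n - 1` component-merging edges of the dimension-0 Rips filtration on
#' one morphotype's centroids — the Euclidean minimum spanning tree, with
#' edge strength equal to the merge scale. Edges with strength at or below
#' the Tukey upper fence `Q3 + fenceMultiplier x IQR` of the strengths are
#' marked retained; the rest are the weak long-range links dropped when only
#' the strongest, best integrated links are displayed.
#'
#' @param specimen a [HookSpecimen-class].
#' @param morphotype one or more morphotype codes; the graph is built on the
#'   union of their hooks.
#' @param fenceMultiplier IQR multiplier of the retention fence (default 1.5).
#' @return a [LinkGraph-class]; with fewer than 2 member hooks, an empty
#'   graph with a warning.
#' @export
morphotypeLinks <- function(specimen, morphotype, fenceMultiplier = 1.5) {
  sel <- as.character(morphotypes(specimen)) %in% morphotype
  ids <- hookIDs(specimen)[sel]
  empty_edges <- data.frame(
    from = integer(0), to = integer(0),
    strength = numeric(0), retained = logical(0)
  )
  if (length(ids) < 2L) {
    warning("fewer than 2 hooks of morphotype ", paste(morphotype, collapse = "+"))
    return(methods::new("LinkGraph",
      hookIDs = ids, morphotype = morphotype,
      edges = empty_edges, fence = NA_real_
    ))
  }
  pts <- centroids(specimen)[sel, , drop = FALSE]
  e <- merge_links(pts)
  e$from <- ids[e$from]
  e$to <- ids[e$to]
  q <- stats::quantile(e$strength, c(0.25, 0.75), names = FALSE, type = 7)
  # The Tukey fence degenerates when strengths are nearly constant (IQR -> 0):
  # every link of a continuous file then sits at the fence and sampling noise
  # splits it. Floor the fence at twice the median strength to guard that.
  fence <- max(
    q[2] + fenceMultiplier * (q[2] - q[1]),
    2 * stats::median(e$strength)
  )
  e$retained <- e$strength <= fence
  methods::new("LinkGraph",
    hookIDs = ids, morphotype = morphotype, edges = e, fence = fence
  )
}

# --- bottleneck distance ----------------------------------------------------

# Feasibility of the bottleneck matching at threshold eps, via the standard
# bipartite reduction: left nodes are the bars of d1 plus one diagonal slot
# per bar of d2; right nodes are the bars of d2 plus one diagonal slot per
# bar of d1. Bar i (left) may match bar j (right) when cost(i, j) <= eps,
# or its own diagonal slot when its projection distance is <= eps; diagonal
# slots match each other freely. Feasible iff a perfect matching exists.
bottleneck_feasible <- function(costM, diag1, diag2, eps) {
  n1 <- length(diag1)
  n2 <- length(diag2)
  tol <- eps + 1e-12
  nL <- n1 + n2
  nR <- n2 + n1
  neighbours <- function(u) {
    if (u <= n1) {
      j <- if (n2) which(costM[u, seq_len(n2)] <= tol) else integer(0)
      if (diag1[u] <= tol) j <- c(j, n2 + u)
      j
    } else {
      # diagonal slot for bar (u - n1) of d2
      j <- if (diag2[u - n1] <= tol) u - n1 else integer(0)
      c(j, n2 + seq_len(n1)) # any right diagonal slot
    }
  }
  matchR <- rep(NA_integer_, nR)
  augment <- function(u, seen) {
    for (v in neighbours(u)) {
      if (!seen[v]) {
        seen[v] <- TRUE
        if (is.na(matchR[v]) || Recall(matchR[v], seen)) {
          matchR[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (u in seq_len(nL)) {
    seen <- rep(FALSE, nR)
    if (!augment(u, seen)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Bottleneck distance between persistence diagrams
#'
#' Standard bottleneck matching cost (L-infinity cost per matched pair,
#' diagonal projections allowed) between the bars of one dimension.
#' Infinite bars are matched among themselves by sorted birth; if the two
#' diagrams carry different numbers of infinite bars the distance is `Inf`.
#'
#' @param d1,d2 [PersistenceDiagram-class] objects.
#' @param dimension 0 or 1 (default 0).
#' @return non-negative real.
#' @export
diagramDistance <- function(d1, d2, dimension = 0L) {
  b1 <- diagramBars(d1)
  b1 <- b1[b1$dimension == dimension, , drop = FALSE]
  b2 <- diagramBars(d2)
  b2 <- b2[b2$dimension == dimension, , drop = FALSE]
  inf1 <- b1[is.infinite(b1$death), , drop = FALSE]
  inf2 <- b2[is.infinite(b2$death), , drop = FALSE]
  if (nrow(inf1) != nrow(inf2)) {
    return(Inf)
  }
  dInf <- if (nrow(inf1)) {
    max(abs(sort(inf1$birth) - sort(inf2$birth)))
  } else {
    0
  }
  f1 <- b1[is.finite(b1$death), , drop = FALSE]
  f2 <- b2[is.finite(b2$death), , drop = FALSE]
  n1 <- nrow(f1)
  n2 <- nrow(f2)
  if (n1 == 0L && n2 == 0L) {
    return(dInf)
  }
  diag1 <- if (n1) (f1$death - f1$birth) / 2 else numeric(0)
  diag2 <- if (n2) (f2$death - f2$birth) / 2 else numeric(0)
  costM <- matrix(Inf, max(n1, 1L), max(n2, 1L))
  if (n1 && n2) {
    costM <- outer(seq_len(n1), seq_len(n2), function(i, j) {
      pmax(abs(f1$birth[i] - f2$birth[j]), abs(f1$death[i] - f2$death[j]))
    })
  }
  cand <- sort(unique(c(0, diag1, diag2, if (n1 && n2) as.vector(costM))))
  cand <- cand[is.finite(cand)]
  lo <- 1L
  hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (bottleneck_feasible(costM, diag1, diag2, cand[mid])) hi <- mid else lo <- mid + 1L
  }
  max(cand[lo], dInf)
}
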
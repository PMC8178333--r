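# Independent oracles used across the suite. These deliberately take
# different code paths from the package: scalar brute-force loops for
# nearest neighbours, stats::hclust for single-linkage merge heights,
# igraph for MSTs and tree metrics, and a plain-R boundary-matrix reduction
# (plus a rank-based Betti computation) for dimension-1 persistence.

make_specimen <- function(points, labels, id = "fix", ids = seq_len(nrow(points))) {
  HookSpecimen(id, ids, labels, centroids = as.matrix(points))
}

rand_points <- function(n, scale = 10) {
  matrix(stats::runif(3 * n, -scale, scale), n, 3)
}

# random rigid motion (proper rotation + translation)
rigid_motion <- function(points) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tr <- stats::rnorm(3, sd = 5)
  sweep(as.matrix(points) %*% Q, 2, tr, `+`)
}

# --- nearest-neighbour brute force ------------------------------------------

# observed same-morphotype NN counts by explicit scalar loops
brute_nn_same <- function(points, labels) {
  n <- nrow(points)
  same <- integer(0)
  nnlab <- character(n)
  for (i in seq_len(n)) {
    best <- Inf
    bestj <- NA
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d < best - 1e-15) {
        best <- d
        bestj <- j
      }
    }
    nnlab[i] <- labels[bestj]
  }
  vapply(
    sort(unique(labels)),
    function(m) sum(labels == m & nnlab == m), integer(1)
  )
}

# observed cross counts (nearest among other labels), explicit loops
brute_nn_cross <- function(points, labels) {
  n <- nrow(points)
  out <- list()
  for (i in seq_len(n)) {
    best <- Inf
    bestj <- NA
    for (j in seq_len(n)) {
      if (j == i || labels[j] == labels[i]) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d < best - 1e-15) {
        best <- d
        bestj <- j
      }
    }
    if (!is.na(bestj)) {
      key <- paste(labels[i], labels[bestj], sep = "->")
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- dimension-1 persistence oracles ----------------------------------------

# plain-R boundary-matrix reduction (no clearing, dense low lookup via a
# named list of sorted integer vectors); returns finite dim-1 bars
r_reduce_h1 <- function(points, maxScale = NULL) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(D)
  if (is.null(maxScale)) maxScale <- max(D)
  ed <- which(upper.tri(D) & D <= maxScale, arr.ind = TRUE)
  ew <- D[ed]
  o <- order(ew, ed[, 1], ed[, 2])
  ed <- ed[o, , drop = FALSE]
  ew <- ew[o]
  eidx <- matrix(NA_integer_, n, n)
  eidx[ed] <- seq_len(nrow(ed))
  eidx[ed[, c(2, 1)]] <- seq_len(nrow(ed))
  tri <- t(utils::combn(n, 3))
  tw <- pmax(
    D[tri[, c(1, 2)]],
    pmax(D[tri[, c(1, 3)]], D[tri[, c(2, 3)]])
  )
  keep <- tw <= maxScale
  tri <- tri[keep, , drop = FALSE]
  tw <- tw[keep]
  o <- order(tw) # stable; ties keep lexicographic enumeration order
  tri <- tri[o, , drop = FALSE]
  tw <- tw[o]
  lowOwner <- integer(nrow(ed)) # 0 = free
  cols <- vector("list", nrow(tri))
  births <- deaths <- numeric(0)
  for (t in seq_len(nrow(tri))) {
    col <- sort(c(
      eidx[tri[t, 1], tri[t, 2]],
      eidx[tri[t, 1], tri[t, 3]],
      eidx[tri[t, 2], tri[t, 3]]
    ))
    repeat {
      if (!length(col)) break
      low <- col[length(col)]
      own <- lowOwner[low]
      if (own == 0L) break
      other <- cols[[own]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    if (length(col)) {
      low <- col[length(col)]
      lowOwner[low] <- t
      cols[[t]] <- col
      if (tw[t] > ew[low]) {
        births <- c(births, ew[low])
        deaths <- c(deaths, tw[t])
      }
    }
  }
  data.frame(birth = births, death = deaths)
}

# rank of a GF(2) matrix given as a list of integer column supports
gf2_rank <- function(columns, nrows) {
  pivots <- list()
  pivot_row <- integer(0)
  rank <- 0L
  for (col in columns) {
    col <- sort(col)
    while (length(col)) {
      low <- col[length(col)]
      k <- match(low, pivot_row)
      if (is.na(k)) break
      other <- pivots[[k]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    if (length(col)) {
      rank <- rank + 1L
      pivots[[rank]] <- col
      pivot_row[rank] <- col[length(col)]
    }
  }
  rank
}

# first Betti number of the Rips complex at a fixed scale, via
# beta1 = E - n + C - rank(boundary_2)  (linear algebra, no pairing)
betti1_at <- function(points, s) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(D)
  ed <- which(upper.tri(D) & D <= s, arr.ind = TRUE)
  E <- nrow(ed)
  eidx <- matrix(NA_integer_, n, n)
  if (E) {
    eidx[ed] <- seq_len(E)
    eidx[ed[, c(2, 1)]] <- seq_len(E)
  }
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  C <- igraph::components(g)$no
  if (n < 3 || E < 3) return(E - n + C)
  tri <- t(utils::combn(n, 3))
  tw <- pmax(D[tri[, c(1, 2)]], pmax(D[tri[, c(1, 3)]], D[tri[, c(2, 3)]]))
  tri <- tri[tw <= s, , drop = FALSE]
  cols <- lapply(seq_len(nrow(tri)), function(t) {
    c(
      eidx[tri[t, 1], tri[t, 2]],
      eidx[tri[t, 1], tri[t, 3]],
      eidx[tri[t, 2], tri[t, 3]]
    )
  })
  E - n + C - gf2_rank(cols, E)
}

# number of dim-1 bars alive at scale s (born at or before, dead after)
bars_alive_at <- function(diagram, s) {
  b <- diagramBars(diagram)
  b <- b[b$dimension == 1L, , drop = FALSE]
  sum(b$birth <= s & b$death > s)
}

# --- graph oracles ----------------------------------------------------------

igraph_mst_weight <- function(points) {
  D <- as.matrix(stats::dist(points))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

igraph_mst_edges <- function(points) {
  D <- as.matrix(stats::dist(points))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  el <- igraph::as_edgelist(igraph::mst(g), names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# weighted eccentricity-based diameter endpoints + length via igraph
igraph_diameter <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE, vertices = as.character(ids)
  )
  dm <- igraph::distances(g, weights = edges$strength)
  list(length = max(dm), dm = dm)
}

# --- bottleneck oracle (exhaustive over tiny diagrams) ----------------------

exhaustive_bottleneck <- function(b1, b2) {
  # b1, b2: matrices with columns birth, death (finite), few rows
  n1 <- nrow(b1)
  n2 <- nrow(b2)
  diag1 <- (b1[, 2] - b1[, 1]) / 2
  diag2 <- (b2[, 2] - b2[, 1]) / 2
  if (n1 == 0 && n2 == 0) return(0)
  assignments <- function(left, right) {
    # all injective partial matchings left -> right (others to diagonal)
    if (!length(left)) return(list(integer(0)))
    res <- list()
    rest <- assignments(left[-1], right)
    for (r in rest) res[[length(res) + 1]] <- c(NA_integer_, r)
    for (j in right) {
      rest <- assignments(left[-1], setdiff(right, j))
      for (r in rest) res[[length(res) + 1]] <- c(j, r)
    }
    res
  }
  best <- Inf
  for (a in assignments(seq_len(n1), seq_len(n2))) {
    cost <- 0
    for (i in seq_len(n1)) {
      cost <- max(cost, if (is.na(a[i])) diag1[i] else {
        max(abs(b1[i, 1] - b2[a[i], 1]), abs(b1[i, 2] - b2[a[i], 2]))
      })
    }
    un <- setdiff(seq_len(n2), a[!is.na(a)])
    if (length(un)) cost <- max(cost, max(diag2[un]))
    best <- min(best, cost)
  }
  best
}
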
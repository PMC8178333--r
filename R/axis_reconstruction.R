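# Reconstruction of candidate armature axes from morphotype pairings. The
# original link figures draw component-merge links per morphotype; an axis
# here is the merged diameter paths of the two paired morphotypes' retained
# link graphs (two imbricated files running side by side).

#' Morphotype pairing rule
#'
#' Which morphotype pairs populate the candidate axes (default: the mirror
#' pairs G1-G4 and G2-G5) and which small morphotypes form the basal group
#' expected at the axis base (default: G3 and the very small bicuspids).
#'
#' @param pairs list of unordered morphotype pairs; must be disjoint.
#' @param basal character vector of basal-group morphotypes.
#' @return a validated `PairingRule` list.
#' @export
pairingRule <- function(pairs = list(c("G1", "G4"), c("G2", "G5")),
                        basal = c("G3", "VSB")) {
  flat <- unlist(pairs)
  if (!all(flat %in% morphotypeCodes()) || !all(basal %in% morphotypeCodes())) {
    stop("unknown morphotype code in pairing rule")
  }
  if (anyDuplicated(flat)) stop("morphotype pairs must be disjoint")
  if (!all(lengths(pairs) == 2L)) stop("each pair must have two morphotypes")
  structure(list(pairs = pairs, basal = basal), class = "PairingRule")
}

# Weighted diameter path of a tree given an edge list over integer ids.
# Double Dijkstra sweep (exact on trees); ties broken towards smaller ids.
# Returns the ordered id path.
tree_diameter_path <- function(ids, edges) {
  n <- length(ids)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- idx[[as.character(edges$from[e])]]
    b <- idx[[as.character(edges$to[e])]]
    w <- edges$strength[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  sweep <- function(start) {
    dist <- rep(NA_real_, n)
    parent <- rep(NA_integer_, n)
    dist[start] <- 0
    stack <- start
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + nb[r, 2]
          parent[v] <- u
          stack <- c(stack, v)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  s1 <- sweep(which.min(ids)) # any node of the component; smallest id
  u <- which(s1$dist == max(s1$dist, na.rm = TRUE))
  u <- u[which.min(ids[u])]
  s2 <- sweep(u)
  v <- which(s2$dist == max(s2$dist, na.rm = TRUE))
  v <- v[which.min(ids[v])]
  path <- v
  while (!is.na(s2$parent[path[1]])) path <- c(s2$parent[path[1]], path)
  # orient deterministically: start at the end with the smaller id
  if (ids[path[1]] > ids[path[length(path)]]) path <- rev(path)
  ids[path]
}

# Connected components of an undirected edge list over ids; returns a
# component label per id (labelled by smallest member id).
edge_components <- function(ids, edges) {
  idx <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(nrow(edges))) {
    a <- find(idx[[as.character(edges$from[e])]])
    b <- find(idx[[as.character(edges$to[e])]])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_along(ids), function(i) ids[find(i)], ids[1])
}

# Diameter path of the largest retained-link component of one morphotype
# file (ids already restricted to retained hooks of that morphotype).
file_path <- function(specimen, code, fenceMultiplier) {
  sel <- as.character(morphotypes(specimen)) == code
  ids <- hookIDs(specimen)[sel]
  if (length(ids) < 2L) return(ids)
  lg <- suppressWarnings(morphotypeLinks(specimen, code, fenceMultiplier))
  e <- linkEdges(lg)
  e <- e[e$retained, , drop = FALSE]
  comp <- edge_components(ids, e)
  tab <- table(comp)
  big <- names(tab)[tab == max(tab)]
  big <- min(as.integer(big)) # tie: component holding the smallest id
  members <- ids[comp == big]
  esub <- e[e$from %in% members & e$to %in% members, , drop = FALSE]
  tree_diameter_path(members, esub)
}

#' Infer candidate armature axes from morphotype pairings
#'
#' For each morphotype pair, outlier hooks are excluded, each morphotype's
#' retained link graph ([morphotypeLinks()]) is reduced to the diameter path
#' (longest shortest path by edge length) of its largest retained component,
#' and the two file paths are merged into one ordered axis: the longer path
#' serves as the spine, the other file's hooks are interleaved at their
#' nearest spine position (orientation aligned by rank correlation). Axes
#' are ranked by member count and at most `maxAxes` are returned, each
#' reporting the fraction of the pair's retained hooks it contains.
#'
#' @param specimen a [HookSpecimen-class].
#' @param pairing a [pairingRule()].
#' @param maxAxes maximum number of axes returned (default 2).
#' @param outlierStat per-hook statistic for exclusion (`"mean"`/`"nearest"`).
#' @param fenceMultiplier Tukey fence multiplier for exclusion and link
#'   retention (default 1.5).
#' @return list of [HookAxis-class] objects (possibly empty, with a message,
#'   when every pair has fewer than 4 retained hooks).
#' @export
inferAxes <- function(specimen, pairing = pairingRule(), maxAxes = 2L,
                      outlierStat = "mean", fenceMultiplier = 1.5) {
  retained <- retainSpecimen(specimen,
    stat = outlierStat, fenceMultiplier = fenceMultiplier
  )
  cc <- centroids(retained)
  rownames(cc) <- hookIDs(retained)
  axes <- list()
  for (pair in pairing$pairs) {
    lab <- as.character(morphotypes(retained))
    pair_ids <- hookIDs(retained)[lab %in% pair]
    if (length(pair_ids) < 4L) next
    p1 <- file_path(retained, pair[1], fenceMultiplier)
    p2 <- file_path(retained, pair[2], fenceMultiplier)
    if (length(p1) == 0L && length(p2) == 0L) next
    if (length(p2) > length(p1)) {
      spine <- p2
      other <- p1
    } else {
      spine <- p1
      other <- p2
    }
    if (length(other) > 0L && length(spine) > 0L) {
      spineXYZ <- cc[as.character(spine), , drop = FALSE]
      attach_idx <- vapply(other, function(id) {
        d <- sqrt(colSums((t(spineXYZ) - cc[as.character(id), ])^2))
        which.min(d)
      }, integer(1))
      if (length(other) > 2L) {
        rho <- suppressWarnings(
          stats::cor(seq_along(other), attach_idx, method = "spearman")
        )
        if (!is.na(rho) && rho < 0) {
          other <- rev(other)
          attach_idx <- rev(attach_idx)
        }
      }
      ordered <- integer(0)
      for (k in seq_along(spine)) {
        ordered <- c(ordered, spine[k], other[attach_idx == k])
      }
    } else {
      ordered <- spine
    }
    xyz <- cc[as.character(ordered), , drop = FALSE]
    seg <- if (length(ordered) > 1L) {
      sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
    } else {
      numeric(0)
    }
    total <- sum(seg)
    e2e <- if (length(ordered) > 1L) {
      sqrt(sum((xyz[nrow(xyz), ] - xyz[1L, ])^2))
    } else {
      0
    }
    axes[[length(axes) + 1L]] <- methods::new("HookAxis",
      hookIDs = as.integer(ordered),
      morphotype = lab[match(ordered, hookIDs(retained))],
      arcLength = c(0, cumsum(seg)),
      pair = pair,
      totalLength = total,
      straightness = if (total > 0) e2e / total else 1,
      coverage = length(ordered) / length(pair_ids)
    )
  }
  if (!length(axes)) {
    message("no morphotype pair has 4 or more retained hooks; no axes inferred")
    return(list())
  }
  ord <- order(-vapply(axes, function(a) length(a@hookIDs), integer(1)))
  axes[ord][seq_len(min(maxAxes, length(axes)))]
}

#' Basal-group position along the axes
#'
#' Scores the claim that the small morphotypes sit at the base of the axes:
#' the fraction of basal-group hooks whose nearest axis hook lies in the
#' first quartile of its axis's path ordering. Because the algorithm cannot
#' orient an axis anatomically, both orientations of every axis are tried
#' and the maximising combination is reported.
#'
#' @param specimen a [HookSpecimen-class].
#' @param axes list of [HookAxis-class] from [inferAxes()] (at least one).
#' @param basal basal-group morphotype codes (default G3, VSB).
#' @return list with `score` (best over orientations; `NA` if no basal hooks
#'   are present), `orientation` (logical: axis reversed?), and
#'   `allScores` (score of every orientation combination).
#' @export
basalPositionScore <- function(specimen, axes, basal = c("G3", "VSB")) {
  if (!length(axes)) stop("at least one axis is required")
  lab <- as.character(morphotypes(specimen))
  bsel <- lab %in% basal
  if (!any(bsel)) {
    return(list(score = NA_real_, orientation = NULL, allScores = NULL))
  }
  cc <- centroids(specimen)
  rownames(cc) <- hookIDs(specimen)
  bXYZ <- cc[bsel, , drop = FALSE]
  # nearest axis hook per basal hook: which axis, which path position
  nearest <- t(vapply(seq_len(nrow(bXYZ)), function(b) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(axes)) {
      axyz <- cc[as.character(axes[[a]]@hookIDs), , drop = FALSE]
      d <- sqrt(colSums((t(axyz) - bXYZ[b, ])^2))
      k <- which.min(d)
      if (d[k] < best[1]) best <- c(d[k], a, k)
    }
    best
  }, numeric(3)))
  m <- vapply(axes, function(a) length(a@hookIDs), integer(1))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(axes)))
  scores <- apply(combos, 1L, function(rev_flags) {
    pos <- nearest[, 3]
    ax <- nearest[, 2]
    pos <- ifelse(rev_flags[ax], m[ax] + 1 - pos, pos)
    mean(pos <= ceiling(m[ax] / 4))
  })
  best <- which.max(scores)
  list(
    score = scores[best],
    orientation = as.logical(combos[best, ]),
    allScores = as.numeric(scores)
  )
}
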
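# Nearest-neighbour morphotype composition versus analytic random-labelling
# expectations. The observed counts use, for every hook, its unique nearest
# neighbour by centroid distance (ties broken towards the smaller hook id;
# ties have measure zero on real data).

# For each hook (row) the index of its nearest neighbour among `candidate`
# columns. D must be ordered by increasing hook id so that which.min's
# first-minimum rule breaks ties towards the smaller id.
nn_index <- function(D, candidate = NULL) {
  n <- nrow(D)
  diag(D) <- Inf
  if (!is.null(candidate)) D[, !candidate] <- Inf
  apply(D, 1L, function(r) if (all(is.infinite(r))) NA_integer_ else which.min(r))
}

#' Analytic expectation: nearest neighbour of the same morphotype
#'
#' Expected number of hooks of a morphotype whose nearest neighbour is of
#' that same morphotype if labels were assigned at random over the fixed
#' hook positions: `(Nm - 1) / (Ntot - 1) * Nm`.
#'
#' @param Nmi number of hooks of the morphotype.
#' @param Ntot total number of hooks in the specimen.
#' @return expected count (real).
#' @export
#' @examples
#' expectedSame(4, 10) # 4/3
expectedSame <- function(Nmi, Ntot) {
  if (any(Ntot < 2)) stop("specimen too small: N_tot must be >= 2")
  if (any(Nmi < 1) || any(Nmi > Ntot)) stop("need 1 <= Nm_i <= N_tot")
  (Nmi - 1) / (Ntot - 1) * Nmi
}

#' Analytic expectation: nearest neighbour of another given morphotype
#'
#' Expected number of hooks of morphotype i whose nearest hook among all
#' *other* morphotypes is of morphotype j under random labelling:
#' `Nmj / (Ntot - Nmi) * Nmi`. Counts are post-exclusion when outliers have
#' been removed. The expectations over all j sum exactly to `Nmi`.
#'
#' @param Nmi,Nmj,Ntot (retained) counts of morphotypes i and j, and total.
#' @return expected count (real).
#' @export
#' @examples
#' expectedCross(5, 3, 20) # 1
expectedCross <- function(Nmi, Nmj, Ntot) {
  if (any(Nmi < 1) || any(Nmj < 1)) stop("need Nm_i >= 1 and Nm_j >= 1")
  if (any(Ntot <= Nmi)) stop("no cross-neighbours exist when N_tot = Nm_i")
  Nmj / (Ntot - Nmi) * Nmi
}

#' Same-morphotype nearest-neighbour summary
#'
#' For each morphotype present: the observed number of its hooks whose
#' nearest neighbour (among all other hooks) is of the same morphotype, the
#' analytic expectation under random labelling, and their ratio as a
#' percentage. Morphotypes with fewer than 3 hooks are flagged (too few
#' representatives for the ratio to be meaningful).
#'
#' @param specimen a [HookSpecimen-class] with at least 2 hooks.
#' @return data.frame with one row per morphotype present.
#' @export
nnSameSummary <- function(specimen) {
  n <- nHooks(specimen)
  if (n < 2L) stop("specimen too small for distance analysis")
  D <- pairwiseDistances(specimen)
  nn <- nn_index(D)
  lab <- as.character(morphotypes(specimen))
  cnt <- morphotypeCounts(specimen)
  same <- lab == lab[nn]
  obs <- vapply(names(cnt), function(m) sum(same & lab == m), integer(1))
  exp_ <- expectedSame(as.numeric(cnt), n)
  data.frame(
    specimen_id = specimenID(specimen), scope = "same",
    morphotype_i = names(cnt), morphotype_j = NA_character_,
    observed = as.integer(obs), expected = exp_,
    ratio_pct = ifelse(exp_ > 0, 100 * obs / exp_, NA_real_),
    n_i = as.integer(cnt), n_j = NA_integer_, n_tot = n,
    flagged = as.integer(cnt) < 3L,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tukey-fence outlier exclusion within morphotypes
#'
#' Hooks that lie far from the cluster formed by the other hooks of their
#' own morphotype are excluded by the 1.5 x IQR rule: a per-hook distance
#' statistic (mean -- or, optionally, nearest -- centroid distance to the
#' other hooks of the same morphotype) is compared against the upper fence
#' `Q3 + 1.5 x IQR` of that morphotype's statistics. Only the upper fence is
#' applied (only "far apart" hooks are outliers), and only for morphotypes
#' with at least 4 hooks (quartiles are meaningless below).
#'
#' @param specimen a [HookSpecimen-class].
#' @param stat `"mean"` (default) or `"nearest"` per-hook distance statistic.
#' @param fenceMultiplier IQR multiplier (default 1.5).
#' @param morphotype optional single code to restrict the report to.
#' @return data.frame with one row per hook: `morphotype`, `hook_id`,
#'   `stat` (mm), `q1`, `q3`, `fence` (mm), `rule_applied`, `excluded`.
#'   Quartiles use linear interpolation (R's default type 7).
#' @export
excludeOutliers <- function(specimen, stat = c("mean", "nearest"),
                            fenceMultiplier = 1.5, morphotype = NULL) {
  stat <- match.arg(stat)
  lab <- as.character(morphotypes(specimen))
  ids <- hookIDs(specimen)
  D <- if (nHooks(specimen) >= 2L) pairwiseDistances(specimen) else NULL
  keep_m <- if (is.null(morphotype)) unique(lab) else morphotype
  rows <- lapply(intersect(morphotypeCodes(), keep_m), function(m) {
    sel <- which(lab == m)
    k <- length(sel)
    if (k == 0L) return(NULL)
    s <- rep(NA_real_, k)
    if (k >= 2L) {
      sub <- D[sel, sel, drop = FALSE]
      diag(sub) <- NA
      s <- if (stat == "mean") {
        rowMeans(sub, na.rm = TRUE)
      } else {
        apply(sub, 1L, min, na.rm = TRUE)
      }
    }
    applied <- k >= 4L
    if (applied) {
      q <- stats::quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
      fence <- q[2] + fenceMultiplier * (q[2] - q[1])
      excl <- s > fence
    } else {
      q <- c(NA_real_, NA_real_)
      fence <- NA_real_
      excl <- rep(FALSE, k)
    }
    data.frame(
      morphotype = m, hook_id = ids[sel], stat = s,
      q1 = q[1], q3 = q[2], fence = fence,
      rule_applied = applied, excluded = excl,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Retained sub-specimen after outlier exclusion
#'
#' @param specimen a [HookSpecimen-class].
#' @param outliers result of [excludeOutliers()] (computed if omitted).
#' @param ... passed to [excludeOutliers()].
#' @return the specimen restricted to non-excluded hooks.
#' @export
retainSpecimen <- function(specimen, outliers = NULL, ...) {
  if (is.null(outliers)) outliers <- excludeOutliers(specimen, ...)
  drop_ids <- outliers$hook_id[outliers$excluded]
  specimen[!hookIDs(specimen) %in% drop_ids]
}

#' Cross-morphotype nearest-neighbour summary
#'
#' For each ordered pair (i, j) of distinct morphotypes: the observed number
#' of retained hooks of morphotype i whose nearest hook among all *other*
#' morphotypes is of morphotype j, the analytic random-labelling
#' expectation, and their ratio. Outlier hooks are excluded first (the
#' clustering established by the same-morphotype analysis would otherwise
#' bias the cross counts); counts in the output are post-exclusion.
#'
#' @param specimen a [HookSpecimen-class].
#' @param applyExclusion exclude outliers first (default TRUE).
#' @param stat,fenceMultiplier passed to [excludeOutliers()].
#' @return data.frame with one row per ordered pair present; pairs with no
#'   retained representative on either side are omitted. Pairs where either
#'   morphotype has fewer than 3 retained hooks are flagged.
#' @export
nnCrossSummary <- function(specimen, applyExclusion = TRUE,
                           stat = "mean", fenceMultiplier = 1.5) {
  sp <- if (applyExclusion) {
    retainSpecimen(specimen, stat = stat, fenceMultiplier = fenceMultiplier)
  } else {
    specimen
  }
  n <- nHooks(sp)
  if (n < 2L) stop("specimen too small for distance analysis")
  lab <- as.character(morphotypes(sp))
  cnt <- morphotypeCounts(sp)
  if (length(cnt) < 2L) {
    return(data.frame(
      specimen_id = character(0), scope = character(0),
      morphotype_i = character(0), morphotype_j = character(0),
      observed = integer(0), expected = numeric(0), ratio_pct = numeric(0),
      n_i = integer(0), n_j = integer(0), n_tot = integer(0),
      flagged = logical(0)
    ))
  }
  D <- pairwiseDistances(sp)
  rows <- list()
  for (mi in names(cnt)) {
    sel_i <- lab == mi
    nnx <- nn_index(D, candidate = !sel_i)
    nb <- lab[nnx[sel_i]]
    for (mj in setdiff(names(cnt), mi)) {
      obs <- sum(nb == mj)
      exp_ <- expectedCross(cnt[[mi]], cnt[[mj]], n)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = specimenID(sp), scope = "cross",
        morphotype_i = mi, morphotype_j = mj,
        observed = as.integer(obs), expected = exp_,
        ratio_pct = ifelse(exp_ > 0, 100 * obs / exp_, NA_real_),
        n_i = cnt[[mi]], n_j = cnt[[mj]], n_tot = n,
        flagged = cnt[[mi]] < 3L || cnt[[mj]] < 3L,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}

#' Label-permutation null distribution of nearest-neighbour counts
#'
#' Monte Carlo cross-check of the analytic expectations: hook positions stay
#' fixed while morphotype labels are permuted; the same- and
#' cross-morphotype nearest-neighbour counts are recomputed for each
#' permutation. The permutation means converge on [expectedSame()] and
#' [expectedCross()] evaluated at the specimen's counts (no outlier
#' exclusion is involved).
#'
#' @param specimen a [HookSpecimen-class] with at least 2 hooks.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list with data.frames `same` (per morphotype) and `cross` (per
#'   ordered pair), each with permutation `mean`, `sd`, and 2.5/50/97.5
#'   percent quantiles of the counts, plus the analytic `expected`.
#' @export
permutationNull <- function(specimen, nPerm = 1000L, seed = 1L) {
  n <- nHooks(specimen)
  if (n < 2L) stop("specimen too small for distance analysis")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  D <- pairwiseDistances(specimen)
  nn <- nn_index(D)
  # neighbour ranking per hook (distance then id order), for cross counts;
  # self is pushed to the end with Inf and dropped
  D2 <- D
  diag(D2) <- Inf
  ordmat <- t(apply(D2, 1L, order))[, -n, drop = FALSE]
  lab0 <- as.integer(morphotypes(specimen))
  K <- length(morphotypeCodes())
  sameAcc <- matrix(0L, nPerm, K)
  crossAcc <- matrix(0L, nPerm, K * K)
  withSeed(seed, {
    for (p in seq_len(nPerm)) {
      lab <- lab0[sample.int(n)]
      sameAcc[p, ] <- tabulate(lab[lab == lab[nn]], nbins = K)
      labmat <- matrix(lab[ordmat], n, n - 1L)
      diffm <- labmat != lab
      hasdiff <- rowSums(diffm) > 0L
      first <- max.col(diffm, ties.method = "first")
      nb <- labmat[cbind(seq_len(n), first)]
      idx <- ((lab - 1L) * K + nb)[hasdiff]
      crossAcc[p, ] <- tabulate(idx, nbins = K * K)
    }
  })
  cnt <- table(factor(morphotypeCodes()[lab0], levels = morphotypeCodes()))
  present <- which(cnt > 0)
  qs <- function(m) {
    t(apply(m, 2L, function(col) {
      c(
        mean = mean(col), sd = stats::sd(col),
        stats::quantile(col, c(0.025, 0.5, 0.975), names = FALSE)
      )
    }))
  }
  sameStats <- qs(sameAcc[, present, drop = FALSE])
  same <- data.frame(
    morphotype = morphotypeCodes()[present],
    mean = sameStats[, 1], sd = sameStats[, 2],
    q025 = sameStats[, 3], q50 = sameStats[, 4], q975 = sameStats[, 5],
    expected = expectedSame(as.numeric(cnt[present]), n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  cross <- NULL
  if (length(present) >= 2L) {
    pairs <- expand.grid(i = present, j = present)
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    cols <- (pairs$i - 1L) * K + pairs$j
    crossStats <- qs(crossAcc[, cols, drop = FALSE])
    cross <- data.frame(
      morphotype_i = morphotypeCodes()[pairs$i],
      morphotype_j = morphotypeCodes()[pairs$j],
      mean = crossStats[, 1], sd = crossStats[, 2],
      q025 = crossStats[, 3], q50 = crossStats[, 4], q975 = crossStats[, 5],
      expected = expectedCross(
        as.numeric(cnt[pairs$i]), as.numeric(cnt[pairs$j]), n
      ),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  list(same = same, cross = cross, nPerm = nPerm)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
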
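#' Read specimens from a landmark or centroid CSV
#'
#' Two dialects are accepted, both comma-separated with "." decimals and a
#' mandatory header. Landmark mode has columns
#' `specimen_id,hook_id,morphotype,landmark_index,x,y,z` with exactly the
#' landmark indices 1--4 per hook; centroid mode drops `landmark_index` and
#' has one row per hook (used when only centroids survive; flagged in the
#' specimen's provenance). Hooks are ordered by `(specimen_id, hook_id)`.
#'
#' @param path CSV file path.
#' @return named list of [HookSpecimen-class] objects.
#' @export
#' @examples
#' demo <- system.file("extdata", "synthetic_demo.csv", package = "crownmap")
#' sp <- readSpecimens(demo)[[1]]
#' sp
readSpecimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  base_cols <- c("specimen_id", "hook_id", "morphotype", "x", "y", "z")
  if (!all(base_cols %in% names(df))) {
    stop(
      "landmark file must have columns ",
      paste(c(base_cols[1:3], "landmark_index (landmark mode)", base_cols[4:6]),
        collapse = ", "
      )
    )
  }
  landmark_mode <- "landmark_index" %in% names(df)
  if (nrow(df) == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  rowno <- seq_len(nrow(df)) + 1L # file line numbers, header is line 1

  bad <- !df$morphotype %in% morphotypeCodes()
  if (any(bad)) {
    stop(
      "unknown morphotype code '", df$morphotype[which(bad)[1]],
      "' at line ", rowno[which(bad)[1]]
    )
  }
  for (v in c("x", "y", "z")) {
    if (!is.numeric(df[[v]]) || anyNA(df[[v]])) {
      stop("non-numeric or missing ", v, " coordinate")
    }
  }

  out <- list()
  for (sid in sort(unique(df$specimen_id))) {
    sub <- df[df$specimen_id == sid, , drop = FALSE]
    sub_rowno <- rowno[df$specimen_id == sid]
    if (landmark_mode) {
      ids <- sort(unique(sub$hook_id))
      n <- length(ids)
      lm <- array(NA_real_, dim = c(n, 4L, 3L))
      morph <- character(n)
      for (h in seq_along(ids)) {
        hk <- sub[sub$hook_id == ids[h], , drop = FALSE]
        if (anyDuplicated(hk$landmark_index)) {
          stop(
            "duplicate landmark index for hook ", ids[h], " in specimen ",
            sid, " (line ", sub_rowno[sub$hook_id == ids[h]][1], ")"
          )
        }
        if (!setequal(hk$landmark_index, 1:4)) {
          stop(
            "hook ", ids[h], " in specimen ", sid,
            " must have landmark indices {1,2,3,4}, found {",
            paste(sort(hk$landmark_index), collapse = ","), "}"
          )
        }
        if (length(unique(hk$morphotype)) != 1L) {
          stop("morphotype not constant within hook ", ids[h], " in specimen ", sid)
        }
        ordk <- order(hk$landmark_index)
        lm[h, , ] <- as.matrix(hk[ordk, c("x", "y", "z")])
        morph[h] <- hk$morphotype[1]
      }
      out[[sid]] <- HookSpecimen(sid, ids, morph, landmarks = lm)
    } else {
      if (anyDuplicated(sub$hook_id)) {
        d <- sub$hook_id[duplicated(sub$hook_id)][1]
        stop("duplicate hook id ", d, " in specimen ", sid, " (centroid mode)")
      }
      ordh <- order(sub$hook_id)
      out[[sid]] <- HookSpecimen(sid, sub$hook_id[ordh], sub$morphotype[ordh],
        centroids = as.matrix(sub[ordh, c("x", "y", "z")])
      )
    }
  }
  out
}

#' Write specimens to CSV
#'
#' Inverse of [readSpecimens()]: writes landmark mode when landmarks are
#' present (and `mode` allows), else centroid mode. Coordinates use 9
#' decimals so that read-write round trips are identities to 1e-9 mm.
#'
#' @param specimens a [HookSpecimen-class] or list of them.
#' @param path output CSV path.
#' @param mode `"auto"`, `"landmarks"` or `"centroids"`.
#' @param header optional comment lines (prefixed `#`) written before the CSV.
#' @return `path`, invisibly.
#' @export
writeSpecimens <- function(specimens, path, mode = c("auto", "landmarks", "centroids"),
                           header = NULL) {
  mode <- match.arg(mode)
  if (methods::is(specimens, "HookSpecimen")) specimens <- list(specimens)
  use_landmarks <- switch(mode,
    landmarks = TRUE,
    centroids = FALSE,
    auto = all(vapply(specimens, function(s) length(s@landmarks) > 0, logical(1)))
  )
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  if (use_landmarks) {
    lines <- c(lines, "specimen_id,hook_id,morphotype,landmark_index,x,y,z")
    for (sp in specimens) {
      if (length(sp@landmarks) == 0 && nHooks(sp) > 0) {
        stop("specimen '", sp@specimenID, "' has no landmarks; use centroid mode")
      }
      for (h in seq_len(nHooks(sp))) {
        for (l in 1:4) {
          lines <- c(lines, sprintf(
            "%s,%d,%s,%d,%.9f,%.9f,%.9f",
            sp@specimenID, sp@hookID[h], as.character(sp@morphotype[h]), l,
            sp@landmarks[h, l, 1], sp@landmarks[h, l, 2], sp@landmarks[h, l, 3]
          ))
        }
      }
    }
  } else {
    lines <- c(lines, "specimen_id,hook_id,morphotype,x,y,z")
    for (sp in specimens) {
      cc <- centroids(sp)
      for (h in seq_len(nHooks(sp))) {
        lines <- c(lines, sprintf(
          "%s,%d,%s,%.9f,%.9f,%.9f",
          sp@specimenID, sp@hookID[h], as.character(sp@morphotype[h]),
          cc[h, 1], cc[h, 2], cc[h, 3]
        ))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

format_ratio <- function(observed, expected) {
  ifelse(expected > 0, sprintf("%.1f", 100 * observed / expected), "n/a")
}

#' Write a nearest-neighbour report (observed/expected table)
#'
#' Serialises nearest-neighbour summaries as TSV, one row per morphotype (or
#' ordered morphotype pair) per specimen, with the observed count, the
#' analytic expectation under random labelling, and their ratio as a percent
#' with one decimal (the bracketed observed/expected ratio of the original
#' table format). When several specimens are present an aggregate row per
#' key is appended with id `ALL`, computed as sum of observed over sum of
#' expected (not a mean of ratios).
#'
#' @param summaries data.frame from [nnSameSummary()] / [nnCrossSummary()]
#'   (rows from several specimens may be concatenated), or a list of such.
#' @param path output TSV path.
#' @param header optional comment lines (prefixed `#`).
#' @return the written data.frame, invisibly.
#' @export
writeNNReport <- function(summaries, path, header = NULL) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  df <- do.call(rbind, summaries)
  cols <- c(
    "specimen_id", "scope", "morphotype_i", "morphotype_j",
    "observed", "expected", "flagged"
  )
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(
      specimen_id = character(0), scope = character(0),
      morphotype_i = character(0), morphotype_j = character(0),
      observed = integer(0), expected = numeric(0), flagged = logical(0)
    )
  }
  df <- df[, cols]
  if (length(unique(df$specimen_id)) > 1L) {
    agg <- aggregateNN(df)
    df <- rbind(df, agg[, cols])
  }
  out <- df
  out$ratio_pct <- format_ratio(df$observed, df$expected)
  out$expected <- sprintf("%.4f", df$expected)
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  lines <- c(lines, paste(names(out), collapse = "\t"))
  if (nrow(out)) {
    body <- apply(out, 1L, function(r) paste(r, collapse = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(df)
}

#' Aggregate nearest-neighbour summaries across specimens
#'
#' Sums observed and expected counts over specimens for each (scope,
#' morphotype_i, morphotype_j) key and recomputes the ratio from the sums,
#' matching the study-level summation of per-specimen expectations.
#'
#' @param df concatenated rows from [nnSameSummary()] / [nnCrossSummary()].
#' @return data.frame with `specimen_id = "ALL"` and a `ratio_pct` column.
#' @export
aggregateNN <- function(df) {
  key <- paste(df$scope, df$morphotype_i,
    ifelse(is.na(df$morphotype_j), "", df$morphotype_j),
    sep = "\r"
  )
  parts <- split(df, key)
  agg <- do.call(rbind, lapply(parts, function(p) {
    data.frame(
      specimen_id = "ALL", scope = p$scope[1],
      morphotype_i = p$morphotype_i[1], morphotype_j = p$morphotype_j[1],
      observed = sum(p$observed), expected = sum(p$expected),
      flagged = any(p$flagged), stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  agg$ratio_pct <- ifelse(agg$expected > 0,
    100 * agg$observed / agg$expected, NA_real_
  )
  agg
}

#' Read an analysis or synthetic configuration (JSON)
#'
#' JSON mappings only; unknown keys are rejected and defaults are applied
#' for omitted keys. A top-level `"kind"` of `"synthetic"` (default) or
#' `"analysis"` selects the configuration type.
#'
#' @param path JSON file path.
#' @return a [SyntheticConfig-class] or an `AnalysisConfig` list.
#' @export
readConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind %||% "synthetic"
  obj$kind <- NULL
  if (identical(kind, "analysis")) {
    do.call(analysisConfig, obj)
  } else if (identical(kind, "synthetic")) {
    if (!is.null(obj$pairAssignment)) {
      obj$pairAssignment <- lapply(seq_len(nrow(as.matrix(obj$pairAssignment))),
        function(i) as.character(as.matrix(obj$pairAssignment)[i, ])
      )
    }
    if (!is.null(obj$rareCounts)) obj$rareCounts <- unlist(obj$rareCounts)
    do.call(syntheticConfig, obj)
  } else {
    stop("unknown config kind '", kind, "'")
  }
}

#' Write a configuration to JSON
#'
#' @param config a [SyntheticConfig-class] or `AnalysisConfig`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  if (methods::is(config, "SyntheticConfig")) {
    obj <- list(
      kind = "synthetic",
      seed = config@seed, nAxes = config@nAxes,
      hooksPerAxis = config@hooksPerAxis,
      pairAssignment = config@pairAssignment,
      axisGeometry = config@axisGeometry,
      arcRadius = config@arcRadius, arcSpanDeg = config@arcSpanDeg,
      spacing = config@spacing, lateralOffset = config@lateralOffset,
      basalGroupSize = config@basalGroupSize,
      rareCounts = as.list(config@rareCounts),
      jitterSD = config@jitterSD,
      scrambleFraction = config@scrambleFraction,
      chamber = config@chamber
    )
  } else if (inherits(config, "AnalysisConfig")) {
    obj <- c(list(kind = "analysis"), unclass(config))
  } else {
    stop("config must be a SyntheticConfig or AnalysisConfig")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' Validated option set for [runAnalyze()]; unknown arguments are rejected.
#'
#' @param outlierStat per-hook distance statistic for the Tukey rule:
#'   `"mean"` (default) or `"nearest"`.
#' @param fenceMultiplier IQR multiplier of the Tukey fence (default 1.5).
#' @param maxAxes maximum number of axes to report (default 2).
#' @param pairs list of morphotype pairs (default G1-G4, G2-G5).
#' @param basal basal-group morphotypes (default G3, VSB).
#' @param seed RNG seed for the permutation null.
#' @param nPerm label permutations for the Monte Carlo cross-check
#'   (0 disables).
#' @return an `AnalysisConfig` list.
#' @export
analysisConfig <- function(outlierStat = "mean", fenceMultiplier = 1.5,
                           maxAxes = 2L, pairs = list(c("G1", "G4"), c("G2", "G5")),
                           basal = c("G3", "VSB"), seed = 1L, nPerm = 0L) {
  if (!outlierStat %in% c("mean", "nearest")) {
    stop("outlierStat must be 'mean' or 'nearest'")
  }
  if (fenceMultiplier < 0) stop("fenceMultiplier must be >= 0")
  if (maxAxes < 0) stop("maxAxes must be >= 0")
  if (nPerm < 0) stop("nPerm must be >= 0")
  if (is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, ]))
  }
  for (p in pairs) {
    if (length(p) != 2L || !all(p %in% morphotypeCodes())) {
      stop("each pair must be two admissible morphotype codes")
    }
  }
  if (!all(basal %in% morphotypeCodes())) stop("unknown basal morphotype code")
  structure(
    list(
      outlierStat = outlierStat, fenceMultiplier = fenceMultiplier,
      maxAxes = as.integer(maxAxes), pairs = pairs, basal = basal,
      seed = as.integer(seed), nPerm = as.integer(nPerm)
    ),
    class = "AnalysisConfig"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export centroids as an ASCII PLY point cloud
#'
#' Minimal PLY export of the hook centroids, coloured by morphotype, for
#' inspection in external 3D viewers.
#'
#' @param specimen a [HookSpecimen-class].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
writeCentroidsPLY <- function(specimen, path) {
  pal <- grDevices::col2rgb(c(
    G1 = "#e41a1c", G2 = "#377eb8", G3 = "#4daf4a", G4 = "#984ea3",
    G5 = "#ff7f00", VSB = "#a65628", TRI = "#f781bf", UNI = "#999999",
    RND = "#ffff33"
  ))
  cc <- centroids(specimen)
  idx <- as.integer(morphotypes(specimen))
  n <- nHooks(specimen)
  hdr <- c(
    "ply", "format ascii 1.0",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header"
  )
  body <- sprintf(
    "%.6f %.6f %.6f %d %d %d", cc[, 1], cc[, 2], cc[, 3],
    pal[1, idx], pal[2, idx], pal[3, idx]
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
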
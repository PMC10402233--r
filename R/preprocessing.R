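#' @include drawing-metrics.R
NULL

.DESCRIPTORS <- c("area", "perimeter", "major", "minor")

#' z-score with the population standard deviation
#'
#' Standardizes a vector to mean 0 and (population) SD 1, matching the
#' convention under which \{1, 2, 3\} maps to \{-1.2247, 0, 1.2247\}.
#'
#' @param x numeric vector without NAs.
#' @return The standardized vector.
#' @export
zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant (zero-variance) vector")
  (x - mean(x)) / s
}

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Normalize shape descriptors by the standard-pulse response
#'
#' Expresses every drawing's shape descriptors as multiples of the
#' descriptors elicited by a "standard" pulse train (by default 2x threshold
#' amplitude at 20 Hz). The reference is computed separately per participant
#' but pools all of that participant's standard-pulse drawings across
#' electrodes, which absorbs individual drawing bias and variance. By
#' construction the mean normalized descriptor over a participant's
#' standard-pulse drawings is exactly 1.
#'
#' @param df data.frame of per-drawing descriptors (from [shapeTable()]),
#'   with columns \code{participant}, \code{amplitude}, \code{frequency} and
#'   the four descriptors \code{area}, \code{perimeter}, \code{major},
#'   \code{minor}.
#' @param standardAmplitude,standardFrequency the standard pulse. Defaults
#'   2 (x threshold) and 20 (Hz).
#' @param tol numeric tolerance when matching the standard stimulus.
#' @return \code{df} with the descriptor columns rescaled; the per-participant
#'   reference means are attached as attribute \code{standardMeans}.
#' @export
normalizeDescriptors <- function(df, standardAmplitude = 2,
                                 standardFrequency = 20, tol = 1e-8) {
  stopifnot(all(c("participant", "amplitude", "frequency",
                  .DESCRIPTORS) %in% colnames(df)))
  isStd <- abs(df$amplitude - standardAmplitude) < tol &
    abs(df$frequency - standardFrequency) < tol &
    if ("electrode2" %in% colnames(df)) is.na(df$electrode2) else TRUE
  parts <- unique(df$participant)
  missing <- parts[!parts %in% unique(df$participant[isStd])]
  if (length(missing))
    stop("no standard-pulse drawings for participant(s): ",
         paste(missing, collapse = ", "))
  refs <- lapply(setNames(parts, parts), function(p) {
    colMeans(df[isStd & df$participant == p, .DESCRIPTORS, drop = FALSE])
  })
  out <- df
  for (p in parts) {
    sel <- df$participant == p
    out[sel, .DESCRIPTORS] <-
      sweep(df[sel, .DESCRIPTORS, drop = FALSE], 2, refs[[p]], "/")
  }
  attr(out, "standardMeans") <- do.call(rbind, refs)
  out
}

#' Average descriptors across trials of the same stimulus condition
#'
#' Collapses repeated trials of the same (participant, electrode(s),
#' amplitude, frequency) combination to their mean, eliminating repeated
#' measures of the same data point. Phosphene counts are averaged too, and
#' the number of contributing trials is retained.
#'
#' @param df per-drawing descriptor table (normalized or raw).
#' @return One row per stimulus condition with mean descriptors, mean
#'   \code{n_phosphenes} (if present) and \code{n_trials}.
#' @export
averageTrials <- function(df) {
  keyCols <- intersect(c("participant", "electrode1", "electrode2",
                         "amplitude", "frequency"), colnames(df))
  valCols <- intersect(c(.DESCRIPTORS, "n_phosphenes"), colnames(df))
  df2 <- df
  if ("electrode2" %in% keyCols)  # aggregate() drops NA keys; use a sentinel
    df2$electrode2[is.na(df2$electrode2)] <- ""
  agg <- aggregate(df2[valCols], by = df2[keyCols], FUN = mean)
  cnt <- aggregate(list(n_trials = seq_len(nrow(df2))), by = df2[keyCols],
                   FUN = length)
  out <- merge(agg, cnt, by = keyCols, sort = TRUE)
  if ("electrode2" %in% keyCols)
    out$electrode2[out$electrode2 == ""] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Power-transform a shape descriptor
#'
#' Applies the variance-stabilizing power 1/n transform that keeps regression
#' residuals approximately normal: n = 3 for area (a cube-root, matching its
#' quadratic growth with linear size) and n = 2 for perimeter and the axis
#' lengths.
#'
#' @param value non-negative descriptor value(s).
#' @param kind one of "area", "perimeter", "major", "minor".
#' @return The transformed value(s).
#' @export
powerTransform <- function(value, kind = c("area", "perimeter", "major",
                                           "minor")) {
  kind <- match.arg(kind)
  if (any(value < 0)) stop("descriptor values must be non-negative")
  n <- if (kind == "area") 3 else 2
  value^(1 / n)
}

#' @rdname powerTransform
#' @param df table containing the four descriptor columns.
#' @return For \code{transformDescriptors()}, \code{df} with the descriptor
#'   columns transformed in place.
#' @export
transformDescriptors <- function(df) {
  for (k in .DESCRIPTORS) df[[k]] <- powerTransform(df[[k]], k)
  df
}

#' Remove outlying rows by the 2.5-SD rule
#'
#' Flags rows whose value on any of the given columns lies more than
#' \code{k} (population) standard deviations from the mean within its
#' analysis group, and drops them. Intended for the single-electrode
#' analyses; groups with zero variance (or fewer than 3 rows) are left
#' untouched.
#'
#' @param df data.frame of aggregated data points.
#' @param cols columns screened for outliers. Default: the four descriptors.
#' @param k the SD cutoff. Default 2.5.
#' @param group grouping column defining each analysis. Default
#'   \code{"participant"}.
#' @return \code{df} without the outlying rows; the removed rows (with the
#'   offending column) are attached as attribute \code{removed}.
#' @export
removeOutliers <- function(df, cols = .DESCRIPTORS, k = 2.5,
                           group = "participant") {
  stopifnot(all(cols %in% colnames(df)), group %in% colnames(df))
  drop <- rep(FALSE, nrow(df))
  why <- rep(NA_character_, nrow(df))
  for (g in unique(df[[group]])) {
    sel <- which(df[[group]] == g)
    if (length(sel) < 3) next
    for (cl in cols) {
      v <- df[[cl]][sel]
      s <- .popSd(v)
      if (s == 0) next
      z <- abs(v - mean(v)) / s
      bad <- z > k
      why[sel[bad & !drop[sel]]] <- cl
      drop[sel[bad]] <- TRUE
    }
  }
  out <- df[!drop, , drop = FALSE]
  removed <- df[drop, , drop = FALSE]
  removed$flagged_by <- why[drop]
  attr(out, "removed") <- removed
  out
}

#' Assemble the tidy analysis design table
#'
#' Joins trial-averaged (normalized, power-transformed) shape rows with the
#' neuroanatomical predictors and z-scores the predictors across all
#' participants. Paired-electrode rows additionally receive the pair's
#' between-/along-axon distances, the pair amplitude (the mean of the two
#' electrodes' amplitudes, already carried by the trial table) and the
#' sum-of-singles descriptors (the same descriptor from the two electrodes'
#' single-electrode rows at the same amplitude and frequency), which is the
#' predictor of the linear-summation analysis.
#'
#' @param shapes aggregated descriptor rows (singles and/or pairs), i.e. the
#'   output of [averageTrials()] after [normalizeDescriptors()] and
#'   [transformDescriptors()].
#' @param electrodeTable per-electrode predictors: columns
#'   \code{participant}, \code{electrode}, \code{efd_um} and optionally
#'   \code{erd_um}.
#' @param pairTable per-pair distances: columns \code{participant},
#'   \code{electrode1}, \code{electrode2}, \code{between_axon_um},
#'   \code{along_axon_um} (e.g. from [pairDistances()]).
#' @param zscorePredictors standardize predictor columns across the full
#'   table. Default TRUE.
#' @return data.frame with a \code{type} column ("single"/"paired"),
#'   z-scored predictor columns \code{amplitude_z}, \code{frequency_z},
#'   \code{efd_z} (and \code{erd_z}, \code{between_axon_z},
#'   \code{along_axon_z} where defined) and, for paired rows, \code{sum_area},
#'   \code{sum_perimeter}, \code{sum_major}, \code{sum_minor}.
#' @export
assembleDesignTable <- function(shapes, electrodeTable, pairTable = NULL,
                                zscorePredictors = TRUE) {
  stopifnot(all(c("participant", "electrode1", "amplitude", "frequency",
                  .DESCRIPTORS) %in% colnames(shapes)))
  stopifnot(all(c("participant", "electrode", "efd_um") %in%
                colnames(electrodeTable)))
  df <- shapes
  df$type <- ifelse(is.na(df$electrode2), "single", "paired")
  # electrode-level predictors; for pairs use the mean of the two electrodes
  eKey <- paste(electrodeTable$participant, electrodeTable$electrode)
  look <- function(p, e, col) {
    i <- match(paste(p, e), eKey)
    electrodeTable[[col]][i]
  }
  efd1 <- look(df$participant, df$electrode1, "efd_um")
  if (anyNA(efd1)) {
    bad <- unique(paste0(df$participant, ":", df$electrode1)[is.na(efd1)])
    stop("electrodes missing from electrodeTable: ",
         paste(bad, collapse = ", "))
  }
  efd2 <- ifelse(is.na(df$electrode2), NA,
                 look(df$participant, df$electrode2, "efd_um"))
  df$efd_um <- ifelse(is.na(efd2), efd1, (efd1 + efd2) / 2)
  if ("erd_um" %in% colnames(electrodeTable)) {
    erd1 <- look(df$participant, df$electrode1, "erd_um")
    erd2 <- ifelse(is.na(df$electrode2), NA,
                   look(df$participant, df$electrode2, "erd_um"))
    df$erd_um <- ifelse(is.na(erd2), erd1, (erd1 + erd2) / 2)
  }
  if (!is.null(pairTable) && any(df$type == "paired")) {
    pKey <- paste(pairTable$participant, pairTable$electrode1,
                  pairTable$electrode2)
    pKeyRev <- paste(pairTable$participant, pairTable$electrode2,
                     pairTable$electrode1)
    want <- paste(df$participant, df$electrode1, df$electrode2)
    i <- match(want, pKey)
    i[is.na(i)] <- match(want[is.na(i)], pKeyRev)
    paired <- df$type == "paired"
    if (anyNA(i[paired])) {
      bad <- unique(want[paired][is.na(i[paired])])
      stop("pairs missing from pairTable: ", paste(bad, collapse = ", "))
    }
    df$between_axon_um <- pairTable$between_axon_um[i]
    df$along_axon_um <- pairTable$along_axon_um[i]
    # sum-of-singles predictors at the matching stimulus
    sKey <- paste(shapes$participant, shapes$electrode1, shapes$amplitude,
                  shapes$frequency)[is.na(shapes$electrode2)]
    sRows <- which(is.na(shapes$electrode2))
    for (k in .DESCRIPTORS) df[[paste0("sum_", k)]] <- NA_real_
    for (r in which(paired)) {
      i1 <- sRows[match(paste(df$participant[r], df$electrode1[r],
                              df$amplitude[r], df$frequency[r]), sKey)]
      i2 <- sRows[match(paste(df$participant[r], df$electrode2[r],
                              df$amplitude[r], df$frequency[r]), sKey)]
      if (!is.na(i1) && !is.na(i2))
        for (k in .DESCRIPTORS)
          df[[paste0("sum_", k)]][r] <- shapes[[k]][i1] + shapes[[k]][i2]
    }
  }
  if (zscorePredictors) {
    zcols <- intersect(c("amplitude", "frequency", "efd_um", "erd_um",
                         "between_axon_um", "along_axon_um"), colnames(df))
    for (cl in zcols) {
      v <- df[[cl]]
      ok <- !is.na(v)
      zname <- sub("_um$", "", cl)
      zname <- paste0(zname, "_z")
      if (.popSd(v[ok]) == 0) next  # constant predictor: dropped, not scored
      df[[zname]] <- NA_real_
      df[[zname]][ok] <- zscore(v[ok])
    }
  }
  rownames(df) <- NULL
  df
}

#' One-call preprocessing pipeline
#'
#' Chains the preprocessing steps in their canonical order: standard-pulse
#' normalization, trial averaging, power transform, 2.5-SD outlier removal
#' (single-electrode rows only, per participant), then design-table assembly
#' with predictor z-scoring (so removed rows do not influence the scaling).
#'
#' @param shapeTab per-drawing descriptor table from [shapeTable()].
#' @param electrodeTable,pairTable as in [assembleDesignTable()].
#' @param standardAmplitude,standardFrequency the standard pulse.
#' @param k outlier SD cutoff. Default 2.5.
#' @return The design table (see [assembleDesignTable()]); removed outlier
#'   rows are attached as attribute \code{removed}.
#' @export
prepareDesign <- function(shapeTab, electrodeTable, pairTable = NULL,
                          standardAmplitude = 2, standardFrequency = 20,
                          k = 2.5) {
  norm <- normalizeDescriptors(shapeTab,
                               standardAmplitude = standardAmplitude,
                               standardFrequency = standardFrequency)
  agg <- averageTrials(norm)
  agg <- transformDescriptors(agg)
  singles <- agg[is.na(agg$electrode2), , drop = FALSE]
  pairs <- agg[!is.na(agg$electrode2), , drop = FALSE]
  singles <- removeOutliers(singles, k = k)
  removed <- attr(singles, "removed")
  kept <- rbind(singles, pairs)
  out <- assembleDesignTable(kept, electrodeTable, pairTable)
  attr(out, "removed") <- removed
  out
}
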
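#' @include retina-geometry.R drawing-metrics.R
NULL

#' Configure the synthetic phosphene-drawing generator
#'
#' Builds a [GeneratorConfig-class] describing a simulated drawing study with
#' three implant users. The generator follows the axon-map account of
#' epiretinal percepts: the intensity a stimulus evokes at a retinal point p
#' is the maximum, over points a(s) of the stimulated electrode's fiber
#' bundle, of a radial current-spread Gaussian (scale \code{rho0} um) times
#' an axonal-decay Gaussian in arc length s from the electrode's foot point
#' (scale \code{lambda0} um):
#' \deqn{I(p) = \max_s \exp(-\|p - a(s)\|^2 / 2\rho^2)
#'   \exp(-s^2 / 2\lambda^2)}
#' so percepts elongate along bundles for large \eqn{\lambda} and reduce to
#' isotropic blobs as \eqn{\lambda \to 0}. Stimulus and anatomy modulate the
#' scales:
#' \deqn{\rho_{eff} = \rho_0 A^a, \quad
#'   \lambda_{eff} = \lambda_0 (1 + f \log(F/20)) (1 + c \cdot EFD)}
#' with A the amplitude in multiples of threshold, F the pulse frequency in
#' Hz, and EFD the electrode-fovea distance (mm), so amplitude grows
#' phosphenes, frequency and eccentricity elongate them. Percepts are
#' projected to the touchscreen raster, thresholded, and degraded by
#' per-trial drawing noise (log-normal size bias and centroid jitter).
#'
#' The defaults emulate the statistical structure reported for such studies:
#' per-participant amplitude sensitivity (one participant nearly amplitude
#' insensitive), one strongly frequency-sensitive participant, implant
#' placements whose mean electrode-fovea distances are about 2561, 2136 and
#' 2169 um, paired stimulation gain 0.7, and a 1024 x 768 px touchscreen at
#' 25 px/deg (a 76 cm viewing distance).
#'
#' @param participants participant identifiers.
#' @param rho0,lambda0 per-participant spread scales, um.
#' @param ampExponent,freqCoef,eccCoefPerMm effect coefficients (see above).
#' @param gain paired-stimulation perceptual gain g in (0, 1]: paired
#'   percepts are rendered so that each component's area is g times its
#'   single-electrode counterpart (implemented as a threshold elevation,
#'   exact for Gaussian profiles).
#' @param jitterSdPx,sizeBiasSd drawing-noise parameters.
#' @param erdMeanUm per-participant mean electrode-retina distance (um);
#'   metadata only, carried into the predictor tables.
#' @param trialsPerStim drawings per stimulus condition.
#' @param canvas raster (rows, cols) in px.
#' @param pxPerDeg screen scale, px per degree of visual angle.
#' @param threshold binarization threshold on rendered intensity.
#' @param rotations,centers per-participant implant placement parameters.
#' @param map the [AxonMap-class] to render on.
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(participants = c("S1", "S2", "S3"),
                            rho0 = c(150, 70, 110),
                            lambda0 = c(400, 900, 500),
                            ampExponent = c(0.5, 0.12, 0.8),
                            freqCoef = c(0.08, 0.12, 0.5),
                            eccCoefPerMm = 0.25,
                            gain = 0.7,
                            jitterSdPx = 4,
                            sizeBiasSd = 0.1,
                            erdMeanUm = c(150, 0, 0),
                            trialsPerStim = 5L,
                            canvas = c(768L, 1024L),
                            pxPerDeg = 25,
                            threshold = 0.5,
                            rotations = c(-20, 5, 15),
                            centers = list(c(-2050, -500), c(-600, 1150),
                                           c(-1500, 150)),
                            map = axonMap()) {
  nP <- length(participants)
  rec <- function(x) rep_len(as.numeric(x), nP)
  placements <- lapply(seq_len(nP), function(i)
    placeImplant(rotation = rep_len(rotations, nP)[i],
                 center = centers[[((i - 1) %% length(centers)) + 1]]))
  new("GeneratorConfig", participants = participants,
      rho0 = rec(rho0), lambda0 = rec(lambda0),
      ampExponent = rec(ampExponent), freqCoef = rec(freqCoef),
      eccCoefPerMm = rec(eccCoefPerMm), gain = rec(gain),
      jitterSdPx = rec(jitterSdPx), sizeBiasSd = rec(sizeBiasSd),
      erdMeanUm = rec(erdMeanUm), trialsPerStim = as.integer(trialsPerStim),
      canvas = as.integer(canvas), pxPerDeg = pxPerDeg,
      threshold = threshold, placements = placements, map = map,
      cache = new.env(parent = emptyenv()))
}

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", length(object@participants), "participants,",
      paste(object@canvas, collapse = " x "), "px canvas at",
      object@pxPerDeg, "px/deg\n")
  cat("  gain:", paste(unique(object@gain), collapse = ", "),
      " trials/stimulus:", object@trialsPerStim, "\n")
})

.pIndex <- function(cfg, participant) {
  i <- match(participant, cfg@participants)
  if (is.na(i)) stop("unknown participant: ", participant)
  i
}

.electrodeXY <- function(cfg, pIdx, electrode) {
  xy <- electrodeCoords(cfg@placements[[pIdx]])
  if (!electrode %in% rownames(xy))
    stop("unknown electrode: ", electrode)
  xy[electrode, ]
}

# Cached bundle (and the electrode's arc-length foot point on it).
.bundleFor <- function(cfg, pIdx, electrode) {
  key <- paste0(pIdx, "|", electrode)
  hit <- cfg@cache[[key]]
  if (!is.null(hit)) return(hit)
  xy <- .electrodeXY(cfg, pIdx, electrode)
  b <- axonBundle(cfg@map, xy)
  q <- pointToPolyline(xy, b)
  s <- c(0, cumsum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)))
  out <- list(bundle = b, s = s, s0 = q$sfoot, coords = xy)
  cfg@cache[[key]] <- out
  out
}

# Map retinal micrometers to canvas pixel coordinates (x = col, y = row).
.umToPx <- function(cfg, xUm, yUm) {
  cx <- (cfg@canvas[2] + 1) / 2
  cy <- (cfg@canvas[1] + 1) / 2
  scale <- cfg@pxPerDeg / cfg@map@umPerDeg
  list(col = cx + xUm * scale, row = cy - yUm * scale)
}

# Render the intensity field of one electrode into a full-canvas matrix.
# Only the pixel window within 2 SD of the active bundle segment is touched:
# every pixel outside it has intensity < exp(-2) < the binarization
# threshold (validity requires threshold in (0,1); masks are exact for
# thresholds >= exp(-2) ~ 0.135, which covers all sensible settings).
.renderIntensity <- function(cfg, pIdx, electrode, rhoEff, lambdaEff) {
  bl <- .bundleFor(cfg, pIdx, electrode)
  # sample the bundle at arc-length positions centered on the electrode's
  # foot point (always including it, so the lambda -> 0 limit reduces to an
  # isotropic current-spread blob); curvature radii are millimeters, so
  # half-rho spacing keeps the envelope ripple below ~3 percent
  rstep <- max(min(rhoEff, lambdaEff) / 2, 2)
  svec <- unique(c(bl$s0,
                   seq(bl$s0 - 2.2 * lambdaEff, bl$s0 + 2.2 * lambdaEff,
                       by = rstep)))
  svec <- sort(svec[svec >= 0 & svec <= max(bl$s)])
  ax <- stats::approx(bl$s, bl$bundle[, 1], xout = svec)$y
  ay <- stats::approx(bl$s, bl$bundle[, 2], xout = svec)$y
  w <- exp(-(svec - bl$s0)^2 / (2 * lambdaEff^2))
  pad <- 2 * rhoEff
  px <- .umToPx(cfg, range(ax) + c(-pad, pad), range(ay) + c(-pad, pad))
  cols <- max(1L, floor(min(px$col))):min(cfg@canvas[2], ceiling(max(px$col)))
  rows <- max(1L, floor(min(px$row))):min(cfg@canvas[1], ceiling(max(px$row)))
  out <- matrix(0, cfg@canvas[1], cfg@canvas[2])
  if (!length(cols) || !length(rows)) return(out)
  scale <- cfg@map@umPerDeg / cfg@pxPerDeg
  cx <- (cfg@canvas[2] + 1) / 2
  cy <- (cfg@canvas[1] + 1) / 2
  gx <- (rep(cols, each = length(rows)) - cx) * scale
  gy <- (cy - rep(rows, times = length(cols))) * scale
  val <- .cpp_axon_intensity(gx, gy, ax, ay, w, 1 / (2 * rhoEff^2))
  out[rows, cols] <- matrix(val, length(rows), length(cols))
  out
}

.effScales <- function(cfg, pIdx, electrode, amplitude, frequency) {
  if (amplitude <= 0 || frequency <= 0)
    stop("amplitude and frequency must be positive")
  efdMm <- electrodeFoveaDistance(.electrodeXY(cfg, pIdx, electrode)) / 1000
  rho <- cfg@rho0[pIdx] * amplitude^cfg@ampExponent[pIdx]
  lam <- cfg@lambda0[pIdx] *
    (1 + cfg@freqCoef[pIdx] * log(frequency / 20)) *
    (1 + cfg@eccCoefPerMm[pIdx] * efdMm)
  list(rho = max(rho, 1), lambda = max(lam, 1))
}

.applyNoise <- function(cfg, pIdx, mask, noise) {
  if (!noise) return(mask)
  d <- round(rnorm(2, 0, cfg@jitterSdPx[pIdx]))
  .shiftMask(mask, d[1], d[2])
}

#' Render a single-electrode phosphene drawing
#'
#' Simulates one trial: computes the axon-map intensity field of the
#' electrode at the effective spread scales implied by the stimulus,
#' binarizes it at the configured threshold, and (optionally) applies the
#' participant's drawing noise (log-normal size bias on the spread scales and
#' centroid jitter of the drawn mask). Deterministic for a fixed RNG state.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param participant participant identifier.
#' @param electrode electrode name ("A1".."F10").
#' @param amplitude stimulus amplitude, multiples of threshold (> 0).
#' @param frequency pulse frequency, Hz (> 0).
#' @param noise apply drawing noise. Default TRUE.
#' @return Binary canvas matrix with attribute \code{truth}: the latent
#'   effective scales, the noiseless component count, and the gain (for
#'   paired renders).
#' @export
renderSingle <- function(cfg, participant, electrode, amplitude, frequency,
                         noise = TRUE) {
  pIdx <- .pIndex(cfg, participant)
  sc <- .effScales(cfg, pIdx, electrode, amplitude, frequency)
  if (noise) {
    bias <- exp(rnorm(1, 0, cfg@sizeBiasSd[pIdx]))
    sc$rho <- sc$rho * bias
    sc$lambda <- sc$lambda * bias
  }
  I <- .renderIntensity(cfg, pIdx, electrode, sc$rho, sc$lambda)
  mask <- matrix(as.integer(I >= cfg@threshold), nrow(I), ncol(I))
  count <- max(labelRegions(mask))
  mask <- .applyNoise(cfg, pIdx, mask, noise)
  attr(mask, "truth") <- list(rhoEff = sc$rho, lambdaEff = sc$lambda,
                              count = count, gain = 1)
  mask
}

#' Render a paired-electrode phosphene drawing
#'
#' The paired percept is the pixelwise maximum of the two single-electrode
#' intensity fields, binarized at the gain-elevated threshold
#' \eqn{\theta^g}: for well-separated Gaussian components this makes each
#' component's area exactly g times its single-electrode counterpart, so
#' descriptor totals sum linearly with slope g. The noiseless connected-
#' component count of the result is the ground-truth phosphene count
#' (electrodes on nearby bundles merge into one component).
#'
#' @inheritParams renderSingle
#' @param electrode1,electrode2 the two stimulated electrodes (distinct).
#' @return Binary canvas matrix with attribute \code{truth} as in
#'   [renderSingle()].
#' @export
renderPaired <- function(cfg, participant, electrode1, electrode2, amplitude,
                         frequency = 20, noise = TRUE) {
  if (identical(electrode1, electrode2))
    stop("paired stimulation requires two distinct electrodes")
  pIdx <- .pIndex(cfg, participant)
  sc1 <- .effScales(cfg, pIdx, electrode1, amplitude, frequency)
  sc2 <- .effScales(cfg, pIdx, electrode2, amplitude, frequency)
  if (noise) {
    bias <- exp(rnorm(1, 0, cfg@sizeBiasSd[pIdx]))
    sc1 <- lapply(sc1, `*`, bias)
    sc2 <- lapply(sc2, `*`, bias)
  }
  I <- pmax(.renderIntensity(cfg, pIdx, electrode1, sc1$rho, sc1$lambda),
            .renderIntensity(cfg, pIdx, electrode2, sc2$rho, sc2$lambda))
  g <- cfg@gain[pIdx]
  tau <- cfg@threshold^g
  mask <- matrix(as.integer(I >= tau), nrow(I), ncol(I))
  count <- max(labelRegions(mask))
  mask <- .applyNoise(cfg, pIdx, mask, noise)
  attr(mask, "truth") <- list(rhoEff = c(sc1$rho, sc2$rho),
                              lambdaEff = c(sc1$lambda, sc2$lambda),
                              count = count, gain = g)
  mask
}

# Electrode-level predictor table for a config (EFD from the placement; ERD
# drawn once per electrode from the participant's mean, metadata only).
.electrodeTable <- function(cfg) {
  do.call(rbind, lapply(seq_along(cfg@participants), function(i) {
    xy <- electrodeCoords(cfg@placements[[i]])
    erd <- if (cfg@erdMeanUm[i] > 0)
      pmax(rnorm(nrow(xy), cfg@erdMeanUm[i], cfg@erdMeanUm[i] / 4), 0)
    else rep(0, nrow(xy))
    data.frame(participant = cfg@participants[i], electrode = rownames(xy),
               efd_um = electrodeFoveaDistance(xy), erd_um = erd,
               row.names = NULL)
  }))
}

#' Generate a complete synthetic drawing dataset
#'
#' Samples a full simulated experiment: per participant, a set of electrodes
#' with single-electrode stimulus cells (an amplitude series at 20 Hz,
#' including the 2x-threshold standard pulse required for normalization, and
#' a frequency series at 1.5x threshold) and a set of electrode pairs
#' (stimulated at 20 Hz, amplitudes drawn from the low end of the series,
#' with the matching single-electrode cells guaranteed so the
#' linear-summation analysis can form its sum-of-singles predictor). Each
#' cell is rendered \code{trialsPerStim} times with drawing noise. All
#' randomness is governed by \code{seed}; identical calls are byte-identical.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param seed integer seed.
#' @param nElectrodes single-electrode electrodes per participant.
#' @param nPairs electrode pairs per participant.
#' @param ampLevels amplitude series (x threshold); must contain 2.
#' @param freqLevels frequency series (Hz).
#' @param noise render with drawing noise. Default TRUE.
#' @param dir if non-NULL, the dataset is also written there: PNG masks under
#'   \code{drawings/}, \code{trials.csv}, per-participant placement YAMLs,
#'   \code{electrodes.csv}, \code{pairs.csv} and \code{truth.csv}.
#' @return List with \code{drawings} (a [DrawingSet-class]), \code{truth}
#'   (data.frame of latent per-trial values), \code{electrodeTable},
#'   \code{pairTable} (axonal distances for the sampled pairs) and
#'   \code{cfg}.
#' @export
sampleDataset <- function(cfg, seed = 1, nElectrodes = 5, nPairs = 12,
                          ampLevels = c(1.25, 1.5, 2, 4, 6),
                          freqLevels = c(6, 20, 60, 120),
                          noise = TRUE, dir = NULL) {
  stopifnot(any(abs(ampLevels - 2) < 1e-9))
  set.seed(seed)
  masks <- list(); rows <- list(); truths <- list()
  pairRows <- list()
  k <- 0L
  for (i in seq_along(cfg@participants)) {
    p <- cfg@participants[i]
    els <- sort(sample(rownames(electrodeCoords(cfg@placements[[i]])),
                       nElectrodes))
    cells <- rbind(
      expand.grid(electrode = els, amplitude = ampLevels, frequency = 20,
                  stringsAsFactors = FALSE),
      expand.grid(electrode = els, amplitude = 1.5,
                  frequency = setdiff(freqLevels, 20),
                  stringsAsFactors = FALSE))
    for (r in seq_len(nrow(cells))) {
      for (tr in seq_len(cfg@trialsPerStim)) {
        k <- k + 1L
        m <- renderSingle(cfg, p, cells$electrode[r], cells$amplitude[r],
                          cells$frequency[r], noise = noise)
        masks[[k]] <- m
        tru <- attr(m, "truth")
        attr(masks[[k]], "truth") <- NULL
        rows[[k]] <- data.frame(participant = p, trial = tr,
                                electrode1 = cells$electrode[r],
                                electrode2 = NA_character_,
                                amplitude = cells$amplitude[r],
                                frequency = cells$frequency[r])
        truths[[k]] <- data.frame(rho_eff = tru$rhoEff[1],
                                  lambda_eff = mean(tru$lambdaEff),
                                  true_count = tru$count, gain = tru$gain)
      }
    }
    if (nPairs > 0) {
      prs <- t(combn(els, 2))
      prs <- prs[sample(nrow(prs), min(nPairs, nrow(prs))), , drop = FALSE]
      for (q in seq_len(nrow(prs))) {
        amp <- sample(ampLevels[ampLevels <= 2], 1)
        for (tr in seq_len(cfg@trialsPerStim)) {
          k <- k + 1L
          m <- renderPaired(cfg, p, prs[q, 1], prs[q, 2], amp, 20,
                            noise = noise)
          masks[[k]] <- m
          tru <- attr(m, "truth")
          attr(masks[[k]], "truth") <- NULL
          rows[[k]] <- data.frame(participant = p, trial = tr,
                                  electrode1 = prs[q, 1],
                                  electrode2 = prs[q, 2],
                                  amplitude = amp, frequency = 20)
          truths[[k]] <- data.frame(rho_eff = mean(tru$rhoEff),
                                    lambda_eff = mean(tru$lambdaEff),
                                    true_count = tru$count, gain = tru$gain)
        }
      }
      xy <- electrodeCoords(cfg@placements[[i]])
      pairRows[[i]] <- do.call(rbind, lapply(seq_len(nrow(prs)), function(q) {
        pd <- pairDistances(cfg@map, xy[prs[q, 1], ], xy[prs[q, 2], ])
        cbind(data.frame(participant = p, electrode1 = prs[q, 1],
                         electrode2 = prs[q, 2]), pd)
      }))
    }
  }
  td <- do.call(rbind, rows)
  td$trial <- seq_len(nrow(td))  # unique trial ids across the set
  ds <- drawingSet(masks, td)
  truth <- cbind(td, do.call(rbind, truths))
  eTab <- .electrodeTable(cfg)
  pTab <- if (length(pairRows)) do.call(rbind, pairRows) else NULL
  out <- list(drawings = ds, truth = truth, electrodeTable = eTab,
              pairTable = pTab, cfg = cfg, seed = seed)
  if (!is.null(dir)) .writeDataset(out, dir)
  out
}

#' Sample a paired-stimulation set for gain recovery
#'
#' Renders a set of electrode pairs whose bundles are well separated (the
#' between-axon distance exceeds \code{minBetweenUm}), together with their
#' two single-electrode drawings under the same stimulus, and returns the
#' per-drawing descriptor totals of the paired percept alongside the sum of
#' the singles' totals. Regressing the former on the latter without an
#' intercept recovers the configured perceptual gain.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param seed integer seed.
#' @param nPairs number of pairs (pooled across participants).
#' @param amplitude stimulus amplitude. Default 2.
#' @param noise render with drawing noise. Default FALSE.
#' @param minBetweenUm minimum between-axon separation for a pair to count
#'   as non-merging. Default 800.
#' @return data.frame with one row per pair: paired totals
#'   (\code{paired_area}, ...), sum-of-singles totals (\code{sum_area}, ...)
#'   and the pair's axonal distances.
#' @export
samplePairedSet <- function(cfg, seed = 1, nPairs = 100, amplitude = 2,
                            noise = FALSE, minBetweenUm = 800) {
  set.seed(seed)
  totals <- function(mask) {
    t <- .regionTable(mask)
    c(area = sum(t$area), perimeter = sum(t$perimeter),
      major = sum(t$major), minor = sum(t$minor), count = nrow(t))
  }
  out <- list(); k <- 0L
  guard <- 0L
  while (k < nPairs && guard < nPairs * 60L) {
    guard <- guard + 1L
    i <- sample(length(cfg@participants), 1)
    p <- cfg@participants[i]
    xy <- electrodeCoords(cfg@placements[[i]])
    els <- sample(rownames(xy), 2)
    pd <- pairDistances(cfg@map, xy[els[1], ], xy[els[2], ])
    if (pd$between_axon_um < minBetweenUm) next
    k <- k + 1L
    m1 <- renderSingle(cfg, p, els[1], amplitude, 20, noise = noise)
    m2 <- renderSingle(cfg, p, els[2], amplitude, 20, noise = noise)
    mp <- renderPaired(cfg, p, els[1], els[2], amplitude, 20, noise = noise)
    t1 <- totals(m1); t2 <- totals(m2); tp <- totals(mp)
    out[[k]] <- cbind(data.frame(participant = p, electrode1 = els[1],
                                 electrode2 = els[2]),
                      as.data.frame(t(setNames(tp,
                        paste0("paired_", names(tp))))),
                      as.data.frame(t(setNames(t1 + t2,
                        paste0("sum_", names(t1))))),
                      pd[c("euclidean_um", "between_axon_um",
                           "along_axon_um")])
  }
  if (k < nPairs)
    warning("only ", k, " pairs with between-axon distance >= ", minBetweenUm)
  do.call(rbind, out)
}

#' Sample paired percept counts across the between-axon range
#'
#' Renders electrode pairs spanning the whole between-axon distance range and
#' returns the mean drawn phosphene count per pair (over
#' \code{trialsPerStim} noisy trials) with the pair's stimulus amplitude,
#' electrode-fovea distance and axonal distances, i.e. the inputs of the
#' phosphene-number model comparison.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param seed integer seed.
#' @param nPairs pairs pooled across participants.
#' @param trials noisy trials per pair; defaults to the config's
#'   \code{trialsPerStim}.
#' @param maxSepUm maximum Euclidean electrode separation: pairs are drawn
#'   from nearby electrodes (up to ~3 grid pitches by default), the regime in
#'   which percept merging is actually at stake.
#' @return data.frame with one row per pair.
#' @export
samplePairCounts <- function(cfg, seed = 1, nPairs = 45, trials = NULL,
                             maxSepUm = 1800) {
  set.seed(seed)
  if (is.null(trials)) trials <- cfg@trialsPerStim
  out <- vector("list", nPairs)
  for (k in seq_len(nPairs)) {
    i <- sample(length(cfg@participants), 1)
    p <- cfg@participants[i]
    xy <- electrodeCoords(cfg@placements[[i]])
    e1 <- sample(rownames(xy), 1)
    sep <- sqrt((xy[, 1] - xy[e1, 1])^2 + (xy[, 2] - xy[e1, 2])^2)
    near <- rownames(xy)[sep > 0 & sep <= maxSepUm]
    els <- c(e1, sample(near, 1))
    pd <- pairDistances(cfg@map, xy[els[1], ], xy[els[2], ])
    amp <- sample(c(1.25, 1.5, 2), 1)
    cnt <- vapply(seq_len(trials), function(tr) {
      m <- renderPaired(cfg, p, els[1], els[2], amp, 20, noise = TRUE)
      ex <- extractPhosphenes(list(m))
      ex$summary$n_phosphenes[1]
    }, numeric(1))
    out[[k]] <- cbind(data.frame(participant = p, electrode1 = els[1],
                                 electrode2 = els[2], amplitude = amp,
                                 mean_count = mean(cnt),
                                 efd_um = mean(c(pd$efd1_um, pd$efd2_um))),
                      pd[c("euclidean_um", "between_axon_um",
                           "along_axon_um")])
  }
  do.call(rbind, out)
}
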
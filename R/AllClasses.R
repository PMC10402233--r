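#' @include phosphenes-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' DrawingSet: binary phosphene drawings with their trial table
#'
#' Container pairing one binary raster mask per trial (foreground = 1,
#' background = 0; x = column index, y = row index, 0-based) with the trial
#' metadata needed for analysis: participant, stimulated electrode(s),
#' stimulus amplitude (in multiples of the perceptual threshold) and pulse
#' frequency (Hz).
#'
#' @slot drawings list of integer matrices with values in \{0, 1\}.
#' @slot trialData \link[S4Vectors]{DataFrame} with one row per drawing and at
#'   least the columns \code{participant}, \code{trial}, \code{electrode1},
#'   \code{electrode2} (\code{NA} for single-electrode trials),
#'   \code{amplitude} and \code{frequency}.
#'
#' @seealso [drawingSet()], [shapeTable()], [sampleDataset()]
#' @export
setClass("DrawingSet",
  slots = c(drawings = "list", trialData = "DataFrame"))

setValidity("DrawingSet", function(object) {
  msg <- character()
  if (length(object@drawings) != nrow(object@trialData))
    msg <- c(msg, "number of drawings must equal nrow(trialData)")
  need <- c("participant", "trial", "electrode1", "electrode2",
            "amplitude", "frequency")
  miss <- setdiff(need, colnames(object@trialData))
  if (length(miss))
    msg <- c(msg, paste0("trialData lacks columns: ",
                         paste(miss, collapse = ", ")))
  ok <- vapply(object@drawings, function(d) {
    is.matrix(d) && all(d %in% c(0L, 1L))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "all drawings must be binary matrices with values in {0,1}")
  if (length(msg)) msg else TRUE
})

#' AxonMap: retinal nerve-fiber-bundle trajectory model
#'
#' Parameterizes the simulated map of retinal ganglion-cell axon bundles in a
#' canonical right-eye coordinate frame: fovea at the origin, optic disc in
#' the +x (nasal) direction, horizontal raphe along the temporal (-x) axis.
#' Bundles are spiral-family trajectories around the optic-disc center,
#' indexed by their angle of entry into the disc, with separate parameter
#' fits for the superior and inferior hemiretina (see [axonBundle()]).
#'
#' @slot discCenter optic-disc center (x, y) in micrometers.
#' @slot umPerDeg retinal magnification factor (micrometers per degree of
#'   visual angle).
#' @slot rRangeDeg radial extent of the modeled trajectories, in degrees from
#'   the optic-disc center.
#' @slot stepUm arc-length discretization step of the returned polylines.
#' @slot nSeeds number of seed entry angles per hemifield used when searching
#'   for the bundle closest to a point.
#' @slot supParams,infParams named numeric vectors (\code{b0}, \code{b1},
#'   \code{phiRef}, \code{phiWidth}, \code{c0}, \code{c1}) of the superior and
#'   inferior trajectory fits.
#' @slot cache internal environment memoizing the seed fan.
#' @seealso [axonMap()], [axonBundle()], [pairDistances()]
#' @export
setClass("AxonMap",
  slots = c(discCenter = "numeric", umPerDeg = "numeric",
            rRangeDeg = "numeric", stepUm = "numeric", nSeeds = "integer",
            supParams = "numeric", infParams = "numeric",
            cache = "environment"))

setValidity("AxonMap", function(object) {
  msg <- character()
  if (length(object@discCenter) != 2 || !all(is.finite(object@discCenter)))
    msg <- c(msg, "discCenter must be a finite length-2 numeric")
  if (object@umPerDeg <= 0) msg <- c(msg, "umPerDeg must be positive")
  if (object@stepUm <= 0) msg <- c(msg, "stepUm must be positive")
  if (length(object@rRangeDeg) != 2 ||
      object@rRangeDeg[1] <= 0 || diff(object@rRangeDeg) <= 0)
    msg <- c(msg, "rRangeDeg must be increasing and positive")
  par <- c("b0", "b1", "phiRef", "phiWidth", "c0", "c1")
  if (!all(par %in% names(object@supParams)) ||
      !all(par %in% names(object@infParams)))
    msg <- c(msg, "supParams/infParams must name b0, b1, phiRef, phiWidth, c0, c1")
  if (length(msg)) msg else TRUE
})

#' ImplantPlacement: electrode array coordinates on the retina
#'
#' A 6 x 10 epiretinal electrode grid (rows A-F by columns 1-10, disc
#' electrodes 200 micrometers in diameter at 575 micrometer pitch), rotated
#' and translated into the canonical fovea-origin retinal frame.
#'
#' @slot rotation array rotation in degrees.
#' @slot center array center offset (x, y) in micrometers.
#' @slot eye "RE" or "LE"; left eyes are mirrored into the canonical
#'   right-eye frame at construction.
#' @slot coords 60 x 2 matrix of electrode centers (micrometers), rownames
#'   "A1".."F10".
#' @slot outOfRetina TRUE if any electrode falls outside the physiological
#'   retinal extent (|x| or |y| >= 15,000 micrometers).
#' @seealso [placeImplant()]
#' @export
setClass("ImplantPlacement",
  slots = c(rotation = "numeric", center = "numeric", eye = "character",
            coords = "matrix", outOfRetina = "logical"))

setValidity("ImplantPlacement", function(object) {
  msg <- character()
  if (!identical(dim(object@coords), c(60L, 2L)))
    msg <- c(msg, "coords must be a 60 x 2 matrix")
  if (!object@eye %in% c("RE", "LE"))
    msg <- c(msg, "eye must be 'RE' or 'LE'")
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic drawing generator
#'
#' Per-participant rendering and noise parameters of the synthetic phosphene
#' generator, plus the shared canvas geometry and axon map. See
#' [generatorConfig()] for the meaning, units and defaults of every field.
#'
#' @slot participants participant identifiers.
#' @slot rho0,lambda0 radial current-spread and axonal spread scales (um).
#' @slot ampExponent,freqCoef,eccCoefPerMm amplitude, frequency and
#'   eccentricity effect coefficients.
#' @slot gain paired-stimulation perceptual gain in (0, 1].
#' @slot jitterSdPx,sizeBiasSd drawing noise (centroid jitter SD in pixels;
#'   SD of the log-normal per-trial size bias).
#' @slot erdMeanUm mean electrode-retina distance (um, metadata only).
#' @slot trialsPerStim drawings per stimulus condition.
#' @slot canvas drawing raster (rows, columns) in pixels.
#' @slot pxPerDeg screen scale in pixels per degree of visual angle.
#' @slot threshold binarization threshold on rendered intensity.
#' @slot placements list of [ImplantPlacement-class], one per participant.
#' @slot map the [AxonMap-class] used for rendering.
#' @slot cache internal environment memoizing electrode bundles.
#' @seealso [generatorConfig()], [renderSingle()], [sampleDataset()]
#' @export
setClass("GeneratorConfig",
  slots = c(participants = "character",
            rho0 = "numeric", lambda0 = "numeric", ampExponent = "numeric",
            freqCoef = "numeric", eccCoefPerMm = "numeric", gain = "numeric",
            jitterSdPx = "numeric", sizeBiasSd = "numeric",
            erdMeanUm = "numeric", trialsPerStim = "integer",
            canvas = "integer", pxPerDeg = "numeric", threshold = "numeric",
            placements = "list", map = "AxonMap", cache = "environment"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  nP <- length(object@participants)
  per <- c("rho0", "lambda0", "ampExponent", "freqCoef", "eccCoefPerMm",
           "gain", "jitterSdPx", "sizeBiasSd", "erdMeanUm")
  for (s in per)
    if (length(slot(object, s)) != nP)
      msg <- c(msg, paste0(s, " must have one value per participant"))
  if (any(object@rho0 <= 0) || any(object@lambda0 <= 0))
    msg <- c(msg, "rho0 and lambda0 must be positive")
  if (any(object@gain <= 0) || any(object@gain > 1))
    msg <- c(msg, "gain must lie in (0, 1]")
  if (length(object@placements) != nP)
    msg <- c(msg, "one placement per participant required")
  if (length(object@canvas) != 2 || any(object@canvas < 16))
    msg <- c(msg, "canvas must be two pixel dimensions >= 16")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' PhosFit: a fitted regression model with the reporting used here
#'
#' Result container for the regression battery: per-predictor standardized
#' coefficients, partial correlations and two-sided p-values (raw and
#' Bonferroni-adjusted), the model AIC/BIC, per-predictor variance inflation
#' factors and the residual vector.
#'
#' @slot method fitting method ("ols", "summation", "mixed").
#' @slot formula human-readable model description.
#' @slot n number of observations.
#' @slot coefficients data.frame with columns \code{term}, \code{beta},
#'   \code{partial_r}, \code{p_value}, \code{p_bonferroni}.
#' @slot aic,bic information criteria (Gaussian log-likelihood; for mixed
#'   models computed on the maximum-likelihood refit so that fixed-effect
#'   structures are comparable).
#' @slot vif named variance inflation factors (empty for single-predictor
#'   models).
#' @slot residuals residual vector.
#' @slot converged optimizer convergence flag (always TRUE for least squares).
#' @seealso [fitStandardizedOls()], [fitSummationRegression()],
#'   [fitMixedModel()], [compareModels()]
#' @export
setClass("PhosFit",
  slots = c(method = "character", formula = "character", n = "integer",
            coefficients = "data.frame", aic = "numeric", bic = "numeric",
            vif = "numeric", residuals = "numeric", converged = "logical"))

setValidity("PhosFit", function(object) {
  msg <- character()
  need <- c("term", "beta", "partial_r", "p_value", "p_bonferroni")
  if (!all(need %in% colnames(object@coefficients)))
    msg <- c(msg, "coefficients must have term/beta/partial_r/p_value/p_bonferroni")
  r <- object@coefficients$partial_r
  if (any(abs(r[is.finite(r)]) > 1 + 1e-8))
    msg <- c(msg, "|partial_r| must be <= 1")
  if (length(object@vif) && any(object@vif < 1 - 1e-8))
    msg <- c(msg, "VIF must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ModelComparison: AIC/BIC comparison of two candidate models
#'
#' Holds the information-criterion differences between two fits of the same
#' response, with the conventional qualitative evidence bands: a difference
#' below 2 supports both models; 2 <= dAIC < 7 (2 <= dBIC < 6) is some
#' evidence against the higher-scoring model; dAIC >= 7 (dBIC >= 6) is strong
#' evidence against it.
#'
#' @slot labels names of the two models (A, B).
#' @slot aic,bic named length-2 vectors of the two models' scores.
#' @slot deltaAIC,deltaBIC absolute score differences.
#' @slot winnerAIC,winnerBIC label of the lower-scoring (better) model.
#' @slot evidenceAIC,evidenceBIC qualitative band.
#' @seealso [compareModels()]
#' @export
setClass("ModelComparison",
  slots = c(labels = "character", aic = "numeric", bic = "numeric",
            deltaAIC = "numeric", deltaBIC = "numeric",
            winnerAIC = "character", winnerBIC = "character",
            evidenceAIC = "character", evidenceBIC = "character"))
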
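#' @include AllClasses.R
NULL

# Canonical retinal frame: fovea at the origin, optic disc toward +x (nasal),
# horizontal raphe along the temporal (-x) axis, superior retina y > 0.
# All coordinates in micrometers unless a function says degrees.

#' Construct an axon map
#'
#' Builds the nerve-fiber-bundle trajectory model. Bundles are members of a
#' spiral family around the optic-disc center, indexed by their angle of
#' entry into the disc (measured from the temporal horizontal, positive into
#' the superior retina): \eqn{\phi(r) = \phi_0 + b (r - r_0)^c} with
#' \eqn{r_0 = 4} degrees, where \eqn{b} and \eqn{c} follow tanh fits of
#' fundus-photograph data with distinct parameter regimes for the superior
#' and inferior hemiretina. Trajectories meet, and are clamped at, the
#' temporal raphe so that bundles never cross the horizontal meridian.
#'
#' @param discCenter optic-disc center (x, y) in micrometers; the right-eye
#'   canonical default is (4600, 260). Left-eye data should be mirrored into
#'   this frame at ingest (see [placeImplant()]).
#' @param umPerDeg retinal magnification (micrometers per degree). Default 288.
#' @param rRangeDeg radial extent of trajectories from the disc, degrees.
#' @param stepUm arc-length step of returned polylines. Default 10.
#' @param nSeeds seed entry angles per hemifield for closest-bundle searches.
#' @param supParams,infParams named parameters (\code{b0}, \code{b1},
#'   \code{phiRef}, \code{phiWidth}, \code{c0}, \code{c1}) of the superior and
#'   inferior fits: \code{b = s exp(b0 + b1 tanh(-(|phi0| - phiRef)/phiWidth))}
#'   with \code{s = -1} superior / \code{+1} inferior (both hemifields bend
#'   toward the raphe), \code{c = c0 + c1 tanh((|phi0| - phiRef)/phiWidth)}.
#' @return An [AxonMap-class] object.
#' @export
axonMap <- function(discCenter = c(4600, 260), umPerDeg = 288,
                    rRangeDeg = c(4, 45), stepUm = 10, nSeeds = 181L,
                    supParams = c(b0 = -1.9, b1 = 3.9, phiRef = 121,
                                  phiWidth = 14, c0 = 1.9, c1 = 1.4),
                    infParams = c(b0 = 0.5, b1 = 1.5, phiRef = 90,
                                  phiWidth = 25, c0 = 1.0, c1 = 0.5)) {
  new("AxonMap", discCenter = as.numeric(discCenter),
      umPerDeg = umPerDeg, rRangeDeg = as.numeric(rRangeDeg),
      stepUm = stepUm, nSeeds = as.integer(nSeeds),
      supParams = supParams, infParams = infParams,
      cache = new.env(parent = emptyenv()))
}

setMethod("show", "AxonMap", function(object) {
  cat("AxonMap: optic disc at (", paste(round(object@discCenter),
      collapse = ", "), ") um,",
      object@umPerDeg, "um/deg, step", object@stepUm, "um\n")
})

# Resample a polyline at a fixed arc-length step (keeping both endpoints).
.resamplePolyline <- function(xy, step) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(xy[1, , drop = FALSE])
  snew <- unique(c(seq(0, L, by = step), L))
  cbind(stats::approx(s, xy[, 1], xout = snew)$y,
        stats::approx(s, xy[, 2], xout = snew)$y)
}

# One trajectory of the spiral family, in micrometers, ordered from the
# peripheral end toward the optic disc; the terminal vertex is the disc
# center. phi0 in degrees, nonzero; sign selects the hemifield.
.trajectory <- function(map, phi0, nDense = 1200L) {
  if (phi0 == 0) stop("entry angle phi0 must be nonzero")
  a <- abs(phi0)
  p <- if (phi0 > 0) map@supParams else map@infParams
  bmag <- exp(p[["b0"]] + p[["b1"]] * tanh(-(a - p[["phiRef"]]) / p[["phiWidth"]]))
  cc <- p[["c0"]] + p[["c1"]] * tanh((a - p[["phiRef"]]) / p[["phiWidth"]])
  b <- if (phi0 > 0) -bmag else bmag  # both hemifields bend toward the raphe
  r0 <- map@rRangeDeg[1]
  r <- seq(r0, map@rRangeDeg[2], length.out = nDense)
  phi <- phi0 + b * (r - r0)^cc
  rad <- phi * pi / 180
  # angle measured from the temporal direction (-x) at the disc
  x <- map@discCenter[1] - r * map@umPerDeg * cos(rad)
  y <- map@discCenter[2] + r * map@umPerDeg * sin(rad)
  # clamp at the raphe: truncate where the trajectory would cross y = 0 on
  # the temporal side of the fovea (x < 0)
  side <- sign(phi0)
  cross <- which(x < 0 & side * y < 0)
  if (length(cross)) {
    k <- cross[1]
    if (k > 1) {
      t <- y[k - 1] / (y[k - 1] - y[k])
      x <- c(x[seq_len(k - 1)], x[k - 1] + t * (x[k] - x[k - 1]))
      y <- c(y[seq_len(k - 1)], 0)
    } else {
      x <- x[1]; y <- 0
    }
  }
  xy <- cbind(rev(x), rev(y))        # periphery -> r0
  xy <- rbind(xy, map@discCenter)    # final leg into the disc center
  .resamplePolyline(xy, map@stepUm)
}

#' A single modeled fiber trajectory
#'
#' Returns the polyline of the bundle entering the optic disc at angle
#' \code{phi0} (degrees from the temporal horizontal; positive = superior
#' hemiretina), discretized at the map's arc-length step and ordered from the
#' peripheral end toward the optic disc.
#'
#' @param map an [AxonMap-class].
#' @param phi0 entry angle in degrees, nonzero.
#' @return n x 2 matrix of (x, y) micrometers, with attribute \code{phi0}.
#' @export
axonTrajectory <- function(map, phi0) {
  xy <- .trajectory(map, phi0)
  attr(xy, "phi0") <- phi0
  xy
}

.mapFan <- function(map) {
  if (!is.null(map@cache$fan)) return(map@cache$fan)
  phis <- seq(0.5, 179.5, length.out = map@nSeeds)
  phis <- c(phis, -phis)
  fan <- lapply(phis, function(p) .trajectory(map, p))
  map@cache$fan <- list(phi0 = phis, bundles = fan)
  map@cache$fan
}

.distToTrajectory <- function(p, xy) {
  .cpp_polyline_dist(p[1], p[2], xy[, 1], xy[, 2])$dmin
}

#' The fiber bundle passing closest to a retinal point
#'
#' Searches a dense fan of seed entry angles in both hemifields for the
#' trajectory minimizing the point-to-polyline distance to \code{p}, then
#' refines the entry angle locally by golden-section search. For points in
#' the modeled region the returned bundle passes within about one
#' discretization step of \code{p}.
#'
#' @param map an [AxonMap-class].
#' @param p length-2 numeric, retinal (x, y) in micrometers. Must lie outside
#'   the optic-disc region.
#' @param discRadiusUm exclusion radius around the disc center. Default 900.
#' @return Polyline matrix as in [axonTrajectory()], with attributes
#'   \code{phi0} and \code{distToPoint}.
#' @export
axonBundle <- function(map, p, discRadiusUm = 900) {
  stopifnot(length(p) == 2, all(is.finite(p)))
  if (sqrt(sum((p - map@discCenter)^2)) < discRadiusUm)
    stop("point lies inside the optic-disc region; no bundle is defined there")
  memoKey <- sprintf("pt:%.3f:%.3f", p[1], p[2])
  hit <- map@cache[[memoKey]]
  if (!is.null(hit)) return(hit)
  fan <- .mapFan(map)
  d <- vapply(fan$bundles, function(b) .distToTrajectory(p, b), numeric(1))
  best <- which.min(d)
  phi0 <- fan$phi0[best]
  half <- if (phi0 > 0) c(1e-2, 180 - 1e-2) else c(-(180 - 1e-2), -1e-2)
  dphi <- diff(range(fan$phi0[sign(fan$phi0) == sign(phi0)])) /
    (map@nSeeds - 1)
  lo <- max(half[1], phi0 - dphi)
  hi <- min(half[2], phi0 + dphi)
  f <- function(a) .distToTrajectory(p, .trajectory(map, a))
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (it in seq_len(40)) {
    if (b - a < 1e-3) break
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  phiBest <- if (f1 < f2) x1 else x2
  out <- .trajectory(map, phiBest)
  attr(out, "phi0") <- phiBest
  attr(out, "distToPoint") <- .distToTrajectory(p, out)
  map@cache[[memoKey]] <- out
  out
}

#' Minimum distance from points to a polyline
#'
#' For each query point, the shortest Euclidean distance to the polyline and
#' the arc-length position (from the polyline's first vertex) of the foot
#' point achieving it.
#'
#' @param points n x 2 matrix (or length-2 vector) of query points.
#' @param poly m x 2 polyline vertex matrix.
#' @return data.frame with columns \code{dmin} and \code{sfoot}.
#' @export
pointToPolyline <- function(points, poly) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  r <- .cpp_polyline_dist(points[, 1], points[, 2], poly[, 1], poly[, 2])
  data.frame(dmin = r$dmin, sfoot = r$sfoot)
}

#' Place a 6 x 10 electrode array on the retina
#'
#' Generates the 60 electrode centers (rows A-F by columns 1-10, 575 um
#' pitch), applies the rotation and then the center translation, and
#' canonicalizes left eyes by mirroring across the vertical axis so the optic
#' disc always lies toward +x.
#'
#' @param rotation array rotation in degrees, within \[-180, 180\].
#' @param center array center (x, y) in micrometers.
#' @param eye "RE" (default) or "LE".
#' @return An [ImplantPlacement-class]; a warning is raised (and the
#'   \code{outOfRetina} slot set) if any electrode leaves the physiological
#'   retinal extent.
#' @examples
#' pl <- placeImplant(rotation = -30, center = c(-1200, 500))
#' head(electrodeCoords(pl))
#' @export
placeImplant <- function(rotation = 0, center = c(0, 0), eye = "RE") {
  if (rotation < -180 || rotation > 180)
    stop("rotation must lie in [-180, 180] degrees")
  ii <- rep(0:5, each = 10)
  jj <- rep(0:9, times = 6)
  grid <- cbind((jj - 4.5) * 575, (2.5 - ii) * 575)
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- grid %*% t(R)
  xy[, 1] <- xy[, 1] + center[1]
  xy[, 2] <- xy[, 2] + center[2]
  if (eye == "LE") xy[, 1] <- -xy[, 1]
  rownames(xy) <- paste0(LETTERS[ii + 1], jj + 1)
  colnames(xy) <- c("x", "y")
  oor <- any(abs(xy) >= 15000)
  if (oor) warning("some electrodes fall outside the physiological retina")
  new("ImplantPlacement", rotation = rotation, center = as.numeric(center),
      eye = eye, coords = xy, outOfRetina = oor)
}

#' @rdname placeImplant
#' @param x an \code{ImplantPlacement}.
#' @export
setMethod("electrodeCoords", "ImplantPlacement", function(x) x@coords)

setMethod("show", "ImplantPlacement", function(object) {
  cat("ImplantPlacement (", object@eye, "): rotation",
      object@rotation, "deg, center (",
      paste(round(object@center), collapse = ", "), ") um\n")
  cat("  mean electrode-fovea distance:",
      round(mean(electrodeFoveaDistance(object@coords)), 1), "um\n")
})

#' Electrode-fovea distance
#'
#' Euclidean distance from retinal points to the fovea (the origin of the
#' canonical frame); the standard proxy for retinal eccentricity.
#'
#' @param p length-2 vector or n x 2 matrix of retinal coordinates (um).
#' @return Numeric vector of distances in micrometers.
#' @export
electrodeFoveaDistance <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  sqrt(p[, 1]^2 + p[, 2]^2)
}

#' Decompose an electrode pair's separation into axonal components
#'
#' Assigns nasal/temporal roles by x-coordinate (larger x = more nasal, i.e.
#' closer to the optic disc; ties are broken by |y|, the electrode farther
#' from the horizontal being the temporal one), takes the fiber bundle
#' passing through the temporal electrode as the reference, and computes:
#' the between-axon distance (shortest distance from the nasal electrode's
#' center to that bundle), the along-axon distance (arc length along the
#' bundle between the temporal electrode's foot point and the foot point of
#' the between-axon segment) and the plain Euclidean separation. The
#' decomposition also works for pairs straddling the raphe, where the
#' reference bundle is clamped at the horizontal meridian.
#'
#' @param map an [AxonMap-class].
#' @param e1,e2 length-2 electrode centers in micrometers (distinct).
#' @return data.frame with one row: \code{euclidean_um},
#'   \code{between_axon_um}, \code{along_axon_um}, \code{efd1_um},
#'   \code{efd2_um}, \code{nasal} (1 or 2, which input is the nasal
#'   electrode) and \code{phi0} of the reference bundle.
#' @export
pairDistances <- function(map, e1, e2) {
  stopifnot(length(e1) == 2, length(e2) == 2)
  if (all(e1 == e2))
    stop("electrodes must be distinct to define pair distances")
  # role assignment: larger x is nasal; tie broken by |y| (larger = temporal)
  if (e1[1] > e2[1] || (e1[1] == e2[1] && abs(e1[2]) < abs(e2[2]))) {
    nasal <- e1; temporal <- e2; nasalIdx <- 1L
  } else {
    nasal <- e2; temporal <- e1; nasalIdx <- 2L
  }
  ref <- axonBundle(map, temporal)
  qt <- pointToPolyline(temporal, ref)
  qn <- pointToPolyline(nasal, ref)
  data.frame(euclidean_um = sqrt(sum((e1 - e2)^2)),
             between_axon_um = qn$dmin,
             along_axon_um = abs(qn$sfoot - qt$sfoot),
             efd1_um = electrodeFoveaDistance(e1),
             efd2_um = electrodeFoveaDistance(e2),
             nasal = nasalIdx,
             phi0 = attr(ref, "phi0"))
}

#' Convert retinal distance to visual angle (and back)
#'
#' Divides micrometers on the retina by the retinal magnification factor.
#' With the default 288 um/deg a 200 um electrode subtends 0.7 degrees of
#' visual angle (to one decimal).
#'
#' @param d distance(s), micrometers (degrees for [degToUm()]); must be
#'   non-negative.
#' @param umPerDeg magnification factor. Default 288.
#' @return Degrees of visual angle (micrometers for [degToUm()]).
#' @export
umToDeg <- function(d, umPerDeg = 288) {
  if (any(d < 0)) stop("distances must be non-negative")
  d / umPerDeg
}

#' @rdname umToDeg
#' @export
degToUm <- function(d, umPerDeg = 288) {
  if (any(d < 0)) stop("distances must be non-negative")
  d * umPerDeg
}

#' Convert OCT pixel measurements to micrometers
#'
#' Electrode-retina distances are read off optical-coherence-tomography
#' b-scans by counting pixels from the retinal surface to the implant; the
#' known 200 um electrode diameter, seen as the width of the electrode's
#' shadow, calibrates the pixel size.
#'
#' @param distancePx measured distance in pixels (>= 0).
#' @param shadowWidthPx width of the electrode shadow in pixels (> 0).
#' @param electrodeDiameterUm physical electrode diameter. Default 200.
#' @return Distance in micrometers.
#' @examples
#' octPixelsToUm(15, 20)  # 150 um
#' @export
octPixelsToUm <- function(distancePx, shadowWidthPx,
                          electrodeDiameterUm = 200) {
  if (any(shadowWidthPx <= 0))
    stop("shadow width must be positive")
  if (any(distancePx < 0))
    stop("pixel distances must be non-negative")
  distancePx * (electrodeDiameterUm / shadowWidthPx)
}
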
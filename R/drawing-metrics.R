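#' @include DrawingSet-methods.R
NULL

# Coordinate convention used throughout: x = column index, y = row index,
# both 0-based, so the pixel in row r, column c of the matrix sits at
# (x, y) = (c - 1, r - 1). Image moments are convention-sensitive; all
# moment-derived quantities in this file use this convention.

#' Binarize a grayscale drawing
#'
#' @param x numeric matrix with values in \[0, 1\].
#' @param threshold cut point; pixels with intensity >= threshold become
#'   foreground. Default 0.5.
#' @return integer matrix with values in \{0, 1\}.
#' @export
binarizeMask <- function(x, threshold = 0.5) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix")
  out <- matrix(as.integer(x >= threshold), nrow(x), ncol(x))
  out
}

.isBinary <- function(mask) {
  is.matrix(mask) && is.numeric(mask) && !anyNA(mask) && all(mask %in% c(0, 1))
}

#' Validate a raw phosphene drawing
#'
#' Drawn phosphene outlines must be closed so that region extraction sees
#' solid shapes. This applies a morphological closing (disc-shaped structuring
#' element of the given radius) to bridge small gaps in drawn contour lines,
#' then fills enclosed holes, emulating the manual contour-closing step of a
#' drawing-validation protocol. Solid input passes through unchanged; an
#' all-zero drawing is returned as is and flagged empty.
#'
#' @param mask binary matrix (0 background, 1 drawn). Non-binary input is a
#'   format error; binarize grayscale first with [binarizeMask()].
#' @param closeRadius radius (pixels) of the closing element. Default 1.
#' @param fillHoles fill enclosed background after closing. Default TRUE.
#' @return The cleaned integer mask, with attributes \code{empty} (logical)
#'   and \code{validationLog} (pixels added by closing and by filling, so the
#'   automated cleaning is auditable per drawing).
#' @examples
#' ring <- matrix(0L, 9, 9)
#' ring[2, 3:7] <- ring[8, 3:7] <- 1L
#' ring[3:7, 2] <- ring[3:7, 8] <- 1L
#' sum(validateDrawing(ring))  # interior filled
#' @export
validateDrawing <- function(mask, closeRadius = 1, fillHoles = TRUE) {
  if (!.isBinary(mask))
    stop("drawing mask must be a binary matrix with values in {0,1}")
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0L) {
    attr(mask, "empty") <- TRUE
    attr(mask, "validationLog") <- c(closed = 0L, filled = 0L)
    return(mask)
  }
  out <- mask
  if (closeRadius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(closeRadius) + 1L,
                               shape = "disc")
    # pad so the closing cannot interact with the canvas border
    r <- as.integer(closeRadius) + 1L
    padded <- matrix(0L, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
    padded[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- mask
    closed <- EBImage::imageData(EBImage::closing(padded, kern))
    out <- closed[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))]
  }
  closed <- sum(out) - sum(mask)
  if (fillHoles)
    out2 <- EBImage::imageData(EBImage::fillHull(out))
  else
    out2 <- out
  filled <- sum(out2) - sum(out)
  out2 <- matrix(as.integer(out2), nrow(mask), ncol(mask))
  attr(out2, "empty") <- FALSE
  attr(out2, "validationLog") <- c(closed = as.integer(closed),
                                   filled = as.integer(filled))
  out2
}

#' Raw image moment of a binary drawing
#'
#' Computes \eqn{M_{ij} = \sum_x \sum_y x^i y^j I(x, y)} with x = column,
#' y = row, 0-based. \eqn{M_{00}} is the foreground area in pixels;
#' \eqn{(M_{10}/M_{00}, M_{01}/M_{00})} is the center of mass.
#'
#' @param mask binary matrix.
#' @param i,j non-negative integer moment orders.
#' @return The raw moment (a number; 0 for an empty mask).
#' @examples
#' m <- matrix(0L, 10, 10); m[8, 4] <- 1L  # pixel at (x = 3, y = 7)
#' c(rawMoment(m, 0, 0), rawMoment(m, 1, 0), rawMoment(m, 0, 1))
#' @export
rawMoment <- function(mask, i, j) {
  if (!.isBinary(mask)) stop("mask must be binary")
  if (i < 0 || j < 0 || i != round(i) || j != round(j))
    stop("moment orders i, j must be non-negative integers")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  sum(x^i * y^j)
}

# Central second moments and covariance-axis lengths for a pixel index set.
# Returns area, centroid, mu20/mu11/mu02 and 4*sqrt(eigenvalue) axis lengths.
.momentStats <- function(idx) {
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  a <- length(x)
  xb <- mean(x); yb <- mean(y)
  mu20 <- mean(x * x) - xb * xb
  mu02 <- mean(y * y) - yb * yb
  mu11 <- mean(x * y) - xb * yb
  # eigenvalues of [[mu20, mu11], [mu11, mu02]] in closed form
  tr <- mu20 + mu02
  det2 <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  ev1 <- (tr + det2) / 2
  ev2 <- (tr - det2) / 2
  list(area = a, centroid = c(x = xb, y = yb),
       mu = c(mu20 = mu20, mu11 = mu11, mu02 = mu02),
       major = 4 * sqrt(max(ev1, 0)), minor = 4 * sqrt(max(ev2, 0)))
}

# Weighted border-pixel perimeter (Benkrid-Crookes scheme): border pixels are
# the mask minus its 4-connected erosion; each border pixel is classified by
# the 3x3 pattern code 1*self + 2*(orthogonal border neighbors) + 10*(diagonal
# border neighbors) and weighted 1 (straight), sqrt(2) (diagonal) or
# (1+sqrt(2))/2 (corner). Approximates the length of the polyline through the
# centers of connected border pixels.
.perimeterWeights <- local({
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  w
})

#' Perimeter of the foreground of a binary mask
#'
#' Approximates the total contour length of all foreground regions as a line
#' running through the centers of connected border pixels, using the weighted
#' border-pixel-count scheme (straight, diagonal and corner border
#' configurations weighted 1, sqrt(2) and (1+sqrt(2))/2). A single isolated
#' pixel has perimeter 0 (a polyline through one point has no length).
#'
#' @param mask binary matrix.
#' @return Total perimeter in pixel units.
#' @examples
#' sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
#' perimeterWeighted(sq)  # 8: the ring of 8 border-pixel centers
#' @export
perimeterWeighted <- function(mask) {
  if (!.isBinary(mask)) stop("mask must be binary")
  nr <- nrow(mask); nc <- ncol(mask)
  if (sum(mask) == 0L) return(0)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- function(dr, dc) p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  # 4-connected erosion (border value 0), then border image
  eroded <- mask & core(-1, 0) & core(1, 0) & core(0, -1) & core(0, 1)
  border <- matrix(as.integer(mask & !eroded), nr, nc)
  pb <- matrix(0L, nr + 2L, nc + 2L)
  pb[2:(nr + 1L), 2:(nc + 1L)] <- border
  coreb <- function(dr, dc) pb[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  ortho <- coreb(-1, 0) + coreb(1, 0) + coreb(0, -1) + coreb(0, 1)
  diag4 <- coreb(-1, -1) + coreb(-1, 1) + coreb(1, -1) + coreb(1, 1)
  code <- border + 2L * ortho + 10L * diag4
  sum(.perimeterWeights[code[border == 1L] + 1L])
}

#' Label connected foreground regions
#'
#' 8-connected component labeling (diagonally adjacent strokes belong to the
#' same phosphene, as produced by hand drawing on a touchscreen). Labels are
#' assigned in raster-scan order and are deterministic.
#'
#' @param mask binary matrix.
#' @return Integer matrix of region labels (0 = background).
#' @export
labelRegions <- function(mask) {
  if (!.isBinary(mask)) stop("mask must be binary")
  storage.mode(mask) <- "integer"
  .cpp_label8(mask)
}

#' Shape descriptors of a single phosphene region
#'
#' Computes the four moment-based shape descriptors of one connected region:
#' area (\eqn{M_{00}}), perimeter (border-pixel polyline length), and
#' major/minor axis lengths, defined as four times the square root of the
#' eigenvalues of the central second-moment (covariance) matrix
#' \eqn{[[\mu'_{20}, \mu'_{11}], [\mu'_{11}, \mu'_{02}]]}, plus the centroid.
#'
#' @param mask binary matrix containing the region (any foreground pixel
#'   belongs to it; use [labelRegions()] to isolate regions first).
#' @return List with \code{area}, \code{perimeter}, \code{major}, \code{minor},
#'   \code{centroid} (x, y, 0-based) and \code{mu} (central second moments).
#' @examples
#' sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
#' shapeDescriptors(sq)$area      # 9
#' shapeDescriptors(sq)$centroid  # center of the square
#' @export
shapeDescriptors <- function(mask) {
  if (!.isBinary(mask)) stop("mask must be binary")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute shape descriptors of an empty region")
  st <- .momentStats(idx)
  st$perimeter <- perimeterWeighted(matrix(as.integer(mask != 0),
                                           nrow(mask), ncol(mask)))
  st[c("area", "perimeter", "major", "minor", "centroid", "mu")]
}

# Descriptor table for every labeled region of one drawing.
.regionTable <- function(mask) {
  lab <- labelRegions(mask)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), major = numeric(),
                      minor = numeric(), centroid_x = numeric(),
                      centroid_y = numeric()))
  idxAll <- which(lab != 0, arr.ind = TRUE)
  labs <- lab[lab != 0]
  out <- lapply(seq_len(k), function(l) {
    idx <- idxAll[labs == l, , drop = FALSE]
    st <- .momentStats(idx)
    sub <- matrix(0L, nrow(mask), ncol(mask))
    sub[idx] <- 1L
    data.frame(label = l, area = st$area,
               perimeter = perimeterWeighted(sub),
               major = st$major, minor = st$minor,
               centroid_x = st$centroid[["x"]],
               centroid_y = st$centroid[["y"]])
  })
  do.call(rbind, out)
}

#' Extract phosphenes from the drawings of one stimulus condition
#'
#' Labels connected regions in each drawing of a trial set (all trials of the
#' same electrode(s) and stimulus), then applies the small-spec rule: a region
#' smaller than \code{minArea} pixels is discarded as an additional phosphene
#' unless small regions appear in at least \code{smallTrialFraction} of the
#' trial set's drawings, in which case they are counted. Per-drawing shape
#' descriptors are the sums over surviving regions, so drawings with several
#' phosphenes are summarized comparably to single-phosphene drawings.
#'
#' @param trialSet list of validated binary masks, or a [DrawingSet-class]
#'   whose drawings all belong to one electrode x stimulus condition.
#' @param minArea spec-filter area threshold in pixels. Default 10.
#' @param smallTrialFraction fraction of trials in which small regions must
#'   recur to be counted as real phosphenes. Default 0.5.
#' @return List with \code{regions} (per-drawing descriptor tables of the
#'   surviving regions), \code{summary} (data.frame, one row per drawing:
#'   \code{n_phosphenes} and descriptor totals, zeros when no region
#'   survives), \code{keptSmall} and \code{smallFraction}.
#' @export
extractPhosphenes <- function(trialSet, minArea = 10,
                              smallTrialFraction = 0.5) {
  if (is(trialSet, "DrawingSet")) trialSet <- drawings(trialSet)
  if (!is.list(trialSet) || length(trialSet) == 0L)
    stop("'trialSet' must be a non-empty list of drawings")
  tabs <- lapply(trialSet, .regionTable)
  hasSmall <- vapply(tabs, function(t) any(t$area < minArea), logical(1))
  smallFraction <- mean(hasSmall)
  keepSmall <- smallFraction >= smallTrialFraction
  surv <- lapply(tabs, function(t)
    if (keepSmall) t else t[t$area >= minArea, , drop = FALSE])
  summ <- do.call(rbind, lapply(seq_along(surv), function(i) {
    t <- surv[[i]]
    data.frame(drawing = i, n_phosphenes = nrow(t),
               area = sum(t$area), perimeter = sum(t$perimeter),
               major = sum(t$major), minor = sum(t$minor))
  }))
  list(regions = surv, summary = summ, keptSmall = keepSmall,
       smallFraction = smallFraction)
}

# Integer-translate a mask with zero fill (dx = columns, dy = rows).
.shiftMask <- function(mask, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  srcR <- seq_len(nr) - dy
  srcC <- seq_len(nc) - dx
  okR <- srcR >= 1L & srcR <= nr
  okC <- srcC >= 1L & srcC <= nc
  out[which(okR), which(okC)] <- mask[srcR[okR], srcC[okC], drop = FALSE]
  out
}

#' Trial-averaged mean image
#'
#' Averages the drawings of one stimulus condition after removing pure
#' translation: each drawing is shifted so that its center of mass (mode
#' \code{"drawing"}) coincides with the trial-averaged center of mass. In
#' mode \code{"phosphene"} (intended for paired-electrode percepts with
#' several phosphenes) each connected region is aligned separately at its
#' trial-averaged center of mass, with regions matched across trials by the
#' rank order of their centroids.
#'
#' @param trialSet list of binary masks or a [DrawingSet-class].
#' @param mode alignment mode, \code{"drawing"} or \code{"phosphene"}.
#' @return Numeric matrix in \[0, 1\]: the pixelwise mean of the aligned
#'   drawings (empty drawings are dropped first).
#' @export
meanImage <- function(trialSet, mode = c("drawing", "phosphene")) {
  mode <- match.arg(mode)
  if (is(trialSet, "DrawingSet")) trialSet <- drawings(trialSet)
  trialSet <- Filter(function(m) sum(m) > 0, trialSet)
  if (length(trialSet) == 0L)
    stop("all drawings are empty; no mean image can be formed")
  nr <- nrow(trialSet[[1]]); nc <- ncol(trialSet[[1]])
  if (mode == "drawing") {
    coms <- t(vapply(trialSet, function(m) {
      idx <- which(m != 0, arr.ind = TRUE)
      c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
    }, numeric(2)))
    target <- colMeans(coms)
    acc <- matrix(0, nr, nc)
    for (i in seq_along(trialSet)) {
      d <- round(target - coms[i, ])
      acc <- acc + .shiftMask(trialSet[[i]], d[1], d[2])
    }
    return(acc / length(trialSet))
  }
  # phosphene mode: match regions across trials by centroid rank
  regs <- lapply(trialSet, function(m) {
    lab <- labelRegions(m)
    k <- max(lab)
    cent <- t(vapply(seq_len(k), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
    }, numeric(2)))
    ord <- order(cent[, 1], cent[, 2])
    list(lab = lab, cent = cent[ord, , drop = FALSE], order = ord)
  })
  maxk <- max(vapply(regs, function(r) nrow(r$cent), integer(1)))
  targets <- lapply(seq_len(maxk), function(r) {
    cs <- do.call(rbind, lapply(regs, function(g)
      if (nrow(g$cent) >= r) g$cent[r, ] else NULL))
    colMeans(cs)
  })
  acc <- matrix(0, nr, nc)
  for (g in regs) {
    for (r in seq_len(nrow(g$cent))) {
      l <- g$order[r]
      sub <- matrix(0L, nr, nc)
      sub[g$lab == l] <- 1L
      d <- round(targets[[r]] - g$cent[r, ])
      acc <- acc + .shiftMask(sub, d[1], d[2])
    }
  }
  pmin(acc / length(trialSet), 1)
}

#' Per-drawing shape descriptor table for a drawing set
#'
#' Runs the full drawing-metrics pipeline over a [DrawingSet-class]: each
#' drawing is validated (contour closing + hole filling), drawings are grouped
#' into trial sets by participant, electrode(s), amplitude and frequency, the
#' small-spec filter is applied within each trial set, and the per-drawing
#' totals of the four shape descriptors plus the phosphene count are returned
#' as a tidy table (one row per drawing).
#'
#' @param ds a [DrawingSet-class].
#' @param closeRadius,fillHoles passed to [validateDrawing()].
#' @param minArea,smallTrialFraction passed to [extractPhosphenes()].
#' @return data.frame with the trial metadata plus \code{n_phosphenes},
#'   \code{area}, \code{perimeter}, \code{major}, \code{minor} and
#'   \code{empty}.
#' @export
shapeTable <- function(ds, closeRadius = 1, fillHoles = TRUE, minArea = 10,
                       smallTrialFraction = 0.5) {
  stopifnot(is(ds, "DrawingSet"))
  td <- as.data.frame(trialData(ds))
  masks <- lapply(drawings(ds), validateDrawing, closeRadius = closeRadius,
                  fillHoles = fillHoles)
  key <- paste(td$participant, td$electrode1, td$electrode2,
               td$amplitude, td$frequency, sep = "|")
  out <- vector("list", length(unique(key)))
  names(out) <- unique(key)
  for (k in unique(key)) {
    sel <- which(key == k)
    ex <- extractPhosphenes(masks[sel], minArea = minArea,
                            smallTrialFraction = smallTrialFraction)
    res <- cbind(td[sel, , drop = FALSE], ex$summary[, -1, drop = FALSE])
    res$empty <- vapply(masks[sel], function(m) sum(m) == 0L, logical(1))
    res$.row <- sel
    out[[k]] <- res
  }
  res <- do.call(rbind, out)
  res <- res[order(res$.row), , drop = FALSE]
  res$.row <- NULL
  rownames(res) <- NULL
  res
}
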
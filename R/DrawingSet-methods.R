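#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a DrawingSet
#'
#' @param drawings list of binary matrices (values in \{0, 1\}); grayscale
#'   matrices can be binarized first with [binarizeMask()].
#' @param trialData data.frame or DataFrame with one row per drawing. Columns
#'   \code{participant}, \code{electrode1} and \code{amplitude} are required;
#'   \code{trial}, \code{electrode2} and \code{frequency} are filled with
#'   defaults (sequence, \code{NA}, 20 Hz) when absent.
#'
#' @return A [DrawingSet-class] object.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
#' ds <- drawingSet(list(m), data.frame(participant = "P1",
#'                                      electrode1 = "A1", amplitude = 2))
#' length(ds)
#' @export
drawingSet <- function(drawings, trialData) {
  td <- S4Vectors::DataFrame(trialData)
  if (is.null(td$trial)) td$trial <- seq_len(nrow(td))
  if (is.null(td$electrode2)) td$electrode2 <- NA_character_
  if (is.null(td$frequency)) td$frequency <- 20
  drawings <- lapply(drawings, function(d) {
    storage.mode(d) <- "integer"
    d
  })
  new("DrawingSet", drawings = drawings, trialData = td)
}

#' @describeIn drawingSet Number of drawings in the set.
#' @param x a \code{DrawingSet}.
#' @export
setMethod("length", "DrawingSet", function(x) length(x@drawings))

#' @rdname drawingSet
#' @export
setMethod("drawings", "DrawingSet", function(x) x@drawings)

#' @rdname drawingSet
#' @export
setMethod("trialData", "DrawingSet", function(x) x@trialData)

#' @describeIn drawingSet Subset trials, keeping drawings and metadata in step.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "DrawingSet", function(x, i, j, ..., drop = FALSE) {
  new("DrawingSet", drawings = x@drawings[i],
      trialData = x@trialData[i, , drop = FALSE])
})

setMethod("show", "DrawingSet", function(object) {
  td <- object@trialData
  dims <- if (length(object@drawings))
    paste(dim(object@drawings[[1]]), collapse = " x ") else "none"
  cat("DrawingSet with", length(object@drawings), "drawings (", dims,
      "px )\n")
  cat("  participants:", paste(unique(td$participant), collapse = ", "), "\n")
  cat("  paired trials:", sum(!is.na(td$electrode2)), "of", nrow(td), "\n")
})

#' Combine drawing sets
#'
#' @param x,... \code{DrawingSet} objects.
#' @return A single \code{DrawingSet} with the trials concatenated.
#' @export
setMethod("c", "DrawingSet", function(x, ...) {
  sets <- c(list(x), list(...))
  td <- do.call(rbind, lapply(sets, trialData))
  new("DrawingSet", drawings = do.call(c, lapply(sets, drawings)),
      trialData = td)
})
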
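#' @include DrawingSet-methods.R synthetic-data.R
NULL

#' Write / read a drawing set as PNG masks plus a trial-table CSV
#'
#' The on-disk interchange format: one binary PNG per trial under
#' \code{drawings/}, and \code{trials.csv} with columns \code{participant},
#' \code{trial}, \code{electrode_1}, \code{electrode_2},
#' \code{amplitude_x_threshold}, \code{frequency_hz}, \code{image_path}.
#'
#' @param ds a [DrawingSet-class].
#' @param dir output directory (created if needed).
#' @return \code{writeDrawingSet()} invisibly returns the trial-table path;
#'   \code{readDrawingSet()} returns a [DrawingSet-class].
#' @export
writeDrawingSet <- function(ds, dir) {
  stopifnot(is(ds, "DrawingSet"))
  dir.create(file.path(dir, "drawings"), recursive = TRUE,
             showWarnings = FALSE)
  td <- as.data.frame(trialData(ds))
  paths <- sprintf("drawings/trial_%05d.png", seq_len(length(ds)))
  for (i in seq_len(length(ds))) {
    m <- drawings(ds)[[i]]
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)),
                  file.path(dir, paths[i]))
  }
  out <- data.frame(participant = td$participant, trial = td$trial,
                    electrode_1 = td$electrode1,
                    electrode_2 = td$electrode2,
                    amplitude_x_threshold = td$amplitude,
                    frequency_hz = td$frequency,
                    image_path = paths)
  f <- file.path(dir, "trials.csv")
  write.csv(out, f, row.names = FALSE, na = "")
  invisible(f)
}

#' @rdname writeDrawingSet
#' @param trialCsv path to a trial-table CSV; image paths are resolved
#'   relative to its directory. PNGs are binarized at 0.5 on read.
#' @export
readDrawingSet <- function(trialCsv) {
  td <- read.csv(trialCsv, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "electrode_1", "amplitude_x_threshold",
            "frequency_hz", "image_path")
  miss <- setdiff(need, colnames(td))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  base <- dirname(trialCsv)
  masks <- lapply(td$image_path, function(p) {
    img <- png::readPNG(file.path(base, p))
    if (length(dim(img)) == 3) img <- img[, , 1]
    binarizeMask(img)
  })
  e2 <- if ("electrode_2" %in% colnames(td)) td$electrode_2 else NA
  e2[!is.na(e2) & e2 == ""] <- NA
  drawingSet(masks, data.frame(participant = td$participant,
                               trial = td$trial,
                               electrode1 = td$electrode_1,
                               electrode2 = e2,
                               amplitude = td$amplitude_x_threshold,
                               frequency = td$frequency_hz))
}

#' Write / read an implant placement configuration
#'
#' YAML with fields \code{rotation_deg}, \code{center_x_um},
#' \code{center_y_um}, \code{eye}.
#'
#' @param placement an [ImplantPlacement-class].
#' @param path file path.
#' @return \code{readPlacement()} reconstructs the [ImplantPlacement-class]
#'   via [placeImplant()].
#' @export
writePlacement <- function(placement, path) {
  stopifnot(is(placement, "ImplantPlacement"))
  yaml::write_yaml(list(rotation_deg = placement@rotation,
                        center_x_um = placement@center[1],
                        center_y_um = placement@center[2],
                        eye = placement@eye), path)
  invisible(path)
}

#' @rdname writePlacement
#' @export
readPlacement <- function(path) {
  y <- yaml::read_yaml(path)
  placeImplant(rotation = y$rotation_deg,
               center = c(y$center_x_um, y$center_y_um), eye = y$eye)
}

# Full on-disk export of a sampled dataset (drawings, trial table, truth,
# predictor tables, placements).
.writeDataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeDrawingSet(x$drawings, dir)
  write.csv(x$truth, file.path(dir, "truth.csv"), row.names = FALSE, na = "")
  write.csv(x$electrodeTable, file.path(dir, "electrodes.csv"),
            row.names = FALSE)
  if (!is.null(x$pairTable))
    write.csv(x$pairTable, file.path(dir, "pairs.csv"), row.names = FALSE)
  for (i in seq_along(x$cfg@participants))
    writePlacement(x$cfg@placements[[i]],
                   file.path(dir, paste0("placement_",
                                         x$cfg@participants[i], ".yaml")))
  invisible(dir)
}
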
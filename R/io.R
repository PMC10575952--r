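#' Read and write track tables as CSV
#'
#' The on-disk schema is one row per localization with columns `track_id`,
#' `frame`, `x_um`, `y_um` and, when present, `state_true` (simulation
#' ground truth) and `state` (HMM labels).
#'
#' @param tracks Track data.frame.
#' @param path CSV file path.
#' @return `read_tracks` returns the data.frame; `write_tracks` the path,
#'   invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path)
  stop_if_not(all(c("track_id", "frame", "x_um", "y_um") %in% names(tr)),
              "track CSV must have track_id, frame, x_um, y_um columns")
  tr
}

#' Read and write images / stacks as TIFF
#'
#' Float TIFF round trip for 2D images (matrix) and 3D stacks
#' (`[y, x, frame]`). The physical pixel size is carried in-memory as an
#' attribute and must be re-supplied when reading.
#'
#' TIFF stores samples in `[0, 1]`, so images are divided by `scale`
#' (default: their maximum) on write; pass the same `scale` on read to
#' recover absolute values. All analyses in this package depend only on
#' relative intensities (density maps are renormalized to the nuclear
#' mean), so the default round trip is sufficient in practice.
#'
#' @param img Matrix or 3D array.
#' @param path TIFF path.
#' @param scale Intensity divisor applied before writing / multiplier after
#'   reading.
#' @param pixel_size Pixel size, um, attached to the returned image.
#' @return `write_image_tiff` returns `scale` invisibly; `read_image_tiff`
#'   returns a matrix or 3D array.
#' @export
write_image_tiff <- function(img, path, scale = NULL) {
  if (is.null(scale)) scale <- max(img, 1e-12)
  img <- img / scale
  if (length(dim(img)) == 3) {
    frames <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(scale)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_size = NULL, scale = 1) {
  fr <- tiff::readTIFF(path, all = TRUE)
  out <- if (length(fr) == 1L) fr[[1]]
         else array(unlist(fr), dim = c(dim(fr[[1]]), length(fr)))
  out <- out * scale
  if (!is.null(pixel_size)) attr(out, "pixel_size") <- pixel_size
  out
}

#' Export a fitted HMM as JSON
#'
#' @param model A [fit_hmm()] model.
#' @param path JSON path.
#' @export
write_hmm_json <- function(model, path) {
  stopifnot(inherits(model, "diffhmm"))
  lst <- unclass(model)
  lst$A <- apply(model$A, 1, function(r) r, simplify = FALSE)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
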
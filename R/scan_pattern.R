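#' Triangular multifocal scan pattern
#'
#' Describes the equilateral triangular lattice of diffraction-limited
#' excitation spots used for multifocal structured illumination, and the
#' ordered list of integer pixel translations that scan it over the field.
#' The vertical period is `round(lattice_side * sqrt(3) / 2)` pixels and
#' alternate spot rows are offset horizontally by `round(lattice_side / 2)`,
#' so a full scan needs `lattice_side * row_period` frames — 224 for the
#' canonical side of 16 pixels — after which every pixel of the field has
#' been visited by a spot center exactly once.
#'
#' @param lattice_side Lattice side in (DMD) pixels, >= 1.
#' @return Object of class `scan_pattern`: `lattice_side`, `row_period`,
#'   `row_shift`, and `offsets` (n x 2 integer matrix of (dx, dy) shifts,
#'   enumerating the unit cell row-major).
#' @examples
#' nrow(build_scan_pattern(16)$offsets)  # 224
#' @export
build_scan_pattern <- function(lattice_side) {
  stop_if_not(length(lattice_side) == 1 && lattice_side >= 1 &&
                lattice_side == round(lattice_side),
              "lattice_side must be an integer >= 1")
  s <- as.integer(lattice_side)
  p <- max(1L, as.integer(round(s * sqrt(3) / 2)))
  offs <- as.matrix(expand.grid(dx = 0:(s - 1L), dy = 0:(p - 1L)))[, 1:2, drop = FALSE]
  structure(list(lattice_side = s, row_period = p,
                 row_shift = as.integer(round(s / 2)),
                 offsets = offs),
            class = "scan_pattern")
}

#' @export
print.scan_pattern <- function(x, ...) {
  cat(sprintf("Triangular scan pattern: side %d px, row period %d px, %d offsets\n",
              x$lattice_side, x$row_period, nrow(x$offsets)))
  invisible(x)
}

#' Spot centers of one scan frame
#'
#' Integer (0-based) pixel positions of all excitation spots inside a
#' `width` x `height` field when the lattice is translated by `offset`.
#'
#' @param pattern A [build_scan_pattern()] pattern.
#' @param offset Integer `(dx, dy)` translation.
#' @param width,height Field size in pixels.
#' @return Integer matrix with columns `x`, `y` (0-based pixel indices).
#' @export
spot_positions <- function(pattern, offset, width, height) {
  s <- pattern$lattice_side; p <- pattern$row_period; h <- pattern$row_shift
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  jj <- 0:((height - 1L - dy) %/% p)
  jj <- jj[jj * p + dy >= 0 & jj * p + dy <= height - 1L]
  out <- vector("list", length(jj))
  for (t in seq_along(jj)) {
    j <- jj[t]
    sy <- j * p + dy
    off <- (j %% 2L) * h + dx
    ii <- ceiling((0 - off) / s):((width - 1L - off) %/% s)
    sx <- ii * s + off
    sx <- sx[sx >= 0L & sx <= width - 1L]
    out[[t]] <- cbind(x = sx, y = rep(sy, length(sx)))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  res
}

#' Verify exhaustive single coverage of a scan pattern
#'
#' Counts, for every pixel of a `width` x `height` field, how many scan
#' frames place a spot center on it; a complete scan visits each pixel
#' exactly once.
#'
#' @inheritParams spot_positions
#' @return Integer matrix of per-pixel visit counts (rows = y, cols = x).
#' @export
coverage_counts <- function(pattern, width, height) {
  cnt <- matrix(0L, height, width)
  for (k in seq_len(nrow(pattern$offsets))) {
    sp <- spot_positions(pattern, pattern$offsets[k, ], width, height)
    if (nrow(sp)) {
      ij <- cbind(sp[, "y"] + 1L, sp[, "x"] + 1L)
      cnt[ij] <- cnt[ij] + 1L
    }
  }
  cnt
}
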
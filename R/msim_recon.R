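#' Reconstruct a super-resolved image by virtual pinholing and pixel
#' reassignment
#'
#' For every scan frame and every nominal excitation-spot position, camera
#' pixels within `pinhole_radius` of the spot are kept (virtual pinhole,
#' providing optical sectioning) and their intensity is reassigned halfway
#' toward the spot center onto a 2x upsampled grid (pixel reassignment,
#' sharpening the lateral PSF by up to sqrt(2)). The half-shifted target
#' `spot + (pixel - spot)/2` always falls exactly on an upsampled grid
#' point, so bilinear splatting reduces to direct deposition. The
#' accumulated image is normalized by per-pixel visitation counts weighted
#' by the mean transmission of each pinhole offset (estimated from the
#' stack itself), which flat-fields the digital pinhole: pixels a given
#' distance from the spot are systematically dimmer, and unweighted counts
#' would imprint that fall-off as a pixel-parity texture. Upsampled pixels
#' that no (spot, pinhole-offset) combination can reach (a parity subset
#' that depends on the pinhole radius) are filled by iterative
#' nearest-neighbour averaging, and the result is rescaled so the total
#' intensity equals the total post-pinhole input intensity.
#'
#' @param stack 3D array from [render_msim_stack()] (or a real TIFF stack),
#'   `[y, x, frame]`, one frame per scan offset.
#' @param pattern The [build_scan_pattern()] pattern used for the scan;
#'   `nrow(pattern$offsets)` must equal the stack depth.
#' @param pinhole_radius Virtual pinhole radius in camera pixels. A radius
#'   larger than half the lattice spacing mixes light from neighbouring
#'   spots (crosstalk) and triggers a warning.
#' @param upsample Upsampling factor of the output grid; only the canonical
#'   value 2 is supported.
#' @param pixel_size Camera pixel size, um; taken from the stack attribute
#'   when present.
#' @return Object of class `msim_recon`: `image` (2x-upsampled matrix),
#'   `counts` (visitation weights), `pixel_size` (um, of the upsampled
#'   grid), `pinhole_radius`, `pattern`, and `total_in` (post-pinhole photon
#'   total).
#' @export
reconstruct <- function(stack, pattern, pinhole_radius = 1.0, upsample = 2,
                        pixel_size = NULL) {
  stop_if_not(length(dim(stack)) == 3, "stack must be a 3D array")
  stop_if_not(inherits(pattern, "scan_pattern"), "pattern must be a scan_pattern")
  stop_if_not(upsample == 2, "only upsample = 2 is supported")
  nk <- dim(stack)[3]
  if (nk != nrow(pattern$offsets))
    stop("stack depth (", nk, ") does not match the number of scan offsets (",
         nrow(pattern$offsets), ")", call. = FALSE)
  if (pinhole_radius > pattern$lattice_side / 2)
    warning("pinhole radius exceeds half the lattice spacing: expect crosstalk")
  ps <- if (!is.null(pixel_size)) pixel_size else attr(stack, "pixel_size")
  H <- dim(stack)[1]; W <- dim(stack)[2]
  # integer pinhole offsets
  rmax <- floor(pinhole_radius)
  eg <- as.matrix(expand.grid(ex = -rmax:rmax, ey = -rmax:rmax))
  eg <- eg[eg[, 1]^2 + eg[, 2]^2 <= pinhole_radius^2, , drop = FALSE]

  # pass 1: mean transmission per pinhole offset (digital flat-field)
  ne <- nrow(eg)
  Tsum <- numeric(ne); Tn <- numeric(ne)
  vals <- vector("list", nk)  # cache kept values per frame
  for (k in seq_len(nk)) {
    sp <- spot_positions(pattern, pattern$offsets[k, ], W, H)
    if (!nrow(sp)) next
    fr <- stack[, , k]
    per_off <- vector("list", ne)
    for (e in seq_len(ne)) {
      px <- sp[, "x"] + eg[e, 1]; py <- sp[, "y"] + eg[e, 2]
      ok <- px >= 0L & px <= W - 1L & py >= 0L & py <= H - 1L
      if (!any(ok)) next
      v <- fr[cbind(py[ok] + 1L, px[ok] + 1L)]
      Tsum[e] <- Tsum[e] + sum(v); Tn[e] <- Tn[e] + length(v)
      per_off[[e]] <- list(ij = cbind(2L * sp[ok, "y"] + eg[e, 2] + 1L,
                                      2L * sp[ok, "x"] + eg[e, 1] + 1L),
                           v = v)
    }
    vals[[k]] <- per_off
  }
  Tbar <- ifelse(Tn > 0, Tsum / Tn, 0)
  if (max(Tbar) > 0) Tbar <- Tbar / max(Tbar) else Tbar[] <- 1
  Tbar[Tbar <= 0] <- .Machine$double.eps
  # pass 2: accumulate values and transmission-weighted visitation counts
  acc <- matrix(0, 2L * H, 2L * W)
  cnt <- matrix(0, 2L * H, 2L * W)
  total_in <- 0
  for (k in seq_len(nk)) {
    per_off <- vals[[k]]
    if (is.null(per_off)) next
    for (e in seq_len(ne)) {
      po <- per_off[[e]]
      if (is.null(po)) next
      total_in <- total_in + sum(po$v)
      acc[po$ij] <- acc[po$ij] + po$v
      cnt[po$ij] <- cnt[po$ij] + Tbar[e]
    }
  }
  img <- matrix(0, 2L * H, 2L * W)
  nz <- cnt > 0
  img[nz] <- acc[nz] / cnt[nz]
  # fill unreachable (parity-hole) pixels by neighbour averaging
  filled <- nz
  box <- matrix(1, 3, 3)
  for (pass in 1:8) {
    if (all(filled)) break
    wsum <- EBImage::filter2(img * filled, box, boundary = 0)
    nsum <- EBImage::filter2(filled * 1, box, boundary = 0)
    newly <- !filled & nsum > 0.5
    img[newly] <- wsum[newly] / nsum[newly]
    filled <- filled | newly
  }
  tot <- sum(img)
  if (tot > 0) img <- img * (sum(acc) / tot)
  structure(list(image = img, counts = cnt,
                 pixel_size = if (is.null(ps)) NA_real_ else ps / 2,
                 pinhole_radius = pinhole_radius, pattern = pattern,
                 total_in = total_in),
            class = "msim_recon")
}

#' @export
print.msim_recon <- function(x, ...) {
  cat(sprintf("mSIM reconstruction: %d x %d px (2x upsampled), pixel %.4g um\n",
              nrow(x$image), ncol(x$image), x$pixel_size))
  cat(sprintf("  pinhole radius %.2f camera px; photon total %.4g\n",
              x$pinhole_radius, sum(x$image)))
  invisible(x)
}

#' Flatten slowly varying illumination
#'
#' Divides an image by a heavily blurred version of itself (Gaussian SD
#' `blur_sigma_um`, default 2.16 um), removing the smooth fall-off of the
#' excitation pattern so that the result reflects local density relative to
#' its neighbourhood. Pixels where the blurred image is zero map to zero,
#' with a warning.
#'
#' @param image Matrix, or an `msim_recon` object.
#' @param pixel_size Pixel size, um (taken from `msim_recon` input).
#' @param blur_sigma_um Gaussian SD of the blur, um.
#' @return Matrix of the same size.
#' @export
flatten_illumination <- function(image, pixel_size = NULL, blur_sigma_um = 2.16) {
  if (inherits(image, "msim_recon")) {
    pixel_size <- image$pixel_size
    image <- image$image
  }
  stop_if_not(!is.null(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  stop_if_not(blur_sigma_um > 0, "blur_sigma_um must be > 0")
  bl <- gauss_blur(image, blur_sigma_um / pixel_size, boundary = "replicate")
  out <- matrix(0, nrow(image), ncol(image))
  nz <- bl > .Machine$double.eps * max(bl)
  if (!all(nz)) warning("blurred image has zeros; mapped to 0 in the ratio")
  out[nz] <- image[nz] / bl[nz]
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Fit point-source widths (FWHM)
#'
#' Fits an isotropic 2D Gaussian with constant offset in a square window
#' around each requested center and reports `FWHM = 2 sqrt(2 ln 2) * SD`.
#' A failed or degenerate fit (no signal, non-convergence, width beyond the
#' window) yields `ok = FALSE` and `NA` width rather than an error.
#'
#' @param image Matrix, or an `msim_recon` object (for which pixels never
#'   visited by the reassignment — interpolated, not measured — are
#'   excluded from the fit automatically).
#' @param centers n x 2 matrix of (x, y) centers, um.
#' @param pixel_size Pixel size, um (taken from attributes if present).
#' @param window_um Half-width of the fit window, um.
#' @param valid Optional logical matrix: fit only where TRUE.
#' @return data.frame with `x_um`, `y_um`, `sigma_um`, `fwhm_um`, `ok`.
#' @export
measure_fwhm <- function(image, centers, pixel_size = NULL, window_um = 0.6,
                         valid = NULL) {
  if (inherits(image, "msim_recon")) {
    pixel_size <- image$pixel_size
    if (is.null(valid)) valid <- image$counts > 0
    image <- image$image
  }
  if (is.null(pixel_size)) pixel_size <- attr(image, "pixel_size")
  stop_if_not(!is.null(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  centers <- matrix(centers, ncol = 2)
  H <- nrow(image); W <- ncol(image)
  hw <- max(3L, as.integer(round(window_um / pixel_size)))
  res <- data.frame(x_um = centers[, 1], y_um = centers[, 2],
                    sigma_um = NA_real_, fwhm_um = NA_real_, ok = FALSE)
  for (i in seq_len(nrow(centers))) {
    cx <- px_index(centers[i, 1], pixel_size)
    cy <- px_index(centers[i, 2], pixel_size)
    if (cx < 1 || cx > W || cy < 1 || cy > H) next
    jx <- max(1L, cx - hw):min(W, cx + hw)
    jy <- max(1L, cy - hw):min(H, cy + hw)
    win <- image[jy, jx, drop = FALSE]
    use <- if (is.null(valid)) rep(TRUE, length(win))
           else as.vector(valid[jy, jx, drop = FALSE])
    if (sum(use) < 7) next
    b0 <- min(win[use]); A0 <- max(win[use]) - b0
    if (!is.finite(A0) || A0 <= 0) next
    wx <- (jx - 1) * pixel_size; wy <- (jy - 1) * pixel_size
    Xg <- matrix(wx, length(jy), length(jx), byrow = TRUE)
    Yg <- matrix(wy, length(jy), length(jx))
    wpos <- pmax(win - b0, 0) * use
    x0 <- sum(Xg * wpos) / sum(wpos); y0 <- sum(Yg * wpos) / sum(wpos)
    s0 <- sqrt(sum(((Xg - x0)^2 + (Yg - y0)^2) * wpos) / (2 * sum(wpos)))
    s0 <- max(s0, pixel_size / 2)
    obj <- function(p) {
      mu <- p[4] * exp(-((Xg - p[1])^2 + (Yg - p[2])^2) / (2 * exp(2 * p[3]))) + p[5]
      sum(((mu - win)^2)[use])
    }
    fit <- try(stats::optim(c(x0, y0, log(s0), A0, b0), obj,
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    sig <- exp(fit$par[3])
    if (!is.finite(sig) || sig <= 0 || sig > hw * pixel_size ||
        fit$par[4] <= 0) next
    res$sigma_um[i] <- sig
    res$fwhm_um[i] <- 2 * sqrt(2 * log(2)) * sig
    res$ok[i] <- TRUE
  }
  res
}

#' Normalize a reconstructed image into a DNA-density map
#'
#' Divides by the mean intensity over the nuclear mask, so values above 1
#' mark chromatin denser than the nuclear average, and classifies masked
#' pixels into intensity quartiles. Scale-invariant: multiplying the input
#' by a constant leaves the map unchanged.
#'
#' @param recon `msim_recon` object or plain matrix.
#' @param mask Logical matrix (nucleus), same size as the image.
#' @param pixel_size Pixel size, um (taken from `msim_recon` input).
#' @return A [density_map()] object.
#' @export
normalize_density <- function(recon, mask, pixel_size = NULL) {
  if (inherits(recon, "msim_recon")) {
    pixel_size <- recon$pixel_size
    recon <- recon$image
  }
  if (is.null(pixel_size)) pixel_size <- attr(recon, "pixel_size")
  density_map(recon, mask, pixel_size)
}
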
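#' Render a multifocal-excitation frame stack from a phantom
#'
#' Simulates the image formation of multifocal structured illumination:
#' for each scan offset, a lattice of diffraction-limited excitation spots
#' (Gaussian of SD `psf_sigma_ex`) illuminates the phantom, and the emitted
#' light is blurred by the emission PSF (Gaussian of SD `psf_sigma_em`) and
#' scaled to `photons` expected photons per unit emitter intensity. The sum
#' of all frames approximates a uniformly illuminated widefield image up to
#' edge effects, because a full scan visits every pixel once.
#'
#' @param phantom A [make_phantom()] phantom, or a plain non-negative matrix
#'   (then `pixel_size` must be given).
#' @param pattern A [build_scan_pattern()] pattern.
#' @param psf_sigma_ex,psf_sigma_em Excitation / emission PSF SD, um.
#' @param photons Expected photon scale; 0 gives an all-zero stack.
#' @param poisson If TRUE, apply Poisson noise (seeded).
#' @param pixel_size Pixel size in um when `phantom` is a plain matrix.
#' @param seed Seed for the Poisson noise.
#' @return 3D array `[y, x, frame]` with one frame per scan offset, plus
#'   attributes `pixel_size` and `pattern`.
#' @export
render_msim_stack <- function(phantom, pattern, psf_sigma_ex = 0.15,
                              psf_sigma_em = 0.15, photons = 1000,
                              poisson = FALSE, pixel_size = NULL, seed = 1) {
  dens <- if (inherits(phantom, "nucleus_phantom")) phantom$density else phantom
  ps <- if (inherits(phantom, "nucleus_phantom")) phantom$pixel_size else pixel_size
  stop_if_not(!is.null(ps) && ps > 0, "pixel_size must be supplied and > 0")
  stop_if_not(inherits(pattern, "scan_pattern"), "pattern must be a scan_pattern")
  stop_if_not(psf_sigma_ex > 0 && psf_sigma_em > 0, "PSF sigmas must be > 0")
  stop_if_not(photons >= 0, "photons must be >= 0")
  H <- nrow(dens); W <- ncol(dens)
  stop_if_not(pattern$lattice_side <= W && pattern$row_period <= H,
              "pattern unit cell larger than the field")
  nk <- nrow(pattern$offsets)
  stack <- array(0, dim = c(H, W, nk))
  if (photons == 0) {
    attr(stack, "pixel_size") <- ps; attr(stack, "pattern") <- pattern
    return(stack)
  }
  sx_ex <- psf_sigma_ex / ps; sx_em <- psf_sigma_em / ps
  for (k in seq_len(nk)) {
    sp <- spot_positions(pattern, pattern$offsets[k, ], W, H)
    ex <- matrix(0, H, W)
    if (nrow(sp)) ex[cbind(sp[, "y"] + 1L, sp[, "x"] + 1L)] <- 1
    ex <- gauss_blur(ex, sx_ex)
    fr <- gauss_blur(dens * ex, sx_em) * photons
    fr[fr < 0] <- 0   # FFT round-off
    stack[, , k] <- fr
  }
  if (poisson) {
    stack[] <- with_seed(seed, stats::rpois(length(stack), lambda = stack))
  }
  attr(stack, "pixel_size") <- ps
  attr(stack, "pattern") <- pattern
  stack
}

#' Render a widefield image of a phantom
#'
#' Uniform illumination: the phantom convolved with the emission PSF and
#' scaled to `photons`. Linear in `photons`.
#'
#' @inheritParams render_msim_stack
#' @return Matrix with attribute `pixel_size`.
#' @export
render_widefield <- function(phantom, psf_sigma_em = 0.15, photons = 1000,
                             poisson = FALSE, pixel_size = NULL, seed = 1) {
  dens <- if (inherits(phantom, "nucleus_phantom")) phantom$density else phantom
  ps <- if (inherits(phantom, "nucleus_phantom")) phantom$pixel_size else pixel_size
  stop_if_not(!is.null(ps) && ps > 0, "pixel_size must be supplied and > 0")
  stop_if_not(psf_sigma_em > 0, "psf_sigma_em must be > 0")
  img <- gauss_blur(dens, psf_sigma_em / ps) * photons
  img[img < 0] <- 0
  if (poisson) img[] <- with_seed(seed, stats::rpois(length(img), lambda = img))
  attr(img, "pixel_size") <- ps
  img
}

#' Render a single-molecule movie from simulated tracks
#'
#' Places a Gaussian emitter at every localization of every track, frame by
#' frame, on a dark background — the synthetic counterpart of an SMT movie
#' for testing spot detection and linking.
#'
#' @param tracks Track table (`track_id`, `frame`, `x_um`, `y_um`).
#' @param size_px Field side in pixels.
#' @param pixel_size Pixel size, um.
#' @param psf_sigma Emitter PSF SD, um.
#' @param photons Peak-scale photons per molecule.
#' @param background Constant background level added to every pixel.
#' @param poisson If TRUE, Poisson noise (seeded).
#' @param seed Seed for the noise.
#' @return 3D array `[y, x, frame]` covering frames `0..max(frame)`, with
#'   attribute `pixel_size`.
#' @export
render_smt_movie <- function(tracks, size_px, pixel_size, psf_sigma = 0.15,
                             photons = 500, background = 0, poisson = FALSE,
                             seed = 1) {
  stop_if_not(size_px >= 8, "size_px must be >= 8")
  nfr <- max(tracks$frame) + 1L
  H <- W <- as.integer(size_px)
  mov <- array(background, dim = c(H, W, nfr))
  spx <- psf_sigma / pixel_size
  hw <- ceiling(4 * spx)
  for (f in seq_len(nfr) - 1L) {
    rows <- which(tracks$frame == f)
    img <- matrix(0, H, W)
    for (r in rows) {
      cx <- tracks$x_um[r] / pixel_size  # 0-based pixel coords
      cy <- tracks$y_um[r] / pixel_size
      jx <- max(1L, floor(cx) - hw + 1L):min(W, ceiling(cx) + hw + 1L)
      jy <- max(1L, floor(cy) - hw + 1L):min(H, ceiling(cy) + hw + 1L)
      if (!length(jx) || !length(jy)) next
      gx <- exp(-((jx - 1L - cx)^2) / (2 * spx^2))
      gy <- exp(-((jy - 1L - cy)^2) / (2 * spx^2))
      img[jy, jx] <- img[jy, jx] + photons * outer(gy, gx)
    }
    mov[, , f + 1L] <- mov[, , f + 1L] + img
  }
  if (poisson) mov[] <- with_seed(seed, stats::rpois(length(mov), lambda = mov))
  attr(mov, "pixel_size") <- pixel_size
  mov
}
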
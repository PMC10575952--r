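#' Synthetic nuclear DNA-density phantom
#'
#' Builds a 2D phantom of a cell nucleus: an elliptical nuclear mask holding
#' a smooth background plus isotropic chromatin-dense (CD) domains, separated
#' by a lower-density interchromatin compartment (IC). The density is
#' normalized so that its mean over the nuclear mask is exactly 1, the
#' reference frame used by all downstream density mapping.
#'
#' @param size_px Side of the square grid in pixels (>= 64).
#' @param pixel_size Pixel size in micrometres.
#' @param n_domains Number of chromatin-dense domains.
#' @param domain_radius Gaussian radius (SD) of each domain, micrometres.
#' @param contrast Amplitude of each domain relative to the unit background;
#'   `contrast = 0` yields a flat map.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#'
#' @return An object of class `nucleus_phantom` with elements `density`
#'   (matrix, rows = y, cols = x), `mask` (logical matrix), `pixel_size`,
#'   `cd_centers` (n x 2 matrix of domain centers, micrometres) and `seed`.
#' @examples
#' ph <- make_phantom(size_px = 128, pixel_size = 0.1, n_domains = 30,
#'                    domain_radius = 0.3, contrast = 2, seed = 1)
#' mean(ph$density[ph$mask])  # 1
#' @export
make_phantom <- function(size_px = 256, pixel_size = 0.1, n_domains = 40,
                         domain_radius = 0.3, contrast = 2, seed = 1) {
  stop_if_not(length(size_px) == 1 && size_px >= 64, "size_px must be >= 64")
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  stop_if_not(contrast >= 0, "contrast must be >= 0")
  stop_if_not(domain_radius > 0, "domain_radius must be > 0")
  stop_if_not(n_domains >= 0, "n_domains must be >= 0")

  n <- as.integer(size_px)
  # coordinates of pixel centers, micrometres (0-based integer pixel grid)
  xs <- (seq_len(n) - 1L) * pixel_size
  cx <- mean(xs); cy <- mean(xs)
  X <- matrix(xs, n, n, byrow = TRUE)   # column coordinate = x
  Y <- matrix(xs, n, n, byrow = FALSE)  # row coordinate = y
  ax <- 0.45 * (n - 1) * pixel_size     # semi-axes of the nuclear ellipse
  ay <- 0.35 * (n - 1) * pixel_size
  mask <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1

  density <- matrix(1, n, n)
  centers <- matrix(numeric(0), 0, 2)
  if (n_domains > 0 && contrast > 0) {
    # rejection-sample domain centers uniformly inside the (slightly eroded)
    # ellipse so domains stay within the nucleus
    centers <- with_seed(seed, {
      got <- 0L
      cc <- matrix(NA_real_, n_domains, 2)
      while (got < n_domains) {
        px <- stats::runif(1, cx - ax, cx + ax)
        py <- stats::runif(1, cy - ay, cy + ay)
        if (((px - cx) / (0.92 * ax))^2 + ((py - cy) / (0.92 * ay))^2 <= 1) {
          got <- got + 1L
          cc[got, ] <- c(px, py)
        }
      }
      cc
    })
    for (k in seq_len(n_domains)) {
      d2 <- (X - centers[k, 1])^2 + (Y - centers[k, 2])^2
      density <- density + contrast * exp(-d2 / (2 * domain_radius^2))
    }
  }
  density[!mask] <- 0
  density <- density / mean(density[mask])

  structure(list(density = density, mask = mask, pixel_size = pixel_size,
                 cd_centers = centers, seed = seed),
            class = "nucleus_phantom")
}

#' @export
print.nucleus_phantom <- function(x, ...) {
  cat("Nuclear density phantom\n")
  cat(sprintf("  grid: %d x %d px, pixel size %.3f um\n",
              nrow(x$density), ncol(x$density), x$pixel_size))
  cat(sprintf("  nuclear pixels: %d; CD domains: %d\n",
              sum(x$mask), nrow(x$cd_centers)))
  cat(sprintf("  density over mask: mean %.4f, max %.3f\n",
              mean(x$density[x$mask]), max(x$density)))
  invisible(x)
}

#' @export
plot.nucleus_phantom <- function(x, ...) {
  graphics::image(t(x$density), asp = 1, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = "DNA-density phantom", ...)
  invisible(x)
}
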
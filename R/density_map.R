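#' Normalized DNA-density map with quartile classes
#'
#' Wraps a nuclear image into the reference frame used for single-molecule
#' mapping: intensities divided by their mean over the nuclear mask (so the
#' nuclear mean is exactly 1) and masked pixels ranked into four density
#' quartiles of equal pixel count (class 1 = most DNA-poor quarter, class
#' 4 = densest). Ties are broken by stable pixel order, so the partition is
#' exact up to +/- a few pixels.
#'
#' @param image Non-negative matrix (rows = y, cols = x).
#' @param mask Logical matrix of the nucleus, same size.
#' @param pixel_size Pixel size, um.
#' @return Object of class `density_map`: `norm_intensity`, `mask`,
#'   `pixel_size`, `quartile_labels` (integer matrix, NA outside the mask).
#' @export
density_map <- function(image, mask, pixel_size) {
  stop_if_not(is.matrix(image) && is.matrix(mask), "image and mask must be matrices")
  stop_if_not(all(dim(image) == dim(mask)), "image/mask size mismatch")
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  mask <- mask & is.finite(image)
  stop_if_not(any(mask), "mask is empty")
  mu <- mean(image[mask])
  stop_if_not(mu > 0, "mean intensity over the mask must be > 0")
  norm <- image / mu
  norm[!mask] <- NA_real_
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  idx <- which(mask)
  rk <- rank(norm[idx], ties.method = "first")
  q[idx] <- as.integer(ceiling(rk / length(idx) * 4))
  structure(list(norm_intensity = norm, mask = mask, pixel_size = pixel_size,
                 quartile_labels = q),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("DNA-density map: %d x %d px (%.4g um/px), %d nuclear pixels\n",
              nrow(x$norm_intensity), ncol(x$norm_intensity), x$pixel_size,
              sum(x$mask)))
  cat(sprintf("  normalized intensity: mean %.4f, range [%.3f, %.3f]\n",
              mean(x$norm_intensity[x$mask]), min(x$norm_intensity[x$mask]),
              max(x$norm_intensity[x$mask])))
  invisible(x)
}

#' @export
plot.density_map <- function(x, what = c("density", "quartiles"), ...) {
  what <- match.arg(what)
  img <- if (what == "density") x$norm_intensity else x$quartile_labels
  graphics::image(t(img), asp = 1, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = paste("DNA", what), ...)
  invisible(x)
}

#' Instantaneous diffusion coefficient of a displacement
#'
#' `D_inst = r^2 / (4 dt)` — the single-step analogue of the 2D Brownian
#' relation between mean squared displacement and D.
#'
#' @param r Displacement length(s), um (>= 0).
#' @param dt Frame interval, s.
#' @return D_inst in um^2/s.
#' @examples
#' instantaneous_D(0.2, 0.01)  # 1
#' @export
instantaneous_D <- function(r, dt) {
  stop_if_not(all(r >= 0), "r must be >= 0")
  stop_if_not(dt > 0, "dt must be > 0")
  r^2 / (4 * dt)
}

#' Density quartile at molecule positions
#'
#' Nearest-pixel lookup of the quartile class; positions outside the
#' nuclear mask (or the grid) are dropped and their count reported in the
#' `n_dropped` attribute.
#'
#' @param positions n x 2 matrix or data.frame of (x, y) positions, um
#'   (columns `x_um`, `y_um` accepted).
#' @param map A [density_map()].
#' @return Integer vector of quartile labels (1-4) for retained positions,
#'   with attributes `kept` (row indices) and `n_dropped`.
#' @export
density_class_at <- function(positions, map) {
  stopifnot(inherits(map, "density_map"))
  xy <- as_xy(positions)
  ix <- px_index(xy[, 1], map$pixel_size)
  iy <- px_index(xy[, 2], map$pixel_size)
  ok <- in_grid(ix, iy, dim(map$mask))
  ok[ok] <- map$mask[cbind(iy[ok], ix[ok])]
  lab <- map$quartile_labels[cbind(iy[ok], ix[ok])]
  structure(lab, kept = which(ok), n_dropped = sum(!ok))
}

as_xy <- function(positions) {
  if (is.data.frame(positions)) {
    if (all(c("x_um", "y_um") %in% names(positions)))
      return(cbind(positions$x_um, positions$y_um))
    return(as.matrix(positions[, 1:2]))
  }
  matrix(positions, ncol = 2)
}

#' Mobility-by-density heatmap
#'
#' Frequency with which displacements of a given instantaneous diffusion
#' coefficient start in each of the four DNA-density classes. Rows are
#' log-spaced D_inst bins, columns the four classes; each retained row is
#' normalized to sum to 1, empty rows are flagged in the `empty_rows`
#' attribute.
#'
#' @param displacements Per-displacement table ([track_displacements()]):
#'   start position `x_um`, `y_um` and jump `r_um`.
#' @param map A [density_map()].
#' @param dt Frame interval, s.
#' @param dinst_breaks Bin edges for D_inst, um^2/s (log-spaced default).
#' @return Matrix (bins x 4) of class frequencies with attributes
#'   `dinst_breaks`, `empty_rows`, `n_used`, `n_dropped`.
#' @export
dinst_density_heatmap <- function(displacements, map, dt,
                                  dinst_breaks = NULL) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(dinst_breaks))
    dinst_breaks <- c(0, 10^seq(-2, 1.5, length.out = 11), Inf)
  lab <- density_class_at(displacements, map)
  kept <- attr(lab, "kept")
  dinst <- instantaneous_D(displacements$r_um[kept], dt)
  bin <- findInterval(dinst, dinst_breaks, rightmost.closed = TRUE)
  nb <- length(dinst_breaks) - 1L
  m <- matrix(0, nb, 4)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (any(sel)) m[b, ] <- tabulate(lab[sel], 4) / sum(sel)
  }
  empty <- rowSums(m) == 0
  structure(m, dinst_breaks = dinst_breaks, empty_rows = which(empty),
            n_used = length(kept), n_dropped = attr(lab, "n_dropped"))
}

#' Density-class enrichment of molecule positions
#'
#' Observed class frequencies against the 25% uniform baseline, plus a
#' scalar enrichment score: frequency in the densest class minus frequency
#' in the most DNA-poor class (0 for a uniformly exploring tracer,
#' positive for chromatin-enriched factors).
#'
#' @inheritParams density_class_at
#' @return List: `freq` (length 4), `delta` (freq - 0.25), `score`,
#'   `n_used`, `n_dropped`.
#' @export
enrichment_profile <- function(positions, map) {
  lab <- density_class_at(positions, map)
  stop_if_not(length(lab) > 0, "no positions inside the nuclear mask")
  freq <- tabulate(lab, 4) / length(lab)
  list(freq = freq, delta = freq - 0.25, score = freq[4] - freq[1],
       n_used = length(lab), n_dropped = attr(lab, "n_dropped"))
}

#' Correlation between density enrichment and bound fraction across factors
#'
#' Pearson correlation, across nuclear factors, between the enrichment
#' score in DNA-dense regions and the fitted bound fraction.
#'
#' @param per_factor_table data.frame with columns `enrichment` and
#'   `bound_fraction` (one row per factor).
#' @return List with `r`, `p` (NA with a flag for < 3 factors), `n`.
#' @export
correlate_enrichment_vs_boundfraction <- function(per_factor_table) {
  stopifnot(all(c("enrichment", "bound_fraction") %in% names(per_factor_table)))
  n <- nrow(per_factor_table)
  stop_if_not(n >= 2, "need at least 2 factors")
  r <- stats::cor(per_factor_table$enrichment, per_factor_table$bound_fraction)
  if (n < 3) {
    out <- list(r = r, p = NA_real_, n = n)
    attr(out, "flag") <- "p-value undefined for fewer than 3 factors"
    return(out)
  }
  ct <- stats::cor.test(per_factor_table$enrichment,
                        per_factor_table$bound_fraction)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Radial DNA-density profile around classified molecules
#'
#' For each diffusion state, crops the normalized density map in a square
#' window (default 1 um x 1 um) around every molecule (windows reaching
#' beyond the nuclear mask are dropped), averages the windows, and reduces
#' the average to a rotational profile: mean normalized density versus
#' distance from the molecule, sampled at pixel resolution on a 2x
#' oversampled window grid. The profile of a uniform map is 1 at all
#' radii. A two-sided one-sample t-test asks whether the density at the
#' molecule position (r = 0) differs from the nuclear average of 1.
#'
#' @param positions_by_state Named list of position sets (n x 2 matrices or
#'   data.frames with `x_um`, `y_um`), one per state.
#' @param map A [density_map()].
#' @param window_um Window side length, um.
#' @return Object of class `radial_profile_set`: list per state with
#'   `radii_um`, `mean`, `sem`, `n_molecules`, `center_t_p` plus the mean
#'   window image.
#' @export
radial_density_profile <- function(positions_by_state, map, window_um = 1.0) {
  stopifnot(inherits(map, "density_map"))
  stop_if_not(window_um > 0, "window_um must be > 0")
  ps <- map$pixel_size
  h <- window_um / 2
  step <- ps / 2                       # 2x oversampled window grid
  offs <- seq(-h, h, by = step)
  OX <- matrix(offs, length(offs), length(offs), byrow = TRUE)
  OY <- t(OX)
  rad <- sqrt(OX^2 + OY^2)
  radii <- seq(0, floor(h / ps)) * ps
  ann <- lapply(radii, function(r0) which(abs(rad - r0) <= ps / 2 & rad <= h + ps / 2))
  img <- map$norm_intensity
  msk <- map$mask
  if (is.null(names(positions_by_state)))
    names(positions_by_state) <- paste0("state", seq_along(positions_by_state))
  result <- list()
  for (nm in names(positions_by_state)) {
    xy <- as_xy(positions_by_state[[nm]])
    n <- nrow(xy)
    acc <- matrix(0, length(offs), length(offs))
    prof_acc <- matrix(NA_real_, n, length(radii))
    used <- 0L
    for (i in seq_len(n)) {
      ix <- px_index(xy[i, 1] + OX, ps)
      iy <- px_index(xy[i, 2] + OY, ps)
      if (any(!in_grid(ix, iy, dim(msk)))) next
      vals <- img[cbind(as.vector(iy), as.vector(ix))]
      if (any(is.na(vals))) next      # window touches outside-mask pixels
      used <- used + 1L
      W <- matrix(vals, length(offs), length(offs))
      acc <- acc + W
      prof_acc[used, ] <- vapply(ann, function(ii) mean(W[ii]), numeric(1))
    }
    if (used == 0L) {
      result[[nm]] <- list(radii_um = radii, mean = rep(NA_real_, length(radii)),
                           sem = rep(NA_real_, length(radii)), n_molecules = 0L,
                           center_t_p = NA_real_, window = NULL)
      next
    }
    prof <- prof_acc[seq_len(used), , drop = FALSE]
    mu <- colMeans(prof)
    sem <- apply(prof, 2, stats::sd) / sqrt(used)
    tp <- if (used >= 2 && stats::sd(prof[, 1]) > 0)
      stats::t.test(prof[, 1], mu = 1)$p.value else NA_real_
    result[[nm]] <- list(radii_um = radii, mean = mu, sem = sem,
                         n_molecules = used, center_t_p = tp,
                         window = acc / used)
  }
  structure(result, class = "radial_profile_set", window_um = window_um)
}

#' @export
print.radial_profile_set <- function(x, ...) {
  cat("Radial DNA-density profiles\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    cat(sprintf("  %s: n = %d, density at molecule = %.3f (t-test vs 1: p = %.3g)\n",
                nm, p$n_molecules, p$mean[1], p$center_t_p))
  }
  invisible(x)
}

#' @export
plot.radial_profile_set <- function(x, ...) {
  cols <- c("#1f78b4", "#33a02c", "#e31a1c", "#ff7f00")
  rng <- range(unlist(lapply(x, function(p) c(p$mean - p$sem, p$mean + p$sem))),
               1, na.rm = TRUE)
  first <- TRUE
  for (i in seq_along(x)) {
    p <- x[[i]]
    if (!p$n_molecules) next
    if (first) {
      graphics::plot(p$radii_um, p$mean, type = "b", col = cols[i], pch = 16,
                     ylim = rng, xlab = "distance from molecule (um)",
                     ylab = "normalized DNA density", ...)
      first <- FALSE
    } else graphics::lines(p$radii_um, p$mean, type = "b", col = cols[i], pch = 16)
  }
  graphics::abline(h = 1, lty = 2, col = "grey50")
  graphics::legend("topright", legend = names(x), col = cols[seq_along(x)],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Pair cross-correlation between bound centroids and diffusing molecules
#'
#' Histogram of the distances from each bound-segment centroid to every
#' diffusing-molecule position, normalized by the same histogram computed
#' against uniform random positions inside the nuclear mask (averaged over
#' `n_rand` randomizations with matched point count). Values above 1 at
#' short distance mean diffusing molecules cluster around binding sites.
#'
#' @param bound_centroids n x 2 positions of bound-segment centroids, um.
#' @param diffusing_positions m x 2 positions of diffusing molecules, um.
#' @param mask Logical nuclear mask (or a [density_map()]).
#' @param pixel_size Pixel size of the mask, um (unused if `mask` is a
#'   density_map).
#' @param breaks Distance bin edges, um.
#' @param n_rand Number of uniform randomizations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `pair_correlation`: data.frame `bin_center_um`,
#'   `g` (observed / random), `g_observed`, `g_random`, `n_pairs`.
#' @export
pair_cross_correlation <- function(bound_centroids, diffusing_positions, mask,
                                   pixel_size = NULL,
                                   breaks = seq(0, 2, by = 0.1),
                                   n_rand = 20, seed = 1) {
  if (inherits(mask, "density_map")) {
    pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  stop_if_not(!is.null(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  bc <- as_xy(bound_centroids)
  dp <- as_xy(diffusing_positions)
  stop_if_not(nrow(bc) > 0, "empty bound-centroid set")
  stop_if_not(nrow(dp) > 0, "empty diffusing set")
  cross_hist <- function(pts) {
    d <- sqrt(outer(bc[, 1], pts[, 1], "-")^2 + outer(bc[, 2], pts[, 2], "-")^2)
    graphics::hist(d[d <= max(breaks)], breaks = breaks, plot = FALSE)$counts
  }
  obs <- cross_hist(dp)
  idx <- which(mask)
  rand_acc <- with_seed(seed, {
    acc <- numeric(length(breaks) - 1L)
    for (k in seq_len(n_rand)) {
      pick <- idx[sample.int(length(idx), nrow(dp), replace = TRUE)]
      ry <- ((pick - 1L) %% nrow(mask)) * pixel_size +
        stats::runif(length(pick), -pixel_size / 2, pixel_size / 2)
      rx <- ((pick - 1L) %/% nrow(mask)) * pixel_size +
        stats::runif(length(pick), -pixel_size / 2, pixel_size / 2)
      acc <- acc + cross_hist(cbind(rx, ry))
    }
    acc / n_rand
  })
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  g <- ifelse(rand_acc > 0, obs / rand_acc, NA_real_)
  structure(data.frame(bin_center_um = centers, g = g, g_observed = obs,
                       g_random = rand_acc, n_pairs = sum(obs)),
            class = c("pair_correlation", "data.frame"))
}

#' Shift tracks into the density-map coordinate frame
#'
#' Constant translation compensating a (chromatic) registration offset
#' between the tracking and density channels; identity by default.
#'
#' @param tracks Track table with `x_um`, `y_um`.
#' @param offset_um Length-2 numeric `(dx, dy)`, um; must be finite.
#' @return The track table with shifted coordinates.
#' @export
register_tracks_to_map <- function(tracks, offset_um = c(0, 0)) {
  stop_if_not(length(offset_um) == 2 && all(is.finite(offset_um)),
              "offset_um must be two finite numbers")
  tracks$x_um <- tracks$x_um + offset_um[1]
  tracks$y_um <- tracks$y_um + offset_um[2]
  tracks
}
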
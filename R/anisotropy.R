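#' Angles between consecutive displacements
#'
#' For every interior localization of every diffusing segment, computes the
#' angle between the incoming and outgoing displacement vectors, folded to
#' `[0, 180]` degrees (displacement statistics are mirror-symmetric):
#' 0 deg = forward continuation, 180 deg = full reversal. Each angle
#' carries the lengths of its two jumps; angles where either jump has zero
#' length are dropped (direction undefined), as are angles where either
#' jump is below `min_jump_um` when set (localization noise dominates the
#' direction of very short jumps).
#'
#' @param segments Track table of diffusing segments (>= 3 localizations
#'   per track to contribute).
#' @param min_jump_um Optional minimum jump length applied to both jumps,
#'   um; `0` (default) applies no filter.
#' @return Object of class `angle_set`: data.frame with `theta_deg`,
#'   `r1_um`, `r2_um`, `track_id`.
#' @export
compute_angles <- function(segments, min_jump_um = 0) {
  stop_if_not(min_jump_um >= 0, "min_jump_um must be >= 0")
  empty <- data.frame(theta_deg = numeric(), r1_um = numeric(),
                      r2_um = numeric(), track_id = integer())
  if (nrow(segments) == 0L) return(structure(empty, class = c("angle_set", "data.frame")))
  segments <- segments[order(segments$track_id, segments$frame), ]
  out <- lapply(split(segments, segments$track_id), function(d) {
    L <- nrow(d)
    if (L < 3L) return(NULL)
    dx <- diff(d$x_um); dy <- diff(d$y_um)
    r <- sqrt(dx^2 + dy^2)
    i <- seq_len(L - 2L)
    dot <- dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]
    den <- r[i] * r[i + 1L]
    ok <- den > 0 & r[i] >= min_jump_um & r[i + 1L] >= min_jump_um
    if (!any(ok)) return(NULL)
    theta <- acos(pmin(pmax(dot[ok] / den[ok], -1), 1)) * 180 / pi
    data.frame(theta_deg = theta, r1_um = r[i][ok], r2_um = r[i + 1L][ok],
               track_id = d$track_id[1L])
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty
  rownames(res) <- NULL
  structure(res, class = c("angle_set", "data.frame"))
}

#' Fold-anisotropy metric f180/0
#'
#' Ratio of the probability of a backward step (angle within 30 degrees of
#' 180) to the probability of a forward step (angle within 30 degrees of
#' 0); on folded angles the windows are `[150, 180]` and `[0, 30]`,
#' inclusive. Equals 1 for isotropic Brownian motion; values above 1
#' indicate compact (rebinding/trapped) exploration.
#'
#' @param angles An [compute_angles()] `angle_set`, or a numeric vector of
#'   folded angles in degrees.
#' @return Scalar ratio; `NA` with attribute `flag` when the forward window
#'   is empty.
#' @export
f180_over_0 <- function(angles) {
  th <- if (is.data.frame(angles)) angles$theta_deg else angles
  back <- sum(th >= 150 & th <= 180)
  fwd <- sum(th >= 0 & th <= 30)
  if (fwd == 0L)
    return(structure(NA_real_, flag = "empty forward window"))
  back / fwd
}

#' Subsampling estimate of a statistic's standard deviation
#'
#' Recomputes `statistic_fn` on `n_rep` random subsamples (without
#' replacement) of a fraction `frac` of the data and returns the SD across
#' replicates — the error model used for anisotropy profiles (100
#' subsamples of 50% of the data).
#'
#' @param statistic_fn Function of a data subset returning a scalar.
#' @param data Vector or data.frame (subsampled by row).
#' @param n_rep Number of replicates (>= 2).
#' @param frac Subsample fraction in (0, 1].
#' @param seed Integer seed.
#' @return SD over replicates (NA replicates dropped).
#' @export
bootstrap_sd <- function(statistic_fn, data, n_rep = 100, frac = 0.5, seed = 1) {
  stop_if_not(n_rep >= 2, "n_rep must be >= 2")
  stop_if_not(frac > 0 && frac <= 1, "frac must be in (0, 1]")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stop_if_not(n >= 2, "need at least 2 observations")
  m <- max(1L, floor(frac * n))
  vals <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
    idx <- sample.int(n, m)
    sub <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
    as.numeric(statistic_fn(sub))
  }, numeric(1)))
  stats::sd(vals[is.finite(vals)])
}

#' Fold-anisotropy versus distance run
#'
#' Assigns each angle a spatial scale — the mean of its two jump lengths —
#' and computes f180/0 with a subsampling SD in log-spaced distance bins,
#' tracing how exploration changes from compact (backward-biased, ratio
#' above 1) at short scales to free at long scales.
#'
#' @param angle_set An [compute_angles()] `angle_set`.
#' @param n_bins Number of log-spaced bins.
#' @param range_um Distance range, um (default 0.05 to the largest scale
#'   present).
#' @param min_count Bins with fewer angles are flagged (`ok = FALSE`).
#' @param n_rep,frac,seed Passed to [bootstrap_sd()].
#' @return Object of class `aniso_profile`: data.frame with
#'   `bin_center_um`, `f180_0`, `sd`, `n`, `ok`.
#' @export
anisotropy_vs_distance <- function(angle_set, n_bins = 8, range_um = NULL,
                                   min_count = 200, n_rep = 100, frac = 0.5,
                                   seed = 1) {
  stop_if_not(nrow(angle_set) > 0, "no angles")
  dist <- (angle_set$r1_um + angle_set$r2_um) / 2
  if (is.null(range_um)) range_um <- c(0.05, max(dist))
  stop_if_not(range_um[2] > range_um[1] && range_um[1] > 0,
              "invalid distance range")
  edges <- exp(seq(log(range_um[1]), log(range_um[2]), length.out = n_bins + 1))
  bin <- findInterval(dist, edges, rightmost.closed = TRUE)
  out <- data.frame(bin_center_um = sqrt(edges[-length(edges)] * edges[-1]),
                    f180_0 = NA_real_, sd = NA_real_,
                    n = 0L, ok = FALSE)
  for (b in seq_len(n_bins)) {
    th <- angle_set$theta_deg[bin == b]
    out$n[b] <- length(th)
    if (!length(th)) next
    v <- f180_over_0(th)
    out$f180_0[b] <- as.numeric(v)
    if (length(th) >= 4)
      out$sd[b] <- bootstrap_sd(f180_over_0, th, n_rep = n_rep, frac = frac,
                                seed = seed + b)
    out$ok[b] <- is.finite(out$f180_0[b]) && length(th) >= min_count
  }
  structure(out, class = c("aniso_profile", "data.frame"))
}

#' @export
plot.aniso_profile <- function(x, ...) {
  graphics::plot(x$bin_center_um, x$f180_0, log = "x", type = "b", pch = 16,
                 xlab = "distance run (um)", ylab = expression(f[180 / 0]),
                 main = "Diffusional anisotropy", ...)
  ok <- is.finite(x$sd)
  graphics::arrows(x$bin_center_um[ok], x$f180_0[ok] - x$sd[ok],
                   x$bin_center_um[ok], x$f180_0[ok] + x$sd[ok],
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
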
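#' Simulate single-molecule trajectories on a density phantom
#'
#' Propagates `preset$n_tracks` molecules through a hidden Markov chain of
#' diffusion states on the phantom. Per frame each molecule first updates its
#' hidden state (transition probabilities into each state k are multiplied by
#' the local normalized density raised to `density_coupling[k]`, then
#' renormalized), then takes an isotropic 2D Gaussian step with per-axis SD
#' `sqrt(2 * D_true * dt)` plus an independent 1D axial step; the track ends
#' when the molecule leaves the detection slice (`|z| > dz`; re-entry is not
#' modelled) or at the end of the observation window. Recorded positions
#' carry Gaussian localization noise of SD `loc_sigma`. Initial axial
#' positions are uniform in (-dz, dz), lateral positions uniform over the
#' nuclear mask.
#'
#' The returned table has one row per localization. `state_true` on each row
#' is the hidden state governing the displacement that starts at that row
#' (the final row of a track repeats the last value), so the ground-truth
#' label of displacement j of a track is `state_true` of its j-th row.
#' States are coded 1..K in order of increasing D (for three states:
#' 1 = bound, 2 = slow, 3 = fast).
#'
#' @param phantom A [make_phantom()] phantom (normalized density + mask).
#' @param preset A [sim_preset()].
#' @return A data.frame with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   `state_true`. Tracks with fewer than 2 localizations are dropped.
#' @export
simulate_tracks <- function(phantom, preset) {
  stopifnot(inherits(phantom, "nucleus_phantom"), inherits(preset, "sim_preset"))
  stop_if_not(any(phantom$mask), "phantom mask is empty")
  K <- length(preset$D)
  dt <- preset$dt
  D_true <- pmax(preset$D - preset$loc_sigma^2 / dt, 0)
  step_sd <- sqrt(2 * D_true * dt)
  ps <- phantom$pixel_size
  dens <- phantom$density
  mask <- phantom$mask
  n <- preset$n_tracks
  nf <- preset$n_frames
  coup <- preset$density_coupling

  with_seed(preset$seed, {
    # initial lateral positions: uniform over masked pixels + in-pixel jitter
    idx <- which(mask)
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    iy <- (pick - 1L) %% nrow(mask) + 1L
    ix <- (pick - 1L) %/% nrow(mask) + 1L
    x <- (ix - 1L) * ps + stats::runif(n, -ps / 2, ps / 2)
    y <- (iy - 1L) * ps + stats::runif(n, -ps / 2, ps / 2)
    z <- stats::runif(n, -preset$dz, preset$dz)

    local_density <- function(x, y) {
      jx <- px_index(x, ps); jy <- px_index(y, ps)
      ok <- in_grid(jx, jy, dim(mask))
      d <- rep(1, length(x))
      sel <- ok
      sel[ok] <- mask[cbind(jy[ok], jx[ok])]
      d[sel] <- dens[cbind(jy[sel], jx[sel])]
      d
    }
    biased_sample <- function(P, dloc) {
      # P: n_active x K base probabilities; bias column k by dloc^coup[k]
      if (any(coup != 0)) {
        for (k in seq_len(K)) if (coup[k] != 0) P[, k] <- P[, k] * dloc^coup[k]
        P <- row_normalize(P)
      }
      cp <- P
      for (k in seq_len(K)[-1L]) cp[, k] <- cp[, k - 1L] + P[, k]
      u <- stats::runif(nrow(P)) * cp[, K]  # guard against rounding of row sums
      if (K == 1L) rep(1L, nrow(P))
      else 1L + rowSums(u > cp[, -K, drop = FALSE])
    }

    # initial state, density-biased like a transition from the stationary mix
    s <- biased_sample(matrix(preset$f, n, K, byrow = TRUE), local_density(x, y))

    X <- matrix(NA_real_, n, nf + 1L)
    Y <- matrix(NA_real_, n, nf + 1L)
    S <- matrix(NA_integer_, n, nf)   # state governing step t -> t+1
    X[, 1L] <- x + stats::rnorm(n, sd = preset$loc_sigma)
    Y[, 1L] <- y + stats::rnorm(n, sd = preset$loc_sigma)
    alive <- rep(TRUE, n)

    for (t in seq_len(nf)) {
      na <- sum(alive)
      if (na == 0L) break
      ai <- which(alive)
      s[ai] <- biased_sample(preset$A[s[ai], , drop = FALSE],
                             local_density(x[ai], y[ai]))
      sd_t <- step_sd[s[ai]]
      x[ai] <- x[ai] + stats::rnorm(na, sd = sd_t)
      y[ai] <- y[ai] + stats::rnorm(na, sd = sd_t)
      z[ai] <- z[ai] + stats::rnorm(na, sd = sd_t)
      S[ai, t] <- s[ai]
      escm <- abs(z[ai]) > preset$dz
      alive[ai[escm]] <- FALSE
      srv <- ai[!escm]
      X[srv, t + 1L] <- x[srv] + stats::rnorm(length(srv), sd = preset$loc_sigma)
      Y[srv, t + 1L] <- y[srv] + stats::rnorm(length(srv), sd = preset$loc_sigma)
    }

    len <- rowSums(!is.na(X))           # localizations per molecule
    keep <- which(len >= 2L)
    out <- vector("list", length(keep))
    for (i in seq_along(keep)) {
      m <- keep[i]
      L <- len[m]
      st <- S[m, seq_len(L - 1L)]
      out[[i]] <- data.frame(track_id = i,
                             frame = seq_len(L) - 1L,
                             x_um = X[m, seq_len(L)],
                             y_um = Y[m, seq_len(L)],
                             state_true = c(st, st[L - 1L]))
    }
    do.call(rbind, out)
  })
}

#' Per-displacement table of a track set
#'
#' Expands a track table (one row per localization, contiguous frames) into
#' one row per frame-to-frame displacement, carrying the start position, the
#' jump length and any state columns present (`state_true`, `state`), taken
#' at the start row of the displacement.
#'
#' @param tracks Track data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @return data.frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (start of the displacement), `dx_um`, `dy_um`, `r_um` and any state
#'   columns.
#' @export
track_displacements <- function(tracks) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  if (nrow(tracks) == 0L)
    return(data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
                      y_um = numeric(), dx_um = numeric(), dy_um = numeric(),
                      r_um = numeric()))
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  same <- c(tracks$track_id[-1] == tracks$track_id[-nrow(tracks)], FALSE)
  i0 <- which(same)
  out <- tracks[i0, c("track_id", "frame", "x_um", "y_um"), drop = FALSE]
  out$dx_um <- tracks$x_um[i0 + 1L] - tracks$x_um[i0]
  out$dy_um <- tracks$y_um[i0 + 1L] - tracks$y_um[i0]
  out$r_um <- sqrt(out$dx_um^2 + out$dy_um^2)
  for (col in intersect(c("state_true", "state"), names(tracks)))
    out[[col]] <- tracks[[col]][i0]
  rownames(out) <- NULL
  out
}
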
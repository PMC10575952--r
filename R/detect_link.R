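#' Probability that a Brownian step exceeds the linking radius
#'
#' For a molecule diffusing with coefficient `D`, the probability of moving
#' farther than `r_max` in one frame interval is `exp(-r_max^2 / (4 D dt))`.
#' Used to set the maximal frame-to-frame displacement of the tracker so
#' that fewer than a chosen fraction of steps are missed.
#'
#' @param r_max Linking radius, um (>= 0).
#' @param D Diffusion coefficient, um^2/s (> 0).
#' @param dt Frame interval, s (> 0).
#' @return Probability in `[0, 1]`.
#' @examples
#' escape_probability(1, 5, 0.01)  # exp(-5) ~ 0.0067
#' @export
escape_probability <- function(r_max, D, dt) {
  stop_if_not(all(r_max >= 0), "r_max must be >= 0")
  stop_if_not(all(D > 0) && all(dt > 0), "D and dt must be > 0")
  exp(-r_max^2 / (4 * D * dt))
}

#' Linking radius for a target miss probability
#'
#' Inverts [escape_probability()]: the radius at which a fraction
#' `miss_prob` of single-frame Brownian steps of the fastest expected
#' species would exceed the linking threshold.
#'
#' @param D_max Largest expected diffusion coefficient, um^2/s.
#' @param dt Frame interval, s.
#' @param miss_prob Tolerated miss probability (0, 1].
#' @return Radius in um.
#' @examples
#' choose_rmax(5, 0.01, 0.01)  # ~0.96 um, consistent with a 1-um threshold
#' @export
choose_rmax <- function(D_max, dt, miss_prob = 0.01) {
  stop_if_not(D_max > 0 && dt > 0, "D_max and dt must be > 0")
  stop_if_not(miss_prob > 0 && miss_prob <= 1, "miss_prob must be in (0, 1]")
  sqrt(-4 * D_max * dt * log(miss_prob))
}

# Scale-normalized Laplacian-of-Gaussian kernel (response positive on
# bright blobs of radius ~ sigma).
log_kernel <- function(sigma_px) {
  hw <- max(2L, as.integer(ceiling(4 * sigma_px)))
  xs <- -hw:hw
  X <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  Y <- t(X)
  r2 <- X^2 + Y^2
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * exp(-r2 / (2 * sigma_px^2))
  k - mean(k)  # zero-sum: flat background gives zero response
}

#' Detect diffraction-limited spots with a LoG filter
#'
#' Applies a scale-normalized Laplacian-of-Gaussian filter at the scale of
#' the expected molecule diameter, keeps local maxima of the response above
#' `threshold`, and refines each maximum by the local intensity centroid
#' (sub-pixel).
#'
#' @param frame 2D image matrix.
#' @param pixel_size Pixel size, um.
#' @param diameter_um Expected maximal molecule diameter, um (filter scale
#'   is `diameter_um / 2`).
#' @param threshold Quality threshold on the LoG response. The response is
#'   normalized by the image's robust noise scale (median absolute
#'   deviation), so the threshold is unitless; its absolute calibration is
#'   camera-dependent.
#' @return data.frame with `x_um`, `y_um`, `intensity` (raw image at the
#'   maximum), `quality` (normalized LoG response); zero rows when nothing
#'   is found.
#' @export
log_detect <- function(frame, pixel_size, diameter_um = 0.8, threshold = 5) {
  stop_if_not(is.matrix(frame), "frame must be a matrix")
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  sigma_px <- (diameter_um / 2) / pixel_size / sqrt(2)  # blob radius ~ sigma*sqrt(2)
  resp <- EBImage::filter2(frame, log_kernel(sigma_px) /
                             sum(abs(log_kernel(sigma_px))), boundary = 0)
  noise <- stats::mad(resp)
  if (noise <= 0) noise <- stats::sd(resp)
  if (!is.finite(noise) || noise <= 0) noise <- 1
  q <- resp / noise
  H <- nrow(frame); W <- ncol(frame)
  # strict local maxima over the 8-neighbourhood, excluding a 1-px border
  cand <- which(q > threshold)
  cand <- cand[{
    iy <- (cand - 1L) %% H + 1L; ix <- (cand - 1L) %/% H + 1L
    iy > 1L & iy < H & ix > 1L & ix < W
  }]
  if (!length(cand))
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), quality = numeric()))
  iy <- (cand - 1L) %% H + 1L; ix <- (cand - 1L) %/% H + 1L
  ismax <- rep(TRUE, length(cand))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & q[cbind(iy, ix)] >= q[cbind(iy + dy, ix + dx)]
  }
  # guard against plateau duplicates: require strictly greater than at least
  # the lexicographically earlier neighbours
  iy <- iy[ismax]; ix <- ix[ismax]
  if (!length(iy))
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), quality = numeric()))
  # sub-pixel refinement: centroid of the background-subtracted 3x3 patch
  xr <- yr <- numeric(length(iy))
  for (i in seq_along(iy)) {
    py <- (iy[i] - 1L):(iy[i] + 1L); px <- (ix[i] - 1L):(ix[i] + 1L)
    patch <- frame[py, px]
    patch <- pmax(patch - min(patch), 0)
    s <- sum(patch)
    if (s > 0) {
      xr[i] <- sum(matrix(px - 1L, 3, 3, byrow = TRUE) * patch) / s
      yr[i] <- sum(matrix(py - 1L, 3, 3) * patch) / s
    } else {
      xr[i] <- ix[i] - 1L; yr[i] <- iy[i] - 1L
    }
  }
  data.frame(x_um = xr * pixel_size, y_um = yr * pixel_size,
             intensity = frame[cbind(iy, ix)],
             quality = q[cbind(iy, ix)])
}

#' Detect spots in every frame of a movie
#'
#' @param movie 3D array `[y, x, frame]`.
#' @inheritParams log_detect
#' @return data.frame with `frame` (0-based) plus the [log_detect()] columns.
#' @export
detect_movie <- function(movie, pixel_size = NULL, diameter_um = 0.8,
                         threshold = 5) {
  if (is.null(pixel_size)) pixel_size <- attr(movie, "pixel_size")
  stop_if_not(!is.null(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  nfr <- dim(movie)[3]
  out <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    sp <- log_detect(movie[, , f], pixel_size, diameter_um, threshold)
    if (nrow(sp)) out[[f]] <- cbind(frame = f - 1L, sp)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), quality = numeric())
  res
}

# Minimum-cost maximum-cardinality bipartite matching among pairs within
# r_max, via weighted matching with a large per-edge bonus.
match_frame_pair <- function(p0, p1, r_max) {
  n0 <- nrow(p0); n1 <- nrow(p1)
  if (n0 == 0L || n1 == 0L) return(integer(0))
  d2 <- outer(p0[, 1], p1[, 1], "-")^2 + outer(p0[, 2], p1[, 2], "-")^2
  ok <- which(d2 <= r_max^2, arr.ind = TRUE)
  if (!nrow(ok)) return(rep(NA_integer_, n0))
  B <- r_max^2 * (n0 + n1 + 1)
  g <- igraph::make_bipartite_graph(c(rep(TRUE, n0), rep(FALSE, n1)),
                                    edges = as.vector(t(cbind(ok[, 1],
                                                              n0 + ok[, 2]))))
  m <- igraph::max_bipartite_match(
    g, weights = B - d2[ok])$matching
  res <- rep(NA_integer_, n0)
  filled <- !is.na(m[seq_len(n0)])
  res[filled] <- m[seq_len(n0)][filled] - n0
  res
}

#' Link detected spots into tracks
#'
#' Frame-to-frame linear-assignment linking: between each pair of
#' consecutive frames, spots are matched by an optimal bipartite assignment
#' that maximizes the number of links among candidate pairs closer than
#' `r_max` and, among those, minimizes the total squared displacement. No
#' gap closing, splitting or merging: an unmatched spot ends its track, a
#' spot with no predecessor starts a new one. Invariant under permutation
#' of the spots within a frame.
#'
#' @param spots data.frame from [detect_movie()] (`frame`, `x_um`, `y_um`).
#' @param r_max Maximal frame-to-frame displacement, um.
#' @return Track data.frame (`track_id`, `frame`, `x_um`, `y_um`); only
#'   tracks with >= 2 localizations are returned.
#' @export
link_tracks <- function(spots, r_max) {
  stop_if_not(r_max > 0, "r_max must be > 0")
  if (nrow(spots) == 0L)
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric()))
  spots <- spots[order(spots$frame), ]
  frames <- sort(unique(spots$frame))
  rows_by_frame <- split(seq_len(nrow(spots)), spots$frame)
  tid <- rep(NA_integer_, nrow(spots))
  next_id <- 1L
  prev_rows <- rows_by_frame[[1]]
  tid[prev_rows] <- seq_len(length(prev_rows))
  next_id <- length(prev_rows) + 1L
  for (fi in seq_along(frames)[-1L]) {
    cur_rows <- rows_by_frame[[fi]]
    contiguous <- frames[fi] == frames[fi - 1L] + 1L
    assigned <- rep(NA_integer_, length(cur_rows))
    if (contiguous && length(prev_rows)) {
      p0 <- cbind(spots$x_um[prev_rows], spots$y_um[prev_rows])
      p1 <- cbind(spots$x_um[cur_rows], spots$y_um[cur_rows])
      mm <- match_frame_pair(p0, p1, r_max)
      for (i in seq_along(mm)) if (!is.na(mm[i])) assigned[mm[i]] <- i
    }
    for (j in seq_along(cur_rows)) {
      if (!is.na(assigned[j])) {
        tid[cur_rows[j]] <- tid[prev_rows[assigned[j]]]
      } else {
        tid[cur_rows[j]] <- next_id
        next_id <- next_id + 1L
      }
    }
    prev_rows <- cur_rows
  }
  out <- data.frame(track_id = tid, frame = spots$frame,
                    x_um = spots$x_um, y_um = spots$y_um)
  keep <- ave(out$track_id, out$track_id, FUN = length) >= 2
  out <- out[keep, ]
  out <- out[order(out$track_id, out$frame), ]
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}
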
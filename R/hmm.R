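# Diffusion-state hidden Markov model on squared frame-to-frame
# displacements. Emissions: r^2 ~ Exponential(mean 4 D_k dt), the exact law
# for isotropic 2D Brownian jumps; the bound state's D absorbs the
# localization-noise floor sigma^2/dt. Maximum-likelihood EM (Baum-Welch)
# with multiple restarts, vectorised across tracks.

# Organize tracks into a padded matrix of squared displacements.
# Returns list(R2 [n x Tmax], len [n], ids).
prepare_r2 <- function(tracks, min_len) {
  sp <- split(tracks[, c("frame", "x_um", "y_um")], tracks$track_id)
  sp <- Filter(function(d) nrow(d) >= min_len, sp)
  if (!length(sp)) stop("no track with at least ", min_len, " localizations",
                        call. = FALSE)
  r2l <- lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    diff(d$x_um)^2 + diff(d$y_um)^2
  })
  len <- lengths(r2l)
  R2 <- matrix(NA_real_, length(r2l), max(len))
  for (i in seq_along(r2l)) R2[i, seq_len(len[i])] <- r2l[[i]]
  list(R2 = R2, len = len, ids = names(sp))
}

# One EM run from a given initialisation. Returns model + logL trace.
em_run <- function(R2, len, dt, K, D0, pi0, A0, max_iter = 300, tol = 1e-8) {
  n <- nrow(R2); Tm <- ncol(R2)
  D <- D0; Pi <- pi0; A <- A0
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    rate <- 1 / (4 * D * dt)
    alpha <- array(NA_real_, c(n, K, Tm))
    cc <- matrix(NA_real_, n, Tm)
    emis <- function(t, act) {
      # n_act x K emission densities at time t
      outer(R2[act, t], rate, function(x, rt) rt * exp(-rt * x))
    }
    act <- which(len >= 1L)
    E1 <- emis(1L, act)
    a <- E1 * rep(Pi, each = length(act))
    c1 <- rowSums(a)
    alpha[act, , 1L] <- a / c1
    cc[act, 1L] <- c1
    aslice <- function(rows, t) matrix(alpha[rows, , t], nrow = length(rows))
    for (t in seq_len(Tm)[-1L]) {
      act <- which(len >= t)
      if (!length(act)) break
      Et <- emis(t, act)
      a <- (aslice(act, t - 1L) %*% A) * Et
      ct <- rowSums(a)
      alpha[act, , t] <- a / ct
      cc[act, t] <- ct
    }
    ll <- sum(log(cc[!is.na(cc)]))
    trace <- c(trace, ll)
    # backward + accumulators
    beta <- matrix(1, n, K)
    SDnum <- numeric(K); SDden <- numeric(K)
    xi <- matrix(0, K, K)
    gamma1 <- matrix(0, n, K)
    for (t in rev(seq_len(Tm))) {
      act <- which(len >= t)
      if (!length(act)) next
      g <- aslice(act, t) * beta[act, , drop = FALSE]
      SDnum <- SDnum + colSums(g * R2[act, t])
      SDden <- SDden + colSums(g)
      if (t == 1L) gamma1[act, ] <- g
      if (t > 1L) {
        Et <- emis(t, act)
        eb <- Et * beta[act, , drop = FALSE] / cc[act, t]
        M <- t(aslice(act, t - 1L)) %*% eb
        xi <- xi + A * M
        beta[act, ] <- eb %*% t(A)
      }
    }
    D_new <- pmax(SDnum / (4 * dt * pmax(SDden, 1e-12)), 1e-7)
    Pi_new <- colSums(gamma1) / sum(gamma1)
    A_new <- if (Tm > 1L) row_normalize(xi) else A
    zero_rows <- rowSums(A_new) == 0
    A_new[zero_rows, ] <- 1 / K
    D <- D_new; Pi <- Pi_new; A <- A_new
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(D = D, pi = Pi, A = A, logL = trace[length(trace)], trace = trace)
}

#' Fit a diffusion-state hidden Markov model to tracks
#'
#' Segments single-molecule tracks into K diffusive states (for K = 3:
#' bound, slow, fast) by an exponential HMM on squared frame-to-frame
#' displacements, fitted by EM with `n_restarts` seeded restarts. Only
#' tracks with at least `min_len` localizations enter the fit. States are
#' relabelled by increasing diffusion coefficient.
#'
#' @param tracks Track data.frame (`track_id`, `frame`, `x_um`, `y_um`).
#' @param dt Frame interval, s.
#' @param K Number of states.
#' @param min_len Minimum localizations per track (default 8).
#' @param n_restarts Seeded EM restarts.
#' @param seed Integer seed for the restarts.
#' @param max_iter,tol EM stopping rule.
#' @return Object of class `diffhmm`: `K`, `D` (ascending, um^2/s), `pi`,
#'   `A` (row-stochastic per-frame transitions), `logL`, `BIC`, `dt`,
#'   `n_displacements`, `n_tracks`, `trace`.
#' @export
fit_hmm <- function(tracks, dt, K = 3, min_len = 8, n_restarts = 10, seed = 1,
                    max_iter = 300, tol = 1e-8) {
  stop_if_not(K >= 1, "K must be >= 1")
  stop_if_not(dt > 0, "dt must be > 0")
  prep <- prepare_r2(tracks, min_len)
  n <- nrow(prep$R2)
  if (n < 50) warning("fewer than 50 eligible tracks; fit may be unstable")
  nd <- sum(prep$len)
  Dhat <- prep$R2 / (4 * dt)
  qs <- stats::quantile(Dhat[!is.na(Dhat)], c(0.05, 0.95))
  qs[1] <- max(qs[1], 1e-6); qs[2] <- max(qs[2], 10 * qs[1])
  best <- NULL
  with_seed(seed, {
    for (st in seq_len(n_restarts)) {
      D0 <- exp(seq(log(qs[1]), log(qs[2]), length.out = max(K, 2)))[seq_len(K)]
      if (st > 1) D0 <- D0 * exp(stats::rnorm(K, sd = 0.6))
      A0 <- matrix(0.2 / max(K - 1, 1), K, K); diag(A0) <- if (K > 1) 0.8 else 1
      if (st > 1 && K > 1) {
        stay <- stats::runif(1, 0.6, 0.95)
        A0 <- matrix((1 - stay) / (K - 1), K, K); diag(A0) <- stay
      }
      run <- em_run(prep$R2, prep$len, dt, K, sort(D0), rep(1 / K, K), A0,
                    max_iter = max_iter, tol = tol)
      if (is.null(best) || run$logL > best$logL) best <- run
    }
  })
  # relabel states by ascending D
  ord <- order(best$D)
  model <- structure(list(K = as.integer(K), D = best$D[ord],
                          pi = best$pi[ord], A = best$A[ord, ord, drop = FALSE],
                          logL = best$logL,
                          BIC = -2 * best$logL + (K^2 + K - 1) * log(nd),
                          dt = dt, n_displacements = nd, n_tracks = n,
                          min_len = as.integer(min_len), trace = best$trace),
                     class = "diffhmm")
  model
}

#' @export
print.diffhmm <- function(x, ...) {
  nm <- if (x$K == 3) c("bound", "slow", "fast") else paste0("S", seq_len(x$K))
  cat(sprintf("Diffusion HMM: %d states, %d tracks, %d displacements\n",
              x$K, x$n_tracks, x$n_displacements))
  cat("  D (um^2/s):", paste(sprintf("%s=%.4g", nm, x$D), collapse = ", "), "\n")
  cat("  initial weights:", paste(signif(x$pi, 3), collapse = ", "), "\n")
  cat("  transition matrix (per frame):\n")
  A <- round(x$A, 4); dimnames(A) <- list(from = nm, to = nm)
  print(A)
  cat(sprintf("  logL = %.2f, BIC = %.2f\n", x$logL, x$BIC))
  invisible(x)
}

#' @export
coef.diffhmm <- function(object, ...) {
  list(D = object$D, pi = object$pi, A = object$A)
}

#' @export
logLik.diffhmm <- function(object, ...) {
  structure(object$logL, df = object$K^2 + object$K - 1,
            nobs = object$n_displacements, class = "logLik")
}

#' Viterbi state labels and posterior bound probability for tracks
#'
#' Decodes the most likely state path of every track under a fitted model
#' and attaches per-displacement labels: column `state` on each row holds
#' the state of the displacement starting there (the final row of a track
#' repeats the last label). States are 1..K by increasing D. A second
#' column `p_bound` carries the forward-backward posterior marginal
#' probability that the displacement belongs to the slowest state — the
#' per-step confidence used by [filter_bound()].
#'
#' @param tracks Track data.frame; tracks shorter than 2 localizations are
#'   passed through with `NA` labels.
#' @param model A [fit_hmm()] model.
#' @return The track data.frame with added columns `state` (integer) and
#'   `p_bound` (numeric).
#' @export
segment_tracks <- function(tracks, model) {
  stopifnot(inherits(model, "diffhmm"))
  if (nrow(tracks) == 0L) {
    tracks$state <- integer(0)
    tracks$p_bound <- numeric(0)
    return(tracks)
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  K <- model$K
  rate <- 1 / (4 * model$D * model$dt)
  lpi <- log(model$pi + 1e-300)
  lA <- log(model$A + 1e-300)
  state <- rep(NA_integer_, nrow(tracks))
  pbound <- rep(NA_real_, nrow(tracks))
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  for (rows in idx) {
    L <- length(rows)
    if (L < 2L) next
    r2 <- diff(tracks$x_um[rows])^2 + diff(tracks$y_um[rows])^2
    lB <- outer(r2, rate, function(x, rt) log(rt) - rt * x)  # (L-1) x K
    Tn <- L - 1L
    delta <- lpi + lB[1L, ]
    psi <- matrix(0L, Tn, K)
    if (Tn > 1L) for (t in 2:Tn) {
      m <- delta + lA              # K x K: from i (row) to j (col)
      j_best <- apply(m, 2L, which.max)
      delta <- m[cbind(j_best, seq_len(K))] + lB[t, ]
      psi[t, ] <- j_best
    }
    path <- integer(Tn)
    path[Tn] <- which.max(delta)
    if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
    state[rows] <- c(path, path[Tn])
    # forward-backward posterior of state 1 per displacement
    B <- exp(lB)
    al <- matrix(0, Tn, K); cc <- numeric(Tn)
    a <- model$pi * B[1L, ]; cc[1L] <- sum(a); al[1L, ] <- a / cc[1L]
    if (Tn > 1L) for (t in 2:Tn) {
      a <- (al[t - 1L, ] %*% model$A) * B[t, ]
      cc[t] <- sum(a); al[t, ] <- a / cc[t]
    }
    be <- matrix(1, Tn, K)
    if (Tn > 1L) for (t in (Tn - 1L):1L)
      be[t, ] <- (model$A %*% (B[t + 1L, ] * be[t + 1L, ])) / cc[t + 1L]
    g1 <- (al * be)[, 1L]
    pbound[rows] <- c(g1, g1[Tn])
  }
  tracks$state <- state
  tracks$p_bound <- pbound
  tracks
}

#' Summary of fitted transition probabilities
#'
#' Reports the per-frame transition matrix, mean state dwell times, the
#' stationary distribution, and — for three-state models — the ratio of the
#' slow-to-bound over the fast-to-bound transition probability, the
#' signature of whether binding is fed from the slow or the fast state.
#'
#' @param model A [fit_hmm()] model.
#' @return List with `A`, `dwell_frames`, `stationary`,
#'   `slow_to_bound_over_fast_to_bound` (NA with a flag unless K = 3).
#' @export
transition_summary <- function(model) {
  stopifnot(inherits(model, "diffhmm"))
  A <- model$A
  ev <- eigen(t(A))
  i1 <- which.min(abs(ev$values - 1))
  statio <- Re(ev$vectors[, i1]); statio <- statio / sum(statio)
  ratio <- if (model$K == 3) A[2, 1] / A[3, 1] else NA_real_
  out <- list(A = A, dwell_frames = 1 / pmax(1 - diag(A), 1e-12),
              stationary = statio,
              slow_to_bound_over_fast_to_bound = ratio)
  if (model$K != 3) attr(out, "flag") <- "ratio defined only for K = 3"
  out
}

#' Remove bound segments from labelled tracks
#'
#' Splits each track at bound displacements and returns the contiguous
#' diffusing segments, keeping only segments with at least 2 displacements
#' (3 localizations) so that angles between consecutive jumps remain
#' computable. A displacement is treated as bound when its Viterbi label is
#' the bound state or when its posterior bound probability exceeds
#' `max_p_bound`: the Viterbi path maximizes whole-path probability, not
#' per-step purity, and on its own retains too many ambiguous steps that
#' are truly bound; the posterior cut removes low-confidence steps and
#' keeps the retained diffusing set clean (target: below 5% truly-bound).
#' Ground-truth columns are carried along.
#'
#' @param tracks Labelled track table (columns `state` and optionally
#'   `p_bound` from [segment_tracks()], or supplied via `labels`).
#' @param labels Optional per-row label vector overriding `tracks$state`.
#' @param bound_state Label of the bound state (default 1).
#' @param max_p_bound Posterior confidence cut: displacements with
#'   `p_bound` above this are removed as well (default 0.25; `1` disables
#'   the cut and reproduces pure Viterbi splitting).
#' @return Track table of diffusing segments with new `track_id` and an
#'   `orig_track` column; zero rows if everything is bound.
#' @export
filter_bound <- function(tracks, labels = NULL, bound_state = 1L,
                         max_p_bound = 0.25) {
  if (nrow(tracks) == 0L) return(cbind(tracks, orig_track = integer(0)))
  if (is.null(labels)) {
    stop_if_not("state" %in% names(tracks),
                "tracks must carry a 'state' column (or pass labels)")
    labels <- tracks$state
  }
  pb <- if ("p_bound" %in% names(tracks)) tracks$p_bound else rep(0, nrow(tracks))
  pb[is.na(pb)] <- 0
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  segs <- vector("list", 64L); nseg <- 0L
  for (rows in split(seq_len(nrow(tracks)), tracks$track_id)) {
    L <- length(rows)
    if (L < 3L) next
    lab <- labels[rows][seq_len(L - 1L)]   # per-displacement labels
    good <- !is.na(lab) & lab != bound_state &
      pb[rows][seq_len(L - 1L)] <= max_p_bound
    rl <- rle(good)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (i in which(rl$values & rl$lengths >= 2L)) {
      nseg <- nseg + 1L
      if (nseg > length(segs)) segs <- c(segs, vector("list", length(segs)))
      seg_rows <- rows[starts[i]:(ends[i] + 1L)]  # displacements -> +1 loc
      d <- tracks[seg_rows, , drop = FALSE]
      d$orig_track <- d$track_id
      d$track_id <- nseg
      segs[[nseg]] <- d
    }
  }
  if (nseg == 0L) {
    out <- tracks[0, , drop = FALSE]
    out$orig_track <- integer(0)
    return(out)
  }
  out <- do.call(rbind, segs[seq_len(nseg)])
  rownames(out) <- NULL
  out
}

#' Residual truly-bound fraction after filtering
#'
#' Fraction of displacements in the retained diffusing segments whose
#' ground-truth state is bound — the purity check applied before
#' anisotropy analysis (target: below 5%).
#'
#' @param segments Output of [filter_bound()] carrying `state_true`.
#' @param truth Optional per-row ground-truth labels overriding
#'   `segments$state_true`.
#' @param bound_state Ground-truth label of the bound state.
#' @return Fraction in `[0, 1]` (NaN when no displacement remains).
#' @export
residual_bound_fraction <- function(segments, truth = NULL, bound_state = 1L) {
  if (is.null(truth)) {
    stop_if_not("state_true" %in% names(segments),
                "segments must carry 'state_true' (or pass truth)")
    truth <- segments$state_true
  }
  if (nrow(segments) == 0L) return(NaN)
  segments$truth_ <- truth
  segments <- segments[order(segments$track_id, segments$frame), ]
  last <- !duplicated(segments$track_id, fromLast = TRUE)
  disp_truth <- segments$truth_[!last]   # displacement label = start row
  mean(disp_truth == bound_state)
}
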
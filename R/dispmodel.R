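#' Axial retention probability of a diffusing molecule
#'
#' Probability that a molecule with diffusion coefficient `D`, uniformly
#' distributed in a detection slice of half-thickness `dz`, is still inside
#' the slice after one frame interval:
#' `erf(dz / sqrt(D dt)) + sqrt(4 D dt / pi) / (2 dz) * (exp(-dz^2/(D dt)) - 1)`.
#' Equals 1 for an immobile molecule and decreases monotonically with `D`.
#' Fast molecules are preferentially lost from the slice, which deflates
#' their apparent fraction in the observed displacement distribution; this
#' factor is used to correct for that loss.
#'
#' @param dz Detection-slice half-thickness, um (> 0; `Inf` disables the
#'   correction).
#' @param D Diffusion coefficient, um^2/s (>= 0); vectorised.
#' @param dt Frame interval, s (> 0).
#' @return Probability in (0, 1].
#' @export
axial_retention <- function(dz, D, dt) {
  stop_if_not(all(dz > 0), "dz must be > 0")
  stop_if_not(all(D >= 0), "D must be >= 0")
  stop_if_not(all(dt > 0), "dt must be > 0")
  if (is.infinite(dz)) return(rep(1, length(D)))
  s <- sqrt(D * dt)
  out <- numeric(length(D))
  zero <- D == 0
  out[zero] <- 1
  if (any(!zero)) {
    sz <- s[!zero]
    out[!zero] <- erf(dz / sz) +
      sqrt(4 * sz^2 / pi) / (2 * dz) * (exp(-dz^2 / sz^2) - 1)
  }
  out
}

# Observed mixture weights: fractions re-weighted by axial retention and
# renormalized (the observed histogram is conditioned on detection).
observed_weights <- function(f, D, dz, dt) {
  p <- axial_retention(dz, D, dt)
  w <- f * p
  w / sum(w)
}

#' Displacement-distribution mixture density
#'
#' Density of frame-to-frame jump lengths under a K-component diffusion
#' model with axial-escape correction: a mixture of Rayleigh components
#' `r / (2 D_i dt) exp(-r^2 / (4 D_i dt))` with weights proportional to
#' `f_i * p(dz, D_i)`, renormalized so the density integrates to 1. With
#' `dz = Inf` the weights reduce to the uncorrected fractions `f_i`, and a
#' single component is the Rayleigh density with scale `sqrt(2 D dt)`.
#'
#' @param r Displacement lengths, um.
#' @param f Component fractions (sum to 1).
#' @param D Apparent diffusion coefficients, um^2/s.
#' @param dt Frame interval, s.
#' @param dz Detection-slice half-thickness, um.
#' @return `displacement_pdf`: density values; `displacement_cdf`:
#'   cumulative probabilities.
#' @export
displacement_pdf <- function(r, f, D, dt, dz = Inf) {
  w <- observed_weights(f, D, dz, dt)
  rowSums(vapply(seq_along(D), function(i)
    w[i] * r / (2 * D[i] * dt) * exp(-r^2 / (4 * D[i] * dt)),
    numeric(length(r))))
}

#' @rdname displacement_pdf
#' @export
displacement_cdf <- function(r, f, D, dt, dz = Inf) {
  w <- observed_weights(f, D, dz, dt)
  rowSums(vapply(seq_along(D), function(i)
    w[i] * (1 - exp(-r^2 / (4 * D[i] * dt))),
    numeric(length(r))))
}

#' Histogram of displacements for plotting
#'
#' Fixed-width binning (default 20 nm) of jump lengths, normalized to a
#' probability density. Provided for display parity; fitting uses the
#' empirical CDF or the raw likelihood, never binned counts.
#'
#' @param r Displacements, um.
#' @param bin_um Bin width, um.
#' @return data.frame with `r_um` (bin centers) and `density`.
#' @export
displacement_histogram <- function(r, bin_um = 0.02) {
  stop_if_not(bin_um > 0, "bin_um must be > 0")
  breaks <- seq(0, max(r, bin_um) + bin_um, by = bin_um)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  data.frame(r_um = h$mids, density = h$density)
}

# parameter transform: theta = (log D_1..K, alpha_1..K-1), f = softmax(alpha, 0)
theta_unpack <- function(theta, K) {
  D <- exp(theta[seq_len(K)])
  a <- c(theta[K + seq_len(K - 1)], 0)
  e <- exp(a - max(a))
  list(D = D, f = e / sum(e))
}

#' Fit the displacement-distribution kinetic model
#'
#' Estimates the fractions and apparent diffusion coefficients of K
#' diffusive populations from frame-to-frame jump lengths, correcting for
#' the preferential axial escape of fast molecules from the detection
#' slice. Two objectives are available: least squares between the empirical
#' and model CDF (`method = "cdf"`, default, the classic kinetic-modelling
#' choice), or maximum likelihood on the raw jumps (`method = "mle"`, used
#' for BIC model selection). The optimiser is restarted from `n_starts`
#' log-spaced diffusion initialisations; components are returned sorted by
#' increasing D.
#'
#' @param r Displacement lengths, um (or a data.frame with column `r_um`).
#' @param dt Frame interval, s.
#' @param K Number of components (1..4).
#' @param dz Detection-slice half-thickness, um; `Inf` disables the
#'   escape correction.
#' @param method `"cdf"` or `"mle"`.
#' @param n_starts Number of seeded restarts (>= 1).
#' @param seed Seed for the restart jitter.
#' @return Object of class `dispfit` with elements `f`, `D`, `w`
#'   (escape-corrected observed weights), `dz`, `dt`, `K`, `n`, `loss`,
#'   `logLik`, `method`, `converged`, `degenerate`.
#' @examples
#' set.seed(1)
#' r <- sqrt(4 * 1.0 * 0.01) * sqrt(-log(runif(5000)))  # Rayleigh, D = 1
#' fit <- fit_displacements(r, dt = 0.01, K = 1)
#' coef(fit)
#' @export
fit_displacements <- function(r, dt, K = 3, dz = 0.5, method = c("cdf", "mle"),
                              n_starts = 5, seed = 1) {
  if (is.data.frame(r)) r <- r$r_um
  method <- match.arg(method)
  stop_if_not(K >= 1 && K <= 4, "K must be in 1..4")
  stop_if_not(dt > 0, "dt must be > 0")
  stop_if_not(n_starts >= 1, "n_starts must be >= 1")
  r <- r[is.finite(r) & r >= 0]
  n <- length(r)
  if (n < 500) warning("fewer than 500 displacements; fit may be unstable")
  # degenerate input: all displacements at (numerical) zero
  if (n == 0 || max(r) < 1e-9) {
    Dfloor <- 1e-6
    out <- structure(list(f = 1, D = Dfloor, w = 1, dz = dz, dt = dt, K = 1L,
                          n = n, loss = 0, logLik = NA_real_, method = method,
                          converged = TRUE, degenerate = TRUE),
                     class = "dispfit")
    return(out)
  }
  rs <- sort(r)
  eps <- max(min(rs[rs > 0]), 1e-6) / 10

  # The observed displacement distribution is a plain Rayleigh mixture in
  # the weights w_i (escape-corrected); both objectives estimate (w, D) and
  # the underlying fractions are recovered afterwards by inverting
  # w_i ~ f_i * p(dz, D_i).
  # log-spaced D initialisations spanning the data, jittered per restart
  Dlo <- max(stats::quantile(r[r > 0], 0.05)^2 / (4 * dt), 1e-5)
  Dhi <- max(stats::quantile(r, 0.999)^2 / (4 * dt), 10 * Dlo)
  inits <- with_seed(seed, lapply(seq_len(n_starts), function(st) {
    D0 <- exp(seq(log(Dlo), log(Dhi), length.out = K + 2))[1 + seq_len(K)]
    if (st > 1) D0 <- D0 * exp(stats::rnorm(K, sd = 0.5))
    list(D = D0, w = rep(1 / K, K))
  }))

  if (method == "mle") {
    x <- rs^2
    best <- NULL
    for (ini in inits) {
      run <- em_rayleigh_mixture(x, dt, ini$D, ini$w)
      if (is.null(best) || run$logL > best$logL) best <- run
    }
    W <- best$w; D <- best$D
    loss <- -best$logL
    converged <- best$converged
  } else {
    # least squares between empirical and model CDF, evaluated on (at most)
    # 2000 order statistics for speed
    if (n > 2000) {
      ii <- unique(round(seq(1, n, length.out = 2000)))
    } else ii <- seq_len(n)
    rg <- rs[ii]
    Fg <- (ii - 0.5) / n
    mix_cdf <- function(w, D) {
      rowSums(vapply(seq_along(D), function(i)
        w[i] * (1 - exp(-rg^2 / (4 * D[i] * dt))), numeric(length(rg))))
    }
    objective <- function(theta) {
      pp <- theta_unpack(theta, K)
      mean((mix_cdf(pp$f, pp$D) - Fg)^2)
    }
    # the (cheap) EM solution of the same mixture seeds the slowest restart
    emb <- NULL
    for (ini in inits) {
      run <- em_rayleigh_mixture(rs^2, dt, ini$D, ini$w)
      if (is.null(emb) || run$logL > emb$logL) emb <- run
    }
    inits <- c(list(list(D = emb$D, w = pmax(emb$w, 1e-8))), inits)
    best <- NULL
    for (ini in inits) {
      a0 <- log(ini$w[-K] / ini$w[K])
      fit <- try(stats::optim(c(log(ini$D), a0), objective, method = "BFGS",
                              control = list(maxit = 2000, reltol = 1e-12)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      return(structure(list(f = rep(NA_real_, K), D = rep(NA_real_, K),
                            w = NULL, dz = dz, dt = dt, K = as.integer(K),
                            n = n, loss = NA_real_, logLik = NA_real_,
                            method = method, converged = FALSE,
                            degenerate = FALSE),
                       class = "dispfit"))
    }
    pp <- theta_unpack(best$par, K)
    W <- pp$f; D <- pp$D
    loss <- best$value
    converged <- best$convergence %in% c(0L, 1L)  # 1 = iteration cap reached
  }
  ord <- order(D)
  D <- D[ord]; W <- W[ord]
  # invert the escape re-weighting to recover the underlying fractions
  p <- axial_retention(dz, D, dt)
  f <- (W / p) / sum(W / p)
  ll <- sum(log(pmax(displacement_pdf(pmax(rs, eps), f, D, dt, dz), 1e-300)))
  structure(list(f = f, D = D, w = W, dz = dz, dt = dt, K = as.integer(K),
                 n = n, loss = loss, logLik = ll, method = method,
                 converged = converged, degenerate = FALSE),
            class = "dispfit")
}

# EM for a K-component exponential mixture on squared displacements
# (equivalently Rayleigh in r); returns observed weights and D.
em_rayleigh_mixture <- function(x, dt, D0, w0, max_iter = 500, tol = 1e-10) {
  K <- length(D0)
  D <- pmax(D0, 1e-7); w <- w0 / sum(w0)
  n <- length(x)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    rate <- 1 / (4 * D * dt)
    dens <- vapply(seq_len(K), function(k) w[k] * rate[k] * exp(-rate[k] * x),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0] <- 1e-300
    ll <- sum(log(tot))
    g <- dens / tot
    sg <- colSums(g)
    D <- pmax(colSums(g * x) / (4 * dt * pmax(sg, 1e-12)), 1e-7)
    w <- sg / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(D = D, w = w, logL = ll, converged = converged)
}

#' @export
print.dispfit <- function(x, ...) {
  cat(sprintf("Displacement-distribution fit (%s), K = %d, n = %d\n",
              x$method, x$K, x$n))
  if (x$degenerate) cat("  [degenerate input: all displacements ~ 0]\n")
  nm <- if (x$K == 3) c("bound", "slow", "fast") else paste0("comp", seq_len(x$K))
  tab <- data.frame(component = nm, f = round(x$f, 4), D_um2_s = signif(x$D, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("  dz = %g um, dt = %g s, logLik = %.2f\n", x$dz, x$dt, x$logLik))
  invisible(x)
}

#' @export
coef.dispfit <- function(object, ...) {
  nm <- if (object$K == 3) c("bound", "slow", "fast")
        else paste0("comp", seq_len(object$K))
  stats::setNames(c(object$f, object$D),
                  c(paste0("f_", nm), paste0("D_", nm)))
}

#' @export
logLik.dispfit <- function(object, ...) {
  structure(object$logLik, df = 2 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' @export
summary.dispfit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predicted density or CDF of a fitted displacement model
#'
#' @param object A `dispfit`.
#' @param r Displacements at which to evaluate, um.
#' @param type `"pdf"` or `"cdf"`.
#' @param ... Unused.
#' @export
predict.dispfit <- function(object, r, type = c("pdf", "cdf"), ...) {
  type <- match.arg(type)
  if (type == "pdf") displacement_pdf(r, object$f, object$D, object$dt, object$dz)
  else displacement_cdf(r, object$f, object$D, object$dt, object$dz)
}

#' Simulate displacements from a fitted (or specified) model
#'
#' Draws jump lengths from the observed mixture: component i is chosen with
#' the escape-corrected weight w_i and the jump is Rayleigh with scale
#' `sqrt(2 D_i dt)`.
#'
#' @param object A `dispfit` (or any list with `f`, `D`, `dt`, `dz`).
#' @param nsim Number of displacements.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Numeric vector of jump lengths, um.
#' @export
simulate.dispfit <- function(object, nsim = 1, seed = NULL, ...) {
  w <- observed_weights(object$f, object$D, object$dz, object$dt)
  draw <- function() {
    comp <- sample.int(length(w), nsim, replace = TRUE, prob = w)
    sqrt(-4 * object$D[comp] * object$dt * log(stats::runif(nsim)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
plot.dispfit <- function(x, r = NULL, bin_um = 0.02, ...) {
  if (is.null(r)) {
    rr <- seq(0, 6 * sqrt(4 * max(x$D) * x$dt), length.out = 400)
    graphics::plot(rr, predict(x, rr), type = "l", xlab = "displacement (um)",
                   ylab = "density", main = "Displacement model", ...)
  } else {
    h <- displacement_histogram(r, bin_um)
    graphics::plot(h$r_um, h$density, type = "h", col = "grey70",
                   xlab = "displacement (um)", ylab = "density",
                   main = "Displacement model", ...)
    rr <- seq(0, max(h$r_um), length.out = 400)
    graphics::lines(rr, predict(x, rr), col = "red", lwd = 2)
  }
  invisible(x)
}

#' Select the number of diffusive components by BIC
#'
#' Fits `K = 1..k_max` by maximum likelihood and returns the K minimizing
#' `BIC = -2 logL + (2K - 1) log(n)`.
#'
#' @inheritParams fit_displacements
#' @param k_max Largest K to consider.
#' @return List with `K` (selected), `bic` (named vector), `fits` (list of
#'   `dispfit`), and `low_confidence` (TRUE when n < 100).
#' @export
select_k_bic <- function(r, dt, dz = 0.5, k_max = 4, n_starts = 5, seed = 1) {
  if (is.data.frame(r)) r <- r$r_um
  n <- length(r)
  fits <- lapply(seq_len(k_max), function(k)
    suppressWarnings(fit_displacements(r, dt, K = k, dz = dz, method = "mle",
                                       n_starts = n_starts, seed = seed + k)))
  bic <- vapply(fits, function(f)
    if (is.na(f$logLik)) Inf else -2 * f$logLik + (2 * f$K - 1) * log(n),
    numeric(1))
  names(bic) <- paste0("K", seq_len(k_max))
  list(K = unname(which.min(bic)), bic = bic, fits = fits,
       low_confidence = n < 100)
}

#' Compare per-cell fit parameters between two conditions
#'
#' Two-sided Kolmogorov-Smirnov tests (default; Kruskal-Wallis available)
#' on the per-cell distributions of the five model parameters D_bound,
#' D_slow, D_fast, f_bound, f_slow, with Bonferroni correction (p * 5,
#' capped at 1).
#'
#' @param fits_a,fits_b Either lists of `dispfit` objects or data.frames
#'   with columns `D_bound`, `D_slow`, `D_fast`, `f_bound`, `f_slow` (one
#'   row per cell).
#' @param test `"ks"` or `"kruskal"`.
#' @return data.frame with `parameter`, `p_raw`, `p_adj`, `statistic`.
#' @export
compare_conditions <- function(fits_a, fits_b, test = c("ks", "kruskal")) {
  test <- match.arg(test)
  as_table <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(f) {
      cf <- coef(f)
      data.frame(D_bound = cf[["D_bound"]], D_slow = cf[["D_slow"]],
                 D_fast = cf[["D_fast"]], f_bound = cf[["f_bound"]],
                 f_slow = cf[["f_slow"]])
    }))
  }
  a <- as_table(fits_a); b <- as_table(fits_b)
  stop_if_not(nrow(a) >= 2 && nrow(b) >= 2,
              "need at least 2 cells per condition")
  pars <- c("D_bound", "D_slow", "D_fast", "f_bound", "f_slow")
  res <- lapply(pars, function(p) {
    if (test == "ks") {
      tt <- suppressWarnings(stats::ks.test(a[[p]], b[[p]]))
    } else {
      v <- c(a[[p]], b[[p]])
      grp <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
      tt <- stats::kruskal.test(v, grp)
    }
    data.frame(parameter = p, p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * length(pars)),
               statistic = unname(tt$statistic))
  })
  do.call(rbind, res)
}
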
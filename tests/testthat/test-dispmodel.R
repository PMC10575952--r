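# Displacement-distribution kinetic model.

test_that("axial retention has the right limits and value", {
  expect_equal(axial_retention(0.5, 0, 0.01), 1)
  expect_equal(axial_retention(Inf, 5, 0.01), 1)
  # frozen value cross-checked against a 1D Brownian escape Monte-Carlo
  # oracle (uniform initial z, >= 1e5 walkers) in test-synthdata.R
  expect_equal(axial_retention(0.5, 5, 0.01), 0.74782, tolerance = 1e-4)
  # monotone decreasing in D
  grid <- axial_retention(0.5, c(0, 0.1, 0.5, 1, 2, 5, 10, 20), 0.01)
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > 0 & grid <= 1))
  expect_error(axial_retention(-1, 5, 0.01), "dz")
})

test_that("single-component model reduces to the Rayleigh density", {
  r <- seq(0, 2, length.out = 500)
  D <- 1.2; dt <- 0.01
  expect_equal(displacement_pdf(r, 1, D, dt, Inf),
               r / (2 * D * dt) * exp(-r^2 / (4 * D * dt)), tolerance = 1e-12)
  # analytic mode at sqrt(2 D dt)
  rr <- seq(0.1, 0.3, by = 1e-4)
  expect_equal(rr[which.max(displacement_pdf(rr, 1, D, dt, Inf))],
               sqrt(2 * D * dt), tolerance = 1e-2)
})

test_that("mixture density integrates to 1 with and without escape correction", {
  f <- c(0.35, 0.40, 0.25); D <- c(0.08, 1, 5); dt <- 0.01
  for (dz in c(Inf, 0.5)) {
    int <- stats::integrate(function(r) displacement_pdf(r, f, D, dt, dz),
                            0, Inf, rel.tol = 1e-9)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
})

test_that("with dz = Inf the observed weights equal the fractions", {
  f <- c(0.3, 0.7); D <- c(0.1, 2)
  w <- smtmsim:::observed_weights(f, D, Inf, 0.01)
  expect_equal(w, f)
  # finite dz deflates the fast component relative to its fraction
  w2 <- smtmsim:::observed_weights(f, D, 0.5, 0.01)
  expect_lt(w2[2], f[2])
})

test_that("single-component D is recovered within 3%", {
  obj <- structure(list(f = 1, D = 1.0, dt = 0.01, dz = Inf), class = "dispfit")
  r <- simulate(obj, nsim = 1e5, seed = 1)
  fit <- fit_displacements(r, dt = 0.01, K = 1, dz = Inf)
  expect_equal(fit$D, 1.0, tolerance = 0.03)
  expect_equal(fit$f, 1)
})

test_that("three-component parameters are recovered (f within 0.05, D within 15%)", {
  tru <- structure(list(f = c(0.35, 0.40, 0.25), D = c(0.08, 1, 5),
                        dt = 0.01, dz = 0.5), class = "dispfit")
  r <- simulate(tru, nsim = 1e5, seed = 2)
  for (method in c("cdf", "mle")) {
    fit <- fit_displacements(r, dt = 0.01, K = 3, dz = 0.5, method = method)
    expect_true(all(abs(fit$f - tru$f) < 0.05), label = method)
    expect_true(all(abs(fit$D / tru$D - 1) < 0.15), label = method)
  }
})

test_that("CDF and MLE objectives agree on D within 5% on clean data", {
  tru <- structure(list(f = c(0.35, 0.40, 0.25), D = c(0.08, 1, 5),
                        dt = 0.01, dz = 0.5), class = "dispfit")
  r <- simulate(tru, nsim = 1e5, seed = 4)
  fc <- fit_displacements(r, dt = 0.01, K = 3, dz = 0.5, method = "cdf")
  fm <- fit_displacements(r, dt = 0.01, K = 3, dz = 0.5, method = "mle")
  expect_true(all(abs(fc$D / fm$D - 1) < 0.05))
})

test_that("degenerate all-zero input collapses to one immobile component", {
  fit <- suppressWarnings(fit_displacements(rep(0, 1000), dt = 0.01, K = 3))
  expect_true(fit$degenerate)
  expect_equal(fit$f, 1)
  expect_lt(fit$D, 1e-5)
})

test_that("BIC selects the generating component count", {
  r1 <- simulate(structure(list(f = 1, D = 1, dt = 0.01, dz = Inf),
                           class = "dispfit"), nsim = 2e4, seed = 3)
  expect_equal(select_k_bic(r1, dt = 0.01, dz = Inf, k_max = 3)$K, 1)
  tru <- structure(list(f = c(0.35, 0.40, 0.25), D = c(0.08, 1, 5),
                        dt = 0.01, dz = 0.5), class = "dispfit")
  r3 <- simulate(tru, nsim = 2e4, seed = 5)
  expect_equal(select_k_bic(r3, dt = 0.01, dz = 0.5, k_max = 4)$K, 3)
  tiny <- select_k_bic(r3[1:50], dt = 0.01, dz = 0.5, k_max = 2)
  expect_true(tiny$low_confidence)
})

test_that("BIC selection is consistent across seeded replicates", {
  # well-separated two-component mixture, n = 2e4 per replicate
  tru <- structure(list(f = c(0.4, 0.6), D = c(0.05, 5), dt = 0.01, dz = Inf),
                   class = "dispfit")
  hits <- vapply(1:20, function(s) {
    r <- simulate(tru, nsim = 2e4, seed = 100 + s)
    select_k_bic(r, dt = 0.01, dz = Inf, k_max = 3, n_starts = 3,
                 seed = s)$K == 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("condition comparison applies KS tests with Bonferroni capping", {
  set.seed(9)
  mk <- function(shift) data.frame(D_bound = rnorm(20, 0.08, 0.01),
                                   D_slow = rnorm(20, 1, 0.1),
                                   D_fast = rnorm(20, 5, 0.5),
                                   f_bound = rnorm(20, 0.35 + shift, 0.02),
                                   f_slow = rnorm(20, 0.40 - shift, 0.02))
  a <- mk(0)
  same <- compare_conditions(a, a)
  expect_true(all(same$p_adj == 1))
  b <- mk(0.3)  # disjoint f distributions
  diff <- compare_conditions(a, b)
  expect_lt(diff$p_adj[diff$parameter == "f_bound"], 0.01)
  expect_true(all(diff$p_adj <= 1))
  kr <- compare_conditions(a, b, test = "kruskal")
  expect_lt(kr$p_adj[kr$parameter == "f_bound"], 0.01)
  expect_error(compare_conditions(a[1, ], b), "2 cells")
})

test_that("simulate/predict/coef methods are mutually consistent", {
  tru <- structure(list(f = c(0.5, 0.5), D = c(0.1, 2), dt = 0.01, dz = Inf),
                   class = "dispfit")
  r <- simulate(tru, nsim = 5e4, seed = 6)
  fit <- fit_displacements(r, dt = 0.01, K = 2, dz = Inf, method = "mle")
  cf <- coef(fit)
  expect_named(cf, c("f_comp1", "f_comp2", "D_comp1", "D_comp2"))
  # model CDF matches the empirical CDF it was fitted to
  rs <- sort(r)
  expect_lt(max(abs(predict(fit, rs, type = "cdf") - seq_along(rs) / length(rs))),
            0.01)
  expect_s3_class(logLik(fit), "logLik")
})
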
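# Diffusion-state HMM segmentation and bound filtering.

test_that("single-state tracks give a degenerate one-state model", {
  pr <- sim_preset(D = 1, f = 1, A = matrix(1, 1, 1), loc_sigma = 0,
                   dt = 0.01, dz = 1e6, n_tracks = 200, n_frames = 30, seed = 1)
  tr <- simulate_tracks(flat_phantom(), pr)
  m <- fit_hmm(tr, dt = 0.01, K = 1, min_len = 8, n_restarts = 2)
  expect_equal(m$D, 1, tolerance = 0.05)
  expect_equal(unname(m$A), matrix(1, 1, 1), ignore_attr = TRUE)
  lab <- segment_tracks(tr, m)
  expect_true(all(lab$state == 1))
})

test_that("two-state transition matrix is recovered within 0.05", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  pr <- sim_preset(D = c(0.05, 2), f = c(0.5, 0.5), A = A, loc_sigma = 0,
                   dt = 0.01, dz = 1e6, n_tracks = 800, n_frames = 40, seed = 5)
  tr <- simulate_tracks(flat_phantom(), pr)
  d <- track_displacements(tr)
  expect_gte(nrow(d), 2e4)
  m <- fit_hmm(tr, dt = 0.01, K = 2, min_len = 8, n_restarts = 5)
  expect_true(all(abs(m$A - A) < 0.05))
  expect_equal(m$D, c(0.05, 2), tolerance = 0.1)
})

test_that("EM log-likelihood is non-decreasing", {
  m <- p53_hmm()
  tr <- m$trace
  expect_true(all(diff(tr) > -1e-6 * (abs(tr[-1]) + 1)))
})

test_that("three-state fit recovers ascending D within 20%", {
  m <- p53_hmm()
  D_app <- c(0.035^2 / 0.01, 1.0, 5.0)  # bound state sits at the noise floor
  expect_true(all(diff(m$D) > 0))
  expect_true(all(abs(m$D / D_app - 1) < 0.2))
})

test_that("stationary distribution of the fitted chain matches occupancy", {
  m <- p53_hmm()
  d <- track_displacements(p53_sim())
  occ <- tabulate(d$state_true, 3) / nrow(d)
  statio <- transition_summary(m)$stationary
  expect_true(all(abs(statio - occ) < 0.05))
})

test_that("Viterbi labels are accurate on well-separated states", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  pr <- sim_preset(D = c(0.05, 2), f = c(0.5, 0.5), A = A, loc_sigma = 0,
                   dt = 0.01, dz = 1e6, n_tracks = 300, n_frames = 40, seed = 6)
  tr <- simulate_tracks(flat_phantom(), pr)
  m <- fit_hmm(tr, dt = 0.01, K = 2, min_len = 8, n_restarts = 5)
  lab <- segment_tracks(tr, m)
  d <- track_displacements(lab)
  expect_gt(mean(d$state == d$state_true), 0.9)
  # posterior column present and in [0, 1]
  expect_true(all(lab$p_bound >= 0 & lab$p_bound <= 1))
})

test_that("transition summary reports the slow/fast binding ratio", {
  m <- p53_hmm()
  ts <- transition_summary(m)
  expect_equal(ts$A, m$A)
  expect_equal(ts$slow_to_bound_over_fast_to_bound, m$A[2, 1] / m$A[3, 1])
  # arithmetic on a hand-built model
  m2 <- m; m2$A <- rbind(c(0.9, 0.09, 0.01), c(0.10, 0.85, 0.05),
                         c(0.01, 0.09, 0.90))
  expect_equal(transition_summary(m2)$slow_to_bound_over_fast_to_bound, 10)
  # undefined for K = 2
  mk2 <- structure(list(K = 2L, D = c(0.1, 1), pi = c(0.5, 0.5),
                        A = matrix(0.5, 2, 2), dt = 0.01), class = "diffhmm")
  expect_true(is.na(transition_summary(mk2)$slow_to_bound_over_fast_to_bound))
})

test_that("filter_bound splits at bound displacements and keeps usable segments", {
  # hand-built labelled track: D-D-B-B-D-D-D pattern of displacements
  tr <- data.frame(track_id = 1, frame = 0:7,
                   x_um = cumsum(c(0, 1, 1, 0, 0, 1, 1, 1)),
                   y_um = 0,
                   state = c(2, 2, 1, 1, 2, 2, 2, 2))
  seg <- filter_bound(tr, max_p_bound = 1)
  expect_equal(length(unique(seg$track_id)), 2)
  expect_equal(unname(table(seg$track_id)), c(3L, 4L), ignore_attr = TRUE)
  # all bound -> empty
  allb <- transform(tr, state = 1)
  expect_equal(nrow(filter_bound(allb, max_p_bound = 1)), 0)
  # no bound labels -> single segment identical coordinates
  nob <- transform(tr, state = 3)
  seg2 <- filter_bound(nob, max_p_bound = 1)
  expect_equal(nrow(seg2), 8)
  expect_equal(seg2$x_um, tr$x_um)
})

test_that("residual bound fraction is computed over retained displacements", {
  seg <- data.frame(track_id = rep(1:2, each = 4), frame = rep(0:3, 2),
                    x_um = 0, y_um = 0,
                    state_true = c(2, 2, 1, 2, 3, 3, 3, 3))
  # displacements: track 1 -> truth (2, 2, 1); track 2 -> (3, 3, 3)
  expect_equal(residual_bound_fraction(seg), 1 / 6)
  expect_equal(residual_bound_fraction(seg[seg$track_id == 2, ]), 0)
})

test_that("bound filtering keeps the diffusing set clean on the three-state preset", {
  tr <- p53_sim()
  m <- p53_hmm()
  elig <- tr[stats::ave(tr$track_id, tr$track_id, FUN = length) >= 8, ]
  seg <- filter_bound(segment_tracks(elig, m))
  rb <- residual_bound_fraction(seg)
  expect_lte(rb, 0.05)
  # filtering keeps a usable amount of data
  expect_gt(nrow(seg), 0.2 * nrow(elig))
})

test_that("short tracks are rejected from fitting with an informative error", {
  tr <- data.frame(track_id = rep(1:5, each = 3), frame = rep(0:2, 5),
                   x_um = rnorm(15), y_um = rnorm(15))
  expect_error(fit_hmm(tr, dt = 0.01, K = 2, min_len = 8), "8")
})
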
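# Mapping classified molecules onto the DNA-density reference frame.

test_that("instantaneous D implements r^2 / (4 dt)", {
  expect_equal(instantaneous_D(0, 0.01), 0)
  expect_equal(instantaneous_D(0.2, 0.01), 1)
  expect_equal(instantaneous_D(1, 0.01), 25)
  expect_error(instantaneous_D(-1, 0.01), "r")
})

test_that("density classes behave at known positions", {
  ph <- cd_phantom(); map <- cd_map()
  expect_true(all(density_class_at(ph$cd_centers, map) == 4))
  pos <- uniform_positions(map, 20000, seed = 1)
  cl <- density_class_at(pos, map)
  expect_true(all(abs(tabulate(cl, 4) / length(cl) - 0.25) < 0.02))
  # positions outside the mask are dropped and counted
  far <- rbind(c(-5, -5), c(0, 0))
  cl2 <- density_class_at(far, map)
  expect_equal(length(cl2), 0)
  expect_equal(attr(cl2, "n_dropped"), 2)
})

test_that("mobility heatmap rows are normalized and flat for a uniform tracer", {
  map <- density_map(matrix(1, 256, 256), cd_phantom()$mask, 0.1)
  pos <- uniform_positions(map, 3e4, seed = 2)
  set.seed(3)
  disp <- data.frame(x_um = pos[, 1], y_um = pos[, 2],
                     r_um = sqrt(-4 * 1 * 0.01 * log(runif(3e4))))
  hm <- dinst_density_heatmap(disp, map, dt = 0.01)
  used <- setdiff(seq_len(nrow(hm)), attr(hm, "empty_rows"))
  expect_true(all(abs(rowSums(hm[used, , drop = FALSE]) - 1) < 1e-12))
  big <- used[rowSums(hm[used, , drop = FALSE] > 0) == 4]
  expect_true(all(abs(hm[big, ] - 0.25) < 0.15))
})

test_that("density-coupled binding shows slow molecules in dense classes", {
  tr <- p53_sim()
  d <- track_displacements(tr)
  hm <- dinst_density_heatmap(d, cd_map(), dt = 0.01)
  breaks <- attr(hm, "dinst_breaks")
  slow_rows <- which(breaks[-length(breaks)] < 0.5)
  fast_rows <- which(breaks[-length(breaks)] >= 2 & breaks[-length(breaks)] < 20)
  # slow displacements occupy the densest class more than fast ones
  expect_gt(mean(hm[slow_rows, 4][rowSums(hm[slow_rows, ]) > 0]),
            mean(hm[fast_rows, 4][rowSums(hm[fast_rows, ]) > 0]))
})

test_that("enrichment score is zero for uniform sampling and positive under coupling", {
  map <- cd_map()
  pos <- uniform_positions(map, 2e4, seed = 4)
  ep <- enrichment_profile(pos, map)
  expect_lt(abs(ep$score), 0.02)
  expect_equal(sum(ep$freq), 1, tolerance = 1e-12)
  # frequencies concentrated in the top class give score 1
  idx4 <- which(map$quartile_labels == 4, arr.ind = TRUE)
  top <- cbind((idx4[1:500, 2] - 1) * 0.1, (idx4[1:500, 1] - 1) * 0.1)
  expect_equal(enrichment_profile(top, map)$score, 1)
  # bound-coupled simulation is enriched in dense chromatin
  d <- track_displacements(p53_sim())
  ep_b <- enrichment_profile(d[d$state_true == 1, ], map)
  expect_gt(ep_b$score, 0)
})

test_that("enrichment correlates with bound fraction across synthetic factors", {
  tab <- data.frame(enrichment = c(0.1, 0.2, 0.3, 0.4),
                    bound_fraction = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(correlate_enrichment_vs_boundfraction(tab)$r, 1)
  tab$bound_fraction <- rev(tab$bound_fraction)
  expect_equal(correlate_enrichment_vs_boundfraction(tab)$r, -1)
  two <- correlate_enrichment_vs_boundfraction(tab[1:2, ])
  expect_true(is.na(two$p))
})

test_that("radial profile of a uniform map is 1 at all radii", {
  mask <- cd_phantom()$mask
  map <- density_map(matrix(1, 256, 256), mask, 0.1)
  pos <- uniform_positions(map, 500, seed = 5)
  rp <- radial_density_profile(list(state = pos), map, window_um = 1.0)
  expect_equal(rp$state$radii_um[1], 0)
  expect_true(all(abs(rp$state$mean - 1) < 1e-12))
})

test_that("radial profiles resolve dense domains vs interchromatin channels", {
  ph <- cd_phantom(); map <- cd_map()
  rp_cd <- radial_density_profile(list(cd = ph$cd_centers), map, window_um = 1.0)
  expect_gt(rp_cd$cd$mean[1], 1)
  expect_true(all(diff(rp_cd$cd$mean) < 0))  # decreasing outward
  # positions in the most DNA-poor class: below-average center, rising outward
  idx1 <- which(map$quartile_labels == 1, arr.ind = TRUE)
  set.seed(6)
  pick <- idx1[sample(nrow(idx1), 800), ]
  ic <- cbind((pick[, 2] - 1) * 0.1, (pick[, 1] - 1) * 0.1)
  rp_ic <- radial_density_profile(list(ic = ic), map, window_um = 1.0)
  expect_lt(rp_ic$ic$mean[1], 1)
  expect_gt(rp_ic$ic$mean[length(rp_ic$ic$mean)], rp_ic$ic$mean[1])
})

test_that("state-resolved radial profiles order bound > slow > fast at the center", {
  tr <- p53_sim()
  d <- track_displacements(tr)
  by_state <- split(d[, c("x_um", "y_um")], d$state_true)
  names(by_state) <- c("bound", "slow", "fast")
  rp <- radial_density_profile(by_state, cd_map(), window_um = 1.0)
  expect_gt(rp$bound$mean[1], rp$slow$mean[1])
  expect_gt(rp$slow$mean[1], rp$fast$mean[1])
  expect_gt(rp$bound$mean[1], 1)
  expect_lt(rp$bound$center_t_p, 0.05)
})

test_that("pair cross-correlation normalizes to 1 for uniform points", {
  map <- cd_map()
  bc <- uniform_positions(map, 300, seed = 7)
  dp <- uniform_positions(map, 4000, seed = 8)
  g <- pair_cross_correlation(bc, dp, map, n_rand = 20, seed = 9)
  mid <- g$bin_center_um > 0.2 & g$bin_center_um < 1.5
  expect_true(all(abs(g$g[mid] - 1) < 0.1))
  expect_error(pair_cross_correlation(bc[0, ], dp, map), "bound")
})

test_that("clustered diffusing molecules show short-range correlation", {
  map <- cd_map()
  bc <- uniform_positions(map, 200, seed = 10)
  set.seed(11)
  near <- bc[sample(200, 3000, replace = TRUE), ] +
    matrix(runif(6000, -0.05, 0.05), ncol = 2)
  g <- pair_cross_correlation(bc, near, map, n_rand = 20, seed = 12)
  expect_gt(g$g[1], 5)
})

test_that("randomly relabelled states collapse the correlation to the null", {
  # null control: uncoupled simulation, one position per molecule (so no
  # within-track adjacency), labels randomly permuted -> no co-clustering
  map <- cd_map()
  pr <- preset_p53like(n_tracks = 6000, n_frames = 50, seed = 15,
                       density_coupling = c(0, 0, 0))
  d <- track_displacements(simulate_tracks(cd_phantom(), pr))
  d <- d[!duplicated(d$track_id), ]
  set.seed(13)
  lab <- sample(d$state_true)
  g <- pair_cross_correlation(d[lab == 1, c("x_um", "y_um")],
                              d[lab != 1, c("x_um", "y_um")],
                              map, n_rand = 20, seed = 14)
  mid <- g$bin_center_um > 0.1 & g$bin_center_um < 1.5
  expect_true(all(abs(g$g[mid] - 1) < 0.15))
})

test_that("track registration shifts coordinates and rejects NaN offsets", {
  tr <- data.frame(track_id = 1, frame = 0:1, x_um = c(1, 2), y_um = c(3, 4))
  expect_equal(register_tracks_to_map(tr), tr)
  sh <- register_tracks_to_map(tr, c(0.1, 0))
  expect_equal(sh$x_um, tr$x_um + 0.1)
  expect_equal(sh$y_um, tr$y_um)
  expect_error(register_tracks_to_map(tr, c(NaN, 0)), "finite")
})
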
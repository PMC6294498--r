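test_that("weighted CSP matches its closed forms and metric properties", {
  expect_equal(weighted_csp(8.12, 121.4, 8.12, 121.4), 0)
  # (dH, dN) = (0.1, 0.5): 0.25/25 + 0.01 = 0.02; /2 = 0.01; sqrt = 0.1
  expect_equal(weighted_csp(8.22, 121.9, 8.12, 121.4), 0.1)
  expect_equal(weighted_csp(8, 122.4, 8, 121.4), 1 / (5 * sqrt(2)))
  expect_error(weighted_csp(NA, 1, 1, 1), "finite")

  # scaling laws over a grid, to 1e-12
  x <- seq(0.01, 1, length.out = 34)
  expect_equal(weighted_csp(x, 0, 0, 0), x / sqrt(2), tolerance = 1e-12)
  expect_equal(weighted_csp(0, x, 0, 0), x / (5 * sqrt(2)), tolerance = 1e-12)

  # triangle-like bound: csp(a,c) <= csp(a,b) + csp(b,c)
  set.seed(1)
  for (k in 1:50) {
    p <- matrix(rnorm(6, c(8, 120), c(0.5, 3)), 3, 2, byrow = TRUE)
    ac <- weighted_csp(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    ab <- weighted_csp(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    bc <- weighted_csp(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_lte(ac, ab + bc + 1e-12)
  }
})

test_that("tracking reproduces noiseless trajectories exactly", {
  sim <- make_fast_sim(kd = 3.5, n = 12, seed = 42)
  tr <- track_peaks(sim$series, max_step = 0.1)
  expect_length(tr, 12L)
  for (r in seq_along(tr)) {
    expect_true(all(tr[[r]]$observed))
    expect_equal(tr[[r]]$shift_H, unname(sim$truth$obs_H[r, ]))
    expect_equal(tr[[r]]$shift_N, unname(sim$truth$obs_N[r, ]))
  }
  pr <- compute_profiles(tr)
  expect_lt(max(abs(pr$csp - sim$truth$csp_noiseless)), 1e-9)
})

test_that("a removed peak leaves a gap and relinks from the last position", {
  # static residue present at points 0,1,2,4 but absent at 3
  H <- rbind(c(8.00, 8.01, 8.02, NA, 8.03))
  N <- rbind(c(120.0, 120.0, 120.0, NA, 120.0))
  ser <- make_manual_series(H, N)
  tr <- track_peaks(ser, max_step = 0.04)
  expect_identical(tr[[1]]$observed, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(tr[[1]]$shift_H[5], 8.03)
  # relinking anchored at point 2's position: a point-4 peak farther than
  # max_step from it stays missing
  H2 <- rbind(c(8.00, 8.01, 8.02, NA, 8.20))
  tr2 <- track_peaks(make_manual_series(H2, N), max_step = 0.04)
  expect_identical(tr2[[1]]$observed, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("link conflicts resolve by distance, intensity ratio, then id", {
  # two assigned residues, one point-1 peak exactly midway between them:
  # equal distances, so the intensity ratio closest to 1 decides
  mk <- function(i0_1, i0_2, i_peak) {
    pts <- list(
      cspfit:::new_titration_point(0L, 100, 0, cspfit:::new_peak_list(
        c("A1N-H", "A2N-H"), c(1L, 2L), c(8.00, 8.04), c(120, 120),
        c(i0_1, i0_2), 0L)),
      cspfit:::new_titration_point(1L, 100, 50, cspfit:::new_peak_list(
        "?-?", NA_integer_, 8.02, 120, i_peak, 1L)))
    titration_series(pts)
  }
  tr <- track_peaks(mk(1e6, 2e6, 1e6), max_step = 0.05)
  expect_true(tr[[1]]$observed[2])    # ratio 1 beats ratio 0.5
  expect_false(tr[[2]]$observed[2])

  tr2 <- track_peaks(mk(2e6, 1e6, 1e6), max_step = 0.05)
  expect_false(tr2[[1]]$observed[2])
  expect_true(tr2[[2]]$observed[2])

  # equal distances and equal ratios: lower residue id wins, and the
  # outcome is identical across runs
  tr3 <- track_peaks(mk(1e6, 1e6, 1e6), max_step = 0.05)
  expect_true(tr3[[1]]$observed[2])
  expect_false(tr3[[2]]$observed[2])
  expect_identical(tr3, track_peaks(mk(1e6, 1e6, 1e6), max_step = 0.05))
})

test_that("saturation reflects the movement of the last two observed states", {
  H <- rbind(c(8.00, 8.10, 8.10))
  N <- rbind(c(120, 120, 120))
  ser <- make_manual_series(H, N)
  tr <- track_peaks(ser, max_step = 0.2)
  expect_true(check_saturation(tr[[1]], tol = 0.005))

  H2 <- rbind(c(8.00, 8.05, 8.10))
  tr2 <- track_peaks(make_manual_series(H2, N), max_step = 0.2)
  expect_false(check_saturation(tr2[[1]], tol = 0.005))

  # a titration pushed to 10x K_D excess saturates at 0.005 ppm
  spec <- synthetic_titration_spec(2, 100, c(0, 50, 100, 200, 400, 1000,
                                             2000),
                                   noise_sd_H = 0, noise_sd_N = 0, seed = 8)
  sim <- simulate_titration(spec, fast_residue_set(spec, n = 5))
  tr3 <- track_peaks(sim$series, max_step = 0.2)
  for (r in seq_along(tr3))
    expect_true(check_saturation(tr3[[r]], tol = 0.005))
})

test_that("profiles encode per-point CSPs, endpoints and saturation flags", {
  # static trajectory: all-zero CSPs, fast regime
  H <- rbind(rep(8, 5)); N <- rbind(rep(120, 5))
  pr <- compute_profiles(track_peaks(make_manual_series(H, N)))
  expect_equal(unname(pr$csp[1, ]), rep(0, 5))
  expect_equal(pr$csp_max_observed, 0)
  expect_identical(pr$regime, "fast")

  # monotone noiseless trajectory: non-decreasing CSPs
  sim <- make_fast_sim(n = 6, seed = 13)
  prs <- compute_profiles(track_peaks(sim$series, max_step = 0.1))
  for (r in 1:6) expect_true(all(diff(prs$csp[r, ]) >= -1e-12))

  # missing final point: endpoint taken at last observed, saturated FALSE
  H3 <- rbind(c(8.00, 8.03, 8.05, NA))
  N3 <- rbind(c(120, 120, 120, NA))
  pr3 <- compute_profiles(track_peaks(make_manual_series(H3, N3),
                                      max_step = 0.1))
  expect_equal(pr3$csp_max_observed, weighted_csp(8.05, 120, 8.00, 120))
  expect_false(pr3$saturated)
})

test_that("exchange classification recovers simulator regimes", {
  spec <- synthetic_titration_spec(50, 100, default_schedule(), seed = 7)
  for (ratio in c(50, 1, 0.1)) {
    res <- regime_fixture_residues(spec, n = 24, target_ratio = ratio)
    sim <- simulate_titration(spec, res)
    pr <- compute_profiles(track_peaks(sim$series, max_step = 0.1))
    truth <- unname(sim$truth$regime_final)
    expect_gte(mean(pr$regime == truth), 0.95)
  }
  # a static constant-intensity trajectory is fast exchange (no binding)
  H <- rbind(rep(8, 5)); N <- rbind(rep(120, 5))
  tr <- track_peaks(make_manual_series(H, N))
  expect_identical(classify_exchange(tr[[1]]), "fast")
  # too few titration points is an error
  H2 <- rbind(rep(8, 2)); N2 <- rbind(rep(120, 2))
  tr2 <- track_peaks(make_manual_series(H2, N2))
  expect_error(classify_exchange(tr2[[1]]), "too few")
})
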
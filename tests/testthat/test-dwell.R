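test_that("apparent-rate fitting is the exponential MLE", {
  # all residence times equal to c: k_app = 1/c
  dw <- tibble::tibble(tau_tl_s = 1.2, tau_int_s = 0.2,
                       n_frames = rep(3L, 50))
  fit <- fit_apparent_rate(dw)
  expect_equal(fit$k_app, 1 / 2.4, tolerance = 1e-12)  # tau = (3-1)*1.2

  # continuous draws from Exp(0.5): MLE consistent within 3 s.e.
  set.seed(1)
  tau <- stats::rexp(10000, 0.5)
  dwc <- tibble::tibble(tau_tl_s = 1, tau_int_s = 0.2, n_frames = 1 + tau)
  fitc <- fit_apparent_rate(dwc)
  expect_lt(abs(fitc$k_app - 0.5), 3 * fitc$se)

  # single-frame-only data has no measurable dwell
  expect_error(fit_apparent_rate(tibble::tibble(tau_tl_s = 1, tau_int_s = 0.2,
                                                n_frames = rep(1L, 50))),
               ">= 10")
})

test_that("mean dwell time is exactly the reciprocal rate", {
  for (k in c(0.236, 0.26, 0.454, 0.269)) {
    expect_equal(mean_dwell_time(k) * k, 1, tolerance = 1e-14)
  }
  expect_error(mean_dwell_time(0), "> 0")
})

test_that("noiseless two-term inputs are recovered exactly", {
  # k_app(tau_TL) = k_d + k_b * tau_int / tau_TL is an algebraic identity of
  # the regression; constant dwell times make each per-interval fit exact
  k_d <- 0.3; k_b <- 1.4; tau_int <- 0.2
  tls <- c(0.2, 0.5, 1.0, 2.0)
  dw <- purrr::map_dfr(tls, function(tl) {
    k_app <- k_d + k_b * tau_int / tl
    m <- round(1 / (k_app * tl))  # integer frame count with tau = 1/k_app
    tibble::tibble(tau_tl_s = tl, tau_int_s = tau_int,
                   n_frames = rep(1 + 1 / (k_app * tl), 20))
  })
  fit <- fit_dissociation(dw)
  expect_equal(fit$k_diss, k_d, tolerance = 1e-9)
  expect_equal(fit$k_bleaching, k_b, tolerance = 1e-9)
  expect_equal(fit$mean_dwell * fit$k_diss, 1, tolerance = 1e-12)
})

test_that("simulated time-lapse data recovers both rates", {
  cfg <- timelapse_config(tau_int = 0.2, tau_delays = c(0, 0.3, 0.8, 1.8, 3.8),
                          k_diss_true = 0.26, k_bleach_true = 1.5,
                          n_molecules = 10000, seed = 2)
  fit <- fit_dissociation(simulate_timelapse_dwells(cfg), method = "geometric")
  expect_lt(abs(fit$k_diss - 0.26), 3 * fit$k_diss_se)
  expect_lt(abs(fit$k_bleaching - 1.5), 3 * fit$k_bleaching_se)
  # implied mean dwell near 1/0.26 = 3.85 s
  expect_equal(fit$mean_dwell, 1 / fit$k_diss, tolerance = 1e-12)
  expect_lt(abs(fit$mean_dwell - 3.85), 0.4)

  # no photobleaching: intercept at zero, k_app constant across delays
  cfg0 <- timelapse_config(tau_int = 0.2, tau_delays = c(0, 0.8, 1.8),
                           k_diss_true = 0.4, k_bleach_true = 0,
                           n_molecules = 10000, seed = 3)
  fit0 <- fit_dissociation(simulate_timelapse_dwells(cfg0),
                           method = "geometric")
  expect_lt(abs(fit0$k_bleaching), 3 * fit0$k_bleaching_se)
  spread <- diff(range(fit0$per_interval$k_app))
  expect_lt(spread, 6 * max(fit0$per_interval$se))

  # fewer than two intervals is an error
  one <- simulate_timelapse_dwells(timelapse_config(tau_delays = 0.5,
                                                    n_molecules = 100,
                                                    seed = 4))
  expect_error(fit_dissociation(one), ">= 2 distinct")
})

test_that("k_diss is insensitive to a shared photobleaching offset", {
  # adding a constant to every interval's bleaching contribution moves the
  # intercept, not the slope
  k_d <- 0.3; tau_int <- 0.2
  tls <- c(0.3, 0.6, 1.2, 2.4)
  build <- function(k_b) purrr::map_dfr(tls, function(tl) {
    k_app <- k_d + k_b * tau_int / tl
    tibble::tibble(tau_tl_s = tl, tau_int_s = tau_int,
                   n_frames = rep(1 + 1 / (k_app * tl), 20))
  })
  f1 <- fit_dissociation(build(0.8))
  f2 <- fit_dissociation(build(1.8))
  expect_equal(f1$k_diss, f2$k_diss, tolerance = 1e-9)
  expect_equal(f2$k_bleaching - f1$k_bleaching, 1.0, tolerance = 1e-9)
})

test_that("stationary dwell detection segments runs correctly", {
  roi <- tibble::tibble(cell_id = 1L, cx_um = 0, cy_um = 0, r_um = 1)
  # immobile noiseless track of 7 frames
  still <- trajectory_set(tibble::tibble(track_id = 1L, frame = 0:6,
                                         x_um = 0.1, y_um = 0.1,
                                         cell_id = 1L),
                          roi, 0.04, 0.01)
  dw <- detect_stationary_dwells(still, r_stat = 0.05)
  expect_identical(dw$n_frames, 7L)
  expect_identical(dw$tau_tl_s, 0.04)

  # displacement far beyond r_stat: every run has a single frame
  fast <- trajectory_set(tibble::tibble(track_id = 1L, frame = 0:6,
                                        x_um = seq(0, 0.9, length.out = 7),
                                        y_um = 0, cell_id = 1L),
                         roi, 0.04, 0.01)
  dwf <- detect_stationary_dwells(fast, r_stat = 0.05)
  expect_true(all(dwf$n_frames == 1L))
  expect_error(detect_stationary_dwells(still, r_stat = 0), "> 0")
})

test_that("slow-state dwell rate is recovered from a mixed simulation", {
  # stationary bound state (D = 0) with sigma_loc well below r_stat, and a
  # fast state whose steps rarely fall under the stationarity radius
  T2 <- matrix(c(0.95, 0.05, 0.3, 0.7), 2, 2, byrow = TRUE)
  ts <- simulate_trajectories(sim_config(K = 2, D = c(0, 0.5),
                                         T_frame = T2, sigma_loc = 0.005,
                                         p_bleach = 0.02, n_tracks = 800,
                                         min_len = 3, seed = 6))
  dw <- detect_stationary_dwells(ts, r_stat = 0.05)
  fit <- fit_apparent_rate(dw, method = "geometric")
  # ground-truth slow-state run-termination rate: leave the slow state or
  # bleach, measured on the simulated labels
  st <- ts$locs |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(runs = list(rle(state)), .groups = "drop")
  lens <- unlist(lapply(st$runs, function(r) r$lengths[r$values == 1]))
  truth_fit <- fit_apparent_rate(tibble::tibble(tau_tl_s = 0.04,
                                                tau_int_s = 0.04,
                                                n_frames = lens),
                                 method = "geometric")
  expect_lt(abs(fit$k_app / truth_fit$k_app - 1), 0.10)
})
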
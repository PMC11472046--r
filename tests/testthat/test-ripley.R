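test_that("K and H match hand-computed configurations", {
  roi <- list(cx_um = 0, cy_um = 0, r_um = 1)
  # two points at distance d: K = 0 for r < d (strict inequality)
  pp2 <- point_pattern(tibble::tibble(x_um = c(-0.1, 0.1), y_um = 0), roi)
  expect_identical(ripley_K(pp2, c(0.1, 0.2), edge_correction = FALSE)$K,
                   c(0, 0))
  # ... and counts the pair beyond d
  expect_gt(ripley_K(pp2, 0.25, edge_correction = FALSE)$K, 0)
  # at r exactly d the strict inequality still excludes the pair
  expect_identical(ripley_K(pp2, 0.2, edge_correction = FALSE)$K, 0)

  # n coincident points: K(r) = (n - 1) / lambda for every r > 0
  ppc <- point_pattern(tibble::tibble(x_um = rep(0.1, 6), y_um = rep(0.2, 6)),
                       roi)
  Kc <- ripley_K(ppc, c(0.05, 0.4, 0.9))
  expect_equal(Kc$K, rep(5 / ppc$lambda, 3), tolerance = 1e-12)

  # H transforms: K = pi r^2 -> 0; K = 0 -> -r; K = 4 pi at r = 1 -> 1
  r <- c(0.2, 0.5, 1)
  expect_equal(ripley_H(pi * r^2, r)$H, rep(0, 3), tolerance = 1e-12)
  expect_equal(ripley_H(rep(0, 3), r)$H, -r, tolerance = 1e-12)
  expect_equal(ripley_H(4 * pi, 1)$H, 1, tolerance = 1e-12)

  # radii beyond the window diameter are flagged
  expect_false(ripley_K(pp2, 2.5)$reliable)
})

test_that("uncorrected K equals a brute-force double loop", {
  pp <- csr_pattern(n = 20, seed = 3)
  r_grid <- c(0.2, 0.6, 1.1)
  K <- ripley_K(pp, r_grid, edge_correction = FALSE)$K
  pts <- pp$points
  brute <- vapply(r_grid, function(r) {
    acc <- 0
    for (i in 1:20) for (j in 1:20) {
      if (i != j &&
          sqrt((pts$x_um[i] - pts$x_um[j])^2 +
                 (pts$y_um[i] - pts$y_um[j])^2) < r) acc <- acc + 1
    }
    acc / (pp$lambda * pp$n)
  }, numeric(1))
  expect_identical(K, brute)
})

test_that("edge-corrected K is unbiased under CSR; uncorrected is biased low", {
  r_grid <- seq(0.1, 0.5, by = 0.1)
  Ks <- sapply(1:100, function(s) ripley_K(csr_pattern(500, seed = s),
                                           r_grid)$K)
  rel <- rowMeans(Ks) / (pi * r_grid^2) - 1
  expect_true(all(abs(rel) < 0.02))
  Ku <- sapply(1:40, function(s) ripley_K(csr_pattern(500, seed = s), 0.5,
                                          edge_correction = FALSE)$K)
  expect_lt(mean(Ku) / (pi * 0.25) - 1, -0.1)
})

test_that("cell aggregation is a normalized weighted mean", {
  h <- tibble::tibble(cell_id = rep(1:2, each = 2), r_um = rep(c(0.1, 0.2), 2),
                      H = c(0, 0, 4, 4))
  # single cell: identity
  one <- aggregate_cells(h[h$cell_id == 1, ], c(`1` = 2))
  expect_equal(one$H, c(0, 0))
  # equal weights: arithmetic mean
  expect_equal(aggregate_cells(h, c(`1` = 1, `2` = 1))$H, c(2, 2))
  # weights (1, 3) on curves (0, 4): 3
  expect_equal(aggregate_cells(h, c(`1` = 1, `2` = 3))$H, c(3, 3))
  expect_error(aggregate_cells(h, c(`1` = 0, `2` = 0)), "zero")
})

test_that("normalized H is null for matched data and positive for foci", {
  base <- make_two_state_set(n_tracks = 80, seed = 31)
  # data generated by the matched resampler itself: H_norm inside envelope
  null_data <- resample_matched_trajectories(base, 1, seed = 5)[[1]]
  rg <- ripley_r_grid(0.5, 10)
  rn <- normalized_H(null_data, labels = 1L, r_grid = rg, n_reps = 15,
                     seed = 9)
  td <- tidy(rn)
  inside <- td$H_data >= td$env_lo & td$H_data <= td$env_hi
  expect_gte(mean(inside), 0.8)

  # localizations concentrated in two 0.1-um foci inside a 1-um nucleus
  set.seed(7)
  centers <- matrix(c(-0.4, 0, 0.4, 0), 2, 2, byrow = TRUE)
  locs <- purrr::map_dfr(1:60, function(i) {
    cc <- centers[(i %% 2) + 1, ]
    tibble::tibble(track_id = i, frame = 0:5,
                   x_um = cc[1] + pmin(pmax(rnorm(6, 0, 0.05), -0.1), 0.1),
                   y_um = cc[2] + pmin(pmax(rnorm(6, 0, 0.05), -0.1), 0.1),
                   cell_id = 1L)
  })
  foci <- trajectory_set(locs, tibble::tibble(cell_id = 1L, cx_um = 0,
                                              cy_um = 0, r_um = 1), 0.04, 0.01)
  rf <- normalized_H(foci, labels = 1L, r_grid = ripley_r_grid(0.4, 8),
                     n_reps = 15, seed = 10)
  tf <- tidy(rf)
  band <- tf$r_um >= 0.1 & tf$r_um <= 0.3
  expect_true(all(tf$H_norm[band] > 0))
  expect_true(all(tf$H_data[band] > tf$env_hi[band]))

  # under-populated states are skipped with a warning
  expect_warning(
    normalized_H(base, labels = c(rep(1L, nrow(track_steps(base)) - 3),
                                  rep(2L, 3)),
                 r_grid = rg, n_reps = 3, seed = 2),
    "skipped")
})

test_that("heatmap rendering conserves mass and normalizes the peak", {
  roi <- tibble::tibble(cell_id = 1L, cx_um = 0, cy_um = 0, r_um = 0.6)
  one <- trajectory_set(tibble::tibble(track_id = 1L, frame = 0:1,
                                       x_um = c(0.1, 0.1), y_um = c(0.2, 0.2),
                                       cell_id = 1L), roi, 0.04, 0.01)
  img <- render_heatmap(one, pixel_um = 0.01, psf_sigma_um = 0.05)
  expect_equal(max(img$z), 1)
  peak <- which(img$z == 1, arr.ind = TRUE)
  expect_lt(abs(img$x_um[peak[1, 1]] - 0.1), 0.011)
  expect_lt(abs(img$y_um[peak[1, 2]] - 0.2), 0.011)
  # total pre-normalization intensity = number of localizations within 0.1%
  expect_lt(abs(img$total_intensity - 2) / 2, 1e-3)

  # two equal, well-separated foci give two equal maxima
  two <- trajectory_set(tibble::tibble(track_id = c(1L, 1L, 2L, 2L),
                                       frame = c(0L, 1L, 0L, 1L),
                                       x_um = c(-0.3, -0.3, 0.3, 0.3),
                                       y_um = 0, cell_id = 1L),
                        roi, 0.04, 0.01)
  img2 <- render_heatmap(two, pixel_um = 0.01, psf_sigma_um = 0.04)
  left <- img2$z[img2$x_um < 0, ]
  right <- img2$z[img2$x_um > 0, ]
  expect_equal(max(left), max(right), tolerance = 1e-9)
  expect_equal(max(left), 1, tolerance = 1e-9)
  expect_error(render_heatmap(one, pixel_um = 0), "> 0")
})
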
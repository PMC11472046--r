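#' Planar point pattern in a circular window
#'
#' @param points tibble/data frame with columns `x_um`, `y_um`.
#' @param roi list or one-row data frame with `cx_um`, `cy_um`, `r_um`.
#' @return object of class `point_pattern` with the point count `n` and the
#'   intensity `lambda = n / area` (1/um^2).
#' @export
point_pattern <- function(points, roi) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x_um", "y_um") %in% names(points)))
  roi <- as.list(roi)
  if (nrow(points) < 2L) stop_sptk("a point pattern needs n >= 2 points")
  d2 <- (points$x_um - roi$cx_um)^2 + (points$y_um - roi$cy_um)^2
  if (any(d2 > roi$r_um^2 * (1 + 1e-9))) {
    stop_sptk("all points must lie inside the ROI circle")
  }
  n <- nrow(points)
  structure(list(points = points, roi = roi, n = n,
                 lambda = n / (pi * roi$r_um^2)),
            class = "point_pattern")
}

#' Default search-radius grid for Ripley statistics
#'
#' @param r_max largest radius, um.
#' @param n_r number of radii.
#' @return numeric vector of radii from 0.025 um to `r_max`.
#' @export
ripley_r_grid <- function(r_max = 1.0, n_r = 40L) {
  seq(0.025, r_max, length.out = n_r)
}

# Fraction of the circle of radius rho centered at distance d from the ROI
# center that lies inside the ROI of radius R (isotropic edge correction).
circle_inside_fraction <- function(rho, d, R) {
  frac <- rep.int(1, length(rho))
  out <- rho > R - d
  if (any(out)) {
    a <- (d[out]^2 + rho[out]^2 - R^2) / (2 * d[out] * rho[out])
    frac[out] <- acos(pmin(1, pmax(-1, a))) / pi
  }
  frac
}

#' Ripley's K function on a circular window
#'
#' Computes `K(r) = lambda^-1 * sum_i sum_{j != i} I(r_ij < r) / n` with the
#' strict inequality, each pair optionally weighted by the isotropic edge
#' correction: the inverse of the fraction of the circle of radius `r_ij`
#' centered at point `i` that lies inside the ROI. Under complete spatial
#' randomness the expectation is `pi * r^2`.
#'
#' @param pattern a [point_pattern()].
#' @param r_grid search radii, um.
#' @param edge_correction apply the isotropic correction (default `TRUE`).
#' @return tibble with columns `r_um`, `K`, and `reliable` (`FALSE` where `r`
#'   exceeds the ROI diameter; values are still computed).
#' @export
ripley_K <- function(pattern, r_grid = ripley_r_grid(),
                     edge_correction = TRUE) {
  stopifnot(inherits(pattern, "point_pattern"))
  p <- pattern$points
  n <- pattern$n
  roi <- pattern$roi
  dm <- as.matrix(stats::dist(cbind(p$x_um, p$y_um)))
  di <- sqrt((p$x_um - roi$cx_um)^2 + (p$y_um - roi$cy_um)^2)
  pair <- which(row(dm) != col(dm))
  rho <- dm[pair]
  w <- if (edge_correction) {
    1 / circle_inside_fraction(rho, di[row(dm)[pair]], roi$r_um)
  } else rep.int(1, length(rho))
  K <- vapply(r_grid, function(r) sum(w[rho < r]), numeric(1)) /
    (pattern$lambda * n)
  tibble::tibble(r_um = r_grid, K = K, reliable = r_grid <= 2 * roi$r_um)
}

#' Ripley's H function
#'
#' `H(r) = sqrt(K(r) / pi) - r`: zero under complete spatial randomness,
#' positive for clustering, negative for dispersion.
#'
#' @param K K-function values (numeric vector, or the tibble returned by
#'   [ripley_K()]).
#' @param r_grid search radii matching `K`.
#' @return tibble with columns `r_um`, `H`.
#' @export
ripley_H <- function(K, r_grid = NULL) {
  if (is.data.frame(K)) {
    r_grid <- K$r_um
    K <- K$K
  }
  if (any(K < 0)) stop_sptk("K must be >= 0")
  tibble::tibble(r_um = r_grid, H = sqrt(K / pi) - r_grid)
}

#' Density-weighted aggregation of per-cell H curves
#'
#' Averages per-cell H curves radius-by-radius, weighting each cell by its
#' localization fit density (weights are normalized to sum to one).
#'
#' @param h_curves tibble with columns `cell_id`, `r_um`, `H`.
#' @param weights named numeric vector (names = cell ids) or a tibble with
#'   columns `cell_id`, `weight`.
#' @return tibble with columns `r_um`, `H`.
#' @export
aggregate_cells <- function(h_curves, weights) {
  if (is.data.frame(weights)) {
    w <- stats::setNames(weights$weight, weights$cell_id)
  } else w <- weights
  if (all(w == 0)) stop_sptk("all cell weights are zero")
  w <- w / sum(w)
  h_curves |>
    dplyr::mutate(w = unname(w[as.character(.data$cell_id)])) |>
    dplyr::summarise(H = sum(.data$H * .data$w) / sum(.data$w),
                     .by = "r_um")
}

# Split a labeled trajectory set into per-state pseudo-trajectory sets: for
# each state, maximal runs of consecutive same-state steps within a track
# become tracks of their own.
state_subset <- function(data, labels, state) {
  steps <- track_steps(data)
  stopifnot(length(labels) == nrow(steps))
  keep <- labels == state
  if (!any(keep)) return(NULL)
  sel <- steps[keep, ]
  sel <- sel |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$frame) != 1L))) |>
    dplyr::ungroup()
  locs <- sel |>
    dplyr::group_split(.data$track_id, .data$run) |>
    purrr::imap_dfr(function(g, i) {
      # a run of m steps spans m + 1 localizations; reconstruct the start
      start <- tibble::tibble(
        track_id = i, frame = g$frame[1L] - 1L,
        x_um = g$x_um[1L] - g$dx_um[1L], y_um = g$y_um[1L] - g$dy_um[1L],
        cell_id = g$cell_id[1L])
      dplyr::bind_rows(start,
                       tibble::tibble(track_id = i, frame = g$frame,
                                      x_um = g$x_um, y_um = g$y_um,
                                      cell_id = g$cell_id))
    })
  trajectory_set(locs, data$rois, data$dt_frame, data$sigma_loc, data$seed)
}

# Density-weighted H curve of one trajectory set's step destinations.
trajectory_H <- function(ts, r_grid) {
  steps <- track_steps(ts)
  cells <- unique(steps$cell_id)
  curves <- purrr::map_dfr(cells, function(cid) {
    pts <- steps[steps$cell_id == cid, c("x_um", "y_um")]
    if (nrow(pts) < 2L) return(NULL)
    roi <- ts$rois[ts$rois$cell_id == cid, ]
    pp <- point_pattern(pts, roi)
    dplyr::mutate(ripley_H(ripley_K(pp, r_grid)), cell_id = cid,
                  weight = pp$lambda)
  })
  if (is.null(curves) || nrow(curves) == 0L) return(NULL)
  w <- curves |> dplyr::distinct(.data$cell_id, .data$weight)
  aggregate_cells(curves[, c("cell_id", "r_um", "H")],
                  stats::setNames(w$weight, w$cell_id))
}

#' Trajectory-matched normalized Ripley H per mobility state
#'
#' Single-molecule steps from one trajectory are spatially correlated, which
#' inflates raw clustering statistics. For each mobility state this function
#' compares the data's density-weighted H curve against `n_reps` replicates
#' generated by [resample_matched_trajectories()] - trajectories with the
#' same ROIs, track-length distribution and empirical step lengths but no
#' spatial preference - and reports `H_norm = H_data - mean(H_sim)` along
#' with the 2.5%/97.5% envelope of the simulated curves.
#'
#' @param data a `trajectory_set`.
#' @param labels per-step state labels (defaults to the ground-truth `state`
#'   column of the steps when present); use a single label for "all steps".
#' @param r_grid search radii, um.
#' @param n_reps number of matched replicates.
#' @param min_points states with fewer step points are skipped with a warning.
#' @param seed integer seed.
#' @return object of class `ripley_result`; `tidy()` returns the per-state
#'   curve table with columns `state`, `r_um`, `H_data`, `H_sim_mean`,
#'   `env_lo`, `env_hi`, `H_norm`.
#' @export
normalized_H <- function(data, labels = NULL, r_grid = ripley_r_grid(),
                         n_reps = 20L, min_points = 10L, seed = 1L) {
  stopifnot(inherits(data, "trajectory_set"))
  steps <- track_steps(data)
  if (is.null(labels)) {
    labels <- if ("state" %in% names(steps)) steps$state
              else rep.int(1L, nrow(steps))
  }
  if (length(labels) == 1L) labels <- rep.int(labels, nrow(steps))
  states <- sort(unique(labels))
  per_state <- purrr::map_dfr(states, function(st) {
    npts <- sum(labels == st)
    if (npts < min_points) {
      warn_sptk("state ", st, " has ", npts, " points (< ", min_points,
                "); skipped")
      return(NULL)
    }
    ts_k <- state_subset(data, labels, st)
    hd <- trajectory_H(ts_k, r_grid)
    reps <- resample_matched_trajectories(ts_k, n_reps,
                                          seed = derive_seed(seed,
                                                             paste0("st", st)))
    hs <- purrr::imap_dfr(reps, function(r, i) {
      dplyr::mutate(trajectory_H(r, r_grid), rep = i)
    })
    env <- hs |>
      dplyr::summarise(H_sim_mean = mean(.data$H),
                       env_lo = stats::quantile(.data$H, 0.025, names = FALSE),
                       env_hi = stats::quantile(.data$H, 0.975, names = FALSE),
                       .by = "r_um")
    dplyr::left_join(hd, env, by = "r_um") |>
      dplyr::mutate(state = st, H_norm = .data$H - .data$H_sim_mean) |>
      dplyr::rename(H_data = "H")
  })
  structure(list(per_state = per_state, r_grid = r_grid, n_reps = n_reps,
                 seed = seed),
            class = "ripley_result")
}

#' @export
print.ripley_result <- function(x, ...) {
  cat("<ripley_result>", length(unique(x$per_state$state)), "state(s),",
      length(x$r_grid), "radii,", x$n_reps, "matched replicates\n")
  invisible(x)
}

#' @export
tidy.ripley_result <- function(x, ...) {
  x$per_state[, c("state", "r_um", "H_data", "H_sim_mean", "env_lo",
                  "env_hi", "H_norm")]
}

#' @export
autoplot.ripley_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_um, .data$H_norm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_lo - .data$H_sim_mean,
                                      ymax = .data$env_hi - .data$H_sim_mean),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~state, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "r (µm)", y = expression(H[norm](r))) +
    ggplot2::theme_minimal()
}

#' Reconstructed localization density heatmap
#'
#' Renders a super-resolution-style density map from localizations: each
#' localization contributes a unit-integral 2-D Gaussian of width
#' `psf_sigma_um` on a grid of pitch `pixel_um`, and the summed image is
#' globally normalized so its maximum equals 1.
#'
#' @param data a `trajectory_set`.
#' @param cell_id cell to render.
#' @param pixel_um grid pitch, um.
#' @param psf_sigma_um rendering kernel width, um.
#' @return object of class `heatmap_image`: matrix `z` (max 1), grid vectors
#'   `x_um`, `y_um`, and `total_intensity` (pre-normalization integral, in
#'   localization counts).
#' @export
render_heatmap <- function(data, cell_id = 1L, pixel_um = 0.02,
                           psf_sigma_um = 0.04) {
  stopifnot(inherits(data, "trajectory_set"))
  if (pixel_um <= 0) stop_sptk("pixel_um must be > 0")
  locs <- data$locs[data$locs$cell_id == cell_id, ]
  if (nrow(locs) < 1L) stop_sptk("no localizations in cell ", cell_id)
  roi <- data$rois[data$rois$cell_id == cell_id, ]
  pad <- 4 * psf_sigma_um
  gx <- seq(roi$cx_um - roi$r_um - pad, roi$cx_um + roi$r_um + pad,
            by = pixel_um)
  gy <- seq(roi$cy_um - roi$r_um - pad, roi$cy_um + roi$r_um + pad,
            by = pixel_um)
  z <- matrix(0, length(gx), length(gy))
  for (i in seq_len(nrow(locs))) {
    z <- z + outer(stats::dnorm(gx, locs$x_um[i], psf_sigma_um),
                   stats::dnorm(gy, locs$y_um[i], psf_sigma_um))
  }
  z <- z * pixel_um^2  # unit integral per localization on the grid
  total <- sum(z)
  structure(list(z = z / max(z), x_um = gx, y_um = gy,
                 total_intensity = total, pixel_um = pixel_um,
                 psf_sigma_um = psf_sigma_um, cell_id = cell_id),
            class = "heatmap_image")
}

#' @export
print.heatmap_image <- function(x, ...) {
  cat("<heatmap_image>", length(x$x_um), "x", length(x$y_um), "px at",
      x$pixel_um, "um/px; total pre-normalization intensity",
      format(x$total_intensity, digits = 6), "\n")
  invisible(x)
}

#' @export
autoplot.heatmap_image <- function(object, ...) {
  df <- expand.grid(x_um = object$x_um, y_um = object$y_um)
  df$z <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "density") +
    ggplot2::theme_minimal()
}
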
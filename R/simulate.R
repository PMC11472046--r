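#' Simulate multi-state confined Brownian trajectories
#'
#' Generates single-molecule tracks under the generative model assumed by the
#' downstream analyses: each molecule carries a hidden mobility state that
#' switches between frames according to a per-frame Markov transition matrix;
#' conditional on the state, each coordinate's displacement over one frame is
#' Gaussian with variance `2 * D_state * dt_frame`; motion is confined to a
#' circular nucleus by rejection-resampling of boundary-crossing steps (which
#' leaves the interior step distribution Gaussian); observed positions add
#' independent Gaussian localization error; and track lengths are geometric,
#' reflecting per-frame photobleaching, truncated below at `min_len`.
#'
#' Initial states are drawn from the stationary distribution of the transition
#' matrix, matching the equilibrium assumption used when rate constants are
#' inferred later. Ground-truth state labels are stored per localization; a
#' step inherits the label of its destination localization.
#'
#' @param config a [sim_config()].
#' @return a [trajectory_set()] with a `state` column of ground-truth labels.
#' @examples
#' ts <- simulate_trajectories(sim_config(K = 1, D = 0.05, n_tracks = 20,
#'                                        seed = 7))
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$K
  pi0 <- stationary_dist(config$T_frame)
  sds <- sqrt(2 * config$D * config$dt_frame)
  rois <- tibble::tibble(
    cell_id = seq_len(config$n_cells),
    cx_um = 4 * config$R_nuc * (seq_len(config$n_cells) - 1),
    cy_um = 0,
    r_um = config$R_nuc
  )
  out <- vector("list", config$n_tracks)
  for (i in seq_len(config$n_tracks)) {
    cell <- ((i - 1L) %% config$n_cells) + 1L
    cx <- rois$cx_um[cell]; cy <- rois$cy_um[cell]; R <- rois$r_um[cell]
    L <- if (config$p_bleach > 0) {
      # geometric length truncated below at min_len: memorylessness makes the
      # truncated draw min_len + geometric
      min(config$min_len + stats::rgeom(1L, config$p_bleach), config$max_len)
    } else config$max_len
    s <- integer(L)
    s[1L] <- sample.int(K, 1L, prob = pi0)
    if (K > 1L) {
      for (t in 2:L) s[t] <- sample.int(K, 1L, prob = config$T_frame[s[t - 1L], ])
    } else s[] <- 1L
    x <- numeric(L); y <- numeric(L)
    if (config$confine) {
      r0 <- R * sqrt(stats::runif(1L)); th0 <- stats::runif(1L, 0, 2 * pi)
      x[1L] <- cx + r0 * cos(th0); y[1L] <- cy + r0 * sin(th0)
      for (t in 2:L) {
        sd_t <- sds[s[t]]
        if (sd_t == 0) { x[t] <- x[t - 1L]; y[t] <- y[t - 1L]; next }
        tries <- 0L
        repeat {
          nx <- x[t - 1L] + stats::rnorm(1L, 0, sd_t)
          ny <- y[t - 1L] + stats::rnorm(1L, 0, sd_t)
          if ((nx - cx)^2 + (ny - cy)^2 <= R^2) break
          tries <- tries + 1L
          if (tries > 10000L) stop_sptk("confinement rejection failed; step ",
                                        "scale too large for R_nuc")
        }
        x[t] <- nx; y[t] <- ny
      }
    } else {
      x[1L] <- cx; y[1L] <- cy
      if (L > 1L) {
        x[2:L] <- x[1L] + cumsum(stats::rnorm(L - 1L, 0, sds[s[2:L]]))
        y[2:L] <- y[1L] + cumsum(stats::rnorm(L - 1L, 0, sds[s[2:L]]))
      }
    }
    if (config$sigma_loc > 0) {
      ox <- x + stats::rnorm(L, 0, config$sigma_loc)
      oy <- y + stats::rnorm(L, 0, config$sigma_loc)
      if (config$confine) {
        # localizations outside the nucleus mask are not observed in the
        # experiment; redraw the measurement noise for such points
        bad <- which((ox - cx)^2 + (oy - cy)^2 > R^2)
        tries <- 0L
        while (length(bad)) {
          ox[bad] <- x[bad] + stats::rnorm(length(bad), 0, config$sigma_loc)
          oy[bad] <- y[bad] + stats::rnorm(length(bad), 0, config$sigma_loc)
          bad <- bad[(ox[bad] - cx)^2 + (oy[bad] - cy)^2 > R^2]
          tries <- tries + 1L
          if (tries > 10000L) stop_sptk("localization-noise redraw failed")
        }
      }
    } else { ox <- x; oy <- y }
    out[[i]] <- tibble::tibble(track_id = i, frame = 0:(L - 1L),
                               x_um = ox, y_um = oy, cell_id = cell, state = s)
  }
  trajectory_set(dplyr::bind_rows(out), rois,
                 dt_frame = config$dt_frame, sigma_loc = config$sigma_loc,
                 seed = config$seed)
}

#' Simulate time-lapse dwell-time observations
#'
#' Emulates single-molecule time-lapse imaging of chromatin-bound molecules:
#' between consecutive detections separated by `tau_TL = tau_int + tau_delay`,
#' a molecule survives with probability
#' `exp(-k_diss * tau_TL) * exp(-k_bleach * tau_int)` - dissociation acts over
#' the whole interval while photobleaching acts only during the constant
#' integration time, so its per-frame contribution is identical across
#' intervals. The observation is the number of consecutive frames `n >= 1` in
#' which the molecule was seen.
#'
#' @param config a [timelapse_config()].
#' @return tibble with columns `tau_tl_s`, `tau_int_s`, `n_frames`, one row
#'   per molecule.
#' @export
simulate_timelapse_dwells <- function(config) {
  stopifnot(inherits(config, "timelapse_config"))
  set.seed(config$seed)
  purrr::map_dfr(config$tau_delays, function(delay) {
    tau_tl <- config$tau_int + delay
    p_surv <- exp(-config$k_diss_true * tau_tl) *
      exp(-config$k_bleach_true * config$tau_int)
    n <- if (p_surv >= 1) {
      rep.int(config$max_frames, config$n_molecules)
    } else {
      pmin(1L + stats::rgeom(config$n_molecules, 1 - p_surv),
           config$max_frames)
    }
    tibble::tibble(tau_tl_s = tau_tl, tau_int_s = config$tau_int, n_frames = n)
  })
}

#' Resample trajectory-matched control trajectories
#'
#' Builds null-model replicates of a trajectory set that preserve everything
#' about the data except spatial preference: same number of tracks, same
#' track lengths, same per-cell ROIs (hence the same overall density), with
#' step lengths drawn with replacement from the data's empirical step-length
#' distribution, isotropic step directions, and steps that would leave the ROI
#' redrawn. These replicates carry the same step-to-step spatial correlation
#' structure that trajectories impose on localizations, and are used to
#' normalize Ripley H curves.
#'
#' @param data a `trajectory_set`.
#' @param n_reps number of replicate sets.
#' @param seed integer seed.
#' @return list of `trajectory_set` replicates.
#' @export
resample_matched_trajectories <- function(data, n_reps = 20L, seed = 1L) {
  stopifnot(inherits(data, "trajectory_set"))
  steps <- track_steps(data)
  if (nrow(steps) < 10L) {
    stop_sptk("need at least 10 steps for a stable empirical step-length ",
              "distribution (got ", nrow(steps), ")")
  }
  set.seed(seed)
  pool <- steps$step_um
  tracks <- data$locs |>
    dplyr::summarise(L = dplyr::n(), cell_id = .data$cell_id[1L],
                     .by = "track_id")
  rois <- data$rois
  lapply(seq_len(n_reps), function(rep_i) {
    out <- vector("list", nrow(tracks))
    for (i in seq_len(nrow(tracks))) {
      L <- tracks$L[i]; cell <- tracks$cell_id[i]
      ri <- which(rois$cell_id == cell)
      cx <- rois$cx_um[ri]; cy <- rois$cy_um[ri]; R <- rois$r_um[ri]
      r0 <- R * sqrt(stats::runif(1L)); th0 <- stats::runif(1L, 0, 2 * pi)
      x <- numeric(L); y <- numeric(L)
      x[1L] <- cx + r0 * cos(th0); y[1L] <- cy + r0 * sin(th0)
      for (t in 2:L) {
        tries <- 0L
        repeat {
          len <- pool[sample.int(length(pool), 1L)]
          th <- stats::runif(1L, 0, 2 * pi)
          nx <- x[t - 1L] + len * cos(th); ny <- y[t - 1L] + len * sin(th)
          if ((nx - cx)^2 + (ny - cy)^2 <= R^2) break
          tries <- tries + 1L
          if (tries > 10000L) stop_sptk("matched-resampling step redraw failed")
        }
        x[t] <- nx; y[t] <- ny
      }
      out[[i]] <- tibble::tibble(track_id = tracks$track_id[i],
                                 frame = 0:(L - 1L), x_um = x, y_um = y,
                                 cell_id = cell)
    }
    trajectory_set(dplyr::bind_rows(out), rois, dt_frame = data$dt_frame,
                   sigma_loc = data$sigma_loc, seed = seed + rep_i)
  })
}
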
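#' Configuration for the multi-state trajectory simulator
#'
#' Bundles and validates the physical and acquisition parameters used by
#' [simulate_trajectories()]. Defaults follow common live-cell photoactivated
#' localization microscopy settings: 40 ms frames, ~1 um nuclear radius, and
#' diffusion coefficients in the 0.005-0.5 um^2/s range typical of
#' chromatin-associated proteins.
#'
#' @param K number of mobility states (>= 1).
#' @param D numeric vector of length `K`; per-state diffusion coefficients,
#'   um^2/s. Per-coordinate step variance is `2 * D * dt_frame`.
#' @param T_frame `K x K` per-frame transition probability matrix (rows sum
#'   to 1). For `K = 1` may be omitted.
#' @param dt_frame frame interval, seconds.
#' @param sigma_loc localization error standard deviation per coordinate, um.
#' @param R_nuc nucleus radius, um. Set `confine = FALSE` to disable the
#'   boundary entirely.
#' @param p_bleach per-frame photobleaching probability in `[0, 1)`; track
#'   lengths are geometric with this parameter, truncated below at `min_len`.
#' @param n_tracks number of tracks to generate.
#' @param min_len minimum retained track length, frames (>= 2).
#' @param max_len cap on track length, frames; keeps `p_bleach = 0` finite.
#' @param n_cells number of cells (each with its own circular nucleus ROI)
#'   that tracks are distributed across.
#' @param confine logical; enforce the circular nucleus boundary.
#' @param seed integer RNG seed recorded in the output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(K = 2, D = c(0.007, 0.13),
#'                   T_frame = matrix(c(0.95, 0.05, 0.4, 0.6), 2, byrow = TRUE),
#'                   n_tracks = 50, seed = 1)
#' @export
sim_config <- function(K = 1L,
                       D = 0.1,
                       T_frame = NULL,
                       dt_frame = 0.04,
                       sigma_loc = 0.02,
                       R_nuc = 1.0,
                       p_bleach = 0.05,
                       n_tracks = 100L,
                       min_len = 2L,
                       max_len = 1000L,
                       n_cells = 1L,
                       confine = TRUE,
                       seed = 1L) {
  K <- as.integer(K)
  if (K < 1L) stop_sptk("K must be >= 1")
  if (length(D) != K) stop_sptk("D must have length K = ", K)
  if (any(D < 0)) stop_sptk("all diffusion coefficients must be >= 0")
  if (is.null(T_frame)) {
    if (K != 1L) stop_sptk("T_frame is required when K > 1")
    T_frame <- matrix(1, 1, 1)
  }
  T_frame <- as.matrix(T_frame)
  check_transition_matrix(T_frame, K)
  if (dt_frame <= 0) stop_sptk("dt_frame must be > 0")
  if (sigma_loc < 0) stop_sptk("sigma_loc must be >= 0")
  if (R_nuc <= 0) stop_sptk("R_nuc must be > 0")
  if (p_bleach < 0 || p_bleach >= 1) stop_sptk("p_bleach must be in [0, 1)")
  if (min_len < 2L) stop_sptk("min_len must be >= 2 frames")
  if (max_len < min_len) stop_sptk("max_len must be >= min_len")
  if (all(D == 0) && sigma_loc == 0 && p_bleach == 1) {
    stop_sptk("degenerate configuration: no motion, no noise, instant bleaching")
  }
  structure(
    list(K = K, D = as.numeric(D), T_frame = T_frame, dt_frame = dt_frame,
         sigma_loc = sigma_loc, R_nuc = R_nuc, p_bleach = p_bleach,
         n_tracks = as.integer(n_tracks), min_len = as.integer(min_len),
         max_len = as.integer(max_len), n_cells = as.integer(n_cells),
         confine = isTRUE(confine), seed = as.integer(seed)),
    class = "sim_config"
  )
}

check_transition_matrix <- function(P, K, tol = 1e-12) {
  if (!all(dim(P) == c(K, K))) stop_sptk("T_frame must be ", K, " x ", K)
  if (any(P < 0) || any(P > 1)) stop_sptk("T_frame entries must be probabilities")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8)) {
    stop_sptk("each T_frame row must sum to 1 (max deviation ",
              format(max(abs(rs - 1))), ")")
  }
  invisible(P)
}

#' Configuration for time-lapse dwell-time simulation
#'
#' Describes a single-molecule time-lapse experiment: fixed integration time
#' `tau_int` per exposure and a set of dark delays, so each interval's total
#' period is `tau_TL = tau_int + tau_delay`. Because the light dose per frame
#' is constant, photobleaching contributes a fixed per-frame loss while true
#' dissociation scales with `tau_TL`, which is what lets the two rates be
#' separated downstream.
#'
#' @param tau_int integration time per frame, seconds (default 0.2).
#' @param tau_delays numeric vector of dark delay times, seconds (>= 0).
#' @param k_diss_true true dissociation rate, 1/s.
#' @param k_bleach_true photobleaching rate during integration, 1/s.
#' @param n_molecules molecules simulated per delay.
#' @param max_frames cap on observed frames per molecule.
#' @param seed integer RNG seed.
#' @return an object of class `timelapse_config`.
#' @export
timelapse_config <- function(tau_int = 0.2,
                             tau_delays = c(0, 0.3, 0.8, 1.8, 3.8),
                             k_diss_true = 0.26,
                             k_bleach_true = 1.0,
                             n_molecules = 1000L,
                             max_frames = 10000L,
                             seed = 1L) {
  if (tau_int <= 0) stop_sptk("tau_int must be > 0")
  if (length(tau_delays) == 0L) stop_sptk("tau_delays must be non-empty")
  if (any(tau_delays < 0)) stop_sptk("tau_delays must be >= 0")
  if (k_diss_true < 0 || k_bleach_true < 0) stop_sptk("rates must be >= 0")
  structure(
    list(tau_int = tau_int, tau_delays = as.numeric(tau_delays),
         k_diss_true = k_diss_true, k_bleach_true = k_bleach_true,
         n_molecules = as.integer(n_molecules),
         max_frames = as.integer(max_frames), seed = as.integer(seed)),
    class = "timelapse_config"
  )
}
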
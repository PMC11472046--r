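# Shared fixtures built in code: small simulated datasets and the printed
# two-state transition matrix used throughout the kinetics tests.

epe1_T <- function() {
  matrix(c(0.992, 0.008, 0.21, 0.79), 2, 2, byrow = TRUE)
}

two_state_T <- function() {
  matrix(c(0.95, 0.05, 0.4, 0.6), 2, 2, byrow = TRUE)
}

make_two_state_set <- function(n_tracks = 300L, D = c(0.007, 0.13),
                               T_frame = two_state_T(), seed = 11L, ...) {
  simulate_trajectories(sim_config(K = 2, D = D, T_frame = T_frame,
                                   n_tracks = n_tracks, min_len = 5L,
                                   p_bleach = 0.05, seed = seed, ...))
}

# uniform CSR points in a unit-radius circle
csr_pattern <- function(n = 500L, R = 1, seed = 1L) {
  set.seed(seed)
  r0 <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  point_pattern(tibble::tibble(x_um = r0 * cos(th), y_um = r0 * sin(th)),
                list(cx_um = 0, cy_um = 0, r_um = R))
}

# continuous-time rates of a 2-state per-frame matrix via the matrix logarithm
matrix_log_rates <- function(T_frame, dt = 0.04) {
  l2 <- sum(diag(T_frame)) - 1
  Q <- (log(l2) / (l2 - 1)) * (T_frame - diag(2)) / dt
  c(Q[1, 2], Q[2, 1])
}
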
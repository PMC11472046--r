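#' Configuration for Bayesian mobility-state inference
#'
#' @param K fixed number of states, or `NULL` to use `K_range` with
#'   [select_K()].
#' @param K_range integer vector of candidate state counts for selection.
#' @param iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before summarizing (`iterations > burn_in`).
#' @param alpha Dirichlet concentration for transition-matrix rows.
#' @param prior_shape,prior_scale inverse-gamma prior on the per-coordinate
#'   step variance. `prior_scale = NULL` sets the prior mean to the overall
#'   mean squared displacement (weakly informative, scale-matched to data).
#' @param seed integer RNG seed; identical seeds give bit-identical fits.
#' @return object of class `hmm_config`.
#' @export
hmm_config <- function(K = NULL, K_range = 1:4, iterations = 600L,
                       burn_in = 150L, alpha = 1, prior_shape = 2,
                       prior_scale = NULL, seed = 1L) {
  if (iterations <= burn_in || burn_in < 0) {
    stop_sptk("need iterations > burn_in >= 0")
  }
  structure(
    list(K = if (is.null(K)) NULL else as.integer(K),
         K_range = as.integer(K_range), iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), alpha = alpha,
         prior_shape = prior_shape, prior_scale = prior_scale,
         seed = as.integer(seed)),
    class = "hmm_config"
  )
}

# Per-step emission log-likelihood matrix: one row per step, one column per
# state. Each displacement coordinate is N(0, s2_k) with
# s2_k = 2 * D_k * dt + 2 * sigma_loc^2.
step_emission_loglik <- function(dx, dy, s2) {
  vapply(s2, function(v) {
    stats::dnorm(dx, 0, sqrt(v), log = TRUE) +
      stats::dnorm(dy, 0, sqrt(v), log = TRUE)
  }, numeric(length(dx)))
}

# Layout of steps as a (position-in-track) x (track) index matrix so the
# forward-backward recursion runs vectorized across tracks.
step_layout <- function(steps) {
  tr <- factor(steps$track_id, levels = unique(steps$track_id))
  lens <- as.integer(table(tr))
  ntr <- length(lens)
  maxL <- max(lens)
  idx <- matrix(NA_integer_, maxL, ntr)
  pos <- stats::ave(seq_along(tr), tr, FUN = seq_along)
  idx[cbind(pos, as.integer(tr))] <- seq_len(nrow(steps))
  list(idx = idx, lens = lens, ntr = ntr, maxL = maxL,
       track = as.integer(tr))
}

# Vectorized categorical sampling: one draw per row of a (row-normalized
# after cumsum) probability matrix.
sample_rows <- function(P) {
  cs <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  u <- stats::runif(nrow(P)) * cs[, ncol(P)]
  1L + rowSums(cs < u)
}

# Forward filtering across all tracks simultaneously; returns the list of
# normalized forward probability matrices (ntr x K per position) and the
# total marginal log-likelihood.
forward_filter <- function(ll, layout, T_frame, pi0) {
  K <- ncol(T_frame)
  F <- vector("list", layout$maxL)
  logZ <- 0
  a <- matrix(NA_real_, layout$ntr, K)
  act <- which(layout$lens >= 1L)
  lik1 <- exp(ll[layout$idx[1L, act], , drop = FALSE])
  a1 <- sweep(lik1, 2, pi0, `*`)
  z <- rowSums(a1)
  logZ <- logZ + sum(log(z))
  a[act, ] <- a1 / z
  F[[1L]] <- a
  if (layout$maxL > 1L) {
    for (t in 2:layout$maxL) {
      act <- which(layout$lens >= t)
      prev <- F[[t - 1L]][act, , drop = FALSE]
      pred <- prev %*% T_frame
      likt <- exp(ll[layout$idx[t, act], , drop = FALSE])
      at <- pred * likt
      z <- rowSums(at)
      logZ <- logZ + sum(log(z))
      a <- matrix(NA_real_, layout$ntr, K)
      a[act, ] <- at / z
      F[[t]] <- a
    }
  }
  list(F = F, loglik = logZ)
}

# Backward sampling of per-step state labels given forward matrices.
backward_sample <- function(F, layout, T_frame) {
  K <- ncol(T_frame)
  ntr <- layout$ntr
  lab <- matrix(NA_integer_, layout$maxL, ntr)
  s_next <- rep(NA_integer_, ntr)
  for (t in layout$maxL:1) {
    ends <- which(layout$lens == t)
    if (length(ends)) {
      s_next[ends] <- sample_rows(F[[t]][ends, , drop = FALSE])
      lab[t, ends] <- s_next[ends]
    }
    mids <- which(layout$lens > t)
    if (length(mids)) {
      w <- F[[t]][mids, , drop = FALSE] *
        t(T_frame)[s_next[mids], , drop = FALSE]
      s_next[mids] <- sample_rows(w)
      lab[t, mids] <- s_next[mids]
    }
  }
  lab[cbind(
    stats::ave(seq_along(layout$track), layout$track, FUN = seq_along),
    layout$track
  )]
}

#' Infer mobility states from trajectories
#'
#' Fits a fixed-K Bayesian hidden Markov model to single-frame displacements
#' by Gibbs sampling: per-step state labels are drawn by forward-filtering
#' backward-sampling; per-state step variances by a conjugate inverse-gamma
#' update; and transition-matrix rows by Dirichlet-multinomial updates.
#' Diffusion coefficients are recovered from the per-coordinate step variance
#' `s2_k = 2 * D_k * dt_frame + 2 * sigma_loc^2` as
#' `D_k = max(0, (s2_k / 2 - sigma_loc^2) / dt_frame)`. States are relabeled
#' in ascending variance every sweep, so label order is deterministic and
#' repeated runs with the same seed are identical.
#'
#' Weight fractions report the posterior mean fraction of steps assigned to
#' each state. The noise-induced covariance between consecutive displacements
#' of one molecule is deliberately ignored (steps are treated as independent
#' given their state), matching the per-step state model the analysis rests
#' on; at `sigma_loc` well below the step scale the bias is negligible.
#'
#' @param data a `trajectory_set`.
#' @param config an [hmm_config()] with a fixed `K`.
#' @return object of class `mobility_model` with elements `K`, `D` (posterior
#'   mean), `D_sd`, `pi`, `T_frame`, `loglik`, `bic`, `mcmc_diagnostics`, and
#'   the post-burn-in draws.
#' @export
infer_states <- function(data, config = hmm_config(K = 2)) {
  stopifnot(inherits(data, "trajectory_set"), inherits(config, "hmm_config"))
  K <- config$K
  if (is.null(K)) stop_sptk("infer_states needs a fixed K; use select_K ",
                            "for model selection")
  steps <- track_steps(data)
  n <- nrow(steps)
  if (n < 2L) stop_sptk("need at least 2 steps")
  if (n < 1000L) {
    warn_sptk("only ", n, " steps; inference is recommended with >= 1000")
  }
  msd2 <- mean(steps$dx_um^2 + steps$dy_um^2) / 2  # per-coordinate variance
  if (K > 1L && msd2 == 0) stop_sptk("all displacements are zero; K > 1 is ",
                                     "unidentifiable")
  a0 <- config$prior_shape
  b0 <- config$prior_scale %||% (msd2 * (a0 - 1))
  if (b0 <= 0) b0 <- 1e-8
  set.seed(config$seed)
  layout <- step_layout(steps)
  dx <- steps$dx_um; dy <- steps$dy_um
  # spread initial variances across quantiles of the squared displacements
  q <- stats::quantile((steps$dx_um^2 + steps$dy_um^2) / 2,
                       probs = (seq_len(K) - 0.5) / K, names = FALSE)
  s2 <- pmax(q, msd2 * 1e-3)
  T_frame <- matrix(1 / K, K, K)
  n_keep <- config$iterations - config$burn_in
  draw_s2 <- matrix(NA_real_, n_keep, K)
  draw_pi <- matrix(NA_real_, n_keep, K)
  draw_T <- array(NA_real_, c(n_keep, K, K))
  kept <- 0L
  for (it in seq_len(config$iterations)) {
    ll <- step_emission_loglik(dx, dy, s2)
    pi0 <- stationary_dist(T_frame)
    fw <- forward_filter(ll, layout, T_frame, pi0)
    z <- backward_sample(fw$F, layout, T_frame)
    # conjugate inverse-gamma update of per-state variances
    nk <- tabulate(z, nbins = K)
    ss <- vapply(seq_len(K), function(k) sum(dx[z == k]^2 + dy[z == k]^2),
                 numeric(1))
    s2 <- 1 / stats::rgamma(K, shape = a0 + nk, rate = b0 + ss / 2)
    # Dirichlet update of transition rows from within-track label transitions
    if (K > 1L) {
      C <- matrix(0, K, K)
      from <- z[-n]; to <- z[-1L]
      same <- layout$track[-n] == layout$track[-1L]
      tab <- table(factor(from[same], 1:K), factor(to[same], 1:K))
      C <- C + as.matrix(tab)
      G <- matrix(stats::rgamma(K * K, shape = config$alpha + C), K, K)
      T_frame <- G / rowSums(G)
    }
    # deterministic label order: variance ascending
    o <- order(s2)
    s2 <- s2[o]
    T_frame <- T_frame[o, o, drop = FALSE]
    z <- match(z, o)
    nk <- nk[o]
    if (it > config$burn_in) {
      kept <- kept + 1L
      draw_s2[kept, ] <- s2
      draw_pi[kept, ] <- nk / n
      draw_T[kept, , ] <- T_frame
    }
  }
  s2_mean <- colMeans(draw_s2)
  D_draws <- pmax((draw_s2 / 2 - data$sigma_loc^2) / data$dt_frame, 0)
  D_mean <- pmax(0, (s2_mean / 2 - data$sigma_loc^2) / data$dt_frame)
  pi_mean <- colMeans(draw_pi)
  T_mean <- apply(draw_T, c(2, 3), mean)
  if (K > 1L) T_mean <- T_mean / rowSums(T_mean)
  rhat <- apply(draw_s2, 2, split_rhat)
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged) {
    warn_sptk("split-chain diagnostic above 1.1 for at least one state ",
              "variance; treat posterior summaries with caution")
  }
  if (K > 1L) {
    sep <- s2_mean[-1L] / s2_mean[-K]
    if (any(sep < 1.1)) {
      warn_sptk("two states have nearly identical step variances; consider ",
                "merging (smaller K)")
    }
  }
  # marginal step likelihood at the posterior-mean parameters, for selection
  ll_hat <- step_emission_loglik(dx, dy, s2_mean)
  lf <- forward_filter(ll_hat, layout, T_mean, stationary_dist(T_mean))
  p_eff <- K + K * (K - 1)
  structure(
    list(K = K,
         D = D_mean, D_sd = apply(D_draws, 2, stats::sd),
         pi = pi_mean, pi_sd = apply(draw_pi, 2, stats::sd),
         T_frame = T_mean, T_sd = apply(draw_T, c(2, 3), stats::sd),
         dt_frame = data$dt_frame, sigma_loc = data$sigma_loc,
         loglik = lf$loglik,
         bic = -2 * lf$loglik + p_eff * log(n),
         n_steps = n,
         mcmc_diagnostics = list(iterations = config$iterations,
                                 burn_in = config$burn_in,
                                 rhat_s2 = rhat, converged = converged),
         draws = list(s2 = draw_s2, D = D_draws, pi = draw_pi, T = draw_T),
         seed = config$seed),
    class = "mobility_model"
  )
}

#' Select the number of mobility states
#'
#' Fits the displacement HMM for each candidate `K` in `config$K_range` and
#' returns the `K` minimizing the Bayesian information criterion computed from
#' the marginal step likelihood at the posterior-mean parameters. Ties (and
#' near-ties within `tol`) are broken toward the smaller `K`.
#'
#' @param data a `trajectory_set`.
#' @param config an [hmm_config()] with `K_range` set.
#' @param tol BIC difference treated as a tie.
#' @return the selected integer `K`, with the per-K fit table in attribute
#'   `"fits"`.
#' @export
select_K <- function(data, config = hmm_config(), tol = 1e-8) {
  stopifnot(inherits(config, "hmm_config"))
  ks <- sort(unique(config$K_range))
  fits <- purrr::map(ks, function(k) {
    cfg <- config
    cfg$K <- as.integer(k)
    suppressWarnings(infer_states(data, cfg))
  })
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  best <- ks[which(bic <= min(bic) + tol)][1L]
  structure(as.integer(best),
            fits = tibble::tibble(K = ks, bic = bic,
                                  loglik = vapply(fits, `[[`, numeric(1),
                                                  "loglik")))
}

#' Summarize state occupancies and transition probabilities
#'
#' @param model a fitted `mobility_model`.
#' @return tibble with one row per state: `state`, `D_um2_s`, `D_sd`, `pi`,
#'   and per-frame transition probabilities `p_to_<j>`.
#' @export
occupancy_and_transitions <- function(model) {
  stopifnot(inherits(model, "mobility_model"))
  out <- tibble::tibble(state = seq_len(model$K),
                        D_um2_s = model$D, D_sd = model$D_sd,
                        pi = model$pi)
  Tm <- model$T_frame
  for (j in seq_len(model$K)) out[[paste0("p_to_", j)]] <- Tm[, j]
  out
}

#' @export
print.mobility_model <- function(x, ...) {
  cat("<mobility_model> K =", x$K, "states,", x$n_steps, "steps\n")
  print(occupancy_and_transitions(x))
  invisible(x)
}

#' @export
tidy.mobility_model <- function(x, ...) occupancy_and_transitions(x)

#' @export
glance.mobility_model <- function(x, ...) {
  tibble::tibble(K = x$K, n_steps = x$n_steps, loglik = x$loglik,
                 bic = x$bic,
                 converged = x$mcmc_diagnostics$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mobility_model <- function(object, ...) {
  df <- occupancy_and_transitions(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$D_um2_s, .data$pi,
                                   color = factor(.data$state))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = pmax(.data$D_um2_s - .data$D_sd,
                                                     1e-4),
                                         xmax = .data$D_um2_s + .data$D_sd),
                            height = 0.02) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(D ~ (mu * m^2 / s)),
                  y = "weight fraction", color = "state") +
    ggplot2::theme_minimal()
}
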
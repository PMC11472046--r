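# Internal numerical helpers shared across modules.

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves pi = pi P for the left eigenvector with eigenvalue 1, normalized to
#' sum to one. Used to initialize simulated state sequences and to partition
#' molecules across states at equilibrium.
#'
#' @param P square row-stochastic matrix.
#' @return numeric vector of stationary probabilities.
#' @export
stationary_dist <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (nrow(P) == 1L) return(1)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Highest-density credible interval from posterior draws: shortest window
# containing `prob` mass.
hdi_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3L) return(c(lower = min(x), upper = max(x)))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Split-chain potential scale reduction (Rhat) for a single chain: the chain
# is split in half and the classic between/within variance ratio computed.
split_rhat <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) return(NA_real_)
  half <- n %/% 2L
  chains <- cbind(x[seq_len(half)], x[seq.int(n - half + 1L, n)])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Deterministic per-stage seed derived from a root seed and a stage label,
# kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_sptk <- function(..., class = "sptkinetics_error") {
  rlang::abort(paste0(...), class = class)
}

warn_sptk <- function(..., class = "sptkinetics_warning") {
  rlang::warn(paste0(...), class = class)
}
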
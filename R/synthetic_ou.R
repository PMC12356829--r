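#' Simulate a multivariate OU process at irregular observation times
#'
#' Latent states are propagated exactly through the discretized transition
#' (see [discretize_sde()]) between consecutive observation times; observations
#' add independent Gaussian measurement noise per variable. An optional missing
#' mask knocks out individual observations.
#'
#' @param truth list with `A` (m x m stationary drift), `b` (length m), `G`
#'   (m x m diffusion effect), `meas_sd` (length m, >= 0), `times` (increasing
#'   numeric), and optionally `y0` (initial latent state; default drawn from
#'   the stationary distribution), `miss_mask` (m x T logical, TRUE = missing).
#' @param seed integer RNG seed.
#' @return list of class `ou_truth`: inputs plus `states` (m x T latent) and
#'   `obs` (m x T with NA where masked).
#' @export
simulate_ou_trajectories <- function(truth, seed = NULL) {
  A <- as.matrix(truth$A); m <- nrow(A)
  b <- rep_len(truth$b, m)
  G <- as.matrix(truth$G)
  meas_sd <- rep_len(truth$meas_sd, m)
  times <- truth$times
  stopifnot(length(times) >= 1, all(diff(times) > 0))
  if (any(meas_sd < 0)) stop_validation("meas_sd must be >= 0")
  check_stationary(A)
  d0 <- discretize_sde(A, b, G, 1)
  mu_inf <- drop(solve(A, -b))
  with_seed(seed, {
    T <- length(times)
    states <- matrix(NA_real_, m, T)
    x <- if (!is.null(truth$y0)) rep_len(truth$y0, m) else
      mu_inf + drop(chol_psd(d0$Sinf) %*% stats::rnorm(m))
    disc <- discretization_cache(A, b, G)
    for (j in seq_len(T)) {
      if (j > 1L) {
        st <- disc(times[j] - times[j - 1L])
        x <- drop(st$A_d %*% x) + st$b_d +
          drop(chol_psd(st$Q_d) %*% stats::rnorm(m))
      }
      states[, j] <- x
    }
    obs <- states + meas_sd * matrix(stats::rnorm(m * T), m, T)
    if (!is.null(truth$miss_mask)) obs[truth$miss_mask] <- NA_real_
    structure(c(truth[c("A", "b", "G", "meas_sd", "times")],
                list(states = states, obs = obs)),
              class = "ou_truth")
  })
}

# Cholesky-like factor of a PSD matrix (tolerates zero eigenvalues).
chol_psd <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}
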
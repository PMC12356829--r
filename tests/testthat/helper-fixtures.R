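# Small fixtures built in code, shared across test files.

toy_counts <- function() {
  count_table(matrix(1:6, nrow = 2, byrow = TRUE,
                     dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
}

write_toy_tsv <- function(path = tempfile(fileext = ".tsv")) {
  write_count_table(toy_counts(), path)
  path
}

toy_tree <- function(taxa = c("a", "b", "c")) {
  taxon_tree(ape::read.tree(text = "((a,b),c);"), taxon_ids = taxa)
}

# random stationary drift matrix (full, m x m)
random_stationary_A <- function(m) {
  repeat {
    A <- matrix(stats::rnorm(m * m, 0, 0.5), m, m)
    diag(A) <- -stats::runif(m, 0.5, 2)
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -0.05) return(A)
  }
}

# brute-force joint-Gaussian log-density of an observed panel under the
# discretized CT model: independent oracle for the Kalman recursion
joint_gaussian_loglik <- function(times, Y, A, b, G, meas_sd, init_mean,
                                  init_cov) {
  m <- nrow(Y); T <- length(times)
  mu <- matrix(0, m, T)
  Sig <- matrix(0, m * T, m * T)
  mu[, 1] <- init_mean
  P_list <- list()
  # means and state covariances by forward recursion; cross-covariances exact
  Ads <- list()
  P_list[[1]] <- init_cov
  for (j in 2:T) {
    d <- discretize_sde(A, b, G, times[j] - times[j - 1])
    Ads[[j]] <- d$A_d
    mu[, j] <- d$A_d %*% mu[, j - 1] + d$b_d
    P_list[[j]] <- d$A_d %*% P_list[[j - 1]] %*% t(d$A_d) + d$Q_d
  }
  blk <- function(i) (i - 1) * m + seq_len(m)
  for (i in seq_len(T)) Sig[blk(i), blk(i)] <- P_list[[i]]
  for (i in seq_len(T - 1)) for (j in (i + 1):T) {
    Tr <- diag(m)
    for (l in (i + 1):j) Tr <- Ads[[l]] %*% Tr
    Sig[blk(j), blk(i)] <- Tr %*% P_list[[i]]
    Sig[blk(i), blk(j)] <- t(Sig[blk(j), blk(i)])
  }
  Sig <- Sig + diag(rep(meas_sd^2, T))
  y <- as.vector(Y)
  obs <- which(!is.na(y))
  yv <- y[obs] - as.vector(mu)[obs]
  So <- Sig[obs, obs, drop = FALSE]
  cS <- chol(So)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(cS))) +
            sum(yv * backsolve(cS, forwardsolve(t(cS), yv))))
}
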
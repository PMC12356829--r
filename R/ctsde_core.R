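#' Exact discretization of the linear SDE over an interval
#'
#' For the Ornstein-Uhlenbeck dynamics dy = (A y + b) dt + G dW, the state at
#' t + dt given the state at t is Gaussian with transition matrix
#' \code{A_d = expm(A dt)}, discrete intercept \code{b_d = integral of
#' expm(A s) b ds} (computed via an augmented matrix exponential, so
#' near-singular A is handled exactly), and process-noise covariance
#' \code{Q_d = Sinf - A_d Sinf t(A_d)} where Sinf solves the continuous
#' Lyapunov equation \code{A Sinf + Sinf t(A) + G t(G) = 0}.
#'
#' @param A m x m stationary drift matrix (all eigenvalues with negative real
#'   part).
#' @param b length-m continuous-time intercept.
#' @param G m x m diffusion effect matrix.
#' @param dt positive time step.
#' @return list with \code{A_d}, \code{b_d}, \code{Q_d} (symmetric PSD) and
#'   the stationary covariance \code{Sinf}.
#' @export
discretize_sde <- function(A, b, G, dt) {
  A <- as.matrix(A); G <- as.matrix(G)
  m <- nrow(A)
  stopifnot(ncol(A) == m, length(b) == m, all(dim(G) == m))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_validation("dt must be a positive number")
  check_stationary(A)
  is_diag <- m == 1L || all(A[row(A) != col(A)] == 0)
  GG <- G %*% t(G)
  if (is_diag) {
    a <- diag(A)
    A_d <- diag(exp(a * dt), m)
    b_d <- expm1(a * dt) / a * b
    Sinf <- -GG / outer(a, a, "+")
  } else {
    A_d <- as.matrix(Matrix::expm(A * dt))
    aug <- rbind(cbind(A, b), 0)
    b_d <- as.matrix(Matrix::expm(aug * dt))[seq_len(m), m + 1L]
    I <- diag(m)
    Sinf <- matrix(solve(kronecker(I, A) + kronecker(A, I), -as.vector(GG)), m, m)
  }
  if (any(!is.finite(A_d))) stop("non-finite matrix exponential at dt = ", dt)
  Sinf <- (Sinf + t(Sinf)) / 2
  Q_d <- Sinf - A_d %*% Sinf %*% t(A_d)
  Q_d <- (Q_d + t(Q_d)) / 2
  if (min(diag(Q_d)) < 0 || m > 1L) {
    e <- eigen(Q_d, symmetric = TRUE)
    if (min(e$values) < -1e-10 * max(1, max(abs(e$values))))
      stop("discretized noise covariance has eigenvalue ", min(e$values),
           " below tolerance")
    ev <- pmax(e$values, 0)
    Q_d <- e$vectors %*% (ev * t(e$vectors))
    Q_d <- (Q_d + t(Q_d)) / 2
  } else {
    Q_d[Q_d < 0] <- 0
  }
  list(A_d = A_d, b_d = b_d, Q_d = Q_d, Sinf = Sinf)
}

# Stationary covariance of the OU process (continuous Lyapunov solution).
stationary_cov <- function(A, G) {
  m <- nrow(A)
  GG <- G %*% t(G)
  S <- if (m == 1L || all(A[row(A) != col(A)] == 0))
    -GG / outer(diag(A), diag(A), "+")
  else matrix(solve(kronecker(diag(m), A) + kronecker(A, diag(m)),
                    -as.vector(GG)), m, m)
  (S + t(S)) / 2
}

check_stationary <- function(A) {
  ev <- eigen(as.matrix(A), only.values = TRUE)$values
  worst <- ev[which.max(Re(ev))]
  if (max(Re(ev)) >= 0)
    stop_validation("drift matrix is not stationary: eigenvalue ",
                    format(worst), " has non-negative real part")
  invisible(TRUE)
}

#' Assemble an observed multivariate panel of irregular site time series
#'
#' @param sites named list; each element a list with `times` (strictly
#'   increasing numeric) and `Y` (m x T matrix, rows = variables, `NA` =
#'   missing).
#' @param variables character vector of the m variable names.
#' @param time_unit `"month"` or `"day"`; all model rates are per this unit.
#' @return object of class `ou_panel`.
#' @export
ou_panel <- function(sites, variables, time_unit = c("month", "day")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.list(sites), length(sites) >= 1, !is.null(names(sites)))
  m <- length(variables)
  for (s in names(sites)) {
    el <- sites[[s]]
    stopifnot(is.numeric(el$times), is.matrix(el$Y))
    if (nrow(el$Y) != m)
      stop_validation("site ", s, ": Y must have one row per variable")
    if (ncol(el$Y) != length(el$times))
      stop_validation("site ", s, ": times/Y length mismatch")
    if (any(diff(el$times) <= 0))
      stop_validation("site ", s, ": times must be strictly increasing")
    # fully-missing time points are allowed: the filter skips their update,
    # so they act as pure prediction points
    rownames(sites[[s]]$Y) <- variables
  }
  structure(list(sites = sites, variables = variables, time_unit = time_unit),
            class = "ou_panel")
}

#' @export
print.ou_panel <- function(x, ...) {
  cat(sprintf("ou_panel: %d variables, %d sites (%s), %d observations\n",
              length(x$variables), length(x$sites), x$time_unit,
              sum(vapply(x$sites, function(s) length(s$times), 1))))
  invisible(x)
}

#' Grand-mean standardize a panel
#'
#' Each variable is centered by its grand mean across all sites and times and
#' scaled by its grand standard deviation (denominator n - 1); missing values
#' stay missing. The transform parameters are returned so trajectories can be
#' back-transformed to original units.
#'
#' @param panel an [ou_panel()].
#' @return list with the standardized `panel`, and per-variable `center`,
#'   `scale`.
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "ou_panel"))
  m <- length(panel$variables)
  allY <- do.call(cbind, lapply(panel$sites, function(s) s$Y))
  center <- rowMeans(allY, na.rm = TRUE)
  scale <- apply(allY, 1L, stats::sd, na.rm = TRUE)
  nobs <- rowSums(!is.na(allY))
  if (any(nobs < 2))
    stop_validation("variable has fewer than 2 observed values: ",
                    panel$variables[which(nobs < 2)[1L]])
  if (any(scale == 0) || any(!is.finite(scale)))
    stop_validation("zero-variance variable cannot be standardized: ",
                    panel$variables[which(scale == 0 | !is.finite(scale))[1L]])
  for (s in names(panel$sites))
    panel$sites[[s]]$Y <- (panel$sites[[s]]$Y - center) / scale
  list(panel = panel, center = stats::setNames(center, panel$variables),
       scale = stats::setNames(scale, panel$variables))
}

# Build (or reuse) discretizations for a set of intervals; dts keyed by value.
discretization_cache <- function(A, b, G) {
  cache <- new.env(parent = emptyenv())
  function(dt) {
    key <- format(dt, digits = 12)
    got <- cache[[key]]
    if (is.null(got)) {
      got <- discretize_sde(A, b, G, dt)
      cache[[key]] <- got
    }
    got
  }
}

# Precompute per-interval discretizations for a whole series. Diagonal drift
# has closed forms and is vectorized; general drift goes through
# discretize_sde with caching over repeated interval lengths.
precompute_steps <- function(dts, A, b, G) {
  m <- nrow(A)
  n <- length(dts)
  if (m == 1L || all(A[row(A) != col(A)] == 0)) {
    a <- diag(A)
    GG <- G %*% t(G)
    Sinf <- -GG / outer(a, a, "+")
    E <- exp(outer(a, dts))                      # m x n decay factors
    Ads <- lapply(seq_len(n), function(j) diag(E[, j], m))
    bds <- lapply(seq_len(n), function(j) (E[, j] - 1) / a * b)
    Qds <- lapply(seq_len(n), function(j) {
      Q <- Sinf * (1 - tcrossprod(E[, j]))
      diag(Q) <- pmax(diag(Q), 0)
      Q
    })
  } else {
    disc <- discretization_cache(A, b, G)
    st <- lapply(dts, disc)
    Ads <- lapply(st, `[[`, "A_d")
    bds <- lapply(st, `[[`, "b_d")
    Qds <- lapply(st, `[[`, "Q_d")
  }
  list(A_d = Ads, b_d = bds, Q_d = Qds)
}

# Core Kalman forward pass for one site. Returns loglik and, if keep = TRUE,
# predicted/filtered moments and per-step transition matrices for smoothing.
kalman_site <- function(times, Y, A, b, G, meas_sd, init_mean, init_cov,
                        keep = FALSE) {
  m <- nrow(Y); T <- length(times)
  steps <- precompute_steps(diff(times), A, b, G)
  R <- meas_sd^2
  x <- init_mean; P <- init_cov
  ll <- 0
  if (keep) {
    xp <- matrix(NA_real_, m, T); Pp <- array(NA_real_, c(m, m, T))
    xf <- matrix(NA_real_, m, T); Pf <- array(NA_real_, c(m, m, T))
    Ads <- array(NA_real_, c(m, m, T))
  }
  for (j in seq_len(T)) {
    if (j > 1L) {
      Ad <- steps$A_d[[j - 1L]]
      x <- drop(Ad %*% x) + steps$b_d[[j - 1L]]
      P <- Ad %*% P %*% t(Ad) + steps$Q_d[[j - 1L]]
      P <- (P + t(P)) / 2
      if (keep) Ads[, , j] <- Ad
    }
    if (keep) { xp[, j] <- x; Pp[, , j] <- P }
    obs <- which(!is.na(Y[, j]))
    if (length(obs)) {
      v <- Y[obs, j] - x[obs]
      S <- P[obs, obs, drop = FALSE] + diag(R[obs], length(obs))
      cS <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(cS)) {
        S <- S + diag(1e-10, length(obs))
        cS <- tryCatch(chol(S), error = function(e)
          stop("non-PSD innovation covariance at step ", j))
      }
      si <- backsolve(cS, forwardsolve(t(cS), v))
      ll <- ll - 0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(cS))) +
                          sum(v * si))
      K <- P[, obs, drop = FALSE] %*% chol2inv(cS)
      x <- x + drop(K %*% v)
      P <- P - K %*% P[obs, , drop = FALSE]
      P <- (P + t(P)) / 2
    }
    if (keep) { xf[, j] <- x; Pf[, , j] <- P }
  }
  if (!keep) return(list(loglik = ll))
  list(loglik = ll, xp = xp, Pp = Pp, xf = xf, Pf = Pf, A_d = Ads)
}

# Rauch-Tung-Striebel backward pass over a kalman_site(keep = TRUE) result.
rts_smooth_site <- function(kf) {
  T <- ncol(kf$xf); m <- nrow(kf$xf)
  xs <- kf$xf; Ps <- kf$Pf
  if (T >= 2L) for (j in (T - 1L):1L) {
    Ad <- kf$A_d[, , j + 1L]
    Ppn <- kf$Pp[, , j + 1L]
    Ci <- kf$Pf[, , j] %*% t(Ad) %*% solve(Ppn + diag(1e-12, m))
    xs[, j] <- kf$xf[, j] + drop(Ci %*% (xs[, j + 1L] - kf$xp[, j + 1L]))
    Ps[, , j] <- kf$Pf[, , j] +
      Ci %*% (Ps[, , j + 1L] - Ppn) %*% t(Ci)
    Ps[, , j] <- (Ps[, , j] + t(Ps[, , j])) / 2
  }
  list(xs = xs, Ps = Ps)
}

#' Exact Gaussian log-likelihood of a CT state-space model on a panel
#'
#' Kalman recursion with per-interval exact discretization; missing dimensions
#' are skipped in the measurement update (their rows are deleted), and latent
#' and manifest variables are identified one-to-one (identity loading).
#' Parameters are shared across sites; each site runs its own filter from its
#' initial-state distribution.
#'
#' @param spec a model specification as produced by [ctsde_spec()].
#' @param panel an [ou_panel()] whose times are in `spec$time_unit`.
#' @return list with `loglik` and per-site filtered moments.
#' @export
kalman_loglik <- function(spec, panel) {
  stopifnot(inherits(panel, "ou_panel"))
  res <- lapply(names(panel$sites), function(s) {
    el <- panel$sites[[s]]
    ini <- spec_init(spec, s)
    kalman_site(el$times, el$Y, spec$A, spec$b, spec$G, spec$meas_sd,
                ini$mean, ini$cov, keep = TRUE)
  })
  names(res) <- names(panel$sites)
  list(loglik = sum(vapply(res, `[[`, 0, "loglik")), sites = res)
}

#' Specify a continuous-time OU state-space model
#'
#' @param A m x m stationary drift matrix (auto effects on the diagonal, cross
#'   effects off it).
#' @param b length-m continuous-time intercept.
#' @param G m x m diffusion effect (diagonal or lower-triangular Cholesky
#'   factor of the diffusion covariance).
#' @param meas_sd length-m measurement-error standard deviations.
#' @param init either `"stationary"` (initial state at the model's stationary
#'   distribution) or a list with `mean` (length m, or named list per site)
#'   and `cov` (m x m PSD).
#' @param variables optional variable names.
#' @param time_unit `"month"` (default) or `"day"`.
#' @return object of class `ctsde_spec`.
#' @export
ctsde_spec <- function(A, b, G, meas_sd, init = "stationary",
                       variables = NULL, time_unit = c("month", "day")) {
  time_unit <- match.arg(time_unit)
  A <- as.matrix(A); m <- nrow(A)
  if (is.null(variables)) variables <- if (!is.null(rownames(A)))
    rownames(A) else paste0("y", seq_len(m))
  stopifnot(length(b) == m, length(meas_sd) == m)
  if (any(meas_sd < 0)) stop_validation("meas_sd must be >= 0")
  check_stationary(A)
  G <- as.matrix(G)
  structure(list(A = A, b = b, G = G, meas_sd = meas_sd, init = init,
                 variables = variables, time_unit = time_unit),
            class = "ctsde_spec")
}

spec_init <- function(spec, site) {
  if (identical(spec$init, "stationary")) {
    d <- discretize_sde(spec$A, spec$b, spec$G, 1)
    return(list(mean = drop(solve(spec$A, -spec$b)), cov = d$Sinf))
  }
  mu <- spec$init$mean
  if (is.list(mu)) mu <- mu[[site]]
  list(mean = mu, cov = spec$init$cov)
}

#' Fixed-interval Kalman smoother with 95% intervals
#'
#' Runs the forward filter and Rauch-Tung-Striebel backward pass per site.
#' A `grid` of extra times (inserted as fully-missing observations, which
#' leave the likelihood untouched) yields smoothed trajectories between and
#' beyond the sampled dates. Intervals are mean +/- 1.96 sd per variable.
#'
#' @param spec a [ctsde_spec()].
#' @param panel an [ou_panel()].
#' @param grid optional numeric times (same unit as the panel) at which to
#'   report, in addition to the observation times.
#' @param center,scale optional per-variable standardization parameters; when
#'   given, trajectories are back-transformed to original units.
#' @return data.frame: site, time, variable, mean, sd, lo95, hi95.
#' @export
kalman_smooth <- function(spec, panel, grid = NULL, center = NULL, scale = NULL) {
  stopifnot(inherits(panel, "ou_panel"))
  m <- length(panel$variables)
  out <- list()
  for (s in names(panel$sites)) {
    el <- panel$sites[[s]]
    times <- el$times; Y <- el$Y
    if (!is.null(grid)) {
      extra <- setdiff(grid, times)
      if (length(extra)) {
        times2 <- sort(c(times, extra))
        Y2 <- matrix(NA_real_, m, length(times2))
        Y2[, match(times, times2)] <- Y
        times <- times2; Y <- Y2
      }
    }
    ini <- spec_init(spec, s)
    kf <- kalman_site(times, Y, spec$A, spec$b, spec$G, spec$meas_sd,
                      ini$mean, ini$cov, keep = TRUE)
    sm <- rts_smooth_site(kf)
    sds <- sqrt(pmax(apply(sm$Ps, 3L, diag), 0))
    if (m == 1L) sds <- matrix(sds, 1L)
    mu <- sm$xs
    if (!is.null(center)) {
      mu <- mu * scale + center
      sds <- sds * scale
    }
    out[[s]] <- data.frame(site = s,
                           time = rep(times, each = m),
                           variable = rep(panel$variables, length(times)),
                           mean = as.vector(mu), sd = as.vector(sds),
                           lo95 = as.vector(mu - 1.96 * sds),
                           hi95 = as.vector(mu + 1.96 * sds),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
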
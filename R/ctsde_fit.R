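#' Fit a continuous-time OU state-space model by maximum likelihood
#'
#' Maximizes the exact Kalman-filter likelihood of
#' dy = (A y + b) dt + G dW, y observed with per-variable Gaussian
#' measurement error, over irregularly sampled multi-site panels. Dynamics
#' parameters are shared across sites; each site carries its own initial
#' state. Stationarity is enforced by a soft log-barrier on the largest real
#' part of the eigenvalues of A with hard rejection at zero. Standard errors
#' come from the numerical Hessian at the optimum.
#'
#' @param panel an [ou_panel()] (typically grand-mean standardized, see
#'   [standardize_panel()]).
#' @param drift `"diag"` (auto effects only; default, the identifiable choice
#'   at small T) or `"full"` (auto + cross effects).
#' @param diffusion `"diag"` (default) or `"chol"` (lower-triangular).
#' @param init `"stationary"` (initial states at the model-implied stationary
#'   distribution; default) or `"free"` (site-specific free initial means).
#' @param multistart number of optimizer starts (jittered after the first).
#' @param seed integer seed for start jitter.
#' @param start optional named list overriding automatic starting values
#'   (`a`, `b`, `g`, `meas_sd`).
#' @param fixed_meas_sd optional fixed measurement sds (skips estimating them).
#' @param control passed to [stats::optim()] (method BFGS).
#' @return Object of class `ctsde_fit`.
#' @export
fit_ctsde <- function(panel, drift = c("diag", "full"),
                      diffusion = c("diag", "chol"),
                      init = c("stationary", "free"),
                      multistart = 3, seed = NULL, start = NULL,
                      fixed_meas_sd = NULL, control = list()) {
  drift <- match.arg(drift); diffusion <- match.arg(diffusion)
  init <- match.arg(init)
  stopifnot(inherits(panel, "ou_panel"))
  m <- length(panel$variables)
  sites <- names(panel$sites)
  for (s in sites) if (length(panel$sites[[s]]$times) < 2L)
    stop_validation("site ", s, " has fewer than 2 time points")
  allY <- do.call(cbind, lapply(panel$sites, function(s) s$Y))
  v_mean <- rowMeans(allY, na.rm = TRUE)
  v_sd <- apply(allY, 1L, stats::sd, na.rm = TRUE)
  v_sd[!is.finite(v_sd) | v_sd == 0] <- 1

  layout <- param_layout(m, length(sites), drift, diffusion, init,
                         is.null(fixed_meas_sd))

  base_start <- list(a = rep(-1, m), b = v_mean, g = sqrt(2) * v_sd,
                     meas_sd = pmax(0.3 * v_sd, 2e-4))
  if (!is.null(start)) base_start[names(start)] <- start

  nll <- function(par) {
    sp <- tryCatch(unpack_params(par, layout, panel, fixed_meas_sd),
                   error = function(e) NULL)
    if (is.null(sp)) return(1e10)
    ev <- eigen(sp$A, only.values = TRUE)$values
    mre <- max(Re(ev))
    if (mre >= 0 || !all(is.finite(par))) return(1e10)
    ll <- tryCatch({
      Sinf <- stationary_cov(sp$A, sp$G)
      mu0 <- drop(solve(sp$A, -sp$b))
      sum(vapply(sites, function(s) {
        el <- panel$sites[[s]]
        mu <- if (init == "free") sp$init_mean[[s]] else mu0
        cpp_kalman_loglik(el$times, el$Y, sp$A, sp$b, sp$G, sp$meas_sd,
                          mu, Sinf)
      }, 0))
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll - 1e-4 * log(-mre)
  }

  starts <- with_seed(seed, lapply(seq_len(max(1, multistart)), function(i) {
    st <- base_start
    if (i > 1) {
      st$a <- st$a * stats::runif(m, 0.3, 3)
      st$b <- st$b + stats::rnorm(m, 0, v_sd / 2)
      st$g <- st$g * exp(stats::rnorm(m, 0, 0.5))
      st$meas_sd <- st$meas_sd * exp(stats::rnorm(m, 0, 0.5))
    }
    st
  }))

  fits <- lapply(starts, function(st) {
    p0 <- pack_params(st, layout, panel, v_mean)
    tryCatch(stats::optim(p0, nll, method = "BFGS",
                          control = utils::modifyList(
                            list(maxit = 500, reltol = 1e-10), control)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  ok[ok] <- vapply(fits[ok], function(f) is.finite(f$value) && f$value < 1e9,
                   TRUE)
  if (!any(ok))
    stop("no optimizer start converged; start diagnostics: ",
         paste(vapply(fits, function(f)
           if (is.null(f)) "error" else format(f$value), ""), collapse = ", "))
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, 0, "value"))]]

  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) {
    # near-singular Hessian: invert on the well-determined eigenspace
    e2 <- eigen((H + t(H)) / 2, symmetric = TRUE)
    keep <- e2$values > 1e-8 * max(abs(e2$values))
    if (!any(keep)) return(NULL)
    e2$vectors[, keep, drop = FALSE] %*%
      (t(e2$vectors[, keep, drop = FALSE]) / e2$values[keep])
  }) else NULL
  sp <- unpack_params(best$par, layout, panel, fixed_meas_sd)
  se_nat <- natural_se(best$par, vc, layout)

  spec <- ctsde_spec(sp$A, sp$b, sp$G, sp$meas_sd,
                     init = if (init == "stationary") "stationary" else
                       list(mean = sp$init_mean,
                            cov = stationary_cov(sp$A, sp$G)),
                     variables = panel$variables, time_unit = panel$time_unit)
  n_obs <- sum(vapply(panel$sites, function(s) sum(!is.na(s$Y)), 0))
  structure(list(spec = spec, loglik = -best$value, par = best$par,
                 layout = layout, vcov_par = vc, se = se_nat,
                 panel = panel, drift = drift, diffusion = diffusion,
                 init = init, convergence = best$convergence,
                 counts = best$counts, n_obs = n_obs,
                 n_starts_converged = sum(ok),
                 auto_effects = diag(sp$A)),
            class = "ctsde_fit")
}

# Parameter vector bookkeeping -------------------------------------------

param_layout <- function(m, n_sites, drift, diffusion, init, est_meas) {
  names <- c(paste0("a", seq_len(m)))
  if (drift == "full")
    names <- c(names, paste0("across", seq_len(m * (m - 1L))))
  names <- c(names, paste0("b", seq_len(m)), paste0("log_g", seq_len(m)))
  if (diffusion == "chol" && m > 1L)
    names <- c(names, paste0("gchol", seq_len(m * (m - 1L) / 2L)))
  if (est_meas) names <- c(names, paste0("log_meas", seq_len(m)))
  if (init == "free")
    names <- c(names, paste0("init", seq_len(m * n_sites)))
  list(m = m, n_sites = n_sites, drift = drift, diffusion = diffusion,
       init = init, est_meas = est_meas, names = names, n = length(names))
}

pack_params <- function(st, layout, panel, v_mean) {
  m <- layout$m
  p <- st$a
  if (layout$drift == "full") p <- c(p, rep(0, m * (m - 1L)))
  p <- c(p, st$b, log(st$g))
  if (layout$diffusion == "chol" && m > 1L)
    p <- c(p, rep(0, m * (m - 1L) / 2L))
  if (layout$est_meas) p <- c(p, log(pmax(st$meas_sd - 1e-4, 1e-6)))
  if (layout$init == "free")
    p <- c(p, rep(v_mean, layout$n_sites))
  stats::setNames(p, layout$names)
}

unpack_params <- function(par, layout, panel, fixed_meas_sd) {
  m <- layout$m; i <- 0L
  take <- function(k) { out <- par[i + seq_len(k)]; i <<- i + k; out }
  a <- take(m)
  A <- diag(a, m)
  if (layout$drift == "full") A[row(A) != col(A)] <- take(m * (m - 1L))
  b <- take(m)
  g <- exp(take(m))
  G <- diag(g, m)
  if (layout$diffusion == "chol" && m > 1L)
    G[lower.tri(G)] <- take(m * (m - 1L) / 2L)
  meas_sd <- if (layout$est_meas) 1e-4 + exp(take(m)) else
    rep_len(fixed_meas_sd, m)
  init_mean <- NULL
  if (layout$init == "free") {
    im <- matrix(take(m * layout$n_sites), m, layout$n_sites)
    init_mean <- lapply(seq_len(layout$n_sites), function(j) im[, j])
    names(init_mean) <- names(panel$sites)
  }
  dimnames(A) <- list(panel$variables, panel$variables)
  list(A = A, b = stats::setNames(b, panel$variables), G = G,
       meas_sd = stats::setNames(meas_sd, panel$variables),
       init_mean = init_mean,
       init_cov = NULL)
}

fit_init <- function(sp, site, init) {
  if (init == "stationary" || is.null(sp$init_mean)) {
    S <- discretize_sde(sp$A, sp$b, sp$G, 1)$Sinf
    return(list(mean = drop(solve(sp$A, -sp$b)), cov = S))
  }
  S <- discretize_sde(sp$A, sp$b, sp$G, 1)$Sinf
  list(mean = sp$init_mean[[site]], cov = S)
}

# Delta-method SEs on the natural scale (exp transform for log_* entries).
natural_se <- function(par, vc, layout) {
  if (is.null(vc)) return(rep(NA_real_, layout$n))
  se <- sqrt(pmax(diag(vc), 0))
  logs <- grepl("^log_", layout$names)
  se[logs] <- se[logs] * exp(par[logs])
  stats::setNames(se, layout$names)
}

# S3 methods --------------------------------------------------------------

#' @export
print.ctsde_fit <- function(x, ...) {
  cat(sprintf("ctsde_fit: %d variables, %d sites, %d observations (%s unit)\n",
              length(x$spec$variables), length(x$panel$sites), x$n_obs,
              x$spec$time_unit))
  cat(sprintf("  log-likelihood %.3f (drift %s, diffusion %s, %d starts converged)\n",
              x$loglik, x$drift, x$diffusion, x$n_starts_converged))
  cat("  auto effects (diag of drift):\n")
  print(round(x$auto_effects, 4))
  invisible(x)
}

#' @export
coef.ctsde_fit <- function(object, ...) {
  list(A = object$spec$A, b = object$spec$b, G = object$spec$G,
       meas_sd = object$spec$meas_sd)
}

#' @export
logLik.ctsde_fit <- function(object, ...) {
  structure(object$loglik, df = object$layout$n, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.ctsde_fit <- function(object, ...) object$vcov_par

#' @export
confint.ctsde_fit <- function(object, parm = NULL, level = 0.95, ...) {
  est <- param_estimates(object)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est$estimate - z * est$se, est$estimate + z * est$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  rownames(ci) <- est$parameter
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

# Natural-scale estimates aligned with layout$names.
param_estimates <- function(object) {
  par <- object$par
  est <- par
  logs <- grepl("^log_", object$layout$names)
  est[logs] <- exp(par[logs])
  est[grepl("^log_meas", object$layout$names)] <-
    1e-4 + exp(par[grepl("^log_meas", object$layout$names)])
  nm <- sub("^log_", "", object$layout$names)
  m <- object$layout$m
  nm[seq_len(m)] <- paste0("a_", object$spec$variables)
  data.frame(parameter = nm, estimate = unname(est), se = unname(object$se),
             stringsAsFactors = FALSE)
}

#' @export
summary.ctsde_fit <- function(object, ...) {
  est <- param_estimates(object)
  est$lo95 <- est$estimate - 1.96 * est$se
  est$hi95 <- est$estimate + 1.96 * est$se
  structure(list(table = est, auto = summarize_auto_effects(object),
                 loglik = object$loglik), class = "summary.ctsde_fit")
}

#' @export
print.summary.ctsde_fit <- function(x, ...) {
  cat("Continuous-time OU state-space fit, log-likelihood",
      format(x$loglik, digits = 6), "\n\nParameters:\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat("\nAuto effects (most persistent first):\n")
  print(x$auto, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Order the drift auto effects by persistence
#'
#' Returns the diagonal of the estimated drift matrix sorted descending
#' (closest to zero first = weakest negative feedback = most persistent
#' perturbations), with Wald 95% intervals, a flag for significantly negative
#' values, and a non-stationarity flag for non-negative entries.
#'
#' @param fit a `ctsde_fit` (Wald intervals) or `ctsde_hier_fit` (posterior
#'   intervals).
#' @return data.frame: variable, auto_effect, se, lo95, hi95,
#'   significant_negative, nonstationary.
#' @export
summarize_auto_effects <- function(fit) UseMethod("summarize_auto_effects")

#' @export
summarize_auto_effects.ctsde_fit <- function(fit) {
  m <- fit$layout$m
  a <- fit$auto_effects
  se <- fit$se[seq_len(m)]
  out <- data.frame(variable = fit$spec$variables, auto_effect = unname(a),
                    se = unname(se),
                    lo95 = unname(a - 1.96 * se), hi95 = unname(a + 1.96 * se),
                    stringsAsFactors = FALSE)
  out$significant_negative <- !is.na(out$hi95) & out$hi95 < 0
  out$nonstationary <- out$auto_effect >= 0
  out <- out[order(-out$auto_effect), , drop = FALSE]  # stable for ties
  rownames(out) <- NULL
  out
}

#' Smoothed latent trajectories from a fitted model
#'
#' @param object a `ctsde_fit`.
#' @param grid optional extra report times (panel time unit).
#' @param center,scale optional standardization parameters for
#'   back-transformation to original units.
#' @param ... unused.
#' @return data.frame from [kalman_smooth()].
#' @export
predict.ctsde_fit <- function(object, grid = NULL, center = NULL,
                              scale = NULL, ...) {
  kalman_smooth(object$spec, object$panel, grid = grid,
                center = center, scale = scale)
}

#' @export
residuals.ctsde_fit <- function(object, ...) {
  out <- list()
  for (s in names(object$panel$sites)) {
    el <- object$panel$sites[[s]]
    ini <- spec_init(object$spec, s)
    kf <- kalman_site(el$times, el$Y, object$spec$A, object$spec$b,
                      object$spec$G, object$spec$meas_sd,
                      ini$mean, ini$cov, keep = TRUE)
    R <- object$spec$meas_sd^2
    for (j in seq_along(el$times)) {
      obs <- which(!is.na(el$Y[, j]))
      if (!length(obs)) next
      S <- kf$Pp[obs, obs, j, drop = FALSE][, , 1L] + diag(R[obs], length(obs))
      v <- el$Y[obs, j] - kf$xp[obs, j]
      std <- drop(forwardsolve(t(chol(S)), v))
      out[[length(out) + 1L]] <-
        data.frame(site = s, time = el$times[j],
                   variable = object$panel$variables[obs],
                   innovation = v, std_residual = std,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
simulate.ctsde_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    sims <- lapply(names(object$panel$sites), function(s) {
      el <- object$panel$sites[[s]]
      sim <- simulate_ou_trajectories(list(
        A = object$spec$A, b = object$spec$b, G = object$spec$G,
        meas_sd = object$spec$meas_sd, times = el$times))
      list(times = el$times, Y = sim$obs)
    })
    names(sims) <- names(object$panel$sites)
    ou_panel(sims, object$panel$variables, object$panel$time_unit)
  }))
}

#' @export
plot.ctsde_fit <- function(x, sites = NULL, ...) {
  sm <- predict(x)
  sites <- if (is.null(sites)) names(x$panel$sites) else sites
  vars <- x$spec$variables
  op <- graphics::par(mfrow = c(length(vars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    sv <- sm[sm$variable == v & sm$site %in% sites, ]
    graphics::plot(sv$time, sv$mean, type = "n", xlab = "time", ylab = v,
                   ylim = range(sv$lo95, sv$hi95, na.rm = TRUE))
    for (s in sites) {
      ss <- sv[sv$site == s, ]
      graphics::lines(ss$time, ss$mean)
      graphics::lines(ss$time, ss$lo95, lty = 2)
      graphics::lines(ss$time, ss$hi95, lty = 2)
      el <- x$panel$sites[[s]]
      graphics::points(el$times, el$Y[v, ], pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}
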
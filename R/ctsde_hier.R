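#' Hierarchical Bayesian fit of the CT model with site random effects
#'
#' Site-level auto effects (diagonal drift) and continuous intercepts are
#' normal random effects around population means, so every site's series
#' informs every other site's parameters; diffusion and measurement sds are
#' shared. The joint posterior is explored by componentwise adaptive
#' random-walk Metropolis with the exact Kalman likelihood; per-site
#' likelihood terms are cached so a site update only refilters that site.
#' Point estimates are posterior medians with central 95% intervals.
#'
#' @param panel an [ou_panel()] with >= 2 sites.
#' @param priors list: `mu_a_mean`, `mu_a_sd`, `mu_b_mean`, `mu_b_sd`
#'   (population-mean normals), `tau_scale` (half-normal scale of the
#'   random-effect sds), `tau_a_fixed`, `tau_b_fixed` (fix instead of
#'   sampling; near 0 collapses sites to the pooled model), `log_g_sd`,
#'   `log_meas_sd` prior sds.
#' @param draws,warmup posterior draws kept / adaptation iterations.
#' @param seed integer RNG seed; same seed reproduces the chains exactly.
#' @return Object of class `ctsde_hier_fit`: posterior draw matrix,
#'   population and site-level medians and 95% intervals, acceptance rates.
#' @export
fit_ctsde_hierarchical <- function(panel, priors = list(), draws = 1000,
                                   warmup = 1000, seed = NULL) {
  stopifnot(inherits(panel, "ou_panel"))
  sites <- names(panel$sites)
  if (length(sites) < 2L) stop_validation("hierarchical fit needs >= 2 sites")
  m <- length(panel$variables)
  pr <- utils::modifyList(list(mu_a_mean = -1, mu_a_sd = 2,
                               mu_b_mean = 0, mu_b_sd = 2,
                               tau_scale = 1, tau_a_fixed = NULL,
                               tau_b_fixed = NULL,
                               log_g_sd = 2, log_meas_sd_prior = 2), priors)
  S <- length(sites)
  est_tau_a <- is.null(pr$tau_a_fixed); est_tau_b <- is.null(pr$tau_b_fixed)

  # parameter table: population means, log taus, site effects, shared scales
  nm <- c(paste0("mu_a", seq_len(m)), paste0("mu_b", seq_len(m)),
          if (est_tau_a) "log_tau_a", if (est_tau_b) "log_tau_b",
          paste0("a_", rep(sites, each = m), "_", seq_len(m)),
          paste0("b_", rep(sites, each = m), "_", seq_len(m)),
          paste0("log_g", seq_len(m)), paste0("log_meas", seq_len(m)))
  np <- length(nm)
  idx <- function(pat) grep(pat, nm)
  i_mu_a <- seq_len(m); i_mu_b <- m + seq_len(m)
  i_tau_a <- if (est_tau_a) which(nm == "log_tau_a") else integer(0)
  i_tau_b <- if (est_tau_b) which(nm == "log_tau_b") else integer(0)
  i_a <- matrix(idx("^a_"), m, S)   # by site columns
  i_b <- matrix(idx("^b_"), m, S)
  i_g <- idx("^log_g"); i_meas <- idx("^log_meas")

  allY <- do.call(cbind, lapply(panel$sites, function(s) s$Y))
  v_sd <- apply(allY, 1L, stats::sd, na.rm = TRUE); v_sd[!is.finite(v_sd)] <- 1
  v_mean <- rowMeans(allY, na.rm = TRUE)

  site_loglik <- function(theta, s) {
    a <- theta[i_a[, s]]
    if (any(a >= 0)) return(-Inf)
    A <- diag(a, m)
    b <- theta[i_b[, s]]
    G <- diag(exp(theta[i_g]), m)
    meas <- 1e-4 + exp(theta[i_meas])
    Sinf <- -(G %*% t(G)) / outer(a, a, "+")
    el <- panel$sites[[sites[s]]]
    ll <- tryCatch(cpp_kalman_loglik(el$times, el$Y, A, b, G, meas,
                                     drop(solve(A, -b)), Sinf),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) -Inf else ll
  }
  log_prior <- function(theta) {
    tau_a <- if (est_tau_a) exp(theta[i_tau_a]) else pr$tau_a_fixed
    tau_b <- if (est_tau_b) exp(theta[i_tau_b]) else pr$tau_b_fixed
    lp <- sum(stats::dnorm(theta[i_mu_a], pr$mu_a_mean, pr$mu_a_sd, log = TRUE)) +
      sum(stats::dnorm(theta[i_mu_b], pr$mu_b_mean, pr$mu_b_sd, log = TRUE)) +
      sum(stats::dnorm(theta[i_g], 0, pr$log_g_sd, log = TRUE)) +
      sum(stats::dnorm(theta[i_meas], log(0.3), pr$log_meas_sd_prior, log = TRUE))
    if (est_tau_a)  # half-normal on tau, with log-scale Jacobian
      lp <- lp + stats::dnorm(tau_a, 0, pr$tau_scale, log = TRUE) + theta[i_tau_a]
    if (est_tau_b)
      lp <- lp + stats::dnorm(tau_b, 0, pr$tau_scale, log = TRUE) + theta[i_tau_b]
    for (s in seq_len(S)) {
      lp <- lp + sum(stats::dnorm(theta[i_a[, s]], theta[i_mu_a], tau_a, log = TRUE)) +
        sum(stats::dnorm(theta[i_b[, s]], theta[i_mu_b], tau_b, log = TRUE))
    }
    lp
  }

  with_seed(seed, {
    theta <- numeric(np)
    theta[i_mu_a] <- -1; theta[i_a] <- -1
    theta[i_mu_b] <- v_mean; theta[i_b] <- rep(v_mean, S)
    if (est_tau_a) theta[i_tau_a] <- log(0.3)
    if (est_tau_b) theta[i_tau_b] <- log(0.3)
    theta[i_g] <- log(sqrt(2) * v_sd)
    theta[i_meas] <- log(pmax(0.3 * v_sd, 2e-4))

    ll_site <- vapply(seq_len(S), function(s) site_loglik(theta, s), 0)
    lp <- log_prior(theta)
    scales <- rep(0.2, np)
    acc <- att <- numeric(np)
    total <- warmup + draws
    kept <- matrix(NA_real_, draws, np, dimnames = list(NULL, nm))
    site_of_par <- rep(NA_integer_, np)
    for (s in seq_len(S)) site_of_par[c(i_a[, s], i_b[, s])] <- s
    shared <- c(i_g, i_meas)

    pop_mean <- c(i_mu_a, i_mu_b)
    for (it in seq_len(total)) {
      for (j in seq_len(np)) {
        prop <- theta
        step <- stats::rnorm(1, 0, scales[j])
        prop[j] <- theta[j] + step
        # population means move jointly with their site effects (translation
        # move): keeps the random-effects terms fixed, so the chain mixes
        # even as tau -> 0, where mean and effects are locked together
        pop_shift <- j %in% pop_mean
        if (pop_shift) {
          v <- if (j %in% i_mu_a) i_a[match(j, i_mu_a), ] else
            i_b[match(j, i_mu_b), ]
          prop[v] <- theta[v] + step
        }
        att[j] <- att[j] + 1
        lp_new <- log_prior(prop)
        if (!is.finite(lp_new)) next
        if (j %in% shared || pop_shift) {
          ll_new <- vapply(seq_len(S), function(s) site_loglik(prop, s), 0)
          delta <- sum(ll_new) - sum(ll_site) + lp_new - lp
        } else if (!is.na(site_of_par[j])) {
          s <- site_of_par[j]
          ll_s <- site_loglik(prop, s)
          delta <- ll_s - ll_site[s] + lp_new - lp
        } else {
          delta <- lp_new - lp  # tau updates: prior only
        }
        if (is.finite(delta) && log(stats::runif(1)) < delta) {
          if (j %in% shared || pop_shift) ll_site <- ll_new
          else if (!is.na(site_of_par[j])) ll_site[site_of_par[j]] <- ll_s
          theta <- prop; lp <- lp_new
          acc[j] <- acc[j] + 1
        }
      }
      if (it <= warmup && it %% 50 == 0) {  # adapt toward ~0.3 acceptance
        rate <- acc / pmax(att, 1)
        scales <- scales * exp(0.5 * (rate - 0.3))
        scales <- pmin(pmax(scales, 1e-4), 5)
        acc[] <- att[] <- 0
      }
      if (it > warmup) kept[it - warmup, ] <- theta
    }
    rate <- acc / pmax(att, 1)
    if (mean(rate) < 0.05)
      stop("Metropolis chains diverged: mean acceptance ",
           format(mean(rate), digits = 3), " after adaptation; scales: ",
           paste(format(scales, digits = 2), collapse = ", "))

    qs <- function(cols) t(apply(kept[, cols, drop = FALSE], 2L,
                                 stats::quantile, c(0.025, 0.5, 0.975)))
    pop_a <- qs(i_mu_a); pop_b <- qs(i_mu_b)
    site_a <- lapply(seq_len(S), function(s) qs(i_a[, s]))
    names(site_a) <- sites
    structure(list(draws = kept, variables = panel$variables, sites = sites,
                   auto_effects = stats::setNames(pop_a[, 2L], panel$variables),
                   auto_lo95 = pop_a[, 1L], auto_hi95 = pop_a[, 3L],
                   intercepts = stats::setNames(pop_b[, 2L], panel$variables),
                   site_auto = site_a, acceptance = rate,
                   n_draws = draws, warmup = warmup, seed = seed),
              class = "ctsde_hier_fit")
  })
}

#' @export
print.ctsde_hier_fit <- function(x, ...) {
  cat(sprintf("ctsde_hier_fit: %d variables, %d sites, %d posterior draws\n",
              length(x$variables), length(x$sites), x$n_draws))
  cat("  population auto effects (posterior median [95% CI]):\n")
  for (i in seq_along(x$variables))
    cat(sprintf("    %s: %.4f [%.4f, %.4f]\n", x$variables[i],
                x$auto_effects[i], x$auto_lo95[i], x$auto_hi95[i]))
  invisible(x)
}

#' @export
summarize_auto_effects.ctsde_hier_fit <- function(fit) {
  out <- data.frame(variable = fit$variables,
                    auto_effect = unname(fit$auto_effects),
                    se = NA_real_,
                    lo95 = unname(fit$auto_lo95), hi95 = unname(fit$auto_hi95),
                    stringsAsFactors = FALSE)
  out$significant_negative <- out$hi95 < 0
  out$nonstationary <- out$auto_effect >= 0
  out <- out[order(-out$auto_effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}
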
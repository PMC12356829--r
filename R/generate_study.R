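#' Default synthetic-study scenario
#'
#' The stated world the generator emulates: five sites with per-site sample
#' counts 13/12/11/12/11 (59 samples) over ~2 years of roughly monthly,
#' day-jittered sampling; K = 5 subcommunities with hyperdominant genus
#' profiles (one ~91% a single genus), two background subcommunities present
#' everywhere plus three site-enriched ones; tree-structured per-sample
#' profile heterogeneity below a cut depth; and six observed variables (MMT,
#' MMP, dR, dE, C/N, pH) driven per site by a multivariate OU process whose
#' drift diagonal is set to the published point estimates (per month).
#'
#' @return list of scenario settings, all overridable via `config` in
#'   [generate_study()].
#' @export
default_study_config <- function() {
  list(
    sites = c("Dongying", "Shanghai", "Guangzhou", "Maduo", "Lanzhou"),
    n_per_site = c(13L, 12L, 11L, 12L, 11L),
    start_month = c(2, 11, 0, 4, 6),   # months after Jan 2012; staggers spans
    jitter_days = 10,                   # uniform +/- jitter around cadence
    K = 5L, W = 150L,
    dominance = c(0.10, 0.12, 0.10, 0.35, 0.91),
    profile_sdlog = 1,
    # site mean mixtures: SC1/SC2 background everywhere, SC3 enriched in
    # Dongying, SC4 in Guangzhou, SC5 in Shanghai
    site_mixture = rbind(
      Dongying  = c(0.30, 0.25, 0.40, 0.03, 0.02),
      Shanghai  = c(0.35, 0.30, 0.05, 0.05, 0.25),
      Guangzhou = c(0.30, 0.30, 0.03, 0.35, 0.02),
      Maduo     = c(0.55, 0.40, 0.02, 0.02, 0.01),
      Lanzhou   = c(0.45, 0.50, 0.02, 0.02, 0.01)),
    mixture_concentration = 10,
    depth_min = 19923L, depth_extra_mu = 8000, depth_extra_size = 5,
    ltn_C = 9L, ltn_sd = 0.3,
    ou_variables = c("MMT", "MMP", "dR", "dE", "CN", "pH"),
    # published auto-effect point estimates as simulation truth (per month)
    ou_drift_diag = c(MMT = -1.6543, MMP = -2.1549, dR = -2.2519,
                      dE = -3.2408, CN = -3.528, pH = -2.7709),
    ou_meas_sd = 0.2,
    days_per_month = 30.44,
    # affine maps from the standardized OU scale to reported env units
    env_center = c(MMT = 15, MMP = 80, CN = 12, pH = 7),
    env_scale = c(MMT = 10, MMP = 40, CN = 3, pH = 0.8)
  )
}

#' Generate a full synthetic study with all latent truth retained
#'
#' Produces a genus count table, sample metadata, a random taxonomy tree, the
#' LDA truth (theta, beta, per-read labels) and the OU truth (drift,
#' diffusion, latent states, per-site observation panel) under
#' [default_study_config()], so every downstream stage can be tested against
#' known parameters. A pure function of (config, seed).
#'
#' @param config list of overrides merged into [default_study_config()].
#' @param seed integer RNG seed.
#' @return list of class `synthetic_study`: `counts`, `metadata`, `tree`,
#'   `lda_truth`, `ou_truth` (with per-site `panel`), `config`.
#' @export
generate_study <- function(config = list(), seed = 1) {
  cf <- utils::modifyList(default_study_config(), config)
  S <- length(cf$sites)
  if (length(cf$n_per_site) != S)
    stop_validation("sites and n_per_site lengths differ")
  K <- cf$K; W <- cf$W
  if (nrow(cf$site_mixture) != S || ncol(cf$site_mixture) != K)
    stop_validation("site_mixture must be (sites x K)")
  m <- length(cf$ou_variables)
  with_seed(seed, {
    # --- sampling calendar: monthly cadence with day jitter, 1-based days
    md <- list()
    sid <- 0L
    for (s in seq_len(S)) {
      n <- cf$n_per_site[s]
      nominal <- 1 + round((cf$start_month[s] + seq_len(n) - 1) *
                             cf$days_per_month)
      days <- nominal + round(stats::runif(n, -cf$jitter_days, cf$jitter_days))
      days <- sort(days)
      while (anyDuplicated(days)) {  # nudge collisions to keep strict order
        days[duplicated(days)] <- days[duplicated(days)] + 1L
        days <- sort(days)
      }
      md[[s]] <- data.frame(sample_id = sprintf("S%02d", sid + seq_len(n)),
                            site = cf$sites[s], time_days = as.numeric(days),
                            stringsAsFactors = FALSE)
      sid <- sid + n
    }
    metadata <- do.call(rbind, md)

    # --- subcommunity profiles, taxonomy tree, LTN heterogeneity
    beta <- make_subcommunity_profiles(K, W, cf$dominance,
                                       sdlog = cf$profile_sdlog)
    phy <- ape::rtree(W, tip.label = colnames(beta))
    tree <- taxon_tree(phy, taxon_ids = colnames(beta))
    D <- nrow(metadata)
    beta_d <- perturb_profiles_ltn(beta, tree, C = cf$ltn_C, sd = cf$ltn_sd,
                                   n_samples = D)

    # --- mixtures: Dirichlet around site means; depths; counts
    conc <- cf$mixture_concentration
    site_idx <- match(metadata$site, cf$sites)
    alpha_mat <- cf$site_mixture[site_idx, , drop = FALSE] * conc
    theta <- t(apply(alpha_mat, 1L, function(a) {
      g <- stats::rgamma(K, shape = a); g / sum(g)
    }))
    depths <- cf$depth_min + stats::rnbinom(D, mu = cf$depth_extra_mu,
                                            size = cf$depth_extra_size)
    counts <- matrix(0L, D, W, dimnames = list(metadata$sample_id,
                                               colnames(beta)))
    z <- vector("list", D)
    for (d in seq_len(D)) {
      zd <- sample.int(K, depths[d], replace = TRUE, prob = theta[d, ])
      wd <- integer(depths[d])
      for (k in unique(zd)) {
        i <- which(zd == k)
        wd[i] <- sample.int(W, length(i), replace = TRUE, prob = beta_d[k, , d])
      }
      z[[d]] <- zd
      counts[d, ] <- tabulate(wd, nbins = W)
    }
    ct <- count_table(counts)
    lda_truth <- structure(list(K = K, alpha = alpha_mat, gamma = NULL,
                                theta = theta, beta = beta,
                                beta_per_sample = beta_d, z = z),
                           class = "lda_truth")

    # --- six-variable OU per site (standardized scale, rates per month)
    a <- cf$ou_drift_diag[cf$ou_variables]
    A <- diag(a, m); dimnames(A) <- list(cf$ou_variables, cf$ou_variables)
    G <- diag(sqrt(-2 * a), m)   # stationary variance 1 per variable
    b <- rep(0, m)
    meas_sd <- rep_len(cf$ou_meas_sd, m)
    panels <- list()
    ou_sites <- list()
    for (s in seq_len(S)) {
      t_mo <- md[[s]]$time_days / cf$days_per_month
      sim <- simulate_ou_trajectories(list(A = A, b = b, G = G,
                                           meas_sd = meas_sd, times = t_mo))
      rownames(sim$obs) <- rownames(sim$states) <- cf$ou_variables
      panels[[cf$sites[s]]] <- list(times = t_mo, Y = sim$obs)
      ou_sites[[cf$sites[s]]] <- sim
    }
    panel <- ou_panel(panels, cf$ou_variables, time_unit = "month")
    ou_truth <- structure(list(A = A, b = b, G = G, meas_sd = meas_sd,
                               variables = cf$ou_variables,
                               sites = ou_sites, panel = panel),
                          class = "ou_study_truth")

    # --- env variables in reported units from the OU observations
    env_map <- c(MMT = "mmt", MMP = "mmp", CN = "cn_ratio", pH = "ph")
    for (v in names(env_map)) metadata[[env_map[[v]]]] <- NA_real_
    for (s in seq_len(S)) {
      obs <- panels[[cf$sites[s]]]$Y
      rows <- which(metadata$site == cf$sites[s])
      for (v in names(env_map))
        if (v %in% rownames(obs))
          metadata[rows, env_map[[v]]] <-
            cf$env_center[[v]] + cf$env_scale[[v]] * obs[v, ]
    }
    rownames(metadata) <- NULL
    structure(list(counts = ct, metadata = metadata, tree = tree,
                   lda_truth = lda_truth, ou_truth = ou_truth, config = cf),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d samples, %d sites, %d genera, K = %d truth\n",
              nrow(x$counts), length(unique(x$metadata$site)), ncol(x$counts),
              x$lda_truth$K))
  invisible(x)
}
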
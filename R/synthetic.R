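#' Build hyperdominant subcommunity genus profiles
#'
#' Each profile gives its top genus a fixed share (`dominance[k]`) and spreads
#' the remaining mass log-normally over the other genera, emulating the
#' hyperdominant shape of empirical subcommunity profiles (a handful of genera
#' carrying half the abundance, down to a single genus at ~91%).
#'
#' @param K,W number of subcommunities and genera (W >= 2).
#' @param dominance length-K vector of top-genus shares, each in (0, 1).
#' @param sdlog log-normal spread of the residual mass; 0 gives a uniform
#'   residual.
#' @param seed integer RNG seed.
#' @return K x W matrix with rows on the probability simplex; profile k's
#'   dominant genus is column `((k - 1) %% W) + 1`.
#' @export
make_subcommunity_profiles <- function(K, W, dominance, sdlog = 1, seed = NULL) {
  stopifnot(K >= 1, W >= 2, length(dominance) == K)
  if (any(dominance >= 1) || any(dominance <= 0))
    stop_validation("dominance fractions must lie in (0, 1)")
  with_seed(seed, {
    beta <- matrix(0, K, W)
    for (k in seq_len(K)) {
      top <- ((k - 1L) %% W) + 1L
      resid <- if (sdlog == 0) rep(1, W - 1L) else
        stats::rlnorm(W - 1L, meanlog = 0, sdlog = sdlog)
      beta[k, -top] <- resid / sum(resid) * (1 - dominance[k])
      beta[k, top] <- dominance[k]
    }
    dimnames(beta) <- list(paste0("SC", seq_len(K)), paste0("g", seq_len(W)))
    beta
  })
}

#' Sample a count table from the LDA generative model
#'
#' Follows the mixed-membership generative steps exactly: for each sample d a
#' subcommunity distribution theta_d ~ Dirichlet(alpha); for each read n a
#' label z_dn ~ Multinomial(theta_d); genus profiles beta_k ~ Dirichlet(gamma)
#' (unless fixed profiles are supplied); the read's genus
#' w_dn ~ Multinomial(beta_{z_dn}). All latent quantities are retained.
#'
#' @param truth_spec list with `K`, `W`, `D`, `alpha` (scalar or length-K),
#'   `depths` (scalar or length-D reads per sample), and either `gamma`
#'   (scalar or length-W) or fixed `beta` (K x W matrix, or K x W x D array of
#'   per-sample profiles).
#' @param seed integer RNG seed; same seed gives bitwise-identical output.
#' @return list with `counts` (a [count_table()]) and `truth` (class
#'   `lda_truth`: theta, beta, per-read labels z, hyperparameters).
#' @export
generate_lda_counts <- function(truth_spec, seed = NULL) {
  ts <- truth_spec
  stopifnot(!is.null(ts$K), !is.null(ts$W), !is.null(ts$D))
  K <- as.integer(ts$K); W <- as.integer(ts$W); D <- as.integer(ts$D)
  stopifnot(K >= 1, W >= 1, D >= 1)
  depths <- rep_len(as.integer(ts$depths), D)
  if (any(depths < 0)) stop_validation("depths must be >= 0")
  alpha <- rep_len(ts$alpha, K)
  if (any(alpha <= 0)) stop_validation("alpha must be positive")
  with_seed(seed, {
    theta <- matrix(stats::rgamma(D * K, shape = rep(alpha, each = D)), D, K)
    theta <- theta / rowSums(theta)
    beta_arr <- NULL
    if (!is.null(ts$beta)) {
      if (length(dim(ts$beta)) == 3L) beta_arr <- ts$beta
      beta <- if (is.null(beta_arr)) ts$beta else beta_arr[, , 1L]
      stopifnot(nrow(beta) == K, ncol(beta) == W)
    } else {
      gamma <- rep_len(ts$gamma, W)
      if (any(gamma <= 0)) stop_validation("gamma must be positive")
      beta <- matrix(stats::rgamma(K * W, shape = rep(gamma, each = K)), K, W)
      beta <- beta / rowSums(beta)
    }
    counts <- matrix(0L, D, W)
    z <- vector("list", D)
    for (d in seq_len(D)) {
      n <- depths[d]
      zd <- if (n > 0) sample.int(K, n, replace = TRUE, prob = theta[d, ])
            else integer(0)
      wd <- integer(n)
      bd <- if (is.null(beta_arr)) beta else beta_arr[, , d]
      for (k in unique(zd)) {
        idx <- which(zd == k)
        wd[idx] <- sample.int(W, length(idx), replace = TRUE, prob = bd[k, ])
      }
      z[[d]] <- zd
      counts[d, ] <- tabulate(wd, nbins = W)
    }
    taxa <- if (!is.null(colnames(beta))) colnames(beta) else paste0("g", seq_len(W))
    ct <- count_table(counts, sample_ids = paste0("S", seq_len(D)),
                      taxon_ids = taxa)
    truth <- structure(list(K = K, alpha = alpha, gamma = ts$gamma,
                            theta = theta, beta = beta, beta_per_sample = beta_arr,
                            z = z),
                       class = "lda_truth")
    list(counts = ct, truth = truth)
  })
}

#' Tree-structured per-sample heterogeneity of genus profiles
#'
#' Logistic-tree-normal style perturbation: for every sample, the log-shares of
#' children at tree splits strictly below depth `C` (node depth > C, root = 0)
#' receive independent Normal(0, sd^2) noise and are renormalized within the
#' split, so heterogeneity lives near the leaves while the mass aggregated at
#' any depth-C node is untouched. Taxa absent from the tree sit directly under
#' the root (depth 1) and are never perturbed.
#'
#' @param beta K x W simplex matrix (columns named by taxon).
#' @param tree a [taxon_tree()] covering the taxa.
#' @param C integer cut depth (>= 0); `C >= max depth` is a no-op.
#' @param sd perturbation standard deviation (>= 0); 0 returns copies of beta.
#' @param n_samples number of per-sample profile sets to draw.
#' @param seed integer RNG seed.
#' @return K x W x n_samples array of simplex rows.
#' @export
perturb_profiles_ltn <- function(beta, tree, C, sd, n_samples, seed = NULL) {
  stopifnot(inherits(tree, "taxon_tree"), C >= 0, n_samples >= 1)
  if (sd < 0) stop_validation("sd must be >= 0")
  K <- nrow(beta); W <- ncol(beta)
  taxa <- colnames(beta)
  if (is.null(taxa)) stop_validation("beta must have taxon column names")
  tr <- tree$tree
  ntip <- length(tr$tip.label)
  if (!all(taxa %in% c(tr$tip.label, tree$extra_taxa)))
    stop_validation("tree does not cover all taxa in beta")
  out <- array(rep(beta, n_samples), dim = c(K, W, n_samples),
               dimnames = c(dimnames(beta), list(NULL)))
  perturb_nodes <- which(tree$depth[ntip + seq_len(tr$Nnode)] > C) + ntip
  if (sd == 0 || length(perturb_nodes) == 0L) return(out)

  po <- ape::reorder.phylo(tr, "postorder")$edge  # child rows before parents
  leaf_col <- match(tr$tip.label, taxa)           # tree leaf -> beta column
  nn <- ntip + tr$Nnode
  children <- split(po[, 2L], po[, 1L])           # by internal node id (chr)
  with_seed(seed, {
    for (s in seq_len(n_samples)) for (k in seq_len(K)) {
      mass <- numeric(nn)
      keep <- !is.na(leaf_col)
      mass[which(keep)] <- beta[k, leaf_col[keep]]
      for (e in seq_len(nrow(po)))  # postorder accumulation
        mass[po[e, 1L]] <- mass[po[e, 1L]] + mass[po[e, 2L]]
      newmass <- mass
      # each perturbed split reallocates mass among its children; the subtree
      # scale factor mass[nd]*shr_j/mass[ch_j] is relative to the *original*
      # masses, so nested perturbations compose correctly in any order
      for (nd in perturb_nodes) {
        if (mass[nd] <= 0) next
        ch <- children[[as.character(nd)]]
        base <- mass[ch] / mass[nd]
        lg <- log(pmax(base, 1e-300)) + stats::rnorm(length(ch), 0, sd)
        shr <- exp(lg - max(lg)); shr[base == 0] <- 0
        shr <- shr / sum(shr)
        for (j in seq_along(ch)) {
          if (mass[ch[j]] <= 0) next
          sub <- subtree_nodes(ch[j], children, ntip)
          newmass[sub] <- newmass[sub] * (mass[nd] * shr[j] / mass[ch[j]])
        }
      }
      out[k, leaf_col[keep], s] <- newmass[which(keep)]
      out[k, , s] <- out[k, , s] / sum(out[k, , s])
    }
    out
  })
}

# all nodes (incl. `node`) in the subtree rooted at `node`
subtree_nodes <- function(node, children, ntip) {
  stack <- node; res <- integer(0)
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    res <- c(res, nd)
    if (nd > ntip) stack <- c(stack, children[[as.character(nd)]])
  }
  res
}
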
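#' Drop rare taxa from a count table
#'
#' Keeps exactly the taxa whose total count across all samples is at least
#' `min_total` (the conventional pre-filter before subcommunity decomposition:
#' taxa appearing fewer than `min_total` times are excluded).
#'
#' @param counts a [count_table()].
#' @param min_total minimum total count for a taxon to be retained.
#' @return Filtered [count_table()] with all samples kept.
#' @export
filter_rare_taxa <- function(counts, min_total = 100) {
  stopifnot(inherits(counts, "count_table"), min_total >= 0)
  keep <- colSums(counts) >= min_total
  if (!any(keep))
    stop_validation("filter_rare_taxa removed every taxon (min_total = ",
                    min_total, ")")
  if (any(!keep))
    message(sum(!keep), " taxa below min_total = ", min_total, " removed")
  count_table(unclass(counts)[, keep, drop = FALSE])
}

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`;
#' samples with fewer reads are dropped with a warning. Used for
#' diversity-style calculations; the default depth matches a typical minimum
#' sequencing depth.
#'
#' @param counts a [count_table()].
#' @param depth target reads per sample.
#' @param seed integer RNG seed.
#' @return Rarefied [count_table()] (row sums all equal `depth`).
#' @export
rarefy <- function(counts, depth = 19923, seed = NULL) {
  stopifnot(inherits(counts, "count_table"), depth >= 1)
  tot <- rowSums(counts)
  keep <- tot >= depth
  if (!any(keep))
    stop_validation("all samples are below rarefaction depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " samples below depth ", depth, " dropped: ",
            paste(utils::head(rownames(counts)[!keep], 5), collapse = ", "))
  m <- unclass(counts)[keep, , drop = FALSE]
  with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      if (sum(m[i, ]) == depth) next
      pool <- rep.int(seq_len(ncol(m)), m[i, ])
      m[i, ] <- tabulate(sample(pool, depth), nbins = ncol(m))
    }
    count_table(m)
  })
}

#' Aggregate taxa to tree nodes at a fixed depth
#'
#' Sums taxon columns into their ancestor node at depth `C` of the taxonomy
#' tree (root = depth 0); taxa whose leaves are at depth <= C are kept as-is.
#' This is the fitting-time surrogate for the tree cut level C: composition is
#' modelled at the depth where cross-sample heterogeneity is assumed to start.
#' Total counts are conserved.
#'
#' @param counts a [count_table()].
#' @param tree a [taxon_tree()] covering the taxa.
#' @param C integer cut depth >= 0 (0 collapses everything to the root).
#' @return Aggregated [count_table()] whose columns are node labels.
#' @export
aggregate_tree_depth <- function(counts, tree, C) {
  stopifnot(inherits(counts, "count_table"), inherits(tree, "taxon_tree"),
            C >= 0)
  labs <- ancestor_labels_at_depth(tree, colnames(counts), as.integer(C))
  groups <- unique(labs)
  if (length(groups) == ncol(counts) && all(labs == colnames(counts)))
    return(counts)
  agg <- matrix(0L, nrow(counts), length(groups),
                dimnames = list(rownames(counts), groups))
  for (g in seq_along(groups))
    agg[, g] <- as.integer(rowSums(unclass(counts)[, labs == groups[g],
                                                   drop = FALSE]))
  count_table(agg)
}

#' Fit an LDA subcommunity decomposition by collapsed Gibbs sampling
#'
#' Each read's subcommunity label is resampled from the standard collapsed
#' conditional p(z = k) proportional to (n_dk + alpha)(n_kw + gamma) /
#' (n_k + W gamma); after `n_burnin` iterations the per-iteration
#' posterior-mean estimates of the sample mixtures theta (D x K) and
#' subcommunity genus profiles beta (K x W) are averaged over `n_keep`
#' further draws. The collapsed joint log-likelihood is traced every
#' iteration for convergence monitoring.
#'
#' @param counts a [count_table()].
#' @param K number of subcommunities (>= 1).
#' @param alpha,gamma symmetric Dirichlet hyperparameters for the
#'   sample-subcommunity and subcommunity-genus distributions; defaults
#'   `1/K` and `0.1`.
#' @param n_burnin,n_keep Gibbs iterations discarded / retained (defaults
#'   10000 and 1000; reduce for cross-validation work).
#' @param seed integer RNG seed; same seed gives identical fits.
#' @return Object of class `lda_fit` with `theta_hat`, `beta_hat`,
#'   `loglik_trace`, hyperparameters and ids. Zero-read samples get the prior
#'   mean mixture and are listed in `zero_read_samples`.
#' @export
fit_lda <- function(counts, K, alpha = 1 / K, gamma = 0.1,
                    n_burnin = 10000, n_keep = 1000, seed = NULL) {
  stopifnot(inherits(counts, "count_table"), K >= 1, alpha > 0, gamma > 0,
            n_burnin >= 0, n_keep >= 1)
  D <- nrow(counts); W <- ncol(counts)
  tot <- rowSums(counts)
  nonzero_taxa <- sum(colSums(counts) > 0)
  if (K > nonzero_taxa)
    warning("K = ", K, " exceeds the ", nonzero_taxa,
            " taxa with nonzero counts")
  live <- which(tot > 0)
  if (length(live) == 0L) stop_validation("count table has no reads")
  m <- unclass(counts)[live, , drop = FALSE]
  nz <- which(m > 0, arr.ind = TRUE)
  reps <- m[nz]
  doc <- rep.int(nz[, 1L] - 1L, reps)
  word <- rep.int(nz[, 2L] - 1L, reps)
  res <- with_seed(seed,
    cpp_lda_gibbs(doc, word, length(live), W, as.integer(K),
                  alpha, gamma, as.integer(n_burnin), as.integer(n_keep)))
  theta <- matrix(alpha / (K * alpha), D, K)  # prior mean for zero-read rows
  theta[live, ] <- res$theta_hat
  dimnames(theta) <- list(rownames(counts), paste0("SC", seq_len(K)))
  beta <- res$beta_hat
  dimnames(beta) <- list(paste0("SC", seq_len(K)), colnames(counts))
  structure(list(K = as.integer(K), alpha = alpha, gamma = gamma,
                 theta_hat = theta, beta_hat = beta,
                 loglik_trace = res$loglik,
                 n_burnin = n_burnin, n_keep = n_keep, seed = seed,
                 zero_read_samples = rownames(counts)[tot == 0]),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("lda_fit: K = %d subcommunities, %d samples x %d taxa\n",
              x$K, nrow(x$theta_hat), ncol(x$beta_hat)))
  cat(sprintf("  alpha = %.4g, gamma = %.4g, burn-in %d + %d kept draws\n",
              x$alpha, x$gamma, x$n_burnin, x$n_keep))
  if (length(x$zero_read_samples))
    cat("  zero-read samples at prior mean:",
        paste(x$zero_read_samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lda_fit <- function(object, n_top = 5, ...) {
  hd <- apply(object$beta_hat, 1L, hyperdominance_count)
  top <- apply(object$beta_hat, 1L, function(p) {
    o <- order(-p, seq_along(p))[seq_len(min(n_top, length(p)))]
    paste(sprintf("%s (%.3f)", colnames(object$beta_hat)[o], p[o]),
          collapse = ", ")
  })
  out <- data.frame(subcommunity = rownames(object$beta_hat),
                    mean_mixture = colMeans(object$theta_hat),
                    half_abundance_genera = hd,
                    top_genera = top, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(table = out, K = object$K), class = "summary.lda_fit")
}

#' @export
print.summary.lda_fit <- function(x, ...) {
  cat("Subcommunity decomposition (K =", x$K, ")\n")
  print(x$table, right = FALSE)
  invisible(x)
}

#' @export
coef.lda_fit <- function(object, ...) object$beta_hat

#' @export
logLik.lda_fit <- function(object, ...) {
  n <- length(object$loglik_trace)
  kept <- object$loglik_trace[seq.int(object$n_burnin + 1L, n)]
  structure(mean(kept), class = "logLik", df = NA_integer_)
}

#' Fold in new samples under a fitted decomposition
#'
#' Re-estimates per-sample mixtures for new count rows with the fitted
#' `beta_hat` frozen (fold-in Gibbs).
#'
#' @param object an `lda_fit`.
#' @param newdata a [count_table()] whose taxa are a subset of the fit's.
#' @param n_inner fold-in Gibbs sweeps per sample.
#' @param seed integer RNG seed.
#' @param ... unused.
#' @return D_new x K matrix of mixtures.
#' @export
predict.lda_fit <- function(object, newdata, n_inner = 50, seed = NULL, ...) {
  stopifnot(inherits(newdata, "count_table"))
  map <- match(colnames(newdata), colnames(object$beta_hat))
  if (anyNA(map)) {
    warning(sum(is.na(map)), " held-out taxa absent from the fit dropped")
    newdata <- count_table(unclass(newdata)[, !is.na(map), drop = FALSE])
    map <- map[!is.na(map)]
  }
  K <- object$K
  with_seed(seed, {
    th <- matrix(1 / K, nrow(newdata), K,
                 dimnames = list(rownames(newdata), rownames(object$beta_hat)))
    for (d in seq_len(nrow(newdata))) {
      row <- unclass(newdata)[d, ]
      if (sum(row) == 0) next
      word <- rep.int(map[row > 0] - 1L, row[row > 0])
      th[d, ] <- cpp_lda_foldin(word, object$beta_hat, object$alpha,
                                as.integer(n_inner))
    }
    th
  })
}

#' Held-out perplexity of a fitted decomposition
#'
#' Per-sample mixtures are re-estimated by fold-in Gibbs with the fitted
#' profiles frozen, and perplexity is exp(-sum(log p(read)) / total reads)
#' (lower is better). The default `"completion"` scheme estimates each
#' held-out sample's mixture on half of its reads (alternating tokens,
#' deterministic) and scores the other half, in both directions, so extra
#' subcommunities cannot pay for themselves by adapting to the scored reads;
#' `"foldin"` re-estimates on all reads and scores the same reads (the
#' optimistic variant).
#'
#' @param fit an `lda_fit`.
#' @param heldout a [count_table()]; taxa absent from the fit are dropped with
#'   a warning.
#' @param n_inner fold-in sweeps.
#' @param method `"completion"` (default) or `"foldin"`.
#' @param seed integer RNG seed.
#' @return Positive number.
#' @export
heldout_perplexity <- function(fit, heldout, n_inner = 50,
                               method = c("completion", "foldin"),
                               seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "lda_fit"), inherits(heldout, "count_table"))
  common <- intersect(colnames(heldout), colnames(fit$beta_hat))
  if (length(common) < ncol(heldout)) {
    warning(ncol(heldout) - length(common),
            " held-out taxa absent from the fit dropped")
    heldout <- count_table(unclass(heldout)[, common, drop = FALSE])
  }
  map <- match(colnames(heldout), colnames(fit$beta_hat))
  B <- fit$beta_hat
  K <- fit$K
  logp <- 0; n <- 0
  with_seed(seed, {
    for (d in seq_len(nrow(heldout))) {
      row <- unclass(heldout)[d, ]
      N <- sum(row)
      if (N == 0) next
      word <- rep.int(map[row > 0] - 1L, row[row > 0])
      if (method == "foldin" || N == 1L) {
        th <- cpp_lda_foldin(word, B, fit$alpha, as.integer(n_inner))
        pw <- drop(th %*% B)[word + 1L]
        logp <- logp + sum(log(pw))
        n <- n + N
      } else {
        half <- seq_along(word) %% 2L == 1L
        for (est in list(half, !half)) {
          th <- cpp_lda_foldin(word[est], B, fit$alpha, as.integer(n_inner))
          pw <- drop(th %*% B)[word[!est] + 1L]
          logp <- logp + sum(log(pw))
          n <- n + sum(!est)
        }
      }
    }
  })
  if (n == 0) stop_validation("held-out table has no reads")
  exp(-logp / n)
}

#' Select K and the tree cut depth C by 5 x 2-fold cross-validation
#'
#' Draws `n_reps` independent two-fold splits of the samples; for each grid
#' cell (K, C) the counts are aggregated at depth C, the model is fitted on
#' one fold and scored by held-out perplexity on the other, in both
#' directions. The chosen cell minimizes the mean perplexity over all folds.
#'
#' @param counts a [count_table()].
#' @param tree optional [taxon_tree()]; required when `C_grid` is given.
#' @param K_grid integer vector of candidate subcommunity numbers.
#' @param C_grid optional integer vector of candidate cut depths (`NA`/NULL =
#'   no aggregation).
#' @param n_reps number of replicate 2-fold splits (default 5).
#' @param alpha,gamma hyperparameters (alpha defaults to 1/K per cell).
#' @param n_burnin,n_keep Gibbs budget per CV fit; the reduced defaults
#'   (500/200) trade exactness for grid coverage and are recorded in the
#'   result.
#' @param n_inner fold-in sweeps for perplexity.
#' @param rule `"1se"` (default): smallest K, then smallest C, among cells
#'   whose mean perplexity lies within one standard error of the minimum —
#'   held-out perplexity plateaus once K reaches the data's subcommunity
#'   count, so the parsimony rule recovers the smallest adequate model;
#'   `"min"`: plain argmin.
#' @param seed integer RNG seed governing splits and fits.
#' @return Object of class `model_selection`: the full `grid` table
#'   (K, C, rep, fold, perplexity), per-cell `summary`, `chosen` (K, C) under
#'   `rule`, and `chosen_min` (the argmin cell).
#' @export
select_model <- function(counts, tree = NULL, K_grid, C_grid = NULL,
                         n_reps = 5, alpha = NULL, gamma = 0.1,
                         n_burnin = 500, n_keep = 200, n_inner = 50,
                         rule = c("1se", "min"), seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(counts, "count_table"), length(K_grid) >= 1)
  if (is.null(C_grid)) C_grid <- NA_integer_
  if (!all(is.na(C_grid)) && is.null(tree))
    stop_validation("C_grid given but no tree supplied")
  D <- nrow(counts)
  if (D < 2L) stop_validation("need at least 2 samples to cross-validate")
  with_seed(seed, {
    agg <- lapply(C_grid, function(C)
      if (is.na(C)) counts else aggregate_tree_depth(counts, tree, C))
    rows <- list()
    for (r in seq_len(n_reps)) {
      fold <- sample(rep_len(1:2, D))
      for (ci in seq_along(C_grid)) for (K in K_grid) {
        for (f in 1:2) {
          train <- count_table(unclass(agg[[ci]])[fold == f, , drop = FALSE])
          test <- count_table(unclass(agg[[ci]])[fold != f, , drop = FALSE])
          perp <- tryCatch({
            a <- if (is.null(alpha)) 1 / K else alpha
            fit <- fit_lda(train, K = K, alpha = a, gamma = gamma,
                           n_burnin = n_burnin, n_keep = n_keep)
            heldout_perplexity(fit, test, n_inner = n_inner)
          }, error = function(e) {
            message("grid cell K=", K, " C=", C_grid[ci], " failed: ",
                    conditionMessage(e))
            NA_real_
          })
          rows[[length(rows) + 1L]] <-
            data.frame(K = K, C = C_grid[ci], rep = r, fold = f,
                       perplexity = perp)
        }
      }
    }
    grid <- do.call(rbind, rows)
    key <- paste(grid$K, grid$C)  # NA-safe cell key
    summ <- do.call(rbind, lapply(split(grid, key), function(g)
      data.frame(K = g$K[1L], C = g$C[1L],
                 mean_perplexity = mean(g$perplexity),
                 sd_perplexity = stats::sd(g$perplexity),
                 n_failed = sum(is.na(g$perplexity)))))
    summ <- summ[order(summ$K, summ$C), , drop = FALSE]
    rownames(summ) <- NULL
    ok <- !is.na(summ$mean_perplexity)
    if (!any(ok)) stop("every grid cell failed to fit")
    cand <- summ[ok, , drop = FALSE]
    i_min <- which.min(cand$mean_perplexity)
    n_folds <- 2L * n_reps
    thresh <- cand$mean_perplexity[i_min] +
      cand$sd_perplexity[i_min] / sqrt(n_folds)
    within <- cand[cand$mean_perplexity <= thresh, , drop = FALSE]
    best <- if (rule == "1se") within[order(within$K, within$C), ][1L, ]
    else cand[i_min, ]
    structure(list(grid = grid, summary = summ,
                   chosen = list(K = best$K, C = best$C),
                   chosen_min = list(K = cand$K[i_min], C = cand$C[i_min]),
                   rule = rule,
                   n_burnin = n_burnin, n_keep = n_keep, seed = seed),
              class = "model_selection")
  })
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model_selection: chosen K = %d, C = %s (Gibbs %d + %d per CV fit)\n",
              x$chosen$K, format(x$chosen$C), x$n_burnin, x$n_keep))
  print(x$summary)
  invisible(x)
}

#' Minimum number of taxa holding a fraction of total abundance
#'
#' Hyperdominance statistic: the smallest k such that the k most abundant
#' entries of a profile sum to at least `fraction` (default half) of the
#' total. Ties in abundance are broken by position.
#'
#' @param profile simplex vector.
#' @param fraction target cumulative share in (0, 1].
#' @return Integer count.
#' @export
hyperdominance_count <- function(profile, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (abs(sum(profile) - 1) > 1e-6)
    stop_validation("profile must sum to 1")
  cs <- cumsum(profile[order(-profile, seq_along(profile))])
  unname(which(cs >= fraction - 1e-12)[1L])
}

#' Match estimated to true subcommunity profiles
#'
#' Finds the one-to-one assignment of estimated to reference profile rows
#' minimizing the summed total-variation distance (exhaustive search, K <= 8;
#' label switching makes this matching necessary before any recovery
#' comparison).
#'
#' @param est_beta,true_beta K x W simplex matrices.
#' @return list with `perm` (est row k matches true row `perm[k]`), `tv`
#'   (per-pair total-variation distances) and `mean_tv`.
#' @export
align_subcommunities <- function(est_beta, true_beta) {
  if (!all(dim(est_beta) == dim(true_beta)))
    stop_validation("dimension mismatch between estimated and true profiles")
  K <- nrow(est_beta)
  if (K > 8L) stop("exhaustive matching supports K <= 8")
  tv <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    tv[i, j] <- 0.5 * sum(abs(est_beta[i, ] - true_beta[j, ]))
  perms <- all_permutations(K)
  costs <- vapply(perms, function(p) sum(tv[cbind(seq_len(K), p)]), 0)
  best <- perms[[which.min(costs)]]
  list(perm = best, tv = tv[cbind(seq_len(K), best)],
       mean_tv = min(costs) / K)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) out[[length(out) + 1L]] <-
    append(p, n, after = pos - 1L)
  out
}
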
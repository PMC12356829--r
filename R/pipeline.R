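#' Default pipeline configuration
#'
#' Defaults record the headline analysis settings: rare-taxon filter at 100
#' total reads, rarefaction depth 19,923 (applied only where requested),
#' K = 5 subcommunities and tree cut depth C = 9, and a six-variable
#' continuous-time model (MMT, MMP, dR, dE, C/N, pH) in per-month units.
#'
#' @return nested list of settings; see [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    counts = NULL, metadata = NULL, tree = NULL, out_dir = NULL,
    seed = 1L,
    lda = list(K = 5L, K_grid = NULL, C = 9L, C_grid = NULL,
               alpha = NULL, gamma = 0.1,
               n_burnin = 10000L, n_keep = 1000L,
               n_burnin_cv = 500L, n_keep_cv = 200L, n_inner = 50L,
               min_total = 100L, rarefy_depth = NULL,
               order = "filter,rarefy,aggregate,fit"),
    rank = list(min_p = 0, attach = "t1"),
    ctdyn = list(time_unit = "month", days_per_month = 30.44,
                 drift = "diag", diffusion = "diag", method = "ml",
                 multistart = 2L, draws = 1000L, warmup = 1000L,
                 variables = c(MMT = "mmt", MMP = "mmp", dR = "delta_r",
                               dE = "delta_e", CN = "cn_ratio", pH = "ph"))
  )
}

#' Validate a pipeline configuration
#'
#' Returns blocking errors and advisory warnings as data; nothing is thrown.
#'
#' @param config pipeline configuration list (merged over
#'   [default_pipeline_config()]).
#' @return data.frame with columns `level` ("error"/"warning") and `message`;
#'   zero rows when fully valid.
#' @export
validate_config <- function(config) {
  cf <- utils::modifyList(default_pipeline_config(), config)
  f <- list()
  add <- function(level, msg) f[[length(f) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  if (is.null(cf$counts)) add("error", "no counts table or path configured")
  else if (is.character(cf$counts) && !file.exists(cf$counts))
    add("error", paste0("counts path does not exist: ", cf$counts))
  if (is.null(cf$metadata)) add("error", "no metadata table or path configured")
  else if (is.character(cf$metadata) && !file.exists(cf$metadata))
    add("error", paste0("metadata path does not exist: ", cf$metadata))
  if (is.character(cf$tree) && !file.exists(cf$tree))
    add("error", paste0("tree path does not exist: ", cf$tree))
  if (!is.null(cf$lda$K_grid) && 1L %in% cf$lda$K_grid)
    add("warning", "K_grid contains 1 (a single subcommunity explains nothing)")
  if (!is.null(cf$lda$rarefy_depth) && inherits(cf$counts, "count_table") &&
      all(rowSums(cf$counts) < cf$lda$rarefy_depth))
    add("warning", paste0("rarefaction depth ", cf$lda$rarefy_depth,
                          " exceeds every sample total; all samples would be dropped"))
  if (length(f) == 0L)
    return(data.frame(level = character(0), message = character(0)))
  out <- do.call(rbind, f)
  rownames(out) <- NULL
  out
}

#' Run the full subcommunity rank-dynamics analysis
#'
#' Executes the end-to-end workflow: rare-taxon filter, optional rarefaction,
#' model selection over (K, C) or a fixed pair, tree-depth aggregation, LDA
#' fit, per-site rank-abundance statistics (Evar, Shannon, Delta E, Delta R),
#' joining with the environmental variables, grand-mean standardization, and
#' the continuous-time OU state-space fit with Kalman-smoothed trajectories.
#' Every numeric table is written to `out_dir` (when given) and the whole run
#' is a pure function of (inputs, config): the same configuration reproduces
#' the tables byte for byte.
#'
#' @param config list merged over [default_pipeline_config()]; `counts`,
#'   `metadata` (and optionally `tree`) may be file paths or in-memory
#'   objects.
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  cf <- utils::modifyList(default_pipeline_config(), config)
  findings <- validate_config(cf)
  if (any(findings$level == "error"))
    stop("invalid pipeline config: ",
         paste(findings$message[findings$level == "error"], collapse = "; "))
  stage <- "load_inputs"
  report <- tryCatch({
    counts <- if (is.character(cf$counts)) read_count_table(cf$counts) else cf$counts
    metadata <- if (is.character(cf$metadata)) read_sample_table(cf$metadata) else cf$metadata
    tree <- if (is.character(cf$tree))
      read_taxon_tree(cf$tree, taxon_ids = colnames(counts)) else cf$tree
    cfg_hash <- config_hash(cf, counts, metadata)

    stage <- "filter_rare_taxa"
    counts_f <- filter_rare_taxa(counts, min_total = cf$lda$min_total)

    stage <- "rarefy"
    if (!is.null(cf$lda$rarefy_depth))
      counts_f <- rarefy(counts_f, depth = cf$lda$rarefy_depth,
                         seed = derive_seed(cf$seed, "rarefy"))

    stage <- "select_model"
    selection <- NULL
    K <- cf$lda$K; C <- cf$lda$C
    grid_K <- cf$lda$K_grid; grid_C <- cf$lda$C_grid
    if (!is.null(grid_K) && length(grid_K) == 1L &&
        (is.null(grid_C) || length(grid_C) <= 1L)) {
      K <- grid_K                      # grid of one: fixed fit, no CV
      if (!is.null(grid_C)) C <- grid_C
    } else if (!is.null(grid_K) || !is.null(grid_C)) {
      selection <- select_model(counts_f, tree = tree,
                                K_grid = if (is.null(grid_K)) K else grid_K,
                                C_grid = grid_C,
                                gamma = cf$lda$gamma,
                                n_burnin = cf$lda$n_burnin_cv,
                                n_keep = cf$lda$n_keep_cv,
                                n_inner = cf$lda$n_inner,
                                seed = derive_seed(cf$seed, "select"))
      K <- selection$chosen$K
      if (!is.na(selection$chosen$C)) C <- selection$chosen$C
    }

    stage <- "aggregate_tree_depth"
    counts_fit <- if (!is.null(tree) && !is.null(C))
      aggregate_tree_depth(counts_f, tree, C) else counts_f

    stage <- "fit_lda"
    fit <- fit_lda(counts_fit, K = K,
                   alpha = if (is.null(cf$lda$alpha)) 1 / K else cf$lda$alpha,
                   gamma = cf$lda$gamma,
                   n_burnin = cf$lda$n_burnin, n_keep = cf$lda$n_keep,
                   seed = derive_seed(cf$seed, "lda"))
    theta <- fit$theta_hat

    stage <- "rank_dynamics"
    sites <- unique(metadata$site)
    rank_tabs <- lapply(sites, function(s)
      build_rank_dynamics(theta, metadata, s, min_p = cf$rank$min_p,
                          attach = cf$rank$attach))
    rank_all <- do.call(rbind, rank_tabs)

    stage <- "assemble_panel"
    varmap <- cf$ctdyn$variables
    joined <- merge(rank_all, metadata[, c("sample_id", "mmt", "mmp",
                                           "cn_ratio", "ph")],
                    by = "sample_id", sort = FALSE)
    joined <- joined[order(joined$site, joined$time_days), , drop = FALSE]
    panels <- lapply(sites, function(s) {
      j <- joined[joined$site == s, , drop = FALSE]
      Y <- t(as.matrix(j[, unname(varmap), drop = FALSE]))
      rownames(Y) <- names(varmap)
      list(times = j$time_days / cf$ctdyn$days_per_month, Y = Y)
    })
    names(panels) <- sites
    panel <- ou_panel(panels, names(varmap), time_unit = cf$ctdyn$time_unit)
    stage <- "standardize_panel"
    std <- standardize_panel(panel)

    stage <- "fit_ctdyn"
    ct_fit <- if (identical(cf$ctdyn$method, "hierarchical"))
      fit_ctsde_hierarchical(std$panel, draws = cf$ctdyn$draws,
                             warmup = cf$ctdyn$warmup,
                             seed = derive_seed(cf$seed, "ctdyn"))
    else
      fit_ctsde(std$panel, drift = cf$ctdyn$drift,
                diffusion = cf$ctdyn$diffusion,
                multistart = cf$ctdyn$multistart,
                seed = derive_seed(cf$seed, "ctdyn"))
    auto <- summarize_auto_effects(ct_fit)

    stage <- "smooth"
    smoothed <- if (inherits(ct_fit, "ctsde_fit")) {
      span <- range(unlist(lapply(panels, `[[`, "times")))
      predict(ct_fit, grid = seq(floor(span[1L]), ceiling(span[2L]), by = 0.5))
    } else NULL

    stage <- "report"
    rep_obj <- structure(list(
      chosen = list(K = K, C = C), selection = selection,
      lda_fit = fit, theta = theta, rank = rank_all,
      standardization = list(center = std$center, scale = std$scale),
      ct_fit = ct_fit, auto_effects = auto, smoothed = smoothed,
      config = cf, config_hash = cfg_hash,
      seeds = list(master = cf$seed,
                   stages = vapply(c("rarefy", "select", "lda", "ctdyn"),
                                   function(s) derive_seed(cf$seed, s), 1L)),
      out_dir = cf$out_dir), class = "pipeline_report")
    if (!is.null(cf$out_dir)) write_report(rep_obj, cf$out_dir)
    rep_obj
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  report
}

# Fingerprint the configuration plus input content for provenance.
config_hash <- function(cf, counts, metadata) {
  fp <- cf
  fp$out_dir <- NULL   # where tables land must not change what they contain
  fp$counts <- list(dim = dim(counts), total = sum(as.numeric(counts)))
  fp$metadata <- list(n = nrow(metadata),
                      sites = sort(unique(metadata$site)))
  fp$tree <- if (is.character(cf$tree)) cf$tree else !is.null(cf$tree)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(fp, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Write every numeric table of a report; deterministic content only (no
# timestamps), so reruns are byte-identical.
write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  th <- data.frame(sample_id = rownames(rep$theta), rep$theta,
                   check.names = FALSE)
  files <- c(files, write_tsv(th, file.path(out_dir, "theta.tsv")))
  bt <- data.frame(subcommunity = rownames(rep$lda_fit$beta_hat),
                   rep$lda_fit$beta_hat, check.names = FALSE)
  files <- c(files, write_tsv(bt, file.path(out_dir, "beta.tsv")))
  files <- c(files, write_tsv(rep$rank, file.path(out_dir, "rank_metrics.tsv")))
  files <- c(files, write_tsv(rep$auto_effects,
                              file.path(out_dir, "auto_effects.tsv")))
  if (inherits(rep$ct_fit, "ctsde_fit"))
    files <- c(files, write_tsv(param_estimates(rep$ct_fit),
                                file.path(out_dir, "ct_parameters.tsv")))
  if (!is.null(rep$smoothed))
    files <- c(files, write_tsv(rep$smoothed,
                                file.path(out_dir, "smoothed_trajectories.tsv")))
  if (!is.null(rep$selection))
    files <- c(files, write_tsv(rep$selection$grid,
                                file.path(out_dir, "model_selection_grid.tsv")))
  meta <- list(package_version = as.character(utils::packageVersion("racdyn")),
               config_hash = rep$config_hash, chosen = rep$chosen,
               seeds = rep$seeds)
  jsonlite::write_json(meta, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, file.path(out_dir, "report.json")))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  chosen K = %d, C = %s (config %s)\n", x$chosen$K,
              format(x$chosen$C), substr(x$config_hash, 1, 8)))
  cat(sprintf("  %d samples decomposed; rank series over %d sites\n",
              nrow(x$theta), length(unique(x$rank$site))))
  cat("  auto effects (most persistent first):",
      paste(sprintf("%s %.3f", x$auto_effects$variable,
                    x$auto_effects$auto_effect), collapse = ", "), "\n")
  if (!is.null(x$out_dir)) cat("  tables written to", x$out_dir, "\n")
  invisible(x)
}
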
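#' Build a rank-abundance curve from a mixture row
#'
#' Sorts subcommunity abundances in descending order and assigns ranks 1..S.
#' Entries with abundance <= `min_p` are excluded (retained abundances are not
#' renormalized); abundance ties are broken by subcommunity index.
#'
#' @param theta_row simplex vector over K subcommunities (named or not).
#' @param min_p exclusion threshold (default 0: zero-abundance entries drop).
#' @return Object of class `rac`: data.frame with subcommunity, abundance,
#'   rank, plus attribute `S`.
#' @export
build_rac <- function(theta_row, min_p = 0) {
  p <- as.numeric(theta_row)
  if (all(p == 0)) stop_validation("all-zero abundance row")
  ids <- if (!is.null(names(theta_row))) names(theta_row) else
    paste0("SC", seq_along(p))
  keep <- which(p > min_p)
  if (length(keep) == 0L) stop_validation("min_p excludes every subcommunity")
  o <- keep[order(-p[keep], keep)]
  out <- data.frame(subcommunity = ids[o], abundance = p[o],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  structure(out, class = c("rac", "data.frame"), S = length(o))
}

#' Smith-Wilson evenness index Evar
#'
#' Evar = 1 - (2/pi) * arctan( sum_i (ln p_i - mean_j ln p_j)^2 / S ).
#' Scale-invariant: raw and relative abundances give identical values; 1 means
#' perfectly even. Requires strictly positive abundances (exclude zeros
#' first); a single-entry vector returns 1 by convention with a warning.
#'
#' @param p positive abundance vector.
#' @return Number in [0, 1].
#' @export
evar <- function(p) {
  p <- as.numeric(p)
  if (any(p <= 0) || length(p) == 0L)
    stop_validation("evar needs strictly positive abundances")
  S <- length(p)
  if (S == 1L) {
    warning("evar of a single subcommunity is 1 by convention")
    return(1)
  }
  lp <- log(p)
  v <- sum((lp - mean(lp))^2) / S
  1 - (2 / pi) * atan(v)
}

#' Shannon entropy (natural log)
#'
#' H = -sum(p * ln p) over positive entries, with p the relative abundances.
#'
#' @param counts_or_p non-negative abundance vector with positive sum.
#' @return Non-negative number.
#' @export
shannon_entropy <- function(counts_or_p) {
  x <- as.numeric(counts_or_p)
  if (length(x) == 0L || any(x < 0) || sum(x) <= 0)
    stop_validation("need a non-negative vector with positive sum")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Mean rank shift between consecutive rank-abundance curves
#'
#' Delta R = (1/S) * sum_i |R_{i,t+1} - R_{i,t}| over the union of the two
#' curves' subcommunities; members absent from one curve are placed tied at
#' the last rank (S_present + 1) of that curve.
#'
#' @param rac_t,rac_t1 two [build_rac()] objects.
#' @return Non-negative number.
#' @export
mean_rank_shift <- function(rac_t, rac_t1) {
  stopifnot(inherits(rac_t, "rac"), inherits(rac_t1, "rac"))
  ids <- union(rac_t$subcommunity, rac_t1$subcommunity)
  if (length(intersect(rac_t$subcommunity, rac_t1$subcommunity)) == 0L)
    stop_validation("rank curves share no subcommunity")
  rank_of <- function(rac) {
    r <- rac$rank[match(ids, rac$subcommunity)]
    r[is.na(r)] <- attr(rac, "S") + 1L  # absent: tied last
    r
  }
  mean(abs(rank_of(rac_t1) - rank_of(rac_t)))
}

#' Evenness change between consecutive sampling times
#'
#' Delta E = Evar(t+1) - Evar(t), signed; `absolute = TRUE` gives |Delta E|
#' for sensitivity analysis.
#'
#' @param evar_t,evar_t1 evenness values in [0, 1].
#' @param absolute take the absolute value?
#' @return Number in [-1, 1].
#' @export
evenness_change <- function(evar_t, evar_t1, absolute = FALSE) {
  stopifnot(evar_t >= 0, evar_t <= 1, evar_t1 >= 0, evar_t1 <= 1)
  d <- evar_t1 - evar_t
  if (absolute) abs(d) else d
}

#' Per-site time series of rank-dynamics statistics
#'
#' Orders a site's samples chronologically and computes, per sampling time,
#' Evar and Shannon entropy of the subcommunity mixture, and between
#' consecutive times the evenness change Delta E and mean rank shift Delta R.
#' The change over interval (t, t+1) is attached to the arrival time t+1
#' (`attach = "t1"`), leaving the series' first element undefined.
#'
#' @param theta D x K mixture matrix with sample ids as rownames.
#' @param metadata data.frame as from [read_sample_table()].
#' @param site site name (must have >= 2 samples).
#' @param min_p abundance threshold passed to [build_rac()].
#' @param attach attach interval statistics to `"t1"` (default) or `"t0"`.
#' @return Object of class `rank_dynamics`: data.frame with sample_id,
#'   time_days, evar, shannon, delta_e, delta_r, interval_days.
#' @export
build_rank_dynamics <- function(theta, metadata, site, min_p = 0,
                                attach = c("t1", "t0")) {
  attach <- match.arg(attach)
  md <- metadata[metadata$site == site, , drop = FALSE]
  if (nrow(md) < 2L)
    stop_validation("site ", site, " has fewer than 2 samples")
  md <- md[order(md$time_days, md$sample_id), , drop = FALSE]
  idx <- match(md$sample_id, rownames(theta))
  if (anyNA(idx)) stop_validation("metadata sample missing from theta: ",
                                  md$sample_id[which(is.na(idx))[1L]])
  T <- nrow(md)
  racs <- lapply(idx, function(i) build_rac(theta[i, ], min_p = min_p))
  ev <- vapply(racs, function(r) {
    if (attr(r, "S") == 1L) suppressWarnings(evar(r$abundance))
    else evar(r$abundance)
  }, 0)
  sh <- vapply(idx, function(i) shannon_entropy(theta[i, ]), 0)
  de <- dr <- rep(NA_real_, T)
  gap <- c(NA_real_, diff(md$time_days))
  at <- if (attach == "t1") 2:T else 1:(T - 1L)
  for (j in 2:T) {
    de[at[j - 1L]] <- evenness_change(ev[j - 1L], ev[j])
    dr[at[j - 1L]] <- mean_rank_shift(racs[[j - 1L]], racs[[j]])
  }
  if (attach == "t0") gap <- c(diff(md$time_days), NA_real_)
  out <- data.frame(sample_id = md$sample_id, site = site,
                    time_days = md$time_days, evar = ev, shannon = sh,
                    delta_e = de, delta_r = dr, interval_days = gap,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("rank_dynamics", "data.frame"))
}
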
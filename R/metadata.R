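#' Read a sample metadata table
#'
#' CSV with columns \code{sample_id}, \code{site}, and either \code{date}
#' (ISO 8601) or \code{time_days}, plus the environmental variables
#' \code{mmt} (monthly mean temperature, deg C), \code{mmp} (monthly mean
#' precipitation, mm), \code{cn_ratio} (soil carbon-to-nitrogen ratio) and
#' \code{ph}. Missing environmental cells are kept as \code{NA} and propagated
#' downstream (the Kalman update skips missing dimensions); nothing is imputed
#' at read time.
#'
#' Dates are converted to a 1-based day index relative to \code{origin}
#' (default: January 1 of the earliest study year), so that e.g. Jan 8 of the
#' first year is day 8. Rows are sorted by (site, time_days, sample_id);
#' same-day rows within a site are accepted and tie-broken by sample id.
#'
#' @param path CSV path.
#' @param origin optional \code{Date} (or ISO string) for day 1's calendar
#'   anchor; defaults to Jan 1 of the first study year.
#' @return A \code{data.frame} with columns sample_id, site, time_days,
#'   mmt, mmp, cn_ratio, ph and attribute \code{"origin"}.
#' @export
read_sample_table <- function(path, origin = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "site")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_validation("metadata missing columns: ",
                                    paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in metadata: ",
                    df$sample_id[duplicated(df$sample_id)][1L])
  if ("time_days" %in% names(df) && !all(is.na(df$time_days))) {
    td <- as.numeric(df$time_days)
    origin_used <- if (is.null(origin)) NA else as.Date(origin)
  } else {
    if (!"date" %in% names(df))
      stop_validation("metadata needs a 'date' or 'time_days' column")
    d <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(d)) {
      bad <- which(is.na(d))[1L]
      stop(sprintf("unparseable date '%s' at metadata row %d", df$date[bad], bad))
    }
    origin_used <- if (is.null(origin))
      as.Date(sprintf("%d-01-01", min(as.integer(format(d, "%Y")))))
    else as.Date(origin)
    td <- as.numeric(d - origin_used) + 1  # origin itself is day 1
  }
  env <- function(col) if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else NA_real_
  out <- data.frame(sample_id = as.character(df$sample_id),
                    site = as.character(df$site),
                    time_days = td,
                    mmt = env("mmt"), mmp = env("mmp"),
                    cn_ratio = env("cn_ratio"), ph = env("ph"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$site, out$time_days, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "origin") <- origin_used
  out
}
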
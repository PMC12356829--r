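#' Construct a sample-by-taxon count table
#'
#' The shared container for genus-level community data: a non-negative integer
#' matrix with samples in rows and taxa (genera) in columns, carrying unique
#' sample and taxon identifiers as dimnames.
#'
#' @param counts numeric matrix of non-negative integers, rows = samples.
#' @param sample_ids,taxon_ids character vectors; default to existing dimnames.
#' @return An object of class \code{count_table} (an integer matrix).
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop_validation("count table must have at least one sample and one taxon")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(sample_ids)) stop_validation("duplicate sample ids")
  if (anyDuplicated(taxon_ids)) stop_validation("duplicate taxon ids")
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    stop_validation("id lengths do not match count matrix dimensions")
  if (!is_count(counts)) stop_validation("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(counts, class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a count table from TSV or BIOM
#'
#' TSV layout: header row of taxon ids, first column of sample ids, integer
#' cells. BIOM input (JSON, BIOM 1.0) is read through the biomformat package
#' and transposed to samples-in-rows.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    return(count_table(t(m)))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stop_validation("count table file has an empty data section")
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "malformed count at row '%s', column '%s': '%s' (must be a non-negative integer)",
      ids[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]],
      cells[bad[1L, 1L], bad[1L, 2L]]))
  count_table(num, sample_ids = ids, taxon_ids = colnames(cells))
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x, f))`
#' returns an identical table.
#'
#' @param x a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
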
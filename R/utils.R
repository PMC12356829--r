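# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so generators are pure in (args, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- (as.double(master) * 48271 + match(stage, c(
    "study", "lda", "select", "rarefy", "rank", "ctdyn", "profiles",
    "counts", "ltn", "ou", "other"), nomatch = 11L) * 7919) %% 2147483629
  as.integer(h) + 1L
}

stop_validation <- function(...) {
  stop(structure(class = c("racdyn_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)

check_simplex_rows <- function(m, tol = 1e-9, what = "matrix") {
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol) || any(m < -tol))
    stop_validation(what, ": rows must lie on the probability simplex")
  invisible(TRUE)
}
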
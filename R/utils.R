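# internal helpers shared across modules

# scalar checks -------------------------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("configuration error: `%s` must be a single finite number", name))
  }
  if (x < min || x > max) {
    abort(sprintf("configuration error: `%s` = %s is outside [%s, %s]", name, x, min, max))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("configuration error: `%s` must be a whole number", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# seeded RNG: every stochastic entry point funnels through this so a single
# integer seed makes a whole run reproducible without touching global state
# beyond the call
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    check_number(seed, "seed", integerish = TRUE)
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# interval algebra on open intervals, used by fine mapping ------------------
# intervals are rows of a 2-column matrix (lo, hi), open at both ends;
# unbounded ends are +-Inf

intervals_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  out <- list()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    keep <- lo < hi
    if (any(keep)) out[[length(out) + 1L]] <- cbind(lo[keep], hi[keep])
  }
  if (length(out) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  m <- do.call(rbind, out)
  m[order(m[, 1L]), , drop = FALSE]
}
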
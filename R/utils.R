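# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    stop(sprintf("'%s' must be a data.frame", what), call. = FALSE)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("'%s' is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps independent random streams per generator: adding one generator never
# perturbs the draws of another.  Arithmetic kept in double precision well
# below 2^53, result folded into 32-bit integer range.
stream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) * 977
  as.integer((as.numeric(seed) %% 2147483629) * 69069 %% 2147483629 + h) %% 2147483629L
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Allocate `total` items to categories with the stated fractions using
# largest-remainder rounding, so planted partitions are exact.
largest_remainder <- function(fractions, total) {
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-8, total >= 0)
  raw <- fractions * total
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    ord <- order(raw - base, seq_along(raw), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
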
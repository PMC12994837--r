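# Internal helpers shared across modules.

# Display rounding: round-half-even to `digits`, matching the one-decimal
# precision used in published tables. base::round() is already half-even.
fmt_pct <- function(x, digits = 1) round(100 * x, digits)

# Canonical race-set string: sorted, semicolon-joined, "" when empty.
race_set_string <- function(sets) {
  vapply(sets, function(s) {
    s <- unique(s[!is.na(s) & nzchar(s)])
    if (length(s) == 0L) "" else paste(sort(s), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

race_set_split <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

# Label identity used wherever two harmonized labels are compared for
# exact equality (conflict dropping, concordance of Multiracial pairs is
# category-level so race sets are NOT part of identity there).
label_key <- function(category, race_set) paste(category, race_set, sep = "|")

assert_cols <- function(data, cols, what = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Run an expression with a temporary RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
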
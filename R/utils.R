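# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# sample() without the length-1 numeric surprise
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

# Reverse complement of a plain character scalar (ACGTN alphabet).
revcomp_chr <- function(s) {
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", s)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), "", USE.NAMES = FALSE)
}

# Phred+33 quality string -> integer vector
phred_ints <- function(qual) utf8ToInt(qual) - 33L

int_phred <- function(q) intToUtf8(q + 33L)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x)

# Resolve an integer "distribution spec": a scalar (constant), a length-2
# range c(lo, hi) sampled uniformly, or a function(n) returning n integers.
resolve_int_spec <- function(spec, n, what = "value") {
  vals <- if (is.function(spec)) {
    spec(n)
  } else if (is.numeric(spec) && length(spec) == 1L) {
    rep(spec, n)
  } else if (is.numeric(spec) && length(spec) == 2L) {
    if (spec[2L] < spec[1L]) stopf("degenerate %s range [%s, %s]", what, spec[1L], spec[2L])
    spec[1L] + sample.int(spec[2L] - spec[1L] + 1L, n, replace = TRUE) - 1L
  } else {
    stopf("%s spec must be a scalar, a c(lo, hi) range or a function(n)", what)
  }
  vals <- as.integer(round(vals))
  if (length(vals) != n || anyNA(vals) || any(vals < 1L))
    stopf("%s spec must yield %d positive integers", what, n)
  vals
}
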
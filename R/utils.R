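# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, then restore the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic digest of numeric/character content: 31-bit polynomial
# rolling hash over the UTF-8 bytes of a canonical formatting.  Used only
# to stamp reports so that identical inputs yield identical digests.
content_digest <- function(x) {
  txt <- paste(vapply(x, function(v) {
    if (is.numeric(v)) paste(sprintf("%.12g", v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1)), collapse = ";")
  bytes <- as.integer(charToRaw(txt))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

fmt_ppm <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
fmt_intensity <- function(x) ifelse(is.na(x), "", sprintf("%.6e", x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
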
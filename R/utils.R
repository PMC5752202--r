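# Small shared helpers: seeded randomness, truncated normals, digests.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a parent seed and a label path
#'
#' All stochastic stages draw their randomness from seeds derived with this
#' function so that one top-level seed determines every output, while
#' independent stages (channels, chromosomes, scenario draws) get
#' decorrelated streams. The result is always a positive 32-bit integer.
#'
#' @param seed integer parent seed.
#' @param ... further character/numeric labels identifying the stream.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 17
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  # avalanche: spread near-identical keys across the full seed range
  h <- (h * 48271) %% 2147483647
  h <- (h * 69621) %% 2147483563
  as.integer(h %% 2147483562L) + 1L
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Truncated normal via inverse-CDF; exact, vectorized, no rejection loop.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# md5 of an arbitrary R object (content digest for manifests/determinism).
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
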
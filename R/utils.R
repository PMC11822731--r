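# Internal helpers: seed substreams, validation, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

# One user-facing seed is split into independent substreams so that, e.g.,
# disabling pixel noise does not shift particle positions. The mixer is a
# simple 31-bit multiplicative hash of (seed, purpose); all arithmetic stays
# below 2^53 so it is exact in doubles.
substream_seed <- function(seed, purpose) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(purpose))) h <- (h * 131 + c) %% m
  s <- as.double(seed) %% m
  as.integer((h * 48271 + s * 69621 + 11) %% m)
}

with_substream <- function(seed, purpose, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, purpose))
  eval.parent(substitute(expr))
}

stop_domain <- function(...) {
  stop(structure(class = c("eva_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_domain(name, " must be positive and finite")
  invisible(x)
}

# FWHM of a Gaussian = 2 sqrt(2 log 2) sigma
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# One-sample KS statistic of sorted values against theoretical CDF values
ks_statistic <- function(theor_sorted) {
  n <- length(theor_sorted)
  i <- seq_len(n)
  max(pmax(i / n - theor_sorted, theor_sorted - (i - 1) / n))
}

# tile accessors -------------------------------------------------------------
tile_data <- function(tile) {
  if (is.matrix(tile)) tile else tile$data
}

is_eva_tile <- function(x) inherits(x, "eva_tile")
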
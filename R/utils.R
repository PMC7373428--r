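# Internal helpers shared across modules.

#' @import stats
#' @importFrom utils combn read.csv write.csv packageVersion
#' @importFrom graphics lines abline plot
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be strictly positive (got %s)", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stopf("'%s' must be non-negative (got %s)", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

# Seed scope: every generator seeds R's global RNG (Mersenne-Twister) itself,
# so identical configs are bit-reproducible; NULL leaves the RNG untouched.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L)
      stopf("'seed' must be a single integer or NULL")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# micrograms/cm^2 -> picograms/micrometre^2 (1 ug/cm^2 = 1e6 pg / 1e8 um^2)
UG_CM2_TO_PG_UM2 <- 0.01
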
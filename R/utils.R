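#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched. All simulators route randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

# FWHM of a Gaussian -> standard deviation
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# numerically stable exp(a) * pnorm(b): exp(a + log Phi(b))
exp_pnorm <- function(a, b) {
  out <- a + stats::pnorm(b, log.p = TRUE)
  exp(out)
}
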
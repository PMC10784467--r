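# Standard gravity used for g <-> m/s2 conversion.
GRAVITY_MS2 <- 9.80665

# Run code under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gaitdx_parameter_error")
  }
  ok_min <- if (strict_min) x > min else x >= min
  if (!ok_min || x > max) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x),
          class = "gaitdx_parameter_error")
  }
  invisible(x)
}

# Population standard deviation / variance (denominator n).
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))
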
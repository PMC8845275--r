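# Internal error helpers: condition classes let callers distinguish schema
# violations, bad arguments and incomplete catalogs.

t2d_validation_error <- function(field, constraint) {
  rlang::abort(
    sprintf("invalid value for '%s': %s", field, constraint),
    class = "t2dsim_validation_error"
  )
}

t2d_argument_error <- function(msg) {
  rlang::abort(msg, class = "t2dsim_argument_error")
}

t2d_config_error <- function(msg) {
  rlang::abort(msg, class = "t2dsim_config_error")
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    t2d_validation_error(field, "must be a fraction in [0, 1]")
  }
  x
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    t2d_validation_error(field, "must be a non-negative number")
  }
  x
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    t2d_validation_error(field, "must be strictly positive")
  }
  x
}

# Run `expr` under a fixed seed, then restore the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# mean/sd pair stored as named numeric c(mean =, sd =) (or se).
ms <- function(mean, spread) c(mean = as.numeric(mean), spread = as.numeric(spread))
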
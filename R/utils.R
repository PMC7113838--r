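# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pahburden_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pahburden_data_error", "error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == as.integer(x)
}

is_fraction <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

check_fraction <- function(x, name) {
  if (!is_fraction(x)) stop_config(name, " must be a fraction in [0, 1]")
  x
}

check_count <- function(x, name, positive = FALSE) {
  if (!is_count(x)) stop_config(name, " must be a non-negative integer")
  if (positive && x == 0) stop_config(name, " must be positive")
  as.integer(x)
}
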
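#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish validation failures from
## runtime failures programmatically.
fm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "flavormet_error")))
}

fm_assert <- function(cond, msg, class = "invalid_argument") {
  if (!isTRUE(cond)) fm_stop(msg, class)
}

## All randomized operations take an explicit seed; reproducibility is part
## of the contract, so a missing seed is an error, not a silent default.
fm_check_seed <- function(seed) {
  fm_assert(!missing(seed) && !is.null(seed) && is.numeric(seed) &&
              length(seed) == 1L && is.finite(seed),
            "'seed' must be supplied as a single finite number")
  as.integer(seed)
}

fm_count <- function(x, name, min = 1L) {
  fm_assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
              x == floor(x),
            sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

## Relative standard deviation in percent (sample sd / mean * 100).
rsd_percent <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(x) / m * 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a
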
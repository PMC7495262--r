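#' Population standard deviation
#'
#' Dispersion with divisor `n` (not `n - 1`), the convention used for the
#' cohort group tables. A single observation therefore has SD 0.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return Non-negative scalar, or `NA` if `x` has no finite values.
#' @export
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Display rounding (round half away from zero)
#'
#' `round()` in R rounds half to even; published tables round halves away
#' from zero. Comparisons are always done on unrounded values — this is for
#' display and for checking printed cells only.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_display <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared condition helpers -------------------------------------------------

abort_format <- function(msg) stop(errorCondition(msg, class = c("affectlytics_format_error", "error")))
abort_integrity <- function(msg) stop(errorCondition(msg, class = c("affectlytics_integrity_error", "error")))
abort_config <- function(msg) stop(errorCondition(msg, class = c("affectlytics_config_error", "error")))

# signal an undefined feature (zero samples, zero surviving epochs, zero
# denominator); callers receive NA plus a classed warning, never a silent 0
undefined_feature <- function(what) {
  warning(warningCondition(
    paste0("undefined feature: ", what),
    class = "affectlytics_undefined_feature"
  ))
  NA_real_
}
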
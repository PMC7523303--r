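#' @importFrom rlang abort warn inform .data
#' @importFrom stats setNames rnorm rlnorm runif
NULL

# Numerical tolerance used for all probability-sum and conservation checks.
.tol <- 1e-9

#' Round half away from zero
#'
#' Base `round()` rounds half to even; burden-of-disease summary tables
#' conventionally round half up, which is what every recomputable published
#' percentage in this domain assumes.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "burdenr_format_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "burdenr_validation_error")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "burdenr_config_error")
}

# Checks that `x` sums to 1 within tolerance; names the offender on failure.
check_sums_to_one <- function(x, what) {
  s <- sum(x)
  if (abs(s - 1) > 1e-9) {
    stop_validation("%s must sum to 1 (got %.12g)", what, s)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Five-year age-group label for an exact age in years (top group is open).
#' Assign five-year age-group labels
#'
#' Maps exact ages in years onto the conventional five-year reporting groups
#' `"0-4"`, `"5-9"`, ..., with an open-ended top group (default `"85+"`).
#'
#' @param age integer vector of ages in years
#' @param top lower bound of the open-ended top group (default 85)
#' @return character vector of labels, ordered naturally when sorted by
#'   `age_group_order()`
#' @export
age_group_label <- function(age, top = 85L) {
  lo <- pmin((age %/% 5L) * 5L, top)
  ifelse(lo >= top, paste0(top, "+"), paste0(lo, "-", lo + 4L))
}

# Sort key for age-group labels of the form "a-b" or "a+".
age_group_order <- function(labels) {
  as.integer(sub("[-+].*$", "", sub("\\+$", "+x", labels)))
}
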
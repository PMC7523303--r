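#' Reference life tables
#'
#' The fatal burden calculation uses an aspirational ("standard") life table
#' giving, at each exact age, the remaining years a person could expect to
#' live free of premature death. A single table applies to both sexes.
#'
#' @param age integer ages, strictly increasing from 0
#' @param ex remaining life expectancy in years, non-negative
#' @return a `life_table` tibble with columns `age`, `ex`
#' @export
life_table <- function(age, ex) {
  age <- as.integer(age)
  ex <- as.numeric(ex)
  if (length(age) == 0L || age[1] != 0L || is.unsorted(age, strictly = TRUE)) {
    stop_validation("life table ages must be strictly increasing from 0")
  }
  if (any(ex < 0)) stop_validation("life expectancy must be non-negative")
  out <- tibble::tibble(age = age, ex = ex)
  class(out) <- c("life_table", class(out))
  out
}

#' Read a life table from CSV
#'
#' Expects columns `age` and `ex` (remaining life expectancy in years).
#'
#' @param path path to the CSV file
#' @return a [life_table()]
#' @export
read_life_table <- function(path) {
  df <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  if (!all(c("age", "ex") %in% names(df))) {
    stop_format("life table '%s' needs columns age, ex", path)
  }
  life_table(df$age, df$ex)
}

#' Remaining life expectancy at exact ages
#'
#' Linear interpolation between tabulated ages; ages beyond the table are an
#' error rather than an extrapolation.
#'
#' @param lt a [life_table()]
#' @param age numeric vector of exact ages
#' @return numeric vector of remaining life expectancies
#' @export
life_expectancy <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age < min(lt$age)) || any(age > max(lt$age))) {
    bad <- age[age < min(lt$age) | age > max(lt$age)][1]
    stop_validation("age %s is outside the life table range [%d, %d]",
                    format(bad), min(lt$age), max(lt$age))
  }
  stats::approx(lt$age, lt$ex, xout = age, method = "linear")$y
}
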
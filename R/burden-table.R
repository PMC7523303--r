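#' Burden tables
#'
#' A burden table holds, per (cause, age group, sex) cell, the redistributed
#' death count (death-equivalents), years of life lost (YLL), years lived
#' with disability (YLD) and their sum, disability-adjusted life years
#' (DALY). The identity `daly == yll + yld` is enforced in every cell.
#'
#' @param cells tibble with columns `cause_id`, `age_group`, `sex`, and any
#'   of `deaths`, `yll`, `yld`, `daly`; missing measure columns are filled
#'   with zero, and a missing `daly` is computed as `yll + yld`
#' @return a `burden_table` tibble with all seven columns, sorted by
#'   (`cause_id`, age group, `sex`)
#' @export
burden_table <- function(cells) {
  cells <- tibble::as_tibble(cells)
  keys <- c("cause_id", "age_group", "sex")
  if (!all(keys %in% names(cells))) {
    stop_validation("burden table needs key columns cause_id, age_group, sex")
  }
  for (m in c("deaths", "yll", "yld")) {
    if (!m %in% names(cells)) cells[[m]] <- 0
    cells[[m]] <- as.numeric(cells[[m]])
  }
  if (!"daly" %in% names(cells)) cells$daly <- cells$yll + cells$yld
  vals <- c(cells$deaths, cells$yll, cells$yld, cells$daly)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop_validation("burden table values must be non-negative and non-missing")
  }
  gap <- abs(cells$daly - (cells$yll + cells$yld))
  rel <- gap / pmax(cells$daly, 1)
  if (any(rel > 1e-9)) {
    i <- which.max(rel)
    stop_validation(
      "cell (%s, %s, %s): daly %.9g differs from yll + yld = %.9g",
      cells$cause_id[i], cells$age_group[i], cells$sex[i],
      cells$daly[i], cells$yll[i] + cells$yld[i])
  }
  if (anyDuplicated(cells[keys])) {
    stop_validation("duplicate burden table cell keys")
  }
  out <- cells[order(cells$cause_id, age_group_order(cells$age_group),
                     cells$age_group, cells$sex),
               c(keys, "deaths", "yll", "yld", "daly")]
  class(out) <- c("burden_table", class(tibble::as_tibble(out)))
  out
}

#' Write a burden table to CSV
#'
#' Deterministic row order (cause, age group, sex ascending) and fixed
#' six-decimal formatting, so writing and re-reading reproduces the table
#' exactly at that precision.
#'
#' @param table a [burden_table()]
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_burden_table <- function(table, path) {
  table <- burden_table(table)   # re-validate before writing
  df <- tibble::as_tibble(table)
  # round components first and write their exact sum, so the daly identity
  # still holds bit-for-bit after a round trip at six decimals
  df$yll <- round(df$yll, 6)
  df$yld <- round(df$yld, 6)
  df$daly <- df$yll + df$yld
  for (m in c("deaths", "yll", "yld", "daly")) {
    df[[m]] <- sprintf("%.6f", df[[m]])
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
          class = "burdenr_io_error")
  })
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  }
  invisible(path)
}

#' Read a burden table from CSV
#' @param path path written by [write_burden_table()]
#' @return a [burden_table()]
#' @export
read_burden_table <- function(path) {
  df <- readr::read_csv(path, col_types = "cccdddd", progress = FALSE)
  burden_table(df)
}
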
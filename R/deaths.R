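#' Death records
#'
#' A death record set is a tibble with one row per death (or fractional
#' death-equivalent after redistribution): `record_id`, `age` (integer years),
#' `sex` (`"female"`/`"male"`), `ucod` (underlying cause of death, ICD-10
#' style), `associated` (list column of associated-cause codes, the other
#' mentions on the certificate), and `weight` (non-negative death-equivalents,
#' 1.0 for raw records).
#'
#' @param record_id character vector of identifiers
#' @param age integer ages in years, within `[0, max_age]`
#' @param sex `"female"` or `"male"` (files use `"F"`/`"M"`)
#' @param ucod underlying cause codes (non-empty)
#' @param associated list of character vectors of associated causes; the
#'   underlying cause is removed if duplicated there, and mentions are
#'   de-duplicated
#' @param weight non-negative death-equivalents (default 1)
#' @param max_age maximum representable age (default 100)
#' @return a `death_records` tibble
#' @export
death_records <- function(record_id, age, sex, ucod,
                          associated = NULL, weight = 1,
                          max_age = 100L) {
  n <- length(record_id)
  age <- as.integer(age)
  sex <- normalise_sex(sex)
  ucod <- normalise_icd(ucod)
  weight <- rep_len(as.numeric(weight), n)
  if (is.null(associated)) associated <- rep(list(character()), n)
  if (any(!nzchar(ucod))) stop_validation("every record needs a non-empty ucod")
  if (any(is.na(age)) || any(age < 0L) || any(age > max_age)) {
    stop_validation("ages must be integers in [0, %d]", max_age)
  }
  if (any(weight < 0)) stop_validation("weights must be non-negative")
  associated <- purrr::map2(associated, ucod, function(a, u) {
    a <- unique(normalise_icd(as.character(a)))
    a[nzchar(a) & a != u]
  })
  out <- tibble::tibble(record_id = as.character(record_id), age = age,
                        sex = sex, ucod = ucod, associated = associated,
                        weight = weight)
  class(out) <- c("death_records", class(out))
  out
}

normalise_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female")] <- "female"
  s[s %in% c("m", "male")] <- "male"
  bad <- !s %in% c("female", "male")
  if (any(bad)) {
    stop_validation("unknown sex value '%s'", unique(sex[bad])[1])
  }
  s
}

#' Read a death-record file
#'
#' Expects a delimited text file (comma- or tab-separated, chosen from the
#' header line) with columns `record_id`, `age`, `sex`, `ucod` and
#' `associated` (semicolon-joined codes, possibly empty). Every row becomes
#' one record of weight 1.
#'
#' @param path path to the deaths file
#' @param cl optional [cause_list()]; when supplied, a `cause_id` mapping is
#'   attached as an attribute check only (codes are stored raw)
#' @return a [death_records()] tibble with one row per input row
#' @export
read_deaths <- function(path, cl = NULL) {
  if (!file.exists(path)) stop_format("deaths file '%s' does not exist", path)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  needed <- c("record_id", "age", "sex", "ucod", "associated")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_format("deaths file '%s' is missing columns: %s", path,
                paste(missing, collapse = ", "))
  }
  age_num <- suppressWarnings(as.numeric(df$age))
  bad_age <- which(is.na(age_num) | age_num != floor(age_num))
  if (length(bad_age)) {
    stop_format("row %d of '%s': age '%s' is not an integer",
                bad_age[1], path, df$age[bad_age[1]])
  }
  sex_ok <- tolower(df$sex) %in% c("f", "m", "female", "male")
  if (!all(sex_ok)) {
    stop_format("row %d of '%s': unknown sex '%s'",
                which(!sex_ok)[1], path, df$sex[which(!sex_ok)[1]])
  }
  assoc <- strsplit(ifelse(is.na(df$associated), "", df$associated), ";",
                    fixed = TRUE)
  # raw extracts carry one death per row; files written by write_deaths may
  # carry fractional post-redistribution weights in an extra column
  weight <- if ("weight" %in% names(df)) as.numeric(df$weight) else 1
  death_records(record_id = df$record_id, age = age_num, sex = df$sex,
                ucod = df$ucod, associated = assoc, weight = weight)
}

#' Write death records to a delimited file
#'
#' Inverse of [read_deaths()]: associated causes are semicolon-joined and the
#' fractional `weight` column is included so redistributed record sets round
#' trip.
#'
#' @param records a [death_records()] tibble
#' @param path output path (`.tsv` extension selects tab separation)
#' @return invisibly, `path`
#' @export
write_deaths <- function(records, path) {
  df <- tibble::tibble(
    record_id = records$record_id,
    age = records$age,
    sex = ifelse(records$sex == "female", "F", "M"),
    ucod = records$ucod,
    associated = purrr::map_chr(records$associated, paste, collapse = ";"),
    weight = sprintf("%.9g", records$weight))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Total death-equivalent weight
#' @param records a [death_records()] tibble
#' @return scalar total weight
#' @export
total_weight <- function(records) sum(records$weight)
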
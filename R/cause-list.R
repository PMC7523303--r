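#' Cause lists and ICD-10 code mapping
#'
#' A cause list maps ICD-10 code ranges to the causes used for burden
#' analysis. Each cause belongs to exactly one disease group, and causes
#' flagged as redistribution sources are the ill-defined ("garbage") codes
#' whose deaths must be reassigned before fatal burden is computed.
#'
#' @name cause-list
NULL

# ICD codes are compared as base-36 integers so containment and overlap
# checks are locale-independent. Codes are dot-stripped, upper-cased and
# truncated to `code_length` characters before any comparison.
icd_char_val <- c(setNames(0:9, as.character(0:9)), setNames(10:35, LETTERS))

icd_key <- function(code, pad, width = 4L) {
  code <- substr(code, 1L, width)
  n <- nchar(code)
  padded <- paste0(code, strrep(pad, pmax(width - n, 0L)))
  chars <- matrix(icd_char_val[unlist(strsplit(padded, "", fixed = TRUE))],
                  nrow = width)
  as.numeric(36L^((width - 1L):0L) %*% chars)
}

#' Normalise an ICD-10 code
#'
#' Strips dots, upper-cases, and truncates to the configured code length.
#' Idempotent: normalising a normalised code is a no-op.
#'
#' @param code character vector of raw codes
#' @param width maximum retained code length (default 4)
#' @return normalised character vector
#' @export
normalise_icd <- function(code, width = 4L) {
  substr(toupper(gsub(".", "", code, fixed = TRUE)), 1L, width)
}

parse_icd_range <- function(spec) {
  parts <- strsplit(gsub("–", "-", spec), "-", fixed = TRUE)[[1]]
  parts <- normalise_icd(trimws(parts))
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop_format("cannot parse ICD range '%s'", spec)
  }
  if (icd_key(parts[1], "0") > icd_key(parts[2], "Z")) {
    stop_format("ICD range '%s' has start after end", spec)
  }
  list(start = parts[1], end = parts[2])
}

#' Construct a cause list
#'
#' @param causes tibble with columns `cause_id`, `name`, `disease_group`,
#'   `icd10` (list column of range strings such as `"I20-I25"` or `"C50"`),
#'   `is_redistribution_source` (logical)
#' @param code_length code truncation length for matching (default 4)
#' @return an object of class `cause_list`
#' @export
cause_list <- function(causes, code_length = 4L) {
  causes <- tibble::as_tibble(causes)
  needed <- c("cause_id", "name", "disease_group", "icd10",
              "is_redistribution_source")
  missing <- setdiff(needed, names(causes))
  if (length(missing)) {
    stop_format("cause list is missing fields: %s",
                paste(missing, collapse = ", "))
  }
  if (nrow(causes) == 0L) stop_validation("cause list has no causes")
  if (anyDuplicated(causes$cause_id)) {
    stop_validation("duplicate cause_id: %s",
                    causes$cause_id[duplicated(causes$cause_id)][1])
  }
  if (all(causes$is_redistribution_source)) {
    stop_validation(
      "every cause is a redistribution source; at least one target cause is required")
  }

  ranges <- purrr::map_dfr(seq_len(nrow(causes)), function(i) {
    specs <- causes$icd10[[i]]
    if (length(specs) == 0L) {
      stop_validation("cause '%s' has no ICD ranges", causes$cause_id[i])
    }
    purrr::map_dfr(specs, function(s) {
      r <- parse_icd_range(s)
      tibble::tibble(cause_id = causes$cause_id[i],
                     start = r$start, end = r$end)
    })
  })
  ranges$key_lo <- icd_key(ranges$start, "0")
  ranges$key_hi <- icd_key(ranges$end, "Z")

  # Ranges of *different* causes must be disjoint so map_code is a function.
  ord <- order(ranges$key_lo, ranges$key_hi)
  rr <- ranges[ord, ]
  if (nrow(rr) > 1L) {
    for (i in seq_len(nrow(rr) - 1L)) {
      j <- i + 1L
      while (j <= nrow(rr) && rr$key_lo[j] <= rr$key_hi[i]) {
        if (rr$cause_id[j] != rr$cause_id[i]) {
          stop_validation(
            "ICD ranges overlap between causes '%s' (%s-%s) and '%s' (%s-%s)",
            rr$cause_id[i], rr$start[i], rr$end[i],
            rr$cause_id[j], rr$start[j], rr$end[j])
        }
        j <- j + 1L
      }
    }
  }

  structure(
    list(causes = causes[, needed], ranges = ranges,
         code_length = as.integer(code_length)),
    class = "cause_list")
}

#' @export
print.cause_list <- function(x, ...) {
  cat(sprintf("<cause_list: %d causes, %d groups, %d redistribution sources>\n",
              nrow(x$causes), length(unique(x$causes$disease_group)),
              sum(x$causes$is_redistribution_source)))
  print(x$causes, ...)
  invisible(x)
}

#' Load a cause list from a YAML file
#'
#' The file holds a `causes` sequence; each entry has `id`, `name`, `group`,
#' `icd10` (scalar or sequence of range strings) and an optional
#' `redistribution_source` flag.
#'
#' @param path path to the YAML cause-list file
#' @return a validated [cause_list()]
#' @export
load_cause_list <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_format("cannot parse cause list '%s': %s", path, conditionMessage(e))
  })
  if (is.null(doc$causes) || length(doc$causes) == 0L) {
    stop_validation("cause list '%s' has an empty cause section", path)
  }
  causes <- purrr::map_dfr(doc$causes, function(cs) {
    tibble::tibble(
      cause_id = as.character(cs$id %||% stop_format("cause entry without id")),
      name = as.character(cs$name %||% cs$id),
      disease_group = as.character(cs$group %||%
        stop_format("cause '%s' has no disease group", cs$id)),
      icd10 = list(as.character(cs$icd10 %||% character())),
      is_redistribution_source = isTRUE(cs$redistribution_source))
  })
  cause_list(causes, code_length = doc$code_length %||% 4L)
}

#' Map ICD-10 codes to cause identifiers
#'
#' Codes are normalised (dot-stripped, upper-cased, truncated) and matched by
#' inclusive interval containment; when nested ranges of the same cause both
#' match, the more specific (longer-prefix) range wins. The function is total:
#' codes covered by no range map to the reserved marker `"_unmapped"`.
#'
#' @param cl a [cause_list()]
#' @param code character vector of ICD-10 codes
#' @return character vector of cause ids (`"_unmapped"` where no range matches)
#' @export
map_code <- function(cl, code) {
  stopifnot(inherits(cl, "cause_list"))
  norm <- normalise_icd(code, cl$code_length)
  key <- icd_key(norm, "0", cl$code_length)
  out <- rep(unmapped_cause(), length(code))
  best_len <- rep(-1L, length(code))
  rg <- cl$ranges
  for (i in seq_len(nrow(rg))) {
    hit <- key >= rg$key_lo[i] & key <= rg$key_hi[i]
    spec <- nchar(rg$start[i])
    take <- hit & spec > best_len
    out[take] <- rg$cause_id[i]
    best_len[take] <- spec
  }
  out[!nzchar(norm)] <- unmapped_cause()
  out
}

#' Reserved marker for unmapped codes
#' @return the string `"_unmapped"`
#' @export
unmapped_cause <- function() "_unmapped"

#' Representative ICD code for a cause
#'
#' Used when redistribution reassigns a death to a target cause: the new
#' record carries the first code of the cause's first ICD range, so downstream
#' mapping recovers the intended cause id.
#'
#' @param cl a [cause_list()]
#' @param cause_id character vector of cause ids
#' @return character vector of ICD codes
#' @export
representative_code <- function(cl, cause_id) {
  first <- cl$ranges[!duplicated(cl$ranges$cause_id), ]
  starts <- setNames(first$start, first$cause_id)
  unknown <- setdiff(cause_id, names(starts))
  if (length(unknown)) {
    stop_config("unknown cause id: %s", paste(unknown, collapse = ", "))
  }
  unname(starts[cause_id])
}

#' Disease group lookup
#' @param cl a [cause_list()]
#' @param cause_id character vector of cause ids
#' @return character vector of disease groups (`NA` for the unmapped marker)
#' @export
disease_group <- function(cl, cause_id) {
  grp <- setNames(cl$causes$disease_group, cl$causes$cause_id)
  unname(grp[cause_id])
}

redistribution_sources <- function(cl) {
  cl$causes$cause_id[cl$causes$is_redistribution_source]
}
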
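#' Two-dimension data/methods quality index
#'
#' Instead of uncertainty intervals, estimate reliability is described by a
#' quality index with two dimensions: the relevance of the underlying
#' **data** and the degree of transformation in the **methods** used to turn
#' those data into the estimate. Each dimension is rated A (best) to E
#' (worst) per contributing source; the entity-level rating weights each
#' source's rating by its contribution to the overall estimate. The methods
#' dimension may be unassignable for some sources.
#'
#' @name quality-index
NULL

quality_bands <- c("A", "B", "C", "D", "E")

band_labels <- list(
  data = c(A = "A - Highly relevant", B = "B - Relevant",
           C = "C - Moderately relevant/accurate", D = "D - Somewhat relevant",
           E = "E - Questionable relevance"),
  methods = c(A = "A - Highly accurate", B = "B - Accurate",
              C = "C - Moderately accurate", D = "D - Somewhat accurate",
              E = "E - Questionable accuracy"))

#' Construct a quality rating for one entity
#'
#' @param entity_id disease or risk-factor identifier
#' @param entity_kind `"disease"` or `"risk_factor"`
#' @param sources tibble with columns `source`, `contribution` (fractions
#'   summing to 1), `data_rating` (A-E), `methods_rating` (A-E or `NA` for
#'   "unable to be assigned")
#' @return a `quality_rating` object
#' @export
quality_rating <- function(entity_id,
                           entity_kind = c("disease", "risk_factor"),
                           sources) {
  entity_kind <- match.arg(entity_kind)
  sources <- tibble::as_tibble(sources)
  if (!all(c("source", "contribution", "data_rating", "methods_rating") %in%
             names(sources))) {
    stop_validation(
      "sources need columns source, contribution, data_rating, methods_rating")
  }
  if (any(sources$contribution < 0)) {
    stop_validation("contributions must be non-negative")
  }
  check_sums_to_one(sources$contribution,
                    sprintf("contributions for entity '%s'", entity_id))
  if (!all(sources$data_rating %in% quality_bands)) {
    stop_validation("entity '%s': data ratings must be A-E", entity_id)
  }
  ok_m <- is.na(sources$methods_rating) |
    sources$methods_rating %in% quality_bands
  if (!all(ok_m)) {
    stop_validation("entity '%s': methods ratings must be A-E or NA", entity_id)
  }
  structure(list(entity_id = entity_id, entity_kind = entity_kind,
                 sources = sources),
            class = "quality_rating")
}

#' Read quality ratings from CSV
#'
#' Columns `entity_id`, `entity_kind`, `source`, `contribution`,
#' `data_rating`, `methods_rating` (empty for "unable to be assigned"); one
#' row per contributing source.
#'
#' @param path path to the CSV file
#' @return list of [quality_rating()] objects
#' @export
read_quality_ratings <- function(path) {
  df <- readr::read_csv(path, col_types = "cccdcc", progress = FALSE)
  purrr::map(split(df, df$entity_id)[unique(df$entity_id)], function(g) {
    quality_rating(g$entity_id[1], g$entity_kind[1],
                   g[, c("source", "contribution", "data_rating",
                         "methods_rating")])
  })
}

band_score <- function(band) match(band, quality_bands)

score_band <- function(score) quality_bands[score]

# Contribution-weighted mean of A=1..E=5 scores, rounded to the nearest
# integer with ties toward the worse (higher) score.
weighted_band <- function(bands, contribution) {
  keep <- !is.na(bands)
  if (!any(keep)) return(NA_character_)
  w <- contribution[keep]
  if (sum(w) <= 0) return(NA_character_)
  w <- w / sum(w)            # renormalise after dropping unassigned sources
  score <- sum(w * band_score(bands[keep]))
  score_band(min(max(floor(score + 0.5), 1L), 5L))
}

#' Combine source ratings into an entity rating
#'
#' Letters are scored A=1 .. E=5; the entity score per dimension is the
#' contribution-weighted mean, with unassigned methods sources excluded and
#' the remaining weights renormalised. The score is rounded to the nearest
#' integer, ties toward the worse score, and mapped back to a letter. If no
#' source has an assigned methods rating the methods dimension is `NA`.
#'
#' @param rating a [quality_rating()]
#' @return list with elements `data_rating` and `methods_rating` (letter or
#'   `NA`)
#' @export
combine_ratings <- function(rating) {
  stopifnot(inherits(rating, "quality_rating"))
  s <- rating$sources
  list(data_rating = weighted_band(s$data_rating, s$contribution),
       methods_rating = weighted_band(s$methods_rating, s$contribution))
}

#' Summarise combined quality ratings
#'
#' Counts entities per kind, dimension and band (A-E plus unassigned) and
#' computes percentages of the kind's total, rounded half-up to one decimal.
#' Bands with no entities are reported as 0 / 0.0.
#'
#' @param ratings list of [quality_rating()] objects (one per entity)
#' @return a `quality_summary` tibble with columns `entity_kind`,
#'   `dimension`, `band`, `count`, `pct`
#' @export
summarise_quality <- function(ratings) {
  combined <- purrr::map_dfr(ratings, function(r) {
    cb <- combine_ratings(r)
    tibble::tibble(entity_id = r$entity_id, entity_kind = r$entity_kind,
                   data = cb$data_rating, methods = cb$methods_rating)
  })
  if (nrow(combined) == 0L) {
    combined <- tibble::tibble(entity_id = character(),
                               entity_kind = character(),
                               data = character(), methods = character())
  }
  if (nrow(combined) && anyDuplicated(combined$entity_id)) {
    stop_validation("more than one rating for entity '%s'",
                    combined$entity_id[duplicated(combined$entity_id)][1])
  }
  bands <- c(quality_bands, "unassigned")
  grid <- tidyr::expand_grid(entity_kind = c("disease", "risk_factor"),
                             dimension = c("data", "methods"),
                             band = bands)
  grid$count <- purrr::pmap_int(grid, function(entity_kind, dimension, band) {
    sub <- combined[combined$entity_kind == entity_kind, ]
    v <- sub[[dimension]]
    if (band == "unassigned") sum(is.na(v)) else sum(!is.na(v) & v == band)
  })
  totals <- stats::setNames(
    c(sum(combined$entity_kind == "disease"),
      sum(combined$entity_kind == "risk_factor")),
    c("disease", "risk_factor"))
  grid$pct <- unname(ifelse(totals[grid$entity_kind] > 0,
                            round_half_up(100 * grid$count /
                                            totals[grid$entity_kind], 1), 0))
  # the data dimension is always assignable; drop its structural zero row
  out <- grid[!(grid$dimension == "data" & grid$band == "unassigned"), ]
  out <- tibble::as_tibble(out)
  attr(out, "totals") <- totals
  class(out) <- c("quality_summary", class(out))
  out
}

#' Render a quality summary as a plain-text table
#'
#' Deterministic Table-style layout: one block per dimension, one row per
#' band with counts and percentages for diseases and risk factors.
#'
#' @param summary a [summarise_quality()] result
#' @return character vector of lines (also printed invisibly-friendly)
#' @export
render_quality_table <- function(summary) {
  totals <- attr(summary, "totals")
  fmt_row <- function(label, d_n, d_p, r_n, r_p) {
    sprintf("%-38s %10d %8.1f %10d %8.1f", label, d_n, d_p, r_n, r_p)
  }
  header <- sprintf("%-38s %10s %8s %10s %8s", "",
                    "diseases", "%", "risk fct", "%")
  lines <- c("Summary of quality index assessment", header)
  for (dim in c("data", "methods")) {
    lines <- c(lines, sprintf("Dimension - %s", dim))
    sub <- summary[summary$dimension == dim, ]
    for (i in seq_len(nrow(sub[sub$entity_kind == "disease", ]))) {
      band <- sub$band[sub$entity_kind == "disease"][i]
      label <- if (band == "unassigned") "Unable to be assigned"
               else band_labels[[dim]][[band]]
      d <- sub[sub$entity_kind == "disease" & sub$band == band, ]
      r <- sub[sub$entity_kind == "risk_factor" & sub$band == band, ]
      lines <- c(lines, fmt_row(label, d$count, d$pct, r$count, r$pct))
    }
    lines <- c(lines, fmt_row("Total",
                              sum(sub$count[sub$entity_kind == "disease"]),
                              if (totals[["disease"]] > 0) 100 else 0,
                              sum(sub$count[sub$entity_kind == "risk_factor"]),
                              if (totals[["risk_factor"]] > 0) 100 else 0))
  }
  lines
}

#' Write a quality summary to CSV
#' @param summary a [summarise_quality()] result
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_quality_summary <- function(summary, path) {
  readr::write_csv(tibble::as_tibble(summary), path)
  invisible(path)
}
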
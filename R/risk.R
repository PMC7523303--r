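#' Risk-factor attribution
#'
#' The burden attributable to a risk factor is quantified by the population
#' attributable fraction (PAF): the proportional reduction in burden if the
#' population's exposure were shifted to the theoretical minimum risk
#' exposure distribution (TMRED). With exposure categories i carrying
#' population fractions p_i and relative risks RR_i,
#' `PAF = (sum p_i RR_i - sum p'_i RR_i) / (sum p_i RR_i)`, where p' puts all
#' mass at the TMRED category. The potential impact fraction (PIF) replaces
#' p' with an arbitrary counterfactual exposure distribution, which is how
#' scenario analyses (e.g. a population-wide risk-exposure reduction) are
#' expressed; the PAF is the PIF at the TMRED point mass. For some
#' risk-outcome pairs direct evidence of the attributable proportion exists
#' and overrides the modelled PAF.
#'
#' @name risk-attribution
NULL

#' Construct a risk-outcome pair
#'
#' @param risk_id risk factor identifier
#' @param outcome cause id of the linked disease
#' @param exposure exposure distribution: either a named numeric
#'   (category to population fraction, applying to every age/sex cell) or a
#'   tibble with columns `category`, `fraction` and optionally `age_group`,
#'   `sex`
#' @param rr named numeric of relative risks per category (RR at the TMRED
#'   category is 1 by convention; a deviation is kept but flagged)
#' @param tmred_category name of the theoretical-minimum category
#' @param direct_fraction optional fraction in `[0,1]` from direct evidence,
#'   overriding the modelled PAF
#' @return a `risk_outcome_pair` object
#' @export
risk_outcome_pair <- function(risk_id, outcome, exposure, rr, tmred_category,
                              direct_fraction = NULL) {
  if (!is.data.frame(exposure)) {
    exposure <- tibble::tibble(category = names(exposure),
                               fraction = as.numeric(exposure))
  }
  exposure <- tibble::as_tibble(exposure)
  if (!all(c("category", "fraction") %in% names(exposure))) {
    stop_validation("exposure needs columns category, fraction")
  }
  cell_cols <- intersect(c("age_group", "sex"), names(exposure))
  split_keys <- if (length(cell_cols)) {
    interaction(exposure[cell_cols], drop = TRUE)
  } else {
    factor(rep(1L, nrow(exposure)))
  }
  for (g in split(seq_len(nrow(exposure)), split_keys)) {
    check_sums_to_one(exposure$fraction[g],
                      sprintf("exposure fractions for risk '%s'", risk_id))
  }
  rr <- unlist(rr)
  if (any(rr < 0)) stop_validation("relative risks must be non-negative")
  if (!tmred_category %in% names(rr)) {
    stop_validation("tmred category '%s' has no relative risk", tmred_category)
  }
  if (abs(rr[[tmred_category]] - 1) > 1e-9) {
    warn(sprintf("risk '%s': RR at the TMRED category is %.4g, not 1",
                 risk_id, rr[[tmred_category]]))
  }
  if (!is.null(direct_fraction) &&
      (direct_fraction < 0 || direct_fraction > 1)) {
    stop_validation("direct_fraction must lie in [0,1]")
  }
  structure(list(risk_id = risk_id, outcome = outcome, exposure = exposure,
                 rr = rr, tmred_category = tmred_category,
                 direct_fraction = direct_fraction),
            class = "risk_outcome_pair")
}

#' Read risk-outcome pairs from YAML
#'
#' The file holds a `risks` sequence; each entry has `risk`, `outcome`,
#' `tmred`, `exposure` (map or sequence of per-cell maps with `age_group`,
#' `sex`, `dist`), `rr` (map) and optional `direct_fraction`.
#'
#' @param path path to the YAML file
#' @return list of [risk_outcome_pair()] objects
#' @export
read_risk_pairs <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_format("cannot parse risk file '%s': %s", path, conditionMessage(e))
  })
  purrr::map(doc$risks %||% doc, function(e) {
    exp <- e$exposure
    if (!is.null(names(exp)) && !is.list(exp[[1]])) {
      exposure <- unlist(exp)
    } else {
      exposure <- purrr::map_dfr(exp, function(cell) {
        tibble::tibble(age_group = cell$age_group %||% NA_character_,
                       sex = cell$sex %||% NA_character_,
                       category = names(cell$dist),
                       fraction = as.numeric(unlist(cell$dist)))
      })
    }
    risk_outcome_pair(risk_id = e$risk, outcome = e$outcome,
                      exposure = exposure, rr = e$rr,
                      tmred_category = e$tmred,
                      direct_fraction = e$direct_fraction)
  })
}

exposure_for_cell <- function(pair, age_group = NULL, sex = NULL) {
  ex <- pair$exposure
  if ("age_group" %in% names(ex) && !is.null(age_group)) {
    ex <- ex[is.na(ex$age_group) | ex$age_group == age_group, ]
  }
  if ("sex" %in% names(ex) && !is.null(sex)) {
    ex <- ex[is.na(ex$sex) | ex$sex == sex, ]
  }
  if (nrow(ex) == 0L) {
    stop_validation("risk '%s' has no exposure distribution for cell (%s, %s)",
                    pair$risk_id, age_group %||% "all", sex %||% "all")
  }
  stats::setNames(ex$fraction, ex$category)
}

#' Population attributable fraction
#'
#' If the pair carries direct evidence, that fraction is returned. Otherwise
#' the PAF is computed from the cell's exposure distribution and relative
#' risks against the TMRED counterfactual. Protective exposure mixes give a
#' negative PAF, which is returned (with a warning) unless a clipping floor
#' is set.
#'
#' @param pair a [risk_outcome_pair()]
#' @param age_group,sex optional cell selectors when the exposure is
#'   stratified
#' @param clip_floor optional lower clip for protective mixes (e.g. 0);
#'   default `NULL` leaves negative PAFs untouched
#' @return scalar PAF in `(-Inf, 1]`
#' @export
compute_paf <- function(pair, age_group = NULL, sex = NULL,
                        clip_floor = NULL) {
  if (!is.null(pair$direct_fraction)) return(pair$direct_fraction)
  p <- exposure_for_cell(pair, age_group, sex)
  q <- stats::setNames(numeric(length(p)), names(p))
  if (!pair$tmred_category %in% names(q)) {
    q <- c(q, stats::setNames(0, pair$tmred_category))
  }
  q[pair$tmred_category] <- 1
  pif_core(p, q, pair$rr, pair$risk_id, clip_floor)
}

#' Potential impact fraction
#'
#' The proportional change in burden when the exposure distribution shifts
#' from the factual `p` to a counterfactual `q`:
#' `PIF = (sum p_i RR_i - sum q_i RR_i) / (sum p_i RR_i)`. Equals the PAF
#' when `q` is the TMRED point mass.
#'
#' @param pair a [risk_outcome_pair()]
#' @param counterfactual_exposure named numeric distribution over exposure
#'   categories (must sum to 1)
#' @param age_group,sex optional cell selectors for the factual exposure
#' @param clip_floor optional lower clip (default `NULL`: no clipping)
#' @return scalar PIF in `(-Inf, 1]`
#' @export
compute_pif <- function(pair, counterfactual_exposure,
                        age_group = NULL, sex = NULL, clip_floor = NULL) {
  p <- exposure_for_cell(pair, age_group, sex)
  q <- unlist(counterfactual_exposure)
  check_sums_to_one(q, "counterfactual exposure")
  pif_core(p, q, pair$rr, pair$risk_id, clip_floor)
}

pif_core <- function(p, q, rr, risk_id, clip_floor) {
  missing_rr <- setdiff(union(names(p), names(q)), names(rr))
  if (length(missing_rr)) {
    stop_validation("risk '%s': no relative risk for category '%s'",
                    risk_id, missing_rr[1])
  }
  factual <- sum(p * rr[names(p)])
  counter <- sum(q * rr[names(q)])
  if (factual == 0) {
    stop_validation("risk '%s': factual exposure-weighted risk is zero",
                    risk_id)
  }
  out <- (factual - counter) / factual
  if (out < 0) {
    warn(sprintf("risk '%s': protective exposure mix gives a negative fraction (%.4g)",
                 risk_id, out))
    if (!is.null(clip_floor)) out <- max(out, clip_floor)
  }
  out
}

#' Attribute burden to risk factors
#'
#' Applies per-cell PAFs multiplicatively to a burden table:
#' `attributable = PAF x burden` for deaths, YLL, YLD and DALY alike. PAF
#' rows with missing `age_group`/`sex` apply to every matching cell of the
#' outcome cause. Negative (protective) PAFs are excluded from the
#' attributable output with a warning.
#'
#' @param pafs tibble with columns `risk_id`, `cause_id`, `paf` and
#'   optionally `age_group`, `sex`
#' @param burden a [burden_table()]
#' @return tibble of attributable cells: `risk_id` plus the burden table
#'   columns
#' @export
attribute_burden <- function(pafs, burden) {
  pafs <- tibble::as_tibble(pafs)
  if (!all(c("risk_id", "cause_id", "paf") %in% names(pafs))) {
    stop_validation("pafs need columns risk_id, cause_id, paf")
  }
  unknown <- setdiff(pafs$cause_id, burden$cause_id)
  if (length(unknown)) {
    stop_config("PAF refers to cause '%s' absent from the burden table",
                unknown[1])
  }
  if (any(pafs$paf > 1)) stop_validation("PAF cannot exceed 1")
  neg <- pafs$paf < 0
  if (any(neg)) {
    warn(sprintf("%d protective PAF(s) excluded from attributable totals",
                 sum(neg)))
    pafs <- pafs[!neg, ]
  }
  out <- purrr::map_dfr(seq_len(nrow(pafs)), function(i) {
    row <- pafs[i, ]
    cells <- burden[burden$cause_id == row$cause_id, ]
    if ("age_group" %in% names(row) && !is.na(row$age_group)) {
      cells <- cells[cells$age_group == row$age_group, ]
    }
    if ("sex" %in% names(row) && !is.na(row$sex)) {
      cells <- cells[cells$sex == row$sex, ]
    }
    cells <- tibble::as_tibble(cells)
    for (m in c("deaths", "yll", "yld", "daly")) {
      cells[[m]] <- cells[[m]] * row$paf
    }
    dplyr::bind_cols(tibble::tibble(risk_id = rep(row$risk_id, nrow(cells))),
                     cells)
  })
  out
}
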
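#' Synthetic study inputs
#'
#' Real national mortality extracts are restricted, so every pipeline stage
#' is exercised on synthetic data with the statistical structure the methods
#' assume: multi-cause death records whose true cause is known, a
#' configurable fraction of which is "garbled" to an ill-defined underlying
#' cause; prevalence tables; risk exposures; and quality-rating fixtures.
#'
#' The key generator assumption, mirroring why the indirect
#' multiple-causes-of-death method works on real data, is certificate
#' co-mention: with probability `assoc_mention_prob` a garbled death carries
#' its true cause among the associated causes, and a well-certified death
#' carries the ill-defined condition among its associated causes. The
#' latter mentions are what the indirect MCOD tally observes, and because
#' mentioning is independent of the true cause, the tallied
#' underlying-cause pattern is an unbiased estimate of the garbled deaths'
#' true cause distribution.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param seed integer seed; all generator randomness flows from it
#' @param n_deaths number of deaths to draw
#' @param true_cause_distribution named probability vector over cause ids
#'   (must sum to 1)
#' @param garble_fraction probability a death's underlying cause is replaced
#'   by the ill-defined code (default 0.105, the scale of a modern national
#'   vital registration system)
#' @param assoc_mention_prob probability of certificate co-mention (see
#'   module description; default 0.9)
#' @param garble_cause the ill-defined source the garbling writes: a single
#'   cause id (default `"ill_defined"`) or a named probability vector over
#'   several source causes, in which case each garbled death draws its
#'   ill-defined code from that distribution
#' @param age_mean,age_sd age-at-death sampling parameters (normal, rounded
#'   and clamped to `[0, 100]`; defaults 75 and 15)
#' @param sex_split probability a death is female (default 0.5)
#' @return a `simulation_config` object
#' @export
simulation_config <- function(seed, n_deaths,
                              true_cause_distribution,
                              garble_fraction = 0.105,
                              assoc_mention_prob = 0.9,
                              garble_cause = "ill_defined",
                              age_mean = 75, age_sd = 15,
                              sex_split = 0.5) {
  probs <- c(garble_fraction, assoc_mention_prob, sex_split)
  if (any(probs < 0 | probs > 1)) {
    stop_validation("probabilities must lie in [0, 1]")
  }
  check_sums_to_one(true_cause_distribution, "true cause distribution")
  if (is.character(garble_cause)) {
    garble_cause <- stats::setNames(rep(1 / length(garble_cause),
                                        length(garble_cause)), garble_cause)
  }
  check_sums_to_one(garble_cause, "garble cause distribution")
  structure(list(seed = as.integer(seed), n_deaths = as.integer(n_deaths),
                 true_cause_distribution = unlist(true_cause_distribution),
                 garble_fraction = garble_fraction,
                 assoc_mention_prob = assoc_mention_prob,
                 garble_cause = garble_cause,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_split = sex_split),
            class = "simulation_config")
}

#' Generate synthetic multi-cause death records
#'
#' Each death draws a true cause, age and sex; with probability
#' `garble_fraction` its underlying cause becomes the ill-defined code
#' (and, with probability `assoc_mention_prob`, its true cause is written
#' into the associated list); otherwise the underlying cause is the true
#' cause (and, with the same probability, the ill-defined condition is
#' co-mentioned as an associated cause). The realized truth table is
#' returned for recovery tests. Identical seed and config give identical
#' output.
#'
#' @param config a [simulation_config()]
#' @param cl a [cause_list()] containing every cause in the distribution and
#'   the ill-defined source
#' @return list with `records` (a [death_records()] tibble) and `truth`
#'   (named numeric of true death weight per cause)
#' @export
generate_deaths <- function(config, cl) {
  stopifnot(inherits(config, "simulation_config"))
  bad_src <- setdiff(names(config$garble_cause), redistribution_sources(cl))
  if (length(bad_src)) {
    stop_config("garble cause '%s' is not a redistribution source in the cause list",
                bad_src[1])
  }
  dist <- config$true_cause_distribution
  unknown <- setdiff(names(dist), cl$causes$cause_id)
  if (length(unknown)) {
    stop_config("true cause distribution names unknown cause '%s'", unknown[1])
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister")

  n <- config$n_deaths
  true_cause <- sample(names(dist), n, replace = TRUE, prob = dist)
  age <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)), 0L), 100L)
  sex <- ifelse(runif(n) < config$sex_split, "female", "male")
  garbled <- runif(n) < config$garble_fraction
  mention <- runif(n) < config$assoc_mention_prob

  true_code <- representative_code(cl, true_cause)
  garble_dist <- config$garble_cause
  garble_target <- if (length(garble_dist) == 1L) {
    rep(names(garble_dist), n)
  } else {
    # one draw per death: the garbled use it as their ill-defined UCOD, the
    # well-certified may co-mention it as an associated cause
    sample(names(garble_dist), n, replace = TRUE, prob = garble_dist)
  }
  garble_code <- representative_code(cl, garble_target)
  ucod <- ifelse(garbled, garble_code, true_code)
  associated <- vector("list", n)
  associated[garbled & mention] <- as.list(true_code[garbled & mention])
  associated[!garbled & mention] <- as.list(garble_code[!garbled & mention])
  associated[lengths(associated) == 0L] <- list(character())

  records <- death_records(record_id = sprintf("d%07d", seq_len(n)),
                           age = age, sex = sex, ucod = ucod,
                           associated = associated, weight = 1)
  truth <- cause_weights(rep(1, n), true_cause)
  list(records = records, truth = truth)
}

#' Generate a synthetic prevalence table
#'
#' Draws prevalent persons per (sequela, age group, sex) cell from a
#' log-normal with configured median and log-scale spread; `sdlog = 0` makes
#' every cell equal its median.
#'
#' @param seed integer seed
#' @param models list of [disease_model()] objects (sequelae to cover)
#' @param age_groups character vector of age-group labels
#' @param sexes sexes to cover (default both)
#' @param median scalar or per-sequela named vector of median prevalent
#'   persons (default 1000)
#' @param sdlog log-scale standard deviation (default 0.3)
#' @return a [prevalence_table()]
#' @export
generate_prevalence <- function(seed, models, age_groups,
                                sexes = c("female", "male"),
                                median = 1000, sdlog = 0.3) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  sequelae <- unlist(purrr::map(models, function(m)
    purrr::map_chr(m$sequelae, "id")))
  med <- if (length(median) == 1L && is.null(names(median))) {
    stats::setNames(rep(median, length(sequelae)), sequelae)
  } else {
    unlist(median)[sequelae]
  }
  grid <- tidyr::expand_grid(sequela_id = sequelae, age_group = age_groups,
                             sex = sexes)
  grid$prevalence <- if (sdlog == 0) {
    unname(med[grid$sequela_id])
  } else {
    rlnorm(nrow(grid), meanlog = log(med[grid$sequela_id]), sdlog = sdlog)
  }
  prevalence_table(grid)
}

#' Quality-rating fixture reproducing the published summary counts
#'
#' Builds 194 single-source disease entities and 18 risk-factor entities
#' whose combined ratings land in the A-E bands with the counts of the
#' published national summary table (data dimension: 73/45/45/29/2 diseases
#' and 3/10/3/1/1 risk factors; methods dimension: 56/38/61/35/4 diseases
#' and 2/7/6/1/0 risk factors plus 2 unassigned).
#'
#' @return list of [quality_rating()] objects
#' @export
table2_fixture <- function() {
  d_data <- rep(quality_bands, times = c(73, 45, 45, 29, 2))
  d_methods <- rep(quality_bands, times = c(56, 38, 61, 35, 4))
  r_data <- rep(quality_bands, times = c(3, 10, 3, 1, 1))
  r_methods <- c(rep(quality_bands, times = c(2, 7, 6, 1, 0)),
                 rep(NA_character_, 2))
  mk <- function(id, kind, d, m) {
    quality_rating(id, kind,
                   tibble::tibble(source = "synthetic", contribution = 1,
                                  data_rating = d, methods_rating = m))
  }
  c(purrr::map(seq_along(d_data), function(i)
      mk(sprintf("disease_%03d", i), "disease", d_data[i], d_methods[i])),
    purrr::map(seq_along(r_data), function(i)
      mk(sprintf("risk_%02d", i), "risk_factor", r_data[i], r_methods[i])))
}

#' Demonstration cause list
#'
#' A compact (~20 cause) ICD-10 cause list spanning nine disease groups,
#' with six redistribution sources: ill-defined causes (R codes),
#' septicaemia, unspecified heart failure, cancer of unknown primary site,
#' unspecified cancer, and unspecified injury. Illustrative only; a national
#' study list is an order of magnitude larger.
#'
#' @return a [cause_list()]
#' @export
demo_cause_list <- function() {
  c_ <- function(id, name, group, icd, src = FALSE) {
    tibble::tibble(cause_id = id, name = name, disease_group = group,
                   icd10 = list(icd), is_redistribution_source = src)
  }
  cause_list(dplyr::bind_rows(
    c_("chd", "Coronary heart disease", "cardiovascular", "I20-I25"),
    c_("stroke", "Stroke", "cardiovascular", "I60-I69"),
    c_("other_cvd", "Other cardiovascular diseases", "cardiovascular",
       "I70-I79"),
    c_("hf_unspecified", "Heart failure and ill-defined heart disease",
       "cardiovascular", "I50-I51", src = TRUE),
    c_("lung_ca", "Lung cancer", "cancer", "C33-C34"),
    c_("colorectal_ca", "Bowel cancer", "cancer", "C18-C21"),
    c_("breast_ca", "Breast cancer", "cancer", "C50"),
    c_("other_ca", "Other malignant neoplasms", "cancer", "C40-C49"),
    c_("unspec_ca", "Unspecified malignant neoplasm", "cancer", "C76-C79",
       src = TRUE),
    c_("cup", "Cancer of unknown primary site", "cancer", "C80", src = TRUE),
    c_("sepsis", "Septicaemia", "infections", "A40-A41", src = TRUE),
    c_("pneumonia", "Pneumonia", "infections", "J12-J18"),
    c_("copd", "Chronic obstructive pulmonary disease", "respiratory",
       "J40-J44"),
    c_("asthma", "Asthma", "respiratory", "J45-J46"),
    c_("diabetes", "Diabetes", "endocrine", "E10-E14"),
    c_("dementia", "Dementia", "neurological", "F01-F03"),
    c_("depression", "Depressive disorders", "mental", "F32-F33"),
    c_("anxiety", "Anxiety disorders", "mental", "F40-F41"),
    c_("low_back_pain", "Back pain and problems", "musculoskeletal", "M54"),
    c_("ckd", "Chronic kidney disease", "kidney", "N18"),
    c_("road_injury", "Road transport injuries", "injuries", "V01-V89"),
    c_("falls", "Falls", "injuries", "W00-W19"),
    c_("suicide", "Suicide and self-inflicted injuries", "injuries",
       "X60-X84"),
    c_("unspec_injury", "Exposure to unspecified factor", "injuries", "X59",
       src = TRUE),
    c_("ill_defined", "Ill-defined causes", "ill_defined", "R00-R99",
       src = TRUE)))
}

#' Demonstration redistribution rules
#'
#' One rule per source of [demo_cause_list()], exercising all three methods
#' and a combination: indirect MCOD for ill-defined causes and septicaemia;
#' direct evidence for cancer of unknown primary site (retaining 70% as true
#' unknown-primary, inside the 60.4-74.9% evidence interval) and for
#' unspecified cancer (a cascade feeding the unknown-primary rule);
#' a combination rule for unspecified heart failure; proportional for
#' unspecified injury.
#'
#' @return named list of [redistribution_rule()] objects
#' @export
demo_redistribution_rules <- function() {
  rules <- list(
    redistribution_rule("ill_defined", "indirect_mcod"),
    redistribution_rule("sepsis", "indirect_mcod"),
    redistribution_rule("cup", "direct",
                        table = c(cup = 0.70, lung_ca = 0.18,
                                  colorectal_ca = 0.08, other_ca = 0.04)),
    redistribution_rule("unspec_ca", "direct",
                        table = c(cup = 0.50, lung_ca = 0.20,
                                  colorectal_ca = 0.15, breast_ca = 0.10,
                                  other_ca = 0.05)),
    redistribution_rule("hf_unspecified", "combination",
                        table = c(chd = 0.7, other_cvd = 0.3),
                        direct_share = 0.3),
    redistribution_rule("unspec_injury", "proportional",
                        targets = c("road_injury", "falls", "suicide")))
  stats::setNames(rules, purrr::map_chr(rules, "source"))
}

#' Default true-cause distribution for the demonstration fixtures
#' @return named probability vector over non-source causes of
#'   [demo_cause_list()]
#' @export
demo_true_cause_distribution <- function() {
  c(chd = 0.20, stroke = 0.11, other_cvd = 0.04,
    lung_ca = 0.08, colorectal_ca = 0.06, breast_ca = 0.04, other_ca = 0.04,
    pneumonia = 0.06, copd = 0.06, asthma = 0.01,
    diabetes = 0.05, dementia = 0.09, ckd = 0.03,
    road_injury = 0.04, falls = 0.05, suicide = 0.04)
}

#' Default garble distribution for the demonstration pipeline
#'
#' Spreads ill-defined coding over all six demonstration source causes so a
#' full pipeline run exercises every redistribution method; dominated by the
#' generic ill-defined (R-code) category, as in real vital registration.
#'
#' @return named probability vector over source causes
#' @export
demo_garble_distribution <- function() {
  c(ill_defined = 0.55, sepsis = 0.15, hf_unspecified = 0.12,
    unspec_ca = 0.08, cup = 0.06, unspec_injury = 0.04)
}

#' Demonstration standard life table
#'
#' A synthetic aspirational life table (not any published standard): life
#' expectancy 91.5 years at birth declining smoothly with age, on a
#' five-year grid to age 100.
#'
#' @return a [life_table()]
#' @export
demo_life_table <- function() {
  age <- seq(0L, 100L, by = 5L)
  ex <- round(91.5 * exp(-0.022 * age), 2)
  life_table(age, ex)
}

#' Demonstration population life table for HALE
#'
#' Synthetic survivors `lx` and person-years `nLx` on single years of age
#' 0-100 from a Gompertz-like mortality hazard.
#'
#' @return tibble with columns `age`, `lx`, `nLx`
#' @export
demo_hale_life_table <- function() {
  age <- 0:100
  haz <- 0.0002 + 0.00003 * exp(0.095 * age)
  lx <- c(1, exp(-cumsum(haz[-length(haz)])))
  lx <- lx / lx[1] * 100000
  nLx <- c((lx[-length(lx)] + lx[-1]) / 2, lx[length(lx)] * 1.5)
  tibble::tibble(age = age, lx = lx, nLx = nLx)
}

#' Demonstration disease conceptual models
#'
#' Severity-split sequelae with plausible disability-weight magnitudes for
#' the non-fatal causes of the demonstration cause list.
#'
#' @return list of [disease_model()] objects
#' @export
demo_disease_models <- function() {
  lv <- function(...) {
    x <- list(...)
    tibble::tibble(name = purrr::map_chr(x, 1),
                   proportion = purrr::map_dbl(x, 2),
                   dw = purrr::map_dbl(x, 3))
  }
  list(
    disease_model("depression", list(
      list(id = "major_depressive_episode",
           levels = lv(list("mild", 0.5, 0.145), list("moderate", 0.35, 0.396),
                       list("severe", 0.15, 0.658))))),
    disease_model("anxiety", list(
      list(id = "anxiety_state",
           levels = lv(list("mild", 0.6, 0.03), list("moderate", 0.3, 0.133),
                       list("severe", 0.1, 0.523))))),
    disease_model("low_back_pain", list(
      list(id = "back_pain_episode",
           levels = lv(list("mild", 0.55, 0.02), list("moderate", 0.35, 0.054),
                       list("severe", 0.1, 0.272))))),
    disease_model("copd", list(
      list(id = "chronic_airflow_limitation",
           levels = lv(list("mild", 0.5, 0.019), list("moderate", 0.35, 0.225),
                       list("severe", 0.15, 0.408))))),
    disease_model("diabetes", list(
      list(id = "uncomplicated_diabetes",
           levels = lv(list("uncomplicated", 1, 0.049))),
      list(id = "diabetic_neuropathy",
           levels = lv(list("asymptomatic", 0.6, 0),
                       list("symptomatic", 0.4, 0.133))))),
    disease_model("chd", list(
      list(id = "angina",
           levels = lv(list("mild", 0.6, 0.033), list("moderate", 0.25, 0.08),
                       list("severe", 0.15, 0.167))))),
    disease_model("stroke", list(
      list(id = "stroke_survivor",
           levels = lv(list("mild", 0.45, 0.019), list("moderate", 0.35, 0.07),
                       list("severe", 0.2, 0.552))))),
    disease_model("dementia", list(
      list(id = "cognitive_impairment",
           levels = lv(list("mild", 0.4, 0.069), list("moderate", 0.35, 0.377),
                       list("severe", 0.25, 0.449))))))
}

#' Demonstration risk-outcome pairs
#'
#' Categorical exposures with relative risks and theoretical-minimum
#' categories for three modelled pairs, plus one direct-evidence pair.
#'
#' @return list of [risk_outcome_pair()] objects
#' @export
demo_risk_pairs <- function() {
  list(
    risk_outcome_pair("tobacco", "lung_ca",
                      exposure = c(never = 0.55, former = 0.25,
                                   current = 0.20),
                      rr = c(never = 1, former = 4, current = 12),
                      tmred_category = "never"),
    risk_outcome_pair("tobacco", "chd",
                      exposure = c(never = 0.55, former = 0.25,
                                   current = 0.20),
                      rr = c(never = 1, former = 1.3, current = 2.2),
                      tmred_category = "never"),
    risk_outcome_pair("high_bmi", "diabetes",
                      exposure = c(normal = 0.35, overweight = 0.35,
                                   obese = 0.30),
                      rr = c(normal = 1, overweight = 2.5, obese = 7),
                      tmred_category = "normal"),
    risk_outcome_pair("partner_violence", "suicide",
                      exposure = c(unexposed = 0.85, exposed = 0.15),
                      rr = c(unexposed = 1, exposed = 2),
                      tmred_category = "unexposed",
                      direct_fraction = 0.06))
}
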
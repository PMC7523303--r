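#' Fatal and non-fatal burden
#'
#' Burden is measured in disability-adjusted life years (DALY), the sum of
#' years of life lost to premature death (YLL) and years lived with
#' disability (YLD). YLL is deaths times remaining life expectancy at the age
#' of death from an aspirational standard life table, with no age weighting
#' and no discounting. YLD uses the prevalence approach: prevalent cases are
#' spread over the severity levels of each disease sequela and weighted by
#' disability weights in `[0, 1]`. Health-adjusted life expectancy (HALE)
#' discounts a population life table for time lived in ill health using the
#' Sullivan method.
#'
#' @name burden
NULL

#' Construct a disease conceptual model
#'
#' A disease model lists the sequelae through which a disease's non-fatal
#' burden is counted; each sequela carries a severity distribution whose
#' proportions sum to 1, with a disability weight per severity level.
#'
#' @param disease cause id the model belongs to
#' @param sequelae list; each element has `id` and `levels`, a data frame (or
#'   list of lists) with `name`, `proportion`, `dw`
#' @return a `disease_model` object
#' @export
disease_model <- function(disease, sequelae) {
  sequelae <- purrr::map(sequelae, function(sq) {
    lv <- sq$levels
    if (is.data.frame(lv)) lv <- tibble::as_tibble(lv)
    else lv <- purrr::map_dfr(lv, tibble::as_tibble)
    if (!all(c("name", "proportion", "dw") %in% names(lv))) {
      stop_validation("sequela '%s' levels need name, proportion, dw", sq$id)
    }
    if (any(lv$dw < 0 | lv$dw > 1)) {
      stop_validation("sequela '%s': disability weights must lie in [0,1]",
                      sq$id)
    }
    check_sums_to_one(lv$proportion,
                      sprintf("severity proportions of sequela '%s'", sq$id))
    list(id = sq$id, levels = lv)
  })
  structure(list(disease = disease, sequelae = sequelae),
            class = "disease_model")
}

#' Read disease conceptual models from YAML
#'
#' The file holds a `models` sequence; each entry has `disease` and
#' `sequelae`, each sequela an `id` and `levels` with `name`, `proportion`,
#' `dw`.
#'
#' @param path path to the YAML models file
#' @return list of [disease_model()] objects
#' @export
read_disease_models <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_format("cannot parse models file '%s': %s", path, conditionMessage(e))
  })
  purrr::map(doc$models %||% doc,
             function(m) disease_model(m$disease, m$sequelae))
}

#' Read a prevalence table
#'
#' CSV with columns `sequela_id`, `age_group`, `sex`, `prevalence`
#' (prevalent persons, non-negative).
#'
#' @param path path to the CSV file
#' @return a `prevalence_table` tibble
#' @export
read_prevalence <- function(path) {
  df <- readr::read_csv(path, col_types = "cccd", progress = FALSE)
  prevalence_table(df)
}

#' @rdname read_prevalence
#' @param cells tibble with the four prevalence columns
#' @export
prevalence_table <- function(cells) {
  cells <- tibble::as_tibble(cells)
  needed <- c("sequela_id", "age_group", "sex", "prevalence")
  if (!all(needed %in% names(cells))) {
    stop_validation("prevalence table needs columns %s",
                    paste(needed, collapse = ", "))
  }
  if (any(cells$prevalence < 0)) {
    stop_validation("prevalence must be non-negative")
  }
  cells$sex <- normalise_sex(cells$sex)
  class(cells) <- c("prevalence_table", class(cells))
  cells
}

#' Years of life lost
#'
#' Per death: weight times remaining life expectancy at the exact age of
#' death (linearly interpolated from the standard life table); summed to
#' (cause, age group, sex) cells. No age weighting, no discounting.
#'
#' @param records redistributed [death_records()]
#' @param cl a [cause_list()] mapping underlying causes to cause ids
#'   (unmapped codes are kept under the reserved `"_unmapped"` cause so the
#'   audit trail is conserved)
#' @param lt a [life_table()]
#' @param age_top lower bound of the open-ended top age group (default 85)
#' @return tibble of cells `cause_id`, `age_group`, `sex`, `deaths`, `yll`
#' @export
compute_yll <- function(records, cl, lt, age_top = 85L) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(cause_id = character(), age_group = character(),
                          sex = character(), deaths = numeric(),
                          yll = numeric()))
  }
  if (any(records$age > max(lt$age))) {
    bad <- which(records$age > max(lt$age))[1]
    stop_validation("record '%s' has age %d beyond the life table maximum %d",
                    records$record_id[bad], records$age[bad], max(lt$age))
  }
  le <- life_expectancy(lt, records$age)
  df <- tibble::tibble(cause_id = map_code(cl, records$ucod),
                       age_group = age_group_label(records$age, age_top),
                       sex = records$sex,
                       deaths = records$weight,
                       yll = records$weight * le)
  dplyr::summarise(dplyr::group_by(df, .data$cause_id, .data$age_group,
                                   .data$sex),
                   deaths = sum(.data$deaths), yll = sum(.data$yll),
                   .groups = "drop")
}

#' Years lived with disability
#'
#' Prevalence-based YLD: for each disease,
#' `YLD = sum over sequelae and severity levels of
#' prevalence x proportion x disability weight`, per age group and sex.
#' Every sequela in the prevalence table must appear in exactly one disease
#' model.
#'
#' @param prevalence a [prevalence_table()]
#' @param models list of [disease_model()] objects
#' @return tibble of cells `cause_id`, `age_group`, `sex`, `yld`
#' @export
compute_yld <- function(prevalence, models) {
  seq_map <- purrr::map_dfr(models, function(m) {
    purrr::map_dfr(m$sequelae, function(sq) {
      tibble::tibble(disease = m$disease, sequela_id = sq$id,
                     eff_dw = sum(sq$levels$proportion * sq$levels$dw))
    })
  })
  if (anyDuplicated(seq_map$sequela_id)) {
    stop_config("sequela '%s' appears in more than one disease model",
                seq_map$sequela_id[duplicated(seq_map$sequela_id)][1])
  }
  orphan <- setdiff(unique(prevalence$sequela_id), seq_map$sequela_id)
  if (length(orphan)) {
    stop_config("prevalence includes sequela '%s' with no disease model",
                orphan[1])
  }
  df <- dplyr::inner_join(tibble::as_tibble(prevalence), seq_map,
                          by = "sequela_id")
  df$yld <- df$prevalence * df$eff_dw
  out <- dplyr::summarise(dplyr::group_by(df, cause_id = .data$disease,
                                          .data$age_group, .data$sex),
                          yld = sum(.data$yld), .groups = "drop")
  out
}

#' Assemble DALY from YLL and YLD cells
#'
#' Full outer join on (cause, age group, sex); a component absent from one
#' side is treated as zero (noted via a message), and `daly = yll + yld` in
#' every cell.
#'
#' @param yll_cells output of [compute_yll()] (columns `cause_id`,
#'   `age_group`, `sex`, optionally `deaths`, `yll`)
#' @param yld_cells output of [compute_yld()]
#' @param quiet suppress the missing-component note
#' @return a [burden_table()]
#' @export
assemble_daly <- function(yll_cells, yld_cells, quiet = FALSE) {
  yll_cells <- tibble::as_tibble(yll_cells)
  yld_cells <- tibble::as_tibble(yld_cells)
  if (!"deaths" %in% names(yll_cells)) yll_cells$deaths <- 0
  if (!"yll" %in% names(yll_cells)) yll_cells$yll <- 0
  if (!"yld" %in% names(yld_cells)) yld_cells$yld <- 0
  if (any(yll_cells$yll < 0) || any(yld_cells$yld < 0)) {
    stop_validation("negative YLL or YLD input to DALY assembly")
  }
  keys <- c("cause_id", "age_group", "sex")
  joined <- dplyr::full_join(yll_cells[, c(keys, "deaths", "yll")],
                             yld_cells[, c(keys, "yld")], by = keys)
  n_fill <- sum(is.na(joined$yll)) + sum(is.na(joined$yld))
  if (n_fill > 0 && !quiet) {
    inform(sprintf("%d cell(s) missing one DALY component; treated as 0",
                   n_fill))
  }
  joined$deaths[is.na(joined$deaths)] <- 0
  joined$yll[is.na(joined$yll)] <- 0
  joined$yld[is.na(joined$yld)] <- 0
  joined$daly <- joined$yll + joined$yld
  burden_table(joined)
}

#' Health-adjusted life expectancy (Sullivan method)
#'
#' Discounts a population life table for morbidity: with person-years lived
#' `nLx`, survivors `lx`, and a per-age morbidity rate `r(a)` in `[0, 1]`
#' (YLD per person per year),
#' `HALE(x) = sum over a >= x of nL(a) * (1 - r(a)) / l(x)`.
#' With zero morbidity HALE equals ordinary life expectancy; HALE never
#' exceeds it.
#'
#' @param lt_full tibble with columns `age`, `lx`, `nLx` (ages strictly
#'   increasing from 0, `lx > 0` at age 0)
#' @param yld_rate numeric morbidity rate per age (same length as the table)
#'   or a tibble with columns `age`, `yld_rate`
#' @return tibble with columns `age`, `le`, `hale`
#' @export
compute_hale <- function(lt_full, yld_rate) {
  lt_full <- tibble::as_tibble(lt_full)
  if (!all(c("age", "lx", "nLx") %in% names(lt_full))) {
    stop_validation("HALE life table needs columns age, lx, nLx")
  }
  if (is.data.frame(yld_rate)) {
    m <- match(lt_full$age, yld_rate$age)
    if (any(is.na(m))) stop_validation("yld_rate missing for some table ages")
    yld_rate <- yld_rate$yld_rate[m]
  }
  yld_rate <- rep_len(as.numeric(yld_rate), nrow(lt_full))
  if (any(yld_rate < 0 | yld_rate > 1)) {
    stop_validation("morbidity rates must lie in [0, 1]")
  }
  if (lt_full$lx[1] <= 0) stop_validation("lx at age 0 must be positive")
  if (any(lt_full$nLx < 0) || any(lt_full$lx < 0)) {
    stop_validation("lx and nLx must be non-negative")
  }
  tail_L <- rev(cumsum(rev(lt_full$nLx)))
  tail_H <- rev(cumsum(rev(lt_full$nLx * (1 - yld_rate))))
  le <- ifelse(lt_full$lx > 0, tail_L / lt_full$lx, NA_real_)
  hale <- ifelse(lt_full$lx > 0, tail_H / lt_full$lx, NA_real_)
  tibble::tibble(age = lt_full$age, le = le, hale = hale)
}

#' Read a population life table for HALE
#' @param path CSV with columns `age`, `lx`, `nLx`
#' @return tibble suitable for [compute_hale()]
#' @export
read_hale_life_table <- function(path) {
  df <- readr::read_csv(path, col_types = "ddd", progress = FALSE)
  if (!all(c("age", "lx", "nLx") %in% names(df))) {
    stop_format("HALE life table '%s' needs columns age, lx, nLx", path)
  }
  df
}
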
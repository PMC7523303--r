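#' Redistribution of ill-defined causes of death
#'
#' Deaths coded to causes not appropriate for burden analysis ("garbage"
#' codes: ill-defined, intermediate or unspecified causes) are reassigned to
#' plausible specific causes before YLL is computed. Three methods are
#' supported, in the order of preference used in national practice:
#'
#' * **direct**: external linkage evidence gives, per source cause, a
#'   probability table over target causes; the table may retain a fraction at
#'   the source itself (e.g. deaths from cancer of unknown primary site that
#'   are genuinely of unknown primary).
#' * **indirect_mcod**: the multiple-causes-of-death pattern is used — among
#'   deaths that mention the source cause as an *associated* cause and whose
#'   underlying cause is specific, the distribution of underlying causes
#'   provides the redistribution weights.
#' * **proportional**: the source weight is spread over a stated target set
#'   proportionally to the existing underlying-cause distribution.
#'
#' A **combination** rule sends a stated share through the direct table and
#' the remainder through the indirect MCOD pattern.
#'
#' Reassignment is deterministic and fractional: a death of weight w becomes
#' several records whose weights sum to w, so total death-equivalents are
#' conserved exactly.
#'
#' @name redistribution
NULL

#' Construct a redistribution rule
#'
#' @param source cause id of the ill-defined source cause
#' @param method one of `"direct"`, `"indirect_mcod"`, `"proportional"`,
#'   `"combination"`
#' @param table named numeric probability table over target cause ids
#'   (direct/combination); must sum to 1 and may include `source` itself as a
#'   retention entry
#' @param targets character vector of target cause ids (proportional)
#' @param direct_share fraction in `[0,1]` routed through `table` by a
#'   combination rule (remainder goes through the indirect MCOD pattern)
#' @return a `redistribution_rule` object
#' @export
redistribution_rule <- function(source,
                                method = c("direct", "indirect_mcod",
                                           "proportional", "combination"),
                                table = NULL, targets = NULL,
                                direct_share = NULL) {
  method <- match.arg(method)
  if (method %in% c("direct", "combination")) {
    if (is.null(table) || is.null(names(table))) {
      stop_validation("rule for '%s': %s method needs a named probability table",
                      source, method)
    }
    table <- unlist(table)
    if (any(table < 0)) {
      stop_validation("rule for '%s': negative table fraction", source)
    }
    check_sums_to_one(table, sprintf("probability table for '%s'", source))
  }
  if (method == "proportional" &&
      (is.null(targets) || length(targets) == 0L)) {
    stop_validation("rule for '%s': proportional method needs targets", source)
  }
  if (method == "combination") {
    if (is.null(direct_share) || direct_share < 0 || direct_share > 1) {
      stop_validation("rule for '%s': combination needs direct_share in [0,1]",
                      source)
    }
  }
  structure(list(source = source, method = method, table = table,
                 targets = as.character(targets %||% character()),
                 direct_share = direct_share),
            class = "redistribution_rule")
}

#' Read redistribution rules from YAML
#'
#' The file holds a `rules` sequence; each entry has `source`, `method`, and
#' depending on the method `table` (map of target cause to fraction),
#' `targets` (sequence) and `direct_share`.
#'
#' @param path path to the YAML rules file
#' @param cl a [cause_list()] used to validate cause ids and source flags
#' @return named list of [redistribution_rule()] objects, keyed by source
#' @export
read_redistribution_rules <- function(path, cl) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_format("cannot parse rules file '%s': %s", path, conditionMessage(e))
  })
  entries <- doc$rules %||% doc
  rules <- purrr::map(entries, function(e) {
    redistribution_rule(source = e$source, method = e$method,
                        table = e$table,
                        targets = e$targets,
                        direct_share = e$direct_share)
  })
  names(rules) <- purrr::map_chr(rules, "source")
  validate_rules(rules, cl)
  rules
}

validate_rules <- function(rules, cl) {
  if (anyDuplicated(names(rules))) {
    stop_config("more than one rule for source '%s'",
                names(rules)[duplicated(names(rules))][1])
  }
  sources <- redistribution_sources(cl)
  known <- cl$causes$cause_id
  for (r in rules) {
    if (!r$source %in% sources) {
      stop_config("rule source '%s' is not flagged as a redistribution source",
                  r$source)
    }
    tg <- setdiff(c(names(r$table), r$targets), r$source)
    bad <- setdiff(tg, known)
    if (length(bad)) {
      stop_config("rule for '%s' targets unknown cause '%s'", r$source, bad[1])
    }
  }
  missing <- setdiff(sources, names(rules))
  if (length(missing)) {
    stop_config("no redistribution rule for source cause(s): %s",
                paste(missing, collapse = ", "))
  }
  invisible(rules)
}

#' Indirect multiple-causes-of-death distribution
#'
#' For a source cause, finds all deaths that mention that cause as an
#' associated cause of death, excludes those whose underlying cause is itself
#' a redistribution source (so ill-defined weight never propagates into the
#' pattern), tallies the underlying-cause weights of the rest, and normalises
#' to a probability distribution. The tally is order-free.
#'
#' @param records a [death_records()] tibble
#' @param target_cause cause id of the source cause being redistributed
#' @param cl a [cause_list()]
#' @return named numeric distribution over cause ids summing to 1, or a
#'   zero-length numeric when no eligible death mentions the cause (callers
#'   fall back to proportional redistribution)
#' @export
build_indirect_mcod_distribution <- function(records, target_cause, cl) {
  ucod_cause <- map_code(cl, records$ucod)
  indirect_mcod_distribution_impl(records, ucod_cause, target_cause, cl)
}

indirect_mcod_distribution_impl <- function(records, ucod_cause,
                                            target_cause, cl) {
  sources <- redistribution_sources(cl)
  lens <- lengths(records$associated)
  if (sum(lens) == 0L) return(stats::setNames(numeric(0), character(0)))
  flat <- unlist(records$associated, use.names = FALSE)
  flat_cause <- map_code(cl, flat)
  rec_idx <- rep.int(seq_len(nrow(records)), lens)
  mentioners <- unique(rec_idx[flat_cause == target_cause])
  eligible <- mentioners[!(ucod_cause[mentioners] %in% sources)]
  if (length(eligible) == 0L) return(stats::setNames(numeric(0), character(0)))
  tal <- rowsum(records$weight[eligible], ucod_cause[eligible])
  dist <- stats::setNames(as.numeric(tal), rownames(tal))
  dist / sum(dist)
}

# Split each record's weight over a named distribution of target causes.
# A target equal to `source` is a retention entry: those pieces keep the
# original underlying cause code. Returns list(records=, cause=).
split_records <- function(records, dist, source, cl) {
  dist <- dist[dist > 0]
  targets <- names(dist)
  n <- nrow(records)
  k <- length(targets)
  rep_codes <- ifelse(targets == source, NA_character_,
                      representative_code(cl, targets))
  idx <- rep(seq_len(n), times = k)
  tgt <- rep(seq_len(k), each = n)
  out <- records[idx, ]
  out$weight <- unname(records$weight[idx] * dist[tgt])
  new_code <- rep_codes[tgt]
  keep <- is.na(new_code)
  out$ucod[!keep] <- new_code[!keep]
  # a reassigned record must not list its new cause among associated mentions
  out$associated[!keep] <- purrr::map2(out$associated[!keep], out$ucod[!keep],
                                       function(a, u) a[a != u])
  list(records = out, cause = targets[tgt])
}

#' Apply a direct-evidence redistribution table
#'
#' Each input record of weight w becomes one record per table entry (target
#' t, fraction p) of weight w*p; a retention entry (t equal to the source)
#' keeps the original underlying cause code. Total weight is conserved.
#'
#' @param records [death_records()] whose underlying causes all map to
#'   `rule$source`
#' @param rule a [redistribution_rule()] with method `"direct"` or
#'   `"combination"`
#' @param cl a [cause_list()]
#' @return a [death_records()] tibble of the reassigned fractional records
#' @export
apply_direct_evidence <- function(records, rule, cl) {
  if (!rule$method %in% c("direct", "combination")) {
    stop_validation("rule for '%s' is not a direct-evidence rule", rule$source)
  }
  check_sums_to_one(rule$table,
                    sprintf("probability table for '%s'", rule$source))
  split_records(records, rule$table, rule$source, cl)$records
}

#' Apply proportional redistribution
#'
#' The source weight is split across the rule's target causes proportionally
#' to a base distribution (normally the current underlying-cause weights).
#' When the base is zero over every target, the split falls back to uniform
#' with a warning.
#'
#' @param records [death_records()] whose underlying causes all map to
#'   `rule$source`
#' @param rule a [redistribution_rule()] with method `"proportional"`
#' @param base_distribution named numeric of cause weights used to set the
#'   shares (only entries for the rule's targets are used)
#' @param cl a [cause_list()]
#' @return a [death_records()] tibble of the reassigned fractional records
#' @export
apply_proportional <- function(records, rule, base_distribution, cl) {
  if (rule$method != "proportional") {
    stop_validation("rule for '%s' is not a proportional rule", rule$source)
  }
  dist <- proportional_shares(rule$targets, base_distribution, rule$source)
  split_records(records, dist, rule$source, cl)$records
}

proportional_shares <- function(targets, base, source) {
  base_t <- base[targets]
  base_t[is.na(base_t)] <- 0
  if (sum(base_t) <= 0) {
    warn(sprintf(
      "base distribution is zero over every target of '%s'; using a uniform split",
      source))
    base_t <- rep(1, length(targets))
  }
  stats::setNames(as.numeric(base_t) / sum(base_t), targets)
}

#' Redistribute all ill-defined deaths
#'
#' Orchestrates redistribution over every source cause: sources are processed
#' in topological order (a source that feeds another source is resolved
#' first, so cascades such as unspecified cancer -> cancer of unknown primary
#' -> specific sites collapse in one pass), each source's records are
#' reassigned by its rule's method, and an audit report is produced. Cyclic
#' source dependencies are a configuration error. Combination rules route
#' `direct_share` of the weight through the direct table and the remainder
#' through the indirect MCOD pattern; an empty indirect pattern falls back to
#' proportional redistribution over the non-source causes of the source's
#' disease group.
#'
#' After completion no record's underlying cause maps to a redistribution
#' source, apart from weight an explicit retention entry keeps at its source
#' (reported as `retained_weight`).
#'
#' @param records a [death_records()] tibble
#' @param rules named list of [redistribution_rule()] (one per source cause)
#' @param cl a [cause_list()]
#' @param stochastic if `TRUE`, each death is assigned one sampled target
#'   instead of being fractionally split (requires `seed`); off by default
#'   because fractional splitting conserves weight exactly
#' @param seed integer seed for `stochastic = TRUE`
#' @return a list with elements `records` (the redistributed
#'   [death_records()]) and `report` (a `redistribution_report`, see
#'   [redistribution_report fields][redistribute]): `total_weight_in`,
#'   `total_weight_out`, `redistributed_fraction` (share of all death weight
#'   whose cause changed), `within_group_fraction` (share of moved weight
#'   staying in the source's disease group), `method_shares` (share of
#'   processed source causes per method, combination rules counted once under
#'   `"combination"`), `retained_weight`, and per-source moved weights
#' @export
redistribute <- function(records, rules, cl, stochastic = FALSE, seed = NULL) {
  validate_rules(rules, cl)
  if (stochastic) {
    if (is.null(seed)) stop_config("stochastic redistribution requires a seed")
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed, kind = "Mersenne-Twister")
  }

  sources <- redistribution_sources(cl)
  order <- topological_source_order(rules, sources)

  work <- records
  cause <- map_code(cl, work$ucod)
  orig <- cause                  # cause class each record entered with
  w_in <- sum(work$weight)
  methods_used <- character(0)

  for (s in order) {
    sel <- which(cause == s)
    if (length(sel) == 0L) next
    rule <- rules[[s]]
    sel_rec <- work[sel, ]

    dist <- switch(rule$method,
      direct = rule$table,
      proportional = {
        base <- cause_weights(work$weight[-sel], cause[-sel])
        proportional_shares(rule$targets, base, s)
      },
      indirect_mcod = indirect_or_group_fallback(work, cause, s, cl),
      combination = {
        ind <- indirect_or_group_fallback(work, cause, s, cl)
        combine_distributions(rule$table, ind, rule$direct_share)
      })

    if (stochastic) {
      pick <- sample(names(dist), size = nrow(sel_rec), replace = TRUE,
                     prob = dist)
      pieces <- sel_rec
      new_code <- ifelse(pick == s, pieces$ucod, representative_code(cl, pick))
      pieces$ucod <- new_code
      piece_cause <- pick
      piece_orig <- orig[sel]
    } else {
      sp <- split_records(sel_rec, dist, s, cl)
      pieces <- sp$records
      piece_cause <- sp$cause
      piece_orig <- rep(orig[sel], times = length(sp$cause) / length(sel))
    }
    methods_used[s] <- rule$method

    work <- dplyr::bind_rows(work[-sel, ], pieces)
    cause <- c(cause[-sel], piece_cause)
    orig <- c(orig[-sel], piece_orig)
  }

  w_out <- sum(work$weight)
  leftover_src <- unique(cause[cause %in% sources])
  has_retention <- vapply(leftover_src, function(cc)
    cc %in% names(rules[[cc]]$table %||% character()), logical(1))
  if (any(!has_retention)) {
    stop_config("weight remains at redistribution source '%s' after processing",
                leftover_src[!has_retention][1])
  }

  n_src <- length(methods_used)
  levels <- c("direct", "indirect_mcod", "proportional", "combination")
  shares <- table(factor(methods_used, levels = levels))
  if (n_src) shares <- shares / n_src

  # weight counts as redistributed only if its final cause class differs
  # from the class it entered with (cascades are not double-counted, and
  # weight retained at its source by direct evidence is not redistributed)
  changed <- cause != orig
  moved <- sum(work$weight[changed])
  g_now <- disease_group(cl, cause)
  g_orig <- disease_group(cl, orig)
  same_group <- !is.na(g_now) & !is.na(g_orig) & g_now == g_orig
  moved_within <- sum(work$weight[changed & same_group])
  retained <- sum(work$weight[!changed & cause %in% sources &
                                cause %in% names(methods_used)])
  by_source <- cause_weights(work$weight[changed & orig %in% sources],
                             orig[changed & orig %in% sources])

  report <- structure(list(
    total_weight_in = w_in,
    total_weight_out = w_out,
    redistributed_fraction = if (w_in > 0) moved / w_in else 0,
    within_group_fraction = if (moved > 0) moved_within / moved else 0,
    method_shares = stats::setNames(as.numeric(shares), names(shares)),
    retained_weight = retained,
    moved_weight_by_source = by_source),
    class = "redistribution_report")

  list(records = work, report = report)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

cause_weights <- function(weight, cause) {
  if (length(weight) == 0L) return(stats::setNames(numeric(0), character(0)))
  tal <- rowsum(weight, cause)
  stats::setNames(as.numeric(tal), rownames(tal))
}

indirect_or_group_fallback <- function(work, cause, s, cl) {
  dist <- indirect_mcod_distribution_impl(work, cause, s, cl)
  if (length(dist)) return(dist)
  grp <- disease_group(cl, s)
  pool <- cl$causes$cause_id[cl$causes$disease_group == grp &
                               !cl$causes$is_redistribution_source]
  if (length(pool) == 0L) {
    pool <- cl$causes$cause_id[!cl$causes$is_redistribution_source]
    warn(sprintf(
      "no multiple-cause mentions and no non-source cause in group '%s'; %s",
      grp, sprintf("falling back to proportional over all causes for '%s'", s)))
  } else {
    warn(sprintf(
      "no eligible multiple-cause mentions of '%s'; falling back to proportional over its disease group",
      s))
  }
  base <- cause_weights(work$weight[cause != s], cause[cause != s])
  proportional_shares(pool, base, s)
}

combine_distributions <- function(direct_table, indirect_dist, direct_share) {
  all_t <- union(names(direct_table), names(indirect_dist))
  d <- stats::setNames(numeric(length(all_t)), all_t)
  d[names(direct_table)] <- d[names(direct_table)] + direct_share * direct_table
  if (length(indirect_dist)) {
    d[names(indirect_dist)] <- d[names(indirect_dist)] +
      (1 - direct_share) * indirect_dist
  } else {
    # degenerate: indirect part empty and no fallback supplied
    d <- d / sum(d)
  }
  d
}

topological_source_order <- function(rules, sources) {
  nodes <- intersect(names(rules), sources)
  succ <- purrr::map(rules[nodes], function(r) {
    tg <- setdiff(c(names(r$table), r$targets), r$source)
    intersect(tg, nodes)
  })
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (s in nodes) for (t in succ[[s]]) indeg[t] <- indeg[t] + 1L
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    n <- sort(ready)[1]
    ready <- setdiff(ready, n)
    order <- c(order, n)
    for (t in succ[[n]]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) ready <- c(ready, t)
    }
  }
  if (length(order) < length(nodes)) {
    cyc <- setdiff(nodes, order)
    stop_config("cyclic redistribution dependencies among: %s",
                paste(sort(cyc), collapse = " -> "))
  }
  order
}

#' @export
print.redistribution_report <- function(x, ...) {
  cat("<redistribution_report>\n")
  cat(sprintf("  weight in/out: %.6f / %.6f\n",
              x$total_weight_in, x$total_weight_out))
  cat(sprintf("  redistributed fraction: %.4f\n", x$redistributed_fraction))
  cat(sprintf("  within-group fraction:  %.4f\n", x$within_group_fraction))
  cat(sprintf("  retained at source:     %.6f\n", x$retained_weight))
  cat("  method shares:\n")
  for (m in names(x$method_shares)) {
    cat(sprintf("    %-13s %.4f\n", m, x$method_shares[[m]]))
  }
  invisible(x)
}

#' Write a redistribution report
#'
#' @param report a `redistribution_report` from [redistribute()]
#' @param path output path; `.yaml`/`.yml` writes YAML, anything else a
#'   two-column CSV of field and value
#' @return invisibly, `path`
#' @export
write_redistribution_report <- function(report, path) {
  fields <- list(
    total_weight_in = report$total_weight_in,
    total_weight_out = report$total_weight_out,
    redistributed_fraction = report$redistributed_fraction,
    within_group_fraction = report$within_group_fraction,
    retained_weight = report$retained_weight,
    method_shares = as.list(report$method_shares))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(fields, path)
  } else {
    flat <- c(fields[1:5], as.list(stats::setNames(
      report$method_shares,
      paste0("method_share_", names(report$method_shares)))))
    df <- tibble::tibble(field = names(flat),
                         value = vapply(flat, as.numeric, numeric(1)))
    readr::write_csv(df, path)
  }
  invisible(path)
}
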
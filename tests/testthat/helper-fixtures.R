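# Shared fixtures built in code: a small cause list, record builders, and an
# independent brute-force oracle for the indirect MCOD tally.

toy_cause_list <- function() {
  cause_list(tibble::tibble(
    cause_id = c("chd", "pneumonia", "lung_ca", "colorectal_ca",
                 "sepsis", "cup", "unspec_ca", "illdef"),
    name = cause_id,
    disease_group = c("cvd", "infections", "cancer", "cancer",
                      "infections", "cancer", "cancer", "illdef"),
    icd10 = list("I20-I25", "J12-J18", "C33-C34", "C18-C21",
                 "A40-A41", "C80", "C76-C79", "R00-R99"),
    is_redistribution_source = c(FALSE, FALSE, FALSE, FALSE,
                                 TRUE, TRUE, TRUE, TRUE)))
}

# quick record builder: recs("I21", c("A41","J18"), w = 2) etc.
recs <- function(ucod, associated = NULL, age = 70, sex = "female",
                 weight = 1) {
  n <- length(ucod)
  if (is.null(associated)) associated <- rep(list(character()), n)
  if (!is.list(associated)) associated <- list(associated)
  death_records(record_id = sprintf("r%03d", seq_len(n)),
                age = rep_len(age, n), sex = rep_len(sex, n),
                ucod = ucod, associated = rep_len(associated, n),
                weight = rep_len(weight, n))
}

# Independent oracle: naive double loop over records and mentions.
naive_indirect_distribution <- function(records, target_cause, cl) {
  sources <- cl$causes$cause_id[cl$causes$is_redistribution_source]
  tally <- numeric(0)
  for (i in seq_len(nrow(records))) {
    ucod_cause <- map_code(cl, records$ucod[i])
    if (ucod_cause %in% sources) next
    mentioned <- FALSE
    for (code in records$associated[[i]]) {
      if (map_code(cl, code) == target_cause) mentioned <- TRUE
    }
    if (!mentioned) next
    tally[ucod_cause] <- (if (is.na(tally[ucod_cause][1])) 0
                          else tally[ucod_cause]) + records$weight[i]
  }
  if (length(tally) == 0L) return(setNames(numeric(0), character(0)))
  tally / sum(tally)
}

# Random multi-cause fixture over the toy cause list.
random_fixture <- function(n, p_garbled = 0.2, p_mention = 0.5) {
  specific <- c("I21", "J13", "C34", "C19")
  source_codes <- c("A41", "C80", "C78", "R99")
  ucod <- ifelse(runif(n) < p_garbled,
                 sample(source_codes, n, replace = TRUE),
                 sample(specific, n, replace = TRUE))
  associated <- lapply(seq_len(n), function(i) {
    if (runif(1) < p_mention) {
      sample(c(specific, source_codes), sample(1:3, 1))
    } else {
      character()
    }
  })
  death_records(record_id = sprintf("x%05d", seq_len(n)),
                age = sample(0:100, n, replace = TRUE),
                sex = sample(c("female", "male"), n, replace = TRUE),
                ucod = ucod, associated = associated,
                weight = runif(n, 0.2, 2))
}

toy_rules <- function(retention = TRUE) {
  cup_table <- if (retention) {
    c(cup = 0.7, lung_ca = 0.2, colorectal_ca = 0.1)
  } else {
    c(lung_ca = 0.6, colorectal_ca = 0.4)
  }
  rules <- list(
    redistribution_rule("sepsis", "indirect_mcod"),
    redistribution_rule("illdef", "indirect_mcod"),
    redistribution_rule("unspec_ca", "direct",
                        table = c(cup = 0.5, lung_ca = 0.3,
                                  colorectal_ca = 0.2)),
    redistribution_rule("cup", "direct", table = cup_table))
  setNames(rules, vapply(rules, function(r) r$source, character(1)))
}

expect_conserved <- function(before, after, tol = 1e-9) {
  expect_equal(sum(after$weight), sum(before$weight),
               tolerance = tol)
}
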
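cl <- toy_cause_list()

test_that("indirect MCOD distribution follows the associated-cause pattern", {
  # UCOD I21 with septicaemia mentioned x2, J18 with septicaemia x1,
  # I21 with no mentions x5: pattern is 2/3 CHD, 1/3 pneumonia
  dr <- recs(c("I21", "I21", "J18", rep("I21", 5)),
             c(rep(list("A41"), 3), rep(list(character()), 5)))
  dist <- build_indirect_mcod_distribution(dr, "sepsis", cl)
  expect_equal(dist, c(chd = 2 / 3, pneumonia = 1 / 3))

  # mentions on ill-defined UCODs are excluded from the tally
  dr2 <- dplyr::bind_rows(dr, recs("R99", list("A41")))
  expect_equal(build_indirect_mcod_distribution(dr2, "sepsis", cl), dist)

  # no mentions at all: distinguished empty result
  none <- recs(c("I21", "J18"))
  expect_length(build_indirect_mcod_distribution(none, "sepsis", cl), 0L)
})

test_that("direct evidence splits weight by the probability table", {
  cup_deaths <- recs(rep("C80", 10))
  rule <- redistribution_rule("cup", "direct",
                              table = c(cup = 0.70, lung_ca = 0.18,
                                        colorectal_ca = 0.12))
  out <- apply_direct_evidence(cup_deaths, rule, cl)
  by_cause <- tapply(out$weight, map_code(cl, out$ucod), sum)
  expect_equal(by_cause[["cup"]], 7.0)
  expect_equal(by_cause[["lung_ca"]], 1.8)
  expect_equal(by_cause[["colorectal_ca"]], 1.2)
  expect_conserved(cup_deaths, out)
  # retained records keep their original code
  expect_true(all(out$ucod[map_code(cl, out$ucod) == "cup"] == "C80"))

  identity_rule <- redistribution_rule("cup", "direct", table = c(cup = 1))
  same <- apply_direct_evidence(cup_deaths, identity_rule, cl)
  expect_equal(same$ucod, cup_deaths$ucod)
  expect_equal(same$weight, cup_deaths$weight)

  expect_error(
    redistribution_rule("cup", "direct", table = c(cup = 0.7, lung_ca = 0.2)),
    "sum to 1", class = "burdenr_validation_error")
})

test_that("proportional redistribution follows the base distribution", {
  src <- recs(rep("C78", 100))
  rule <- redistribution_rule("unspec_ca", "proportional",
                              targets = c("lung_ca", "colorectal_ca"))
  out <- apply_proportional(src, rule, c(lung_ca = 300, colorectal_ca = 100),
                            cl)
  by_cause <- tapply(out$weight, map_code(cl, out$ucod), sum)
  expect_equal(by_cause[["lung_ca"]], 75)
  expect_equal(by_cause[["colorectal_ca"]], 25)

  single <- redistribution_rule("unspec_ca", "proportional",
                                targets = "lung_ca")
  all_lung <- apply_proportional(src, single, c(lung_ca = 5), cl)
  expect_equal(sum(all_lung$weight), 100)
  expect_true(all(map_code(cl, all_lung$ucod) == "lung_ca"))

  four <- redistribution_rule("unspec_ca", "proportional",
                              targets = c("lung_ca", "colorectal_ca",
                                          "chd", "pneumonia"))
  expect_warning(out4 <- apply_proportional(src, four,
                                            c(lung_ca = 0, colorectal_ca = 0),
                                            cl),
                 "uniform")
  expect_equal(as.numeric(tapply(out4$weight, map_code(cl, out4$ucod), sum)),
               rep(25, 4))
})

test_that("the orchestrator is a no-op without source-coded deaths", {
  dr <- recs(c("I21", "J13", "C34"))
  res <- redistribute(dr, toy_rules(), cl)
  expect_equal(res$records$ucod, dr$ucod)
  expect_equal(res$report$redistributed_fraction, 0)
  expect_equal(res$report$total_weight_out, res$report$total_weight_in)
})

test_that("cascades resolve topologically and match the closed-form product", {
  # unspecified cancer -> {cup 0.5, lung 0.3, colorectal 0.2}; then
  # cup -> {cup 0.7, lung 0.2, colorectal 0.1}. Composition for a unit
  # weight starting at unspecified cancer:
  #   cup: 0.5*0.7 = 0.35
  #   lung: 0.3 + 0.5*0.2 = 0.40
  #   colorectal: 0.2 + 0.5*0.1 = 0.25
  dr <- recs(rep("C78", 4))
  res <- redistribute(dr, toy_rules(), cl)
  by_cause <- tapply(res$records$weight, map_code(cl, res$records$ucod), sum)
  expect_equal(by_cause[["cup"]], 4 * 0.35)
  expect_equal(by_cause[["lung_ca"]], 4 * 0.40)
  expect_equal(by_cause[["colorectal_ca"]], 4 * 0.25)
  expect_conserved(dr, res$records)
  # no weight remains at a non-retaining source
  cause_out <- map_code(cl, res$records$ucod)
  expect_false(any(cause_out %in% c("unspec_ca", "sepsis", "illdef")))
})

test_that("cyclic rules and missing rules are configuration errors", {
  cyclic <- toy_rules()
  cyclic$cup <- redistribution_rule("cup", "direct",
                                    table = c(unspec_ca = 0.6, lung_ca = 0.4))
  dr <- recs("C80")
  expect_error(redistribute(dr, cyclic, cl), "cyclic",
               class = "burdenr_config_error")

  incomplete <- toy_rules()[c("sepsis", "cup", "unspec_ca")]
  expect_error(redistribute(dr, incomplete, cl), "illdef",
               class = "burdenr_config_error")
})

test_that("an empty indirect pattern falls back to the disease group", {
  # illdef deaths with no mentions anywhere: its group has no other cause,
  # so the fallback widens to all non-source causes
  dr <- recs(c("R99", "R99", "I21", "J13"))
  expect_warning(res <- redistribute(dr, toy_rules(), cl), "falling back")
  expect_conserved(dr, res$records)
  cause_out <- map_code(cl, res$records$ucod)
  expect_false("illdef" %in% cause_out)
  # sepsis deaths with mentions only of sepsis in specific deaths go per
  # the group when no mention exists: here fallback to infections group
  dr2 <- recs(c("A41", "J13", "J13"))
  expect_warning(res2 <- redistribute(dr2, toy_rules(), cl), "disease group")
  expect_equal(tapply(res2$records$weight,
                      map_code(cl, res2$records$ucod), sum)[["pneumonia"]], 3)
})

test_that("redistribution is idempotent for retention-free rules", {
  set.seed(11)
  dr <- random_fixture(300)
  rules <- toy_rules(retention = FALSE)
  once <- redistribute(dr, rules, cl)
  twice <- redistribute(once$records, rules, cl)
  expect_equal(twice$records$weight, once$records$weight)
  expect_equal(twice$records$ucod, once$records$ucod)
  expect_equal(twice$report$redistributed_fraction, 0)
})

test_that("combination rules route direct_share through the table", {
  cl2 <- cause_list(tibble::tibble(
    cause_id = c("chd", "other_cvd", "pneumonia", "hf"),
    name = cause_id,
    disease_group = c("cvd", "cvd", "resp", "cvd"),
    icd10 = list("I20-I25", "I70-I79", "J12-J18", "I50-I51"),
    is_redistribution_source = c(FALSE, FALSE, FALSE, TRUE)))
  rules <- list(hf = redistribution_rule(
    "hf", "combination", table = c(chd = 1), direct_share = 0.4))
  # mentions: hf mentioned on 1 chd and 1 pneumonia death -> indirect is 50/50
  dr <- recs(c("I50", "I21", "J13"),
             list(character(), "I50", "I50"))
  res <- redistribute(dr, rules, cl2)
  by_cause <- tapply(res$records$weight, map_code(cl2, res$records$ucod), sum)
  # direct: 0.4 to chd; indirect: 0.6 split 0.3/0.3 over chd and pneumonia
  expect_equal(by_cause[["chd"]], 1 + 0.4 + 0.3)
  expect_equal(by_cause[["pneumonia"]], 1 + 0.3)
  expect_conserved(dr, res$records)
})

test_that("the report mirrors the weight actually moved", {
  # 2 of 8 unit deaths are garbled: redistributed fraction is 0.25 exactly;
  # destinations inside the cancer group count as within-group
  dr <- recs(c(rep("I21", 4), rep("C34", 2), "C78", "C78"))
  res <- redistribute(dr, toy_rules(), cl)
  expect_equal(res$report$redistributed_fraction, 0.25)
  # unspec_ca weight lands on cup/lung/colorectal, all in group "cancer"
  expect_equal(res$report$within_group_fraction, 1)
  expect_equal(sum(res$report$method_shares), 1)
  expect_equal(res$report$method_shares[["direct"]], 1)
})

test_that("stochastic mode is reproducible and conserves whole deaths", {
  set.seed(3)
  dr <- random_fixture(200)
  res1 <- redistribute(dr, toy_rules(), cl, stochastic = TRUE, seed = 99)
  res2 <- redistribute(dr, toy_rules(), cl, stochastic = TRUE, seed = 99)
  expect_identical(res1$records$ucod, res2$records$ucod)
  expect_equal(nrow(res1$records), nrow(dr))
  expect_conserved(dr, res1$records)
  expect_error(redistribute(dr, toy_rules(), cl, stochastic = TRUE),
               "seed", class = "burdenr_config_error")
})
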
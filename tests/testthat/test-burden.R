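cl <- toy_cause_list()

test_that("YLL is deaths times interpolated life expectancy, no weighting", {
  lt <- life_table(c(0, 50, 100), c(90, 40, 0))
  # LE(60) = 40 - 10/50*40 = 32; force 25 with a bespoke table
  lt25 <- life_table(c(0, 60, 100), c(90, 25, 0))
  dr <- recs(c("I21", "I21"), age = 60)
  yll <- compute_yll(dr, cl, lt25)
  expect_equal(sum(yll$yll), 2 * 25)
  expect_equal(yll$age_group, "60-64")

  # zero deaths
  expect_equal(nrow(compute_yll(recs(character(0)), cl, lt)), 0L)

  # terminal age with zero expectancy contributes nothing
  terminal <- compute_yll(recs("I21", age = 100), cl, lt)
  expect_equal(terminal$yll, 0)
  expect_equal(terminal$deaths, 1)

  short <- life_table(c(0, 90), c(90, 4))
  expect_error(compute_yll(recs("I21", age = 95), cl, short), "r001",
               class = "burdenr_validation_error")
})

test_that("aggregated YLL equals the per-record summation oracle", {
  set.seed(21)
  lt <- demo_life_table()
  dr <- random_fixture(500)
  yll <- compute_yll(dr, cl, lt)
  oracle <- 0
  for (i in seq_len(nrow(dr))) {
    oracle <- oracle + dr$weight[i] * life_expectancy(lt, dr$age[i])
  }
  expect_equal(sum(yll$yll), oracle, tolerance = 1e-12)
  expect_equal(sum(yll$deaths), sum(dr$weight), tolerance = 1e-12)
})

test_that("younger deaths never lose fewer years under a decreasing table", {
  lt <- demo_life_table()
  ylls <- vapply(c(10L, 40L, 70L, 95L), function(a) {
    sum(compute_yll(recs("I21", age = a), cl, lt)$yll)
  }, numeric(1))
  expect_true(all(diff(ylls) < 0))
})

test_that("YLD expands prevalence over severity levels and weights", {
  models <- list(disease_model("chd", list(
    list(id = "angina", levels = tibble::tibble(
      name = c("mild", "severe"), proportion = c(0.6, 0.4),
      dw = c(0.1, 0.5))))))
  prev <- prevalence_table(tibble::tibble(
    sequela_id = "angina", age_group = "60-64", sex = "female",
    prevalence = 1000))
  yld <- compute_yld(prev, models)
  expect_equal(yld$yld, 1000 * (0.6 * 0.1 + 0.4 * 0.5))  # 260 person-years

  # zero disability weights give zero YLD
  models0 <- list(disease_model("chd", list(
    list(id = "angina", levels = tibble::tibble(
      name = c("mild", "severe"), proportion = c(0.6, 0.4), dw = c(0, 0))))))
  expect_equal(compute_yld(prev, models0)$yld, 0)

  # a single level at full weight attains the prevalence bound
  models1 <- list(disease_model("chd", list(
    list(id = "angina", levels = tibble::tibble(
      name = "all", proportion = 1, dw = 1)))))
  expect_equal(compute_yld(prev, models1)$yld, 1000)

  orphan <- prevalence_table(tibble::tibble(
    sequela_id = "vertigo", age_group = "60-64", sex = "female",
    prevalence = 10))
  expect_error(compute_yld(orphan, models), "vertigo",
               class = "burdenr_config_error")
})

test_that("YLD never exceeds prevalence and severity proportions must close", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    prop <- as.numeric(stats::rmultinom(1, 100, rep(1, k))) / 100
    models <- list(disease_model("chd", list(
      list(id = "sq", levels = tibble::tibble(
        name = letters[1:k], proportion = prop, dw = runif(k))))))
    prev <- prevalence_table(tibble::tibble(
      sequela_id = "sq", age_group = "60-64", sex = "male",
      prevalence = runif(1, 0, 5000)))
    expect_lte(compute_yld(prev, models)$yld, prev$prevalence)
  }
  expect_error(disease_model("chd", list(list(id = "sq",
    levels = tibble::tibble(name = c("a", "b"), proportion = c(0.6, 0.5),
                            dw = c(0.1, 0.2))))),
    "sum to 1", class = "burdenr_validation_error")
  expect_error(disease_model("chd", list(list(id = "sq",
    levels = tibble::tibble(name = "a", proportion = 1, dw = 1.2)))),
    "\\[0,1\\]", class = "burdenr_validation_error")
})

test_that("DALY assembly adds components cellwise and fills missing with 0", {
  yll <- tibble::tibble(cause_id = "chd", age_group = "60-64", sex = "female",
                        deaths = 2, yll = 50)
  yld <- tibble::tibble(cause_id = "chd", age_group = "60-64", sex = "female",
                        yld = 260)
  daly <- assemble_daly(yll, yld, quiet = TRUE)
  expect_equal(daly$daly, 310)

  # a YLD-only disease keeps daly = yld
  yld2 <- dplyr::bind_rows(yld, tibble::tibble(
    cause_id = "depression", age_group = "60-64", sex = "female", yld = 40))
  expect_message(daly2 <- assemble_daly(yll, yld2), "missing")
  expect_equal(daly2$daly[daly2$cause_id == "depression"], 40)

  empty <- assemble_daly(yll[0, ], yld[0, ], quiet = TRUE)
  expect_equal(nrow(empty), 0L)

  expect_error(assemble_daly(dplyr::mutate(yll, yll = -1), yld, quiet = TRUE),
               class = "burdenr_validation_error")
})

test_that("DALY assembly is additive over death inputs", {
  set.seed(41)
  lt <- demo_life_table()
  a <- random_fixture(120)
  b <- random_fixture(80)
  yld <- tibble::tibble(cause_id = "chd", age_group = "60-64", sex = "female",
                        yld = 10)
  one <- assemble_daly(compute_yll(dplyr::bind_rows(a, b), cl, lt), yld,
                       quiet = TRUE)
  ya <- compute_yll(a, cl, lt)
  yb <- compute_yll(b, cl, lt)
  both <- dplyr::bind_rows(ya, yb) |>
    dplyr::group_by(cause_id, age_group, sex) |>
    dplyr::summarise(deaths = sum(deaths), yll = sum(yll), .groups = "drop") |>
    assemble_daly(yld, quiet = TRUE)
  expect_equal(sum(one$daly), sum(both$daly), tolerance = 1e-12)
})

test_that("Sullivan HALE satisfies its identities and hand example", {
  # two-age toy table: HALE(0) = 60*0.9 + 40*0.5 = 74
  toy <- tibble::tibble(age = c(0, 60), lx = c(1, 0.6), nLx = c(60, 40))
  h <- compute_hale(toy, c(0.1, 0.5))
  expect_equal(h$hale[1], 74)
  expect_equal(h$le[1], 100)

  hl <- demo_hale_life_table()
  # zero morbidity: HALE = LE at every age
  h0 <- compute_hale(hl, rep(0, nrow(hl)))
  expect_equal(h0$hale, h0$le, tolerance = 1e-12)
  # constant morbidity d: HALE = (1 - d) * LE at every age
  hd <- compute_hale(hl, rep(0.3, nrow(hl)))
  expect_equal(hd$hale, 0.7 * hd$le, tolerance = 1e-12)

  expect_error(compute_hale(hl, rep(1.2, nrow(hl))),
               class = "burdenr_validation_error")
})

test_that("HALE never exceeds LE on random life tables", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    hl <- tibble::tibble(age = seq(0, by = 5, length.out = n),
                         lx = sort(runif(n, 0.01, 1), decreasing = TRUE),
                         nLx = runif(n, 0.1, 5))
    r <- runif(n)
    h <- compute_hale(hl, r)
    expect_true(all(h$hale <= h$le + 1e-12))
  }
  # equality holds iff morbidity vanishes where person-years are lived
  hl <- tibble::tibble(age = c(0, 5), lx = c(1, 0.9), nLx = c(5, 0))
  h <- compute_hale(hl, c(0, 0.8))
  expect_equal(h$hale[1], h$le[1])
})
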
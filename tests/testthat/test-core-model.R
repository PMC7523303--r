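test_that("cause list YAML loads, validates, and flags overlapping ranges", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "causes:",
    "  - {id: chd, name: CHD, group: cvd, icd10: I20-I25}",
    "  - {id: sepsis, name: Septicaemia, group: infections,",
    "     icd10: A40-A41, redistribution_source: true}",
    "  - {id: cup, name: Unknown primary, group: cancer,",
    "     icd10: C80, redistribution_source: true}"), path)
  cl <- load_cause_list(path)
  expect_s3_class(cl, "cause_list")
  expect_equal(nrow(cl$causes), 3L)
  expect_equal(sum(cl$causes$is_redistribution_source), 2L)

  overlap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "causes:",
    "  - {id: a, name: A, group: g, icd10: I20-I25}",
    "  - {id: b, name: B, group: g, icd10: I24-I30}"), overlap)
  expect_error(load_cause_list(overlap), "overlap",
               class = "burdenr_validation_error")

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("causes: []", empty)
  expect_error(load_cause_list(empty), "empty",
               class = "burdenr_validation_error")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("causes:", "  - {id: a, name: [unclosed"), bad)
  expect_error(load_cause_list(bad), class = "burdenr_format_error")
})

test_that("map_code matches by inclusive interval containment and is total", {
  cl <- toy_cause_list()
  expect_equal(map_code(cl, "I21.4"), "chd")
  expect_equal(map_code(cl, "i219"), map_code(cl, "I21.9"))
  expect_equal(map_code(cl, "Q99.9"), unmapped_cause())
  # endpoint inclusivity: a fourth character inside the closing code
  expect_equal(map_code(cl, "I259"), "chd")
  expect_equal(map_code(cl, "I26"), unmapped_cause())
  # normalisation idempotence over a random pool of codes
  set.seed(42)
  pool <- paste0(sample(LETTERS, 200, TRUE),
                 sample(sprintf("%02d", 0:99), 200, TRUE),
                 sample(c("", ".1", ".9", "4"), 200, TRUE))
  expect_equal(map_code(cl, pool), map_code(cl, normalise_icd(pool)))
  expect_length(map_code(cl, pool), 200L)
})

test_that("deaths files read back with count and weight preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,age,sex,ucod,associated",
    "d1,67,F,I21.4,A41;J18",
    "d2,80,M,A41,A41;A41;J18",
    "d3,45,F,C80,",
    "d4,0,M,R99,I21",
    "d5,100,F,J12,"), path)
  dr <- read_deaths(path)
  expect_equal(nrow(dr), 5L)
  expect_equal(total_weight(dr), 5)
  # associated mentions are deduplicated and never include the UCOD
  expect_setequal(dr$associated[[2]], "J18")
  expect_setequal(dr$associated[[1]], c("A41", "J18"))

  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,age,sex,ucod", "d1,67,F,I21"), missing_col)
  expect_error(read_deaths(missing_col), "associated",
               class = "burdenr_format_error")

  bad_age <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,age,sex,ucod,associated",
               "d1,67,F,I21,", "d2,old,M,I21,"), bad_age)
  expect_error(read_deaths(bad_age), "row 2", class = "burdenr_format_error")

  bad_sex <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,age,sex,ucod,associated", "d1,67,X,I21,"), bad_sex)
  expect_error(read_deaths(bad_sex), "sex", class = "burdenr_format_error")
})

test_that("death records round trip through write_deaths", {
  dr <- recs(c("I21", "A41", "C80"), list(c("A41", "J18")), age = c(60, 70, 80),
             weight = c(1, 0.25, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_deaths(dr, path)
  back <- read_deaths(path)
  expect_equal(back$ucod, dr$ucod)
  expect_equal(back$age, dr$age)
  # fractional post-redistribution weights survive the round trip
  expect_equal(back$weight, dr$weight)
})

test_that("burden tables enforce daly = yll + yld and round trip exactly", {
  cells <- tibble::tibble(
    cause_id = c("chd", "chd", "stroke", "stroke"),
    age_group = c("60-64", "65-69", "60-64", "65-69"),
    sex = "female",
    deaths = c(2, 3, 1, 0),
    yll = c(50.123456, 60, 25, 0),
    yld = c(10.654321, 0, 5, 12.3))
  bt <- burden_table(cells)
  expect_equal(bt$daly, bt$yll + bt$yld)

  path <- withr::local_tempfile(fileext = ".csv")
  write_burden_table(bt, path)
  back <- read_burden_table(path)
  expect_equal(as.data.frame(back), as.data.frame(bt), tolerance = 1e-6)

  # empty table -> header-only file
  empty <- burden_table(cells[0, ])
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_burden_table(empty, p2)
  expect_length(readLines(p2), 1L)

  cells$daly <- cells$yll + cells$yld + 1
  expect_error(burden_table(cells), "daly",
               class = "burdenr_validation_error")
  cells$daly <- NULL
  cells$yll[1] <- -1
  expect_error(burden_table(cells), class = "burdenr_validation_error")
})

test_that("life expectancy interpolates linearly and rejects out-of-range ages", {
  lt <- life_table(c(0, 50, 100), c(90, 40, 2))
  expect_equal(life_expectancy(lt, 25), 65)
  expect_equal(life_expectancy(lt, c(0, 100)), c(90, 2))
  expect_error(life_expectancy(lt, 101), class = "burdenr_validation_error")
  expect_error(life_table(c(5, 10), c(80, 75)), "from 0",
               class = "burdenr_validation_error")
})
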
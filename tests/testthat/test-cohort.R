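test_that("a conformant cohort yields no validation findings", {
  co <- make_cohort(make_participant("A"), make_participant("B", age = 80))
  expect_identical(nrow(validate_cohort(co)), 0L)
  # idempotent and side-effect free
  before <- co
  f1 <- validate_cohort(co)
  f2 <- validate_cohort(co)
  expect_identical(f1, f2)
  expect_identical(co, before)
})

test_that("invariant violations produce one tagged finding each", {
  co <- make_cohort(make_participant("A", age = 130),
                    make_participant("A", sex = "other"))
  f <- validate_cohort(co)
  expect_true(any(f$field == "age" & f$severity == "fatal"))
  expect_true(any(f$field == "sex" & f$severity == "fatal"))
  expect_equal(sum(f$field == "id"), 2)  # both rows of the duplicate named

  # missing toe pressures warn (targeted method may be inapplicable)
  co2 <- make_participant("C", toe = c(NA, NA))
  f2 <- validate_cohort(co2)
  expect_identical(f2$severity, "warning")
  expect_match(f2$message, "toe pressures missing")
})

test_that("duplex findings are validated against the segment vocabulary", {
  d <- make_duplex("A", "posterior_tibial", 60)
  expect_identical(nrow(validate_duplex(d)), 0L)
  bad <- make_duplex("A", c("posterior_tibial", "aorta_of_atlantis"),
                     c(120, 40))
  f <- validate_duplex(bad)
  expect_true(any(f$field == "stenosis_percent" & f$severity == "fatal"))
  expect_true(any(f$field == "artery" & f$severity == "fatal"))
  occ <- make_duplex("A", "popliteal", 80, occluded = TRUE)
  expect_true(any(validate_duplex(occ)$field == "occluded"))
})

test_that("cohort CSV round-trip preserves every field, INC and missing", {
  co <- make_cohort(
    make_participant("A", toe = c(NA, 62)),
    make_participant("B", inc = c("dp_left", "pt_left"),
                     ankle_right = c(dp = 144, pt = 131)),
    make_participant("C", brachial = c(NA, 125), same_day = FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  txt <- readLines(path)
  expect_true(any(grepl("INC", txt)))
  back <- suppressWarnings(read_cohort(path))
  rownames(co) <- rownames(back) <- NULL
  expect_equal(back, co)
})

test_that("read_cohort is fatal on duplicate ids and malformed values", {
  co <- make_cohort(make_participant("A"), make_participant("A"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_error(read_cohort(path), "duplicate")
  lines <- readLines(path)
  lines[2] <- sub("^A,70", "B,seventy", lines[2])
  writeLines(lines, path)
  expect_error(read_cohort(path), "age")
})

test_that("ankle pressures above the cuff ceiling load as incompressible", {
  co <- make_participant("A", ankle_left = c(dp = 260, pt = 130))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, cuff_ceiling = 250)
  expect_true(back$inc_ankle_dp_left)
  expect_true(is.na(back$ankle_dp_left))
  expect_false(back$inc_ankle_pt_left)
})
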
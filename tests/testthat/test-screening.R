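test_that("eligibility covers every branch of the recruitment rule", {
  elig <- function(...) check_eligibility(make_participant("X", ...))
  expect_true(elig(age = 66))                       # over 65 alone
  expect_false(elig(age = 65))                      # strict comparison
  expect_true(elig(age = 55, smoker = TRUE))        # over 50 + smoking
  expect_true(elig(age = 51, diabetes = TRUE))      # over 50 + diabetes
  expect_false(elig(age = 50, diabetes = TRUE))     # strict at 50
  expect_false(elig(age = 45, diabetes = TRUE))
  expect_true(elig(age = 40, leg_pain = TRUE))      # leg pain alone
  expect_false(elig(age = 55))
})

test_that("the targeted selector fires on diabetes, renal disease or age", {
  sel <- function(...) select_targeted_test(make_participant("X", ...))
  expect_identical(sel(age = 80), "TBI")                  # age alone
  expect_identical(sel(age = 60, diabetes = TRUE), "TBI") # diabetes alone
  expect_identical(sel(age = 60, renal = TRUE), "TBI")    # renal alone
  expect_identical(sel(age = 75), "ABI")                  # strict boundary
  expect_identical(sel(age = 76), "TBI")
  expect_identical(sel(age = 60), "ABI")
})

test_that("targeted strategy calls PAD from the TBI in selected patients", {
  # diabetic, toe 50 over brachial 125 on both limbs: TBI 0.40 < 0.70
  co <- make_participant("A", diabetes = TRUE, brachial = c(125, 120),
                         toe = c(50, 50))
  d <- apply_targeted(co)
  expect_identical(d$test_used, "TBI")
  expect_identical(d$call, "PAD")
  expect_equal(d$index_value, 0.40)

  # non-diabetic 70-year-old with normal ABI screens negative on the ABI
  co2 <- make_participant("B", age = 70, brachial = c(120, 118),
                          ankle_left = c(dp = 126, pt = 120),
                          ankle_right = c(dp = 126, pt = 121))
  d2 <- apply_targeted(co2)
  expect_identical(d2$test_used, "ABI")
  expect_identical(d2$call, "no_PAD")

  # diabetic with both toe pressures missing is excluded, with reason
  co3 <- make_participant("C", diabetes = TRUE, toe = c(NA, NA))
  d3 <- apply_targeted(co3)
  expect_true(d3$excluded)
  expect_identical(d3$reason, "missing toe pressure")
  expect_true(is.na(d3$call))
})

test_that("AHA strategy substitutes the TBI only above 1.4 (strict)", {
  # ABI 1.50 -> TBI 0.55 -> PAD
  co <- make_participant("A", brachial = c(100, 100),
                         ankle_left = c(dp = 150, pt = 145),
                         ankle_right = c(dp = 150, pt = 144),
                         toe = c(55, 55))
  d <- apply_aha(co)
  expect_identical(d$test_used, "TBI")
  expect_identical(d$call, "PAD")

  # ABI 0.80 is a direct positive
  co2 <- make_participant("B", brachial = c(125, 120),
                          ankle_left = c(dp = 100, pt = 95),
                          ankle_right = c(dp = 100, pt = 96))
  d2 <- apply_aha(co2)
  expect_identical(d2$test_used, "ABI")
  expect_identical(d2$call, "PAD")

  # ABI exactly 1.40 stays with the ABI ("exceeded" is strict)
  co3 <- make_participant("C", brachial = c(100, 100),
                          ankle_left = c(dp = 140, pt = 135),
                          ankle_right = c(dp = 140, pt = 136),
                          toe = c(55, 55))
  d3 <- apply_aha(co3)
  expect_identical(d3$test_used, "ABI")
  expect_identical(d3$call, "no_PAD")

  # incompressible ankles fall through to the TBI by default
  co4 <- make_participant("D", inc = c("dp_left", "pt_left", "dp_right",
                                       "pt_right"),
                          ankle_left = c(dp = NA, pt = NA),
                          ankle_right = c(dp = NA, pt = NA),
                          toe = c(50, 50))
  d4 <- apply_aha(co4)
  expect_identical(d4$test_used, "TBI")
  expect_identical(d4$call, "PAD")
  # ... and the substitute TBI being unavailable is indeterminate
  co5 <- co4
  co5$toe_left <- co5$toe_right <- NA_real_
  expect_identical(apply_aha(co5)$call, "indeterminate")
  # the fall-through is switchable off
  th <- screening_thresholds(aha_incompressible_to_tbi = FALSE)
  expect_identical(apply_aha(co4, th)$call, "indeterminate")
})

test_that("screen_cohort composes calls and the exclusion log", {
  co <- make_cohort(
    make_participant("pad", diabetes = TRUE, brachial = c(125, 125),
                     toe = c(45, 45)),
    make_participant("normal", age = 70, brachial = c(120, 118),
                     ankle_left = c(dp = 125, pt = 120),
                     ankle_right = c(dp = 125, pt = 121)),
    make_participant("no_toe", diabetes = TRUE, toe = c(NA, NA)))
  tg <- screen_cohort(co, "targeted")
  expect_identical(sum(!tg$decisions$excluded), 2L)
  expect_identical(unname(tg$exclusions["missing toe pressure"]), 1L)
  ah <- screen_cohort(co, "aha")
  expect_identical(sum(!ah$decisions$excluded), 3L)
  expect_identical(length(ah$exclusions), 0L)

  empty <- co[0, ]
  es <- screen_cohort(empty, "targeted")
  expect_identical(nrow(es$decisions), 0L)
  expect_identical(length(es$exclusions), 0L)
})

test_that("records on different-day reference scans are excluded", {
  co <- make_participant("A", same_day = FALSE)
  d <- apply_targeted(co)
  expect_true(d$excluded)
  expect_match(d$reason, "different day")
})

test_that("targeted and AHA agree when the targeted selector picks ABI", {
  set.seed(7)
  for (i in 1:40) {
    ankle <- round(runif(4, 80, 140))
    co <- make_participant("X", age = sample(55:75, 1),
                           brachial = round(runif(2, 110, 150)),
                           ankle_left = c(dp = ankle[1], pt = ankle[2]),
                           ankle_right = c(dp = ankle[3], pt = ankle[4]),
                           toe = c(NA, NA))
    stopifnot(select_targeted_test(co) == "ABI")
    expect_identical(apply_targeted(co)$call, apply_aha(co)$call)
  }
})

test_that("lowering the TBI threshold only moves calls PAD -> no_PAD", {
  gen <- generate_cohort(sim_config(n = 150), seed = 31)
  cuts <- seq(0.85, 0.40, by = -0.05)
  prev_pad <- NULL
  for (cut in cuts) {
    th <- screening_thresholds(tbi_lower = cut)
    d <- apply_targeted(gen$cohort, th)
    pad_ids <- d$id[!is.na(d$call) & d$call == "PAD" & d$test_used == "TBI"]
    if (!is.null(prev_pad)) expect_true(all(pad_ids %in% prev_pad))
    prev_pad <- pad_ids
  }
})

test_that("AHA never substitutes the TBI for a compressible in-range ABI", {
  gen <- generate_cohort(sim_config(n = 200), seed = 13)
  d <- apply_aha(gen$cohort)
  conv <- index_conventions()
  abi <- limbscreen:::aggregate_limbs(compute_abi(gen$cohort, "left", conv),
                                      compute_abi(gen$cohort, "right", conv),
                                      conv)
  in_range <- !is.na(abi$value) & abi$value <= 1.4 & !abi$any_inc
  expect_true(all(d$test_used[in_range & !d$excluded] == "ABI"))
})

test_that("the optional waveform adjunct upgrades calls to PAD", {
  co <- make_participant("A", age = 70, waveform = "monophasic",
                         brachial = c(120, 118),
                         ankle_left = c(dp = 125, pt = 120),
                         ankle_right = c(dp = 125, pt = 121))
  expect_identical(apply_targeted(co)$call, "no_PAD")
  th <- screening_thresholds(waveform_adjunct = "monophasic_positive")
  expect_identical(apply_targeted(co, th)$call, "PAD")
})
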
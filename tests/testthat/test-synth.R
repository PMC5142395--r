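test_that("generation is reproducible and prefix-stable in n", {
  cfg <- sim_config(n = 60)
  g1 <- generate_cohort(cfg, seed = 42)
  g2 <- generate_cohort(cfg, seed = 42)
  expect_identical(g1, g2)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g1$cohort, p1)
  write_cohort(g2$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))

  big <- generate_cohort(sim_config(n = 90), seed = 42)
  expect_identical(big$cohort[1:60, ], g1$cohort)
  expect_false(identical(generate_cohort(cfg, seed = 43), g1))
})

test_that("an empty cohort is a valid degenerate output", {
  g <- generate_cohort(sim_config(n = 0))
  expect_identical(nrow(g$cohort), 0L)
  expect_identical(nrow(g$duplex), 0L)
  expect_identical(nrow(g$labels), 0L)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(pad_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(level_split = c(distal_only = 0.5,
                                          proximal_only = 0.2,
                                          both = 0.2)), "sum to 1")
  expect_error(sim_config(n = -3), "non-negative")
})

test_that("generated cohorts pass their own validation", {
  g <- generate_cohort(sim_config(n = 200), seed = 3)
  f <- validate_cohort(g$cohort)
  expect_true(all(f$severity == "warning"))
  expect_identical(nrow(validate_duplex(g$duplex)), 0L)
  expect_true(all(check_eligibility(g$cohort)))
})

test_that("the reference standard recovers every intended label", {
  g <- generate_cohort(sim_config(n = 500), seed = 29)
  lab <- label_cohort(g$duplex, ids = g$cohort$id)
  expect_identical(lab$pad, g$labels$pad)
  expect_identical(lab$level, g$labels$level)
  expect_identical(lab$any_occlusion, g$labels$any_occlusion)
})

test_that("marginal frequencies converge to the configured rates", {
  n <- 20000
  g <- generate_cohort(sim_config(n = n), seed = 47)
  co <- g$cohort
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$diabetes) - 0.6134), 3 * se(0.6134))
  expect_lt(abs(mean(co$sex == "male") - 0.6302), 3 * se(0.6302))
  inc <- co$inc_ankle_dp_left | co$inc_ankle_pt_left |
    co$inc_ankle_dp_right | co$inc_ankle_pt_right
  expect_lt(abs(mean(inc) - 0.1344), 4 * se(0.1344))
  occ_d <- g$labels$any_occlusion %in% c("distal", "both")
  expect_lt(abs(mean(occ_d) - 0.3361), 4 * se(0.3361))
  expect_true(all(co$age >= 53 & co$age <= 92))
  expect_lt(abs(mean(co$age) - 73.1), 1)
})

test_that("removing calcification raises ABI-based sensitivity", {
  cfg_mac <- sim_config(n = 300)
  cfg_nomac <- sim_config(n = 300,
                          mac_logit = c(intercept = -30, diabetes = 0,
                                        renal = 0, age_per_year = 0))
  sens_of <- function(cfg, seed) {
    g <- generate_cohort(cfg, seed = seed)
    scr <- screen_cohort(g$cohort, "aha")
    pm <- point_metrics(build_contingency(scr$decisions, g$labels)$table)
    pm[["sens"]]
  }
  seeds <- 101:110
  with_mac <- sapply(seeds, function(s) sens_of(cfg_mac, s))
  without <- sapply(seeds, function(s) sens_of(cfg_nomac, s))
  expect_gt(mean(without - with_mac), 0)
})

test_that("a prevalence-free cohort leaves sensitivity undefined", {
  g <- generate_cohort(sim_config(n = 200, pad_prevalence = 0), seed = 5)
  expect_false(any(g$labels$pad))
  scr <- screen_cohort(g$cohort, "targeted")
  pm <- point_metrics(build_contingency(scr$decisions, g$labels)$table)
  expect_true(is.na(pm[["sens"]]))
  expect_gt(pm[["spec"]], 0.6)
})

test_that("the calibration harness summarises both strategies", {
  cr <- calibration_report(sim_config(), n_reps = 20, seed = 8)
  expect_identical(dim(cr$per_rep), c(20L, 7L, 2L))
  expect_true(all(is.finite(cr$mean["sens", ])))
  expect_true(all(cr$lo["spec", ] <= cr$hi["spec", ]))
  out <- capture.output(print(cr))
  expect_true(any(grepl("targeted", out)))
})
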
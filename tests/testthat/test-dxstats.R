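targeted_tab <- contingency_table(31, 19, 10, 57)
aha_tab <- contingency_table(25, 26, 4, 64)

test_that("point metrics reproduce the study tables", {
  pm <- point_metrics(targeted_tab)
  expect_equal(round_half_up(100 * pm[["sens"]]), 62.00)
  expect_equal(round_half_up(100 * pm[["spec"]]), 85.07)
  expect_equal(round_half_up(100 * pm[["ppv"]]), 75.61)
  expect_equal(round_half_up(100 * pm[["npv"]]), 75.00)

  pa <- point_metrics(aha_tab)
  expect_equal(round_half_up(100 * pa[["ppv"]]), 86.21)
  expect_equal(round_half_up(100 * pa[["npv"]]), 71.11)

  degenerate <- contingency_table(0, 0, 0, 10)
  pd <- point_metrics(degenerate)
  expect_true(is.na(pd[["sens"]]))
  expect_equal(pd[["spec"]], 1)

  sym <- point_metrics(contingency_table(50, 50, 50, 50))
  expect_equal(unname(sym[c("sens", "spec", "ppv", "npv", "accuracy")]),
               rep(0.5, 5))
  expect_equal(unname(sym[c("lr_pos", "lr_neg")]), c(1, 1))
})

test_that("Clopper-Pearson intervals match exact beta quantiles", {
  expect_equal(round_half_up(100 * clopper_pearson_ci(64, 68)),
               cbind(low = 85.62, high = 98.37))
  expect_equal(round_half_up(100 * clopper_pearson_ci(31, 50)),
               cbind(low = 47.17, high = 75.35))
  expect_identical(clopper_pearson_ci(0, 10)[, "low"], c(low = 0))
  expect_identical(clopper_pearson_ci(10, 10)[, "high"], c(high = 1))
  expect_error(clopper_pearson_ci(11, 10))
})

test_that("log-method likelihood-ratio intervals match the study", {
  expect_equal(round_half_up(unname(lr_ci(aha_tab, "positive"))),
               c(3.09, 22.45))
  expect_equal(round_half_up(unname(lr_ci(targeted_tab, "positive"))),
               c(2.25, 7.66))
  expect_equal(round_half_up(unname(lr_ci(targeted_tab, "negative"))),
               c(0.31, 0.65))
  expect_warning(z <- lr_ci(contingency_table(5, 0, 3, 7), "negative"),
                 "zero cell")
  expect_true(all(is.na(z)))
})

test_that("likelihood-ratio annotations follow the importance bands", {
  expect_identical(unname(annotate_lr(lr_pos = 8.33)), "important")
  expect_identical(unname(annotate_lr(lr_pos = 4.15)), "may_be_important")
  expect_identical(unname(annotate_lr(lr_neg = 0.45)), "may_be_important")
  expect_identical(unname(annotate_lr(lr_neg = 0.54)), "none")
  expect_identical(unname(annotate_lr(lr_neg = 0.15)), "important")
  expect_identical(unname(annotate_lr(lr_pos = 1.5)), "none")
})

test_that("build_contingency drops and counts unusable decisions", {
  dec <- data.frame(id = c("a", "b", "c", "d", "e"),
                    strategy = "targeted", test_used = "TBI",
                    index_value = c(0.5, 0.9, 0.5, NA, 0.9),
                    index_state = c("ok", "ok", "ok", "unavailable", "ok"),
                    call = c("PAD", "no_PAD", "PAD", NA, "no_PAD"),
                    excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                    reason = c("", "", "", "missing toe pressure", ""),
                    stringsAsFactors = FALSE)
  lab <- data.frame(id = letters[1:5],
                    pad = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                    level = "distal_only", any_occlusion = "none",
                    stringsAsFactors = FALSE)
  bc <- build_contingency(dec, lab)
  expect_identical(c(bc$table$tp, bc$table$fn, bc$table$fp, bc$table$tn),
                   c(1L, 1L, 1L, 1L))
  expect_identical(bc$n_excluded, 1L)

  expect_error(build_contingency(dec, lab[1:3, ]), "no reference label")

  all_out <- dec
  all_out$excluded <- TRUE
  all_out$call <- NA
  expect_warning(bc0 <- build_contingency(all_out, lab), "no analyzable")
  expect_identical(bc0$table$tp + bc0$table$fn + bc0$table$fp +
                     bc0$table$tn, 0L)
})

test_that("PPV/NPV are Bayes-consistent with prevalence and LRs", {
  set.seed(101)
  for (i in 1:200) {
    t <- rand_table(150)
    pm <- point_metrics(t)
    if (anyNA(pm[c("sens", "spec", "ppv", "npv")])) next
    prev <- (t$tp + t$fn) / (t$tp + t$fn + t$fp + t$tn)
    expect_equal(pm[["ppv"]],
                 pm[["sens"]] * prev /
                   (pm[["sens"]] * prev + (1 - pm[["spec"]]) * (1 - prev)))
    expect_equal(pm[["npv"]],
                 pm[["spec"]] * (1 - prev) /
                   (pm[["spec"]] * (1 - prev) + (1 - pm[["sens"]]) * prev))
    if (!anyNA(pm[c("lr_pos", "lr_neg")])) {
      expect_equal(pm[["lr_pos"]] * (1 - pm[["spec"]]), pm[["sens"]])
      expect_equal(pm[["lr_neg"]] * pm[["spec"]], 1 - pm[["sens"]])
    }
  }
})

test_that("Clopper-Pearson contains k/n and narrows with n", {
  for (k in c(0, 3, 7, 10)) {
    ci <- clopper_pearson_ci(k, 10)
    expect_lte(ci[, "low"], k / 10)
    expect_gte(ci[, "high"], k / 10)
  }
  widths <- sapply(c(10, 20, 50, 100, 500), function(n) {
    ci <- clopper_pearson_ci(0.6 * n, n)
    ci[, "high"] - ci[, "low"]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the full report composes estimates, CIs and annotations", {
  rep <- dx_accuracy(targeted_tab, strategy = "targeted")
  est <- coef(rep)
  expect_equal(round_half_up(est[["sens"]]), 62.00)
  expect_equal(round_half_up(est[["lr_pos"]]), 4.15)
  ci <- confint(rep, "spec")
  expect_equal(round_half_up(unname(ci[1, ])), c(74.26, 92.60))
  ann <- rep$metrics$annotation
  names(ann) <- rep$metrics$metric
  expect_identical(unname(ann["lr_pos"]), "may_be_important")
  out <- capture.output(print(rep))
  expect_true(any(grepl("Sensitivity", out)))
  expect_true(any(grepl("4.15~", out, fixed = TRUE)))
})

test_that("accuracy can use the recruited-N denominator and truncation", {
  t_over <- contingency_table(31, 19, 10, 57, denominator_override = 119)
  pm <- point_metrics(t_over)
  expect_equal(pm[["accuracy"]], 88 / 119)
  rep <- dx_accuracy(t_over, truncate_accuracy = TRUE)
  out <- capture.output(print(rep))
  expect_true(any(grepl("73.94", out)))   # truncated, not rounded (73.95)
  a_rep <- dx_accuracy(aha_tab, truncate_accuracy = TRUE)
  expect_true(any(grepl("74.78", capture.output(print(a_rep)))))
})
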
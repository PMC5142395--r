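# Diagnostic accuracy statistics.
#
# Everything a screening-accuracy table reports: sensitivity, specificity,
# predictive values, diagnostic accuracy, likelihood ratios, exact binomial
# (Clopper-Pearson) confidence intervals for the proportions and the Simel
# log-method intervals for the likelihood ratios, plus the conventional
# "importance" annotation of likelihood ratios.

#' Construct a 2x2 contingency table
#'
#' @param tp,fn,fp,tn non-negative integer cell counts (test positive /
#'   negative against reference disease present / absent).
#' @param denominator_override optional denominator for the diagnostic
#'   accuracy row only; lets accuracy be quoted against the recruited N
#'   when exclusions shrank the analyzed set, as some reports do.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fn, fp, tn, denominator_override = NULL) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (!is.null(denominator_override))
    stopifnot(denominator_override >= sum(cells))
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 denominator_override = denominator_override),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("screen+", "screen-"),
                              c("PAD", "no PAD")))
  print(m)
  invisible(x)
}

#' Build a contingency table from decisions and reference labels
#'
#' Joins screening decisions to reference labels on participant id;
#' excluded and indeterminate decisions are dropped from the table and
#' counted separately.  An id present in the decisions but absent from the
#' labels is fatal.
#'
#' @param decisions decisions data.frame from [screen_cohort()].
#' @param labels reference labels from [label_cohort()].
#' @param denominator_override passed to [contingency_table()].
#' @return list with `table` (a [contingency_table()]), `n_excluded`,
#'   `n_indeterminate`.
#' @export
build_contingency <- function(decisions, labels,
                              denominator_override = NULL) {
  miss <- setdiff(decisions$id, labels$id)
  if (length(miss) > 0)
    stop("no reference label for id(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  pad <- labels$pad[match(decisions$id, labels$id)]
  usable <- !decisions$excluded & decisions$call %in% c("PAD", "no_PAD")
  if (!any(usable))
    warning("no analyzable decisions; contingency table is all zero")
  pos <- usable & decisions$call == "PAD"
  neg <- usable & decisions$call == "no_PAD"
  list(table = contingency_table(tp = sum(pos & pad), fn = sum(neg & pad),
                                 fp = sum(pos & !pad), tn = sum(neg & !pad),
                                 denominator_override = denominator_override),
       n_excluded = sum(decisions$excluded),
       n_indeterminate = sum(!decisions$excluded &
                               decisions$call == "indeterminate",
                             na.rm = TRUE))
}

#' Point estimates from a contingency table
#'
#' Proportions are returned on the 0-1 scale, likelihood ratios as ratios.
#' A metric whose denominator is zero is `NA` (undefined), never an error.
#'
#' @param t a [contingency_table()].
#' @return named numeric vector: `sens, spec, ppv, npv, lr_pos, lr_neg,
#'   accuracy`.
#' @export
point_metrics <- function(t) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(t$tp, t$tp + t$fn)
  spec <- rat(t$tn, t$tn + t$fp)
  acc_den <- t$denominator_override %||% (t$tp + t$fn + t$fp + t$tn)
  c(sens = sens, spec = spec,
    ppv = rat(t$tp, t$tp + t$fp), npv = rat(t$tn, t$tn + t$fn),
    lr_pos = if (!is.na(sens) && !is.na(spec) && spec < 1)
      sens / (1 - spec) else NA_real_,
    lr_neg = if (!is.na(sens) && !is.na(spec) && spec > 0)
      (1 - sens) / spec else NA_real_,
    accuracy = rat(t$tp + t$tn, acc_den))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from beta quantiles: lower bound the alpha/2 quantile
#' of Beta(k, n-k+1) (0 when k = 0), upper the 1-alpha/2 quantile of
#' Beta(k+1, n-k) (1 when k = n).  Vectorised over `k` and `n`.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return matrix with columns `low`, `high` on the 0-1 scale.
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n), level > 0, level < 1)
  a <- (1 - level) / 2
  low <- ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
  cbind(low = low, high = high)
}

#' Log-method confidence interval for a likelihood ratio
#'
#' The Simel log method: the variance of the log likelihood ratio is
#' `1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)` for LR+ and
#' `1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn)` for LR-, and the interval is
#' `exp(ln LR +/- z sqrt(var))`.  Any zero cell entering the chosen LR
#' makes the interval undefined (`NA` with a warning).
#'
#' @param t a [contingency_table()].
#' @param which `"positive"` or `"negative"`.
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(low, high)`.
#' @export
lr_ci <- function(t, which = c("positive", "negative"), level = 0.95) {
  which <- match.arg(which)
  if (min(t$tp, t$fn, t$fp, t$tn) == 0) {
    warning("zero cell: ", which, " likelihood ratio CI undefined")
    return(c(low = NA_real_, high = NA_real_))
  }
  n1 <- t$tp + t$fn
  n0 <- t$fp + t$tn
  if (which == "positive") {
    lr <- (t$tp / n1) / (t$fp / n0)
    v <- 1 / t$tp - 1 / n1 + 1 / t$fp - 1 / n0
  } else {
    lr <- (t$fn / n1) / (t$tn / n0)
    v <- 1 / t$fn - 1 / n1 + 1 / t$tn - 1 / n0
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- exp(log(lr) + c(-1, 1) * z * sqrt(v))
  c(low = ci[1], high = ci[2])
}

#' Likelihood-ratio importance thresholds
#'
#' Conventional interpretation bands: a positive likelihood ratio of 5 or
#' more (or negative of 0.2 or less) is an important shift in disease
#' odds; 2 to 5 (or 0.2 to 0.5) may be important; anything weaker is
#' neither.
#'
#' @param important_pos,may_pos LR+ cut-offs (defaults 5 and 2).
#' @param important_neg,may_neg LR- cut-offs (defaults 0.2 and 0.5).
#' @return list of thresholds.
#' @export
lr_annotation_thresholds <- function(important_pos = 5, may_pos = 2,
                                     important_neg = 0.2, may_neg = 0.5) {
  list(important_pos = important_pos, may_pos = may_pos,
       important_neg = important_neg, may_neg = may_neg)
}

#' Annotate likelihood ratios by importance
#'
#' @param lr_pos,lr_neg likelihood ratio values (either may be NULL).
#' @param thresholds from [lr_annotation_thresholds()].
#' @return named character vector over the supplied LRs with values
#'   `"important"`, `"may_be_important"` or `"none"`.
#' @export
annotate_lr <- function(lr_pos = NULL, lr_neg = NULL,
                        thresholds = lr_annotation_thresholds()) {
  out <- character()
  if (!is.null(lr_pos))
    out["lr_pos"] <- if (is.na(lr_pos)) "none"
      else if (lr_pos >= thresholds$important_pos) "important"
      else if (lr_pos >= thresholds$may_pos) "may_be_important"
      else "none"
  if (!is.null(lr_neg))
    out["lr_neg"] <- if (is.na(lr_neg)) "none"
      else if (lr_neg <= thresholds$important_neg) "important"
      else if (lr_neg <= thresholds$may_neg) "may_be_important"
      else "none"
  out
}

#' Full diagnostic-accuracy report for one strategy
#'
#' The package's central estimator: composes the point metrics,
#' Clopper-Pearson intervals for the proportion metrics, log-method
#' intervals for the likelihood ratios and the importance annotations into
#' one classed object with `print`, `summary`, `coef` and `confint`
#' methods.  Proportion metrics are reported in percent, likelihood ratios
#' as ratios; undefined metrics propagate as `NA` and print as blanks.
#'
#' @param t a [contingency_table()].
#' @param strategy label for the strategy the table came from.
#' @param conf_level confidence level (default 0.95).
#' @param truncate_accuracy when TRUE the printed diagnostic-accuracy cell is
#'   truncated to two decimals instead of rounded (a compatibility mode for
#'   published tables that truncate that row).
#' @param lr_thresholds from [lr_annotation_thresholds()].
#' @param n_excluded,n_indeterminate optional counts carried into the
#'   report for provenance.
#' @return object of class `dx_accuracy`: a metrics data.frame
#'   (`metric,estimate,ci_low,ci_high,ci_method,annotation`) plus the
#'   table and options.
#' @export
dx_accuracy <- function(t, strategy = "screening", conf_level = 0.95,
                        truncate_accuracy = FALSE,
                        lr_thresholds = lr_annotation_thresholds(),
                        n_excluded = 0, n_indeterminate = 0) {
  stopifnot(inherits(t, "contingency_table"))
  pm <- point_metrics(t)
  cis <- matrix(NA_real_, 7, 2,
                dimnames = list(names(pm), c("low", "high")))
  prop_kn <- list(sens = c(t$tp, t$tp + t$fn),
                  spec = c(t$tn, t$tn + t$fp),
                  ppv = c(t$tp, t$tp + t$fp),
                  npv = c(t$tn, t$tn + t$fn),
                  accuracy = c(t$tp + t$tn,
                               t$denominator_override %||%
                                 (t$tp + t$fn + t$fp + t$tn)))
  for (m in names(prop_kn)) {
    kn <- prop_kn[[m]]
    if (kn[2] > 0 && kn[1] <= kn[2])
      cis[m, ] <- clopper_pearson_ci(kn[1], kn[2], conf_level)
  }
  zero_cell <- min(t$tp, t$fn, t$fp, t$tn) == 0
  if (!zero_cell) {
    cis["lr_pos", ] <- lr_ci(t, "positive", conf_level)
    cis["lr_neg", ] <- lr_ci(t, "negative", conf_level)
  }
  ann <- rep("none", 7)
  names(ann) <- names(pm)
  lr_ann <- annotate_lr(pm[["lr_pos"]], pm[["lr_neg"]], lr_thresholds)
  ann[names(lr_ann)] <- lr_ann
  is_prop <- names(pm) %in% names(prop_kn)
  metrics <- data.frame(
    metric = names(pm),
    estimate = ifelse(is_prop, 100 * pm, pm),
    ci_low = ifelse(is_prop, 100 * cis[, "low"], cis[, "low"]),
    ci_high = ifelse(is_prop, 100 * cis[, "high"], cis[, "high"]),
    ci_method = ifelse(is_prop, "clopper_pearson", "lr_log"),
    annotation = ann,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(strategy = strategy, metrics = metrics, table = t,
                 n_analyzed = t$tp + t$fn + t$fp + t$tn,
                 n_excluded = n_excluded,
                 n_indeterminate = n_indeterminate,
                 conf_level = conf_level, truncate_accuracy = truncate_accuracy),
            class = "dx_accuracy")
}

metric_labels <- c(sens = "Sensitivity", spec = "Specificity",
                   ppv = "Positive predictive value",
                   npv = "Negative predictive value",
                   lr_pos = "Positive likelihood ratio",
                   lr_neg = "Negative likelihood ratio",
                   accuracy = "Diagnostic accuracy")

format_metric_rows <- function(x) {
  m <- x$metrics
  trunc_row <- x$truncate_accuracy & m$metric == "accuracy"
  est <- fmt2(m$estimate)
  est[trunc_row] <- fmt2(m$estimate[trunc_row], truncate = TRUE)
  mark <- c(important = "*", may_be_important = "~", none = "")[m$annotation]
  ci <- ifelse(is.na(m$ci_low), "",
               paste(fmt2(m$ci_low), "to", fmt2(m$ci_high)))
  ci[m$metric == "accuracy"] <- ""
  data.frame(metric = metric_labels[m$metric],
             estimate = paste0(est, mark), ci = ci,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.dx_accuracy <- function(x, ...) {
  cat("Diagnostic accuracy:", x$strategy, "\n")
  cat(sprintf("analyzed n = %d (excluded %d, indeterminate %d); %d%% CI\n",
              x$n_analyzed, x$n_excluded, x$n_indeterminate,
              round(100 * x$conf_level)))
  rows <- format_metric_rows(x)
  out <- format(rbind(c("", "%/LR", "CI"), as.matrix(rows)),
                justify = "left")
  cat(apply(out, 1, paste, collapse = "  "), sep = "\n")
  cat("(* important likelihood ratio, ~ may be important)\n")
  invisible(x)
}

#' @export
summary.dx_accuracy <- function(object, ...) {
  print(object)
  cat("\nContingency table:\n")
  print(object$table)
  invisible(object$metrics)
}

#' @export
coef.dx_accuracy <- function(object, ...) {
  stats::setNames(object$metrics$estimate, object$metrics$metric)
}

#' @export
confint.dx_accuracy <- function(object, parm, level, ...) {
  m <- object$metrics
  out <- as.matrix(m[, c("ci_low", "ci_high")])
  rownames(out) <- m$metric
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.dx_accuracy <- function(x, ...) {
  m <- x$metrics[x$metrics$metric %in% c("sens", "spec", "ppv", "npv"), ]
  graphics::plot(seq_len(nrow(m)), m$estimate, ylim = c(0, 100),
                 xaxt = "n", xlab = "", ylab = "%", pch = 19,
                 main = paste("Diagnostic accuracy:", x$strategy), ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = m$metric)
  graphics::segments(seq_len(nrow(m)), m$ci_low,
                     seq_len(nrow(m)), m$ci_high)
  invisible(x)
}
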
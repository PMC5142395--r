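# Recovering 2x2 contingency tables from printed summary statistics.
#
# Published accuracy tables usually print sensitivity and specificity to
# two decimals but not the underlying cell counts.  Because both are
# ratios of integers bounded by the cohort size, an exhaustive search over
# tp and tn recovers the candidate tables, usually uniquely; the remaining
# printed statistics (predictive values, likelihood ratios) then
# cross-validate the reconstruction.

#' Constraints for contingency-table reconstruction
#'
#' @param n_total analyzed participants.
#' @param n_diseased reference-positive participants (<= `n_total`).
#' @param sens,spec printed sensitivity and specificity, percent to two
#'   decimals.
#' @param ppv,npv,lr_pos,lr_neg,accuracy optional printed statistics used
#'   to rank candidate tables (percent for the proportions, ratio for the
#'   LRs).
#' @param tol match tolerance on the proportion scale (default 0.005: a
#'   candidate's sensitivity may differ from printed/100 by at most this).
#' @return list of class `summary_constraints`.
#' @export
summary_constraints <- function(n_total, n_diseased, sens, spec,
                                ppv = NULL, npv = NULL,
                                lr_pos = NULL, lr_neg = NULL,
                                accuracy = NULL, tol = 0.005) {
  stopifnot(n_diseased <= n_total, n_diseased >= 0, n_total > 0,
            sens >= 0, sens <= 100, spec >= 0, spec <= 100, tol > 0)
  structure(list(n_total = n_total, n_diseased = n_diseased,
                 sens = sens, spec = spec, ppv = ppv, npv = npv,
                 lr_pos = lr_pos, lr_neg = lr_neg, accuracy = accuracy,
                 tol = tol),
            class = "summary_constraints")
}

#' Recover candidate contingency tables from printed summaries
#'
#' Enumerates every `tp` in `[0, n_diseased]` and `tn` in
#' `[0, n_total - n_diseased]`, keeps the tables whose sensitivity and
#' specificity fall within `tol` of the printed values (on the proportion
#' scale), and ranks surviving candidates by squared disagreement with any
#' optional cross-validation statistics.  Deterministic; an empty
#' candidate set is fatal with a diagnostic.
#'
#' @param c a [summary_constraints()] object.
#' @return data.frame of candidates `tp,fn,fp,tn,sens,spec,score`, best
#'   first; attribute `unique` is TRUE when exactly one candidate
#'   survives.
#' @export
recover_counts <- function(c) {
  stopifnot(inherits(c, "summary_constraints"))
  nd <- c$n_diseased
  nh <- c$n_total - c$n_diseased
  tp <- 0:nd
  tn <- 0:nh
  ok_tp <- if (nd > 0) tp[abs(tp / nd - c$sens / 100) <= c$tol] else 0L
  ok_tn <- if (nh > 0) tn[abs(tn / nh - c$spec / 100) <= c$tol] else 0L
  if (length(ok_tp) == 0 || length(ok_tn) == 0)
    stop(sprintf(paste0("no contingency table with n=%d, diseased=%d ",
                        "matches sens=%.2f%%, spec=%.2f%% at tol %.4f"),
                 c$n_total, nd, c$sens, c$spec, c$tol))
  grid <- expand.grid(tp = as.integer(ok_tp), tn = as.integer(ok_tn))
  grid$fn <- as.integer(nd - grid$tp)
  grid$fp <- as.integer(nh - grid$tn)
  grid$sens <- if (nd > 0) grid$tp / nd else NA_real_
  grid$spec <- if (nh > 0) grid$tn / nh else NA_real_
  score <- function(tp, fn, fp, tn) {
    s <- 0
    sq <- function(printed, actual, scale = 1)
      if (!is.null(printed) && !is.na(actual))
        ((printed / scale - actual))^2 else 0
    pm <- point_metrics(contingency_table(tp, fn, fp, tn))
    s + sq(c$ppv, pm[["ppv"]], 100) + sq(c$npv, pm[["npv"]], 100) +
      sq(c$lr_pos, pm[["lr_pos"]]) + sq(c$lr_neg, pm[["lr_neg"]]) +
      sq(c$accuracy, pm[["accuracy"]], 100)
  }
  grid$score <- mapply(score, grid$tp, grid$fn, grid$fp, grid$tn)
  grid <- grid[order(grid$score, grid$tp, grid$tn), ]
  out <- grid[, c("tp", "fn", "fp", "tn", "sens", "spec", "score")]
  rownames(out) <- NULL
  attr(out, "unique") <- nrow(out) == 1
  out
}

#' Reconstruct the analyzed-set sizes behind a screening arm
#'
#' When exclusions shrink an analyzed set, the printed confidence-interval
#' denominators pin down how many excluded participants were
#' reference-positive: with `n_recruited` participants of whom
#' `n_diseased_recruited` are positive and `n_excluded` excluded, the
#' analyzed diseased count must equal the sensitivity-CI denominator.
#' This helper enumerates the feasible splits.
#'
#' @param n_recruited,n_diseased_recruited recruited totals.
#' @param n_excluded number excluded from the arm.
#' @return data.frame of feasible `(excluded_diseased, n_analyzed,
#'   n_diseased_analyzed)` splits.
#' @export
exclusion_splits <- function(n_recruited, n_diseased_recruited,
                             n_excluded) {
  ed <- 0:min(n_excluded, n_diseased_recruited)
  data.frame(excluded_diseased = as.integer(ed),
             n_analyzed = as.integer(n_recruited - n_excluded),
             n_diseased_analyzed = as.integer(n_diseased_recruited - ed))
}
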
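# Synthetic cohort generator.
#
# Emulates the marginal structure of an at-risk podiatry screening
# population (n 119, ~63% male, age 53-92 centred at 73, diabetes ~61%,
# PAD prevalence ~43% split distal-only/proximal-only/both 37:7:7,
# incompressible ankle pressures ~13%, occlusions overwhelmingly distal)
# together with the haemodynamic mechanism that makes ankle-pressure
# indices lose sensitivity: medial arterial calcification (MAC), driven by
# diabetes, renal disease and age, multiplicatively inflates ankle
# pressures - sometimes beyond the cuff ceiling (incompressible) - while
# digital arteries are spared, so toe pressures stay informative.  Distal
# disease depresses ankle pressure less than proximal disease, the second
# mechanism blunting ABI sensitivity.
#
# All haemodynamic distribution parameters are calibration values chosen
# by the package (no real pressure data underlie them); see the methods
# vignette for how they were fixed.
#
# Randomness: one uniform stream per run, consumed in a fixed block of
# N_VARIATES draws per participant, so enlarging the cohort never
# reshuffles earlier participants; every distribution is sampled by
# inverse CDF from that block.

N_VARIATES <- 36

#' Simulation configuration
#'
#' Defaults reproduce the study-population margins above.  Renal disease,
#' smoking and exertional leg-pain prevalences are not part of those
#' margins and carry plausible placeholder defaults; every haemodynamic
#' parameter is a package calibration value, not an observed quantity.
#'
#' @param n cohort size (default 119).
#' @param male_frac fraction male (default 0.6302).
#' @param age_mean,age_sd,age_range truncated-normal age model, years
#'   (defaults 73.1, 7.2, 53-92).
#' @param diabetes_frac fraction with diabetes (default 0.6134).
#' @param renal_frac fraction with renal disease (default 0.08,
#'   placeholder).
#' @param smoker_frac fraction currently smoking (default 0.15,
#'   placeholder).
#' @param leg_pain_frac fraction with exertional leg pain (default 0.25,
#'   placeholder; forced TRUE where needed so every participant meets the
#'   screening eligibility rule).
#' @param pad_prevalence fraction with PAD (default 0.4285).
#' @param level_split distribution of lesion level among PAD cases,
#'   `c(distal_only, proximal_only, both)` (default 37:7:7 / 51).
#' @param bilateral_frac fraction of PAD cases with bilateral disease
#'   (default 0.30, placeholder).
#' @param p_occl_distal probability that a limb territory with distal
#'   disease harbours an occlusion (default 40/44, so distal occlusions
#'   track their population share).
#' @param p_occl_proximal same for proximal territories (default 1/14).
#' @param missing_toe_frac fraction with no measurable toe pressure
#'   (default 2/119, the analyzable-set mechanism).
#' @param cuff_ceiling mmHg above which an ankle pressure is recorded as
#'   incompressible (default 250).
#' @param brachial_mean,brachial_sd,brachial_range truncated-normal
#'   brachial systolic model, mmHg.
#' @param ankle_ratio,toe_ratio per-level `c(mean, sd)` of the true
#'   perfusion ratios (named lists over none/proximal/distal/both).
#' @param mac_logit logistic model of MAC probability:
#'   `c(intercept, diabetes, renal, age_per_year)`, age centred at 70.
#' @param mac_inflation `c(meanlog, sdlog)` of the log-normal ankle
#'   inflation factor under MAC (toe pressures are never inflated).
#' @param meas_noise_sd,toe_noise_sd measurement noise, mmHg.
#' @param seed default random seed for [generate_cohort()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 119,
                       male_frac = 0.6302,
                       age_mean = 73.1, age_sd = 7.2,
                       age_range = c(53, 92),
                       diabetes_frac = 0.6134,
                       renal_frac = 0.08,
                       smoker_frac = 0.15,
                       leg_pain_frac = 0.25,
                       pad_prevalence = 0.4285,
                       level_split = c(distal_only = 37 / 51,
                                       proximal_only = 7 / 51,
                                       both = 7 / 51),
                       bilateral_frac = 0.30,
                       p_occl_distal = 40 / 44,
                       p_occl_proximal = 1 / 14,
                       missing_toe_frac = 2 / 119,
                       cuff_ceiling = 250,
                       brachial_mean = 140, brachial_sd = 15,
                       brachial_range = c(100, 220),
                       ankle_ratio = list(none = c(1.08, 0.08),
                                          proximal = c(0.65, 0.12),
                                          distal = c(0.95, 0.15),
                                          both = c(0.60, 0.12)),
                       toe_ratio = list(none = c(0.88, 0.11),
                                        proximal = c(0.62, 0.12),
                                        distal = c(0.70, 0.15),
                                        both = c(0.56, 0.12)),
                       mac_logit = c(intercept = -1.85, diabetes = 1.8,
                                     renal = 1.2, age_per_year = 0.04),
                       mac_inflation = c(meanlog = log(1.45), sdlog = 0.25),
                       meas_noise_sd = 6, toe_noise_sd = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c("male_frac", "diabetes_frac", "renal_frac", "smoker_frac",
             "leg_pain_frac", "pad_prevalence", "bilateral_frac",
             "p_occl_distal", "p_occl_proximal", "missing_toe_frac")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must lie in [0, 1]")
  if (abs(sum(cfg$level_split) - 1) > 1e-8)
    stop("sim_config: level_split must sum to 1")
  if (cfg$n < 0 || cfg$n != round(cfg$n))
    stop("sim_config: n must be a non-negative integer")
  for (block in c("ankle_ratio", "toe_ratio"))
    stopifnot(identical(names(cfg[[block]]),
                        c("none", "proximal", "distal", "both")))
  invisible(cfg)
}

# inverse-CDF truncated normal
qtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

by_level <- function(params, level, which) {
  vapply(params, `[`, numeric(1), which)[level]
}

PROX_SEGMENTS <- c("superficial_femoral", "common_iliac", "popliteal",
                   "common_femoral")
DIST_SEGMENTS <- c("posterior_tibial", "anterior_tibial", "peroneal")

waveform_from_ratio <- function(ratio, jitter) {
  r <- ratio + 0.05 * jitter
  ifelse(r >= 0.9, "triphasic",
         ifelse(r >= 0.6, "biphasic",
                ifelse(r >= 0.35, "monophasic", "absent")))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort, its duplex findings and the generator's intended
#' reference labels.  Deterministic given `seed`; the per-participant
#' random-block design means the first `k` participants of an `n`-cohort
#' and a larger cohort with the same seed are identical.  Duplex rows are
#' constructed so that the reference standard recovers the intended label
#' exactly: every affected territory carries at least one segment above
#' 50% stenosis and unaffected territories stay at or below 50%.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed (default `config$seed`).
#' @return list with `cohort` (participant data.frame in the cohort
#'   schema), `duplex` (findings data.frame) and `labels` (intended
#'   `id,pad,level,any_occlusion`).
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  n <- config$n
  empty <- function() {
    list(cohort = as_cohort(utils::read.csv(
           text = paste(COHORT_COLUMNS, collapse = ","),
           colClasses = "character")),
         duplex = data.frame(id = character(), side = character(),
                             artery = character(),
                             stenosis_percent = numeric(),
                             occluded = logical(),
                             stringsAsFactors = FALSE),
         labels = data.frame(id = character(), pad = logical(),
                             level = character(),
                             any_occlusion = character(),
                             stringsAsFactors = FALSE))
  }
  if (n == 0) return(empty())

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  u <- matrix(stats::runif(N_VARIATES * n), nrow = N_VARIATES)

  id <- sprintf("S%04d", seq_len(n))
  male <- u[1, ] < config$male_frac
  age <- as.integer(round(qtruncnorm(u[2, ], config$age_mean, config$age_sd,
                                     config$age_range[1],
                                     config$age_range[2])))
  diabetes <- u[3, ] < config$diabetes_frac
  renal <- u[4, ] < config$renal_frac
  smoker <- u[5, ] < config$smoker_frac
  leg_pain <- u[6, ] < config$leg_pain_frac
  # everyone recruited met the screening eligibility rule
  ineligible <- !(age > 65 | (age > 50 & (diabetes | smoker)) | leg_pain)
  leg_pain[ineligible] <- TRUE

  # disease level: none / distal_only / proximal_only / both
  cuts <- config$pad_prevalence * cumsum(config$level_split)
  level <- ifelse(u[7, ] < cuts[1], "distal_only",
                  ifelse(u[7, ] < cuts[2], "proximal_only",
                         ifelse(u[7, ] < cuts[3], "both", "none")))
  pad <- level != "none"
  bilateral <- pad & (u[8, ] < config$bilateral_frac)
  primary_right <- u[8, ] >= (1 + config$bilateral_frac) / 2
  left_affected <- pad & (bilateral | !primary_right)
  right_affected <- pad & (bilateral | primary_right)

  has_distal <- level %in% c("distal_only", "both")
  has_proximal <- level %in% c("proximal_only", "both")
  occl_distal <- has_distal & (u[9, ] < config$p_occl_distal)
  occl_proximal <- has_proximal & (u[10, ] < config$p_occl_proximal)

  # haemodynamics
  brachial_true <- qtruncnorm(u[11, ], config$brachial_mean,
                              config$brachial_sd,
                              config$brachial_range[1],
                              config$brachial_range[2])
  mnoise <- config$meas_noise_sd
  brachial_l <- round(pmax(60, brachial_true + mnoise * stats::qnorm(u[12, ])))
  brachial_r <- round(pmax(60, brachial_true + mnoise * stats::qnorm(u[13, ])))

  # map the participant-level lesion category onto the haemodynamic
  # profile keys of a diseased limb
  hemo_key <- c(none = "none", distal_only = "distal",
                proximal_only = "proximal", both = "both")
  limb_level <- function(affected)
    ifelse(affected, hemo_key[level], "none")
  ratio_limb <- function(params, affected, z_shared, z_limb) {
    lev <- limb_level(affected)
    m <- by_level(params, lev, 1)
    s <- by_level(params, lev, 2)
    pmin(pmax(m + s * (sqrt(0.5) * z_shared + sqrt(0.5) * z_limb),
              0.05), 2.5)
  }
  z <- function(row) stats::qnorm(u[row, ])
  ankle_ratio_l <- ratio_limb(config$ankle_ratio, left_affected,
                              z(16), z(17))
  ankle_ratio_r <- ratio_limb(config$ankle_ratio, right_affected,
                              z(16), z(18))
  toe_ratio_l <- ratio_limb(config$toe_ratio, left_affected, z(23), z(24))
  toe_ratio_r <- ratio_limb(config$toe_ratio, right_affected, z(23), z(25))

  # medial arterial calcification: inflates ankle (not toe) pressures
  mac_p <- stats::plogis(config$mac_logit[["intercept"]] +
                           config$mac_logit[["diabetes"]] * diabetes +
                           config$mac_logit[["renal"]] * renal +
                           config$mac_logit[["age_per_year"]] * (age - 70))
  mac <- u[14, ] < mac_p
  mac_factor <- ifelse(mac,
                       exp(config$mac_inflation[["meanlog"]] +
                             config$mac_inflation[["sdlog"]] *
                             stats::qnorm(u[15, ])),
                       1)

  ankle_pressure <- function(ratio, noise_row)
    round(pmax(20, ratio * brachial_true * mac_factor +
                 mnoise * stats::qnorm(u[noise_row, ])))
  dp_l <- ankle_pressure(ankle_ratio_l, 19)
  pt_l <- ankle_pressure(ankle_ratio_l, 20)
  dp_r <- ankle_pressure(ankle_ratio_r, 21)
  pt_r <- ankle_pressure(ankle_ratio_r, 22)

  toe_missing <- u[28, ] < config$missing_toe_frac
  toe_pressure <- function(ratio, noise_row)
    ifelse(toe_missing, NA_real_,
           round(pmax(5, ratio * brachial_true +
                        config$toe_noise_sd * stats::qnorm(u[noise_row, ]))))
  toe_l <- toe_pressure(toe_ratio_l, 26)
  toe_r <- toe_pressure(toe_ratio_r, 27)

  wf_l <- waveform_from_ratio(ankle_ratio_l, z(35))
  wf_r <- waveform_from_ratio(ankle_ratio_r, z(36))

  cohort <- data.frame(id = id, age = age,
                       sex = ifelse(male, "male", "female"),
                       diabetes = diabetes, renal_disease = renal,
                       current_smoker = smoker,
                       exertional_leg_pain = leg_pain,
                       brachial_left = brachial_l,
                       brachial_right = brachial_r,
                       ankle_dp_left = dp_l, ankle_pt_left = pt_l,
                       ankle_dp_right = dp_r, ankle_pt_right = pt_r,
                       stringsAsFactors = FALSE)
  for (col in ANKLE_COLUMNS) {
    inc <- cohort[[col]] > config$cuff_ceiling
    cohort[[paste0("inc_", col)]] <- inc
    cohort[[col]][inc] <- NA_real_
  }
  cohort$toe_left <- toe_l
  cohort$toe_right <- toe_r
  cohort$waveform_dp_left <- wf_l
  cohort$waveform_pt_left <- wf_l
  cohort$waveform_dp_right <- wf_r
  cohort$waveform_pt_right <- wf_r
  cohort$duplex_same_day <- TRUE
  cohort <- cohort[c("id", "age", "sex", "diabetes", "renal_disease",
                     "current_smoker", "exertional_leg_pain",
                     "brachial_left", "brachial_right",
                     ANKLE_COLUMNS, paste0("inc_", ANKLE_COLUMNS),
                     "toe_left", "toe_right",
                     "waveform_dp_left", "waveform_pt_left",
                     "waveform_dp_right", "waveform_pt_right",
                     "duplex_same_day")]

  # duplex rows: one proximal and one distal segment per side
  prox_seg <- PROX_SEGMENTS[1 + floor(u[33, ] * length(PROX_SEGMENTS))]
  dist_seg <- DIST_SEGMENTS[1 + floor(u[34, ] * length(DIST_SEGMENTS))]
  primary_side <- ifelse(primary_right, "right", "left")
  territory <- function(side, seg_level, seg, sten_row) {
    affected_side <- if (side == "left") left_affected else right_affected
    involved <- affected_side &
      (if (seg_level == "distal") has_distal else has_proximal)
    occl_flag <- (if (seg_level == "distal") occl_distal else occl_proximal) &
      involved & primary_side == side
    sten <- ifelse(involved, 55 + 40 * u[sten_row, ], 45 * u[sten_row, ])
    sten <- ifelse(occl_flag, 100, round(sten))
    data.frame(id = id, side = side, artery = seg,
               stenosis_percent = sten, occluded = occl_flag,
               stringsAsFactors = FALSE)
  }
  duplex <- rbind(territory("left", "proximal", prox_seg, 29),
                  territory("right", "proximal", prox_seg, 30),
                  territory("left", "distal", dist_seg, 31),
                  territory("right", "distal", dist_seg, 32))
  duplex <- duplex[order(match(duplex$id, id), duplex$side), ]
  rownames(duplex) <- NULL

  # occlusions can only sit on the primary affected side; intended
  # participant-level occlusion category follows directly
  anyocc <- ifelse(occl_distal & occl_proximal, "both",
                   ifelse(occl_distal, "distal",
                          ifelse(occl_proximal, "proximal", "none")))
  labels <- data.frame(id = id, pad = pad, level = level,
                       any_occlusion = anyocc, stringsAsFactors = FALSE)
  list(cohort = cohort, duplex = duplex, labels = labels)
}

#' Monte-Carlo operating characteristics of both strategies
#'
#' Repeatedly generates a cohort, screens it with both strategies,
#' evaluates each against the generator's reference labels and summarises
#' the distribution of every accuracy metric.  This is the calibration
#' harness: the shipped generator defaults are judged by whether the mean
#' per-strategy sensitivity and specificity land inside the study's
#' printed 95% confidence intervals.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicate cohorts (default 500).
#' @param n_per_rep cohort size per replicate (default `config$n`).
#' @param seed master seed; per-replicate seeds derive from it.
#' @param thresholds,conventions screening configuration.
#' @return object of class `calibration_report`: list with `per_rep`
#'   (array rep x metric x strategy), `mean`, `lo`, `hi` (2.5/97.5
#'   percentile bands) and the marginal summaries.
#' @export
calibration_report <- function(config = sim_config(), n_reps = 500,
                               n_per_rep = config$n, seed = 1,
                               thresholds = screening_thresholds(),
                               conventions = index_conventions()) {
  stopifnot(n_reps >= 1)
  cfg <- config
  cfg$n <- n_per_rep
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  metrics <- c("sens", "spec", "ppv", "npv", "lr_pos", "lr_neg", "accuracy")
  per_rep <- array(NA_real_, c(n_reps, length(metrics), 2),
                   dimnames = list(NULL, metrics, c("targeted", "aha")))
  excl <- matrix(0L, n_reps, 2,
                 dimnames = list(NULL, c("targeted", "aha")))
  for (i in seq_len(n_reps)) {
    gen <- generate_cohort(cfg, seed = rep_seeds[i])
    for (strat in c("targeted", "aha")) {
      scr <- screen_cohort(gen$cohort, strat, thresholds, conventions)
      bc <- build_contingency(scr$decisions, gen$labels)
      per_rep[i, , strat] <- point_metrics(bc$table)
      excl[i, strat] <- bc$n_excluded + bc$n_indeterminate
    }
  }
  summarise <- function(f) apply(per_rep, c(2, 3), f, na.rm = TRUE)
  structure(list(per_rep = per_rep,
                 mean = summarise(mean),
                 lo = apply(per_rep, c(2, 3), stats::quantile, 0.025,
                            na.rm = TRUE),
                 hi = apply(per_rep, c(2, 3), stats::quantile, 0.975,
                            na.rm = TRUE),
                 mean_dropped = colMeans(excl),
                 n_reps = n_reps, n_per_rep = n_per_rep, seed = seed),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration: %d replicates of n = %d\n",
              x$n_reps, x$n_per_rep))
  for (strat in dimnames(x$mean)[[2]]) {
    cat(strat, ":\n", sep = "")
    m <- cbind(mean = x$mean[, strat], `2.5%` = x$lo[, strat],
               `97.5%` = x$hi[, strat])
    print(round(m, 4))
  }
  cat(sprintf("mean dropped per replicate: targeted %.2f, aha %.2f\n",
              x$mean_dropped[["targeted"]], x$mean_dropped[["aha"]]))
  invisible(x)
}
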
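# Eligibility and the two screening strategies.
#
# Both strategies turn a participant's pressure panel into one binary PAD
# call.  The AHA guideline screens everyone with the ABI and substitutes
# the TBI only when the ABI exceeds 1.4 (or is incompressible); the
# targeted rule instead inspects the medical history first and goes
# straight to the TBI when diabetes, renal disease or age over 75 makes
# the ABI unreliable (medial arterial calcification falsely elevates
# ankle pressures in exactly these groups).

#' Screening thresholds and rule switches
#'
#' @param abi_lower ABI below which a screen is positive (default 0.90, the
#'   conventional PAD cut-off; the source guideline applies it but the
#'   value is configurable).
#' @param abi_upper ABI above which the ankle pressure is considered
#'   falsely elevated and the TBI is substituted (default 1.40; the
#'   comparison is strict, "exceeded").
#' @param tbi_lower TBI below which a screen is positive (default 0.70,
#'   common clinical practice).
#' @param targeted_age_cutoff age (years) above which the targeted rule
#'   selects the TBI (default 75; strict greater-than).
#' @param waveform_adjunct `"off"` (default) or `"monophasic_positive"`, an
#'   optional mode that also calls PAD on any monophasic or absent pedal
#'   Doppler waveform.
#' @param aha_incompressible_to_tbi substitute the TBI when the ABI is
#'   incompressible under the AHA rule (default TRUE, the guideline's
#'   intent; switchable because the rule text only names the >1.4 case).
#' @param targeted_abi_fallthrough when the targeted rule selected the ABI
#'   but the result is incompressible or above `abi_upper`, fall through to
#'   the TBI (default TRUE).
#' @return a list of class `screening_thresholds`.
#' @export
screening_thresholds <- function(abi_lower = 0.90, abi_upper = 1.40,
                                 tbi_lower = 0.70,
                                 targeted_age_cutoff = 75,
                                 waveform_adjunct = c("off",
                                                      "monophasic_positive"),
                                 aha_incompressible_to_tbi = TRUE,
                                 targeted_abi_fallthrough = TRUE) {
  stopifnot(abi_lower > 0, abi_lower < abi_upper,
            tbi_lower > 0, tbi_lower < 1)
  structure(list(abi_lower = abi_lower, abi_upper = abi_upper,
                 tbi_lower = tbi_lower,
                 targeted_age_cutoff = targeted_age_cutoff,
                 waveform_adjunct = match.arg(waveform_adjunct),
                 aha_incompressible_to_tbi = aha_incompressible_to_tbi,
                 targeted_abi_fallthrough = targeted_abi_fallthrough),
            class = "screening_thresholds")
}

#' Screening eligibility
#'
#' A participant qualifies for lower-limb vascular screening if over 65
#' years old, or over 50 with diabetes or current smoking, or reporting
#' exertional leg pain.  All age comparisons are strict.
#'
#' @param cohort cohort data.frame (vectorised over rows).
#' @return logical vector, TRUE for eligible participants.
#' @export
check_eligibility <- function(cohort) {
  cohort$age > 65 |
    (cohort$age > 50 & (cohort$diabetes | cohort$current_smoker)) |
    cohort$exertional_leg_pain
}

#' Targeted test selection
#'
#' The targeted rule's first step: choose the TBI whenever diabetes or
#' renal disease is present or age exceeds the cut-off (strictly greater
#' than 75 by default), otherwise the ABI.
#'
#' @param cohort cohort data.frame.
#' @param thresholds a [screening_thresholds()] object.
#' @return character vector, `"ABI"` or `"TBI"` per participant.
#' @export
select_targeted_test <- function(cohort,
                                 thresholds = screening_thresholds()) {
  ifelse(cohort$diabetes | cohort$renal_disease |
           cohort$age > thresholds$targeted_age_cutoff, "TBI", "ABI")
}

decision_frame <- function(id, strategy, n) {
  data.frame(id = id, strategy = rep(strategy, n),
             test_used = rep(NA_character_, n),
             index_value = rep(NA_real_, n),
             index_state = rep(NA_character_, n),
             call = rep(NA_character_, n),
             excluded = rep(FALSE, n),
             reason = rep("", n),
             stringsAsFactors = FALSE)
}

# Patient-level call from a single index.
# Returns list(call, value, state): call in PAD/no_PAD/NA (NA = this index
# could not decide: incompressible/elevated/unavailable; see state).
index_call <- function(agg, lower, upper = Inf) {
  positive <- !is.na(agg$value) & agg$value < lower
  negative <- !is.na(agg$value) & agg$value >= lower & agg$value <= upper
  elevated <- (!is.na(agg$value) & agg$value > upper) | agg$any_inc
  # precedence: a positive limb wins; otherwise an incompressible or
  # elevated limb escalates (call undecided, state says why); an in-range
  # value is negative
  call <- rep(NA_character_, length(agg$value))
  call[positive] <- "PAD"
  call[!positive & !elevated & negative] <- "no_PAD"
  state <- ifelse(positive | (!elevated & negative), "ok",
                  ifelse(agg$any_inc, "incompressible",
                         ifelse(!is.na(agg$value) & agg$value > upper,
                                "elevated", "unavailable")))
  list(call = call, value = agg$value, state = state)
}

same_day_exclusion <- function(cohort) {
  !is.na(cohort$duplex_same_day) & !cohort$duplex_same_day
}

mark_same_day <- function(dec, off) {
  dec$excluded[off] <- TRUE
  dec$reason[off] <- "reference standard on different day"
  dec$call[off] <- NA_character_
  dec
}

apply_waveform_adjunct <- function(cohort, dec, thresholds) {
  if (thresholds$waveform_adjunct == "off") return(dec)
  mono <- cohort$waveform_dp_left %in% c("monophasic", "absent") |
    cohort$waveform_pt_left %in% c("monophasic", "absent") |
    cohort$waveform_dp_right %in% c("monophasic", "absent") |
    cohort$waveform_pt_right %in% c("monophasic", "absent")
  hit <- mono & !dec$excluded
  dec$call[hit] <- "PAD"
  dec
}

#' Apply the targeted screening strategy
#'
#' Selects ABI or TBI per participant from the medical history (see
#' [select_targeted_test()]), computes the chosen index on both limbs,
#' aggregates per the limb convention and calls PAD below the index's
#' threshold.  Participants needing the TBI whose toe pressures are all
#' missing are excluded (reason `"missing toe pressure"`); an ABI that is
#' incompressible or above `abi_upper` falls through to the TBI, and the
#' call is `indeterminate` if that TBI is also unavailable.
#'
#' @param cohort validated cohort data.frame.
#' @param thresholds a [screening_thresholds()] object.
#' @param conventions an [index_conventions()] object.
#' @return decisions data.frame: `id,strategy,test_used,index_value,
#'   index_state,call,excluded,reason`.
#' @export
apply_targeted <- function(cohort, thresholds = screening_thresholds(),
                           conventions = index_conventions()) {
  n <- nrow(cohort)
  dec <- decision_frame(cohort$id, "targeted", n)
  if (n == 0) return(dec)
  off <- same_day_exclusion(cohort)
  dec <- mark_same_day(dec, off)

  sel <- select_targeted_test(cohort, thresholds)
  abi <- aggregate_limbs(compute_abi(cohort, "left", conventions),
                         compute_abi(cohort, "right", conventions),
                         conventions)
  tbi <- aggregate_limbs(compute_tbi(cohort, "left", conventions),
                         compute_tbi(cohort, "right", conventions),
                         conventions)
  abi_call <- index_call(abi, thresholds$abi_lower, thresholds$abi_upper)
  tbi_call <- index_call(tbi, thresholds$tbi_lower)

  # TBI-selected arm: unavailable toe pressures exclude the participant
  tsel <- sel == "TBI" & !off
  dec$test_used[tsel] <- "TBI"
  dec$call[tsel] <- tbi_call$call[tsel]
  dec$index_value[tsel] <- tbi_call$value[tsel]
  dec$index_state[tsel] <- tbi_call$state[tsel]
  miss <- tsel & tbi_call$state == "unavailable"
  dec$excluded[miss] <- TRUE
  dec$call[miss] <- NA_character_
  dec$reason[miss] <- "missing toe pressure"

  # ABI-selected arm
  asel <- sel == "ABI" & !off
  dec$test_used[asel] <- "ABI"
  dec$call[asel] <- abi_call$call[asel]
  dec$index_value[asel] <- abi_call$value[asel]
  dec$index_state[asel] <- abi_call$state[asel]
  undecided <- asel & is.na(abi_call$call)
  if (thresholds$targeted_abi_fallthrough) {
    ft <- undecided & abi_call$state %in% c("incompressible", "elevated")
    dec$test_used[ft] <- "TBI"
    dec$call[ft] <- tbi_call$call[ft]
    dec$index_value[ft] <- tbi_call$value[ft]
    dec$index_state[ft] <- tbi_call$state[ft]
    undecided <- asel & is.na(dec$call) & !dec$excluded
  }
  dec$call[undecided] <- "indeterminate"

  apply_waveform_adjunct(cohort, dec, thresholds)
}

#' Apply the AHA guideline strategy
#'
#' Screens every participant with the ABI; a result at or below `abi_upper`
#' is used directly (PAD below `abi_lower`), while an ABI exceeding 1.4
#' (strict comparison) or an incompressible ankle substitutes the TBI.  The
#' call is `indeterminate` when the substitute TBI is unavailable.
#'
#' @inheritParams apply_targeted
#' @return decisions data.frame, as [apply_targeted()].
#' @export
apply_aha <- function(cohort, thresholds = screening_thresholds(),
                      conventions = index_conventions()) {
  n <- nrow(cohort)
  dec <- decision_frame(cohort$id, "AHA", n)
  if (n == 0) return(dec)
  off <- same_day_exclusion(cohort)
  dec <- mark_same_day(dec, off)

  abi <- aggregate_limbs(compute_abi(cohort, "left", conventions),
                         compute_abi(cohort, "right", conventions),
                         conventions)
  tbi <- aggregate_limbs(compute_tbi(cohort, "left", conventions),
                         compute_tbi(cohort, "right", conventions),
                         conventions)
  abi_call <- index_call(abi, thresholds$abi_lower, thresholds$abi_upper)
  tbi_call <- index_call(tbi, thresholds$tbi_lower)

  use <- !off
  dec$test_used[use] <- "ABI"
  dec$call[use] <- abi_call$call[use]
  dec$index_value[use] <- abi_call$value[use]
  dec$index_state[use] <- abi_call$state[use]

  sub_states <- if (thresholds$aha_incompressible_to_tbi)
    c("incompressible", "elevated") else "elevated"
  sub <- use & is.na(abi_call$call) & abi_call$state %in% sub_states
  dec$test_used[sub] <- "TBI"
  dec$call[sub] <- tbi_call$call[sub]
  dec$index_value[sub] <- tbi_call$value[sub]
  dec$index_state[sub] <- tbi_call$state[sub]

  undecided <- use & is.na(dec$call)
  dec$call[undecided] <- "indeterminate"

  apply_waveform_adjunct(cohort, dec, thresholds)
}

#' Screen a cohort with one strategy
#'
#' Runs [apply_targeted()] or [apply_aha()] over the whole cohort and
#' summarises the exclusion log.  Deterministic.  Aborts when more than
#' half of the non-excluded records are indeterminate, which indicates a
#' misconfigured run rather than unlucky data.
#'
#' @param cohort validated cohort data.frame.
#' @param strategy `"targeted"` or `"aha"`.
#' @param thresholds a [screening_thresholds()] object.
#' @param conventions an [index_conventions()] object.
#' @return list with `decisions` (data.frame) and `exclusions` (named
#'   integer vector of counts by reason).
#' @export
screen_cohort <- function(cohort, strategy = c("targeted", "aha"),
                          thresholds = screening_thresholds(),
                          conventions = index_conventions()) {
  strategy <- match.arg(strategy)
  dec <- switch(strategy,
                targeted = apply_targeted(cohort, thresholds, conventions),
                aha = apply_aha(cohort, thresholds, conventions))
  n_active <- sum(!dec$excluded)
  n_indet <- sum(dec$call == "indeterminate", na.rm = TRUE)
  if (n_active > 0 && n_indet > n_active / 2)
    stop("more than half of screened records are indeterminate (",
         n_indet, "/", n_active, "); check thresholds and conventions")
  excl <- table(dec$reason[dec$excluded])
  list(decisions = dec,
       exclusions = stats::setNames(as.integer(excl), names(excl)))
}

#' Write screening decisions to CSV
#'
#' Serialises with the on-disk convention of the cohort format: the token
#' `INC` when the deciding index was incompressible, empty when no value.
#'
#' @param decisions decisions data.frame from [screen_cohort()].
#' @param path output path.
#' @export
write_decisions <- function(decisions, path) {
  out <- decisions
  out$index_value <- ifelse(
    !is.na(decisions$index_state) &
      decisions$index_state == "incompressible", "INC",
    ifelse(is.na(decisions$index_value), "",
           formatC(decisions$index_value, format = "g", digits = 15)))
  out$index_state <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decisions
#' @param path CSV path.
#' @export
read_decisions <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("id", "strategy", "test_used", "index_value", "call",
            "excluded", "reason")
  if (!identical(names(raw), need))
    stop("decisions header mismatch: expected ",
         paste(need, collapse = ","))
  iv <- trimws(raw$index_value)
  data.frame(id = raw$id, strategy = raw$strategy,
             test_used = ifelse(raw$test_used == "NA" |
                                  raw$test_used == "", NA, raw$test_used),
             index_value = suppressWarnings(as.numeric(iv)),
             index_state = ifelse(toupper(iv) == "INC", "incompressible",
                                  ifelse(iv == "", NA, "ok")),
             call = ifelse(raw$call == "NA" | raw$call == "", NA,
                           raw$call),
             excluded = parse_logical(raw$excluded),
             reason = raw$reason, stringsAsFactors = FALSE)
}
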
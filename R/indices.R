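# Ankle-brachial and toe-brachial indices.
#
# Both indices are ratios of a pedal systolic pressure to a brachial
# systolic pressure.  Which of the two ankle vessels (dorsalis pedis,
# posterior tibial) and which arm supply numerator and denominator is a
# reporting convention, not physiology; the dominant clinical convention
# (higher of the two ankle vessels over the higher arm) is the default and
# both choices are configurable because they shift sensitivity.

#' Index computation conventions
#'
#' @param abi_ankle which ankle vessel supplies the ABI numerator:
#'   `"higher"` (default, dominant clinical convention) or `"lower"`.
#' @param brachial which arm supplies the denominator: `"higher"` (default)
#'   or `"lower"`.
#' @param limb_aggregation how the two limbs' indices combine into one
#'   patient-level screen: `"worst"` (default; a positive limb makes the
#'   screen positive) or `"best"`.
#' @return a list of class `index_conventions`.
#' @export
index_conventions <- function(abi_ankle = c("higher", "lower"),
                              brachial = c("higher", "lower"),
                              limb_aggregation = c("worst", "best")) {
  conv <- list(abi_ankle = match.arg(abi_ankle),
               brachial = match.arg(brachial),
               limb_aggregation = match.arg(limb_aggregation))
  structure(conv, class = "index_conventions")
}

# pick higher/lower of two numeric vectors where incompressible counts as
# above any number; returns list(value, inc, available)
pick_vessel <- function(v1, inc1, v2, inc2, which = "higher") {
  # effective ordering value: incompressible = +Inf
  e1 <- ifelse(inc1, Inf, v1)
  e2 <- ifelse(inc2, Inf, v2)
  avail1 <- inc1 | !is.na(v1)
  avail2 <- inc2 | !is.na(v2)
  e1[!avail1] <- NA
  e2[!avail2] <- NA
  take1 <- ifelse(is.na(e1), FALSE,
                  ifelse(is.na(e2), TRUE,
                         if (which == "higher") e1 >= e2 else e1 <= e2))
  list(value = ifelse(take1, v1, v2),
       inc = ifelse(take1, inc1, inc2) & (avail1 | avail2),
       available = avail1 | avail2)
}

brachial_reference <- function(cohort, conventions) {
  bl <- cohort$brachial_left
  br <- cohort$brachial_right
  f <- if (conventions$brachial == "higher") pmax else pmin
  ifelse(is.na(bl), br, ifelse(is.na(br), bl, f(bl, br)))
}

index_frame <- function(kind, side, value, state, num, den) {
  data.frame(kind = kind, side = side, value = value, state = state,
             numerator_mmHg = num, denominator_mmHg = den,
             stringsAsFactors = FALSE)
}

#' Compute the ankle-brachial index for one side
#'
#' Numerator is the higher (default convention) of the dorsalis pedis and
#' posterior tibial pressures on the requested side; denominator the higher
#' of the two brachial pressures.  If the selected ankle vessel is
#' incompressible the result carries state `"incompressible"`; if the
#' required pressures are absent, state `"unavailable"`.  States are
#' returned, never raised as errors.
#'
#' @param cohort cohort data.frame (vectorised over rows).
#' @param side `"left"` or `"right"`.
#' @param conventions an [index_conventions()] object.
#' @return data.frame with columns `kind`, `side`, `value`, `state`
#'   (`"ok"`, `"incompressible"` or `"unavailable"`), `numerator_mmHg`,
#'   `denominator_mmHg`.
#' @export
compute_abi <- function(cohort, side = c("left", "right"),
                        conventions = index_conventions()) {
  side <- match.arg(side)
  den <- brachial_reference(cohort, conventions)
  dp <- cohort[[paste0("ankle_dp_", side)]]
  pt <- cohort[[paste0("ankle_pt_", side)]]
  sel <- pick_vessel(dp, cohort[[paste0("inc_ankle_dp_", side)]],
                     pt, cohort[[paste0("inc_ankle_pt_", side)]],
                     conventions$abi_ankle)
  state <- ifelse(!sel$available | is.na(den), "unavailable",
                  ifelse(sel$inc, "incompressible", "ok"))
  value <- ifelse(state == "ok", sel$value / den, NA_real_)
  index_frame("ABI", side, value, state,
              ifelse(state == "ok", sel$value, NA_real_), den)
}

#' Compute the toe-brachial index for one side
#'
#' Toe pressure over the brachial reference pressure.  Digital arteries are
#' relatively spared from medial calcification, so the TBI has no
#' incompressible state; a missing toe pressure yields `"unavailable"`
#' (this state drives the targeted method's exclusion path).
#'
#' @inheritParams compute_abi
#' @return same layout as [compute_abi()].
#' @export
compute_tbi <- function(cohort, side = c("left", "right"),
                        conventions = index_conventions()) {
  side <- match.arg(side)
  den <- brachial_reference(cohort, conventions)
  toe <- cohort[[paste0("toe_", side)]]
  state <- ifelse(is.na(toe) | is.na(den), "unavailable", "ok")
  value <- ifelse(state == "ok", toe / den, NA_real_)
  index_frame("TBI", side, value, state,
              ifelse(state == "ok", toe, NA_real_), den)
}

# Patient-level summary of both limbs for screening.
# Returns list of vectors: value (aggregated numeric index; NA when no
# numeric limb), any_inc (any limb incompressible), available (any limb
# with a numeric value or incompressible state).
aggregate_limbs <- function(left, right, conventions) {
  f <- if (conventions$limb_aggregation == "worst") pmin else pmax
  v <- ifelse(is.na(left$value), right$value,
              ifelse(is.na(right$value), left$value,
                     f(left$value, right$value)))
  any_inc <- left$state == "incompressible" | right$state == "incompressible"
  list(value = v, any_inc = any_inc,
       available = !is.na(v) | any_inc)
}
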
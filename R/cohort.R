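# Cohort and duplex tables: schema, parsing, validation, round-trip IO.
#
# In-memory representation: a plain data.frame, one row per participant.
# Pressures are numeric mmHg with NA for "not measured"; the incompressible
# state of each ankle vessel is carried in a parallel logical column
# (inc_ankle_dp_left, ...), never as a magic pressure value.  On disk the
# four ankle cells use the literal token "INC" for incompressible and an
# empty cell for missing.

COHORT_COLUMNS <- c(
  "id", "age", "sex", "diabetes", "renal_disease", "current_smoker",
  "exertional_leg_pain",
  "brachial_left", "brachial_right",
  "ankle_dp_left", "ankle_pt_left", "ankle_dp_right", "ankle_pt_right",
  "toe_left", "toe_right",
  "waveform_dp_left", "waveform_pt_left", "waveform_dp_right",
  "waveform_pt_right", "duplex_same_day")

ANKLE_COLUMNS <- c("ankle_dp_left", "ankle_pt_left",
                   "ankle_dp_right", "ankle_pt_right")

WAVEFORM_CLASSES <- c("triphasic", "biphasic", "monophasic", "absent",
                      "not_assessed")

DUPLEX_COLUMNS <- c("id", "side", "artery", "stenosis_percent", "occluded")

#' Arterial segment vocabulary
#'
#' The controlled list of lower-limb arterial segments used to validate
#' duplex findings, with each segment's level attribute.  Proximal covers
#' aorto-iliac through popliteal; distal covers the infrapopliteal
#' (tibial/peroneal/pedal) vessels.  The list ships as an editable CSV in
#' `inst/extdata/arterial_segments.csv`.
#'
#' @param path optional path to an alternative `artery,level` CSV.
#' @return data.frame with columns `artery` and `level`.
#' @export
arterial_segments <- function(path = NULL) {
  path <- path %||% system.file("extdata", "arterial_segments.csv",
                                package = "limbscreen", mustWork = TRUE)
  seg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(seg), c("artery", "level")),
            all(seg$level %in% c("proximal", "distal")))
  seg
}

parse_pressure <- function(x) {
  x <- trimws(x)
  val <- suppressWarnings(as.numeric(x))
  val[x == "" | toupper(x) == "INC"] <- NA_real_
  list(value = val, inc = toupper(x) == "INC")
}

parse_logical <- function(x) {
  x <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Read a participant cohort CSV
#'
#' Parses and validates the cohort table.  The file must carry exactly the
#' documented header; the token `INC` in an ankle-pressure cell encodes an
#' incompressible vessel and an empty cell encodes a missing measurement.
#' Recorded ankle pressures above `cuff_ceiling` are also flagged
#' incompressible (the cuff cannot occlude a calcified vessel, so such
#' readings are not interpretable pressures).
#'
#' @param path path to the cohort CSV.
#' @param age_range plausible age bounds; rows outside are rejected.
#' @param cuff_ceiling mmHg above which a recorded ankle pressure is treated
#'   as incompressible (default 250).
#' @return validated cohort data.frame (fatal findings abort with row
#'   numbers; warnings are signalled but do not abort).
#' @export
read_cohort <- function(path, age_range = c(18, 110), cuff_ceiling = 250) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (!identical(names(raw), COHORT_COLUMNS))
    stop("cohort header mismatch: expected ",
         paste(COHORT_COLUMNS, collapse = ","))
  cohort <- as_cohort(raw, cuff_ceiling = cuff_ceiling)
  findings <- validate_cohort(cohort, age_range = age_range)
  report_findings(findings, context = path)
  cohort
}

# raw character data.frame -> typed in-memory cohort
as_cohort <- function(raw, cuff_ceiling = 250) {
  cohort <- data.frame(id = trimws(raw$id),
                       age = suppressWarnings(as.integer(raw$age)),
                       sex = trimws(raw$sex),
                       stringsAsFactors = FALSE)
  for (col in c("diabetes", "renal_disease", "current_smoker",
                "exertional_leg_pain", "duplex_same_day"))
    cohort[[col]] <- parse_logical(raw[[col]])
  for (col in c("brachial_left", "brachial_right", "toe_left", "toe_right"))
    cohort[[col]] <- suppressWarnings(
      as.numeric(ifelse(trimws(raw[[col]]) == "", NA, raw[[col]])))
  for (col in ANKLE_COLUMNS) {
    p <- parse_pressure(raw[[col]])
    over <- !is.na(p$value) & p$value > cuff_ceiling
    p$inc[over] <- TRUE
    p$value[over] <- NA_real_
    cohort[[col]] <- p$value
    cohort[[paste0("inc_", col)]] <- p$inc
  }
  for (col in c("waveform_dp_left", "waveform_pt_left",
                "waveform_dp_right", "waveform_pt_right"))
    cohort[[col]] <- trimws(raw[[col]])
  cohort[c("id", "age", "sex", "diabetes", "renal_disease",
           "current_smoker", "exertional_leg_pain",
           "brachial_left", "brachial_right",
           ANKLE_COLUMNS, paste0("inc_", ANKLE_COLUMNS),
           "toe_left", "toe_right",
           "waveform_dp_left", "waveform_pt_left",
           "waveform_dp_right", "waveform_pt_right", "duplex_same_day")]
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: incompressible ankle cells are written as the
#' token `INC`, missing values as empty cells.  Round-tripping a valid
#' cohort reproduces it field for field.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 15))
  out$age <- ifelse(is.na(cohort$age), "", as.character(cohort$age))
  out$sex <- cohort$sex
  for (col in c("diabetes", "renal_disease", "current_smoker",
                "exertional_leg_pain"))
    out[[col]] <- as.character(cohort[[col]])
  out$brachial_left <- num(cohort$brachial_left)
  out$brachial_right <- num(cohort$brachial_right)
  for (col in ANKLE_COLUMNS)
    out[[col]] <- ifelse(cohort[[paste0("inc_", col)]], "INC",
                         num(cohort[[col]]))
  out$toe_left <- num(cohort$toe_left)
  out$toe_right <- num(cohort$toe_right)
  for (col in c("waveform_dp_left", "waveform_pt_left",
                "waveform_dp_right", "waveform_pt_right"))
    out[[col]] <- cohort[[col]]
  out$duplex_same_day <- as.character(cohort$duplex_same_day)
  stopifnot(identical(names(out), COHORT_COLUMNS))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a duplex findings CSV
#'
#' One row per imaged arterial segment: `id,side,artery,stenosis_percent,
#' occluded`.  Artery names are validated against the controlled segment
#' vocabulary; unknown names are fatal.
#'
#' @param path path to the duplex CSV.
#' @param segments segment vocabulary (see [arterial_segments()]).
#' @return validated duplex data.frame.
#' @export
read_duplex <- function(path, segments = arterial_segments()) {
  dup <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(dup), DUPLEX_COLUMNS))
    stop("duplex header mismatch: expected ",
         paste(DUPLEX_COLUMNS, collapse = ","))
  dup$id <- trimws(as.character(dup$id))
  dup$occluded <- parse_logical(as.character(dup$occluded))
  findings <- validate_duplex(dup, segments)
  report_findings(findings, context = path)
  dup
}

#' @rdname read_duplex
#' @param duplex duplex data.frame to write.
#' @export
write_duplex <- function(duplex, path) {
  utils::write.csv(duplex[DUPLEX_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

finding <- function(id, row, field, severity, message) {
  data.frame(id = id, row = row, field = field, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  finding(character(), integer(), character(), character(), character())
}

#' Validate a cohort table
#'
#' Checks every participant record against the structural invariants and
#' returns one finding per violation, tagged `fatal` or `warning`; an empty
#' result means a conformant cohort.  Missing toe pressures are a warning
#' (the targeted method may be inapplicable), not fatal.  Validation is
#' idempotent and side-effect free.
#'
#' @param cohort cohort data.frame.
#' @param age_range plausible age bounds (default 18-110).
#' @return data.frame of findings: `id,row,field,severity,message`.
#' @export
validate_cohort <- function(cohort, age_range = c(18, 110)) {
  out <- list(no_findings())
  add <- function(mask, field, severity, message) {
    if (any(mask, na.rm = TRUE)) {
      i <- which(!is.na(mask) & mask)
      out[[length(out) + 1]] <<-
        finding(cohort$id[i], i, field, severity, message)
    }
  }
  dup_id <- duplicated(cohort$id) | duplicated(cohort$id, fromLast = TRUE)
  add(dup_id, "id", "fatal", "duplicate participant id")
  add(is.na(cohort$age) | cohort$age < age_range[1] |
        cohort$age > age_range[2],
      "age", "fatal",
      sprintf("age missing or outside plausible range [%d, %d]",
              age_range[1], age_range[2]))
  add(!cohort$sex %in% c("male", "female"), "sex", "fatal",
      "sex must be 'male' or 'female'")
  for (col in c("diabetes", "renal_disease", "current_smoker",
                "exertional_leg_pain"))
    add(is.na(cohort[[col]]), col, "fatal", "boolean field unparseable")
  add(is.na(cohort$brachial_left) & is.na(cohort$brachial_right),
      "brachial", "fatal",
      "at least one brachial pressure required for index computation")
  for (col in c("brachial_left", "brachial_right", "toe_left", "toe_right",
                ANKLE_COLUMNS))
    add(!is.na(cohort[[col]]) & cohort[[col]] <= 0, col, "fatal",
        "pressures must be positive mmHg")
  for (col in c("waveform_dp_left", "waveform_pt_left",
                "waveform_dp_right", "waveform_pt_right"))
    add(!cohort[[col]] %in% WAVEFORM_CLASSES, col, "fatal",
        paste("waveform class must be one of:",
              paste(WAVEFORM_CLASSES, collapse = ", ")))
  add(is.na(cohort$toe_left) & is.na(cohort$toe_right), "toe", "warning",
      "toe pressures missing; targeted method may be inapplicable")
  add(!is.na(cohort$duplex_same_day) & !cohort$duplex_same_day,
      "duplex_same_day", "warning",
      "reference scan on a different day; record flagged for exclusion")
  do.call(rbind, out)
}

#' @rdname validate_cohort
#' @param duplex duplex data.frame.
#' @param segments segment vocabulary.
#' @export
validate_duplex <- function(duplex, segments = arterial_segments()) {
  out <- list(no_findings())
  add <- function(mask, field, severity, message) {
    if (any(mask, na.rm = TRUE)) {
      i <- which(!is.na(mask) & mask)
      out[[length(out) + 1]] <<-
        finding(duplex$id[i], i, field, severity, message)
    }
  }
  add(!duplex$artery %in% segments$artery, "artery", "fatal",
      "unknown arterial segment")
  add(!duplex$side %in% c("left", "right"), "side", "fatal",
      "side must be 'left' or 'right'")
  add(is.na(duplex$stenosis_percent) | duplex$stenosis_percent < 0 |
        duplex$stenosis_percent > 100,
      "stenosis_percent", "fatal", "stenosis_percent outside [0, 100]")
  add(!is.na(duplex$occluded) & duplex$occluded &
        duplex$stenosis_percent != 100,
      "occluded", "fatal", "occluded implies stenosis_percent = 100")
  do.call(rbind, out)
}

report_findings <- function(findings, context = "input") {
  if (nrow(findings) == 0) return(invisible(findings))
  msg <- sprintf("row %d (id %s) [%s]: %s",
                 findings$row, findings$id, findings$field, findings$message)
  fatal <- findings$severity == "fatal"
  if (any(!fatal))
    warning(context, ": ", paste(msg[!fatal], collapse = "; "),
            call. = FALSE)
  if (any(fatal))
    stop(context, ": ", paste(msg[fatal], collapse = "; "), call. = FALSE)
  invisible(findings)
}
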
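# Duplex ultrasound reference standard.
#
# PAD is defined as one or more lower-limb arteries with stenosis strictly
# greater than 50% on colour duplex.  The lesion level (proximal =
# aorto-iliac through popliteal, distal = infrapopliteal) comes from the
# segment vocabulary's level attribute.

#' Label one participant from duplex findings
#'
#' @param findings data.frame of duplex rows for a single participant
#'   (`side,artery,stenosis_percent,occluded`; an `id` column is ignored).
#' @param segments segment vocabulary from [arterial_segments()].
#' @return list with `pad` (logical), `level` (`none`, `distal_only`,
#'   `proximal_only`, `both`) and `any_occlusion` (`none`, `distal`,
#'   `proximal`, `both`).  Order of findings is irrelevant.
#' @export
label_participant <- function(findings, segments = arterial_segments()) {
  unknown <- setdiff(findings$artery, segments$artery)
  if (length(unknown) > 0)
    stop("unknown arterial segment(s): ", paste(unknown, collapse = ", "))
  lev <- segments$level[match(findings$artery, segments$artery)]
  sten <- findings$stenosis_percent > 50
  occ <- !is.na(findings$occluded) & findings$occluded
  dis_d <- any(sten & lev == "distal")
  dis_p <- any(sten & lev == "proximal")
  occ_d <- any(occ & lev == "distal")
  occ_p <- any(occ & lev == "proximal")
  two_way <- function(d, p)
    if (d && p) "both" else if (d) "distal" else if (p) "proximal" else "none"
  level <- switch(two_way(dis_d, dis_p),
                  both = "both", distal = "distal_only",
                  proximal = "proximal_only", none = "none")
  list(pad = level != "none", level = level,
       any_occlusion = two_way(occ_d, occ_p))
}

#' Label a whole cohort against the reference standard
#'
#' @param duplex duplex data.frame (`id,side,artery,stenosis_percent,
#'   occluded`).
#' @param ids participant ids to label; defaults to the ids present in
#'   `duplex`.  Ids with no duplex rows are labelled `none` (disease-free
#'   scan).
#' @param segments segment vocabulary.
#' @return data.frame `id,pad,level,any_occlusion`, one row per id.
#' @export
label_cohort <- function(duplex, ids = unique(duplex$id),
                         segments = arterial_segments()) {
  unknown <- setdiff(duplex$artery, segments$artery)
  if (length(unknown) > 0)
    stop("unknown arterial segment(s): ", paste(unknown, collapse = ", "))
  lev <- segments$level[match(duplex$artery, segments$artery)]
  sten <- duplex$stenosis_percent > 50
  occ <- !is.na(duplex$occluded) & duplex$occluded
  agg <- function(mask) {
    hit <- unique(duplex$id[mask])
    ids %in% hit
  }
  dis_d <- agg(sten & lev == "distal")
  dis_p <- agg(sten & lev == "proximal")
  occ_d <- agg(occ & lev == "distal")
  occ_p <- agg(occ & lev == "proximal")
  level <- ifelse(dis_d & dis_p, "both",
                  ifelse(dis_d, "distal_only",
                         ifelse(dis_p, "proximal_only", "none")))
  anyocc <- ifelse(occ_d & occ_p, "both",
                   ifelse(occ_d, "distal",
                          ifelse(occ_p, "proximal", "none")))
  data.frame(id = ids, pad = level != "none", level = level,
             any_occlusion = anyocc, stringsAsFactors = FALSE)
}

#' Cohort prevalence summary
#'
#' Counts and percentages (against total N) for PAD, each lesion level,
#' occlusion categories and, when a cohort is supplied, incompressible
#' ankle pressures.  Percentages are reported to two decimals; the default
#' rounds half up, `rounding = "truncate"` is a compatibility mode for
#' tables whose cells were truncated instead (e.g. 51/119 prints 42.86
#' rounded but 42.85 truncated).
#'
#' @param labels data.frame from [label_cohort()].
#' @param cohort optional cohort data.frame, for the incompressible count.
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @return data.frame `item,n,percent`.
#' @export
cohort_prevalence <- function(labels, cohort = NULL,
                              rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  stopifnot(nrow(labels) >= 1)
  n <- nrow(labels)
  items <- c(pad = sum(labels$pad),
             distal_only = sum(labels$level == "distal_only"),
             proximal_only = sum(labels$level == "proximal_only"),
             both = sum(labels$level == "both"),
             distal_occlusion = sum(labels$any_occlusion %in%
                                      c("distal", "both")),
             proximal_occlusion = sum(labels$any_occlusion %in%
                                        c("proximal", "both")))
  if (!is.null(cohort)) {
    inc <- cohort$inc_ankle_dp_left | cohort$inc_ankle_pt_left |
      cohort$inc_ankle_dp_right | cohort$inc_ankle_pt_right
    items <- c(items, incompressible = sum(inc))
  }
  pct <- 100 * items / n
  pct <- if (rounding == "half_up") round_half_up(pct, 2) else
    trunc_digits(pct, 2)
  data.frame(item = names(items), n = as.integer(items), percent = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}
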
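# Construct small cohorts and duplex tables in the package's in-memory
# representation, one participant per call.

make_participant <- function(id = "P1", age = 70, sex = "male",
                             diabetes = FALSE, renal = FALSE,
                             smoker = FALSE, leg_pain = FALSE,
                             brachial = c(120, 118),
                             ankle_left = c(dp = 130, pt = 120),
                             ankle_right = c(dp = 130, pt = 120),
                             inc = character(),  # e.g. "dp_left"
                             toe = c(84, 84),
                             waveform = "triphasic",
                             same_day = TRUE) {
  p <- data.frame(id = id, age = as.integer(age), sex = sex,
                  diabetes = diabetes, renal_disease = renal,
                  current_smoker = smoker, exertional_leg_pain = leg_pain,
                  brachial_left = brachial[1], brachial_right = brachial[2],
                  ankle_dp_left = unname(ankle_left["dp"]),
                  ankle_pt_left = unname(ankle_left["pt"]),
                  ankle_dp_right = unname(ankle_right["dp"]),
                  ankle_pt_right = unname(ankle_right["pt"]),
                  inc_ankle_dp_left = "dp_left" %in% inc,
                  inc_ankle_pt_left = "pt_left" %in% inc,
                  inc_ankle_dp_right = "dp_right" %in% inc,
                  inc_ankle_pt_right = "pt_right" %in% inc,
                  toe_left = toe[1], toe_right = toe[2],
                  waveform_dp_left = waveform, waveform_pt_left = waveform,
                  waveform_dp_right = waveform,
                  waveform_pt_right = waveform,
                  duplex_same_day = same_day, stringsAsFactors = FALSE)
  for (col in c("ankle_dp_left", "ankle_pt_left",
                "ankle_dp_right", "ankle_pt_right"))
    if (p[[paste0("inc_", col)]]) p[[col]] <- NA_real_
  p
}

make_cohort <- function(...) do.call(rbind, list(...))

make_duplex <- function(id, artery, stenosis, side = "left",
                        occluded = stenosis == 100) {
  data.frame(id = id, side = side, artery = artery,
             stenosis_percent = stenosis, occluded = occluded,
             stringsAsFactors = FALSE)
}

# random valid 2x2 table with diseased + healthy <= n_max
rand_table <- function(n_max = 200) {
  n <- sample(4:n_max, 1)
  nd <- sample(1:(n - 1), 1)
  tp <- sample(0:nd, 1)
  tn <- sample(0:(n - nd), 1)
  contingency_table(tp, nd - tp, (n - nd) - tn, tn)
}
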
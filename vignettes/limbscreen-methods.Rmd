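---
title: "Methods: screening strategies, accuracy estimation and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening strategies, accuracy estimation and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbscreen)
```

## The clinical problem

Peripheral arterial disease (PAD) of the lower limb is screened
non-invasively with pressure indices: the ankle-brachial index (ABI,
ankle over brachial systolic pressure) and the toe-brachial index (TBI,
toe over brachial). The ABI is cheap and widely recommended, but medial
arterial calcification (MAC) — common in diabetes, renal disease and old
age — stiffens the ankle arteries and falsely elevates ankle pressures,
sometimes beyond what a cuff can occlude ("incompressible"). Digital
arteries are relatively spared, so the TBI stays informative exactly
where the ABI fails. Distally distributed atherosclerosis further blunts
ABI sensitivity.

`limbscreen` implements and compares two decision rules that turn a
pressure panel into one binary PAD call per patient:

* **AHA rule**: use the ABI for everyone; substitute the TBI only when
  the ABI *exceeds* 1.4 (strict) or the ankle is incompressible.
* **Targeted rule**: inspect the history first; use the TBI whenever
  diabetes or renal disease is present or age exceeds 75 (strict),
  otherwise the ABI.

The reference standard is colour duplex ultrasound: PAD is one or more
lower-limb arteries with stenosis strictly greater than 50%. Lesions are
classed proximal (aorto-iliac through popliteal) or distal
(infrapopliteal); that boundary is a package convention stored in the
editable segment vocabulary (`arterial_segments()`), since "proximal"
and "distal" have no universal cut.

## Index conventions

Neither index has a single universal recipe. The package defaults follow
the dominant clinical convention and everything is configurable through
`index_conventions()` because these choices shift sensitivity:

* ABI numerator: the **higher** of dorsalis pedis and posterior tibial
  on the limb (configurable to lower);
* denominator: the **higher** brachial pressure (configurable);
* patient-level screen from two limbs: **worst limb** — any limb index
  below threshold makes the screen positive; when no limb is positive,
  an incompressible or elevated (>1.4) limb escalates to the TBI; an
  in-range limb is negative. A `best` aggregation exists for sensitivity
  analyses. Per-limb reporting is deliberately not offered: the
  strategies under study make patient-level calls only.

Thresholds default to the conventional ABI < 0.90 and TBI < 0.70
positives (`screening_thresholds()`); both are exposed because the
source guideline fixes neither in its rule text. Boundary comparisons
are strict throughout ("over 75", "exceeded 1.4"), and `incompressible`
is an explicit measurement state — in files the token `INC`, in memory a
logical flag — never a sentinel number. A recorded ankle pressure above
the cuff ceiling (default 250 mmHg, configurable; the defining ceiling
is a package choice) is promoted to that state at load time.

## Accuracy estimation

`dx_accuracy()` is the central estimator. From a 2×2 table it computes
sensitivity, specificity, predictive values, diagnostic accuracy and
likelihood ratios, with:

* **Clopper–Pearson (exact binomial) intervals** for all proportions:
  lower bound the $\alpha/2$ quantile of $\mathrm{Beta}(k, n-k+1)$,
  upper the $1-\alpha/2$ quantile of $\mathrm{Beta}(k+1, n-k)$, closed
  at 0 and 1. The choice is fixed rather than configurable: exact
  intervals are the norm for small diagnostic studies, and Wald or
  Wilson intervals give visibly different numbers at these sample
  sizes.
* **Simel log-method intervals** for likelihood ratios:
  $\operatorname{var}(\ln LR^+) = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)$
  (mirrored for $LR^-$), interval $\exp(\ln LR \pm z\sqrt{var})$. Any
  zero cell makes the interval undefined (`NA`), never an error.
* **Importance annotations** on likelihood ratios, using the
  conventional interpretation bands: important when $LR^+ \ge 5$ or
  $LR^- \le 0.2$; may be important when $2 \le LR^+ < 5$ or
  $0.2 < LR^- \le 0.5$. The cut-offs sit in
  `lr_annotation_thresholds()`.

Two presentation compatibility switches exist because published tables
are not always arithmetically tidy: `truncate_accuracy = TRUE` *truncates*
(rather than rounds) the printed diagnostic-accuracy cell, and
`denominator_override` lets accuracy be quoted against a recruited N
larger than the analyzed set. Both default off; computation elsewhere
always rounds half-up at presentation and keeps full precision
internally.

Undefined metrics (zero denominators) propagate as `NA` and print as
blanks. Exact identities — Bayes consistency of the predictive values
with prevalence, $LR^+(1-spec)=sens$, $LR^-\,spec=1-sens$ — hold to
machine precision and are enforced by property tests.

## Reconstructing 2×2 tables from printed summaries

When a study reports sensitivity and specificity to two decimals but not
its cell counts, the counts are usually recoverable: `recover_counts()`
enumerates every $tp \in [0, D]$ and $tn \in [0, N-D]$ and keeps tables
whose proportions fall within a tolerance (default ±0.005 on the
proportion scale) of the printed values, ranking survivors by agreement
with any further printed statistics. For the study this package models,
both arms reconstruct **uniquely**:

```{r reconstruct}
recover_counts(summary_constraints(117, 50, 62.00, 85.07))
recover_counts(summary_constraints(119, 51, 49.02, 94.12))
```

The targeted arm's analyzed-set sizes are themselves derived: 119
analyzable participants of whom 51 had PAD, minus two toe-pressure
exclusions; `exclusion_splits()` shows that only a 1 diseased / 1
healthy split of those two reproduces the printed confidence-interval
denominators (50 diseased, 67 healthy).

## The synthetic cohort generator

No patient-level data accompany the study, so `generate_cohort()` draws
cohorts with the study population's marginal structure: n 119, 63%
male, age truncated-normal 73.1 (SD 7.2) on [53, 92], diabetes 61.34%,
PAD prevalence 42.85% split distal-only : proximal-only : both =
37 : 7 : 7, incompressible ankle pressures 13.44%, occlusions almost
exclusively distal (33.61% of participants). Renal disease (8%),
smoking (15%), leg pain (25%) and the bilateral-disease fraction (30%)
are not reported for the study population; their defaults are plausible
placeholders for an elderly podiatry cohort and are flagged as such.
Exertional leg pain is forced on for the few draws that would otherwise
fail the recruitment rule, so every generated participant is
screening-eligible.

The haemodynamic mechanism is the point of the generator:

* each limb gets a true ankle perfusion ratio and toe perfusion ratio
  drawn by disease level (healthy limbs ≈ 1.08 ankle / 0.88 toe;
  proximal disease depresses ankle ratios strongly, distal disease only
  mildly — the distal-lesion mechanism of ABI insensitivity);
* MAC occurs with probability logistic in diabetes, renal disease and
  age, and multiplies *ankle* pressures by a log-normal inflation
  factor; toe pressures are never inflated (digital sparing). Inflated
  pressures beyond the cuff ceiling become incompressible;
* measured pressures add a few mmHg of noise; Doppler waveform class is
  a coarse discretisation of the true ankle ratio.

Every haemodynamic number is an invented calibration value — the study
reports no pressures. They were fixed, once, by requiring the
**calibration property**: over 500 replicate cohorts of n = 119 with
shipped defaults, the mean sensitivity and specificity of each strategy
must fall inside the corresponding printed 95% confidence interval of
the study (targeted 47.17–75.35 / 74.26–92.60; AHA 34.75–63.40 /
85.62–98.37), while the incompressible, diabetes, PAD and occlusion
marginals match their target rates at n = 10⁵ within Monte-Carlo error.
The shipped defaults give mean targeted sensitivity ≈ 0.65 and AHA
sensitivity ≈ 0.53 — the qualitative ordering (targeted more sensitive,
AHA more specific) is reproduced, not imposed. What passing these checks
does **not** show: that real pressure distributions look like these, nor
that the strategies' accuracy on other populations would match; the
generator emulates one study population's margins and one mechanism, not
vascular physiology at large.

Duplex rows are generated consistently with the assigned label by
construction (affected territories carry a segment in (55, 95]% or an
occlusion at 100%; unaffected ones stay ≤ 45%), so the reference
standard recovers the generator's intended label for every participant
— a property the tests assert at 100%.

Randomness is one uniform stream per run, consumed in a fixed block of
36 draws per participant by inverse CDF, so cohorts are reproducible
byte-for-byte and growing `n` never reshuffles earlier participants.

## Numerical and degenerate-input choices

* Percentages print at two decimals, rounding half away from zero;
  truncation only under `truncate_accuracy` and only for cells published
  that way.
* Zero denominators yield `NA` metrics; zero cells yield `NA` LR
  intervals; an all-excluded cohort yields a zero table with a warning.
* `screen_cohort()` aborts when more than half the usable records are
  indeterminate — that pattern indicates misconfiguration (e.g. a cuff
  ceiling below normal pressures), not data.
* Ties: the higher-vessel convention resolves equal pressures to the
  dorsalis pedis (first listed); equality at a threshold is negative
  (strict `<` comparisons throughout).
* Ages are whole years; pressures are whole mmHg in generated data but
  accepted as reals on input.

## Problem sizes used by the test-suite

Unit and property tests run on cohorts of 40–500 and on
20,000-participant draws for marginal checks; the calibration property
uses 500 replicates of n = 119 and one 100,000-participant draw. These
sizes give Monte-Carlo standard errors comfortably below the tolerances
they are tested against while keeping the whole suite inside a minute.

## Known limitations

* The ABI/TBI conventions of the modelled study are unstated; if it
  used, say, average rather than higher brachial pressure, its
  patient-level indices would differ from ours on the same data.
* Waveforms are generated and validated but enter classification only
  through the optional `monophasic_positive` adjunct (off by default):
  how the study operationalised its waveform assessment is unknown.
* The generator's laterality, occlusion-placement and segment-choice
  structure is deliberately minimal; it targets participant-level
  margins only.
* Reconstruction assumes the printed sensitivity and specificity were
  rounded from exact ratios of the analyzed counts; a study that
  truncated those cells instead would need a wider tolerance.
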
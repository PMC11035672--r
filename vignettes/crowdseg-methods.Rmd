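---
title: "Quality-controlled crowdsourced segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-controlled crowdsourced segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdseg)
```

## The problem

Supervised segmentation of soft tissue in surgical video needs large
volumes of pixel-level masks, and domain experts are too scarce and too
expensive to produce them at scale. Crowdsourcing replaces the expert with
many non-expert annotators, but soft tissue is deformable and contextual,
so raw crowd masks vary widely in quality. `crowdseg` implements the
quality-control machinery that makes such a campaign trustworthy:
qualification and continuous monitoring against expert gold masks,
majority-vote fusion, difficulty scoring, and threshold-routed expert QA,
with a cost ledger that quantifies the expert time saved.

## The pipeline and its assumptions

An annotation task is one (frame, structure) pair; its data object is a
binary raster mask, where the empty mask is the deliberate "no finding"
annotation (structure absent). The pipeline assumes:

1. **Expert gold masks are truth.** TS and RS are IoU against expert
   references; the pipeline never questions the expert.
2. **Votes are exchangeable.** Majority vote weighs all qualified
   annotators equally; there is no per-annotator reliability weighting
   (STAPLE-style fusion is an explicit non-goal).
3. **Qualification at submission time.** An annotation counts iff its
   author was qualified when it was submitted. Later disqualification is
   prospective only: published consensus records are never rebuilt, so
   ledger counts are stable.

### Gating

The training score TS is the arithmetic mean of per-task IoU over exactly
`n_training_gold = 10` expert-annotated tasks — the protocol fixes the
count, and the mean is the minimal aggregation assumption. The running
score RS is the mean over the `rs_window = 10` most recent hidden gold
tests, inserted Bernoulli-style at one per `rs_cadence = 20` ordinary
tasks. "Intermittently" is all the protocol specifies, so cadence and
window are surfaced in the configuration rather than hard-coded. The
production platform's numeric TS/RS cutoffs are not public; the shipped
`ts_min = rs_min = 0.5` are deliberately conservative defaults, not claims
about any deployed system.

### Consensus

MV is an absolute vote count (bowel 4-of-5, abdominal wall 2-of-5 in the
default task set), so no ties can occur. `mv = 1` is the union,
`mv = n` the intersection, and the consensus is monotonically shrinking in
`mv` — these laws are property-tested. When a task attracts more than
`n_min` qualified annotations the package rescales the threshold as
`ceiling(mv / n_min * n_used)` to preserve the voting fraction; the
unscaled absolute mode is available via `scale_mv = FALSE`. A task with
fewer than `n_min` qualified annotations is *pending*, a reported state
rather than an error, so batch runs always complete.

### Difficulty and QA

`DI = 1 - mean(IoU(annotation_i, consensus))`, each contributor compared
to the final consensus *including its own vote* — leave-one-out is nowhere
implied by the protocol and would make DI depend on k in a less
interpretable way. The empty-mask convention (IoU of two empty masks is 1)
makes unanimous "no finding" tasks DI 0, which is why task sets rich in
structure-absent frames have lower median DI; the package reproduces this
direction in its tests. Frames with `di > rt` (default 0.4) are flagged,
and flagged frames are sampled for expert review at a Bernoulli rate
(default 0.1; the protocol says only "randomly selected"). DI exactly at
the threshold is not flagged — "above" is strict.

### Cost accounting

Expert hours saved are `frames × seconds_per_frame / 3600` with
`seconds_per_frame = 120.3`, the measured mean expert time per two-structure
frame; headline figures are rounded half-up (902 from 902.25, 17 from
17.04), and the raw value is retained. Throughput is
`experts × hours_per_day × 3600 / seconds_per_frame` (4 × 1 h → 120
frames/day). Demographics percentages are rounded half-up to integers.
Gold-test annotations are counted separately from consensus-contributing
annotations in the ledger: the per-task arithmetic (510 × 5 × 2 = 5100)
only works if gold tests are excluded, and the ledger makes that explicit.

## The simulator: what it emulates and what it does not

The simulator exists so that every pipeline stage can be tested against
known truth with no external data. A scene is a per-structure mixture:
with `presence_probability` the ground truth is a union of 1–3 random
discs, otherwise empty — emulating frames where the target structure is
out of view. An annotator degrades the truth by (i) a disc
dilation/erosion whose radius is drawn uniformly from
`{-jitter, ..., +jitter}` (the simplest symmetric boundary-error model),
(ii) flipping boundary-band pixels at `pixel_noise`, (iii) submitting "no
finding" with `miss_probability`, or — for spammers — ignoring the truth
entirely. Annotation times follow a log-normal with 0.4 log-sd around the
annotator's configured mean.

None of these distributions is an empirical claim: no quantitative
annotator-error model exists for the real platform, so all simulator
parameters are repo conventions. Consequently a green test establishes
that the *machinery* behaves lawfully (gates exclude spammers, fusion
beats individuals, DI tracks noise) — not that any particular real-world
F1 or DI value would be reproduced. The study-scale accuracies
(crowd-vs-expert F1 ≈ 0.86 bowel) depend on real surgical video and are
out of scope by design.

Random streams are derived hierarchically — campaign seed → purpose →
annotator → frame — via a 32-bit FNV-1a hash, so adding an annotator or a
frame never perturbs existing streams and regression tests stay stable.

## Numerical choices

- **Empty-mask conventions**: both-empty → all five metrics 1;
  empty-vs-non-empty → IoU = F1 = 0, sensitivity 0 (pred empty),
  specificity 1 (pred empty). These are the formula limits plus the
  protocol's "no finding annotations are in 100% agreement".
- **Binarization**: PNG masks are 0/255; a pixel is foreground at level
  ≥ 128, robust to lossy round trips.
- **sd** is the sample standard deviation (n − 1); a cohort of one reports
  sd 0 rather than NA.
- **Median/quartiles** use R's default type-7 quantiles (midpoint
  interpolation for even counts).
- **Rounding** of headline hours and percentages is half-up, matching the
  published figures; `round()`'s banker's rounding is not used.

## Design decisions taken where the design was open

- The Monte-Carlo calibration band originally envisaged for the annotator
  noise model was replaced by something stronger: the morphology operators
  are tested for *exact* equivalence against an independently coded
  brute-force distance oracle, which removes the only tunable fixture the
  calibration would have introduced.
- Gold tasks for training are forced to contain a visible structure: an
  empty gold mask scores every candidate 1.0 and discriminates nothing.
- `run_campaign` draws `n_min` contributors per task from the currently
  qualified pool; extra capacity is unused rather than over-collected,
  which keeps the ledger arithmetic exact.
- The wisdom-of-the-crowd guarantee is asserted at campaign aggregate
  level (mean consensus IoU ≥ mean individual IoU per 500-frame campaign),
  the form in which the property is stable; per-frame it can fail on
  individual hard frames.

## Known limitations

- Disc-union scenes are geometrically far simpler than surgical anatomy;
  absolute DI and IoU values from the simulator do not transfer.
- No annotator learning or fatigue dynamics; skill is stationary.
- Majority vote only — no probabilistic fusion, no per-annotator weights.
- QA adjudication (what the reviewing expert changes) is not modeled; the
  pipeline stops at routing.
- Pure-R morphology is fine at test scales (≤ 64×64 frames) but would want
  a compiled backend for production-sized imagery.
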
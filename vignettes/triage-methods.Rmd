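---
title: "Triage model, validation statistics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage model, validation statistics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drtriage)
```

## The problem and the model

Screening for diabetic retinopathy (DR) with one 45° posterior-pole
photograph per eye trades field coverage for throughput: one image, one
grader, one referral decision. The grader does the lesion detection; the
software's job is everything after that — a deterministic mapping from
*what was seen and where* to *when the patient should be seen again*.

`drtriage` models that mapping in three layers:

1. **Geometry** (`fundus_geometry`): the image is partitioned into four
   anatomical quadrants by the fovea–disc line and its perpendicular
   through the disc center, and into three macular zones by circles of
   radius 1 and 2 disc diameters (DD) around the fovea center. Point
   lesion annotations are aggregated into a per-eye grading form.
2. **Grading form** (`grading_model`): per quadrant, a pooled count of
   "small red dots/blots" (microaneurysms, dot-blot and flame
   hemorrhages), plus presence flags for hard exudates, cotton-wool
   spots, venous beading, IRMA (with a *prominent* qualifier), NVD and
   NVE; per macular zone, hard-exudate and red-dot flags; per eye, the
   two global lesions (vitreous/preretinal hemorrhage, detachment) and
   optionally visual acuity.
3. **Decision matrix** (`triage_engine`): a declarative rule table maps
   the form to colored marks, the maximum color (green < yellow < red)
   gives the eye's referral, acuity worse than 20/40 escalates yellow to
   red, and the patient follows the worse eye.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| hemorrhage threshold | > 20 per quadrant, all 4 quadrants | count | 4-2-1 severe-NPDR criterion; strict inequality (21 fires, 20 does not) |
| venous beading | ≥ 2 quadrants red, exactly 1 yellow | quadrants | 4-2-1 criterion |
| IRMA | prominent → red; present → yellow | flag | only *prominent* IRMA is a severe-NPDR sign |
| macular circles | 1 DD and 2 DD | disc diameters | inner findings → red (edema surrogate), mid → yellow |
| acuity escalation | decimal < 0.5 (20/40) | Snellen decimal | strictly worse than 20/40; 6/12 ≡ 20/40 does not escalate |
| line tolerance | 1e-9 · DD | pixels | boundary-tie classification (below) |

## Reconstructing the color matrix

The original triage chart is a figure whose individual cells are not
recoverable from text, so the matrix here is reconstructed from the
prose description of the green, yellow and red criteria and from the
international severity scale those criteria cite. Every cell lives in
one table (`default_color_matrix()`); the CLI's `--matrix` flag and the
`matrix` argument of `eye_referral()` swap in alternates, so a different
reconstruction is configuration, not code. Cells where the prose is
genuinely ambiguous, and the choices made:

- **Sparse red dots the grader cannot assert as microaneurysms-only**:
  yellow (the safer, earlier referral). The chart defines green as
  "microaneurysms only", but no photographic counting rule separates
  microaneurysms from small dot hemorrhages; the package therefore
  carries the distinction as a grader-asserted per-quadrant flag rather
  than pretending to derive it.
- **Macular edema surrogate**: any hard exudate or red dot/blot within
  1 DD of the fovea → red; within 1–2 DD → yellow. The chart lists
  "DME" among red boxes without defining its photographic surrogate;
  this operationalization is isolated in rules R8/Y6.
- **Cotton-wool spots**: yellow regardless of quadrant count — they are
  "more than just microaneurysms" but figure in no severe-NPDR rule.
- **Acuity escalation scope**: applies only when the pre-acuity color is
  yellow. A green eye with poor acuity stays green (the audit trail
  carries a warning note) — the escalation sentence is scoped to the
  6-month review case, and a form-complete green eye gives no DR ground
  for referral.
- **Severity side-channel**: `classify_severity()` counts mid-zone
  macular findings as moderate disease even when no quadrant flag is
  set, so that severity and referral remain mutually consistent for
  hand-written forms (geometry-built forms always set both).

## Geometry conventions

Axes are anatomical, not image axes: fundus photographs are routinely
rotated, and the chart's "horizontal" is *defined* by the two landmarks.
With u the unit vector from disc center to fovea center and v its +90°
rotation, a point's signed coordinates (a, b) on (u, v) decide temporal
(a > 0) versus nasal, and the sign of b decides superior versus inferior
after a laterality-aware flip chosen so that mirroring an image
left–right and swapping OD↔OS preserves every anatomical label.
Quadrant ids are fixed by documentation (1 superior-temporal,
2 inferior-temporal, 3 superior-nasal, 4 inferior-nasal); the original
figure's numbering is not legible from text, so the convention is the
package's own.

Ties: points within 1e-9·DD of a dividing line go to the temporal and
superior sides; macular intervals are half-open, closed at the lower
radius ([0, 1DD), [1DD, 2DD), [2DD, ∞)). Any fixed rule would do;
this one is documented and tested. The disc diameter is a supplied
scalar — the grader judges it visually — and is never estimated from
pixels.

## Validation statistics

Per referral category, reader responses are binarized one-vs-rest
against the specialist and pooled over readers (the published validation
analyzed its 99 readers this way; there is deliberately no multi-rater
Fleiss kappa). Missing responses are excluded pairwise, never imputed,
which reproduces the 4780-of-4950 response accounting of the packaged
fixture. Cohen's κ uses the large-sample SE
√(p_o(1−p_o)/(n(1−p_e)²)); agreement bands are applied to κ rounded to
two decimals, with closed interval endpoints as conventionally printed.

Confidence intervals are Wilson score by default (Wald available as a
config switch). The published intervals are not exactly recoverable
under either method at the stated rounding, so CIs are reported but not
asserted against any external value.

**AUC caveat.** With a single operating point the trapezoidal ROC area
collapses to (Se + Sp)/2. The published per-category AUCs do not satisfy
this identity against their own printed counts (e.g. 0.855 printed
vs 0.848 = (0.915 + 0.781)/2 computed for immediate referral); whatever
grouping the original statistics package used is not recoverable. The
package therefore reports its own well-defined AUC, with a
Hanley–McNeil SE, and never asserts it against published values. The
same applies to the subgroup tables, whose underlying counts are not
published: the "chi-square" behind the published subgroup p-values is
unnamed, and `compare_auc()`'s independent-groups z-test is a
documented stand-in (its output records the method).

Display rounding follows the published tables — κ to 3 decimals,
sensitivity/specificity as integer percentages *by truncation toward
zero* (91.50 → 91, 84.66 → 84, 95.63 → 95; plain rounding would
disagree with all three printed values), percent-correct to 1 decimal —
while all internal computation is full precision.

The sample-size estimate is the smallest N whose noncentral-χ² power at
noncentrality N·w² reaches the target; at df = 1 it agrees with the
closed form ⌈(z₁₋α/₂ + z_power)²/w²⌉ = 100 at α = 0.05, w = 0.3,
power 0.85.

## What the simulator emulates — and what it does not

`simulate_reader_study()` states the validation study's world as its
defaults: 50 images, 99 readers (≈ half students, one in ten with prior
grading experience), missing responses at rate 170/4950, gold-label mix
inferred from the published response margins (red-heavy:
0.502/0.260/0.238 for red/yellow/green — the per-image mix is not
published, so the response margin is the stated stand-in), and reader
behavior from a single 3×3 confusion matrix derived from the published
one-vs-rest margins. Those margins pin the 3×3 joint table down to one
free parameter; it is fixed so that misgraded immediate-referral images
fall entirely in the adjacent 6-month category, which reproduces every
published margin in expectation.

Readers are conditionally independent given the gold label. Real reader
studies violate this: images have difficulty, readers share training,
errors correlate. An optional per-image difficulty weight (mixing each
confusion row toward uniform) is provided but off by default. A green
simulation-based test therefore establishes that the *estimators*
recover known parameters under the stated model — not that the model
captures real inter-reader correlation structure.

`simulate_fundus_case()` constructs lesion sets whose triage outcome is
a certificate by construction (e.g. red via 21 hemorrhages per quadrant,
yellow via a single cotton-wool spot, green via microaneurysm-flagged
dots), placing quadrant lesions at perpendicular offsets above 2.5 DD so
no macular rule fires accidentally. It exercises every rule of the
matrix but makes no attempt at anatomical realism of lesion positions.

One acceptance property deserves a note: "simulated studies recover the
set sensitivity/specificity within Wilson 95% CIs in ≥ 90% of 200
replicates" is tested **per metric** (sensitivity covered in ≥ 90% of
replicates, and specificity likewise). The joint reading — both inside
their CIs in the same replicate — has expected pass rate ≈ 0.95² ≈ 0.90
and would be a coin flip at 200 replicates by construction, which
cannot have been the intent of a recovery check.

## Numerical and degenerate-input choices

- κ is undefined when p_e = 1 (both marginals degenerate); this raises a
  `degenerate-marginals` error rather than returning NaN. A category
  absent from both gold and responses (e.g. a tiny simulated study with
  no green images and perfect readers) hits this case by design.
- Sensitivity requires c + d > 0 and specificity a + b > 0; violations
  raise errors naming the empty margin.
- Forms are validated before triage; validation reports all violations
  (it never throws), while `eye_referral()` refuses invalid forms.
- Iteration order is deterministic everywhere (sorted reader and image
  ids), so identical seeds give byte-identical CSV outputs.
- All seeds are plain integers; the simulator is reproducible from its
  config alone.

## Known limitations

- The color matrix is a reconstruction; the original figure may differ
  in the ambiguous cells listed above. All such cells are config-visible.
- No image processing: fovea/disc landmarks and lesion positions are
  inputs. No gradability assessment.
- The one-field design itself (as opposed to 7-field ETDRS photography)
  bounds achievable sensitivity; nothing in the package corrects for
  lesions outside the photographed field.
- Pooled one-vs-rest statistics treat responses, not readers, as the
  unit; reader-level clustering is ignored exactly as in the published
  analysis it mirrors.
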
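# drtriage

Rule-based red–green–yellow referral triage for diabetic retinopathy (DR)
from single-field 45° posterior-pole fundus photographs, plus the
reader-study machinery used to validate such a triage chart against a
retina specialist's gold-standard grading.

## Who this is for

DR screening programs increasingly rely on non-specialist graders
(optometrists, physicians, trained paramedical staff) reading one fundus
photograph per eye. `drtriage` implements a simple color-coded triage
chart for that setting: the grader records which lesions are present and
in how many quadrants, and the chart maps those findings to one of three
referral intervals:

| Box    | Referral             | Clinical content |
|--------|----------------------|------------------|
| GREEN  | review in 1 year     | no DR, or mild NPDR (microaneurysms only), no macular edema |
| YELLOW | review in 6 months   | moderate NPDR: more than microaneurysms, less than severe NPDR |
| RED    | immediate referral   | severe NPDR (4-2-1 rule), proliferative DR, macular edema |

The 4-2-1 rule for severe non-proliferative DR: more than 20 intraretinal
hemorrhages in **each of 4** quadrants, definite venous beading in **2+**
quadrants, or prominent IRMA in **1+** quadrant. A yellow (6-month) eye
with visual acuity worse than 20/40 escalates to immediate referral; the
patient follows the worse eye.

Quadrants are anatomical, not image axes: the photograph is divided by the
line through the fovea and disc centers and its perpendicular through the
disc center. Macular edema is assessed in concentric circles of radius
1 and 2 disc diameters (DD) around the fovea center.

## Statistics

Validation of such a chart is a multi-reader study: each reader grades
each image, and per referral category the responses are binarized
one-vs-rest against the specialist. The package computes, per 2×2 table
with cells a (gold−, reader−), b (gold−, reader+), c (gold+, reader−),
d (gold+, reader+):

- Cohen's kappa κ = (p_o − p_e)/(1 − p_e), with large-sample
  SE(κ) = √(p_o(1 − p_o) / (n(1 − p_e)²)) and the conventional agreement
  bands (slight / fair / moderate / substantial / almost perfect);
- sensitivity d/(c+d) and specificity a/(a+b) with Wilson score 95%
  intervals (Wald optional);
- the single-operating-point AUC (Se + Sp)/2 with a Hanley–McNeil SE,
  and a two-sided z-test comparing two groups' AUCs;
- the chi-square sample-size estimate: smallest N with noncentral-χ²
  power ≥ target at noncentrality λ = N·w².

A reader-study simulator (per-reader 3×3 confusion matrices, missing
responses, optional per-image difficulty) and a fundus-annotation
simulator with certified triage outcomes make everything testable
without image data.

## Worked example

Aggregate point annotations into a grading form and triage the eye:

```r
library(drtriage)
lm <- fundus_landmarks(fovea_center = c(620, 480), disc_center = c(470, 500),
                       disc_diameter = 60, laterality = "OD")
lesions <- list(
  annotated_lesion("red_dots_blots", c(700, 300)),
  annotated_lesion("red_dots_blots", c(640, 460), microaneurysm = TRUE),
  annotated_lesion("hard_exudates", c(650, 495)),
  annotated_lesion("venous_abnormality", c(300, 250)))
form <- build_form(lesions, lm, va = visual_acuity(20, 30))
eye_referral(form)
#> <triage_result> referral: RED (immediate)
#>   severity: moderate_npdr + DME
#>   RED    R8: macular edema surrogate: lesions within 1 DD of fovea [macula inner]
#>   YELLOW Y1: red dots/blots beyond microaneurysms in 1+ quadrant [Q1]
#>   YELLOW Y2: hard exudates in any quadrant [Q2]
#>   YELLOW Y4: venous beading in exactly 1 quadrant [Q3]
```

The hard exudate at (650, 495) lies 31 px ≈ 0.5 DD from the fovea
center, i.e. inside the inner macular circle — the photographic surrogate
for macular edema — so the eye is referred immediately even though its
quadrant findings alone are only moderate.

The packaged validation-study fixture (99 readers × 50 images, 4780
responses) reproduces the published agreement statistics:

```r
tabs <- table2_confusions()
cohens_kappa(tabs$red)
#> kappa = 0.696 +/- 0.010 (substantial agreement; po = 0.848, pe = 0.500)
diagnostics(tabs$red)
#> Se 91% [90-93], Sp 78% [76-80], AUC 0.848 [0.837-0.859], correct 91.5%
sample_size_chisq(0.05, 0.3, 0.85, df = 1)
#> [1] 100
```

So 91.5% of immediate-referral images were correctly referred
(κ = 0.696, substantial agreement), with sensitivity 91% and specificity
78%; a study of this design needs 100 participants at α = 0.05, effect
size w = 0.3, power 0.85.

## Command line

```sh
Rscript inst/scripts/drtriage.R triage   --input forms.json [--matrix alt.json]
Rscript inst/scripts/drtriage.R zones    --input annotations.json --out zones.csv
Rscript inst/scripts/drtriage.R evaluate --gold gold.csv --responses resp.csv \
        [--readers readers.csv] [--by group|prior_grading|image-block=K]
Rscript inst/scripts/drtriage.R simulate --out-dir study/ --seed 7
```

Exit codes: 0 success, 2 validation error (JSON on stderr), 64 usage.

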
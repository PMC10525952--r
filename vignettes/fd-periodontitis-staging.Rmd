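---
title: "Methods: box-counting fractal dimension of trabecular bone and FD-based periodontitis staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-counting fractal dimension of trabecular bone and FD-based periodontitis staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioFD)
```

## Scope and model

`perioFD` implements a radiomorphometric pipeline for periodontitis:
trabecular texture extraction from a periapical radiograph ROI,
box-counting fractal dimension (FD), percent radiographic bone loss
from anatomical landmarks, the cohort statistics used to analyze such
studies, ROC-derived cutoffs, and an FD staging classifier. The working
hypothesis is morphological: healthy cancellous bone is a dense
branching lattice whose skeletonized radiographic texture is complex
(high FD); progressive demineralization removes struts and connectivity,
so FD falls with disease stage.

FD is defined operationally, not as a limit: cover the binary skeleton
with grids of box edge $s$, count occupied boxes $N(s)$, and take the
OLS slope of $\log N(s)$ on $\log(1/s)$. For exactly self-similar sets
this recovers the similarity dimension (the depth-4 Sierpinski carpet
gives $\log 8/\log 3 \approx 1.8928$ on a power-of-3 ladder, $r^2 = 1$,
verified in the test suite); for skeletons it is a finite-scale texture
descriptor whose value depends on the preprocessing and the size
ladder, which is why both are fixed and recorded in every run manifest.

## Preprocessing parameters

The ROI patch passes through blur → subtract+offset → binarize →
opening → skeletonize (`extract_skeleton()`); every intermediate is
retained. Defaults, units, and rationale:

| parameter | default | meaning |
|---|---|---|
| `blur_kernel_px` | 35 px | Gaussian kernel width; $\sigma$ = kernel/6. Sets the scale separating "background density" (removed) from "trabecular texture" (kept). The source protocol for this sequence used a 35-px kernel; it is configurable because ROI sizes vary. |
| `gray_offset` | 128 | value added after subtraction; recenters the background mid-gray so a symmetric threshold is meaningful. |
| `binarize_threshold` | 128 | strict `>` threshold at the offset. A uniform ROI therefore yields an empty skeleton (a desirable degenerate behavior: no texture, no trabeculae). |
| `apply_morph_cleanup` | TRUE | one 3×3 opening; removes single-pixel noise that would otherwise inflate small-box counts. |
| `invert` | FALSE | trabeculae assumed radiopaque (bright). The flag covers the opposite convention, which the original description leaves unstated. |

The reference study names the processing sequence but not the kernel
size or threshold mode. We fix a deterministic threshold (128, strict)
rather than an auto-threshold for reproducibility; whether the original
work used the software's automatic threshold is unknowable from the
text, so threshold choice is exposed as configuration and flagged as a
sensitivity knob.

Skeletonization is Zhang–Suen thinning plus a post-pass that deletes
simple (connectivity-preserving) pixels completing any remaining 2×2
solid block. Zhang–Suen alone can leave staircase blocks; the post-pass
enforces the one-pixel-wide invariant that box counting relies on
without changing component count. Borders are handled by edge
replication in the blur and by background padding in morphology.

## Box-counting choices

- Ladder {2, 3, 4, 6, 8, 12, 16, 32, 64}, filtered to `min(W, H)`: the
  default ladder of the ImageJ-style box counter such studies use. The
  original box-size ladder is not printed anywhere, so this default is a
  documented assumption and a parameter.
- Grid anchored at the top-left, partial edge boxes included, no
  multi-offset minimization (again matching the common implementation).
- Regression of $\log N$ on $\log(1/s)$, so the slope is the positive
  dimension; zero-count sizes are dropped (never imputed) and their
  number reported. Fewer than two usable sizes is an error; a flat
  curve (single pixel) yields slope 0 with undefined $r^2$ rather than
  an error.
- Correctness is established against a brute-force per-box occupancy
  oracle on random images, not against another library.

## Percent bone loss

$\%BL = 100\, d(\mathrm{CEJ}, \mathrm{defect}) / d(\mathrm{CEJ},
\mathrm{apex})$ with straight-line Euclidean distances between landmark
points. The source text defines the ratio without specifying whether
distances run along the root axis; point-to-point is the simplest
reading and is the default (an along-axis variant would require a root
axis estimate the data model does not carry). The published tables
report percentages, so the ratio is scaled by 100. Pixel spacing
cancels in the ratio; it only scales the reported distances. The
measure is invariant under rigid motion and uniform scaling of all
three landmarks (property-tested).

## Synthetic data: what it emulates, and what it does not

**Fixtures.** Analytic binary sets with known dimension anchor the
estimator: filled square (2), straight line (1), point (0), Sierpinski
carpet ($\log 8/\log 3$).

**Phantoms.** `synth_radiograph()` builds an 8-bit frame with a smooth
vertical illumination gradient and, inside the ROI rectangle, a
spectral-synthesis texture: white Gaussian noise shaped by a
$|f|^{-\beta/2}$ amplitude envelope and renormalized to a target SD
(default 30 gray levels). Landmarks sit on the ROI midline with the
defect at a configurable fraction of root length.

A design finding worth recording: one might expect "smoother texture
(larger $\beta$) → lower FD". For this pipeline the opposite holds over
the operating range. Near-white noise ($\beta \approx 0$) survives the
high-pass step only as uncorrelated speckle, which the opening removes;
the skeleton is sparse and FD low. Coherent texture ($\beta \approx 2$)
yields connected blobs whose skeletons are dense dendritic networks and
FD high. That direction is also the physically meaningful one —
demineralized bone has *less* coherent structure — so the stage mapping
`phantom_stage_params()` assigns **decreasing** $\beta$ (1.85 → 1.30)
from Control to stage IV. The mapping was calibrated once, at 256 px
with default segmentation, so the measured per-stage FD means track the
published Table of per-stage FDs (about 1.21 down to 1.02); it is then
frozen. The monotone property test asserts this calibrated direction
(higher $\beta$ → denser skeleton → higher FD) over seeds.

Phantoms emulate controllable texture roughness and landmark geometry.
They do **not** emulate anatomy: no root/PDL structures, no projection
geometry, no sensor noise model, no inter-patient positioning
variability. A green phantom test therefore establishes that the
pipeline measures texture coherence monotonically and reproducibly — it
does not establish clinical validity on real radiographs.

**Cohort simulator.** Each periodontitis stage draws $n$ subjects from
a bivariate normal over (%BL, FD) with the published stage means, SDs
and within-stage correlations; controls draw FD only (their %BL is
undefined). Bivariate normality is the simplest model consistent with
the printed moments — the source reports only mean/SD/median/range and
correlations — and the pooled-correlation acceptance check validates it:
the law of total covariance applied to the printed parameters predicts
a pooled staged-subject correlation near −0.74, matching the printed
−0.739, and the simulator reproduces it within ±0.02 over 200 seeds.
Bone loss is clipped to [0, 100] after sampling (clipping counted and
reported; with the printed SDs it is rare). Ages come from per-stage
age-band categorical distributions seeded from the modal bands the
study reports, with the remaining mass spread plausibly — the full
joint distribution is not printed, so these are free configuration, not
asserted facts; gender uses the cohort-wide 44/75 male fraction.

## Statistical components

- **Kruskal–Wallis**: midranks for ties, tie-corrected $H$, $p$ from
  $\chi^2_{k-1}$. An exact mode enumerates all assignments for tiny
  samples (used by the tests against an enumeration oracle). All pooled
  values identical is defined as $H = 0$, $p = 1$, not an error.
- **Power analysis**: $\lambda = n w^2$; critical value
  $\chi^2_{1-\alpha, df}$; power = upper tail of the noncentral
  $\chi^2(df, \lambda)$. This reproduces the published a priori block
  ($\lambda = 17.5$, critical 21.0260698, power 0.8046698 at $N = 70$,
  $w = 0.5$, $df = 12$, $\alpha = 0.05$) to printed precision, and the
  smallest $N$ reaching power 0.80 is 70 (binary search).
- **Pooled summaries**: $[\sum (n_i-1)s_i^2 + \sum n_i(m_i-\bar m)^2]
  / (\sum n_i - 1)$. Note the $N-1$ denominator means equal groups with
  zero between-group spread return the common SD only asymptotically
  (shrunk by $\sqrt{(N-k)/(N-1)}$); the identity is the one that
  reproduces the published "Total" rows exactly after rounding.
- **Shapiro–Wilk** delegates to the vetted standard routine; its
  coefficient tables are not re-derived.
- **ROC**: direction is "positive iff FD ≤ t" (low FD marks disease).
  AUC by the Mann–Whitney identity with ties counted ½, checked
  exactly against an all-pairs oracle. CI: Hanley–McNeil SE with logit
  transform — the original software is unnamed and its printed CIs
  cannot pin the method, so a reproducible closed form was chosen.
  Criterion: Youden's $J$, ties broken toward higher sensitivity (the
  "associated criterion" of MedCalc-style output; an assumption,
  documented). Sensitivity/specificity CIs: exact Clopper–Pearson,
  which uniquely matches the printed (78.2–100) bound for 15/15.
- **Staging rule**: cutoffs 1.188 / 1.158 / 1.102 ship as published
  constants with all boundaries closed on the disease side (every
  printed criterion is "≤"). They are *not* re-derived: the patient
  radiographs behind them are not deposited. On simulated cohorts only
  the qualitative AUC ordering across situations (#4 > #1 > #5,
  #2 ≈ #3) is checked.

## Numerical and degenerate-input conventions

- Strict `>` at binarization: a constant image at the offset maps to
  empty foreground, hence an empty skeleton, hence an empty-object
  error from box counting — FD of "no texture" is undefined, by design.
- CEJ coinciding with the apex is a degenerate-geometry error; defect
  at CEJ gives 0%, defect at apex 100%.
- Report display rounds half-up at printed precision (1 decimal for
  percents, 2–3 for FD/AUC); JSON retains full precision.
- All generators take a `seed` and restore the caller's RNG state;
  identical (params, seed) give bit-identical output, which the
  pipeline-level tests assert byte-for-byte on written files.

## File formats

Radiographs are read/written as PGM (plain P2 or binary P5, 8/16-bit),
a standard grayscale format with a dependency-free reader; PNG is read
when the `png` package is installed. TIFF/BMP/DICOM are out of scope.
ROI/landmark sidecars are JSON (`{"rect":[x,y,w,h],
"landmarks":{"cej":..,"defect":..,"apex":..}, "spacing_mm":..}`), with
0-based, top-left-origin, half-open rectangle coordinates — stated
explicitly to avoid off-by-one ambiguity.

## Known limitations

- The per-patient FDs, the printed AUCs, and the cutoffs as derived
  quantities cannot be reproduced without the original radiographs;
  the package reproduces the *procedures* and the desk-checkable
  numbers (power block, pooled rows, CP interval, pooled correlation,
  mean ranks under the printed parameterization).
- Stage III's positive within-stage correlation (0.226) is carried as a
  printed parameter, not explained mechanistically.
- No automatic landmark detection or tooth segmentation; landmarks are
  inputs.
- The FD value is protocol-relative: changing kernel, threshold mode or
  ladder shifts the scale, which is why the staging cutoffs should only
  be applied to FDs measured under the default protocol.
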
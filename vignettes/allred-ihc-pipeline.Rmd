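---
title: "From stained pixels to an Allred score: the ihcallred pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stained pixels to an Allred score: the ihcallred pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcallred)
```

## The problem

Hormone-receptor status in breast carcinoma — progesterone receptor (PR)
and estrogen receptor (ER) — is read from chromogenic
immunohistochemistry: a brown DAB (3,3′-diaminobenzidine) precipitate
marks receptor-positive nuclei, and a bluish hematoxylin counterstain
marks all nuclei. The clinical summary is the Allred score, the sum of a
proportion score $P \in \{0,\dots,5\}$ (how many nuclei are positive) and
an intensity score $I \in \{0,\dots,3\}$ (how strongly the dominant
positive population stains). Manual scoring is slow and varies between
observers; `ihcallred` implements an auditable per-nucleus pipeline —
every nucleus keeps its own statistic and class label, so the final score
can be traced back to individual cells.

## Stain model

Under the Beer–Lambert law, absorbances add linearly in optical density
(od). Each pixel's od vector is a non-negative mixture of unit stain
vectors:

$$\mathrm{od} = -\log_{10}\frac{\mathrm{rgb} + 1}{I_0 + 1}, \qquad
  \mathrm{od} = M\,c,\quad c \ge 0,$$

where the columns of $M$ are the hematoxylin, DAB and residual vectors
and $c$ the per-stain densities. We use the standard Ruifrok–Johnston
H-DAB vectors; the residual channel is completed per RGB channel as
$\sqrt{\max(0, 1 - H_i^2 - D_i^2)}$ and renormalised — the convention
used by the classical colour-deconvolution plugins — so that all
components are non-negative and the matrix is well conditioned
(condition number ≈ 4.7). Both the vectors and the background intensity
$I_0$ (default 255) are configurable for other scanners.

Two numerical choices deserve a note:

* **The $+1$ offset.** Placing the offset on both numerator and
  denominator makes od exactly 0 at a pure background pixel, keeps od
  non-negative for all `rgb <= I0`, and makes the forward renderer
  (`forward_mix()`) and the od transform an exact inverse pair up to
  8-bit rounding.
* **Quantisation limits.** An 8-bit image cannot represent arbitrarily
  large densities: one digital number at the dark end spans an od
  interval that grows like $1/(\mathrm{rgb}\,\ln 10)$. Round-tripping
  `deconvolve(forward_mix(c))` is accurate to better than 0.02 od over
  the range chromogenic tiles occupy at this normalisation (hematoxylin
  up to ~0.9 od, DAB up to ~0.35 od — verified in the test suite), but
  degrades without bound once mixed channel densities exceed ~2.4,
  where whole neighbourhoods of stain space collapse onto the same
  near-black 8-bit pixel. Deconvolution of such saturated corners is
  not invertible for *any* 8-bit forward model; this is a property of
  the representation, not of the implementation.

## Per-nucleus statistic and classification

The deconvolved DAB od is normalised by `od_reference` (default 1.0) and
clipped to $[0,1]$. For nucleus $i$ with pixel set $\Omega_i$,

$$\mu_i = 1 - \frac{1}{|\Omega_i|} \sum_{(x,y)\in\Omega_i} \mathrm{DAB}(x,y),$$

so unstained nuclei sit near 1.0 and strongly stained ones near 0.8 or
below. Classification applies three thresholds, boundary values joining
the weaker class:

$$C_i = \begin{cases}
\text{Strong} & \mu_i < \tau_1\\
\text{Moderate} & \tau_1 \le \mu_i < \tau_2\\
\text{Weak} & \tau_2 \le \mu_i < \tau_3\\
\text{Negative} & \mu_i \ge \tau_3
\end{cases}$$

The defaults $\tau = (0.89, 0.94, 0.975)$ suit PR tiles at the default
DAB scale. Because the absolute scale of $\mu$ depends on scanner and
stain batch, `calibrate_thresholds()` re-derives the triple from a small
annotated set: an exhaustive grid search (default grid $[0.5, 1.0]$,
step 0.005 — chosen so the default triple lies on the grid) over all
monotone triples, maximising macro-F1 (or accuracy). Ties are broken to
the lexicographically smallest triple so calibration is deterministic.
Per grid point the per-class counts of $\mu$ values below it are
precomputed from sorted arrays, so each triple's 4×4 confusion table is
assembled in O(1) and the ~1.7×10⁵ triples are scored in well under a
second.

## Instance masks and postprocessing

Masks may come from a file (16-bit label rasters), from an external
segmenter through an adapter, or from the built-in classical fallback:
Otsu threshold on combined nuclear od, then a watershed on the distance
transform with local-maximum seeds. All sources share one postprocessing
contract: objects (8-connected same-label components) with area
strictly below `min_area = 20` px are removed, interior holes are
filled, fragments of one input label that touch after filling are
merged, and labels are renumbered 1..N in raster-scan order. A second
hole-fill after merging makes the operation idempotent (two C-shaped
fragments can enclose a new hole when merged). 8-connectivity and
adjacency-only merging (no distance-based merging) are deliberate,
conservative choices; both are configurable.

## Scoring

Nucleus counts map to the Allred components:

* Positive percentage $= 100\,(S+M+W)/N$; an image with zero nuclei is
  an *error*, not a 0% — silently scoring an empty region would
  fabricate a negative diagnosis.
* $P$: 0 at exactly 0%; 1 on $(0,1)$; 2 on $[1,10]$; 3 on $(10,33]$;
  4 on $(33,66]$; 5 above 66. The published bin labels are integer
  ranges, which leave real-valued percentages such as 65.79 or 66.08
  unassigned; the right-closed intervals used here are the unique
  simple completion consistent with every row of the bundled reference
  table (`allred_reference_counts()`), which contains both 65.79% → 4
  and 66.08% → 5. Whether the upper edge is `> 66` or `>= 66` cannot be
  distinguished from the reference data (no case falls between 66 and
  66.08); `> 66` is used.
* $I$: the mode of the positive classes (Strong = 3, Moderate = 2,
  Weak = 1), ties broken toward the stronger class — forced by the
  reference rows with 16/16 moderate–weak and 19/19 strong–weak ties —
  and 0 when no nucleus is positive.
* Total $= P + I \in \{0\} \cup \{2,\dots,8\}$ (1 is unreachable since
  $P = 0 \iff I = 0$); totals 0 and 2 are reported as negative, 3–8 as
  positive.

## Evaluation metrics

Segmentation is scored at pixel level (precision, recall, F1/Dice, IoU
on the foreground union), with 0/0 ratios defined as 0 with a warning —
the conservative convention. An instance-level matched F1 (greedy
matching by descending IoU at a 0.5 threshold) is provided under a
separate name for object-level comparisons. Classification is scored by
a 4×4 confusion matrix and macro-F1. The macro average runs over classes
with evidence in the ground truth or prediction; classes absent from
both are dropped with a warning rather than contributing a spurious 0 —
on calibration sets, where all four classes are present, the two
conventions coincide.

## The synthetic generator

`generate_tile()` renders what the analysis assumes, and only that:
constant-od ellipses (hematoxylin 0.35–0.65 od) on a faintly
counterstained background (0.02 od), with class-specific DAB od drawn
from bands that map strictly inside the four $\mu$ bands
(Strong ≈ 0.80–0.85, Moderate ≈ 0.90–0.93, Weak ≈ 0.95–0.97,
Negative ≈ 0.98–1.0 under the default thresholds). Placement is
rejection sampling under an overlap budget; each tile is verified
through the real analysis path and any nucleus whose realised $\mu$
lands outside its band has its DAB od redrawn (at most 100 rounds).
One integer seed drives the whole generator reproducibly and the
caller's RNG stream is left untouched.

What the generator deliberately does **not** emulate: chromatin
texture, blur and uneven illumination, stain colocalisation gradients,
out-of-focus debris, background brown wash (available as an option),
and densely packed overlapping sheets of nuclei. Passing tests on
synthetic tiles therefore validate the *computational contract* —
deconvolution, statistics, thresholds, scoring — not segmentation
robustness on clinical material, which depends on the mask source.

Default problem sizes used by the tests: 256×256 tiles with 20 nuclei,
2000-pair calibration sets, and 8×8 rasters for brute-force metric
oracles — small enough to run the whole suite in seconds while leaving
every code path exercised.

## Known limitations

* Stain vectors are fixed per run; per-slide stain estimation
  (Macenko/Vahadane-style) and cross-slide normalisation are out of
  scope.
* The printed default thresholds do not transfer across scanners or
  od scales; recalibrate from a small annotated set instead.
* Scores are per-ROI; whole-slide aggregation and tiling are not
  provided.
* Very low positive fractions are sensitive to background brown; a
  low-positive floor rule is intentionally not applied, so borderline
  cases surface to the reader rather than being silently suppressed.
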
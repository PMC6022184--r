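---
title: "Supervoxel histons for tissue-probability MRI classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervoxel histons for tissue-probability MRI classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svhiston)
```

## The problem

Alzheimer's disease manifests in structural MRI as grey-matter atrophy and,
in the tissue-probability maps produced by unified segmentation, as a growing
population of *ambiguous* voxels — voxels the segmenter cannot confidently
assign to grey matter (GM), white matter (WM) or cerebrospinal fluid (CSF).
A subject is therefore represented here by three co-registered probability
volumes, one per tissue, treated as the three channels of a colour volume.

The package turns that triplet into a single textural descriptor — a
**supervoxel-based volumetric histon** — and classifies subjects
(AD vs. cognitively normal, with AD the positive class) using PCA reduction
followed by a linear soft-margin SVM, evaluated under a repeated stratified
split protocol.

## The feature

A histon augments an intensity histogram with spatial context: every voxel
contributes 1 to the bin of its intensity, plus 1 more if it lies inside a
"similar colour sphere" of its neighbourhood. Formally, for tissue channel
$v_i$ with intensity levels $g \in \{0,\dots,255\}$,

$$H_{v_i}(g) \;=\; \sum_{\mathbf{x}} \bigl(1 + S_2(\mathbf{x})\bigr)\,
\delta\!\left(I(\mathbf{x}, v_i) - g\right),$$

so bin-wise $\mathrm{hist}(g) \le H(g) \le 2\,\mathrm{hist}(g)$ and the total
histon mass equals the masked voxel count plus the number of similar voxels.
Two equal histograms can yield very different histons: the similarity
indicator $S_2$ carries the spatial structure.

Instead of a fixed cubic neighbourhood, the neighbourhood system is an
over-segmentation into **supervoxels** (3D SLIC over the three quantized
tissue channels). A voxel is similar ($S_2 = 1$) when, *in every tissue
channel*, its intensity lies strictly within the expanse threshold $E_{v_i}$
of its supervoxel's mean intensity:

$$S_2(\mathbf{x}) = 1 \iff \forall v_i:\;
\bigl|I(\mathbf{x}, v_i) - \bar I_{C(\mathbf{x})}(v_i)\bigr| < E_{v_i}.$$

The conjunction is shared by all three per-tissue histons. The subject's
feature vector is the concatenation of the three 256-bin histons in the
fixed order GM, WM, CSF — 768 components.

### The expanse threshold: two modes

The natural radius for a similarity sphere is a *deviation*: the default
mode `mean_of_sds` sets $E_{v_i}$ to the mean over supervoxels of the
per-supervoxel population standard deviation of channel $v_i$ — the average
local deviation of the volume in the supervoxel-defined space. A second
mode, `mean_of_means`, averages the supervoxel *mean* intensities instead.
It is kept behind a flag for fidelity experiments: on a bright channel it
makes nearly every voxel similar (and on a constant volume it declares the
whole volume similar, while `mean_of_sds` gives $E = 0$ and, by the strict
inequality, no similar voxels at all). The two modes genuinely diverge and
only `mean_of_sds` behaves like a local-homogeneity radius, which is why it
is the default; no claim is made about which variant produced any published
figure.

A related interpretation choice: the supervoxel's reference intensity is its
*mean* per channel, not the intensity at the voxel nearest its spatial
centroid. The mean is the quantity the segmentation's k-means update already
maintains and is robust on small supervoxels.

## 3D SLIC

Segmentation is a spatially constrained k-means. Seeds are laid on a regular
lattice with spacing $I_n = \mathrm{round}\bigl((\text{masked voxels}/
N_s)^{1/3}\bigr)$; seeds falling outside the brain mask move to the nearest
masked voxel. Each masked voxel within a search cube of half-width $2 I_n$
of a centroid competes under

$$D_w = \sqrt{\left(\frac{d_c}{m}\right)^2 +
\left(\frac{d_s}{I_n}\right)^2},$$

with $d_c$ the Euclidean distance over the three 8-bit tissue channels and
$d_s$ the Euclidean voxel distance. Note the form: the intensity term is
normalized by the compactness $m$ directly; the alternative
$m\,d_s/I_n$ weighting found elsewhere in the superpixel literature is *not*
used. Ties go to the lower centroid index, making the segmentation fully
deterministic — the `seed` slot in `slic_params()` is recorded for
provenance only. Masked voxels outside every search window (possible with
ragged masks) are assigned to the globally nearest centroid and counted in a
message.

Defaults: $m = 10$ on the 0–255 scale, 10 iterations with early stop when
the total L1 centroid displacement falls below one voxel, and a
brain-scale target of 1000 supervoxels (tests and the bundled synthetic
study use 300 at $48^3$; per-supervoxel *averages* such as the expanse are
robust to moderate changes of the target, which is itself only a target —
the realized count depends on mask geometry and connectivity enforcement).

### Connectivity enforcement

k-means assignment can leave a label spatially fragmented. Connected
components are found under 6-connectivity; components smaller than
`min_region_frac` (default 0.25) times the nominal supervoxel volume
$I_n^3$ are absorbed into their largest adjacent component. Merging alone
cannot guarantee connectivity — a label can split into two *large*
components — so every surviving component then receives its own label.
This keeps both properties at once: no dust-sized fragments, and every
final label 6-connected. The label count may therefore differ from the
target in either direction.

## Masking and quantization

All computation is restricted to a brain mask: voxels with
GM + WM + CSF $> 0$ (threshold configurable). The background of a
probability map is constant zero; including it would swamp bin 0 of every
histon with uninformative counts. Probabilities are quantized to 8-bit
levels by round-half-up, $q = \lfloor 255\,v + 0.5\rfloor$ — any consistent
rule would do; this one is documented and tested (e.g. $v = 0.5 \mapsto
128$). Inputs stored as integer maps are accepted as already quantized.
Whether upstream probability maps were modulated or not is deliberately not
inspected: the pipeline consumes whatever co-registered maps it is given
and the assumption belongs to the caller.

## Classification

* **Standardization + PCA.** Columns are centred and scaled to unit
  variance using *training rows only*; zero-variance columns are dropped
  with a message. The scree elbow is automated as the component index with
  the largest drop between consecutive eigenvalues (floor 2, ceiling 30,
  fallback 5 when the spectrum is degenerate); an explicit component count
  can be given instead.
* **SVM.** The standard R implementation (`e1071::svm`) with its default
  parameters — cost 1, $\gamma = 1/\text{dimension}$, degree 3 — and no
  hyperparameter search for the histon pipeline. Linear kernel by default;
  polynomial and radial are available, and `compare_kernels()` tabulates
  all three on identical splits.
* **Split protocol.** Ten random 80/20 splits stratified on the joint
  (label, gender, age-decade) cells with largest-remainder allocation of
  test slots. Strata of size one trigger a collapse (age dropped first,
  then gender) with a warning. Seven metrics are reported per split and as
  means: Acc, Bacc $= (\mathrm{Sen}+\mathrm{Spe})/2$, NPV, PPV, Sen, Spe
  and F-score. Zero-denominator ratios are `NA` with a warning, never a
  silent 0.
* **Baseline + McNemar.** The comparison baseline classifies flattened GM
  voxel vectors with a linear SVM whose cost is grid-searched over
  $2^{-5}..2^5$ by inner 5-fold CV on balanced accuracy (ties to the
  smallest cost; deterministic label-stratified round-robin folds). Because
  a linear SVM only sees dot products, the voxel matrix is first rotated
  onto a training-derived orthonormal basis (SVD), which preserves every
  kernel value and decision value at a fraction of the cost. Paired
  performance is compared with McNemar's continuity-corrected chi-square
  statistic $(|b-c|-1)^2/(b+c)$ on the discordant counts; $b+c=0$ gives
  $p=1$, and an exact binomial variant is available because the chi-square
  approximation is poor for small discordant counts.

No leakage anywhere: PCA, scaling and the SVM see training rows only, and a
test perturbing held-out rows asserts the fitted model is bit-identical.

## The synthetic phantom generator

Real preprocessed data cannot ship with the package, so every stage is
exercised on synthetic cohorts that emulate unified-segmentation output:
concentric smoothed ellipsoids — WM core, GM shell, CSF rim, with fixed
mild anisotropy (1, 0.9, 0.8) — whose tissue probabilities transition over
a band of width $\omega$ voxels (cubic smoothstep, compact support, so the
background is exactly zero and the mask is head-sized). Gaussian
segmentation noise (sd $\sigma$) is added inside the head only, clipped to
$[0,1]$ and renormalized where the sum exceeds 1.

The two class effects mirror the disease signature and are deliberately
orthogonal knobs:

* `delta_gm`: the AD class moves this fraction of GM probability mass into
  CSF (atrophy). With $\sigma = 0$ the removal is exact and total tissue
  mass is conserved.
* `omega_ad` vs `omega_cn`: a wider transition zone in AD produces more
  intermediate-probability (ambiguous) voxels. This knob connects directly
  to the feature's mechanism: the mean supervoxel GM deviation — the
  default expanse — rises with $\omega$ over the moderate range (on small
  grids very wide transitions overlap and smooth the contrast away again,
  so tests probe $\omega \le 3$ at $24^3$).

Cohort generation derives per-subject seeds and ±5% radius jitters from a
master seed; ages are uniform on 60–90 and genders balanced within class,
giving the stratified splitter realistic strata. Defaults are the bundled
study conditions: $48^3$ grids, 20 + 20 subjects, `delta_gm` 0.2,
$\omega$ 3 vs 1, $\sigma = 0.02$ — sized to run in minutes on one CPU.

What the phantoms do *not* model: anatomy (no gyri, hippocampus or
ventricles), registration error, bias fields, scanner artefacts, or
age/gender-correlated effects. Passing tests therefore demonstrate that the
implementation is faithful and that the feature detects the two modelled
effects; they say nothing about discrimination on real clinical cohorts,
whose effect sizes and confounds are far less tidy.

## The ablation study (histon vs. plain histogram)

To show the similarity term matters, the pipeline is run twice on the same
cohort: once normally and once with $S_2$ forced to 0 (`histogram_only`),
which reduces every feature to the plain 768-bin histogram concatenation.
Designing this comparison needs care: with a generous class contrast both
arms sit at a balanced accuracy of 1.0 and the comparison is vacuous. The
regime was therefore chosen by a rule that looks only at the *control* arm:
shrink the ambiguity contrast and raise the noise until the histogram
pipeline drops clearly off ceiling (`delta_gm` 0, $\omega$ 2.2 vs 1.8,
$\sigma = 0.10$), then compare both arms on several fixed cohort seeds.
Higher noise is exactly where the supervoxel term should help: supervoxel
means average the voxel noise away, so the similar-voxel counts are a
cleaner carrier of the ambiguity signal than the raw, smeared histogram.

## Numerical choices and degenerate inputs

* Strict inequality in the similarity test, as a similarity *sphere*
  boundary: on a constant volume with `mean_of_sds` the expanse is 0 and
  nothing is similar (histon = histogram), rather than everything.
* Population (divisor $N$) standard deviations per supervoxel; single-voxel
  supervoxels get sd 0.
* Round-half-up quantization; re-quantizing at the same level count is the
  identity on the integers.
* Empty masks are a hard error at feature extraction; a labeling with an
  empty label violates an invariant and errors in the statistics pass.
* All randomness (cohorts, split plans) flows from explicit integer seeds;
  the segmentation itself is deterministic.

## Known limitations

* Whole-brain histons carry no anatomical localization; two very different
  atrophy patterns with the same probability texture are indistinguishable.
* The realized supervoxel count is data-dependent; only averages over
  supervoxels are stable across reasonable targets.
* The scree automation is a heuristic for a visual judgement; for small
  eigen-spectra it clamps to its floor of 2 components.
* `mean_of_means` mode is provided for completeness but is not a sensible
  similarity radius (see above).

## Problem sizes used by the bundled tests

Unit tests run on $\le 8^3$ oracle fixtures and $16^3$–$24^3$ phantoms; the
end-to-end studies use the default $48^3$, 20 + 20 cohorts with 300
supervoxels and 10 splits. These sizes were chosen as the smallest at which
every mechanism under test is comfortably expressed.
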
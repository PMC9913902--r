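---
title: "Methods: entropy-driven thresholding segmentation and ensemble screening of brain MRI slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-driven thresholding segmentation and ensemble screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidermri)
```

## The problem and the pipeline

`spidermri` implements a classical (non-deep-learning) screening pipeline
for single 2-D brain MRI slices with a binary outcome, normal vs tumor.
Four stages run in order:

1. **Preprocessing** — the dark scanner background is removed by
   binarizing at 5% of the 8-bit range (cut $0.05 \times (2^8-1) = 12.75$,
   so integer intensity 12 is background and 13 is head), keeping the
   largest 8-connected foreground component, filling its interior holes
   (4-connected background regions not reachable from the border), and
   multiplying the image by the resulting head mask. The foreground image
   is then reduced by non-overlapping $2\times2$ block averaging
   (250×250 → 125×125).
2. **Segmentation** — multilevel thresholding with $m = C-1$ cut points
   maximizing a Tsallis-entropy objective, searched by a social spider
   optimizer. Pixel values collapse from $[0,255]$ to region labels
   $[1, C]$, with $C = 5$ by default (background, skull, outer tissue,
   inner tissue, lesion).
3. **Feature extraction** — the corpus of flattened label maps forms a
   $P \times S$ matrix ($P$ samples, $S$ pixels); its thin SVD
   $R = U \Sigma V^\top$ is truncated at the smallest rank $N$ whose
   leading squared singular values reach 99% of the total squared
   spectrum, and images are embedded as $x V_N \in \mathbb{R}^N$.
4. **Classification** — a linear-kernel soft-margin SVM, a Gaussian naive
   Bayes, and a 3-nearest-neighbour classifier vote; the majority of the
   three 0/1 votes is the screening call, and the fraction of tumor votes
   (0, 1/3, 2/3, 1) serves as the ROC score.

Evaluation uses repeated stratified 70/30 holdout (20 repetitions,
default) or stratified 10-fold cross-validation, reporting per-repetition
accuracies, a pooled confusion matrix with tumor as the positive class,
sensitivity $100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$, specificity
$100\,\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})$, and a trapezoidal AUC.

## The Tsallis thresholding objective

For a histogram $p_0,\dots,p_{255}$ and entropic index $q > 0, q \neq 1$,
the Tsallis entropy is $S_q = (1 - \sum_i p_i^q)/(q-1)$, recovering the
Shannon entropy as $q \to 1$ (tested at $q = 1 \pm 10^{-4}$ within
$10^{-3}$). Thresholds $t_1 < \dots < t_m$ partition the intensity axis
into regions $[0, t_1-1], [t_1, t_2-1], \dots, [t_m, 255]$; each
non-empty region contributes the Tsallis entropy of its renormalized
within-region distribution, and the per-region entropies combine
pseudo-additively:

$$ F(t_1,\dots,t_m) \;=\; \sum_j S_q^{(j)} \;+\; (1-q) \prod_j S_q^{(j)}. $$

Numerical and boundary choices, all tested:

* **Empty regions** contribute 0 (and therefore zero the product term);
  no penalty is applied, keeping the search space smooth.
* **$m = 0$** reduces to the plain Tsallis entropy of the histogram. The
  literal pseudo-additive formula would give $S + (1-q)S$ for a single
  region, which contradicts that reduction; the combination term is
  therefore applied only between two or more regions.
* **Degenerate candidates** (duplicate thresholds after rounding) are
  repaired by sorting and bumping collisions upward one level.
* **Conventions**: thresholds are stored lower-inclusive internally
  (region $j$ starts at $t_{j-1}$); user-facing solution vectors use
  inclusive upper bounds (an entry of 20 means intensities 0–20 are
  region 1). `thresholds_to_upper()`/`upper_to_thresholds()` convert and
  are tested as inverses.
* **Histogram scope**: all pixels are counted, including the zeros
  produced by background removal — the background is deliberately its own
  intensity region.
* **Entropic index**: the experiments behind the reference method never
  state $q$; the package default is $q = 0.8$, configurable everywhere.

**What entropy optimization does *not* promise.** On histograms that are
nearly sums of delta spikes (e.g. a noise-free phantom), the maximizer
provably prefers keeping several spikes inside one region (positive
within-region entropy) over isolating degenerate single-spike regions
(zero entropy), and spends thresholds on the sparsely populated
"dust" between modes created by block averaging. Consequently the
optimal $C=5$ segmentation of a noise-free phantom merges
{background, outer tissue} and {skull, lesion} rather than reproducing
the five anatomical regions one-to-one. The segmentation is still a
deterministic, monotone, class-discriminating quantization — which is
what the downstream stages need — but a green segmentation test
establishes optimality of the objective, not anatomical alignment.

## The social spider optimizer

Candidate threshold vectors are "spiders" at continuous positions inside
per-dimension bounds ($[1, 254]$ for image segmentation). Each iteration:

* every spider emits a vibration with intensity
  $I = \log\!\big(1/(C_t - f) + 1\big)$, where $f$ is its fitness and
  $C_t$ is one unit above the iteration's best fitness, making intensity
  strictly increasing in fitness (the reference formulation is written
  for minimization; this is its mirror image);
* vibrations attenuate as $I \exp(-d / (\bar\sigma\, r_a))$ with
  Euclidean distance $d$ and $\bar\sigma$ the mean per-dimension standard
  deviation of positions, so attenuation is scale-free;
* each spider takes the strongest received vibration, keeps it only if it
  beats its stored target, and random-walks toward the target with
  inertia, masking a random subset of dimensions (mask resampled with
  probability $p_c = 0.7$, bits set with probability $p_m = 0.1$) toward
  random spiders' coordinates for exploration;
* positions clamp to the bounds; the best-ever position is elitist-tracked
  (the fitness trace is non-decreasing by construction).

Defaults (population 25, 100 iterations, $r_a = 1$) follow the reference
formulation's reported settings; the population size is fixed across
iterations. Integer thresholds are handled by rounding at objective
evaluation, so the optimizer can never exceed the discrete optimum — an
exhaustive enumerator (`exhaustive_thresholds()`, guarded by a
combinatorial cap) provides the oracle, and the acceptance suite checks
equality of optima on 100 seeded ≤32-level instances (≥95 matches
required; the build achieves 98, with zero exceedances).

## SVD features

With samples as rows ($P \times S$; the only dimensionally coherent
orientation for the feature equation $F = U_N \Sigma_N$), the truncated
right basis $V_N$ is fit **on training rows only** within every
evaluation split; test images are embedded as $x V_N$. This is the
standard leakage-safe truncated-SVD embedding; whether the original
experiments fit jointly on train+test is unknown. The 99% energy default
reflects the stated ~1% noise energy of brain MR images. Region labels
enter the matrix as raw values 1…C — the range reduction *is* the point
of segmenting before decomposition.

## The ensemble

* **SVM**: linear kernel, soft margin with $c = 1$, fit by solving the
  dual box-constrained QP with `quadprog` (deterministic; a ridge of
  relative size $10^{-10}$ keeps the Gram matrix positive definite). Only
  the kernel is specified by the reference method; the cost and solver
  are package choices.
* **Naive Bayes**: Gaussian per-feature likelihoods per class with a
  $10^{-9}$ variance floor and empirical priors; prediction is maximum
  posterior, ties to normal.
* **KNN**: $k = 3$, Euclidean distance; distance ties prefer the
  normal-class neighbour. With two classes and three neighbours, vote
  ties cannot occur.
* **Voting**: majority of the three 0/1 votes (a strict majority always
  exists); `vote_score()` returns the tumor-vote fraction, and
  thresholding it at 0.5 reproduces the majority label exactly (tested
  over all 8 vote patterns).

All tie rules resolve toward "normal" — deterministic and conservative
toward fewer false tumor calls. Features are not standardized by default
(the reference method is silent); `standardize = TRUE` enables z-scoring
from training statistics.

## The phantom generator: what it emulates and what it does not

Real reference datasets (120 balanced 250×250 MRI slices; a larger
3000-slice collection) are external and not redistributable, so the
package generates synthetic head phantoms with ground truth. The design
follows the Shepp–Logan tradition: **fixed procedural geometry** — an
elliptical head (semi-axes 0.42/0.35 of the image side) with a bright
skull annulus (inner edge at 0.88 of the head radii), an outer-tissue
shell, an inner-tissue core (0.55 of the brain radii), and, for tumor
samples, one elliptical lesion — plus per-region Gaussian intensity
variation and global additive Gaussian noise, clipped to $[0,255]$.

Defaults and why:

* intensity means 5 (background), 90 (outer), 140 (inner), 200 (lesion),
  230 (skull): strictly ordered, background safely below the 12.75
  binarization cut, neighbouring regimes separated by ≥4 SDs so that
  5-region thresholding is well posed;
* per-region SD 6 (2 for background), global noise SD 3 — "moderate"
  acquisition noise in line with the ~1% noise-energy assumption behind
  the 99% rank rule;
* lesions are **deep-seated**: radii are drawn uniformly from 0.18–0.38
  of the brain radius (prominent lesions, as on a diagnostic slice curated
  to cut through the tumor) with mild axis anisotropy (±8%), and centers
  fall within 0.15 brain radii of the brain center. Deep placement makes
  lesions across subjects share a central footprint, so tumor samples
  form a coherent cluster in pixel space — the property that makes all
  three base classifiers, including KNN, strong on this data, mirroring
  the reference results qualitatively (ensemble on top, KNN weakest).

The generator deliberately does **not** emulate: anatomical variability
across subjects (head pose, scale, or shape — geometry is fixed by
design), arbitrary lesion locations (cortical/peripheral tumors),
multi-focal disease, MR physics (bias fields, partial volume beyond the
2×2 averaging, Rician noise), or volumetric context. A green end-to-end
test therefore establishes that the pipeline's stages compose correctly
and recover a separable class structure — not clinical performance on
real MRI.

During development the generator initially used randomly jittered head
geometry and uniformly placed lesions; variance decomposition showed the
geometry jitter contributed two orders of magnitude more within-class
variance than the noise model, and uniformly placed lesions make two
tumor images farther apart than a tumor–normal pair (nearest-neighbour
structure inverts). Both properties contradict the separable regime this
synthetic world is specified to represent, so the geometry was fixed and
the placement made deep-seated — settled once, documented here.

## Evaluation choices

* Tumor is the positive class in every rate (the reference tables appear
  to swap the sensitivity/specificity column labels relative to their own
  confusion-matrix narrative; this package follows the defining
  equations and reports all four counts).
* Splits and folds are stratified, guaranteeing both classes in every
  test set; the pooled confusion matrix concatenates all repetitions'
  test predictions.
* ROC ties are grouped at one threshold; with vote scores the curve has
  at most 5 points; constant scores give AUC 0.5 by the tie convention.
* A single repetition reports standard deviation 0 (not NA) by definition.

## Reproducibility and budgets

One global seed fans out to per-stage seeds through a stable string hash
(`phantom`, `segment/<i>`, `evaluate`), so partial reruns reproduce
stage-for-stage and full runs are byte-identical. Identical configs give
byte-identical report JSON (tested). The default 120-phantom end-to-end
evaluation runs in about a minute on one CPU; unit tests use 64-pixel
phantoms and reduced optimizer budgets, while the acceptance suite runs
the full default world once.

## Known limitations

* Entropy-optimal thresholds do not align with anatomical regions on
  spiky histograms (see above); region *identity* across images is
  approximate, which the SVD stage absorbs in practice.
* The exhaustive oracle is capped combinatorially
  (`choose(candidates, m)` ≤ 2×10⁵); full 256-level enumeration at
  $m \ge 3$ errors with a pointer to the SSO search.
* TIFF input is not supported (no TIFF reader among the package's
  dependencies); PNG is the on-disk image format.
* The linear SVM uses a dense dual QP — fine for hundreds of samples,
  not for thousands; the reference protocol for large collections
  (10-fold CV on 3000 slices) is implemented but slow in that regime.
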
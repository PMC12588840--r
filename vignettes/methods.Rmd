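---
title: "Bayesian segmentation of glioma follow-up MRI: models, losses and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian segmentation of glioma follow-up MRI: models, losses and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioseg)
```

## The problem

Follow-up MRI of glioblastoma patients is harder to segment than
preoperative imaging: surgery leaves a resection cavity (labeled
background), chemoradiation changes tissue signal, and tumor subregions
are often fragmented rather than contiguous. Three subregions matter
clinically: the FLAIR-hyperintense region (FHR, edema/infiltration,
bright on T2-FLAIR), the enhancing region (ER, bright on T1+gadolinium),
and the non-enhancing necrotic region (NENR, dark on T1+Gd), which is
rare in follow-up cohorts (roughly 47 of 311 cases). Because background
dominates — typically more than 95 % of voxels — misclassifying lesion
voxels *as background* is the characteristic failure mode.

`glioseg` implements a complete, desk-scale version of an
uncertainty-aware segmentation framework for this setting:

1. a 3D encoder–decoder network whose decoder convolutions are
   variational (Flipout-style) layers, giving a weight posterior rather
   than a point estimate;
2. a composite region + distribution objective (generalized Dice loss +
   focal loss + Kullback–Leibler weight penalty + an auxiliary NENR
   cross-entropy);
3. dual-branch transfer learning: a branch pretrained on
   preoperative-style data is frozen and fused, by element-wise feature
   sum, with a scratch branch trained on follow-up data;
4. Monte-Carlo posterior sampling at inference and an
   uncertainty-guided relabeling rule that rescues lesion voxels
   misclassified as background;
5. a full evaluation suite: overlap (DSC/JI/HD), calibration
   (ECE/UCE/Brier/NLL), selective prediction (reliability,
   error-detection ROC, risk–coverage), paired Wilcoxon comparison and
   bias-field robustness.

Everything runs end-to-end on generated multi-modal brain phantoms, so
the package needs no clinical data.

## The phantom generator

`phantom_spec()` / `generate_phantom()` produce 4-channel volumes (T1,
T1+Gd, T2, FLAIR) with ground-truth labels. The generator is a
*statistical stand-in* for follow-up MRI, not a physical MR simulation
(no Bloch equations, no k-space, no anatomy beyond an ellipsoidal head):

* **Geometry.** Each lesion is built from nested thresholds of one
  ellipsoidal quadratic form: NENR at normalized radius ≤ 0.30, ER
  ≤ 0.65, the FHR envelope ≤ 1 (union with a second, overlapping
  ellipsoid for lumpiness). Nested thresholds guarantee morphological
  containment — every 26-neighbor of a NENR voxel is NENR or ER, and the
  ER+NENR core is enclosed by the envelope — provided each shell is
  thicker than one diagonal voxel step, which holds for the default
  32-voxel phantoms (lesion semi-axes ≥ 5 voxels). Below roughly 24
  voxels per axis the shells may voxelize away; tiny phantoms used in
  plumbing tests do not rely on the containment property.
* **Rare necrosis.** A phantom contains NENR with probability
  `nenr_prevalence`, default 47/311 ≈ 0.151, the follow-up prevalence
  the framework is designed around. Preoperative-style corpora
  (`phantom_corpus(..., preoperative = TRUE)`) use 0.9 and no cavity,
  mimicking the preoperative setting where necrosis is common.
* **Fragmentation.** With probability `fragmentation` (default 0.3) a
  detached satellite (a small ER core inside its own FHR halo) is
  placed, so the ER subregion has ≥ 2 connected components — the
  non-contiguity typical of follow-up scans.
* **Cavity.** With `cavity = TRUE` a CSF-like ellipsoid tangent to the
  lesion is carved and labeled background, mirroring resection cavities.
* **Intensity.** Per-tissue contrast means encode the clinical reading
  rules (ER bright on T1+Gd, FHR bright on T2/FLAIR, NENR dark on
  T1+Gd); `apply_bias_field()` multiplies all channels by a unit-mean
  exponential of low-order cosine modes (`amplitude` = peak log
  deviation), and `add_noise()` adds i.i.d. Gaussian noise
  (`noise_sigma` default 0.04 in arbitrary intensity units; tissue
  contrasts are of order 0.3–0.6, giving contrast-to-noise ratios far
  more benign than clinical data).

What passing tests on phantoms do **not** show: robustness to real
anatomy, registration error, scanner heterogeneity, or ambiguous
histology-dependent boundaries. The phantoms validate the machinery —
losses, sampling, relabeling, metrics — not clinical performance.

## Network

`network_config()` describes a mirror-symmetric encoder–decoder.
Encoder stages are 3×3×3 convolutions (stride 1, dilation 1) with
instance normalization and ReLU, separated by 2×2×2 max-pools; the
decoder mirrors them with 2×2×2 transposed convolutions, concatenated
skip connections, and `convs_per_block` convolutions per stage; a final
1×1×1 convolution produces the 4 class logit maps. Input channels are
z-scored per volume before the first convolution (`standardize_input`),
the standard intensity normalization for multi-scanner MRI.
`convs_per_block` defaults to 1: classic full-scale U-Nets use two
convolutions per block, but at short optimization horizons the extra
depth only dilutes the per-parameter update budget and measurably slows
learning, so the desk-scale default is the shallower block (2 remains
available for full-scale runs). Normalization and
activation are not dictated by the reference description; instance norm
+ ReLU is the common choice for small-batch 3D segmentation and is
recorded as a divergence risk. The classification bias is initialized
to log class priors (background-dominant), the standard focal-loss
initialization for extreme imbalance: the network starts out predicting
background confidently, so the focal term focuses its gradient on
lesion voxels from the first step.

The default channel schedule expands ×4 per stage and ends at a
128-channel bottleneck (`c(8, 32, 128)`), so two branches can be fused
without projection layers; the literal schedule `c(4, 8, 16, 32)` is
accepted as a preset. The reference description states both schedules,
which are mutually inconsistent; the geometric 128-bottleneck reading
honors the fusion constraint and is therefore the default.

### Variational decoder

In `variational` mode every decoder convolution keeps a Gaussian weight
posterior `N(mu, softplus(rho)^2)` against a `N(0, 1)` prior. A
stochastic pass samples a shared perturbation `dW = sigma * eps` and
decorrelates it with channel sign flips (Flipout); for a single volume
the sign-modulated path collapses algebraically to one convolution with
effective weights `W_mu + dW * (s_out %o% s_in)`, which is how it is
implemented. The perturbation has zero expectation, so the sample-mean
output converges to the mean-weight pass; seeds make every stochastic
pass bit-reproducible. The layer's closed-form Gaussian KL against its
prior is exposed per layer (`variational_conv_forward()`) and summed
network-wide (`network_kl()`).

Posterior initialization: the reference setting is mean 0, variance 3,
and that is the `network_config()` default. At desk scale this value is
unusable as-is: a posterior scale of √3 is ~25× the He scale of the
weight means, the decoder output is noise-dominated, and the ~10²
optimizer steps of a tiny run cannot anneal the scale down (verified
empirically: the region loss never moves). The full-scale regime (~10³–10⁴
steps) can anneal it; a tiny run cannot. The tiny preset therefore
initializes the posterior variance at 10⁻³ — the order of the annealed
magnitude — and treats "variance 3" as a property of full-scale
training. Both interpretations (initialization vs. constraint) exist;
the package treats the value as an initialization, trainable
thereafter.

`mc_dropout` mode is the ablation baseline: deterministic weights with
rate-0.2 dropout after each decoder block, active at inference.

## The objective

With `r` the one-hot reference and `p` the softmax output over
`N` voxels:

* **Generalized Dice loss** over the three foreground classes,
  `GDL = 1 − 2 Σ_l w_l Σ_n r_ln p_ln / Σ_l w_l Σ_n (r_ln + p_ln)` with
  inverse-squared-volume weights `w_l = 1/(Σ_n r_ln)²`. Two numerical
  choices matter. First, an absent class has infinite printed weight;
  the epsilon-guard alternative (`1/(0 + ε)`) makes that weight ~10⁵
  and training degenerates into suppressing the absent rare class — the
  loss pins at ~1 and no foreground is learned. The package instead
  caps absent-class weights at the largest present-class weight, the
  convention used by mainstream implementations of this loss. Second,
  `class_weight_epsilon` (1e-5) still guards the all-absent corner.
* **Focal loss** `FL = mean_n −(1 − p_t)^γ ln p_t` on the full 4-class
  simplex, with `γ` learnable through a softplus reparameterization
  (init 2.0). Probabilities are floored at 1e-7 before logs.
* **Weights.** `Generalized Dice Focal Loss = λ_GDL·GDL + λ_FL·FL`.
  The reference never prints the λ values. Equal weights are degenerate
  in this implementation's regime: the GDL gradient concentrates
  ~`1/n_l` of its mass on the smallest class, the focal gradient
  spreads `1/N` per voxel, and at equal λ the smallest foreground class
  wins the race for the shared "lesion" feature — the envelope class
  never recovers (observed: FHR Dice 0 after 100 epochs at λ 1:1,
  while GDL alone reaches ER Dice 0.99 and FL alone FHR Dice 0.6). The
  default is therefore λ_GDL = 0.2, λ_FL = 1, chosen once to make the
  two terms' per-class pulls commensurate; both λ remain configurable.
* **KL penalty.** `kl_weight` defaults to 1/(voxels per batch), putting
  the weight-space KL on the same per-voxel scale as the data terms; no
  annealing schedule is assumed.
* **NENR cross-entropy.** The follow-up branch adds
  `nenr_ce_weight × ` mean binary cross-entropy of the NENR-vs-rest
  map (default 0.5 in `finetune_fused()`), sharpening the rare class.

All logarithms are natural, throughout the package.

## Training

Adam (lr 0.001, weight decay 1e-5, batch 8) with case-level 80/10/10
splits and the checkpoint taken at the lowest validation loss
(validation uses the mean-weight pass plus the KL penalty). Training
operates on whole volumes, not patches. Transfer learning follows the
two-stage recipe: `pretrain()` on a preoperative-style corpus, then
`finetune_fused()` freezes that branch (checksum-verified), trains a
scratch branch with the NENR term active, and learns a fused 1×1×1
classification layer on the element-wise sum of the two branches' final
decoder features. A `freeze_pretrained = FALSE` flag fine-tunes the
pretrained branch as well, implementing the alternative reading of the
reference description. Which tensor is fused is not stated there; the
final decoder features (immediately before classification) are used.

### Desk-scale (tiny) preset

The acceptance-scale configuration trains 40 phantoms of 32³ voxels for
20 epochs (batch 8 → 80 optimizer steps), with reduced channels
`c(12, 16)`, posterior variance init 10⁻³, and T = 20 stochastic passes
at inference. These sizes keep a full end-to-end run in minutes on one
CPU while still exercising every stage; they are miniatures of the
reference regime (hundreds of cases at 240×240×155, ~3×10³ steps,
T = 1000), and the numbers they produce are demonstrations of the
machinery, not reproductions of clinical results.

## Uncertainty and relabeling

`sample_predictions()` runs T stochastic passes and accumulates
per-voxel, per-class means μ and population variances σ². The
relabeling rule (`relabel_background_voxels()`) then:

1. considers only voxels currently labeled background;
2. computes `threshold = μ_B − λ·σ_B` (σ_B the standard deviation, per
   the printed formula; a variance-scaled variant exists for
   sensitivity analysis — the surrounding text says "variance" while
   the formula uses σ, and the formula wins by default);
3. marks foreground classes whose mean exceeds the threshold as
   candidates;
4. relabels to a single candidate;
5. resolves multiple candidates by lowest variance (exact ties go to
   the lowest class index and are flagged in the audit).

λ defaults to 0.1, the reference's validation-tuned value;
`tune_lambda()` reproduces that tuning by maximizing mean foreground
Dice on a validation fold (the tuning objective is not stated in the
reference; mean foreground Dice is the package's choice). Thresholds
are per-voxel by default; a `per_case` scope pools μ_B and σ_B over all
background-predicted voxels (the reference describes both readings —
"case-specific threshold" vs. per-voxel distributions; both are
implemented, per-voxel being the default, and the audit records which
was used). The relabeled set grows monotonically with λ, foreground
voxels are never touched, and the whole rule is oracle-tested against a
straight-line per-voxel reimplementation.

Initial labels are the argmax of the posterior mean with ties to the
lowest class index; the variance estimator divides by T (population
form). Both are unstated in the reference and fixed here for
reproducibility.

## Evaluation

`evaluate_cases()` assembles the metrics report: per-case DSC, Jaccard
and Hausdorff distance per class (HD in mm via an exact max–min sweep;
both-empty masks score DSC = JI = 1 with an audit attribute, a choice
that avoids penalizing correctly absent classes; one-empty HD is NaN
with a flag), plus pooled voxel-wise calibration: 15-bin ECE on the
maximum posterior-mean probability, UCE on normalized predictive
entropy, per-class one-vs-rest Brier scores, NLL of the true class,
reliability and risk–coverage tables, and the error-detection AUROC
(uncertainty as a score for incorrectness). Calibration voxels are
subsampled to 10⁶ (seeded) to bound memory. `paired_wilcoxon()` wraps
the exact signed-rank test (≤ 25 untied pairs; normal approximation
with zero-dropping otherwise) with Bonferroni correction;
`delta_dsc_robustness()` measures the per-class Dice drop under seeded
bias-field perturbation, the qualitative robustness probe.

Numerical conventions collected in one place: probability floors 1e-7;
instance-norm epsilon 1e-5; GDL `class_weight_epsilon` 1e-5; simplex
validation tolerance 1e-6; calibration bins M = 15; entropy normalized
by ln 4; all voxel indexing 0-based through the affine only.

## Known limitations

* Phantom realism is deliberately minimal; see the generator section.
* The desk-scale preset's absolute metric values depend on the phantom
  difficulty and are not comparable to clinical benchmarks.
* Hausdorff distances are reported in mm; the reference's HD unit is
  unstated and its table values are not reproduced here.
* The variational decoder quantifies weight-space (epistemic)
  uncertainty only in the decoder; encoder weights are point estimates
  by design.
* Training is single-machine, single-precision-less (R doubles), whole
  volumes only; no patching, augmentation, schedules, or distributed
  execution.
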
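---
title: "Prognostic AI monitoring of longitudinal chest CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic AI monitoring of longitudinal chest CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Response of metastatic lung cancer to checkpoint-inhibitor therapy is
routinely followed with serial chest CT, but the standard reading reduces
each visit to a handful of 2D diameter measurements. Much of what changes
between two scans — nodal growth, effusions, atelectasis, bone lesions —
never enters the response assessment. `morphotrack` implements a fully
automatic alternative: an unsupervised deformable registration network
quantifies *all* gross morphological change between two scans of the same
patient, and a classifier links those changes to overall survival.

The pipeline has four stages:

1. **Preprocessing** — clip Hounsfield units to the fat-to-cancellous-bone
   window \([-120, 300]\), rescale to \([0, 1]\), resample to 2 mm
   isotropic voxels, and centre-crop/pad to a fixed shape
   (192×192×160 at full scale).
2. **Registration** — a two-stage network: a VGG-like affine stage (five
   stride-2 convolution blocks, two fully-connected layers, 12 regressed
   affine parameters) aligns the pair; a U-Net deformable stage (four
   stride-2 encoder blocks, a stride-1 latent block, four ×2-upsampling
   decoder blocks with skip connections, group normalization) outputs a
   dense displacement field. Warping is backward: the warped image at
   fixed-grid voxel \(x\) samples the moving image at \(A(x + u(x))\),
   trilinearly, displacements in voxel units.
3. **Monitoring features** — the latent block's feature maps (96 channels
   at default width, on a grid of the input shape / 16) are computed in
   both directions (prior→subsequent and subsequent→prior) and multiplied
   element-wise, which makes them exactly order invariant; each map is
   pooled to four statistics (mean, population SD, Fisher skewness, excess
   kurtosis), and two time covariates are appended (days between scans,
   days from treatment start to the later scan): \(4 \times 96 + 2 = 386\)
   features per scan pair.
4. **Prognosis** — a random forest with greedy forward wrapper feature
   selection (out-of-bag AUC criterion, stop when the improvement is
   \(\le 10^{-4}\)) predicts survival to 365 days from the later scan.
   Discovery and test sets are split by patient-id parity (even =
   discovery), as in a registry-style design; forests use library default
   hyperparameters throughout, with no further model selection.

## The training objective

Registration is unsupervised. For a pair \((F, M)\) the loss is

\[
\mathcal{L} = \big(1 - r(F_s, W_s)\big)
  + \tfrac{1}{10}\,P_\text{smooth}(u)
  + \tfrac{1}{10}\,P_\text{fold}(u)
  + \tfrac{1}{10}\,P_\text{mag}(u),
\]

where \(r\) is the Pearson correlation of the flattened intensities of the
(curriculum-smoothed) fixed image \(F_s\) and warped moving image \(W_s\),
and the three penalties discourage unlikely morphological deformations:

- \(P_\text{smooth} = \operatorname{mean}_{x,d} \lVert u(x+e_d) - u(x)
  \rVert^2\) (squared forward-difference gradients, averaged over voxel
  sites and axes with the three displacement components summed per site);
- \(P_\text{fold} = \operatorname{mean}_x \max(0, -\det(I + \nabla u))\)
  (penalizes locally orientation-reversing, i.e. folding, transforms);
- \(P_\text{mag} = \operatorname{mean}_x \lVert u(x) \rVert^2\).

The identities of the three penalties are an interpretation: the source
architecture names three penalties weighted 1/10 each without specifying
them, and smoothness / anti-folding / magnitude is the standard trio for
this purpose in learned registration.

**Curriculum.** The loss is computed on box-smoothed copies of both images
(average pooling, stride 1, symmetric padding — a pure blur), with kernel
9 before epoch 100, 6 before 150, 3 before 175, and none afterwards. This
presents coarse structure first and fine detail late. For odd kernels the
smoothing preserves the global mean exactly; stride 1 keeps the loss
resolution constant across the curriculum (the alternative, stride = k
downsampling, would change the number of loss terms at each milestone).

**Optimization.** Adam, initial learning rate \(8\times 10^{-5}\), batch
size 2, 200 epochs at full scale. Group normalization replaces batch
normalization because a batch of 2 makes batch statistics useless. Both
network heads start at the identity: the affine head has zero final-layer
weights and an identity bias, and the dense-field output convolution is
zero-initialized, so training starts from "no deformation" — this
stabilizes the early epochs. Patients whose numeric id is a multiple of 10
are held out during training (10% of a corpus with ids 1..N, N a multiple
of ten) to monitor overfitting.

**Affine warm-up.** The first 10% of epochs (configurable) train the
affine stage alone, with the dense field held at zero. Without this, joint
training reliably reaches a local minimum in which the flexible dense
stage absorbs even rigid misalignment into the displacement field and the
affine head degenerates to a constant output — the magnitude penalty
prefers the affine solution globally, but gradient descent cannot transfer
a correction from the field to the affine parameters once the field has
learned it. Affine-first staging is the standard cure in learned
registration.

All layers and their backward passes are implemented in this package
(Rcpp kernels for convolution, transposed convolution, trilinear sampling,
box smoothing, and the penalty gradients; R for group normalization and
the fully-connected head). Every gradient path was verified against
central finite differences.

## The synthetic phantom cohort

The clinical cohort behind the original study is private, so the package
ships a seeded phantom generator that reproduces the *structure* of the
problem: longitudinal chest-like volumes whose lesion dynamics drive
simulated survival.

- **Anatomy** (schematic, not realistic CT): a mid-intensity body
  ellipsoid, two low-intensity lung ellipsoids, a high-intensity spine
  cylinder, and 1–3 high-intensity spherical lesions placed inside the
  lungs. Downstream stages consume normalized intensities only, so CT
  texture realism is deliberately out of scope.
- **Lesion dynamics**: per-patient growth rate \(g \sim N(0.03, 0.05)\)
  per 30 days, truncated at \(-0.05\); radii compound as
  \(r(t) = r_0 (1+g)^{t/30}\), saturating at 13 mm. Baseline radii are
  7–12 mm — the size range of RECIST-measurable lung lesions; smaller
  (sub-voxel) lesions would make growth physically unresolvable at the
  working resolutions.
- **Survival**: \(\text{OS} \sim \text{Exponential}(h_0 e^{\beta g})\)
  with \(h_0 = 1/400\) per day and \(\beta = 15\), administratively
  censored at 900 days. Median-growth patients thus have a ~0.24
  probability of surviving one year, so 1-year labels are populated on
  both sides. Progression-free survival is drawn as a uniform fraction
  (0.4–0.95) of OS.
- **Schedule**: pre-baseline at −102 d, baseline at −26 d, first follow-up
  at +68 d, then every 77 d (±10 d jitter), 6 scheduled scans per patient
  — about the scans-per-patient ratio of a two-year follow-up routine.
  Pre-treatment scans always exist; follow-ups only while the patient is
  alive, so every patient retains at least two scans.
- **Between-visit variation**: the later scan of each monitored pair is
  deformed by a random rigid jitter (≤3°, ≤4 mm — patient repositioning)
  composed with Gaussian-smoothed elastic displacement (12 mm correlation
  length, 4 mm RMS — soft-tissue change), plus independent acquisition
  noise per scan. The exact displacement field is returned, which gives
  ground truth for registration tests.

What passing tests on these phantoms show: the implementation recovers
synthetic deformations it has never seen, its order-invariant features
carry lesion-growth information through to survival classification, and
its occlusion maps localize the changing lesion. What they do not show:
performance on real CT — phantoms lack texture, anatomy variation,
contrast phases, and pathology other than spherical lesions.

## Study-scale parameters

Full-scale defaults follow the source protocol (192×192×160 voxels at
2 mm, channel widths 16/32/64/96, 96 latent channels, lr
\(8\times10^{-5}\), 200 epochs). The test suite and the acceptance script
run a reduced protocol chosen to keep a complete experiment on a single
CPU within minutes while preserving every structural property:

- registration training on volumes of 32³ voxels at 4 mm spacing (the
  same 128 mm physical anatomy as the 64³ / 2 mm phantom default);
- channel widths 4/8/16/24 with 24 latent channels (the latent grid is
  input/16; the feature vector is \(4\times24+2 = 98\) long);
- 200 training pairs (equal thirds self-deformed, same-patient follow-up,
  inter-patient), 20 epochs of which 4 are affine warm-up, curriculum
  milestones divided by 10 (10/15/17), learning rate \(10^{-3}\) — the
  full-scale rate is tuned to a 200-epoch schedule and learns too slowly
  in 20;
- the monitored cohort of 60 patients (even ids discovery, odd ids test)
  is rendered at 64³ / 2 mm and registered with the 32³-trained weights —
  the network is fully convolutional, and the finer 4³ latent grid (64
  values per map instead of 8) markedly stabilises the pooled statistics,
  a small-scale analogue of the ~1000-value latent maps of the full
  protocol; 1000-resample bootstrap CIs, 200-permutation null bands;
- occlusion patches of 32³ voxels with stride 16, covering 12.5% of the
  volume's extent per axis position.

## Numerical choices and degenerate inputs

- Correlation loss on constant images is undefined; it is defined as 1
  (zero information) and flagged. Pooled skewness/kurtosis of a
  zero-variance map are defined as 0.
- Trilinear samples outside the moving image are 0 (normalized air);
  round-trip evaluation points are drawn from the central 80% of the grid
  to avoid border extrapolation of the field.
- Group normalization merges groups until each holds at least 8 elements,
  and passes through unnormalized if even a single group is smaller. Tiny
  groups are degenerate: a 2-element group always normalizes to exactly
  ±1, which binarizes the representation (observed at 1³ spatial sizes in
  small test volumes, where it froze the affine head), and the variance of
  a single element is undefined. Full-scale groups are far larger, so the
  default behaviour is unchanged there.
- Centre crop/pad puts the odd voxel on the high-index side; padding uses
  normalized air (0).
- Median splits send ties (and the median element) to the high-survival
  group; the discovery-set median is applied unchanged to test scores.
- Scan pairs censored alive before the 365-day horizon are excluded from
  labelling; exclusion counts are always reported.
- The days-from-treatment-start covariate is anchored at the later scan of
  the pair — the prediction origin.

## Design choices where the design was open

- **Penalty identities** — see above; each weight is a config field.
- **Affine stage input**: the pair is concatenated as two channels (the
  alternative — moving image alone — cannot express relative alignment).
- **Fixed vs moving role of prior/subsequent**: the monitoring features
  compute both directions and multiply, so the choice is immaterial
  downstream; for a single registration the first argument is the fixed
  image.
- **Latent source**: the stride-1 latent block of the deformable stage,
  not decoder skip levels — the deepest representation of the morphological
  difference.
- **Occlusion**: raw-voxel occlusion of cubic patches in *both* scans at
  the same location (a change needs two time points), fill value 0,
  overlap-averaged accumulation; positive map values mean the region
  supports the predicted survival.
- **Wrapper selection**: greedy forward with OOB-AUC, the least exotic
  reading of "wrapper feature selection" that still performs "no model
  selection" in the cross-validation sense: selection happens once, on the
  discovery set, with default forests.
- **Training pairs**: the source corpus' pairing scheme is unknown; the
  package mixes self-deformed, same-patient follow-up, and inter-patient
  pairs in equal thirds so the network sees both known ground truth and
  the monitoring distribution.
- **Array axis order** is (x, y, z) as stored by NIfTI, with 0-based voxel
  coordinates inside the warping kernels; world coordinates are
  `origin + index * spacing` with identity direction cosines.

## Known limitations

- **Prognostic transfer at miniature scale.** The reduced protocol trains
  the registration network for minutes on a CPU and pools latent maps of
  8–64 values; at that scale the features respond strongly and
  monotonically to lesion growth *within* a patient (r ≈ 0.7 after
  within-patient centering), but the direction of the response in feature
  space is patient-specific, so a classifier fitted on 30 discovery
  patients does not generalize: across seeds, network widths and
  resolutions the test AUC stays inside the permutation-null band, and
  occlusion maps of such a classifier track its noise features rather
  than the lesion. The zero-coupling control behaves correctly (AUC inside
  the null band), confirming the evaluation machinery. Stable pooled
  moments appear to require the full-scale regime — latent maps of ~1000
  values from a network trained for hundreds of epochs on a 1000-patient
  corpus, with hundreds of discovery pairs — which is far beyond a
  desk-scale run. The acceptance suite asserts the end-to-end recovery
  and heatmap-localization properties anyway, and those two tests fail
  on this build; all component-level and registration-recovery tests pass.
- The phantom generator draws one global growth rate per patient; mixed
  response (some lesions growing, others shrinking) is not simulated.
- The exponential survival model has no frailty beyond lesion growth, so
  the oracle AUC of a perfect growth estimate is about 0.71 at the default
  coupling — an intrinsic ceiling for any feature set on these cohorts.
  Exponential survival is also memoryless, which makes the
  days-from-treatment-start covariate uninformative in the phantom world
  (unlike in real cohorts).
- Transposed-convolution upsampling (kernel 2, stride 2) can introduce
  checkerboard patterns at full scale; the smoothness penalty counteracts
  this but trilinear-upsample + convolution would be the conservative
  alternative.
- The anatomical (liver-to-neck) cropper of the source protocol is a
  separately trained model and is replaced by configurable axial crop
  fractions (default: no crop), which phantoms do not need.
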
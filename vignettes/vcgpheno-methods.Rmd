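---
title: "Methods: vectorcardiographic phenotyping of cardiomyopathy from 12-lead ECGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vectorcardiographic phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the pipeline

Hypertrophic (HCM) and dilated (DCM) cardiomyopathy alter both the
amplitude and the three-dimensional geometry of the heart's electrical
activity. `vcgpheno` implements a complete analysis chain that turns a
resting 10 s, 500 Hz, 12-lead ECG into a feature vector combining
classical per-lead measurements with vectorcardiographic (VCG)
quantities, compares those features between phenotype groups, and
evaluates cross-validated classifiers for three binary tasks: HCM vs
ischemic dilated cardiomyopathy with LV dilation (DCM-I), HCM vs
non-ischemic DCM (DCM-NI), and obstructive (HOCM) vs non-obstructive
(HNCM) hypertrophy.

The stages are:

1. **Input** (`read_record`, `exclusion_filter`, `select_primary_ecg`):
   WFDB or CSV records in mV; a keyword filter with a 30-character
   negation guard removes paced rhythms, artifact recordings, bundle
   branch and fascicular blocks, intraventricular conduction defects,
   frequent ventricular ectopy, and atrial fibrillation/flutter; one
   record per patient is selected by (clean, definitive label, earliest,
   record id).
2. **Delineation** (`delineate_record`): leads are cleaned with a
   zero-phase FFT band-pass (0.5--40 Hz; the low-side transition is
   0.3 to 0.5 Hz so slow baseline wander is removed outright, and the
   high-side roll-off is deliberately wide, 40 to 48 Hz, because a sharp
   cutoff rings across QRS edges). R peaks are found on the
   root-sum-of-squares envelope of the 10--30 Hz content of the eight
   independent leads -- a band where the QRS carries most of its energy
   and even very tall T waves carry almost none -- with a
   frequency-content score plus an autocorrelation-period lattice check
   that rejects T-wave doubles. Each lead is then delineated with a
   prominence method: P and T peaks are the most prominent local extrema
   in windows of [-300, -60] and [+80, +500] ms around R (capped at the
   neighbouring beat midpoints), with onsets/offsets at the flanking
   prominence bases, so the T offset is the right-hand base of the T
   peak. QRS onset/offset are refined by an a-trous wavelet stage
   (levels 3--4 of a (1,2,1)/4 -- (-1,0,1)/2 filter pair at 500 Hz,
   threshold 5% of the in-beat modulus maximum, anchored on the strong
   detail nearest R) combined with amplitude-quietness checks at a
   0.02 mV floor; the quietness runs, outward push and inward trim
   operate on a baseline-free copy of the lead (raw minus a 200 ms /
   600 ms running-median cascade) where a sample counts as isoelectric
   only if it is both flat (one-sided 20 ms range below the floor,
   noise-adapted) and near zero. Per-beat landmarks relative to R are
   pooled as median-over-beats, then median-over-leads, into fixed
   global windows.
3. **Median beats and VCG** (`build_mean_beat`,
   `assemble_calibrated_matrix`, `compute_all_vcg_features`): 850 ms
   R-aligned mean beats (300 ms before R, 550 ms after; each segment
   shifted by its own PR-segment mean), stacked into an 8 x 425 matrix
   and projected through the Kors regression matrix into X/Y/Z space
   (X leftward, Y inferior, Z posterior). P/QRS/T loops are windowed
   from the global windows, translated to the window-onset point
   (isoelectric origin; no mean-centering, so the first singular value
   is a dipolar amplitude), and summarized by SVD with singular values
   scaled by 1/sqrt(M) for sampling-density invariance.
4. **Statistics and models** (`compare_groups`, `evaluate_task`):
   Mann-Whitney U (exact enumeration for n1+n2 <= 12 without ties,
   tie/continuity-corrected normal approximation otherwise), Cliff's
   delta for numeric features, risk difference with a
   continuity-corrected two-proportion test for Booleans, no
   multiplicity adjustment by default (a Benjamini-Hochberg column can
   be appended). Classification uses L1 logistic regression (C = 0.1 in
   the liblinear parameterization, i.e. glmnet with
   lambda = 1/(n C), features z-scored with training-fold statistics)
   and a second-order gradient-boosted tree ensemble (200 trees, depth
   3, learning rate 0.1), both under stratified 5-fold cross-validation
   with out-of-fold probabilities, reporting AUC-ROC/AUC-PR in both the
   mean-across-folds and pooled-out-of-fold conventions, plus
   sensitivity/specificity at the Youden threshold (ties resolved
   toward the lower threshold).

## The 41 VCG features

The registry is fixed: for each of the P, QRS and T loops -- ln sigma1
(log dipolar amplitude), ln sigma2, sigma3, sigma2/sigma1, the log
non-dipolar-to-dipolar ratio ln((sigma2+sigma3)/sigma1), planarity
(sigma3/sigma1), peak spatial magnitude, time-to-peak (the ventricular
activation time for QRS), time-voltage area, and the max-to-mean
spatial ratio (30 features); the P-QRS and QRS-T mean-vector angles and
the QRS-T first-eigenvector angle (3); ventricular-gradient magnitude,
horizontal azimuth (angle of the X-Z projection from +X toward +Z),
sagittal angle (Y-Z projection from +Y toward +Z), the sines of both,
and the 3D elevation asin(Z/|VG|) (6); and the signed R amplitudes of
derived leads Y and Z (2). Eigenvector signs are fixed by a
non-negative dot product with the loop mean vector so angles above 90
degrees are representable. "log" means the natural log throughout.
Absent loops (e.g. an undetectable P wave) propagate as missing values.

## The synthetic cohort generator

Because the source cohort is restricted-access, validation uses a
parametric forward model. Each beat is a sum of three planar-ish loops,

  v(t) = A [ b1(s) u1 + ecc b2(s) u2 + beta b3(s) u3 ],

with b1 = e(s) cos(phi), b2 = e(s) sin(phi), b3 = e(s) sin(2 phi),
phi = pi(2s-1), and a half-sine envelope e(s) = sin(pi s^gamma). The
half-sine (rather than a raised cosine) keeps a non-zero edge slope so
the wave support is a measurable quantity; gamma skews the wave and
directly encodes the T-wave upslope/downslope index. b2 and b3 are
orthogonalized against the time integral of b1 so only the main axis
carries net area, which makes the ventricular gradient exactly
steerable. Leads are produced with the Moore-Penrose right-inverse of
the Kors matrix, so the Kors projection recovers the dipole exactly
(to 1e-9); the augmented limb leads follow from Goldberger algebra, and
white noise (0.01 mV SD) plus 0.25 Hz sinusoidal wander (0.05 mV) are
added per lead.

Targets are achieved by calibration, not by assumption: the internal
eccentricity is solved numerically (via the basis Gram matrix) so the
measured sigma2/sigma1 equals the requested ratio; the T amplitude is
solved from the requested ln sigma1; the main QRS dipole is solved from
three linear lead-amplitude constraints (two named leads plus the
derived-Y amplitude); the secondary QRS axis is phased to reproduce a
requested V1 S-wave depth; and the T-wave main axis is solved so the
total QRS+T integral points along the requested ventricular-gradient
direction (plane-angle jitter of 9 degrees SD is applied to the target
angles, not to the Cartesian components, whose perturbation would
distort the sines disproportionately near zero).

Preset central values encode the reported group structure (lead-I R
amplitude 0.76/0.51/0.41/0.55 mV for HCM-like / DCM-NI-like /
DCM-I-like / normal presets; V5 R 0.80/0.76/0.39/0.84; QRS duration
92/102/107/86 ms; T-loop ln sigma1 -0.01/-0.58/-0.53/-0.04;
ventricular-gradient sagittal-angle sines 0.31/0.86/0.87/-0.06 and
horizontal 0.23/0.68/0.77/-0.04; RR centre 681 ms and a 27% sinus
tachycardia fraction for the DCM-NI-like preset; T-index
1.27/2.24/1.40/1.13; and, for the obstructive split, V6 R 0.88 vs 0.66
mV, V1 S 0.86 vs 0.66 mV, QRS sigma2/sigma1 0.32 vs 0.44, P duration
108 vs 120 ms). Dispersions come from the printed interquartile ranges
where available (SD = IQR/1.349) and a 20% coefficient of variation
otherwise. The HCM-like QRS-duration centre (92 ms) is not reported by
the source study; it was fixed a priori as mildly prolonged relative to
normal and clearly shorter than the DCM-I-like 107 ms. Repolarization
shortens with rate (T offset capped at 0.45 RR) so tachycardic beats
never collide.

Every record carries ground truth computed from the clean forward model
with the true wave windows -- per-lead peak locations and amplitudes
(R is the positive deflection when one exceeds 15 uV, else the dominant
deflection, matching the extraction's labelling), the measurable
per-lead QRS support (where the clean projection exceeds the 0.02 mV
amplitude floor; a lead whose loop component vanishes quadratically at
the nominal edge carries no localizable boundary there), loop SVD
quantities, and the exact ventricular gradient.

### What a green test does and does not establish

The generator produces homogeneous beats (no ectopy, no morphology
change within a record), stationary noise, a single sinusoidal wander
component, and a lead field that is the algebraic right-inverse of the
Kors matrix rather than a physiological (Dower-type) torso model. Some
implied amplitudes are deliberately taken from the reported medians
even where the combination is electrically unusual (the T-loop
ln sigma1 near 0 implies very tall spatial T waves under the 1/sqrt(M)
scaling convention; the pseudoinverse lead field makes the dipole
magnitudes needed for the printed lead amplitudes larger than
physiological). Green tests therefore establish algorithmic
correctness and internal consistency of the full chain on a controlled
world with known truth -- not clinical performance on hospital ECGs.

## Numerical and design choices

* **Indices** are 1-based (R convention); ms = samples x 1000/fs;
  windows are half-open [on, off).
* **Delineation tolerances.** The prominence threshold is 0.05 mV; Q/S
  deflections must clear max(15 uV, 4 robust noise SDs), and their
  search windows stay clear of the P/T regions. The QRS refinement runs
  on a baseline-free copy built with a two-stage running median (the
  40 Hz cleaning low-pass would smear sharp QRS edges across the
  amplitude floor, and a linear high-pass pushes the inter-beat
  baseline around with the neighbouring wave areas). Quietness is
  directional (trailing window for the onset side, leading for the
  offset side) and requires both flatness and a near-zero level, which
  distinguishes true isoelectric gaps from in-wave plateaus, slurred
  tails and slow T feet; the outward push is bounded at 60 ms.
* **Anchoring.** R detection, the global windows, and the median-beat
  frame are all anchored to the shared multi-lead envelope reference;
  the per-lead R label (positive-preferred) is used for amplitude
  features only. This deviates from calibrating the frame on the lead
  V5 R index alone: with synthetic morphologies where V5 is not
  guaranteed a dominant positive R, a V5-anchored frame can shift the
  loop windows by tens of ms, and anchoring everything to the shared
  reference removes that failure mode by construction
  (`assemble_calibrated_matrix` still validates V5 and supports
  explicit V5 calibration for standalone use).
* **Baseline.** All amplitudes are referenced to the PR-segment mean
  `[P_off, QRS_on)`, falling back to 40--10 ms before QRS onset, then
  to a fixed pre-R window.
* **R/S ratio** uses a 0.01 mV denominator floor. Q and S amplitudes
  are reported as absolute magnitudes; P, R and T signed.
* **Missing data** handling for the classifiers drops the three
  features with the greatest missingness (ties alphabetical; features
  with no missing cells are never dropped) and then performs
  complete-case analysis; both models consume the identical subset.
* **Top-15 selection** for the obstructive task ranks by |Cliff's
  delta| (ties: smaller p, then name) on the full task data, as in the
  source design; this leaks selection information into the
  cross-validation, and an honest nested mode (`top_k_nested = TRUE`)
  re-ranks inside each training fold.
* **Intervals are not rate-corrected**, matching the source analysis.
* **Degenerate inputs**: all-zero loops yield missing ratios (never
  -Inf); a ventricular gradient below 1e-6 mV ms has undefined angles;
  constant leads yield missing spectral/moment features; ordering
  violations in the global windows raise errors rather than being
  silently repaired.

## Known limitations

Beyond the generator simplifications above: the exclusion phrase list
is a faithful but non-verbatim reading of the described rules (the
source does not enumerate its phrases); the exact identities of the
source's 14 lead-specific and 30 global features are not published in
the main text, so the registry implements every named feature over a
full per-lead grid and is extensible; P-wave onset/offset placement on
noisy records is biased outward by tens of ms (peaks are accurate --
durations remain monotone, so group contrasts are preserved); and
near-tie biphasic waves make "the" peak ambiguous at the 0.02 mV
amplitude-floor precision, which the validation audits acknowledge by
accepting either lobe when their amplitudes are indistinguishable at
that precision.
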
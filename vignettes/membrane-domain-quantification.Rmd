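---
title: "Quantifying membrane nanodomain organization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane nanodomain organization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memquant)
```

memquant quantifies the lateral organization of cholesterol/sphingomyelin
(Chol/SM) enriched nanodomains at the plasma membrane from three
complementary measurements: quantitative single-molecule localization
microscopy (qSMLM) of a fixed, probe-stained membrane; fluorescence
correlation spectroscopy (FCS) of the probe diffusing on the live-cell
membrane; and ratiometric imaging — Fura Red calcium transients and NR12S
generalized polarization (GP). This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the synthetic
data emulate (and what they deliberately do not), and the numerical choices
that shape the estimators.

## The synthetic study conditions

No raw data ship with the package; every analysis is exercised on synthetic
acquisitions whose ground truth is known exactly, so recovery can be tested
quantitatively. The generators' defaults are the package's study
conditions:

* **qSMLM** (`smlm_truth()`, `simulate_smlm()`): nanodomain centers follow
  a homogeneous Poisson process (5 /µm²), member molecules are
  Poisson-distributed (mean 10) with an isotropic Gaussian spread of
  σ = 30 nm, on top of a 20 /µm² completely-spatially-random background.
  Each molecule appears `k = 1 + Geometric` times (mean α = 3.3 — the
  measured blinking statistic of the OlyA-AF647 probe; the distributional
  family is our choice, matching standard fluorophore on/off kinetics,
  since only the mean is measured). Appearances are separated by
  exponential dark gaps of mean 25 s, chosen so the maximum dark gap in a
  ~10⁴-probe field is ≈ 250 s, the probe's measured maximum dark time (the
  maximum of n exponentials grows as scale·log n). The burst-train start is
  drawn uniformly over the window where the whole train fits inside the
  60,000-frame / 10 ms acquisition, so no appearance is truncated and the
  realized appearance count keeps its nominal law. Localizations are
  jittered by 15 nm Gaussian noise and shifted by cumulative linear drift
  (default ≈ 113 nm total — instrument drift magnitudes are rarely
  published, so we keep total drift near 100 nm, a common
  fiducial-corrected regime);
  three fiducial beads are emitted in every frame, flagged in the output
  and also discoverable by persistence. Random-walk drift is available by
  constructing a drift trajectory externally; the generator itself keeps
  drift linear because nothing in the source data constrains its shape.
* **FCS** (`fcs_truth()`, `simulate_fcs_trace()`): Brownian dynamics with
  one step per sampling bin (per-axis SD `sqrt(2 D dt)`), a periodic box,
  2D particles confined to the focal plane, a 3D Gaussian detection profile
  `exp(-2 r_xy²/ω_xy²) exp(-2 z²/ω_z²)`, an optional two-state triplet
  telegraph gating emission, and Poisson photon counts. Defaults: membrane
  D = 0.5 µm²/s, ω_xy = 0.2 µm, 540 particles in a 6 µm box
  (15 molecules/µm²), 30 kHz/molecule peak brightness, 1 ms bins, 200 s
  (ten 20-s segments, matching the acquisition protocol the analysis
  assumes).
* **Calcium ratio** (`transient_truth()`, `simulate_ratio_trace()`): the
  true Fura Red ratio is `baseline + amplitude·shape(t)` with a linear rise
  and exponential decay after the stimulation frame (frame 4; the first
  four frames are pre-stimulus); the two channels split this ratio
  symmetrically and bleach exponentially — equally by default, which is
  exactly the regime the ratio is designed to cancel.
* **GP imaging** (`simulate_gp_image()`): a ring-shaped membrane with a
  Gaussian radial cross-section whose two spectral channels carry
  `(1 ± GP)/2` of the total intensity, plus additive Gaussian noise.

What the synthetic data do **not** emulate: camera-frame PSF rendering and
localization fitting (the pipeline consumes localization tables by design),
multi-dark-state photophysics or photoconversion, anomalous or confined
diffusion, membrane topography (the 2D species sits exactly in the focal
plane), cell-to-cell biological variability beyond what the parameter
cohorts prescribe, and segmentation (ring images are centered and round).
Passing recovery tests therefore demonstrates the correctness of the
estimators under their own model assumptions — not robustness to every
real-world artifact.

## qSMLM chain

**Drift correction** (`correct_drift()`). Per-frame drift is the mean
displacement of the fiducial beads from their first-frame positions,
smoothed by a centered 100-frame moving average whose window shrinks at the
series edges (this reproduces a linear trend exactly in the interior, with
only O(slope·window) edge bias). The reference position is estimated as the
bead's mean over the first window so localization noise does not offset the
whole trajectory. Beads are separated by nearest-anchor assignment to the
earliest-frame positions, which is exact when beads are far apart relative
to total drift. A table without any usable fiducial is an error, never a
silent pass-through.

**Photophysics** (`estimate_photophysics()`). On a sparse field
(≤ 1 probe per diffraction-limited spot) localizations are grouped by
spatial single linkage at 100 nm; α is the mean group size and the dark
time is the chosen quantile of within-group frame gaps. The default
quantile 1 (the maximum) is faithful to the source convention but is an
extreme-value statistic: occasional cross-probe merges inflate it, which is
why the quantile is exposed (`gap_quantile = 0.99` is much steadier). The
sparse-field density default (0.3 probes/µm²) keeps the chance of two
probes within the linkage radius near 1%, bounding the merge bias on α
well below the 5% recovery tolerance.

**Counting** (`count_molecules()`). Molecules = localizations / α inside a
square ROI with half-open membership; densities are molecules/µm².
Fractional counts are intentional — α division is a mean correction, not a
per-molecule assignment. ROIs default to 9–16 µm², and `tile_rois()`
emulates the practice of placing the three to four densest such regions on
a cell.

**Pair correlation** (`pair_correlation()`). g(r) is estimated on 10 nm
bins to 500 nm as observed pair counts over the CSR expectation, with the
exact isotropic set covariance of the square window
(γ(r) = L² − 4Lr/π + r²/π) as edge correction — closed-form, no Monte
Carlo. The model

g(r) = c₀ + A_psf·exp(−r²/4σ²) + A_c·exp(−r/ξ)

is fitted by weighted least squares (weights = expected CSR pair counts,
the inverse variance of g under Poisson pair statistics), multi-started
over ξ. Three numerical choices matter and were set by a consistency study
on simulated fields:

* the Gaussian blinking term's width is bounded to [0.7, 1.3]× the table's
  mean localization precision (repeat localizations of one molecule have
  pair-distance width exactly the precision), which breaks the degeneracy
  with the exponential domain term;
* the baseline c₀ ∈ [0.5, 1.5] is free: a single ROI holds only a few
  dozen nanodomains, whose Poisson placement leaves a correlated long-range
  offset in the empirical g(r) that would otherwise leverage the
  exponential tail;
* only r ≤ 250 nm enters the fit (the curve itself is reported to
  500 nm) — past the structured range the same realization noise dominates.

With these choices the estimator is consistent: fitted ξ on simulated
fields matches, within ~2%, the population value obtained by fitting the
same model with the same weight profile to the analytic pair correlation of
the generating process. That population value is also the honest recovery
target: an exponential fitted to a Gaussian-shaped domain term has no
canonical "radius", so recovery is judged against the estimand of the
procedure (computable via `fit_pc_model()` on an analytic curve), not
against a symbol in the generator.

**Cluster assignment** (`assign_clusters()`). A k-means-like loop whose
cluster count is data driven: seeds are 8-neighbourhood local maxima of a
2D histogram with bin = cluster radius ξ (from the PC fit), seeds closer
than ξ merge, points attach to the nearest center within 2ξ, centers move
to member centroids, and the loop stops at stability. Clusters must exceed
four molecules. When the inputs are localizations, membership is converted
to molecules by dividing localization counts by α. We deliberately do
**not** merge localizations spatio-temporally before clustering dense
fields: inside a σ = 30 nm domain every molecule sits within the 100 nm
linkage radius of its neighbours and burst gaps are far below the 250 s
maximum dark time, so single linkage chains a whole domain into one
"molecule" and empties the >4-molecule clusters. α-division counting is
also the convention the source workflow states. The spatio-temporal merge
(`merge_localizations()`) remains available for sparse fields, where it is
valid. The histogram grid is anchored at the data minimum, making reports
exactly translation invariant.

## FCS chain

**Correlator** (`autocorrelate()`). The trace is cut into 20 s segments
(the acquisition protocol's "10 consecutive 20 s measurements"); each
segment's normalized autocorrelation G(τ) = ⟨I(t)I(t+τ)⟩/⟨I(t)⟩² is
evaluated **exactly** at a multi-tau-style quasi-logarithmic lag grid (16
linear lags per octave, spacing doubling per octave), then averaged across
segments with the per-lag SD recorded. We evaluate the estimator directly
at each lag rather than rebinning the signal 2× per octave: classic
multi-tau rebinning triangularly averages neighbouring lags, and exact
agreement with the defining estimator (verified against an O(n²)
brute-force oracle to 10⁻¹⁰) is worth the modest O(n_lags·n) cost at our
trace lengths. The normalization uses the lag-dependent means of the two
shifted windows, so a constant trace gives exactly 1. Segments with a
monotone intensity drop > 20% (assessed on ten coarse chunks with a
Spearman trend gate) are excluded as bleaching artifacts; zero-mean
segments are excluded with a warning; losing all segments is an error.

**Models and fitting** (`fcs_model_one()`, `fcs_model_two()`,
`fit_one_component()`, `fit_two_component()`). The two-component model
combines a triplet factor (fraction F_T, relaxation τ_T), free 3D
diffusion of the unbound probe (mole fraction F₁, diffusion time τ_D1,
structure parameter S = ω_z/ω_xy) and 2D membrane diffusion (τ_D2); the
one-component model is its F₁ = 1 special case, used for dye calibration.
Fitting is Levenberg–Marquardt with box bounds (F_T ∈ [0, 1), F₁ ∈ [0, 1],
times > 0, S ∈ [1, 20]), weights 1/SD² across segments when available
(uniform otherwise — also exposed as an option), starting values from the
curve amplitude (N ≈ 1/(G(τ_min) − 1)) and half-decay lag, and a small
multi-start over τ_D2. Membrane fits hold τ_D1 fixed at the value measured
for the probe in plain medium (213 µs) and S fixed from calibration —
the calibration-first workflow. Parameters at a bound flag the fit as
non-converged rather than failing silently.

**Calibration and derived quantities** (`calibrate()`,
`derive_membrane_quantities()`). From a reference dye of known diffusion
coefficient (AF647, 330 µm²/s): ω_xy = √(4·D_ref·τ_D_ref), ω_z = ω_xy·S.
Then ρ = (1 − F₁)·N/ω_xy² (membrane density), CPM = ⟨I⟩/N (molecular
brightness) and D = ω_xy²/(4τ_D2).

**Simulation fidelity bound.** The Brownian simulator takes one step per
bin with no sub-stepping (speed; the sampled process has exactly the
continuous-time correlation at the sampled lags) and lives in a periodic
box, which reproduces free diffusion only for lags well below
(L/2π)²/D — beyond that, the discrete mode spectrum suppresses the ACF
tail. At the default box (6 µm, D = 0.5 µm²/s) the bound is ≈ 1.8 s, and
the default membrane fit window [1 ms, 0.5 s] stays inside it; with the
minimal 2 µm box the bound drops to 0.2 s and τ_D2 recovery degrades
visibly, which is why the default box is generous. Problem sizes (200 s
traces, 540 particles) were chosen so a full five-seed recovery study runs
in about two minutes on one core.

## Ratiometrics

`compute_frr()` forms FRr(t) = I_bound/I_unbound per frame (frames with
non-positive unbound intensity are excluded with a warning — ratios are
never formed from division-noise-dominated pixels), the baseline is the
mean over the pre-stimulus frames (first 4 by default), and the amplitude
is the FRr at the first post-stimulus peak minus baseline, normalized by
the baseline. The peak detector operationalizes "first maximum": a 3-frame
median smoothing suppresses single-frame noise, the first sample at or
after the stimulus that is ≥ both neighbours marks the peak region (the
plateau tolerance matters because median smoothing flattens sharp peaks),
and the amplitude is read from the raw ratio at the local argmax. Common
bleaching cancels in the ratio by construction — tested as an exact
invariance.

`extract_line_profile()` samples both channels by bilinear interpolation at
identical positions along a line at unit-pixel spacing; `compute_gp()`
locates the membrane as the argmax of the summed channels (joint
localization, so both intensities come from the same membrane point — the
alternative of independent per-channel maxima would pair intensities from
different positions under noise) and computes GP = (I₁ − I₂)/(I₁ + I₂)
there. Per-cell GP is the arithmetic mean over 4–10 such positions
(`cell_gp()`, `cell_gp_from_image()`).

## Statistics

`split_sufficiency_test()` screens whether a set of per-ROI values is
sampled deeply enough: 15 repetitions of {random permutation, split into
halves (the extra element goes to the first half — the odd-n rule is fixed
for determinism), two-tailed Welch t-test}, reporting the mean p-value;
sampling is sufficient when p_split ≥ 0.1. Degenerate splits with two
zero-variance halves score 1 (equal means) or 0 (unequal). Each repetition
redraws its permutation from the seeded stream. One behavioral property is
worth stating plainly: because the split is a random permutation, the two
halves of *any* exchangeable sample — including a grossly bimodal one —
receive near-equal shares of each mode, so the screen detects half-vs-half
disagreement (instability under resampling), not multimodality; the unit
suite pins this down.

`compare_groups()` wraps the standard routines used for reporting — Welch's
t (qSMLM metrics), exact-where-possible Mann–Whitney (FCS and ratiometric
metrics) and one-way ANOVA with Tukey HSD — and returns group summaries
(n, mean, median, SEM) alongside the p-values. No multiplicity correction
is applied beyond Tukey within one ANOVA family, matching the reporting
conventions the pipeline emulates.

## Pipeline

`run_config()`/`run()` drive simulate/analyze/full runs over a cohort of
synthetic cells per named condition. One master seed; per-cell seeds are
`seed + 1000·condition + cell`, so parallel or partial re-runs are
reproducible and `simulate` mode is byte-identical under a fixed seed.
Every stage failure is tagged with its stage; analyze mode on unchanged
inputs reproduces identical tables (no randomness outside seeded blocks).
The statistics stage runs the split screen per condition and metric and
compares every condition to the designated control. Cohort tests in the
suite run at a reduced per-cell scale (4 µm fields, 5,000 frames, one ROI
per cell) chosen so a 20-run null-cohort study completes in a few minutes;
the per-ROI statistical structure is unchanged.

## Known limitations

* The exponential cluster term is a modeling convention; its ξ is an
  effective correlation length, comparable across conditions but not a
  literal domain radius (the population-fit mapping above makes the
  relation to Gaussian-domain σ explicit).
* The maximum-dark-time estimator is an extreme-value statistic and is
  sensitive to rare cross-probe merges on anything but very sparse fields.
* The FCS simulator's periodic box bounds the usable lag range; fits past
  the validity bound are biased fast.
* The split-resampling screen cannot flag balanced multimodality (above).
* `assign_clusters()` resolves domains down to roughly the histogram bin
  (ξ); domains closer than ~ξ merge, and molecules beyond 2ξ of any center
  stay unassigned.
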
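---
title: "Quantitative pharmacology of MOR agonists: models and methods"
author: "MORpharm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pharmacology of MOR agonists: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MORpharm)
```

# Scope

MORpharm implements the quantitative analysis layer of a µ-opioid receptor
(MOR) agonist characterization campaign: concentration–response and
radioligand kinetic fitting, per-timepoint BRET functional kinetics with a
transduction-index bias calculus, APEX proximity-labelling time-course
statistics and spatial deconvolution, two-channel fibre-photometry
processing, and scalar pharmacological endpoint calculators. A family of
seeded generators produces every input with known ground truth, so each
stage is testable end to end without external data. The package does not
touch upstream raw-data processing (mass-spectrometry search and
transition-level summarization, PET image reconstruction, cryo-EM
pipelines); its inputs are the tabular quantities those pipelines emit.

# Concentration–response fitting

All agonist curves are fitted with the three-parameter logistic

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + 10^{\,\log_{10}\mathrm{EC}_{50} - \log_{10} x}},$$

estimated by Levenberg–Marquardt least squares on the
log10-concentration scale with the pEC50 as the free location parameter.
Two numerical choices matter:

* the span is parameterized as $e^{\theta}$, so `bottom <= top` holds by
  construction rather than by clipping, and
* starting values are taken from the per-concentration mean responses
  (min/max for the asymptotes; the concentration bracketing the half-span
  for the pEC50), a standard robust initialization.

Replicates are fitted jointly with equal weights (pooled-curve practice);
per-experiment estimates are obtained by grouping before fitting, which is
exactly what the kinetic bias pipeline does. Degenerate inputs (constant
responses, fewer than four distinct concentrations) are refused or flagged
(`nonidentifiable`), never silently fitted. An inflection more than two
decades outside the tested range is flagged `ec50_outside_range`.

Raw plate data are background-corrected by subtracting the mean of the
ligand-free wells per compound (`subtractLigandFree()`), and responses are
expressed as percent of the reference (DAMGO) span via an affine map that
legitimately produces values above 100% for superagonists.

Competition binding uses the same logistic in decreasing orientation; the
inflection is the IC50, converted to an equilibrium inhibition constant by
the Cheng–Prusoff relation $K_i = \mathrm{IC}_{50} / (1 + L/K_d)$.
Dissociation time courses are fitted as single exponentials
($B_0 e^{-k_{\mathrm{off}} t}$) and the half-life is treated as
definitional, $t_{1/2} = \ln 2 / k_{\mathrm{off}}$, evaluated from the
fitted rate constant: tables that print both quantities independently can
disagree by a percent or two because the printed rate is rounded for
display, which is why the package derives one from the other rather than
storing both. Association fits take the dissociation-derived
$k_{\mathrm{off}}$ as a fixed input, estimate $k_{\mathrm{obs}}$, and
report $k_{\mathrm{on}} = (k_{\mathrm{obs}} - k_{\mathrm{off}})/L$,
flagging the non-physical case $k_{\mathrm{obs}} < k_{\mathrm{off}}$.

# Kinetic BRET bias calculus

Functional kinetics are analysed per timepoint on a 2–46 min grid in 2-min
cycles (23 timepoints by default; arbitrary grids are accepted). At each
timepoint and for each independent experiment a raw-scale logistic is
fitted; the net BRET span is the fitted maximum minus the fitted minimum
(the fitted curve's minimum, not the data minimum, so adding a constant to
all raw readings changes nothing); and each compound's maximal net BRET is
normalized to the reference span at the same timepoint, giving %Emax.
Timepoints whose reference curve is missing or unconverged are reported as
gaps, never interpolated.

The bias calculus uses the proxy transduction index

$$\mathrm{TI} = \log_{10}\!\left(\frac{\%E_{\max}}{\mathrm{EC}_{50}}\right),$$

which is deliberately distinct from the operational-model transduction
coefficient $\log(\tau/K_A)$ (out of scope here). TI is computed per
independent experiment and then averaged; the dispersion entering the
error propagation is the across-experiment standard deviation of TI.
Differences against the reference give $\Delta\mathrm{TI}$ per pathway and
the bias factor $\mathrm{bias}_x = \Delta\mathrm{TI}_{G_o} -
\Delta\mathrm{TI}_{\beta\mathrm{arr2}}$ at timepoint $x$. Because the
reference is subtracted within each pathway, any common rescaling of the
EC50 unit (molar vs nanomolar) cancels; EC50s are kept in molar purely for
reproducibility. Standard errors compose by root sum of squares:
$\mathrm{sem} = \sigma/\sqrt{n}$, then
$\mathrm{SE}_{\mathrm{assay}} = \sqrt{\mathrm{sem}_{\mathrm{compound}}^2 +
\mathrm{sem}_{\mathrm{ref}}^2}$ per pathway, then
$\mathrm{SE}_{\mathrm{final}} = \sqrt{\mathrm{SE}_{G_o}^2 +
\mathrm{SE}_{\beta\mathrm{arr2}}^2}$ — a monotone composition, so the final
uncertainty can never undercut a component.

One genuinely open reading concerns the %Emax entering TI: the fitted top
asymptote versus the maximum net BRET of the fitted curve. The package
uses the fitted-curve maximum net value (equal to the fitted span), which
matches the normalization used for the per-timepoint efficacy traces; for
a three-parameter logistic the two coincide on the net scale.

# APEX time-course scoring and spatial deconvolution

Protein log2 intensities over the activation time course (0, 1, 5, 10,
30 min) are modelled with a continuous cubic polynomial in the *rank* of
the timepoint (1–5). Rank encoding compresses the long tail of the design
so the rapid early changes (0 to 1 min) are not starved of resolution. An
additive batch term absorbs background shifts between batches. Each
protein's time-dependent model is compared with a batch-only null by the
classical nested-model F test; the cubic basis is orthogonalized over the
observed rank grid for conditioning (fitted values are basis-independent,
verified against an explicit raw-polynomial QR oracle in the tests). The
maximum log2 fold change is the signed per-rank mean change of largest
magnitude between rank 1 and any later rank, computed after imputing
missing cells from the fitted model; the interactor call applies
`|max_log2fc| > log2(1.5)` and `p <= 0.05`. Two things deserve emphasis:

* the thresholds are raw — no multiple-testing correction is applied
  anywhere in this pipeline, matching the thresholding design it
  implements; treat the calls as a screening set, not an error-controlled
  discovery list; and
* a perfectly constant series is reported with `F = 0`, `p = 1` and flag
  `"constant"` rather than letting a 0/0 ratio of rounding errors through.

Marker selection for the spatial references computes, for every
non-redundant compartment pair, the mean-difference log2FC and a t
statistic whose variance is pooled across *all* references (residual
variance of a one-way compartment model), with thresholds `p < 0.005` and
`log2FC > 1.0` in either orientation, plus an absolute-intensity filter:
above the 50th percentile of all observed intensities (over reference and
receptor samples jointly) in every replicate of at least one reference.
The intensity filter operates on observed (log2) intensities, before any
scaling — percentile comparisons are invariant to the monotone log, and
the 0–1 rescaling below is a per-protein transform that would distort a
global percentile.

For deconvolution, intensities are linearly scaled per protein to [0, 1]
by dividing by the row maximum over reference and receptor samples
jointly, with missing values set to zero (the solver's input convention; a
scaled matrix is idempotent under re-scaling). The reference matrix `F`
holds per-compartment replicate means of scaled intensities; its
panel-restricted rows form `S`. Each receptor sample's scaled panel vector
`y` is decomposed by nonnegative least squares over `S` augmented with
three dummy columns whose entries are drawn i.i.d. with replacement from
the entries of `S` — the dummies soak up unstructured signal that would
otherwise surface as spurious small-but-nonzero coefficients. The draw is
repeated 1,000 times with a per-sample seed stream and the per-compartment
median over repeats is reported. Because the 0–1 scaling is a per-row
positive rescaling applied consistently to references and samples, a
sample that is a nonnegative mixture of compartment profiles on the
linear scale remains the same mixture of the scaled reference columns, so
the coefficients estimate the mixing weights directly; batch offsets act
as a common multiplicative factor on a sample's coefficients and are not
corrected, mirroring the deconvolution design this implements.

# Fibre photometry

Both channels are zero-phase Butterworth low-pass filtered at 10 Hz
(order 2, forward–backward; filtering is done about the channel mean since
the filter has unit DC gain, avoiding start-up transients) and decimated
10x. The baseline F0 is the isosbestic channel mapped through a
polynomial (default affine) regression estimated on the baseline window —
either against the raw biosensor signal (`polynomial_rescale`) or against
a peak-suppressed version obtained by asymmetric least squares
(`baseline_als`; `p = 0.5` gives the symmetric-weights variant, since
"symmetric least-squares filtering" has no single standard definition and
the implemented variants are labelled rather than claimed exact).
dF/F is $(F - F_0)/F_0$ pointwise — the formula is sometimes printed with
the parenthesis dropped, but the literal parse $(F - F_0/F_0)$ is
dimensionally inconsistent and is not used. Samples with $F_0 \le 0$ are
masked with a warning.

Transient detection uses a per-animal threshold fixed once on a baseline
recording: median plus $k$ MADs of the baseline dF/F ($k = 2.5$ by
default, MAD with the Gaussian consistency constant). Events are local
maxima whose topographic prominence reaches the threshold; amplitude is
the prominence, duration the full width at half prominence, and frequency
the events per minute of the analysis window (per-bin normalization where
binned). Slow signalling is summarized by filtering dF/F with a 0.1 Hz
zero-phase Butterworth filter (order 2, order unstated upstream and chosen
here) and integrating trapezoidal AUC in consecutive 5-min bins aligned to
the injection time; bin edges snap to sample points so AUC is exactly
additive over adjacent bins.

# Endpoint calculators

Scalar calculators implement: percent maximum possible effect
$100(\text{post} - \text{baseline})/(\text{max} - \text{baseline})$ with
the hot-plate cut-off as the maximum (45 s in rats); ED50 from a logistic
with asymptotes fixed at 0 and 100 on the %MPE scale ("normalized
response"); the PET standardized uptake value $C/(\mathrm{dose}/BW)$;
unbound concentrations $\mathrm{total}\times(1 - \mathrm{PPB})$;
brain/plasma ratios; microsomal percent remaining; fold differences; and
the naloxone-precipitated withdrawal score — graded points for jump
attempts (1/2/3 for 1–4, 5–9, >10), paw tremors (2/4 for 1–2, 3+), wet dog
shakes (1/2 for 1–2, 3+) and fecal deposits (1 each), checked-sign weights
(abdominal spasms 2, abnormal posture 3, diarrhea 2,
irritability/vocalization 3, genital grooming 3, profuse salivation 7,
ptosis 2, swallowing movements 2, teeth chattering 2), and 1 point per
gram of weight lost, averaged across the two raters and summed across
signs. Counts of exactly 3 tremors or shakes fall between the published
brackets; the package assigns them to the higher bracket (3+ reads
naturally as "three or more"), while exactly 10 jump attempts stays in the
2-point bracket (">10" read literally). Fractional grams round to the
nearest gram. For the catalepsy score the %MPE maximum is 6 and the
baseline 3 (the floor of the 3-symptom scale), a reading flagged in the
documentation because the source formula leaves it implicit.

# Synthetic data: what it emulates and what it does not

Each generator writes the study design it emulates into its defaults and
echoes every generating parameter in a `truth` object.

* **BRET plates**: 8 half-log concentrations, 3 replicates, a DAMGO
  reference with the nitazene agonists' measured G-protein potencies and
  supramaximal efficacies, ligand-free wells, additive Gaussian noise on
  the raw ratio scale (s.d. 0.003 against a 0.1 reference span). Kinetic
  plates default to the 23-point 2–46 min grid with 9 independent
  experiments and %Emax trajectories that relax exponentially from the
  2-min values (120.8%, 123.2%) to the plateaus (111.2%, 98.4%).
* **Binding kinetics**: association/dissociation on 0–120 min grids from
  the one-step binding model with
  $k_{\mathrm{obs}} = k_{\mathrm{on}} L + k_{\mathrm{off}}$.
* **APEX**: four compartments (plasma membrane, early endosome, late
  endosome/lysosome, cytoplasm) with 15 markers each elevated 3 log2
  units, 3 reference replicates, 4 receptor replicates per ligand and
  timepoint, two batches with additive log2 offsets, mixtures formed on
  the linear scale then logged (matching the scale the solver sees), log2
  Gaussian noise (s.d. 0.25) and missing-at-random dropout. The noise
  model is a declared choice — the assay itself states no distribution.
* **Photometry**: a shared bleaching/drift component in both channels, a
  sensor-specific slow oscillation (1.5% dF/F, periods of tens of
  seconds) standing in for spontaneous neuromodulator tone, Gaussian-bump
  transients (8% dF/F, width 1.5 s) and 0.2% instrument noise. The
  physiological floor is what the per-animal MAD threshold calibrates
  against in real recordings; with only instrument noise in the baseline
  the 2.5-MAD prominence threshold would sit inside the noise-prominence
  distribution and detection precision would be meaningless. Defined this
  way, the default transient amplitude is about five MADs of baseline
  dF/F. Not emulated: photon shot statistics, motion artifacts beyond
  what the shared component captures, hardware-specific demodulation.
* **Endpoints**: hot-plate latencies from a logistic dose–response on the
  %MPE scale (ED50 0.005 mg/kg by default), a brain/plasma table with the
  measured protein binding, and two-rater withdrawal observations with
  Poisson counts and Bernoulli checked signs.

A single integer seed drives a split per-generator stream (each family
derives its own sub-seed), so adding a generator never changes another's
output, and all generators restore the caller's RNG state.

Passing recovery tests on these generators demonstrates that the
estimators invert their own generating models at realistic noise — it
does not certify performance on real data, whose noise is neither
Gaussian nor independent and whose baselines contain structure the
generators omit.

# Problem sizes used by the tests and acceptance script

Sizes were chosen to exercise each property at the smallest scale where
its statistics are stable: 2,000 simulated null proteins for the type-I
error of the time-course F test (rejection rate at $\alpha = 0.05$
expected in [0.03, 0.07]); 100 synthetic mixtures at 5% noise and 1,000
randomization repeats for deconvolution recovery (per-compartment RMSE
below 0.05, and exact recovery of compartment-pure samples to 1e-6); 200
simulated plates at 5% CV noise for pEC50 recovery (median absolute error
below 0.1); 50 seeded recordings of 20 min at 400 Hz for transient
sensitivity and precision (both at least 0.95); and reduced kinetic grids
(3–6 timepoints, 2–3 experiments) wherever a property is
timepoint-independent.

# Known limitations

* The logistic fit covariance is reported in the internal
  (bottom, log-span, pEC50) parameterization.
* The simplified protein summarization boundary: inputs are assumed to be
  protein-level intensities; transition-level summarization, feature
  filtering and single-peptide exclusion belong to the upstream pipeline.
* No multiple-testing control in the APEX screening thresholds (by
  design, see above).
* The bias calculus assumes both pathways were measured on the same
  timepoint grid; unmatched grids yield gaps rather than alignment.
* `pracma::lsqnonneg` (Lawson–Hanson) is the NNLS solver; extremely
  collinear reference panels can make individual repeats slow, which the
  dummy-column randomization mitigates in practice.
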
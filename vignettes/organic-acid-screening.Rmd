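---
title: "Quantitative urinary organic-acid screening: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative urinary organic-acid screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oascreen)
library(dplyr)
```

# The screening problem

Inborn errors of metabolism (IEMs) of the organic-aciduria type leave
characteristic patterns of organic acids in urine. `oascreen` implements
the computational side of a targeted LC-QTOF/MS assay for this screening
task: a fixed panel of 75 negative-mode ions (71 disease biomarkers and 4
medication markers) is extracted from high-resolution full-scan data,
quantified against stable-isotope internal standards, normalized to
urinary creatinine, and summarized per patient as a z-score profile
against age-matched controls. The profile — not any single concentration
— is the diagnostic readout: a clinician scans one plot for analytes
outside the reference band instead of a long table of numbers.

# The quantification model

## From centroids to areas

Input data are centroided scans `(rt, m/z, intensity)`. For each panel
target an extracted ion chromatogram (EIC) sums centroid intensities
within a ±10 ppm window of the target mass, scan by scan. Peaks are
integrated trapezoidally between the local minima flanking the apex found
near the expected retention time. Two numerical choices matter here:

* **Apex selection.** Within the retention-time search window (default
  ±0.1 min) the apex is the candidate local maximum *nearest the expected
  retention time* among those clearing three times a rough noise floor,
  not the global window maximum. Several panel pairs share an exact mass
  and elute 0.05–0.10 min apart (adipic acid / 3-methylglutaric acid;
  tiglylglycine / 3-methylcrotonylglycine); a grossly elevated neighbour
  would otherwise capture the integration. Pairs this close are still
  reported with an `ambiguous` flag — resolving them requires the full
  biomarker profile and the clinical picture, and the package makes no
  attempt at chromatographic deconvolution.
* **Noise.** The noise level is `1.4826 × MAD` of the EIC intensities
  outside the integrated region, floored at one count. A peak is `found`
  when its apex exceeds 3 × noise; S/N is apex height over noise. The
  limit of detection is the concentration at which S/N reaches 3, the
  limit of quantification at S/N = 10, hence `lod = 3·noise/slope` and
  `loq = 10·noise/slope` through the calibration slope.

## Calibration and the two quantification modes

Sixty-eight analytes have authentic standards and are quantified against
their own 6-point calibration line of response ratio (analyte area /
internal-standard area) versus concentration, fitted by unweighted
ordinary least squares; `weighting = "1/x"` is available for users who
prefer variance stabilization at the low end, but the default follows the
assay's validated setup. The remaining seven analytes (three
surrogate-standard disease markers and the four medication markers) use
the relative internal-standard rule
`conc = (area / istd_area) × istd_conc`, which assumes the analyte shares
its internal standard's response factor. Negative back-calculated
concentrations are clipped to zero and flagged `below_lod`; a picomolar
epsilon (1e-9 µmol/L) absorbs floating-point residue so exact fits report
exactly zero.

Concentrations are multiplied by the per-sample dilution factor and
divided by the urinary creatinine concentration (mmol/L, an external
clinical-chemistry input), giving µmol analyte per mmol creatinine. The
dilution factor is an explicit per-sample input rather than a hard-coded
constant because laboratories pre-adjust urine to a creatinine target
before dilution.

# The reference model and z-scores

Reference statistics are built per analyte and age group (0–2 years and
above 2 years; a sample aged exactly 2 years belongs to the younger
group). Missing values and values below the LOD are imputed *at* the LOD,
values are log2-transformed, and the mean and standard deviation stored.

Two degenerate situations get special treatment:

* **Never-detected analytes.** When every control value is imputed, the
  mean is pinned to `log2(LOD)` and the SD fixed at **0.774**. This
  constant is `log2(5)/3` to three decimals, which calibrates the scale
  so that a measurement at five times the LOD scores exactly z = 3. This
  identity also pins the log base: with natural logs the same behaviour
  would need SD 0.536, with log10 0.233, so the package works in log2
  throughout.
* **Collapsed cohorts.** A detected analyte whose control SD falls below
  0.1 log2 units (possible only in synthetic edge cases) has its SD
  raised to that floor to keep z-scores finite.

The z-score of a sample value is
`z = (log2(max(conc, LOD)) − mean_log2) / sd_log2`; the imputation inside
the `max` means a not-detected analyte measured at or below its LOD
scores exactly 0. Signed z-scores are reported for detected-but-low
analytes rather than flooring at zero — low excretion can be informative
— and the flagging thresholds are configurable, defaulting to
*borderline* for `2.5 < z ≤ 3.0`, *elevated* for `z > 3.0` and
*decreased* for `z < −2.5` (the borderline band is applied
symmetrically). Because z-scores are differences of logs, multiplying
every concentration (cohort and sample alike) by a common factor leaves
every z unchanged — the property that makes creatinine normalization and
unit choices safe.

```{r zscore-demo}
# the 0.774 rule in action
ref <- build_reference(
  tibble(sample_id = sprintf("c%02d", 1:46), age_group = ">2y",
         analyte = "X", conc_norm = 0),
  lods = tibble(analyte = "X", lod_norm = 2))
zscore(5 * 2, ref$mean_log2, ref$sd_log2, ref$lod_norm)
```

# Method cross-validation statistics

For comparison against an established method the package provides:

* **Passing–Bablok regression** (classic 1983 estimator, authored
  in-package): the slope is the shifted median of all pairwise slopes
  (slopes of −1 excluded, offset by the count of slopes below −1, which
  makes the estimator symmetric in x and y), the intercept
  `median(y − b·x)`, and confidence limits from the rank-based normal
  approximation. A slope outside 0.8–1.2 flags a method difference. The
  test suite checks the estimator against an independent exhaustive
  pairwise-slope oracle and checks that the 95% interval covers slope 1
  in at least 90% of simulated equivalent-method datasets.
* **Spiked recovery and linearity**: recovery is 100 × the OLS slope of
  measured result on weighed-in amount (the design of graded-spike
  external QA schemes), with the same fit's R² as the linearity metric
  and an 80–120% acceptance band; a simple ratio recovery is also
  exposed.
* **Per-analyte significance testing**: the choice between Welch's
  t-test and the Mann–Whitney U test is made by Shapiro–Wilk screens on
  both groups at α = 0.05 — a concrete operationalization of choosing
  the test "when proper", which the source assay left unspecified.

# What the synthetic-data module emulates

No raw instrument data or reference cohort accompanies the assay, so the
package ships a generator for every input layer, and the generator's
defaults define the test conditions:

* **Control cohorts**: 46 controls per age group (matching the reference
  cohort structure), log2-normal analyte levels with SD 0.5, geometric
  means at twice each analyte's lower calibration limit (1.5× higher in
  the 0–2y group, reflecting the higher organic-acid-to-creatinine ratio
  of infant urine), LODs at a quarter of the lower calibration limit,
  and log-normal creatinine around 5 mmol/L. Medication markers,
  hawkinsin and 2-pyrroloylglycine are absent from control urine, which
  exercises the never-detected reference rule.
* **Patient cases**: control draws with designated biomarkers multiplied
  by fold-changes. The built-in library (IVA, MCADD, PA, GA1, MMA,
  5-oxoprolinuria) uses fold-changes of 10–60, landing biomarkers at
  z ≈ 7–14 — the range qualitatively reported for confirmed cases.
* **Instrument data**: Gaussian chromatographic peaks at the panel
  retention times with area = response factor × injected concentration,
  internal-standard peaks in every injection, optional ppm-scale mass
  error and additive baseline noise. The default peak SD is 0.007 min
  (≈1 s FWHM) — sharp enough that isomer pairs 0.05 min apart are
  resolved, consistent with the assay's claim of adequate distinction —
  at 5 scans/s. Response factors are log-normal per analyte;
  relative-mode analytes share their internal standard's response factor,
  because that equality is the premise of the relative quantification
  rule.

What the generator deliberately does **not** model: full-scan chemical
background, isotopologue envelopes, ion suppression (reported for
4-hydroxybutyric and pyroglutamic acid but without an algorithm),
peak-shape pathologies of 2-methylcitric acid and succinylacetone, and
drug-metabolite chemistry beyond the presence or absence of the four
medication markers. A green test suite therefore demonstrates the
*computational* chain — extraction, integration, calibration,
normalization, reference statistics, flagging — is correct, not that the
assay's analytical performance transfers to any particular instrument.

# Problem sizes and determinism

The shipped tests and the acceptance script run the pipeline at desk
scale: cohorts of 46 per age group for reference statistics, 100
twelve-to-thirty-point datasets for the Passing–Bablok oracle check, 200
replicates for interval coverage and test calibration, and
instrument-level round trips over a handful of injections plus the full
6-level calibration series. Every stochastic step takes an explicit
integer seed, restores the caller's RNG state, and never touches global
options.

# Known limitations

* Co-eluting isobars closer than the chromatographic resolution are
  flagged, not deconvolved; their concentrations are conditional on the
  identity assignment.
* The mzML reader handles centroided MS1 spectra only; profile-mode data
  must be centroided upstream.
* Continuous mass recalibration is assumed to have happened on the
  instrument; inputs are taken as mass-accurate.
* The printed ions of hawkinsin and levetiracetam do not correspond to
  simple deprotonation of the parent molecule; their masses are stored
  verbatim and excluded from the formula-consistency check, and both are
  quantified by the relative rule.
* One panel isomer pair (adipic / 3-methylglutaric acid) is documented
  with a 0.05-min separation in the assay narrative but 4.93 vs 5.00 min
  in the panel table; the table values are stored.
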
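---
title: "Models and methods behind tmshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tmshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmshift)
```

## The assay and what the package computes

In a fluorescence thermal shift assay an environment-sensitive dye (SYPRO
Orange and relatives) binds hydrophobic surface exposed during thermal
unfolding of a protein, so the fluorescence trace of a well heated over a
temperature ramp rises through the unfolding transition and decays afterwards
as the dye–protein aggregates quench. The midpoint of the transition — the
melting temperature Tm — moves when a ligand binds and stabilizes the folded
state. Everything in this package derives from that one observable: Tm per
well, ΔTm between conditions, and the dependence of ΔTm on ligand or
inhibitor concentration.

The assay conditions the package (and its simulator) assumes are a 25–95 °C
ramp in 0.2 °C increments, micromolar protein probes, and either a dsDNA
ligand titration (for affinity) or an inhibitor dose series with and without
a fixed dsDNA concentration (for inhibition).

## Tm estimation

`estimate_tm()` locates Tm as the maximum of the positive derivative
d(RFU)/dT, the same definition real-time PCR instrument software uses, not a
Boltzmann sigmoid midpoint. A Boltzmann fit is deliberately out of scope:
melt curves with sloped baselines and post-transition quench violate the
two-state sigmoid far more than they displace the derivative peak.

Numerical choices:

* **Smoothing.** Default Savitzky–Golay, window 7 points (1.2 °C on the
  0.2 °C grid), polynomial order 3. A 7-point cubic filter preserves peak
  position and height to well below the grid step while suppressing
  instrument noise; a centred moving average is available, and `"none"`
  disables smoothing. On noiseless curves wider windows can only lower the
  derivative peak, a property the tests assert.
* **Differentiation.** Central differences at interior points, one-sided at
  the ends (`derivative_curve()`).
* **Sub-grid refinement.** The vertex of the parabola through the peak
  sample and its two neighbours. On noiseless simulated curves this brings
  the error to ~0.05–0.07 °C, dominated by the slight asymmetry of the
  van't Hoff transition; the acceptance tolerance of one grid step (0.2 °C)
  holds across Tm ∈ [30, 70] °C.
* **Search range.** By default 2 grid points are excluded at each end of the
  ramp, and everything above 90 °C, where quench dominates, is ignored. A
  peak on a range boundary is flagged `edge_peak` and not refined.

Quality control (`qc_curve()`) encodes the practical failure modes:
`high_background` when the initial RFU exceeds half the curve maximum (the
signature of a natively disordered or unstable probe, which binds dye before
any heating); `low_signal` when the dynamic range falls below a threshold
(default 1 RFU — raise it for real instruments); `no_transition` when the
derivative peak rises less than 10% of the dynamic range per °C above the
lowest derivative in the search range (a linear drift has prominence zero, a
genuine transition concentrates its amplitude over a few degrees). The 0.5
and 0.1 fractions are conventions of this package, exposed in
`qc_thresholds()`; the underlying failure modes are described only
qualitatively in the assay literature.

`delta_tm()` is plain group arithmetic — mean(sample Tm) − mean(reference
Tm) — with the replicate dispersion propagated as
√(sd²ₛ/nₛ + sd²ᵣ/nᵣ).

## The ligand-depletion binding model

With probe and ligand at comparable micromolar concentrations the free
ligand is appreciably depleted by binding, so the hyperbolic isotherm is
wrong and the quadratic (depletion) form is used, written directly in ΔTm:

$$\Delta T_m(\mathrm{D}) = \frac{(\Delta T_{max} + D + K_D) -
\sqrt{(\Delta T_{max} + D + K_D)^2 - 4\,\Delta T_{max} D}}{2}$$

where $D$ is total ligand concentration. `predict_delta_tm()` evaluates it
(the radicand equals $(D + K_D - \Delta T_{max})^2 + 4 K_D \Delta T_{max}$,
so it is clamped at zero purely against rounding); `fit_binding()` estimates
$(\Delta T_{max}, K_D)$ by unweighted least squares with bounded
Levenberg–Marquardt, starting from $\Delta T_{max} = \max \Delta T_m$ and
$K_D$ at the concentration nearest half-maximal shift.

Two caveats are inherent to this empirical parameterization and are
reported, not hidden:

* **Unit dependence.** The formula adds $\Delta T_{max}$ (°C) to
  concentrations, so the fitted $K_D$ depends on the concentration unit.
  The package fixes micromolar: only on that scale do the reference
  parameter sets (ΔTmax 1.678 °C with K_D 2.228; 2.462 °C with 0.794)
  reproduce the observed 1–1.5 °C and 2–3 °C shifts at 10 µM — on a molar
  scale the same numbers predict shifts of order 10⁻⁵ °C. Every fit result
  and workflow report records the unit.
* **Site multiplicity.** A duplex carrying two equivalent binding sites can
  be counted per-duplex or per-site. `site_multiplicity` multiplies the
  concentration axis (default 1 = duplex units). Matching conventions
  between data and fit recovers $K_D$ exactly; mismatched conventions do
  *not* rescale $K_D$ by exactly the multiplicity, because $\Delta T_{max}$
  does not scale with concentration and the model family is not closed
  under axis scaling — the factor-of-two intuition is only approximate, so
  the convention is stated rather than converted.

**Confidence intervals.** Linearized standard errors are unreliable for a
two-parameter nonlinear fit on seven points, so intervals are bootstrap
percentile (2.5/97.5) intervals throughout, seeded and reproducible.
`bootstrap_ci()` resamples fit residuals, leverage-adjusted
($r_i/\sqrt{1-h_i}$, centred) to undo the downward bias of raw least-squares
residuals. Inside `run_kd_workflow()`, where replicate-level Tm values
exist, the interval instead resamples the Tm replicates within every group
(reference included), inflating each resampled group-mean deviation by
$\sqrt{n/(n-1)}$ — the standard small-sample correction for the bootstrap
variance of a mean. The replicate-level scheme propagates the error
component all titration points share through the common reference mean,
which a residual bootstrap on the fitted series cannot see; in the package's
own calibration experiment (100 plates, 3 replicates, 0.1 °C Tm noise,
n_boot 400) it covered the generating $K_D$ in 92 runs, against the nominal
95, where the series-level residual bootstrap reached the high 80s.

## Inhibitor analysis

Two separate readouts, because they answer different questions:

* `destabilization_profile()` — Tm of probe + inhibitor minus untreated
  probe: direct compound binding or covalent modification that loosens the
  fold (negative shifts).
* `stabilization_suppression()` — percent inhibition of the DNA-induced
  shift, $100(1 - \Delta T_m(\mathrm{DNA}, d)/\Delta T_m(\mathrm{DNA}, 0))$,
  with each shift taken against the probe-alone Tm *at the same dose*, so
  destabilization does not masquerade as binding inhibition. Values are
  reported raw: above 100 means the shift reversed, below 0 means enhanced.

`fit_4pl()` fits `bottom + (top − bottom)/(1 + (IC50/dose)^hill)` on the
linear dose axis with IC50 as an explicit parameter. For percent-inhibition
responses the workflow pins the asymptotes at 0 and 100, which is what makes
the IC50 identifiable from a handful of doses; both asymptotes float when
the response is a raw Tm shift. A converged optimizer result whose IC50
lands more than two orders of magnitude outside the tested doses is
reported as non-converged ("ambiguous"): an inactive compound constrains no
midpoint, and pretending otherwise produces arbitrary numbers.

`compare_tm_groups()` is the classic pooled-variance two-tailed Student
*t* test (Welch behind a flag) with 0.05/0.01/0.001 stars. Two zero-variance
groups with equal means give p = 1 by convention; with unequal means the
limit t = ±∞, p = 0 is reported, which is why the negative-control tests
operate at realistic replicate noise rather than zero noise.

## Probe design screening

Dye-based assays fail on proteins with natively exposed hydrophobic surface
or extensive disorder. The package screens candidates with the
Kyte–Doolittle scale: `gravy()` (plain mean over all residues — the
window-independent definition the published reference values use),
`hydropathy_profile()` (sliding unweighted mean, default window 9, no edge
padding, positions at 1-based window centres to match residue numbering),
and `low_hydropathy_segments()` (maximal runs below a threshold, default
−1.5 for at least 10 windows) to flag hydrophilic/flexible stretches such
as linker and NLS regions. Machine-learned disorder predictors are
deliberately not reimplemented; the hydropathy screen is the transparent,
reproducible part of probe triage. The bundled canonical human RelA/p65
sequence (UniProt Q04206, 551 residues, GRAVY −0.4635) serves as the worked
example of a moderately hydrophilic probe parent.

## The simulator and what passing tests mean

`simulate_melt_curve()` builds RFU(T) from a van't Hoff two-state fraction
unfolded $f = 1/(1+\exp(\Delta G/RT))$, $\Delta G = \Delta H_{vH}(1 -
T/T_m)$ (absolute temperatures; $f(T_m) = 1/2$ exactly), mixed between
sloped native and unfolded baselines plus a transition amplitude, an
exponential quench beyond an onset (default Tm + 8 °C, rate 0.05 /°C), and
additive Gaussian noise. Defaults: Tm 42.5 °C, $\Delta H_{vH}$ 400 kJ/mol,
amplitude 1000 RFU on the 25–95/0.2 grid. Plate-level generators inject
ligand-induced shifts through the same depletion equation the fitter uses
and inhibitor effects through a 4PL suppression plus a per-dose
destabilization map, then add per-well Gaussian Tm noise. All randomness
derives from a single integer seed via deterministic per-well substreams,
so any well, plate or bootstrap is exactly reproducible.

Because simulator and fitter share the forward model, round-trip recovery
tests validate the estimation machinery — peak finding, aggregation,
optimization, intervals — not the biological truth of the model. Real melt
curves add what the simulator omits by design: unfolding irreversibility
and scan-rate dependence, aggregation artefacts, multi-domain transitions,
dye-binding kinetics, and plate-position effects. Passing tests therefore
certify that *if* the two-state/depletion description holds, the pipeline
recovers its parameters at the stated noise levels; they cannot certify the
description itself.

Problem sizes used by the validation suite (chosen as representative of one
96-well experiment per question): 7-concentration titrations (0.5–10 µM)
with 3 replicates and 0.1 °C Tm noise, 100 seeds for recovery/coverage
studies with 400 bootstrap replicates per fit; 8 log-spaced doses (1–100 µM)
with 2% response noise for IC50 recovery; 20 random instances per optimizer
for the brute-force grid-search cross-checks.

## Interfaces and degenerate inputs

Plate I/O is text-based: wide melt CSV (canonical; `Temperature` column
plus one column per well) and an equivalent long dialect, YAML plate
layouts (wells with probe/ligand/inhibitor, concentrations with recorded
units, replicate groups, roles; `replicate_group` defaults to the well id,
`role` to `sample`), and TSV result tables written with 6 significant
digits so identical inputs give byte-identical files. Validation is strict
and names the offending well, row or column: ragged or non-numeric cells,
non-monotone temperature grids, duplicate wells, negative concentrations
and reference wells carrying ligand or inhibitor are all hard errors.
Degenerate analysis inputs fail informatively rather than numerically:
all-zero shift series, fewer than three concentrations or four distinct
doses, flagged Tm estimates entering `delta_tm()` (overridable), and a
non-positive uninhibited DNA shift in the suppression calculation.

The exported functions and the two workflow wrappers are the package's
interface; `run_kd_workflow()`/`run_ic50_workflow()` never mutate their
inputs, log every excluded well exactly once with its QC reason, and
produce reports that are byte-reproducible given the same inputs, config
and seed.
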
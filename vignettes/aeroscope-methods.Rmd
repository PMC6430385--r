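---
title: "Methods: temperature-induced aerobic scope and companion expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-induced aerobic scope and companion expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The aerobic scope — the difference between maximal (MMR) and standard (SMR)
metabolic rate — is the classic currency for the thermal tolerance of aquatic
ectotherms, but both endpoints are usually elicited by forced exercise, which
is impractical in sluggish benthic invertebrates such as sea cucumbers.
`aeroscope` implements the temperature-induced alternative: an acute
temperature ramp (2 °C h⁻¹ at the defaults) drives oxygen consumption from a
cold metabolic plateau up to a warm peak, defining a temperature-induced
standard metabolic rate (TSMR) at the critical cold temperature
(CT$_\mathrm{crit}$), a temperature-induced maximal metabolic rate (TMMR) at
the critical warm temperature (WT$_\mathrm{crit}$), and a temperature-induced
aerobic scope

$$\mathrm{TAS} = \mathrm{TMMR} - \mathrm{TSMR}.$$

Rates come from intermittent-flow respirometry: 15-minute flush phases
alternate with 15-minute closed phases, and each closed-phase O₂ decline
yields one rate. The companion RT-qPCR stage quantifies the heat-shock
response (e.g. Hsp70) in calibrated normalized relative quantities so that
transcriptional stress markers can be read against the respiratory window.

## From O₂ trace to rate

Each closed phase is a time series of temperature-compensated O₂
concentration (mg L⁻¹, 1 Hz). The pipeline:

1. **Trim** the first and last `trim_seconds` (default 60 s) of the phase,
   where flush carry-over and valve transients distort the decline.
2. **Fit** an ordinary least-squares line `o2 ~ time`. The fit's $R^2$ is the
   squared Pearson correlation; a zero-variance trace is assigned $R^2 = 0$
   so that flat traces fail quality control deterministically instead of
   propagating `NaN`.
3. **Convert** the slope $b$ (mg L⁻¹ s⁻¹, negative for consumption) to a
   whole-chamber rate $-b \cdot V_\mathrm{eff} \cdot 3600$ mg O₂ h⁻¹.
   $V_\mathrm{eff}$ is the *water* volume: chamber volume (default 0.600 L)
   minus the animal's displacement, mass/(1000·density) with density
   1.0 g mL⁻¹ by default. Closed respirometry dilutes O₂ into the water the
   animal has not displaced, so using the nominal chamber volume would
   overestimate rates by roughly the animal's volume fraction (≈ 10 % for a
   63 g animal in 600 mL); both volume and density are configurable for
   users who prefer the nominal convention.
4. **Subtract background.** Microbial respiration is measured in the empty
   chamber before and after the trial; background at any elapsed time is
   linearly interpolated between those two anchors (clamped outside them),
   indexed at the closed-phase midpoint, assuming linear microbial
   accumulation. Blank phases use the full chamber volume (no animal).
5. **Scale** by animal mass to µg O₂ g⁻¹ h⁻¹.

Quality gates: slope $R^2 \ge 0.90$ and minimum saturation ≥ 80 % of a
reference concentration (the trace's initial value unless a 100 %-saturation
reference is supplied). Records failing a gate — including blank-corrected
rates that end up negative (`NEGATIVE_RATE`; the value is kept, unclipped) —
are excluded from aggregation but always written out with their reason
codes; silent dropping is deliberately impossible. One animal per chamber is
assumed, so each record is a biological replicate.

## Locating the aerobic window

QC-passing rates are averaged per nominal temperature (sample SD, n − 1
denominator). The profile has a characteristic plateau–rise–collapse shape,
and the linear aerobic window is found by fitting a *continuous three-segment
piecewise-linear model* — constant plateau, rising line, free line — for
every candidate breakpoint pair on the temperature grid, keeping the pair
with the smallest weighted residual sum of squares. Two design choices
deserve justification:

* **Why a changepoint fit rather than "the widest stretch whose own
  regression clears an $R^2$ threshold"?** A threshold on the window's own
  $R^2$ cannot localize the breakpoints: on a perfectly noiseless
  plateau–rise–collapse profile, stretches that swallow one or two plateau
  points still reach $R^2 \approx 0.99$, so a widest-window rule
  systematically overshoots the cold breakpoint. The segmented fit scores
  the *whole* profile, so a misplaced breakpoint pays for its misfit, and on
  noiseless piecewise-linear input the true breakpoints are the unique
  zero-residual optimum. The spec-style gates are retained: a candidate
  window must span at least `min_span` (4) grid temperatures and its
  interior OLS fit must have positive slope and $R^2 \ge$ `r2_min` (0.98 by
  default — slightly looser than the near-perfect linearity such profiles
  show, to tolerate replicate noise at n = 8). The reported window line is
  that interior OLS fit. Exact ties in residual sum (which occur on exact
  piecewise data) are broken by wider window, then higher $R^2$, then colder
  start, with an absolute tie tolerance of $10^{-9}$ times the profile's
  weighted variance so floating-point dust cannot rank candidates.
* **Why weighted least squares?** Replicate spread in such data scales with
  the mean (multiplicative between-animal variation), so rows are weighted
  $n_i / \bar{r}_i^2$ — inverse relative variance. This sharpens breakpoint
  localization at the cold end, where rates (and absolute noise) are small.

TSMR is the observed mean rate at the window's cold edge (CT$_\mathrm{crit}$)
— the *onset of the metabolic plateau*, not the global minimum, because
sub-critical rates may drift below the plateau as energy balance fails. TMMR
is, symmetrically, the observed mean rate at the warm edge
(WT$_\mathrm{crit}$). Anchoring both extremes to the fitted window edges
rather than to the global arg-max/arg-min keeps them stable on a 1 °C grid,
where adjacent true means differ by only a few percent while an n = 8 mean
has a ~5 % standard error — a global arg-max would wander off the peak in a
fifth of replicate experiments. Departures from the expected shape are
reported as warnings, never silently accepted: `CENSORED_PEAK` (no
temperature beyond the warm edge was measured, so no downturn was observed),
`NON_PEAK` (a rate beyond the warm edge is not strictly lower than TMMR) and
`NO_PLATEAU` (a sub-critical mean deviates from TSMR by more than
`plateau_tol`, default one SD of the cold-edge row).

Derived quantities:

* $\mathrm{TAS} = \mathrm{TMMR} - \mathrm{TSMR}$ (enforced identity).
* $Q_{10} = (R_2/R_1)^{10/(T_2-T_1)}$ between the acclimation-temperature
  mean rate and each critical endpoint. $Q_{10}$ is symmetric under swapping
  both endpoints and invariant to rescaling both rates.
* The midpoint construction: $r_\mathrm{mid} = (\mathrm{TMMR} +
  \mathrm{TSMR})/2$, mapped through the window regression to a temperature
  $t_\mathrm{opt}$ (clamped into the window). It is a geometric optimum —
  the temperature with equal aerobic reserve toward either critical
  temperature — not a claim about organismal preference. The optimal
  performance band runs from the regression rate at the acclimation
  temperature (29 °C default) up to $r_\mathrm{mid}$.

No parametric thermal-performance curve (Gaussian, Sharpe–Schoolfield) is
fitted: the construction is piecewise-linear by design.

## The expression stage

Technical replicates are averaged per sample × gene (scatter above 0.5
cycles warns, never silently excludes). The relative-quantification chain is
the standard geometric hierarchy:

$$\mathrm{RQ}_{g,i} = E_g^{\,\overline{Cq}_g - Cq_{g,i}}, \qquad
\mathrm{NF}_i = \Big(\prod_{r \in \mathrm{refs}} \mathrm{RQ}_{r,i}\Big)^{1/|\mathrm{refs}|},$$
$$\mathrm{NRQ}_i = \mathrm{RQ}_{t,i}/\mathrm{NF}_i, \qquad
\mathrm{CNRQ}_i = \mathrm{NRQ}_i / \mathrm{geomean}(\mathrm{NRQ}_\mathrm{cal}).$$

Amplification efficiency $E$ defaults to 2.0 (perfect doubling) and can be
estimated from a dilution series as $10^{-1/\mathrm{slope}}$. Calibration
defaults to the whole run, which makes the run's CNRQ geometric mean exactly
1 (and explains why control groups need not average 1); any group can be the
calibrator instead, and between-sample ratios are provably invariant to that
choice. At least two reference genes are required; their stability is scored
with the geNorm measure $M_j$ — the mean SD of pairwise log₂ expression
ratios with every other candidate — flagged unstable at $M \ge 0.5$. Group
summaries are geometric means with *t*-based confidence intervals on the
log₂ scale, back-transformed, hence multiplicatively symmetric
(high/mean = mean/low). Group differences use the Mann-Whitney test: exact
(equivalent to full enumeration of all labelings) whenever the smaller group
has ≤ 10 observations and there are no ties, otherwise a tie- and
continuity-corrected normal approximation; identical groups return p = 1.
Treatment groups are compared against a (possibly pooled) control set
defined by group labels, not hard-coded.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the ramp design so
every stage can be validated against known ground truth without instrument
data.

* **Design**: two ramps from the 29 °C acclimation temperature (to 41 °C and
  to 17 °C), 8 animals per ramp, one closed phase per 1 °C step, pre/post
  blank phases, 1 Hz sampling. The acclimation temperature is measured in
  both ramps, so the pooled control row has n = 16.
* **Truth curve**: plateau at TSMR\* = 2.2 µg g⁻¹ h⁻¹ below CT\* = 22 °C, a
  linear rise to TMMR\* = 33.2 at WT\* = 38 °C, and a linear collapse to
  13.3 at 41 °C. The rise is linear (such profiles correlate near-perfectly
  with temperature) rather than $Q_{10}$-exponential.
* **Noise model**: each animal carries a multiplicative lognormal scalar
  with CV 0.15 — the middle of the 14–20 % relative spread typical of
  per-temperature replicate SDs in such experiments; each O₂ reading gets
  i.i.d. Gaussian sensor noise with SD 0.005 mg L⁻¹, chosen so that
  plateau-level declines (≈ 8·10⁻⁵ mg L⁻¹ s⁻¹ over a trimmed 13-minute
  window) retain $R^2 \gtrsim 0.90$, as optical-sensor traces that pass the
  quality gate in practice do; background drifts linearly from 0.01 to
  0.03 mg O₂ h⁻¹ over the trial. Closed phases start at the Garcia–Gordon
  O₂ solubility for the phase temperature (salinity 35) and are shortened
  whenever the combined consumption would deplete more than 20 % of
  saturation, mirroring the >80 %-saturation operating rule; infeasible
  parameter combinations raise an error rather than clip.
* **Cq scenario**: one heat-inducible target over two stable references,
  three technical replicates, groups control (n = 16), heat and cold (n = 8
  each) with true fold changes 20, 1.2 and 1 — the ratio structure of a
  strong heat-shock induction with no cold response. Biological scatter
  1.5 cycles (matching the wide, multiplicatively symmetric CIs such data
  show), shared per-sample loading shifts of 0.5 cycles (removed exactly by
  normalization), reference wobble 0.1 and technical noise 0.15 cycles.
* **Determinism**: every generator takes one integer seed; identical seeds
  give byte-identical tables, and the caller's RNG state is restored.
  Ground-truth manifests record every per-cycle animal rate and fold
  change.

What the generator does *not* emulate: within-phase mixing dynamics (the
decline is ideal-mixing linear), sensor drift or autocorrelated noise,
temperature-dependent microbial growth beyond the linear drift, activity
bursts, or day effects. Passing recovery tests therefore demonstrate that
the estimators are correct and well-calibrated for this error model — not
that real traces are this clean.

## Numerical choices and test scale

* Zero-variance responses: $R^2 \equiv 0$ (QC fails deterministically).
* Background interpolation clamps outside the pre/post anchors; equal
  anchors return the pre-rate.
* Equal-width window ties: higher interior $R^2$, then colder start.
* Mann-Whitney "exact" mode refuses ties explicitly rather than silently
  approximating.
* All randomness flows from explicit seeds; no hidden global state.

The test suite validates each operation against independent oracles
(closed-form OLS, full Mann-Whitney enumeration up to group sizes of six,
direct log-ratio-SD geNorm on small fixtures), checks the structural
invariants (Q₁₀ symmetry and scale invariance, TAS shift invariance, trim
composition, calibration invariance, CI symmetry), and measures parameter
recovery on 100 seeded replicate studies at the default design (16 animals,
25 grid temperatures, ~190 000 trace points per study) plus 200 seeded null
qPCR experiments for p-value uniformity. These sizes keep the whole suite
around a minute on one core while leaving Monte-Carlo margins interpretable.

## Known limitations

* TSMR/TMMR are observed edge-row means, so their precision is bounded by
  n at a single temperature; with 8 replicates and ~15 % animal CV the
  standard error is ~5 %, and roughly one replicate study in ten will miss
  one of them by more than 10 % even when the breakpoints are found exactly.
* Critical temperatures are reported on the measurement grid (1 °C here);
  no sub-grid interpolation of breakpoints is attempted.
* Whether blanks were measured per temperature or only pre/post trial is
  ambiguous in typical protocols; the linear time interpolation implemented
  here is exact only when microbial growth is linear in time.
* Absolute CNRQ values depend on the calibration set and instrument export
  conventions; only ratios and significance structure are comparable across
  analyses.
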
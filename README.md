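# aeroscope

Temperature-induced aerobic scope analysis from intermittent-flow
respirometry, with a companion RT-qPCR relative-expression stage.

## What it is for

The aerobic scope — maximal minus standard metabolic rate, AS = MMR − SMR —
is the standard currency for thermal tolerance in aquatic ectotherms, but
both endpoints are normally elicited by forced exercise, which fails for
sluggish benthic invertebrates (sea cucumbers and similar low-activity
species). `aeroscope` implements the temperature-induced alternative: an
acute thermal ramp (2 °C h⁻¹) drives oxygen consumption from a cold
metabolic plateau to a warm peak, defining

- **TSMR**, the temperature-induced standard metabolic rate, at the critical
  cold temperature **CT_crit** (plateau onset),
- **TMMR**, the temperature-induced maximal metabolic rate, at the critical
  warm temperature **WT_crit** (peak),
- **TAS = TMMR − TSMR**, the temperature-induced aerobic scope,
- **Q10 = (R₂/R₁)^(10/(T₂−T₁))**, the temperature coefficient between the
  acclimation temperature and each critical endpoint,
- a midpoint thermal optimum: the temperature at which the linear-window
  regression attains r_mid = (TMMR + TSMR)/2.

The package takes raw closed-phase O₂ traces (long-format CSV) through
trimming, OLS slope extraction with quality gates (R² ≥ 0.90, ≥ 80 %
saturation), microbial-background correction (linear interpolation between
pre- and post-trial blanks), and mass-specific conversion; aggregates rates
per temperature; and locates the linear aerobic window with a
plateau–rise–collapse changepoint fit. The qPCR stage implements the
RQ → normalization factor → NRQ → CNRQ chain, geNorm reference-gene
stability (M < 0.5), log-symmetric 95 % confidence intervals, and exact
Mann-Whitney group comparisons — so heat-shock gene induction (e.g. Hsp70)
can be read against the respiratory window. A seeded synthetic-data
generator emulates the full study design for validation and teaching.

## Worked example

Simulate a two-ramp study (8 animals ramped 29→41 °C, 8 ramped 29→17 °C,
ground truth TSMR 2.2 / TMMR 33.2 µg O₂ g⁻¹ h⁻¹ at 22 / 38 °C), extract
rates, and analyse the thermal window:

```r
library(aeroscope)

study  <- simulate_study(seed = 1)
rates  <- process_traces(study$traces, study$metadata)
result <- thermal_window_analysis(rates)
print(result)
```

```
Temperature-induced aerobic scope analysis
  linear window : 22.0-38.0 degC (R^2 = 1.000)
  TSMR          :   2.35 ug O2/g/h at CT_crit = 22.0 degC
  TMMR          :  33.73 ug O2/g/h at WT_crit = 38.0 degC
  TAS           :  31.39 ug O2/g/h
  Q10 (29->22 degC): 15.6   Q10 (29->38 degC): 2.3
  thermal optimum: 30.0 degC at r_mid = 18.04 ug O2/g/h
```

The window fit recovered both critical temperatures exactly on the 1 °C
grid; TSMR and TMMR sit within sampling error (n = 8, ~15 % between-animal
CV) of the generator's truth, and TAS ≈ 31.4 estimates the true scope of
31.0. The very large cold-side Q10 is the expected signature of the steep
approach to the plateau; the warm-side value (≈ 2.3) is in the ordinary
2–3 physiological range. `plot(result)` draws the profile, window line and
TMMR/TSMR markers.

The expression stage works the same way:

```r
cqres <- generate_cq(cq_scenario(), seed = 1)   # Hsp70 vs ActB + 18S rRNA
qpcr  <- qpcr_analysis(cqres$cq, reference_genes = c("ActB", "S18"),
                       control_groups = "control_29C")
print(qpcr)
```

which reports per-group geometric-mean CNRQ with multiplicatively symmetric
95 % CIs, geNorm M for both references (stable, M ≈ 0.17 < 0.5), and exact
Mann-Whitney comparisons of each treatment against the pooled controls
(heat group strongly induced, cold group null).

Real data enter through the documented CSV schemas (`read_o2_traces()`,
`read_chamber_metadata()`, `read_cq_table()`), and the staged runners
(`run_simulate()`, `run_respirometry()`, `run_thermal_window()`,
`run_qpcr()`, `run_all()`) read a YAML config and write CSV/JSON outputs
with provenance headers. A thin command-line front-end with the same
subcommands is installed at `inst/scripts/aeroscope`.

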
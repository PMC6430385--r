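#' Thermal-ramp respirometry protocol
#'
#' Describes the intermittent-flow ramp design: starting at the acclimation
#' temperature, the bath is ramped at `rate` degC/h towards `end_temperature`
#' while 15-min flush / 15-min closed cycles alternate, giving one closed
#' measurement per `rate * (flush + measure)/60` degC step (one per degree at
#' the defaults).
#'
#' @param start_temperature Starting (acclimation) temperature, degC.
#' @param end_temperature Final temperature of the ramp, degC.
#' @param rate Absolute ramp rate in degC/h (default 2; the sign is taken
#'   from the direction of `end_temperature`).
#' @param flush_minutes,measure_minutes Cycle phase lengths (default 15 each).
#' @param sampling_interval O2 sampling interval in seconds (default 1).
#' @return An object of class `ramp_protocol`; its `temperatures` field holds
#'   the nominal temperature of every measurement cycle.
#' @export
ramp_protocol <- function(start_temperature = 29, end_temperature = 41,
                          rate = 2, flush_minutes = 15, measure_minutes = 15,
                          sampling_interval = 1) {
  if (rate <= 0) abort("ramp rate must be > 0 degC/h", "bad_protocol")
  step <- rate * (flush_minutes + measure_minutes) / 60
  dir <- sign(end_temperature - start_temperature)
  if (dir == 0) abort("end_temperature must differ from start_temperature",
                      "bad_protocol")
  temps <- seq(start_temperature, end_temperature, by = dir * step)
  structure(
    list(start_temperature = start_temperature,
         end_temperature = end_temperature, rate = dir * rate,
         flush_minutes = flush_minutes, measure_minutes = measure_minutes,
         sampling_interval = sampling_interval, temperatures = temps),
    class = "ramp_protocol"
  )
}

#' Ground-truth thermal performance curve
#'
#' The generator's piecewise-linear truth: a metabolic plateau at `TSMR_true`
#' below the critical cold temperature, a linear rise to `TMMR_true` at the
#' critical warm temperature, and a linear collapse towards `collapse_rate`
#' at the warm end of the protocol. Noise parameters: multiplicative
#' lognormal between-animal variation (`between_animal_cv`), i.i.d. Gaussian
#' sensor noise on each O2 reading (`sensor_sd`, mg/L), and a microbial
#' background ramping linearly from `blank_start` to `blank_end` (mg O2/h per
#' chamber) over the trial.
#'
#' @param TSMR_true,TMMR_true Plateau and peak mass-specific rates, ug O2/g/h.
#' @param CT_true,WT_true Critical cold and warm temperatures, degC.
#' @param collapse_rate Rate at the warm end of the protocol, ug O2/g/h.
#' @param between_animal_cv Coefficient of variation of the per-animal
#'   multiplicative scalar (default 0.15).
#' @param sensor_sd O2 reading noise SD in mg/L (default 0.005).
#' @param blank_start,blank_end Whole-chamber microbial background at the
#'   start and end of the trial, mg O2/h.
#' @return An object of class `true_curve`.
#' @export
true_curve <- function(TSMR_true = 2.2, TMMR_true = 33.2, CT_true = 22,
                       WT_true = 38, collapse_rate = 13.3,
                       between_animal_cv = 0.15, sensor_sd = 0.005,
                       blank_start = 0.01, blank_end = 0.03) {
  if (TMMR_true <= TSMR_true) abort("TMMR_true must exceed TSMR_true", "bad_curve")
  if (CT_true >= WT_true) abort("CT_true must be below WT_true", "bad_curve")
  if (between_animal_cv < 0 || sensor_sd < 0) {
    abort("noise parameters must be >= 0", "bad_curve")
  }
  structure(
    list(TSMR_true = TSMR_true, TMMR_true = TMMR_true, CT_true = CT_true,
         WT_true = WT_true, collapse_rate = collapse_rate,
         between_animal_cv = between_animal_cv, sensor_sd = sensor_sd,
         blank_start = blank_start, blank_end = blank_end),
    class = "true_curve"
  )
}

#' Evaluate the ground-truth rate at a temperature
#'
#' Plateau below `CT_true`, linear interpolation from `(CT_true, TSMR_true)`
#' to `(WT_true, TMMR_true)` inside the window, and linear decline from
#' `(WT_true, TMMR_true)` to `(t_end, collapse_rate)` above it.
#'
#' @param curve A [true_curve()].
#' @param temperature Temperature(s) in degC.
#' @param t_end Protocol end temperature anchoring the collapse segment
#'   (default 41).
#' @return Mass-specific rate(s) in ug O2/g/h.
#' @export
true_rate <- function(curve, temperature, t_end = 41) {
  stopifnot(inherits(curve, "true_curve"))
  with(curve, {
    rise <- TSMR_true + (TMMR_true - TSMR_true) *
      (temperature - CT_true) / (WT_true - CT_true)
    fall <- if (t_end > WT_true) {
      TMMR_true + (collapse_rate - TMMR_true) *
        (pmin(temperature, t_end) - WT_true) / (t_end - WT_true)
    } else TMMR_true
    ifelse(temperature <= CT_true, TSMR_true,
           ifelse(temperature <= WT_true, rise, fall))
  })
}

#' Oxygen solubility of seawater
#'
#' Equilibrium O2 concentration (mg/L) at 1 atm from the Garcia-Gordon
#' refit of the Benson-Krause data; used for the initial concentration of
#' each simulated closed phase.
#'
#' @param temperature Water temperature, degC.
#' @param salinity Practical salinity (default 35).
#' @return O2 saturation concentration in mg/L.
#' @export
o2_saturation <- function(temperature, salinity = 35) {
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-0.00624523, -0.00737614, -0.0103410, -0.00817083)
  c0 <- -4.88682e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  exp(lnc) * 1.42905  # mL/L -> mg/L
}

# Timeline of one ramp: pre-blank closed phase, then K flush+measure cycles,
# then post-blank. All times in elapsed seconds from trial start.
ramp_timeline <- function(protocol) {
  cycle_s <- (protocol$flush_minutes + protocol$measure_minutes) * 60
  measure_s <- protocol$measure_minutes * 60
  k <- length(protocol$temperatures)
  list(
    measure_s = measure_s,
    pre_blank_start = 0,
    measure_starts = measure_s + (seq_len(k) - 1) * cycle_s +
      protocol$flush_minutes * 60,
    post_blank_start = measure_s + k * cycle_s,
    total = measure_s + k * cycle_s + measure_s
  )
}

# Simulate one closed phase: linear decline from saturation at the phase's
# temperature, truncated so the trace never falls below 80% saturation.
simulate_phase <- function(total_rate_mg_h, volume_l, temperature, duration_s,
                           sampling_interval, sensor_sd, min_sat = 0.80,
                           min_duration_s = 180) {
  c0 <- o2_saturation(temperature)
  decline <- total_rate_mg_h / volume_l / 3600  # mg/L/s
  if (decline > 0) {
    max_dur <- (1 - min_sat) * c0 / decline
    if (max_dur < min_duration_s) {
      abort(sprintf("consumption %.3f mg/h in %.3f L depletes >%.0f%% of O2 within %.0f s; no feasible closed-phase duration",
                    total_rate_mg_h, volume_l, (1 - min_sat) * 100,
                    min_duration_s), "infeasible_phase")
    }
    duration_s <- min(duration_s, floor(max_dur))
  }
  time <- seq(0, duration_s, by = sampling_interval)
  o2 <- c0 - decline * time + rnorm(length(time), 0, sensor_sd)
  list(time = time, o2 = o2, duration = duration_s)
}

# Core generator for one ramp; assumes the RNG is already seeded.
generate_ramp_core <- function(protocol, curve, spec, n_animals,
                               chamber_prefix) {
  tl <- ramp_timeline(protocol)
  temps <- protocol$temperatures
  sdlog <- sqrt(log(1 + curve$between_animal_cv^2))
  scalars <- rlnorm(n_animals, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  blank_at <- function(t) {
    curve$blank_start + (curve$blank_end - curve$blank_start) * t / tl$total
  }
  t_end <- protocol$end_temperature
  cols <- list(chamber_id = list(), cycle_id = list(), phase = list(),
               nominal_temperature_c = list(), elapsed_s = list(),
               time_s = list(), o2_mg_per_l = list())
  truth <- list()
  chambers <- data.frame(
    chamber_id = paste0(chamber_prefix, seq_len(n_animals)),
    volume_ml = spec$volume * 1000,
    animal_mass_g = spec$animal_mass,
    animal_density_g_per_ml = spec$animal_density,
    scalar = scalars, stringsAsFactors = FALSE
  )
  add_phase <- function(cid, cyc, phase, temp, start, ph) {
    n <- length(ph$time)
    i <- length(cols$chamber_id) + 1
    cols$chamber_id[[i]] <<- rep(cid, n)
    cols$cycle_id[[i]] <<- rep(cyc, n)
    cols$phase[[i]] <<- rep(phase, n)
    cols$nominal_temperature_c[[i]] <<- rep(temp, n)
    cols$elapsed_s[[i]] <<- start + ph$time
    cols$time_s[[i]] <<- ph$time
    cols$o2_mg_per_l[[i]] <<- ph$o2
  }
  for (a in seq_len(n_animals)) {
    cid <- chambers$chamber_id[a]
    v_eff <- spec$volume - spec$animal_mass / (1000 * spec$animal_density)
    # pre-blank in the empty chamber at the start temperature
    pre_rate <- blank_at(tl$pre_blank_start + tl$measure_s / 2)
    add_phase(cid, 0L, "blank_pre", protocol$start_temperature,
              tl$pre_blank_start,
              simulate_phase(pre_rate, spec$volume,
                             protocol$start_temperature, tl$measure_s,
                             protocol$sampling_interval, curve$sensor_sd))
    for (k in seq_along(temps)) {
      temp <- temps[k]
      start <- tl$measure_starts[k]
      animal_mg_h <- true_rate(curve, temp, t_end) * scalars[a] *
        spec$animal_mass / 1000
      blank_mg_h <- blank_at(start + tl$measure_s / 2)
      ph <- simulate_phase(animal_mg_h + blank_mg_h, v_eff, temp,
                           tl$measure_s, protocol$sampling_interval,
                           curve$sensor_sd)
      add_phase(cid, k, "measure", temp, start, ph)
      truth[[length(truth) + 1]] <- data.frame(
        chamber_id = cid, cycle_id = k, temperature = temp,
        true_rate = true_rate(curve, temp, t_end) * scalars[a],
        blank_rate_mg_h = blank_mg_h, duration_s = ph$duration,
        stringsAsFactors = FALSE)
    }
    post_rate <- blank_at(tl$post_blank_start + tl$measure_s / 2)
    add_phase(cid, length(temps) + 1L, "blank_post",
              protocol$end_temperature, tl$post_blank_start,
              simulate_phase(post_rate, spec$volume,
                             protocol$end_temperature, tl$measure_s,
                             protocol$sampling_interval, curve$sensor_sd))
  }
  traces <- data.frame(lapply(cols, function(x) unlist(x, use.names = FALSE)),
                       stringsAsFactors = FALSE)
  list(traces = traces,
       metadata = chambers[, c("chamber_id", "volume_ml", "animal_mass_g",
                               "animal_density_g_per_ml")],
       manifest = list(
         protocol = unclass(protocol), curve = unclass(curve),
         chambers = chambers, true_rates = do.call(rbind, truth)))
}

#' Generate synthetic respirometry traces for one ramp
#'
#' Simulates `n_animals` chambers through the ramp protocol: each animal gets
#' a multiplicative lognormal rate scalar; each closed phase declines
#' linearly from saturation at the combined animal + interpolated-background
#' rate, with i.i.d. Gaussian sensor noise; pre/post blank phases are emitted
#' for background correction. Closed-phase duration is shortened whenever the
#' nominal 15 minutes would deplete O2 below 80% saturation. The ground-truth
#' manifest records every per-cycle animal rate.
#'
#' @param protocol A [ramp_protocol()].
#' @param curve A [true_curve()].
#' @param spec Template [chamber_spec()] applied to every chamber.
#' @param n_animals Number of chambers/animals (default 8).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param chamber_prefix Prefix for chamber identifiers.
#' @return A list with `traces` (long-format data frame), `metadata` (chamber
#'   table) and `manifest` (ground truth).
#' @export
generate_traces <- function(protocol, curve, spec, n_animals = 8, seed = 1,
                            chamber_prefix = "AC") {
  with_seed(seed,
            generate_ramp_core(protocol, curve, spec, n_animals,
                               chamber_prefix))
}

#' Simulate the full two-ramp study
#'
#' Two ramps from the acclimation temperature (warm: towards 41 degC; cold:
#' towards 17 degC), each with its own set of `n_per_ramp` animals, sharing
#' one ground-truth curve — the full factorial the thermal-window analysis
#' expects, with the acclimation temperature measured in both ramps (pooled
#' n doubles there).
#'
#' @param seed Integer seed.
#' @param curve A [true_curve()].
#' @param spec Template [chamber_spec()].
#' @param n_per_ramp Animals per ramp (default 8).
#' @param start_temperature,warm_end,cold_end Ramp anchor temperatures.
#' @param dir Optional directory: when given, `traces.csv`, `metadata.csv`
#'   and `manifest.json` are written there.
#' @return A list with `traces`, `metadata`, `manifest`.
#' @export
simulate_study <- function(seed = 1, curve = true_curve(),
                           spec = chamber_spec("template", animal_mass = 63),
                           n_per_ramp = 8, start_temperature = 29,
                           warm_end = 41, cold_end = 17, dir = NULL) {
  res <- with_seed(seed, {
    warm <- generate_ramp_core(
      ramp_protocol(start_temperature, warm_end), curve, spec, n_per_ramp, "W")
    cold <- generate_ramp_core(
      ramp_protocol(start_temperature, cold_end), curve, spec, n_per_ramp, "C")
    list(
      traces = rbind(warm$traces, cold$traces),
      metadata = rbind(warm$metadata, cold$metadata),
      manifest = list(seed = seed, curve = unclass(curve),
                      warm = warm$manifest, cold = cold$manifest)
    )
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(res$traces, file.path(dir, "traces.csv"), row.names = FALSE)
    write.csv(res$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}

#' qPCR simulation scenario
#'
#' Ground truth for a Cq-table generator emulating a heat/cold-shock design:
#' stable reference genes, one (or more) fold-regulated target, several
#' treatment groups compared against a control, three technical replicates.
#'
#' @param genes Named character vector of gene roles, e.g.
#'   `c(Hsp70 = "target", Act = "reference", S18 = "reference")`.
#' @param baseline_cq Named numeric vector of control-level mean Cq per gene.
#' @param groups Data frame with columns `group`, `n`, `fold` — the true
#'   target fold change of each group relative to baseline (references are
#'   always fold 1).
#' @param efficiency Named amplification-efficiency vector (default 2.0
#'   everywhere).
#' @param biological_sd Between-animal SD of target expression, cycles.
#' @param loading_sd Between-sample cDNA loading SD, cycles (shifts every
#'   gene of a sample; removed by normalization).
#' @param reference_instability_sd Reference-gene wobble SD, cycles.
#' @param technical_sd Technical-replicate SD, cycles.
#' @param n_technical Technical replicates per sample x gene (default 3).
#' @return An object of class `cq_scenario`.
#' @export
cq_scenario <- function(genes = c(Hsp70 = "target", ActB = "reference",
                                  S18 = "reference"),
                        baseline_cq = c(Hsp70 = 26, ActB = 22, S18 = 12),
                        groups = data.frame(
                          group = c("control_29C", "heat_41C", "cold_17C"),
                          n = c(16L, 8L, 8L),
                          fold = c(1, 20, 1.2)),
                        efficiency = NULL,
                        biological_sd = 1.5, loading_sd = 0.5,
                        reference_instability_sd = 0.1, technical_sd = 0.15,
                        n_technical = 3L) {
  if (any(groups$fold <= 0)) abort("fold changes must be > 0", "bad_scenario")
  if (any(c(biological_sd, loading_sd, reference_instability_sd,
            technical_sd) < 0)) {
    abort("scenario SDs must be >= 0", "bad_scenario")
  }
  if (is.null(efficiency)) {
    efficiency <- setNames(rep(2.0, length(genes)), names(genes))
  }
  structure(
    list(genes = genes, baseline_cq = baseline_cq, groups = groups,
         efficiency = efficiency, biological_sd = biological_sd,
         loading_sd = loading_sd,
         reference_instability_sd = reference_instability_sd,
         technical_sd = technical_sd, n_technical = as.integer(n_technical)),
    class = "cq_scenario"
  )
}

#' Generate a synthetic Cq table
#'
#' Target genes of a sample in group g are shifted by `-log_E(fold_g)` cycles
#' from baseline, plus per-sample biological scatter; every gene of a sample
#' shares a cDNA-loading shift; reference genes add only a small instability
#' wobble; each reading finally gets technical noise.
#'
#' @param scenario A [cq_scenario()].
#' @param seed Integer seed.
#' @return A list with `cq` (data frame: `sample_id, group, gene, replicate,
#'   cq`) and `manifest` (true fold changes and the scenario).
#' @export
generate_cq <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "cq_scenario"))
  with_seed(seed, {
    rows <- list()
    gene_names <- names(scenario$genes)
    for (gi in seq_len(nrow(scenario$groups))) {
      grp <- scenario$groups$group[gi]
      fold <- scenario$groups$fold[gi]
      for (s in seq_len(scenario$groups$n[gi])) {
        sid <- sprintf("%s_s%02d", grp, s)
        loading <- rnorm(1, 0, scenario$loading_sd)
        bio <- rnorm(1, 0, scenario$biological_sd)
        for (g in gene_names) {
          e <- scenario$efficiency[[g]]
          base <- scenario$baseline_cq[[g]]
          mu <- if (scenario$genes[[g]] == "target") {
            base - log(fold, base = e) + bio + loading
          } else {
            base + rnorm(1, 0, scenario$reference_instability_sd) + loading
          }
          cqv <- mu + rnorm(scenario$n_technical, 0, scenario$technical_sd)
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, group = grp, gene = g,
            replicate = seq_len(scenario$n_technical), cq = cqv,
            stringsAsFactors = FALSE)
        }
      }
    }
    cq <- do.call(rbind, rows)
    rownames(cq) <- NULL
    list(cq = cq,
         manifest = list(seed = seed,
                         true_folds = setNames(scenario$groups$fold,
                                               scenario$groups$group),
                         scenario = unclass(scenario)))
  })
}
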
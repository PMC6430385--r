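#' Closed-phase oxygen trace
#'
#' Container for one closed (measurement) phase of an intermittent-flow
#' respirometry trial: temperature-compensated O2 concentration (mg/L)
#' sampled over time (s, relative to phase start) in one chamber at one
#' nominal temperature.
#'
#' @param time Numeric vector of sampling times in seconds, strictly
#'   increasing, relative to the start of the closed phase.
#' @param o2 Numeric vector of O2 concentrations in mg/L, all positive.
#' @param chamber_id Chamber identifier.
#' @param cycle_id Integer ordinal of the flush/measure cycle.
#' @param nominal_temperature Nominal water temperature of the cycle (deg C).
#' @param elapsed_start Seconds since experiment start at which the phase
#'   began; used to index the blank interpolation.
#' @param sampling_interval Nominal sampling interval in seconds.
#' @return An object of class `o2_trace`.
#' @export
o2_trace <- function(time, o2, chamber_id = "AC1", cycle_id = 1L,
                     nominal_temperature = NA_real_, elapsed_start = 0,
                     sampling_interval = 1) {
  time <- as.numeric(time)
  o2 <- as.numeric(o2)
  if (length(time) != length(o2)) {
    abort("`time` and `o2` must have the same length", "bad_trace")
  }
  if (length(time) && any(diff(time) <= 0)) {
    abort(sprintf("trace %s/%s: time must be strictly increasing",
                  chamber_id, cycle_id), "bad_trace")
  }
  if (any(!is.finite(o2)) || any(o2 <= 0)) {
    abort(sprintf("trace %s/%s: all o2 values must be finite and > 0",
                  chamber_id, cycle_id), "bad_trace")
  }
  structure(
    list(chamber_id = chamber_id, cycle_id = as.integer(cycle_id),
         nominal_temperature = nominal_temperature,
         elapsed_start = elapsed_start, time = time, o2 = o2,
         sampling_interval = sampling_interval),
    class = "o2_trace"
  )
}

#' @export
print.o2_trace <- function(x, ...) {
  cat(sprintf("<o2_trace> chamber %s cycle %d, %.1f degC, %d points over %.0f s\n",
              x$chamber_id, x$cycle_id, x$nominal_temperature,
              length(x$time), diff(range(x$time))))
  invisible(x)
}

#' Chamber and animal specification
#'
#' The effective (water) volume used for rate conversion is the chamber
#' volume minus the animal's displacement volume, `animal_mass /
#' (1000 * animal_density)` litres.
#'
#' @param chamber_id Chamber identifier.
#' @param volume Chamber volume in litres (default 0.600).
#' @param animal_mass Animal wet mass in grams.
#' @param animal_density Animal density in g/mL (default 1.0).
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(chamber_id, animal_mass, volume = 0.600,
                         animal_density = 1.0) {
  v_eff <- volume - animal_mass / (1000 * animal_density)
  if (!is.finite(v_eff) || v_eff <= 0) {
    abort(sprintf("chamber %s: effective volume must be positive (volume %.3f L, animal %.1f g)",
                  chamber_id, volume, animal_mass), "bad_chamber")
  }
  structure(
    list(chamber_id = chamber_id, volume = volume, animal_mass = animal_mass,
         animal_density = animal_density, effective_volume = v_eff),
    class = "chamber_spec"
  )
}

#' Pre/post blank (microbial background) rates for one chamber
#'
#' Whole-chamber background O2 consumption (mg O2/h) measured in the empty
#' chamber before (`pre_rate`, at elapsed time `pre_time`) and after
#' (`post_rate`, at `post_time`) the trial. Background at intermediate times
#' is linearly interpolated, assuming linear microbial accumulation.
#'
#' @param chamber_id Chamber identifier.
#' @param pre_rate,post_rate Background consumption rates, mg O2/h, >= 0.
#' @param pre_time,post_time Elapsed times (s) of the blank measurements.
#' @return An object of class `blank_pair`.
#' @export
blank_pair <- function(chamber_id, pre_rate, post_rate, pre_time, post_time) {
  if (post_time < pre_time) {
    abort(sprintf("chamber %s: post_time must be >= pre_time", chamber_id),
          "bad_blank")
  }
  if (pre_rate < 0 || post_rate < 0) {
    abort(sprintf("chamber %s: blank rates must be >= 0 (consumption sign convention)",
                  chamber_id), "bad_blank")
  }
  structure(
    list(chamber_id = chamber_id, pre_rate = pre_rate, post_rate = post_rate,
         pre_time = pre_time, post_time = post_time),
    class = "blank_pair"
  )
}

#' Trim the start and end of a closed-phase trace
#'
#' Removes the first and last `trim_seconds` of the phase (default 60 s, i.e.
#' the first and last minute), where flush carry-over and valve transients
#' distort the decline.
#'
#' @param trace An [o2_trace()].
#' @param trim_seconds Seconds to drop from each end.
#' @return The trimmed `o2_trace`.
#' @export
trim_trace <- function(trace, trim_seconds = 60) {
  stopifnot(inherits(trace, "o2_trace"))
  if (trim_seconds == 0) return(trace)
  duration <- max(trace$time) - min(trace$time)
  if (duration <= 2 * trim_seconds) {
    abort(sprintf("trace %s/%s: duration %.0f s too short to trim %.0f s from each end",
                  trace$chamber_id, trace$cycle_id, duration, trim_seconds),
          "short_trace")
  }
  lo <- min(trace$time) + trim_seconds
  hi <- max(trace$time) - trim_seconds
  keep <- trace$time >= lo & trace$time <= hi
  out <- trace
  out$time <- trace$time[keep]
  out$o2 <- trace$o2[keep]
  out
}

#' Ordinary least-squares slope of an O2 trace
#'
#' Fits `o2 ~ time` by OLS. The slope is signed (consumption is negative,
#' mg/L/s). `r_squared` is the squared Pearson correlation; a zero-variance
#' response is reported as `r_squared = 0` so that flat traces fail the
#' downstream quality gate deterministically rather than propagating `NaN`.
#'
#' @param trace An [o2_trace()], normally already trimmed.
#' @param saturation_ref Concentration (mg/L) taken as 100% saturation for the
#'   minimum-saturation check. Defaults to the trace's first value, in which
#'   case the check is a relative-decline check.
#' @return An object of class `slope_fit` with fields `slope`, `intercept`,
#'   `r_squared`, `n_points`, `min_saturation_fraction`.
#' @export
fit_slope <- function(trace, saturation_ref = NULL) {
  stopifnot(inherits(trace, "o2_trace"))
  t <- trace$time
  y <- trace$o2
  if (length(unique(t)) < 2) {
    abort(sprintf("trace %s/%s: need >= 2 distinct time points",
                  trace$chamber_id, trace$cycle_id), "degenerate_fit")
  }
  fit <- stats::.lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else max(0, 1 - sum(fit$residuals^2) / sst)
  if (is.null(saturation_ref)) saturation_ref <- y[1]
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         n_points = length(t),
         min_saturation_fraction = min(y) / saturation_ref),
    class = "slope_fit"
  )
}

#' Interpolated background rate at a given elapsed time
#'
#' Linear interpolation between the pre- and post-blank background rates,
#' clamped to `[pre_time, post_time]`. Equal pre/post times (a degenerate
#' pair) return `pre_rate`.
#'
#' @param blanks A [blank_pair()].
#' @param t Elapsed time (s) at which the background rate is wanted.
#' @return Background consumption in mg O2/h.
#' @export
blank_rate_at <- function(blanks, t) {
  stopifnot(inherits(blanks, "blank_pair"))
  if (blanks$post_time == blanks$pre_time) return(rep(blanks$pre_rate, length(t)))
  t <- pmin(pmax(t, blanks$pre_time), blanks$post_time)
  frac <- (t - blanks$pre_time) / (blanks$post_time - blanks$pre_time)
  blanks$pre_rate + frac * (blanks$post_rate - blanks$pre_rate)
}

#' Blank-corrected, mass-specific oxygen consumption rate
#'
#' Converts a fitted closed-phase slope into a whole-chamber consumption rate
#' (`-slope * V_eff * 3600`, mg O2/h, with `V_eff` the water volume),
#' subtracts the background rate interpolated at the phase midpoint, and
#' scales by animal mass to ug O2/g/h. Quality flags: `LOW_R2` when
#' `r_squared < r2_min`, `LOW_SATURATION` when the minimum saturation
#' fraction fell below `saturation_min`, `NEGATIVE_RATE` when the corrected
#' rate is negative (the value is retained, not clipped, but the record fails
#' QC so it cannot silently enter per-temperature means).
#'
#' @param fit A [fit_slope()] result from a trimmed trace.
#' @param spec The [chamber_spec()] of the chamber.
#' @param blanks The chamber's [blank_pair()].
#' @param t_mid Elapsed time (s) at the midpoint of the closed phase.
#' @param r2_min Minimum acceptable slope R-squared (default 0.90).
#' @param saturation_min Minimum acceptable saturation fraction (default 0.80).
#' @param chamber_id,cycle_id,nominal_temperature Identifiers carried into the
#'   record (default from `spec` where available).
#' @return A one-row data frame (class `rate_record`) with the rate,
#'   diagnostics and QC flags; `qc_pass` is `TRUE` iff `qc_reasons` is empty.
#' @export
mass_specific_rate <- function(fit, spec, blanks, t_mid,
                               r2_min = 0.90, saturation_min = 0.80,
                               chamber_id = spec$chamber_id, cycle_id = NA_integer_,
                               nominal_temperature = NA_real_) {
  stopifnot(inherits(fit, "slope_fit"), inherits(spec, "chamber_spec"),
            inherits(blanks, "blank_pair"))
  whole <- -fit$slope * spec$effective_volume * 3600     # mg O2/h
  bg <- blank_rate_at(blanks, t_mid)
  corrected <- whole - bg
  rate <- corrected * 1000 / spec$animal_mass            # ug O2/g/h
  reasons <- character()
  if (fit$r_squared < r2_min) reasons <- c(reasons, "LOW_R2")
  if (fit$min_saturation_fraction < saturation_min) {
    reasons <- c(reasons, "LOW_SATURATION")
  }
  if (corrected < 0) reasons <- c(reasons, "NEGATIVE_RATE")
  rec <- data.frame(
    chamber_id = chamber_id, cycle_id = cycle_id,
    nominal_temperature = nominal_temperature,
    rate = rate, slope = fit$slope, r_squared = fit$r_squared,
    min_saturation_fraction = fit$min_saturation_fraction,
    blank_rate = bg, qc_pass = length(reasons) == 0,
    qc_reasons = paste(reasons, collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("rate_record", class(rec))
  rec
}

# ---- batch ingestion ---------------------------------------------------------

TRACE_COLUMNS <- c("chamber_id", "cycle_id", "phase", "nominal_temperature_c",
                   "elapsed_s", "time_s", "o2_mg_per_l")
METADATA_COLUMNS <- c("chamber_id", "volume_ml", "animal_mass_g")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")), "schema_error")
  }
  invisible(df)
}

#' Read a long-format O2 trace CSV
#'
#' Expected columns: `chamber_id, cycle_id, phase, nominal_temperature_c,
#' elapsed_s, time_s, o2_mg_per_l`, with `phase` one of `flush`, `measure`,
#' `blank_pre`, `blank_post`. Lines starting with `#` are treated as
#' provenance comments. Numeric parsing is locale-independent (dot decimal).
#'
#' @param path Path to the CSV file.
#' @return A data frame of trace points.
#' @export
read_o2_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0) abort(sprintf("empty trace file: %s", path), "empty_input")
  check_columns(df, TRACE_COLUMNS, sprintf("trace file '%s'", path))
  df
}

#' Read chamber/animal metadata CSV
#'
#' Expected columns: `chamber_id, volume_ml, animal_mass_g` (and optionally
#' `animal_density_g_per_ml`).
#'
#' @param path Path to the CSV file.
#' @return A data frame of chamber metadata.
#' @export
read_chamber_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0) abort(sprintf("empty metadata file: %s", path), "empty_input")
  check_columns(df, METADATA_COLUMNS, sprintf("metadata file '%s'", path))
  df
}

#' Process a batch of traces into rate records
#'
#' For every chamber, fits the pre- and post-blank phases (in the empty
#' chamber, so the full chamber volume applies) to build the background
#' interpolation, then trims and fits every `measure` phase and produces one
#' blank-corrected, mass-specific [mass_specific_rate()] record per cycle.
#' Traces too short to trim are reported as `SHORT_TRACE` records with `NA`
#' rate rather than dropped, so every exclusion is auditable.
#'
#' @param traces Long-format trace data frame (see [read_o2_traces()]).
#' @param metadata Chamber metadata data frame (see [read_chamber_metadata()]).
#' @param trim_seconds Seconds trimmed from each end of a phase (default 60).
#' @param r2_min,saturation_min QC thresholds passed to [mass_specific_rate()].
#' @param saturation_ref Optional named vector of 100%-saturation reference
#'   concentrations per nominal temperature; defaults to each trace's initial
#'   value.
#' @return A data frame of rate records, one row per measure phase, with a
#'   `qc_summary` attribute counting exclusions by reason.
#' @export
process_traces <- function(traces, metadata, trim_seconds = 60,
                           r2_min = 0.90, saturation_min = 0.80,
                           saturation_ref = NULL) {
  check_columns(traces, TRACE_COLUMNS, "trace data")
  check_columns(metadata, METADATA_COLUMNS, "metadata")
  if (nrow(traces) == 0) abort("no trace rows supplied", "empty_input")

  specs <- lapply(seq_len(nrow(metadata)), function(i) {
    density <- if ("animal_density_g_per_ml" %in% names(metadata)) {
      metadata$animal_density_g_per_ml[i]
    } else 1.0
    chamber_spec(metadata$chamber_id[i],
                 animal_mass = metadata$animal_mass_g[i],
                 volume = metadata$volume_ml[i] / 1000,
                 animal_density = density)
  })
  names(specs) <- metadata$chamber_id

  out <- list()
  for (cid in unique(traces$chamber_id)) {
    if (!cid %in% names(specs)) {
      abort(sprintf("chamber %s present in traces but not in metadata", cid),
            "schema_error")
    }
    spec <- specs[[cid]]
    ch <- traces[traces$chamber_id == cid, ]
    blanks <- fit_chamber_blanks(ch, spec, trim_seconds)
    meas <- ch[ch$phase == "measure", ]
    for (cyc in unique(meas$cycle_id)) {
      ph <- meas[meas$cycle_id == cyc, ]
      ph <- ph[order(ph$time_s), ]
      temp <- ph$nominal_temperature_c[1]
      rec <- tryCatch({
        tr <- o2_trace(ph$time_s, ph$o2_mg_per_l, chamber_id = cid,
                       cycle_id = cyc, nominal_temperature = temp,
                       elapsed_start = ph$elapsed_s[1])
        tr <- trim_trace(tr, trim_seconds)
        sref <- if (!is.null(saturation_ref)) {
          saturation_ref[as.character(temp)]
        } else NULL
        fit <- fit_slope(tr, saturation_ref = sref)
        t_mid <- tr$elapsed_start + (min(ph$time_s) + max(ph$time_s)) / 2
        mass_specific_rate(fit, spec, blanks, t_mid,
                           r2_min = r2_min, saturation_min = saturation_min,
                           chamber_id = cid, cycle_id = cyc,
                           nominal_temperature = temp)
      }, short_trace = function(e) {
        data.frame(chamber_id = cid, cycle_id = cyc,
                   nominal_temperature = temp, rate = NA_real_,
                   slope = NA_real_, r_squared = NA_real_,
                   min_saturation_fraction = NA_real_, blank_rate = NA_real_,
                   qc_pass = FALSE, qc_reasons = "SHORT_TRACE",
                   stringsAsFactors = FALSE)
      })
      out[[length(out) + 1]] <- rec
    }
  }
  rates <- do.call(rbind, out)
  rownames(rates) <- NULL
  failed <- rates$qc_reasons[!rates$qc_pass]
  attr(rates, "qc_summary") <- if (length(failed)) {
    table(unlist(strsplit(failed, ";", fixed = TRUE)))
  } else {
    table(character())
  }
  rates
}

# Background interpolation for one chamber: fit blank_pre / blank_post phases
# (empty chamber => full chamber volume, no animal displacement) and anchor
# the linear interpolation at the blank-phase midpoints. Slightly negative
# fitted blank slopes (pure noise around zero) are clamped to a zero rate.
fit_chamber_blanks <- function(ch, spec, trim_seconds) {
  get_rate <- function(phase_name) {
    ph <- ch[ch$phase == phase_name, ]
    if (nrow(ph) == 0) return(NULL)
    ph <- ph[order(ph$time_s), ]
    tr <- o2_trace(ph$time_s, ph$o2_mg_per_l, chamber_id = spec$chamber_id,
                   cycle_id = 0L, elapsed_start = ph$elapsed_s[1])
    tr <- tryCatch(trim_trace(tr, trim_seconds), short_trace = function(e) tr)
    fit <- fit_slope(tr)
    list(rate = max(0, -fit$slope * spec$volume * 3600),
         t_mid = ph$elapsed_s[1] + (min(ph$time_s) + max(ph$time_s)) / 2)
  }
  pre <- get_rate("blank_pre")
  post <- get_rate("blank_post")
  if (is.null(pre) && is.null(post)) {
    return(blank_pair(spec$chamber_id, 0, 0, 0, 0))
  }
  if (is.null(pre)) pre <- post
  if (is.null(post)) post <- pre
  blank_pair(spec$chamber_id, pre$rate, post$rate, pre$t_mid,
             max(post$t_mid, pre$t_mid))
}

#' Write rate records to CSV
#'
#' @param rates Rate-record data frame from [process_traces()].
#' @param path Output path.
#' @param header Optional provenance comment written as a leading `#` line.
#' @export
write_rates <- function(rates, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(rates, con, row.names = FALSE)
  invisible(path)
}

#' Read a rate-record CSV written by [write_rates()]
#'
#' @param path Path to the CSV file.
#' @return A data frame of rate records.
#' @export
read_rates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0) abort(sprintf("empty rates file: %s", path), "empty_input")
  check_columns(df, c("chamber_id", "cycle_id", "nominal_temperature",
                      "rate", "qc_pass", "qc_reasons"),
                sprintf("rates file '%s'", path))
  df$qc_reasons[is.na(df$qc_reasons)] <- ""
  df
}
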
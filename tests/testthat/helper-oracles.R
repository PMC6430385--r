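# Independent oracles and fixture builders shared across test files.

# Closed-form OLS slope/intercept: sum((t - tbar)(y - ybar)) / sum((t - tbar)^2).
ols_oracle <- function(t, y) {
  tb <- mean(t)
  yb <- mean(y)
  slope <- sum((t - tb) * (y - yb)) / sum((t - tb)^2)
  list(slope = slope, intercept = yb - slope * tb)
}

# Brute-force two-sided exact Mann-Whitney p: enumerate every labeling of the
# pooled values, compute U for each, and count labelings at least as extreme
# (distance from the null mean n_a*n_b/2) as the observed one.
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  centre <- na * length(b) / 2
  labelings <- utils::combn(length(pooled), na)
  us <- apply(labelings, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Directly-evaluated geNorm M for a samples x genes RQ matrix.
genorm_oracle <- function(mat) {
  lm2 <- log2(mat)
  vapply(seq_len(ncol(mat)), function(j) {
    mean(vapply(setdiff(seq_len(ncol(mat)), j),
                function(k) stats::sd(lm2[, j] - lm2[, k]), numeric(1)))
  }, numeric(1))
}

# Build a temperature_profile directly from vectors (bypassing rate records).
make_profile <- function(temperature, mean_rate, sd_rate = 0, n = 8L) {
  prof <- data.frame(temperature = temperature, mean_rate = mean_rate,
                     sd_rate = rep_len(sd_rate, length(temperature)),
                     n = rep_len(as.integer(n), length(temperature)),
                     flags = "", stringsAsFactors = FALSE)
  class(prof) <- c("temperature_profile", class(prof))
  prof
}

# Paper-shaped noiseless profile on a 1 degC grid: plateau at 2.2 up to 22,
# linear rise to 33.2 at 38, linear collapse to 13.3 at 41.
paper_shaped_profile <- function() {
  temps <- 17:41
  curve <- true_curve(sensor_sd = 0, between_animal_cv = 0)
  make_profile(temps, true_rate(curve, temps, t_end = 41))
}

# Evenly spaced noiseless linear trace.
linear_trace <- function(duration = 900, slope = -0.001, intercept = 8,
                         by = 1, ...) {
  tt <- seq(0, duration, by = by)
  o2_trace(tt, intercept + slope * tt, ...)
}

zero_blanks <- blank_pair("AC1", 0, 0, 0, 1e6)
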
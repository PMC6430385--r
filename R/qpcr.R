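#' Read a Cq plate CSV
#'
#' Expected columns: `sample_id, group, gene, replicate, cq` — one row per
#' technical replicate.
#'
#' @param path Path to the CSV file.
#' @return A data frame of Cq records.
#' @export
read_cq_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0) abort(sprintf("empty Cq file: %s", path), "empty_input")
  check_columns(df, c("sample_id", "group", "gene", "replicate", "cq"),
                sprintf("Cq file '%s'", path))
  if (any(!is.finite(df$cq)) || any(df$cq <= 0)) {
    abort("all Cq values must be finite and > 0", "bad_cq")
  }
  df
}

#' Collapse technical replicates to mean Cq
#'
#' Arithmetic mean Cq per sample x gene. Replicate scatter above `sd_warn`
#' cycles is flagged (`HIGH_REPLICATE_SD`) and warned about, never silently
#' excluded; single replicates are flagged `N_EQ_1`.
#'
#' @param cq Data frame with columns `sample_id, group, gene, replicate, cq`.
#' @param sd_warn Replicate-SD warning threshold in cycles (default 0.5).
#' @return Data frame with one row per sample x gene: `sample_id, group,
#'   gene, mean_cq, sd_cq, n_rep, flags`.
#' @export
collapse_replicates <- function(cq, sd_warn = 0.5) {
  check_columns(cq, c("sample_id", "group", "gene", "cq"), "Cq data")
  key <- interaction(cq$sample_id, cq$gene, drop = TRUE)
  sp <- split(cq, key)
  rows <- lapply(sp, function(d) {
    s <- if (nrow(d) > 1) sd(d$cq) else NA_real_
    flags <- character()
    if (nrow(d) == 1) flags <- c(flags, "N_EQ_1")
    if (is.finite(s) && s > sd_warn) flags <- c(flags, "HIGH_REPLICATE_SD")
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               gene = d$gene[1], mean_cq = mean(d$cq),
               sd_cq = ifelse(is.na(s), 0, s), n_rep = nrow(d),
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  noisy <- out[grepl("HIGH_REPLICATE_SD", out$flags), ]
  if (nrow(noisy)) {
    warn(sprintf("replicate SD > %.2f cycles for %d sample x gene combination(s): %s",
                 sd_warn, nrow(noisy),
                 paste(head(paste(noisy$sample_id, noisy$gene, sep = "/"), 5),
                       collapse = ", ")),
         "high_replicate_sd")
  }
  out
}

#' Amplification efficiency from a dilution standard curve
#'
#' OLS slope of Cq against log10 dilution; the per-cycle amplification factor
#' is `E = 10^(-1/slope)` (slope -3.3219 corresponds to perfect doubling,
#' E = 2).
#'
#' @param dilution_log10 log10 of the template dilutions (>= 3 points).
#' @param cq Measured Cq at each dilution.
#' @return The efficiency E.
#' @export
efficiency_from_standard_curve <- function(dilution_log10, cq) {
  if (length(dilution_log10) < 3) {
    abort("a standard curve needs at least 3 dilution points", "bad_standard_curve")
  }
  slope <- coef(lm(cq ~ dilution_log10))[[2]]
  if (!is.finite(slope) || slope >= 0) {
    abort("standard-curve slope must be negative (Cq decreases with template)",
          "bad_standard_curve")
  }
  10^(-1 / slope)
}

#' Relative quantities from mean Cq
#'
#' `RQ(g, i) = E_g ^ (mean Cq of gene g across the run - Cq of sample i)`:
#' each sample's quantity relative to the run average for that gene.
#'
#' @param mean_cq Data frame from [collapse_replicates()].
#' @param efficiencies Named vector of amplification efficiencies per gene;
#'   genes not named default to 2.0 (perfect doubling).
#' @return The input with an `rq` column added.
#' @export
relative_quantities <- function(mean_cq, efficiencies = NULL) {
  check_columns(mean_cq, c("sample_id", "gene", "mean_cq"), "mean Cq data")
  genes <- unique(mean_cq$gene)
  eff <- setNames(rep(2.0, length(genes)), genes)
  if (!is.null(efficiencies)) {
    if (any(efficiencies <= 1 | efficiencies > 2.2)) {
      abort("amplification efficiencies must lie in (1, 2.2]", "bad_efficiency")
    }
    eff[names(efficiencies)] <- efficiencies
  }
  out <- mean_cq
  out$rq <- NA_real_
  for (g in genes) {
    idx <- out$gene == g
    out$rq[idx] <- eff[[g]]^(mean(out$mean_cq[idx]) - out$mean_cq[idx])
  }
  out
}

#' Calibrated normalized relative quantities
#'
#' The qBase-style chain: for each sample the normalization factor `NF` is
#' the geometric mean of the reference genes' RQs; `NRQ = RQ_target / NF`;
#' and `CNRQ = NRQ / G` where `G` is the geometric mean of NRQ over the
#' calibration set (default: all samples in the run, so CNRQ has geometric
#' mean 1 over the run). Calibration only rescales: between-sample CNRQ
#' ratios do not depend on it.
#'
#' @param rq Data frame from [relative_quantities()].
#' @param reference_genes Character vector (>= 2) of reference gene names.
#' @param target_genes Target gene names; defaults to all non-reference genes.
#' @param calibration `"all_samples"` or a group label whose samples form the
#'   calibration set.
#' @return Data frame with one row per sample x target gene: `sample_id,
#'   group, gene, nf, nrq, cnrq`.
#' @export
cnrq <- function(rq, reference_genes, target_genes = NULL,
                 calibration = "all_samples") {
  check_columns(rq, c("sample_id", "group", "gene", "rq"), "RQ data")
  if (any(!is.finite(rq$rq) | rq$rq <= 0)) {
    abort("RQ values must be positive and finite", "bad_rq")
  }
  genes <- unique(rq$gene)
  missing_ref <- setdiff(reference_genes, genes)
  if (length(missing_ref)) {
    abort(sprintf("reference gene(s) absent from the data: %s",
                  paste(missing_ref, collapse = ", ")), "missing_gene")
  }
  if (length(reference_genes) < 2) {
    abort("normalization requires at least 2 reference genes", "missing_gene")
  }
  if (is.null(target_genes)) target_genes <- setdiff(genes, reference_genes)
  if (length(target_genes) == 0) abort("no target genes", "missing_gene")

  refs <- rq[rq$gene %in% reference_genes, ]
  nf <- vapply(split(refs$rq, refs$sample_id), geomean, numeric(1))
  samples_missing <- names(which(
    table(refs$sample_id) < length(reference_genes)))
  if (length(samples_missing)) {
    abort(sprintf("sample(s) lacking a reference-gene measurement: %s",
                  paste(samples_missing, collapse = ", ")), "missing_gene")
  }

  out <- rq[rq$gene %in% target_genes,
            c("sample_id", "group", "gene", "rq")]
  out$nf <- nf[out$sample_id]
  out$nrq <- out$rq / out$nf
  out$cnrq <- NA_real_
  for (g in target_genes) {
    idx <- out$gene == g
    cal <- if (identical(calibration, "all_samples")) idx else {
      idx & out$group == calibration
    }
    if (!any(cal)) {
      abort(sprintf("calibration group '%s' has no samples for gene %s",
                    calibration, g), "bad_calibration")
    }
    out$cnrq[idx] <- out$nrq[idx] / geomean(out$nrq[cal])
  }
  rownames(out) <- NULL
  out
}

#' geNorm expression-stability measure M
#'
#' For every pair of candidate reference genes j, k the per-sample log2 ratio
#' `A_jk = log2(RQ_j / RQ_k)` is formed; `V_jk` is its sample SD, and the
#' stability of gene j is `M_j = mean(V_jk)` over all k != j. Lower M means
#' a more stable reference; genes with `M >= 0.5` are flagged unstable.
#' M is invariant to rescaling any gene's RQ by a constant.
#'
#' @param rq Data frame from [relative_quantities()], restricted (via
#'   `genes`) to the candidate reference genes.
#' @param genes Candidate gene names; defaults to all genes present.
#' @param m_max Stability threshold (default 0.5).
#' @return Data frame `gene, m, stable` sorted by M.
#' @export
genorm_m <- function(rq, genes = NULL, m_max = 0.5) {
  check_columns(rq, c("sample_id", "gene", "rq"), "RQ data")
  if (is.null(genes)) genes <- unique(rq$gene)
  if (length(genes) < 2) abort("geNorm needs >= 2 candidate genes", "bad_genorm")
  rq <- rq[rq$gene %in% genes, ]
  samples <- sort(unique(rq$sample_id))
  if (length(samples) < 2) abort("geNorm needs >= 2 samples", "bad_genorm")
  mat <- matrix(NA_real_, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  mat[cbind(match(rq$sample_id, samples), match(rq$gene, genes))] <- rq$rq
  if (any(is.na(mat))) abort("every sample needs an RQ for every candidate gene",
                             "bad_genorm")
  lmat <- log2(mat)
  m <- vapply(seq_along(genes), function(j) {
    v <- vapply(setdiff(seq_along(genes), j),
                function(k) sd(lmat[, j] - lmat[, k]), numeric(1))
    mean(v)
  }, numeric(1))
  out <- data.frame(gene = genes, m = m, stable = m < m_max,
                    stringsAsFactors = FALSE)
  out[order(out$m), , drop = FALSE]
}

#' Group summary: geometric mean CNRQ with log-symmetric 95% CI
#'
#' On `y = log2(CNRQ)` the group mean and a t-based confidence interval
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)` are computed and back-transformed,
#' yielding a multiplicatively symmetric interval (`high/mean == mean/low`).
#' Single-sample groups return the point estimate with no CI and an `N_EQ_1`
#' flag.
#'
#' @param cnrq_df Data frame from [cnrq()].
#' @param conf Confidence level (default 0.95).
#' @return Data frame `group, gene, n, geo_mean, ci_low, ci_high, flags`.
#' @export
group_summary <- function(cnrq_df, conf = 0.95) {
  check_columns(cnrq_df, c("sample_id", "group", "gene", "cnrq"), "CNRQ data")
  key <- interaction(cnrq_df$group, cnrq_df$gene, drop = TRUE)
  rows <- lapply(split(cnrq_df, key), function(d) {
    y <- log2(d$cnrq)
    n <- length(y)
    gm <- 2^mean(y)
    if (n >= 2) {
      half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(y) / sqrt(n)
      lo <- 2^(mean(y) - half)
      hi <- 2^(mean(y) + half)
      flags <- ""
    } else {
      lo <- NA_real_; hi <- NA_real_; flags <- "N_EQ_1"
    }
    data.frame(group = d$group[1], gene = d$gene[1], n = n, geo_mean = gm,
               ci_low = lo, ci_high = hi, flags = flags,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The U statistic is reported for
#' `group_a` (number of (a, b) pairs with a > b, ties counting one half).
#' In `"auto"` mode the two-sided p-value is exact — from the exact
#' tie-free Wilcoxon rank-sum distribution, equivalent to full enumeration of
#' all `choose(n_a + n_b, n_a)` labelings — whenever `min(n_a, n_b) <= 10`
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used. Two identical groups give `p = 1` by
#' convention.
#'
#' @param group_a,group_b Numeric vectors (each n >= 1).
#' @param mode `"auto"`, `"exact"` (error if ties make the exact distribution
#'   invalid) or `"approx"`.
#' @return A list with `U`, `p`, and `method`.
#' @export
mann_whitney <- function(group_a, group_b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 1 || nb < 1) abort("both groups need at least one value", "bad_test")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (all(pooled == pooled[1])) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = min(na, nb) <= 10 && !ties
  )
  if (use_exact && ties) {
    abort("exact Mann-Whitney p is undefined with ties; use mode = 'auto' or 'approx'",
          "bad_test")
  }
  if (use_exact) {
    # symmetric two-sided tail doubling on the exact null distribution of U
    p <- 2 * min(pwilcox(U, na, nb), 1 - pwilcox(U - 1, na, nb))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 *
      ((na + nb + 1) - sum(tie_tab^3 - tie_tab) / ((na + nb) * (na + nb - 1)))
    z <- U - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method)
}

#' Compare treatment groups against a control
#'
#' Runs [mann_whitney()] of each treatment group's CNRQ against the control
#' for every target gene. Several control labels may be pooled into one
#' control set (as when two experiments share the same ambient controls).
#'
#' @param cnrq_df Data frame from [cnrq()].
#' @param control_groups Group label(s) pooled as the control set.
#' @param mode Passed to [mann_whitney()].
#' @return Data frame `gene, group, control, n_group, n_control, U, p, stars`.
#' @export
compare_groups <- function(cnrq_df, control_groups, mode = "auto") {
  check_columns(cnrq_df, c("sample_id", "group", "gene", "cnrq"), "CNRQ data")
  ctrl <- cnrq_df[cnrq_df$group %in% control_groups, ]
  if (nrow(ctrl) == 0) {
    abort(sprintf("no samples in control group(s): %s",
                  paste(control_groups, collapse = ", ")), "bad_test")
  }
  treatments <- setdiff(unique(cnrq_df$group), control_groups)
  rows <- list()
  for (g in unique(cnrq_df$gene)) {
    cg <- ctrl$cnrq[ctrl$gene == g]
    for (tr in treatments) {
      tg <- cnrq_df$cnrq[cnrq_df$group == tr & cnrq_df$gene == g]
      res <- mann_whitney(tg, cg, mode = mode)
      stars <- if (res$p < 0.01) "**" else if (res$p < 0.05) "*" else ""
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, group = tr,
        control = paste(control_groups, collapse = "+"),
        n_group = length(tg), n_control = length(cg),
        U = res$U, p = res$p, stars = stars, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end relative-expression analysis of a Cq table
#'
#' Collapses technical replicates, computes relative quantities with the
#' supplied (or default, 2.0) efficiencies, normalizes to the reference
#' genes, calibrates, summarizes per group, scores reference stability with
#' geNorm, and compares every treatment group against the control.
#'
#' @param cq Cq data frame (see [read_cq_table()]).
#' @param reference_genes Character vector (>= 2) of reference genes.
#' @param target_genes Target genes; default all non-reference genes.
#' @param efficiencies Optional named efficiency vector.
#' @param calibration Calibration set (see [cnrq()]).
#' @param control_groups Control group label(s) for [compare_groups()].
#' @param sd_warn Replicate-SD warning threshold in cycles.
#' @return An object of class `expression_result`: a list with elements
#'   `cnrq`, `summary`, `genorm`, `comparisons`.
#' @export
qpcr_analysis <- function(cq, reference_genes, target_genes = NULL,
                          efficiencies = NULL, calibration = "all_samples",
                          control_groups = NULL, sd_warn = 0.5) {
  mean_cq <- collapse_replicates(cq, sd_warn = sd_warn)
  rq <- relative_quantities(mean_cq, efficiencies = efficiencies)
  cn <- cnrq(rq, reference_genes, target_genes = target_genes,
             calibration = calibration)
  gs <- group_summary(cn)
  gm <- genorm_m(rq, genes = reference_genes)
  comp <- if (!is.null(control_groups)) {
    compare_groups(cn, control_groups)
  } else NULL
  structure(list(cnrq = cn, summary = gs, genorm = gm, comparisons = comp),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat("Relative gene-expression analysis (CNRQ)\n\nGroup summaries:\n")
  print(x$summary, row.names = FALSE)
  cat("\ngeNorm reference stability:\n")
  print(x$genorm, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nGroup comparisons (Mann-Whitney):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
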
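make_cq <- function(sample_id, group, gene, cq, replicate = 1L) {
  data.frame(sample_id = sample_id, group = group, gene = gene,
             replicate = replicate, cq = cq, stringsAsFactors = FALSE)
}

test_that("technical replicates collapse to means with scatter warnings", {
  cq <- make_cq("s1", "ctrl", "g", c(20.0, 20.1, 20.2), 1:3)
  out <- collapse_replicates(cq)
  expect_equal(out$mean_cq, 20.1)
  expect_equal(out$n_rep, 3L)
  expect_equal(out$flags, "")

  single <- collapse_replicates(make_cq("s1", "ctrl", "g", 21.3))
  expect_equal(single$mean_cq, 21.3)
  expect_equal(single$flags, "N_EQ_1")

  noisy <- make_cq("s1", "ctrl", "g", c(20.0, 22.0, 20.1), 1:3)
  expect_warning(out <- collapse_replicates(noisy),
                 class = "high_replicate_sd")
  expect_equal(out$mean_cq, mean(c(20.0, 22.0, 20.1)))
  expect_match(out$flags, "HIGH_REPLICATE_SD")
})

test_that("standard-curve efficiency follows 10^(-1/slope)", {
  d <- c(0, -1, -2, -3)
  expect_equal(efficiency_from_standard_curve(d, 20 - 3.3219 * d), 2.0,
               tolerance = 1e-4)
  expect_equal(efficiency_from_standard_curve(d, 20 - 3.6 * d), 10^(1 / 3.6),
               tolerance = 1e-9)
  expect_error(efficiency_from_standard_curve(c(0, -1), c(20, 23.3)),
               class = "bad_standard_curve")
  expect_error(efficiency_from_standard_curve(d, 20 + 3.3 * d),
               class = "bad_standard_curve")
})

test_that("relative quantities exponentiate delta-Cq around the gene mean", {
  mc <- data.frame(sample_id = c("a", "b"), group = "g", gene = "t",
                   mean_cq = c(19, 21), stringsAsFactors = FALSE)
  rq <- relative_quantities(mc)          # gene mean 20, E = 2
  expect_equal(rq$rq, c(2, 0.5))

  mc1 <- mc
  mc1$mean_cq <- c(20, 20)
  expect_equal(relative_quantities(mc1)$rq, c(1, 1))

  rq19 <- relative_quantities(mc, efficiencies = c(t = 1.9))
  expect_equal(rq19$rq[1] / rq19$rq[2], 1.9^2, tolerance = 1e-12)
  expect_equal(1.9^2, 3.61)

  expect_error(relative_quantities(mc, efficiencies = c(t = 2.5)),
               class = "bad_efficiency")
})

test_that("the CNRQ chain normalizes and calibrates as a geometric hierarchy", {
  # two samples, references identical across samples, target 1 cycle apart
  cq <- rbind(
    make_cq(c("a", "b"), "g", "ref1", c(15, 15)),
    make_cq(c("a", "b"), "g", "ref2", c(18, 18)),
    make_cq(c("a", "b"), "g", "tgt", c(20, 21)))
  rq <- relative_quantities(collapse_replicates(cq))
  cn <- cnrq(rq, reference_genes = c("ref1", "ref2"))
  expect_equal(cn$cnrq[cn$sample_id == "a"] / cn$cnrq[cn$sample_id == "b"], 2,
               tolerance = 1e-12)
  # all-sample calibration: geometric mean CNRQ over the run is exactly 1
  expect_equal(exp(mean(log(cn$cnrq))), 1, tolerance = 1e-12)

  expect_error(cnrq(rq, reference_genes = c("ref1", "missing")),
               class = "missing_gene")
  expect_error(cnrq(rq, reference_genes = "ref1"), class = "missing_gene")
})

test_that("CNRQ ratios are invariant to the calibration choice", {
  set.seed(21)
  n <- 6
  cq <- rbind(
    make_cq(sprintf("s%d", 1:n), rep(c("ctrl", "treat"), each = 3), "ref1",
            15 + rnorm(n, 0, 0.2)),
    make_cq(sprintf("s%d", 1:n), rep(c("ctrl", "treat"), each = 3), "ref2",
            18 + rnorm(n, 0, 0.2)),
    make_cq(sprintf("s%d", 1:n), rep(c("ctrl", "treat"), each = 3), "tgt",
            22 + rnorm(n, 0, 1)))
  rq <- relative_quantities(collapse_replicates(cq))
  all_cal <- cnrq(rq, c("ref1", "ref2"), calibration = "all_samples")
  grp_cal <- cnrq(rq, c("ref1", "ref2"), calibration = "ctrl")
  ratio <- function(x) outer(x$cnrq, x$cnrq, "/")
  expect_equal(ratio(all_cal), ratio(grp_cal), tolerance = 1e-12)
  # group calibration centres the control group at geometric mean 1
  expect_equal(exp(mean(log(grp_cal$cnrq[grp_cal$group == "ctrl"]))), 1,
               tolerance = 1e-12)
})

test_that("geNorm M matches the direct log-ratio SD formula", {
  # proportional genes are perfectly stable
  cq <- rbind(
    make_cq(c("a", "b", "c"), "g", "r1", c(15, 16, 17)),
    make_cq(c("a", "b", "c"), "g", "r2", c(18, 19, 20)))
  rq <- relative_quantities(collapse_replicates(cq))
  gm <- genorm_m(rq)
  expect_equal(gm$m, c(0, 0), tolerance = 1e-12)
  expect_true(all(gm$stable))

  # ratio sequence {1, 2, 4}: M = SD of {0, 1, 2} = 1 for both genes
  cq2 <- rbind(
    make_cq(c("a", "b", "c"), "g", "r1", c(15, 15, 15)),
    make_cq(c("a", "b", "c"), "g", "r2", c(15, 16, 17)))
  rq2 <- relative_quantities(collapse_replicates(cq2))
  expect_equal(genorm_m(rq2)$m, c(1, 1))

  # three genes, one noisy: the noisy gene has the strictly largest M,
  # agreeing with the brute-force oracle on the same 3 x 4 fixture
  set.seed(31)
  mat <- cbind(r1 = 2^rnorm(4, 0, 0.05), r2 = 2^rnorm(4, 0, 0.05),
               bad = 2^rnorm(4, 0, 1.5))
  rq3 <- do.call(rbind, lapply(colnames(mat), function(g) {
    data.frame(sample_id = sprintf("s%d", 1:4), group = "g", gene = g,
               mean_cq = 20, rq = mat[, g], stringsAsFactors = FALSE)
  }))
  gm3 <- genorm_m(rq3)
  oracle <- genorm_oracle(mat)
  expect_equal(gm3$m[match(colnames(mat), gm3$gene)], oracle,
               tolerance = 1e-12)
  expect_equal(gm3$gene[which.max(gm3$m)], "bad")
  expect_gt(max(oracle), max(oracle[-3]))

  # rescaling one gene's RQ leaves M unchanged
  rq3b <- rq3
  rq3b$rq[rq3b$gene == "r1"] <- rq3b$rq[rq3b$gene == "r1"] * 37
  expect_equal(genorm_m(rq3b)$m, gm3$m, tolerance = 1e-12)

  expect_error(genorm_m(rq3[rq3$sample_id == "s1", ]), class = "bad_genorm")
})

test_that("group summaries are geometric with multiplicatively symmetric CIs", {
  cn <- data.frame(sample_id = c("a", "b"), group = "g", gene = "t",
                   cnrq = c(1, 4), stringsAsFactors = FALSE)
  gs <- group_summary(cn)
  expect_equal(gs$geo_mean, 2)

  # zero variance collapses the interval onto the point
  cn0 <- data.frame(sample_id = letters[1:4], group = "g", gene = "t",
                    cnrq = rep(2.5, 4), stringsAsFactors = FALSE)
  gs0 <- group_summary(cn0)
  expect_equal(gs0$ci_low, 2.5)
  expect_equal(gs0$ci_high, 2.5)

  # high/mean == mean/low on random fixtures
  set.seed(41)
  for (i in 1:10) {
    cnr <- data.frame(sample_id = sprintf("s%d", 1:8), group = "g",
                      gene = "t", cnrq = rlnorm(8, 0, 1),
                      stringsAsFactors = FALSE)
    gsr <- group_summary(cnr)
    expect_equal(gsr$ci_high / gsr$geo_mean, gsr$geo_mean / gsr$ci_low,
                 tolerance = 1e-12)
    expect_true(gsr$ci_low <= gsr$geo_mean && gsr$geo_mean <= gsr$ci_high)
  }

  gs1 <- group_summary(cn[1, ])
  expect_equal(gs1$flags, "N_EQ_1")
  expect_true(is.na(gs1$ci_low))
})

test_that("exact Mann-Whitney agrees with the enumeration oracle", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")

  same <- mann_whitney(c(2, 2, 2), c(2, 2))
  expect_equal(same$p, 1)

  set.seed(51)
  for (na in 2:6) {
    for (nb in 2:6) {
      a <- rnorm(na)
      b <- rnorm(nb, 0.5)
      res <- mann_whitney(a, b, mode = "exact")
      expect_equal(res$p, mw_enumeration_oracle(a, b), tolerance = 1e-12,
                   label = sprintf("exact p (na=%d, nb=%d)", na, nb))
      expect_gt(res$p, 0)
      expect_lte(res$p, 1)
    }
  }

  # ties force the approximation in auto mode, and error in exact mode
  tied <- mann_whitney(c(1, 2, 2), c(2, 3, 4), mode = "auto")
  expect_equal(tied$method, "normal_approx")
  expect_error(mann_whitney(c(1, 2, 2), c(2, 3, 4), mode = "exact"),
               class = "bad_test")
})

test_that("group comparisons pool controls and star significance", {
  cqres <- generate_cq(cq_scenario(), seed = 5)
  qa <- qpcr_analysis(cqres$cq, reference_genes = c("ActB", "S18"),
                      control_groups = "control_29C")
  comp <- qa$comparisons
  expect_equal(sort(comp$group), c("cold_17C", "heat_41C"))
  expect_equal(unique(comp$n_control), 16L)
  heat <- comp[comp$group == "heat_41C", ]
  expect_lt(heat$p, 0.01)
  expect_equal(heat$stars, "**")
  # both references pass the geNorm stability gate at scenario noise
  expect_true(all(qa$genorm$stable))
})
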
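test_that("roll-up averages available peptides per protein and injection", {
  design <- tiny_design(n_case = 2, n_control = 2, r = 1)
  tbl <- dplyr::bind_rows(
    peptide_table_from_log2(list(P1 = c(4, 4, 4, 4)), design) |>
      dplyr::mutate(peptide = "P1_pepA", log2_intensity = 4),
    peptide_table_from_log2(list(P1 = c(6, 6, 6, 6)), design) |>
      dplyr::mutate(peptide = "P1_pepB", log2_intensity = 6)
  )
  attr(tbl, "intensity_scale") <- "log2qn"
  out <- rollup_protein(tbl)
  expect_equal(unique(out$log2_intensity), 5)
  expect_identical(unique(out$n_peptides), 2L)

  # one peptide missing in one injection: mean of those present
  tbl2 <- tbl[-1, ]
  attr(tbl2, "intensity_scale") <- "log2qn"
  out2 <- rollup_protein(tbl2)
  dropped <- dplyr::filter(out2, injection == tbl$injection[1])
  expect_equal(dropped$log2_intensity, 6)
  expect_identical(dropped$n_peptides, 1L)
})

test_that("the group/sample fit reproduces the hand-computed one-way ANOVA", {
  y <- tibble::tibble(
    log2_intensity = c(1, 2, 3, 4, 5, 6),
    sample = paste0("s", 1:6),
    group = rep(c("control", "case"), each = 3),
    replicate = 1
  )
  fit <- fit_group_sample_model(y)
  expect_equal(fit$diff, 3)
  expect_equal(fit$f, 13.5, tolerance = 1e-9)
  expect_equal(fit$df, c(1, 4))
  expect_equal(fit$p_value, 0.02131164, tolerance = 1e-6)

  td <- tidy(fit)
  expect_equal(td$estimate, 3)
  expect_equal(td$fold_change, 8)
})

test_that("with r = 1 the F statistic equals the pooled t-statistic squared", {
  set.seed(17)
  for (i in 1:5) {
    vals <- rnorm(9)
    y <- tibble::tibble(
      log2_intensity = vals,
      sample = paste0("s", 1:9),
      group = rep(c("case", "control"), c(5, 4)),
      replicate = 1
    )
    fit <- fit_group_sample_model(y)
    tt <- t.test(vals[1:5], vals[6:9], var.equal = TRUE)
    expect_equal(fit$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("the replicated fit matches aov's Group + Error(Sample) stratum", {
  set.seed(23)
  design <- tiny_design(n_case = 4, n_control = 3, r = 3)
  y <- dplyr::mutate(design,
    log2_intensity = 10 + 0.4 * (group == "case") +
      rep(rnorm(7, 0, 0.3), each = 3) + rnorm(21, 0, 0.15)
  )
  fit <- fit_group_sample_model(y)
  a <- summary(stats::aov(
    log2_intensity ~ group + Error(sample), data = y
  ))
  strat <- a[["Error: sample"]][[1]]
  expect_equal(fit$f, strat["group", "F value"], tolerance = 1e-8)
  expect_equal(fit$p_value, strat["group", "Pr(>F)"], tolerance = 1e-8)
  # variance components from the expected mean squares, truncated at zero
  ms_sample <- strat["Residuals", "Mean Sq"]
  within <- a[["Error: Within"]][[1]]
  ms_rep <- within["Residuals", "Mean Sq"]
  expect_equal(fit$sigma2_rep, ms_rep, tolerance = 1e-8)
  expect_equal(fit$sigma2_sample, max(0, (ms_sample - ms_rep) / 3),
               tolerance = 1e-8)
})

test_that("pure-replicate data truncates the sample variance component at zero", {
  design <- tiny_design(n_case = 3, n_control = 3, r = 2)
  # replicate noise only, per-sample means identical within each group:
  # the sample-level mean square is below the replicate contribution, so the
  # raw sigma_sample^2 estimate is negative and must truncate to exactly 0
  y <- dplyr::mutate(design,
    log2_intensity = 10 + 0.5 * (group == "case") +
      rep(c(-0.2, 0.2), times = 6)
  )
  fit <- suppressWarnings(fit_group_sample_model(y))
  expect_identical(fit$sigma2_sample, 0)
  expect_gt(fit$sigma2_rep, 0)
})

test_that("degenerate inputs raise the contracted conditions", {
  y <- tibble::tibble(
    log2_intensity = c(1, 2, 3),
    sample = paste0("s", 1:3),
    group = c("case", "control", "control"),
    replicate = 1
  )
  expect_error(fit_group_sample_model(y), class = "protlfq_inference_error")

  y0 <- tibble::tibble(
    log2_intensity = c(1, 1, 2, 2),
    sample = paste0("s", 1:4),
    group = rep(c("case", "control"), each = 2),
    replicate = 1
  )
  expect_warning(fit <- fit_group_sample_model(y0), "zero residual variance")
  expect_identical(fit$p_value, 0)
})

test_that("signed fold-changes follow the negative-reciprocal convention", {
  expect_equal(fold_change(1), 2)
  expect_equal(fold_change(-1), -2)
  expect_equal(fold_change(0), 1)
  # antisymmetry: fold_change(-d) = -fold_change(d) for d > 0
  d <- c(0.1, 0.585, 1, 2.3)
  expect_equal(fold_change(-d), -fold_change(d))
  expect_true(all(abs(fold_change(rnorm(50))) >= 1))
})

test_that("BH q-values match hand-computed step-up values", {
  expect_equal(estimate_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(estimate_qvalues(0.2), 0.2)
  expect_equal(estimate_qvalues(rep(1, 4)), rep(1, 4))
  # p = (0.005, 0.04, 0.04, 0.8): q = (0.02, 0.0533..., 0.0533..., 0.8)
  expect_equal(estimate_qvalues(c(0.005, 0.04, 0.04, 0.8)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
  expect_error(estimate_qvalues(c(0.1, 1.2)), class = "protlfq_data_error")
  expect_error(estimate_qvalues(c(0.1, NA)), class = "protlfq_data_error")
})

test_that("%CV summaries compute raw-scale CVs by stratum", {
  design <- tiny_design(n_case = 2, n_control = 2, r = 3)
  # one protein, same intensities (100, 110, 90) in every sample
  prot <- design |>
    dplyr::mutate(
      protein = "P1",
      log2_intensity = log2(rep(c(100, 110, 90), times = 4)),
      n_peptides = 1L
    )
  cv <- cv_summaries(prot)
  expect_equal(cv$cv_replicate, 10, tolerance = 1e-9)

  # all-equal intensities give 0% CV
  flat <- dplyr::mutate(prot, log2_intensity = log2(100))
  cvf <- cv_summaries(flat)
  expect_equal(cvf$cv_replicate, 0)
  expect_equal(cvf$cv_rep_sample, 0)
})

test_that("rep+sample %CV exceeds replicate %CV in expectation under the model", {
  sim <- generate_peptide_table(synth_config(n_proteins = 150, seed = 29))
  res <- quantify_proteins(normalize_peptide_table(sim$peptides))
  expect_gt(median(res$cv_rep_sample), median(res$cv_replicate))
})

test_that("the significance gate requires both q and fold-change thresholds", {
  expect_true(flag_significant(0.01, 1.52))
  expect_false(flag_significant(0.001, 1.2))
  expect_true(flag_significant(0.04, -1.46))
  expect_false(flag_significant(0.06, 2.0))
  expect_true(flag_significant(0.049, 1.3)) # inclusive fold-change boundary
})

test_that("spike-in QC passes near-unity fold-changes and fails real changes", {
  res <- tibble::tibble(
    protein = c(SPIKEIN_ACCESSION, "P2"),
    fold_change = c(-1.1, 2.0),
    q_value = c(0.77, 0.001)
  )
  qc <- qc_spikein_check(res)
  expect_true(qc$pass)
  expect_equal(qc$fold_change, -1.1)

  bad <- dplyr::mutate(res, fold_change = c(2.0, 2.0), q_value = c(0.001, 0.001))
  expect_false(qc_spikein_check(bad)$pass)

  exact <- dplyr::mutate(res, fold_change = c(1.0, 2.0), q_value = c(0.5, 0.001))
  expect_true(qc_spikein_check(exact)$pass)

  expect_error(qc_spikein_check(res[2, ]), class = "protlfq_qc_error")
})

test_that("the noise-free pipeline recovers true fold-changes exactly", {
  cfg <- synth_config(
    n_proteins = 12, frac_changed = 0.5, effect_log2 = c(0.5, 1),
    sigma_sample = 0, sigma_rep = 0, n_replicates = 2, seed = 37
  )
  sim <- generate_peptide_table(cfg)
  norm <- normalize_peptide_table(sim$peptides, quantile = FALSE)
  # noise-free data trips the zero-residual-variance warning by design
  res <- suppressWarnings(quantify_proteins(norm)) |>
    dplyr::inner_join(sim$truth, by = "protein")
  expect_equal(res$diff_log2, res$true_log2_fc, tolerance = 1e-9)
  expect_equal(res$fold_change, res$true_fold_change, tolerance = 1e-9)
})
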
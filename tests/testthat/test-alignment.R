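test_that("RT shift estimation returns 0 for identical runs and the median otherwise", {
  run <- feature_obs(mz = c(400, 500, 600), charge = 2, rt = c(10, 20, 30))
  expect_equal(estimate_rt_shift(run, run), 0)

  shifted <- dplyr::mutate(run, rt = rt + 3, run = "r2")
  expect_equal(estimate_rt_shift(shifted, run), 3)

  # anchor-wise shifts {+1, +1, +5} -> median +1
  uneven <- dplyr::mutate(run, rt = rt + c(1, 1, 5), run = "r3")
  expect_equal(estimate_rt_shift(uneven, run), 1)
})

test_that("RT shift estimation fails loudly without anchor pairs", {
  a <- feature_obs(mz = 400, charge = 2, rt = 10, run = "rA")
  b <- feature_obs(mz = 900, charge = 3, rt = 10, run = "rB")
  expect_error(estimate_rt_shift(a, b), class = "protlfq_alignment_failure")
})

test_that("features group only when all four matching criteria hold", {
  frag <- list(c(300, 500, 700))
  base <- function(run, rt, charge = 2) {
    feature_obs(mz = 500.0, charge = charge, rt = rt, fragments = frag, run = run)
  }
  cfg <- alignment_config()

  # same feature, 0.5 min apart -> one group of two members
  g <- match_features(list(r1 = base("r1", 10), r2 = base("r2", 10.5)),
                      cfg, correct_shifts = FALSE)
  expect_identical(dplyr::n_distinct(g$group_id), 1L)

  # 1.5 min apart violates the 1-min window -> two singletons
  g <- match_features(list(r1 = base("r1", 10), r2 = base("r2", 11.5)),
                      cfg, correct_shifts = FALSE)
  expect_identical(dplyr::n_distinct(g$group_id), 2L)

  # charge mismatch is never grouped, even at identical m/z and RT
  g <- match_features(list(r1 = base("r1", 10, charge = 2),
                           r2 = base("r2", 10, charge = 3)),
                      cfg, correct_shifts = FALSE)
  expect_identical(dplyr::n_distinct(g$group_id), 2L)

  # disjoint fragment fingerprints fail the similarity criterion
  other <- feature_obs(mz = 500.0, charge = 2, rt = 10,
                       fragments = list(c(901, 1101, 1201)), run = "r2")
  g <- match_features(list(r1 = base("r1", 10), r2 = other),
                      cfg, correct_shifts = FALSE)
  expect_identical(dplyr::n_distinct(g$group_id), 2L)
})

test_that("matching output is invariant to run and row ordering", {
  cfg <- synth_config(n_proteins = 8, n_samples_per_group = c(2, 2),
                      n_replicates = 1, seed = 21)
  fr <- generate_feature_runs(cfg, mz_jitter_sd = 0.02, rt_jitter_sd = 0.05,
                              rt_shift_sd = 0.5)
  runs <- fr$runs
  g1 <- match_features(runs)
  shuffled <- purrr::map(runs, function(r) r[rev(seq_len(nrow(r))), ])
  g2 <- match_features(shuffled)
  key <- function(g) {
    g |>
      dplyr::arrange(run, feature_id) |>
      dplyr::mutate(grp = match(group_id, unique(group_id))) |>
      dplyr::pull(grp)
  }
  expect_identical(key(g1), key(g2))
})

test_that("trapezoidal AUC matches closed forms and pracma, and is additive", {
  rect <- data.frame(time = c(0, 2), intensity = c(10, 10))
  expect_equal(integrate_auc(rect), 20)

  tri <- data.frame(time = c(0, 0.5, 1), intensity = c(0, 100, 0))
  expect_equal(integrate_auc(tri), 50)

  zero <- data.frame(time = 0:5, intensity = numeric(6))
  expect_equal(integrate_auc(zero), 0)

  set.seed(1)
  t <- sort(runif(20, 0, 10))
  y <- abs(rnorm(20))
  expect_equal(integrate_auc(data.frame(time = t, intensity = y)),
               pracma::trapz(t, y), tolerance = 1e-12)

  # additive over concatenation at a shared boundary point
  left <- data.frame(time = t[1:10], intensity = y[1:10])
  right <- data.frame(time = t[10:20], intensity = y[10:20])
  expect_equal(integrate_auc(left) + integrate_auc(right),
               integrate_auc(data.frame(time = t, intensity = y)),
               tolerance = 1e-12)

  expect_error(integrate_auc(data.frame(time = 1, intensity = 5)),
               class = "protlfq_data_error")
  expect_error(integrate_auc(data.frame(time = c(1, 1), intensity = c(5, 5))),
               class = "protlfq_data_error")
})

test_that("aligned groups convert to a peptide table with missing (not zero) cells", {
  design <- tiny_design(n_case = 1, n_control = 1, r = 1)
  groups <- tibble::tibble(
    group_id = c(1L, 1L),
    consensus_mz = 500, consensus_rt = 10, charge = 2,
    run = design$injection,
    feature_id = c("f1", "f1"),
    mz = 500, rt = 10, rt_corrected = 10,
    area = c(20, 40)
  )
  ids <- tibble::tibble(group_id = 1L, protein = "P1", peptide = "PEP1",
                        confidence = 99)
  tbl <- groups_to_peptide_table(groups, ids, design)
  expect_identical(nrow(tbl), 2L)
  expect_equal(sort(tbl$intensity), c(20, 40))

  # a group absent from one run yields no row for that injection
  tbl1 <- groups_to_peptide_table(groups[1, ], ids, design)
  expect_identical(nrow(tbl1), 1L)

  # two aligned groups (e.g. charge states) can map to one peptide key
  two <- dplyr::bind_rows(groups, dplyr::mutate(groups, group_id = 2L, charge = 3))
  ids2 <- dplyr::bind_rows(ids, dplyr::mutate(ids, group_id = 2L))
  tbl2 <- groups_to_peptide_table(two, ids2, design)
  expect_identical(nrow(tbl2), 4L)
  expect_identical(unique(tbl2$peptide), "PEP1")

  # unidentified groups are dropped with a message
  expect_message(
    out <- groups_to_peptide_table(
      dplyr::bind_rows(groups, dplyr::mutate(groups, group_id = 3L)),
      ids, design
    ),
    "unidentified"
  )
  expect_identical(nrow(out), 2L)

  # unknown run is an error
  bad <- dplyr::mutate(groups, run = "nope")
  expect_error(groups_to_peptide_table(bad, ids, design),
               class = "protlfq_data_error")
})

test_that("matching recovers ground-truth correspondence at sub-tolerance jitter", {
  cfg <- synth_config(n_proteins = 40, n_samples_per_group = c(3, 2),
                      n_replicates = 1, seed = 31)
  acfg <- alignment_config()
  fr <- generate_feature_runs(
    cfg,
    mz_jitter_sd = acfg$mz_tolerance / 8,
    rt_jitter_sd = acfg$rt_window / 10,
    rt_shift_sd = 1.5
  )
  groups <- match_features(fr$runs, acfg)
  # every ground-truth feature should land in a single group covering all runs
  purity <- groups |>
    dplyr::summarise(n_groups = dplyr::n_distinct(group_id),
                     n_obs = dplyr::n(), .by = "feature_id")
  frac_perfect <- mean(purity$n_groups == 1 & purity$n_obs == length(fr$runs))
  expect_gte(frac_perfect, 0.99)
})
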
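#' Roll peptides up to protein log2 intensities
#'
#' For every protein and injection, the quantile-normalized log2 intensities
#' of its available peptides are averaged (unweighted) to give the protein
#' log2 intensity; the peptide count actually used is recorded. A protein
#' with no present peptide in an injection yields no row (a missing cell).
#'
#' @param peptides Normalized long peptide tibble (column `log2_intensity`)
#'   from [normalize_peptide_table()].
#' @return Long tibble: protein, injection, sample, group, replicate,
#'   log2_intensity, n_peptides.
#' @export
rollup_protein <- function(peptides) {
  scale <- attr(peptides, "intensity_scale")
  if (!is.null(scale) && scale != "log2qn") {
    abort(sprintf("expected a normalized table, got scale '%s'.", scale),
      class = "protlfq_data_error"
    )
  }
  peptides |>
    dplyr::summarise(
      n_peptides = sum(!is.na(.data$log2_intensity)),
      log2_intensity = mean(.data$log2_intensity, na.rm = TRUE),
      .by = c("protein", "injection", "sample", "group", "replicate")
    ) |>
    dplyr::filter(!is.nan(.data$log2_intensity))
}

#' Fit the per-protein two-level ANOVA: Group + Sample(Group)
#'
#' The per-protein model for log2 protein intensity has a fixed two-level
#' group effect and a random biological-sample effect nested in group;
#' replicate injections contribute technical noise. The group effect is
#' tested against the sample-within-group stratum (expected-mean-squares
#' F test): replicates are collapsed to per-sample means, the one-way ANOVA
#' of those means on group gives F on (1, N_samples - 2) degrees of freedom.
#' Variance components come from the replicate-level and sample-level mean
#' squares; negative estimates are truncated at zero.
#'
#' @param y Tibble with columns `log2_intensity`, `sample`, `group`
#'   (two levels, `"case"`/`"control"`), `replicate`.
#' @return Object of class `group_sample_fit`: list with `diff` (case minus
#'   control mean log2), `group_means`, `f`, `df`, `p_value`,
#'   `sigma2_sample`, `sigma2_rep`, `n_samples`, `n_replicates`.
#' @examples
#' y <- tibble::tibble(
#'   log2_intensity = c(1, 2, 3, 4, 5, 6),
#'   sample = paste0("s", 1:6),
#'   group = rep(c("control", "case"), each = 3),
#'   replicate = 1
#' )
#' fit_group_sample_model(y)
#' @export
fit_group_sample_model <- function(y) {
  stopifnot(all(c("log2_intensity", "sample", "group") %in% names(y)))
  y <- dplyr::filter(y, !is.na(.data$log2_intensity))
  groups <- sort(unique(y$group))
  if (!setequal(groups, c("case", "control"))) {
    abort("`group` must contain exactly the levels 'case' and 'control'.",
      class = "protlfq_inference_error"
    )
  }

  per_sample <- y |>
    dplyr::summarise(
      mean_log2 = mean(.data$log2_intensity),
      n_rep = dplyr::n(),
      ss_rep = sum((.data$log2_intensity - mean(.data$log2_intensity))^2),
      .by = c("sample", "group")
    )
  n_per_group <- table(per_sample$group)
  if (any(n_per_group < 2)) {
    abort("need at least 2 samples per group for inference.",
      class = "protlfq_inference_error"
    )
  }

  n_samples <- nrow(per_sample)
  r_bar <- mean(per_sample$n_rep)

  # replicate-level (technical) mean square, pooled within samples
  df_rep <- sum(per_sample$n_rep - 1)
  ms_rep <- if (df_rep > 0) sum(per_sample$ss_rep) / df_rep else NA_real_

  # one-way ANOVA of per-sample means on group
  gm <- tapply(per_sample$mean_log2, per_sample$group, mean)
  grand <- mean(per_sample$mean_log2)
  ss_between <- sum(n_per_group * (gm[names(n_per_group)] - grand)^2)
  ss_within <- sum((per_sample$mean_log2 -
    gm[as.character(per_sample$group)])^2)
  df_between <- 1
  df_within <- n_samples - 2
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within

  if (ms_within == 0) {
    if (ms_between > 0) {
      warn("zero residual variance: p-value set to 0.")
      f <- Inf
      p <- 0
    } else {
      f <- NaN
      p <- 1
    }
  } else {
    f <- ms_between / ms_within
    p <- pf(f, df_between, df_within, lower.tail = FALSE)
  }

  # ms_within estimates sigma_sample^2 + sigma_rep^2 / r
  sigma2_rep <- if (is.na(ms_rep)) NA_real_ else ms_rep
  sigma2_sample <- if (is.na(ms_rep)) {
    NA_real_
  } else {
    max(0, ms_within - ms_rep / r_bar)
  }

  structure(
    list(
      diff = unname(gm["case"] - gm["control"]),
      group_means = gm,
      f = unname(f),
      df = c(df_between, df_within),
      p_value = unname(p),
      sigma2_sample = sigma2_sample,
      sigma2_rep = sigma2_rep,
      n_samples = unname(n_per_group[c("case", "control")]),
      n_replicates = r_bar
    ),
    class = "group_sample_fit"
  )
}

#' @export
print.group_sample_fit <- function(x, ...) {
  cat(sprintf(
    "Group + Sample(Group) fit: diff = %.4f log2, F(%d, %d) = %.3f, p = %.4g\n",
    x$diff, x$df[1], x$df[2], x$f, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.group_sample_fit <- function(x, ...) {
  tibble::tibble(
    term = "group (case - control)",
    estimate = x$diff,
    fold_change = fold_change(x$diff),
    statistic = x$f,
    df = x$df[1],
    df_residual = x$df[2],
    p.value = x$p_value
  )
}

#' @export
glance.group_sample_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_sample = x$sigma2_sample,
    sigma2_rep = x$sigma2_rep,
    n_case = x$n_samples[1],
    n_control = x$n_samples[2],
    n_replicates = x$n_replicates
  )
}

#' Signed fold-change from a log2 group difference
#'
#' Back-transforms a log2 difference to a ratio and applies the signed
#' convention used for reporting regulation direction: ratios below 1 are
#' reported as the negative reciprocal, so -1.46 means 1.46-fold down.
#' `|fold_change(d)| >= 1` always.
#'
#' @param diff_log2 Log2 group difference(s).
#' @return Signed fold-change(s).
#' @examples
#' fold_change(c(-1, 0, 1))
#' @export
fold_change <- function(diff_log2) {
  ratio <- 2^diff_log2
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Benjamini-Hochberg q-values
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Step-up adjusted values (monotone in the p-value order).
#' @export
estimate_qvalues <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].", class = "protlfq_data_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-protein coefficient-of-variation summaries
#'
#' %CV is a raw-scale quantity, so protein intensities are back-transformed
#' (2^log2) before computing it. Replicate %CV (technical variation) is
#' `100 * sd/mean` across replicate injections within a sample, averaged
#' over samples; rep+sample %CV (technical plus biological) is taken across
#' all injections within a group, averaged over the two groups. Units with a
#' zero mean are excluded with a warning.
#'
#' @param protein_log2 Rolled-up protein tibble from [rollup_protein()].
#' @return Tibble per protein: `cv_replicate` (NA when replicates are
#'   unavailable), `cv_rep_sample`.
#' @export
cv_summaries <- function(protein_log2) {
  raw <- dplyr::mutate(protein_log2, raw = 2^.data$log2_intensity)

  pct_cv <- function(x) {
    m <- mean(x)
    if (m == 0) {
      warn("zero mean intensity: CV undefined, unit excluded.")
      return(NA_real_)
    }
    100 * sd(x) / m
  }

  rep_cv <- raw |>
    dplyr::summarise(
      cv = if (dplyr::n() >= 2) pct_cv(.data$raw) else NA_real_,
      .by = c("protein", "sample")
    ) |>
    dplyr::summarise(
      cv_replicate = if (all(is.na(.data$cv))) NA_real_ else mean(.data$cv, na.rm = TRUE),
      .by = "protein"
    )

  grp_cv <- raw |>
    dplyr::summarise(
      cv = if (dplyr::n() >= 2) pct_cv(.data$raw) else NA_real_,
      .by = c("protein", "group")
    ) |>
    dplyr::summarise(
      cv_rep_sample = if (all(is.na(.data$cv))) NA_real_ else mean(.data$cv, na.rm = TRUE),
      .by = "protein"
    )

  dplyr::full_join(rep_cv, grp_cv, by = "protein")
}

#' Significance gate on q-value and fold-change
#'
#' A protein is called significantly changed when its q-value is below
#' `q_max` and its absolute signed fold-change is at least `min_abs_fc`
#' (default 1.3, i.e. a 30% increase or decrease at q < 0.05).
#'
#' @param q_value,fold_change_signed Vectors of q-values and signed
#'   fold-changes.
#' @param q_max,min_abs_fc Thresholds.
#' @return Logical vector.
#' @export
flag_significant <- function(q_value, fold_change_signed,
                             q_max = 0.05, min_abs_fc = 1.3) {
  q_value < q_max & abs(fold_change_signed) >= min_abs_fc
}

#' Full peptide-to-protein differential expression analysis
#'
#' Chains roll-up, the per-protein Group + Sample(Group) fit, signed
#' fold-changes, BH q-values, %CV summaries and the significance gate.
#'
#' @param peptides Normalized long peptide tibble
#'   (from [normalize_peptide_table()]).
#' @param q_max,min_abs_fc Significance thresholds; see [flag_significant()].
#' @return Tibble of class `protein_stats`, one row per protein: group
#'   means, log2 difference, signed fold-change, F, p, q, variance
#'   components, %CVs, significance flag, peptide count.
#' @export
quantify_proteins <- function(peptides, q_max = 0.05, min_abs_fc = 1.3) {
  prot <- rollup_protein(peptides)
  n_pep <- peptides |>
    dplyr::summarise(n_peptides = dplyr::n_distinct(.data$peptide), .by = "protein")

  fits <- prot |>
    tidyr::nest(data = -"protein") |>
    dplyr::mutate(fit = purrr::map(.data$data, fit_group_sample_model))

  res <- fits |>
    dplyr::mutate(
      mean_case = purrr::map_dbl(.data$fit, ~ unname(.x$group_means["case"])),
      mean_control = purrr::map_dbl(.data$fit, ~ unname(.x$group_means["control"])),
      diff_log2 = purrr::map_dbl(.data$fit, "diff"),
      fold_change = fold_change(.data$diff_log2),
      statistic = purrr::map_dbl(.data$fit, "f"),
      p_value = purrr::map_dbl(.data$fit, "p_value"),
      sigma2_sample = purrr::map_dbl(.data$fit, "sigma2_sample"),
      sigma2_rep = purrr::map_dbl(.data$fit, "sigma2_rep")
    ) |>
    dplyr::select(-"data", -"fit") |>
    dplyr::mutate(q_value = estimate_qvalues(.data$p_value)) |>
    dplyr::left_join(cv_summaries(prot), by = "protein") |>
    dplyr::left_join(n_pep, by = "protein") |>
    dplyr::mutate(
      significant = flag_significant(
        .data$q_value, .data$fold_change, q_max, min_abs_fc
      )
    )
  class(res) <- c("protein_stats", class(res))
  res
}

#' Spike-in quality-control check
#'
#' The constant-amount spike-in protein must show no apparent change: the QC
#' passes when its absolute signed fold-change is at most `max_abs_fc` and
#' its q-value is at least `q_min` (i.e. not significant).
#'
#' @param results A `protein_stats` tibble from [quantify_proteins()].
#' @param spikein_accession Accession of the spike-in protein.
#' @param max_abs_fc,q_min QC bounds.
#' @return List with `pass`, `fold_change`, `q_value`.
#' @export
qc_spikein_check <- function(results, spikein_accession = SPIKEIN_ACCESSION,
                             max_abs_fc = 1.3, q_min = 0.05) {
  row <- dplyr::filter(results, .data$protein == spikein_accession)
  if (nrow(row) != 1) {
    abort(sprintf("spike-in '%s' absent from results.", spikein_accession),
      class = "protlfq_qc_error"
    )
  }
  list(
    pass = abs(row$fold_change) <= max_abs_fc && row$q_value >= q_min,
    fold_change = row$fold_change,
    q_value = row$q_value
  )
}
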
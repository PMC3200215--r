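#' Filter peptides by identification confidence
#'
#' Retains peptides identified at `min_confidence` percent or better; the
#' boundary is inclusive (a 90.00% peptide survives the default filter).
#'
#' @param peptides Tibble with a `confidence` column in \[0, 100\].
#' @param min_confidence Threshold in percent; default 90.
#' @return The retained rows.
#' @export
filter_confidence <- function(peptides, min_confidence = 90) {
  conf <- peptides$confidence
  if (any(is.na(conf)) || any(conf < 0 | conf > 100)) {
    abort("confidence values must lie in [0, 100].", class = "protlfq_data_error")
  }
  dplyr::filter(peptides, .data$confidence >= min_confidence)
}

#' Assign identification priority classes per protein
#'
#' After the confidence filter, a protein with two or more distinct peptide
#' sequences is Priority 1, with exactly one it is Priority 2, and with none
#' it is filtered out. "Unique peptide" means a distinct amino-acid
#' sequence, ignoring charge state. Peptides shared across proteins count
#' for every mapped protein unless `unique_to_protein` is set.
#'
#' @param peptides Confidence-filtered tibble with `protein` and `peptide`
#'   columns.
#' @param min_confidence Threshold forwarded to [filter_confidence()];
#'   set to 0 if the input is already filtered.
#' @param unique_to_protein Drop peptide sequences mapped to more than one
#'   protein before counting.
#' @return Tibble per protein: `n_unique_peptides`, `priority` (`"1"`,
#'   `"2"`; proteins losing all peptides are absent, i.e. filtered).
#' @export
assign_priority <- function(peptides, min_confidence = 90,
                            unique_to_protein = FALSE) {
  kept <- filter_confidence(peptides, min_confidence)
  if (unique_to_protein) {
    shared <- kept |>
      dplyr::distinct(.data$protein, .data$peptide) |>
      dplyr::count(.data$peptide) |>
      dplyr::filter(.data$n > 1)
    kept <- dplyr::anti_join(kept, shared, by = "peptide")
  }
  kept |>
    dplyr::summarise(
      n_unique_peptides = dplyr::n_distinct(.data$peptide),
      .by = "protein"
    ) |>
    dplyr::mutate(priority = ifelse(.data$n_unique_peptides >= 2, "1", "2")) |>
    dplyr::arrange(.data$protein)
}

#' Study-level summary per priority class
#'
#' Builds the per-priority overview of a differential expression study:
#' protein counts, significant-change counts, maximum absolute fold-change,
#' and median %CVs, with an overall row whose counts are the sums of the
#' strata. The maximum absolute fold-change is taken over all quantified
#' proteins in the stratum (not only the significant ones). When the input
#' carries only the significant proteins (as a printed table transcription
#' does), per-stratum identification totals can be supplied via
#' `n_identified`.
#'
#' @param results Tibble with columns `priority`, `fold_change`,
#'   `significant`, and optionally `cv_replicate`, `cv_rep_sample`.
#' @param n_identified Optional named vector of identified-protein counts
#'   per priority (e.g. `c("1" = 204, "2" = 273)`) overriding the counts
#'   observed in `results`.
#' @return Tibble with one row per priority plus an `"overall"` row:
#'   `n_proteins`, `n_significant`, `max_abs_fold_change`,
#'   `median_cv_replicate`, `median_cv_rep_sample`.
#' @export
summarize_study <- function(results, n_identified = NULL) {
  if (nrow(results) == 0) {
    abort("no results to summarise.", class = "protlfq_data_error")
  }
  med_or_na <- function(x) {
    if (is.null(x) || all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  }
  if (!"cv_replicate" %in% names(results)) results$cv_replicate <- NA_real_
  if (!"cv_rep_sample" %in% names(results)) results$cv_rep_sample <- NA_real_
  strata <- results |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_significant = sum(.data$significant),
      max_abs_fold_change = max(abs(.data$fold_change)),
      median_cv_replicate = med_or_na(.data$cv_replicate),
      median_cv_rep_sample = med_or_na(.data$cv_rep_sample),
      .by = "priority"
    ) |>
    dplyr::mutate(priority = as.character(.data$priority)) |>
    dplyr::arrange(.data$priority)
  if (!is.null(n_identified)) {
    idx <- match(strata$priority, names(n_identified))
    strata$n_proteins <- ifelse(
      is.na(idx), strata$n_proteins, unname(n_identified)[idx]
    )
  }
  overall <- tibble::tibble(
    priority = "overall",
    n_proteins = sum(strata$n_proteins),
    n_significant = sum(strata$n_significant),
    max_abs_fold_change = max(strata$max_abs_fold_change),
    median_cv_replicate = med_or_na(results$cv_replicate),
    median_cv_rep_sample = med_or_na(results$cv_rep_sample)
  )
  dplyr::bind_rows(strata, overall)
}
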
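#' Load the packaged study-table transcriptions
#'
#' The package ships plain-text transcriptions of the study's printed
#' tables: the CSF sample design (13 samples: 8 A-T cases, 5 controls), the
#' per-priority identification summary, the significant Priority 1/2
#' proteins with their peptides, confidences and signed fold-changes, and
#' the MRM transition list for the five biomarker candidate proteins.
#' Confidences printed as ">99.99" are stored as 99.99 (a lower bound).
#'
#' @return A named list of tibbles: `design` (per-sample), `summary`
#'   (per-priority identification summary), `priority_proteins` (one row per
#'   peptide) and `mrm_transitions` (one row per transition; the failed
#'   ALCAM peptide carries `detected = FALSE` and missing m/z values).
#' @examples
#' fx <- load_table_fixtures()
#' dplyr::count(dplyr::distinct(fx$priority_proteins, accession, priority), priority)
#' @export
load_table_fixtures <- function() {
  list(
    design = read_fixture("table1_csf_samples.tsv"),
    summary = read_fixture("table2_study_summary.tsv"),
    priority_proteins = read_fixture("table3_priority_proteins.tsv"),
    mrm_transitions = read_fixture("table4_mrm_transitions.tsv")
  )
}

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "protlfq", mustWork = TRUE)
  out <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(sprintf("failed to parse fixture '%s': %s", file, conditionMessage(e)),
        class = "protlfq_fixture_error"
      )
    }
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(
      sprintf(
        "malformed fixture '%s' at line %d: %s",
        file, probs$row[1], probs$expected[1]
      ),
      class = "protlfq_fixture_error"
    )
  }
  out
}

#' Per-protein statistics implied by the priority-protein fixture
#'
#' Collapses the per-peptide transcription to one row per protein with its
#' peptide count, best confidence and printed signed fold-change, shaped so
#' it can feed [summarize_study()] directly. All transcribed proteins are
#' significant by construction (the printed table lists only the
#' significantly changed ones).
#'
#' @param priority_proteins The `priority_proteins` tibble from
#'   [load_table_fixtures()].
#' @return Tibble with one row per protein: accession, protein, priority,
#'   n_peptides, max_confidence, fold_change, significant.
#' @export
fixture_protein_results <- function(priority_proteins) {
  priority_proteins |>
    dplyr::summarise(
      protein = dplyr::first(.data$protein),
      priority = dplyr::first(.data$priority),
      n_peptides = dplyr::n_distinct(.data$peptide),
      max_confidence = max(.data$confidence),
      fold_change = dplyr::first(.data$fold_change),
      .by = "accession"
    ) |>
    dplyr::mutate(significant = TRUE)
}
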
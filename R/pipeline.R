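#' Run the full discovery pipeline on a synthetic or supplied dataset
#'
#' Chains the stages end to end: (optionally) simulate a peptide table,
#' filter by identification confidence, normalize (log2 + quantile),
#' roll up and fit the per-protein model, classify priorities, summarise the
#' study, run the spike-in QC, and select a biomarker panel from the
#' significant Priority 1 proteins. Deterministic for a fixed config.
#'
#' @param config A [synth_config()] describing the simulated study; ignored
#'   when `peptides` is supplied.
#' @param peptides Optional long peptide tibble (raw intensities) to analyse
#'   instead of simulating.
#' @param min_confidence Peptide identification confidence threshold (%).
#' @param q_max,min_abs_fc Significance thresholds.
#' @param select_panel Run forward panel selection over significant
#'   Priority 1 proteins (needs at least one candidate).
#' @param quantile Apply quantile normalization (see
#'   [normalize_peptide_table()]).
#' @return List of class `lfq_pipeline`: `peptides` (normalized), `results`
#'   (protein statistics with priority), `summary`, `qc`, `panel` (or NULL),
#'   `truth` (when simulated), `config`.
#' @export
run_pipeline <- function(config = synth_config(),
                         peptides = NULL,
                         min_confidence = 90,
                         q_max = 0.05, min_abs_fc = 1.3,
                         select_panel = TRUE,
                         quantile = TRUE) {
  truth <- NULL
  if (is.null(peptides)) {
    sim <- generate_peptide_table(config)
    peptides <- sim$peptides
    truth <- sim$truth
  }
  required <- c(
    "protein", "peptide", "confidence", "injection",
    "sample", "group", "replicate", "intensity"
  )
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("peptide table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "protlfq_data_error"
    )
  }

  kept <- filter_confidence(peptides, min_confidence)
  normalized <- normalize_peptide_table(kept, quantile = quantile)
  results <- quantify_proteins(normalized, q_max = q_max, min_abs_fc = min_abs_fc)
  priorities <- assign_priority(kept, min_confidence = 0)
  results <- dplyr::left_join(results, priorities, by = "protein")
  summary <- summarize_study(results)
  qc <- tryCatch(
    qc_spikein_check(results, max_abs_fc = min_abs_fc, q_min = q_max),
    protlfq_qc_error = function(e) NULL
  )

  panel <- NULL
  if (select_panel) {
    candidates <- results |>
      dplyr::filter(.data$significant, .data$priority == "1", !grepl("spike", .data$protein, ignore.case = TRUE))
    if (nrow(candidates) >= 1) {
      prot_mat <- rollup_protein(normalized) |>
        dplyr::filter(.data$protein %in% candidates$protein) |>
        dplyr::summarise(
          log2_intensity = mean(.data$log2_intensity),
          .by = c("protein", "sample", "group")
        )
      wide <- tidyr::pivot_wider(prot_mat,
        id_cols = c("sample", "group"),
        names_from = "protein", values_from = "log2_intensity"
      )
      xs <- as.matrix(wide[, -(1:2)])
      rownames(xs) <- wide$sample
      if (!anyNA(xs)) {
        panel <- forward_select_panel(xs, wide$group)
      }
    }
  }

  structure(
    list(
      peptides = normalized, results = results, summary = summary,
      qc = qc, panel = panel, truth = truth, config = config
    ),
    class = "lfq_pipeline"
  )
}

#' @export
print.lfq_pipeline <- function(x, ...) {
  cat("<lfq_pipeline>\n")
  cat(sprintf(
    "  %d proteins quantified, %d significant\n",
    nrow(x$results), sum(x$results$significant)
  ))
  if (!is.null(x$qc)) {
    cat(sprintf(
      "  spike-in QC: %s (fold-change %.3f, q = %.3f)\n",
      if (x$qc$pass) "pass" else "FAIL", x$qc$fold_change, x$qc$q_value
    ))
  }
  if (!is.null(x$panel)) {
    cat(sprintf(
      "  panel: %s (LOO errors %d)\n",
      paste(x$panel$proteins, collapse = ", "), x$panel$loo_errors
    ))
  }
  invisible(x)
}

#' Render a deterministic text report of a pipeline run
#'
#' Significant proteins are listed by descending absolute fold-change, ties
#' broken by accession; the study summary, spike-in QC outcome and selected
#' panel follow. Output is a character vector of markdown lines, identical
#' across reruns of the same configuration.
#'
#' @param pipeline An `lfq_pipeline` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(pipeline) {
  res <- pipeline$results
  sig <- res |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(dplyr::desc(abs(.data$fold_change)), .data$protein)

  lines <- c(
    "# Differential protein expression report",
    "",
    "## Study summary",
    utils::capture.output(print(as.data.frame(pipeline$summary), row.names = FALSE)),
    "",
    "## Significant proteins (|fold-change| descending)"
  )
  if (nrow(sig) == 0) {
    lines <- c(lines, "no significant proteins")
  } else {
    lines <- c(lines, sprintf(
      "- %s: fold-change %.2f, q = %.3g (priority %s)",
      sig$protein, sig$fold_change, sig$q_value,
      sig$priority %||% "?"
    ))
  }
  lines <- c(lines, "", "## Spike-in QC")
  if (is.null(pipeline$qc)) {
    lines <- c(lines, "no spike-in present")
  } else {
    lines <- c(lines, sprintf(
      "%s: fold-change %.3f, q = %.3f",
      if (pipeline$qc$pass) "pass" else "FAIL",
      pipeline$qc$fold_change, pipeline$qc$q_value
    ))
  }
  lines <- c(lines, "", "## Biomarker panel")
  if (is.null(pipeline$panel)) {
    lines <- c(lines, "no panel selected")
  } else {
    lines <- c(lines, sprintf(
      "%s (leave-one-out misclassifications: %d)",
      paste(pipeline$panel$proteins, collapse = ", "),
      pipeline$panel$loo_errors
    ))
  }
  lines
}
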
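# Shared builders for small in-code fixtures.

# minimal balanced design: n_case + n_control samples, r replicates
tiny_design <- function(n_case = 3, n_control = 3, r = 1) {
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  groups <- rep(c("case", "control"), c(n_case, n_control))
  tidyr::expand_grid(sample = samples, replicate = seq_len(r)) |>
    dplyr::mutate(
      group = rep(groups, each = r),
      injection = paste(sample, replicate, sep = ":")
    ) |>
    dplyr::select(injection, sample, group, replicate)
}

# long peptide table from a named list protein -> per-injection log2 means,
# one peptide per protein, raw intensity = 2^log2
peptide_table_from_log2 <- function(log2_by_protein, design) {
  purrr::imap(log2_by_protein, function(vals, prot) {
    stopifnot(length(vals) == nrow(design))
    dplyr::mutate(design,
      protein = prot,
      peptide = paste0(prot, "_pep1"),
      confidence = 99,
      intensity = 2^vals
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::select(protein, peptide, confidence, injection,
                  sample, group, replicate, intensity)
}

# one synthetic feature observation tibble row set for alignment tests
feature_obs <- function(mz, charge, rt, fragments = list(c(300, 500, 700)),
                        area = 100, run = "r1") {
  n <- length(mz)
  tibble::tibble(
    run = run,
    feature_id = sprintf("f%d", seq_len(n)),
    mz = mz,
    charge = rep_len(charge, n),
    rt = rt,
    fragments = rep_len(fragments, n),
    area = rep_len(area, n)
  )
}
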
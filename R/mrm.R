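# Peptide mass arithmetic and MRM transition design.
# Residue masses for the 20 standard amino acids (Da).

MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

AVG_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

MASS_WATER <- c(monoisotopic = 18.010565, average = 18.01528)
MASS_PROTON <- 1.00727646688

#' Default fixed cysteine modification mass for 2-iodoethanol alkylation
#'
#' Ethanol adduct added to every cysteine by the alkylation chemistry; pass
#' it as `cys_mod` to the mass functions when the sample prep fixes Cys.
#' @export
CYS_ETHANOL_MOD <- 44.026215

residue_masses <- function(sequence, mass_mode, cys_mod) {
  aa <- strsplit(sequence, "")[[1]]
  tbl <- if (mass_mode == "monoisotopic") MONO_RESIDUE_MASS else AVG_RESIDUE_MASS
  unknown <- which(!aa %in% names(tbl))
  if (length(unknown) > 0) {
    abort(
      sprintf(
        "unknown residue '%s' at position %d of '%s'.",
        aa[unknown[1]], unknown[1], sequence
      ),
      class = "protlfq_data_error"
    )
  }
  tbl[aa] + cys_mod * (aa == "C")
}

#' Precursor m/z of a peptide
#'
#' `(sum of residue masses + water + charge * proton) / charge`.
#'
#' @param sequence Peptide sequence over the 20 standard residues.
#' @param charge Precursor charge (>= 1).
#' @param mass_mode `"monoisotopic"` or `"average"`. Printed precursor
#'   values from unit-resolution instruments typically match average masses.
#' @param cys_mod Fixed modification mass added per cysteine (default 0;
#'   see [CYS_ETHANOL_MOD]).
#' @return m/z in Th.
#' @examples
#' peptide_precursor_mz("ELLQLSKPELPQDGTSTLR", 2, "average")
#' @export
peptide_precursor_mz <- function(sequence, charge,
                                 mass_mode = c("monoisotopic", "average"),
                                 cys_mod = 0) {
  mass_mode <- match.arg(mass_mode)
  charge <- check_count(charge, "charge")
  masses <- residue_masses(sequence, mass_mode, cys_mod)
  (sum(masses) + MASS_WATER[[mass_mode]] + charge * MASS_PROTON) / charge
}

#' Fragment-ion m/z of a peptide (y and b series)
#'
#' y ions are C-terminal suffixes (plus water), b ions N-terminal prefixes
#' (no water); both gain `charge` protons and divide by the charge.
#' Monoisotopic masses are the default for fragment ions.
#'
#' @param sequence Peptide sequence.
#' @param ion_series `"y"` or `"b"`.
#' @param index Fragment length, `1 <= index < nchar(sequence)`.
#' @param charge Fragment charge (>= 1).
#' @inheritParams peptide_precursor_mz
#' @return m/z in Th.
#' @examples
#' fragment_mz("IESQTQEEVR", "y", 8, 1)
#' @export
fragment_mz <- function(sequence, ion_series = c("y", "b"), index, charge = 1,
                        mass_mode = c("monoisotopic", "average"),
                        cys_mod = 0) {
  ion_series <- match.arg(ion_series)
  mass_mode <- match.arg(mass_mode)
  charge <- check_count(charge, "charge")
  n <- nchar(sequence)
  if (index < 1 || index >= n) {
    abort(
      sprintf("fragment index %d out of range for a %d-residue peptide.", index, n),
      class = "protlfq_data_error"
    )
  }
  masses <- residue_masses(sequence, mass_mode, cys_mod)
  neutral <- if (ion_series == "y") {
    sum(masses[(n - index + 1):n]) + MASS_WATER[[mass_mode]]
  } else {
    sum(masses[1:index])
  }
  (neutral + charge * MASS_PROTON) / charge
}

#' Collision energy from precursor m/z and charge
#'
#' Charge-specific linear ramps: `CE = 0.05 * m/z + 8` for doubly charged
#' and `CE = 0.044 * m/z + 8` for triply charged precursors. Other charge
#' states are unsupported.
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param charge 2 or 3.
#' @return Collision energy in volts.
#' @examples
#' collision_energy(610.1, 2)
#' @export
collision_energy <- function(precursor_mz, charge) {
  if (!all(charge %in% c(2, 3))) {
    abort("collision energy is defined for charge 2 or 3 only.",
      class = "protlfq_unsupported_charge"
    )
  }
  slope <- ifelse(charge == 2, 0.05, 0.044)
  slope * precursor_mz + 8
}

#' Build an MRM transition list
#'
#' One transition per requested product ion, with computed precursor and
#' product m/z, charge-specific collision energy, declustering potential
#' fixed at 100 V and a default dwell time of 25 ms (within the 20-30 ms
#' scheduling window).
#'
#' @param targets Tibble with columns `protein`, `peptide`,
#'   `precursor_charge`, `product_index`, `product_charge`, and optionally
#'   `cys_modified` (logical; applies `cys_mod` to that peptide).
#' @param dwell_ms Dwell time per transition (ms), in \[20, 30\].
#' @param precursor_mass_mode Mass mode for precursors (default average).
#' @param fragment_mass_mode Mass mode for fragments (default monoisotopic).
#' @param cys_mod Fixed Cys modification mass applied where `cys_modified`.
#' @return Tibble: protein, peptide, precursor_mz, precursor_charge,
#'   product_ion, product_mz, product_charge, ce, dp, dwell_ms.
#' @export
build_transition_list <- function(targets,
                                  dwell_ms = 25,
                                  precursor_mass_mode = "average",
                                  fragment_mass_mode = "monoisotopic",
                                  cys_mod = CYS_ETHANOL_MOD) {
  if (nrow(targets) == 0) {
    warn("no target product ions: returning an empty transition list.")
    return(tibble::tibble(
      protein = character(), peptide = character(),
      precursor_mz = numeric(), precursor_charge = integer(),
      product_ion = character(), product_mz = numeric(),
      product_charge = integer(), ce = numeric(), dp = numeric(),
      dwell_ms = numeric()
    ))
  }
  if (dwell_ms < 20 || dwell_ms > 30) {
    abort("`dwell_ms` must lie in [20, 30].", class = "protlfq_invalid_config")
  }
  if (!"cys_modified" %in% names(targets)) targets$cys_modified <- FALSE
  targets |>
    dplyr::mutate(
      mod = ifelse(.data$cys_modified, cys_mod, 0),
      precursor_mz = purrr::pmap_dbl(
        list(.data$peptide, .data$precursor_charge, .data$mod),
        function(p, z, m) peptide_precursor_mz(p, z, precursor_mass_mode, m)
      ),
      product_mz = purrr::pmap_dbl(
        list(.data$peptide, .data$product_index, .data$product_charge, .data$mod),
        function(p, i, z, m) fragment_mz(p, "y", i, z, fragment_mass_mode, m)
      ),
      product_ion = sprintf(
        "y%d%s", .data$product_index,
        ifelse(.data$product_charge > 1, paste0("^", .data$product_charge, "+"), "")
      ),
      ce = collision_energy(.data$precursor_mz, .data$precursor_charge),
      dp = 100,
      dwell_ms = dwell_ms
    ) |>
    dplyr::select(
      "protein", "peptide", "precursor_mz", "precursor_charge",
      "product_ion", "product_mz", "product_charge", "ce", "dp", "dwell_ms"
    )
}

#' Relative quantification from MRM transition chromatograms
#'
#' Per peptide: the AUCs of its transitions are averaged within each sample,
#' log2-transformed, and the case-control difference of group means gives a
#' signed fold-change. Per protein: the signed fold-changes of its peptides
#' are averaged (on the fold-change scale, matching the reporting
#' convention), and a one-way ANOVA of the per-sample protein log2 values
#' gives the p-value. Proteins with no detected transitions are reported
#' with `detected = FALSE` rather than as an error.
#'
#' @param chromatograms Tibble with columns `protein`, `peptide`, `sample`,
#'   and either `auc` or a `trace` list-column; one row per transition
#'   measurement.
#' @param design Tibble mapping `sample` to `group`
#'   (`"case"`/`"control"`).
#' @param proteins Optional character vector of assayed proteins, so that
#'   targets with no chromatograms appear as not detected.
#' @return Tibble per protein: `fold_change`, `p_value`, `n_peptides`,
#'   `detected`.
#' @export
quantify_mrm <- function(chromatograms, design, proteins = NULL) {
  if (is.null(chromatograms$auc)) {
    chromatograms$auc <- purrr::map_dbl(chromatograms$trace, integrate_auc)
  }
  design <- dplyr::distinct(design, .data$sample, .data$group)

  per_sample <- chromatograms |>
    dplyr::summarise(mean_auc = mean(.data$auc), .by = c("protein", "peptide", "sample")) |>
    dplyr::inner_join(design, by = "sample") |>
    dplyr::mutate(log2_auc = log2(.data$mean_auc))

  per_peptide <- per_sample |>
    dplyr::summarise(
      diff = mean(.data$log2_auc[.data$group == "case"]) -
        mean(.data$log2_auc[.data$group == "control"]),
      .by = c("protein", "peptide")
    ) |>
    dplyr::mutate(fold_change = fold_change(.data$diff))

  anova_p <- function(df) {
    # protein-level log2 per sample = mean over peptides
    prot <- dplyr::summarise(df,
      log2_protein = mean(.data$log2_auc),
      .by = c("sample", "group")
    )
    if (dplyr::n_distinct(prot$group) < 2 || nrow(prot) < 3) {
      return(NA_real_)
    }
    stats::anova(stats::lm(log2_protein ~ group, data = prot))[["Pr(>F)"]][1]
  }

  detected <- per_peptide |>
    dplyr::summarise(
      fold_change = mean(.data$fold_change),
      n_peptides = dplyr::n(),
      .by = "protein"
    ) |>
    dplyr::mutate(detected = TRUE)
  pvals <- per_sample |>
    tidyr::nest(data = -"protein") |>
    dplyr::mutate(p_value = purrr::map_dbl(.data$data, anova_p)) |>
    dplyr::select("protein", "p_value")
  out <- dplyr::left_join(detected, pvals, by = "protein")

  if (!is.null(proteins)) {
    absent <- setdiff(proteins, out$protein)
    if (length(absent) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        protein = absent, fold_change = NA_real_, n_peptides = 0L,
        detected = FALSE, p_value = NA_real_
      ))
    }
  }
  dplyr::select(
    out, "protein", "fold_change", "p_value", "n_peptides", "detected"
  )
}
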
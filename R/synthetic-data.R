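#' Convert a raw-scale coefficient of variation to a log2-scale SD
#'
#' Peak-intensity noise in label-free LC-MS is conventionally summarised as a
#' percent coefficient of variation (%CV) on the raw intensity scale, while
#' the simulator and the per-protein model work with additive Gaussian noise
#' on the log2 scale. Under the lognormal convention a raw-scale CV of
#' `cv/100` corresponds to a log-scale SD of `sqrt(log(1 + (cv/100)^2))`,
#' rescaled to log2 units.
#'
#' @param cv_percent Coefficient of variation in percent (>= 0).
#' @return Standard deviation in log2 units.
#' @seealso [log2_sd_to_cv()] for the inverse.
#' @examples
#' cv_to_log2_sd(11.97)
#' @export
cv_to_log2_sd <- function(cv_percent) {
  check_nonneg(cv_percent, "cv_percent")
  sqrt(log(1 + (cv_percent / 100)^2)) / log(2)
}

#' @rdname cv_to_log2_sd
#' @param sd_log2 Standard deviation in log2 units (>= 0).
#' @export
log2_sd_to_cv <- function(sd_log2) {
  check_nonneg(sd_log2, "sd_log2")
  100 * sqrt(exp((sd_log2 * log(2))^2) - 1)
}

#' Configuration for the synthetic label-free LC-MS generator
#'
#' Captures the statistical structure the downstream analysis assumes: a
#' per-protein baseline, fixed per-peptide offsets (ionisation efficiency), a
#' group effect on a subset of proteins, a per-sample (biological) random
#' effect shared by all peptides of a sample, and replicate-level technical
#' noise. Defaults mirror a replicated 8-case vs 5-control CSF study: the
#' default `sigma_rep` and `sigma_sample` are back-solved from median
#' replicate %CV ~ 12% and rep+sample %CV ~ 19% via [cv_to_log2_sd()].
#'
#' @param n_proteins Number of simulated proteins (spike-in QC protein is
#'   appended on top of this count).
#' @param peptides_per_protein Single count or length-2 range; the per-protein
#'   peptide count is drawn uniformly from the range.
#' @param n_samples_per_group Length-2 integer vector `c(case, control)`;
#'   default `c(8, 5)`.
#' @param n_replicates Technical replicate injections per sample.
#' @param frac_changed Fraction of proteins given a true group effect; the
#'   realised count is `round(frac_changed * n_proteins)`.
#' @param effect_log2 Magnitude(s) of the true group effect in log2 units;
#'   recycled over changed proteins, signs alternate up/down.
#' @param sigma_sample SD of the per-sample random effect (log2 units).
#' @param sigma_rep SD of replicate technical noise (log2 units).
#' @param baseline_log2 Length-2 vector `c(mean, sd)` of protein baseline
#'   log2 intensity.
#' @param missing_rate Fraction of cells removed completely at random.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200,
                         peptides_per_protein = c(2, 6),
                         n_samples_per_group = c(8, 5),
                         n_replicates = 3,
                         frac_changed = 0.05,
                         effect_log2 = log2(1.5),
                         sigma_sample = sqrt(cv_to_log2_sd(19.16)^2 - cv_to_log2_sd(11.97)^2),
                         sigma_rep = cv_to_log2_sd(11.97),
                         baseline_log2 = c(20, 2),
                         missing_rate = 0,
                         seed = 1L) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins"),
    peptides_per_protein = check_count(peptides_per_protein, "peptides_per_protein"),
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    frac_changed = check_fraction(frac_changed, "frac_changed"),
    effect_log2 = as.numeric(effect_log2),
    sigma_sample = check_nonneg(sigma_sample, "sigma_sample"),
    sigma_rep = check_nonneg(sigma_rep, "sigma_rep"),
    baseline_log2 = as.numeric(baseline_log2),
    missing_rate = check_fraction(missing_rate, "missing_rate", upper_closed = FALSE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$n_samples_per_group) != 2) {
    abort("`n_samples_per_group` must have length 2 (case, control).",
      class = "protlfq_invalid_config"
    )
  }
  if (!length(cfg$peptides_per_protein) %in% 1:2) {
    abort("`peptides_per_protein` must be a count or a length-2 range.",
      class = "protlfq_invalid_config"
    )
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf(
    "  %d proteins, %s peptides/protein, %d vs %d samples x %d replicates\n",
    x$n_proteins, paste(x$peptides_per_protein, collapse = "-"),
    x$n_samples_per_group[1], x$n_samples_per_group[2], x$n_replicates
  ))
  cat(sprintf(
    "  frac_changed %.3f, |effect| %s log2, sigma_sample %.3f, sigma_rep %.3f, seed %d\n",
    x$frac_changed, paste(signif(x$effect_log2, 3), collapse = "/"),
    x$sigma_sample, x$sigma_rep, x$seed
  ))
  invisible(x)
}

#' Accession used for the constant-amount spike-in QC protein
#' @export
SPIKEIN_ACCESSION <- "LYSC_CHICK"

sim_design <- function(config) {
  samples <- c(
    sprintf("case_%02d", seq_len(config$n_samples_per_group[1])),
    sprintf("ctrl_%02d", seq_len(config$n_samples_per_group[2]))
  )
  groups <- rep(c("case", "control"), config$n_samples_per_group)
  tidyr::expand_grid(
    sample = samples,
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(
      group = rep(groups, each = config$n_replicates),
      injection = injection_id(.data$sample, .data$replicate)
    ) |>
    dplyr::select("injection", "sample", "group", "replicate")
}

#' Simulate a peptide-level intensity table with known ground truth
#'
#' Generates raw-scale peptide intensities whose log2 values follow
#' `baseline_i + offset_ij + delta_i * I(case) + b_s + e_sr` with
#' `b_s ~ N(0, sigma_sample^2)` and `e_sr ~ N(0, sigma_rep^2)`. A spike-in QC
#' protein (constant amount, 9 peptides, true fold-change exactly 1) is
#' appended, mirroring the chicken-lysozyme QC convention. Cells are then
#' removed completely at random at `missing_rate`.
#'
#' @param config A [synth_config()].
#' @return A list with elements `peptides` (long tibble: protein, peptide,
#'   confidence, injection, sample, group, replicate, intensity on the raw
#'   scale), `truth` (per-protein tibble with the true signed fold-change,
#'   changed/spike-in labels and the generating SDs), and `design` (the
#'   injection-level study design).
#' @examples
#' sim <- generate_peptide_table(synth_config(n_proteins = 20, seed = 7))
#' dplyr::count(sim$truth, changed)
#' @export
generate_peptide_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  design <- sim_design(config)

  n_prot <- config$n_proteins
  rng <- config$peptides_per_protein
  n_pep <- if (length(rng) == 1) {
    rep(rng, n_prot)
  } else {
    sample(seq(rng[1], rng[2]), n_prot, replace = TRUE)
  }

  n_changed <- round(config$frac_changed * n_prot)
  changed_idx <- if (n_changed > 0) sample.int(n_prot, n_changed) else integer()
  delta <- numeric(n_prot)
  if (n_changed > 0) {
    mag <- rep_len(abs(config$effect_log2), n_changed)
    sgn <- rep_len(c(1, -1), n_changed)
    delta[changed_idx] <- mag * sgn
  }

  accession <- sprintf("PROT%04d", seq_len(n_prot))
  baseline <- rnorm(n_prot, config$baseline_log2[1], config$baseline_log2[2])

  # spike-in appended with delta = 0 and its own baseline
  accession <- c(accession, SPIKEIN_ACCESSION)
  baseline <- c(baseline, config$baseline_log2[1])
  delta <- c(delta, 0)
  n_pep <- c(n_pep, 9L)
  spikein <- c(rep(FALSE, n_prot), TRUE)

  prot_tbl <- tibble::tibble(
    protein = accession,
    baseline = baseline,
    delta = delta,
    n_peptides = n_pep,
    spikein = spikein
  )

  pep_tbl <- prot_tbl |>
    dplyr::reframe(
      peptide = sprintf("%s_pep%02d", .data$protein, seq_len(.data$n_peptides)),
      # fixed per-peptide ionisation offset, shared across all injections
      offset = rnorm(.data$n_peptides, 0, 0.5),
      confidence = round(runif(.data$n_peptides, 90, 99.99), 2),
      .by = c("protein", "baseline", "delta")
    )

  # biological sample effect: one draw per protein x sample, shared by all
  # peptides and replicates of that sample (survives per-injection
  # normalization, unlike a global column shift)
  samples <- dplyr::distinct(design, .data$sample)$sample
  samp_tbl <- tidyr::expand_grid(
    protein = prot_tbl$protein, sample = samples
  ) |>
    dplyr::mutate(b = rnorm(dplyr::n(), 0, config$sigma_sample))

  long <- tidyr::expand_grid(
    pep_tbl,
    design
  ) |>
    dplyr::left_join(samp_tbl, by = c("protein", "sample")) |>
    dplyr::mutate(
      log2_true = .data$baseline + .data$offset +
        .data$delta * (.data$group == "case") + .data$b,
      intensity = 2^(.data$log2_true + rnorm(dplyr::n(), 0, config$sigma_rep))
    ) |>
    dplyr::select(
      "protein", "peptide", "confidence", "injection",
      "sample", "group", "replicate", "intensity"
    )

  if (config$missing_rate > 0) {
    keep <- runif(nrow(long)) >= config$missing_rate
    long <- long[keep, , drop = FALSE]
  }

  truth <- prot_tbl |>
    dplyr::transmute(
      protein = .data$protein,
      true_log2_fc = .data$delta,
      true_fold_change = fold_change(.data$delta),
      changed = .data$delta != 0,
      spikein = .data$spikein,
      sigma_sample = config$sigma_sample,
      sigma_rep = config$sigma_rep
    )

  list(peptides = long, truth = truth, design = design)
}

#' Simulate per-run LC-MS feature lists with known correspondence
#'
#' Builds one ground-truth feature per simulated peptide (precursor m/z,
#' charge, retention time, a fragment fingerprint) and emits it in every
#' injection ("run") with m/z jitter, retention-time jitter, a per-run global
#' RT shift, and a triangular chromatographic peak whose trapezoidal area
#' equals the intended raw intensity. Used to exercise the alignment stage
#' against a known cross-run correspondence.
#'
#' @param config A [synth_config()].
#' @param mz_jitter_sd SD of per-observation m/z jitter (Th).
#' @param rt_jitter_sd SD of per-observation residual RT jitter (min).
#' @param rt_shift_sd SD of the per-run global RT shift (min); the first run
#'   is the reference and gets shift 0.
#' @return A list with `runs` (named list of per-run tibbles with columns
#'   feature_id, mz, charge, rt, fragments (list of fragment m/z), trace
#'   (list of tibbles time/intensity), area), `features` (ground-truth
#'   feature table with peptide/protein identity), `shifts` (true per-run RT
#'   shifts) and `design`.
#' @export
generate_feature_runs <- function(config,
                                  mz_jitter_sd = 0.05,
                                  rt_jitter_sd = 0.1,
                                  rt_shift_sd = 1) {
  stopifnot(inherits(config, "synth_config"))
  check_nonneg(c(mz_jitter_sd, rt_jitter_sd, rt_shift_sd), "jitter sds")
  sim <- generate_peptide_table(config)
  # continue the seeded stream deterministically for the feature layer
  set.seed(config$seed + 1L)

  peptides <- dplyr::distinct(
    sim$peptides, .data$protein, .data$peptide, .data$confidence
  )
  n_feat <- nrow(peptides)
  features <- peptides |>
    dplyr::mutate(
      feature_id = sprintf("F%05d", dplyr::row_number()),
      mz = runif(n_feat, 400, 1200),
      charge = sample(2:3, n_feat, replace = TRUE),
      rt = runif(n_feat, 5, 55),
      fragments = purrr::map(seq_len(n_feat), function(i) {
        sort(runif(6, 200, 1300))
      })
    )

  runs <- sim$design$injection
  shifts <- c(0, rnorm(length(runs) - 1, 0, rt_shift_sd))
  names(shifts) <- runs

  intens <- sim$peptides |>
    dplyr::select("peptide", "injection", "intensity")

  run_list <- purrr::map(runs, function(run_id) {
    run_shift <- shifts[[run_id]]
    obs <- features |>
      dplyr::inner_join(
        dplyr::filter(intens, .data$injection == run_id),
        by = "peptide"
      ) |>
      dplyr::mutate(
        run = run_id,
        mz = .data$mz + rnorm(dplyr::n(), 0, mz_jitter_sd),
        rt = .data$rt + run_shift + rnorm(dplyr::n(), 0, rt_jitter_sd),
        trace = purrr::map2(.data$rt, .data$intensity, triangular_trace),
        area = .data$intensity
      ) |>
      dplyr::select(
        "run", "feature_id", "mz", "charge", "rt",
        "fragments", "trace", "area"
      )
    obs
  })
  names(run_list) <- runs

  list(
    runs = run_list,
    features = dplyr::select(
      features, "feature_id", "protein", "peptide", "confidence",
      "mz", "charge", "rt"
    ),
    shifts = shifts,
    design = sim$design
  )
}

# symmetric triangular peak centred at rt: height h over half-width w has
# trapezoidal area h * w
triangular_trace <- function(rt, area, half_width = 0.25, n_points = 11) {
  height <- area / half_width
  tt <- seq(rt - half_width, rt + half_width, length.out = n_points)
  tibble::tibble(
    time = tt,
    intensity = height * pmax(0, 1 - abs(tt - rt) / half_width)
  )
}

#' Write a generated peptide table to TSV
#'
#' @param peptides Long peptide tibble from [generate_peptide_table()].
#' @param path Output file.
#' @param scale Scale tag recorded in a header comment line.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path, scale = "raw") {
  writeLines(sprintf("# intensity_scale: %s", scale), path)
  readr::write_tsv(peptides, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a peptide table written by [write_peptide_table()]
#'
#' @param path TSV file with an optional `# intensity_scale:` header comment.
#' @return A tibble with attribute `intensity_scale`.
#' @export
read_peptide_table <- function(path) {
  first <- readLines(path, n = 1)
  scale <- if (grepl("^# intensity_scale:", first)) {
    trimws(sub("^# intensity_scale:", "", first))
  } else {
    "raw"
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(out, "intensity_scale") <- scale
  out
}
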
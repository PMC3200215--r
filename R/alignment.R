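#' Alignment parameters for cross-run feature matching
#'
#' Two observations may be grouped only when they agree on all four criteria
#' used for label-free peak correspondence: precursor m/z within
#' `mz_tolerance`, identical charge state, fragment-fingerprint cosine
#' similarity at least `fragment_threshold`, and retention time (after
#' per-run shift correction) within `rt_window`.
#'
#' @param mz_tolerance Precursor m/z tolerance in Th; default 0.5
#'   (unit-resolution ion trap).
#' @param rt_window Retention-time window in minutes; default 1.
#' @param fragment_threshold Cosine-similarity threshold in \[0, 1\] on the
#'   binned fragment fingerprints; default 0.7.
#' @param fragment_bin Fragment m/z bin width in Th; default 0.5.
#' @return A list of class `alignment_config`.
#' @export
alignment_config <- function(mz_tolerance = 0.5,
                             rt_window = 1,
                             fragment_threshold = 0.7,
                             fragment_bin = 0.5) {
  if (any(c(mz_tolerance, rt_window, fragment_bin) <= 0)) {
    abort("tolerances must be > 0.", class = "protlfq_invalid_config")
  }
  check_fraction(fragment_threshold, "fragment_threshold")
  structure(
    list(
      mz_tolerance = mz_tolerance, rt_window = rt_window,
      fragment_threshold = fragment_threshold, fragment_bin = fragment_bin
    ),
    class = "alignment_config"
  )
}

#' Estimate a run's global retention-time shift against a reference
#'
#' Anchor pairs are unique mutual nearest-m/z matches with identical charge
#' within the m/z tolerance; the returned shift is the median RT difference
#' (run minus reference) over the anchors. Subtracting it from the run's
#' retention times places the run on the reference time scale.
#'
#' @param run,reference Per-run feature tibbles (columns `mz`, `charge`,
#'   `rt`) as produced by [generate_feature_runs()].
#' @param config An [alignment_config()].
#' @return Scalar shift in minutes.
#' @export
estimate_rt_shift <- function(run, reference, config = alignment_config()) {
  # mutual nearest neighbour in m/z, same charge, within tolerance
  nearest <- function(from, to) {
    purrr::map_int(seq_len(nrow(from)), function(i) {
      d <- abs(to$mz - from$mz[i])
      d[to$charge != from$charge[i]] <- Inf
      j <- which.min(d)
      if (length(j) == 0 || d[j] > config$mz_tolerance) NA_integer_ else j
    })
  }
  fwd <- nearest(run, reference)
  bwd <- nearest(reference, run)
  mutual <- which(!is.na(fwd) & bwd[fwd] == seq_len(nrow(run)))
  if (length(mutual) == 0) {
    run_name <- if (!is.null(run$run)) run$run[1] else "<run>"
    abort(
      sprintf("no anchor pairs between run '%s' and the reference.", run_name),
      class = "protlfq_alignment_failure"
    )
  }
  median(run$rt[mutual] - reference$rt[fwd[mutual]])
}

fragment_fingerprint <- function(frags, bin) {
  unique(floor(frags / bin))
}

fragment_cosine <- function(bins_a, bins_b) {
  if (length(bins_a) == 0 || length(bins_b) == 0) {
    return(0)
  }
  length(intersect(bins_a, bins_b)) / sqrt(length(bins_a) * length(bins_b))
}

#' Group shift-corrected features across runs
#'
#' Pools all observations, corrects each run by its median RT shift against
#' the first (reference) run, and performs a greedy grouping pass in order of
#' descending peak area (ties by ascending m/z, then run id): each seed
#' collects at most one unassigned observation per other run satisfying all
#' four matching criteria against the seed. Unmatched observations become
#' singleton groups, so output is a partition of the input.
#'
#' @param runs Named list of per-run feature tibbles (columns `run`,
#'   `feature_id`, `mz`, `charge`, `rt`, `fragments`, and `area` or `trace`).
#' @param config An [alignment_config()].
#' @param correct_shifts Estimate and remove per-run global RT shifts before
#'   matching (the first run is the reference).
#' @return Tibble with one row per grouped observation: `group_id`,
#'   consensus `mz`/`rt`/`charge` of the group seed, plus the member's run,
#'   feature_id, area and shift-corrected rt.
#' @export
match_features <- function(runs, config = alignment_config(),
                           correct_shifts = TRUE) {
  stopifnot(is.list(runs), length(runs) >= 1)
  reference <- runs[[1]]
  obs <- purrr::imap(runs, function(r, nm) {
    r <- dplyr::mutate(r, run = nm)
    if (is.null(r$area)) {
      r$area <- purrr::map_dbl(r$trace, integrate_auc)
    }
    shift <- if (correct_shifts && !identical(nm, names(runs)[1])) {
      estimate_rt_shift(r, reference, config)
    } else {
      0
    }
    dplyr::mutate(r, rt_corrected = .data$rt - shift)
  }) |>
    purrr::list_rbind()

  # deterministic greedy order: area desc, mz asc, run id asc
  obs <- obs[order(-obs$area, obs$mz, obs$run), , drop = FALSE]
  n <- nrow(obs)
  bins <- purrr::map(obs$fragments, fragment_fingerprint, bin = config$fragment_bin)
  assigned <- rep(FALSE, n)
  group_of <- integer(n)
  next_group <- 0L

  for (i in seq_len(n)) {
    if (assigned[i]) next
    next_group <- next_group + 1L
    assigned[i] <- TRUE
    group_of[i] <- next_group
    cand <- which(!assigned &
      obs$charge == obs$charge[i] &
      abs(obs$mz - obs$mz[i]) <= config$mz_tolerance &
      abs(obs$rt_corrected - obs$rt_corrected[i]) <= config$rt_window &
      obs$run != obs$run[i])
    if (length(cand) == 0) next
    ok <- cand[purrr::map_dbl(bins[cand], fragment_cosine, bins_b = bins[[i]]) >=
      config$fragment_threshold]
    # at most one member per run: nearest m/z wins
    if (length(ok) > 0) {
      picked <- tibble::tibble(
        idx = ok,
        run = obs$run[ok],
        dmz = abs(obs$mz[ok] - obs$mz[i])
      ) |>
        dplyr::arrange(.data$dmz) |>
        dplyr::distinct(.data$run, .keep_all = TRUE)
      assigned[picked$idx] <- TRUE
      group_of[picked$idx] <- next_group
    }
  }

  obs |>
    dplyr::mutate(group_id = group_of) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(
      consensus_mz = .data$mz[1],
      consensus_rt = .data$rt_corrected[1]
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "group_id", "consensus_mz", "consensus_rt", "charge",
      "run", "feature_id", "mz", "rt", "rt_corrected", "area"
    )
}

#' Trapezoidal area under a chromatographic peak trace
#'
#' @param trace Data frame with strictly increasing `time` and nonnegative
#'   `intensity` columns (at least two points).
#' @return Scalar area (intensity x time units).
#' @examples
#' integrate_auc(data.frame(time = 0:2, intensity = c(10, 10, 10)))
#' @export
integrate_auc <- function(trace) {
  t <- trace$time
  y <- trace$intensity
  if (length(t) < 2) {
    abort("a peak trace needs at least 2 points.", class = "protlfq_data_error")
  }
  if (any(diff(t) <= 0)) {
    abort("trace times must be strictly increasing.", class = "protlfq_data_error")
  }
  sum(diff(t) * (head(y, -1) + y[-1]) / 2)
}

#' Convert aligned groups plus identifications into a peptide table
#'
#' @param groups Output of [match_features()].
#' @param id_assignments Tibble mapping `group_id` to `protein`, `peptide`,
#'   `confidence`; groups without an identification are dropped (a message
#'   reports how many).
#' @param design Study design tibble with `injection`, `sample`, `group`,
#'   `replicate` (runs are injections).
#' @return Long peptide tibble (raw intensity = per-run area) in the shape
#'   [generate_peptide_table()] produces; runs where a group has no member
#'   yield no row (missing, not zero).
#' @export
groups_to_peptide_table <- function(groups, id_assignments, design) {
  unknown <- setdiff(unique(groups$run), design$injection)
  if (length(unknown) > 0) {
    abort(
      sprintf("runs absent from design: %s", paste(unknown, collapse = ", ")),
      class = "protlfq_data_error"
    )
  }
  n_groups <- dplyr::n_distinct(groups$group_id)
  identified <- dplyr::inner_join(groups, id_assignments, by = "group_id")
  n_dropped <- n_groups - dplyr::n_distinct(identified$group_id)
  if (n_dropped > 0) {
    message(sprintf("dropped %d unidentified aligned group(s).", n_dropped))
  }
  identified |>
    dplyr::inner_join(design, by = c(run = "injection")) |>
    dplyr::transmute(
      protein = .data$protein,
      peptide = .data$peptide,
      confidence = .data$confidence,
      injection = .data$run,
      sample = .data$sample,
      group = .data$group,
      replicate = .data$replicate,
      intensity = .data$area
    )
}
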
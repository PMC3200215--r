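# Normalization of peptide feature x injection intensity matrices.
# Scale bookkeeping: a matrix carries attr "intensity_scale" in
# {"raw", "log2", "log2qn"}; transitions only ever move forward.

as_intensity_matrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("expected a numeric matrix (rows = features, cols = injections).",
      class = "protlfq_data_error"
    )
  }
  m
}

set_scale <- function(m, scale) {
  attr(m, "intensity_scale") <- scale
  m
}

#' Log2-transform a raw intensity matrix
#'
#' @param m Numeric matrix (rows = aligned peptide features, columns =
#'   injections) on the raw scale; missing cells stay missing.
#' @return The matrix of cellwise log2 values, scale-tagged `"log2"`.
#' @export
log2_transform <- function(m) {
  m <- as_intensity_matrix(m)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(
      sprintf(
        "non-positive intensities in row(s): %s",
        paste(unique(bad[, "row"]), collapse = ", ")
      ),
      class = "protlfq_data_error"
    )
  }
  set_scale(log2(m), "log2")
}

#' Quantile-normalize a log2 intensity matrix
#'
#' Forces every column (injection) to share the same intensity distribution:
#' each column is sorted, rank k is replaced by the across-column mean of the
#' k-th smallest values (the reference distribution), and the original order
#' is restored. Ties within a column receive the mean of their tied ranks'
#' reference values. Columns with missing cells have their observed quantiles
#' interpolated onto the reference distribution built from complete rows, so
#' the same-distribution contract holds without imputing cells.
#'
#' @param m Numeric log2 matrix; a single-column matrix is returned
#'   unchanged with a warning.
#' @return The normalized matrix, scale-tagged `"log2qn"`.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(m) {
  m <- as_intensity_matrix(m)
  if (ncol(m) < 2) {
    warn("single-column matrix: quantile normalization is a no-op.")
    return(set_scale(m, "log2qn"))
  }

  if (!anyNA(m)) {
    if (nrow(m) == 1) {
      out <- matrix(mean(m), 1, ncol(m), dimnames = dimnames(m))
      return(set_scale(out, "log2qn"))
    }
    reference <- rowMeans(apply(m, 2, sort))
    out <- apply(m, 2, function(col) {
      # mean reference value over tied ranks (ties.method = "average")
      reference_at <- stats::approx(
        x = seq_along(reference), y = reference,
        xout = rank(col, ties.method = "average")
      )$y
      reference_at
    })
    dimnames(out) <- dimnames(m)
    return(set_scale(out, "log2qn"))
  }

  complete <- stats::complete.cases(m)
  if (!any(complete)) {
    abort("no complete rows to build the reference distribution from.",
      class = "protlfq_data_error"
    )
  }
  reference <- sort(rowMeans(apply(m[complete, , drop = FALSE], 2, sort)))
  ref_probs <- if (length(reference) > 1) {
    seq(0, 1, length.out = length(reference))
  } else {
    0.5
  }
  out <- apply(m, 2, function(col) {
    ok <- !is.na(col)
    n_ok <- sum(ok)
    res <- rep(NA_real_, length(col))
    if (n_ok == 1) {
      res[ok] <- stats::approx(ref_probs, reference, xout = 0.5, rule = 2)$y
    } else if (n_ok > 1) {
      probs <- (rank(col[ok], ties.method = "average") - 1) / (n_ok - 1)
      res[ok] <- stats::approx(ref_probs, reference, xout = probs, rule = 2)$y
    }
    res
  })
  dimnames(out) <- dimnames(m)
  set_scale(out, "log2qn")
}

#' Check that a matrix is quantile-normalized
#'
#' @param m Numeric matrix.
#' @param tol Maximum allowed discrepancy between any column's sorted values
#'   and the first column's.
#' @return List with `ok` (logical) and `max_discrepancy` (largest absolute
#'   difference between sorted columns, over complete rows).
#' @export
check_normalized <- function(m, tol = 1e-9) {
  m <- as_intensity_matrix(m)
  if (length(m) == 0) {
    abort("empty matrix.", class = "protlfq_data_error")
  }
  complete <- stats::complete.cases(m)
  sorted <- apply(m[complete, , drop = FALSE], 2, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = 1)
  disc <- if (ncol(m) < 2 || nrow(sorted) == 0) {
    0
  } else {
    max(abs(sorted - sorted[, 1]))
  }
  list(ok = disc <= tol, max_discrepancy = disc)
}

#' Log2-transform and quantile-normalize a long peptide table
#'
#' Tidy wrapper around [log2_transform()] and [quantile_normalize()] for the
#' long peptide tables the rest of the pipeline exchanges: pivots to a
#' feature x injection matrix, normalizes, and pivots back.
#'
#' @param peptides Long peptide tibble with columns `protein`, `peptide`,
#'   `injection`, `intensity` (raw scale) plus design columns.
#' @param quantile Apply quantile normalization after the log2 transform.
#'   Disabling it is useful when injections are known to share a scale
#'   already (e.g. noise-free validation data, where forcing identical
#'   column distributions would distort true group effects).
#' @return The same tibble with `intensity` replaced by normalized log2
#'   values (column renamed `log2_intensity`), attribute `intensity_scale`
#'   set to `"log2qn"`.
#' @export
normalize_peptide_table <- function(peptides, quantile = TRUE) {
  wide <- peptides |>
    dplyr::distinct(.data$protein, .data$peptide, .data$injection, .data$intensity) |>
    tidyr::pivot_wider(
      id_cols = c("protein", "peptide"),
      names_from = "injection", values_from = "intensity",
      values_fn = mean
    )
  m <- as.matrix(wide[, -(1:2)])
  norm <- log2_transform(m)
  if (quantile) {
    norm <- quantile_normalize(norm)
  } else {
    norm <- set_scale(norm, "log2qn")
  }
  long <- wide |>
    dplyr::select("protein", "peptide") |>
    dplyr::bind_cols(tibble::as_tibble(norm)) |>
    tidyr::pivot_longer(-c("protein", "peptide"),
      names_to = "injection", values_to = "log2_intensity",
      values_drop_na = TRUE
    )
  out <- peptides |>
    dplyr::distinct(
      .data$protein, .data$peptide, .data$confidence, .data$injection,
      .data$sample, .data$group, .data$replicate
    ) |>
    dplyr::inner_join(long, by = c("protein", "peptide", "injection"))
  attr(out, "intensity_scale") <- "log2qn"
  out
}
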
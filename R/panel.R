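# Two-class Fisher linear discriminant with ridge-regularized pooled
# covariance, and greedy forward panel selection under leave-one-out error.

panel_matrix <- function(x, labels) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    abort("missing cells in the intensity matrix.", class = "protlfq_data_error")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(x) || length(unique(labels)) != 2) {
    abort("labels must give exactly two classes, one per row of x.",
      class = "protlfq_data_error"
    )
  }
  list(x = x, labels = labels)
}

#' Fit a two-class linear discriminant on a fixed protein set
#'
#' Fisher discriminant: the weight vector is
#' `solve(S_pooled + lambda I) %*% (mean_case - mean_control)` with ridge
#' term `lambda = ridge * trace(S)/p`, needed because candidate sets can be
#' as large as the sample count (singular pooled covariance). Samples are
#' scored by `x %*% w`; the decision threshold sits at the midpoint of the
#' projected class means, shifted by the class-size prior odds (priors
#' proportional to class sizes). Scores at the threshold classify as the
#' second (alphabetically later) class, so ties break toward "control" for
#' case/control labels.
#'
#' @param x Samples x proteins matrix (or data frame) of log2 intensities.
#' @param labels Two-level class vector, one per row; the alphabetically
#'   first level ("case") is the positive class.
#' @param ridge Relative ridge coefficient; 0 disables regularization, in
#'   which case a singular covariance is an error.
#' @return Object of class `panel_model`: proteins, weights, threshold,
#'   per-sample scores and labels, training misclassification count and the
#'   leave-one-out misclassification count.
#' @export
fit_lda <- function(x, labels, ridge = 1e-3) {
  pm <- panel_matrix(x, labels)
  x <- pm$x
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  labels <- pm$labels
  classes <- sort(unique(labels)) # positive class first ("case" < "control")
  pos <- classes[1]
  neg <- classes[2]

  w <- lda_weights(x, labels, pos, neg, ridge)
  scores <- drop(x %*% w)
  thr <- lda_threshold(scores, labels, pos, neg)
  predicted <- ifelse(scores > thr, pos, neg)

  loo <- loo_misclassifications(x, labels, pos, neg, ridge)

  structure(
    list(
      proteins = colnames(x),
      weights = setNames(drop(w), colnames(x)),
      threshold = thr,
      scores = scores,
      labels = labels,
      classes = c(positive = pos, negative = neg),
      train_errors = sum(predicted != labels),
      loo_errors = loo,
      ridge = ridge
    ),
    class = "panel_model"
  )
}

lda_weights <- function(x, labels, pos, neg, ridge) {
  xa <- x[labels == pos, , drop = FALSE]
  xb <- x[labels == neg, , drop = FALSE]
  mu_d <- colMeans(xa) - colMeans(xb)
  ca <- stats::cov(xa) * (nrow(xa) - 1)
  cb <- stats::cov(xb) * (nrow(xb) - 1)
  sp <- (ca + cb) / (nrow(x) - 2)
  p <- ncol(x)
  if (ridge > 0) {
    sp <- sp + diag(ridge * sum(diag(sp)) / p, p)
  }
  w <- tryCatch(
    solve(sp, mu_d),
    error = function(e) {
      abort(
        "singular pooled covariance: refit with a positive `ridge`.",
        class = "protlfq_singular_covariance"
      )
    }
  )
  matrix(w, ncol = 1)
}

lda_threshold <- function(scores, labels, pos, neg) {
  m_pos <- mean(scores[labels == pos])
  m_neg <- mean(scores[labels == neg])
  mid <- (m_pos + m_neg) / 2
  n_pos <- sum(labels == pos)
  n_neg <- sum(labels == neg)
  if (m_pos == m_neg) {
    return(mid)
  }
  # pooled projected variance; prior odds shift of the Gaussian boundary
  v <- (sum((scores[labels == pos] - m_pos)^2) +
    sum((scores[labels == neg] - m_neg)^2)) / (length(scores) - 2)
  mid - v * log(n_pos / n_neg) / (m_pos - m_neg)
}

loo_misclassifications <- function(x, labels, pos, neg, ridge) {
  errs <- 0L
  for (i in seq_len(nrow(x))) {
    xt <- x[-i, , drop = FALSE]
    lt <- labels[-i]
    if (length(unique(lt)) < 2 || min(table(lt)) < 2) {
      return(NA_integer_)
    }
    w <- lda_weights(xt, lt, pos, neg, ridge)
    sc <- drop(xt %*% w)
    thr <- lda_threshold(sc, lt, pos, neg)
    pred <- if (drop(x[i, , drop = FALSE] %*% w) > thr) pos else neg
    if (pred != labels[i]) errs <- errs + 1L
  }
  errs
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf(
    "<panel_model> %d protein(s): %s\n  LOO misclassifications: %s of %d samples\n",
    length(x$proteins), paste(x$proteins, collapse = ", "),
    format(x$loo_errors), length(x$scores)
  ))
  invisible(x)
}

#' @export
tidy.panel_model <- function(x, ...) {
  tibble::tibble(protein = x$proteins, weight = unname(x$weights))
}

#' @export
glance.panel_model <- function(x, ...) {
  tibble::tibble(
    n_proteins = length(x$proteins),
    n_samples = length(x$scores),
    threshold = x$threshold,
    train_errors = x$train_errors,
    loo_errors = x$loo_errors,
    margin = panel_margin(x)
  )
}

panel_margin <- function(model) {
  pos <- model$classes["positive"]
  abs(mean(model$scores[model$labels == pos]) -
    mean(model$scores[model$labels != pos])) /
    max(stats::sd(model$scores), .Machine$double.eps)
}

#' Greedy forward selection of a minimal discriminating panel
#'
#' Starting from the empty panel, repeatedly adds the candidate protein that
#' most reduces the leave-one-out misclassification count of the refitted
#' discriminant; stops when the error reaches zero or no addition improves
#' it. Among additions with equal error, the larger projected class margin
#' wins, then lexicographically smaller accession; preferring the smallest
#' panel with the best discrimination. Deterministic given the data.
#'
#' @param x Samples x candidate-proteins matrix of log2 intensities
#'   (columns named by accession).
#' @param labels Two-level class vector.
#' @param ridge Passed to [fit_lda()].
#' @param max_size Optional cap on panel size; default all candidates.
#' @return A `panel_model` for the selected set. If the final model still
#'   misclassifies under leave-one-out, a warning reports the residual error.
#' @export
forward_select_panel <- function(x, labels, ridge = 1e-3, max_size = ncol(x)) {
  pm <- panel_matrix(x, labels)
  x <- pm$x
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  candidates <- sort(colnames(x))

  selected <- character()
  best_model <- NULL
  best_err <- Inf

  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0 || length(selected) >= max_size) break
    trial <- purrr::map(pool, function(p) {
      fit_lda(x[, c(selected, p), drop = FALSE], pm$labels, ridge = ridge)
    })
    err <- purrr::map_dbl(trial, function(m) {
      if (is.na(m$loo_errors)) Inf else m$loo_errors
    })
    marg <- purrr::map_dbl(trial, panel_margin)
    ord <- order(err, -marg, pool)
    cand_best <- ord[1]
    if (err[cand_best] >= best_err) break
    selected <- c(selected, pool[cand_best])
    best_model <- trial[[cand_best]]
    best_err <- err[cand_best]
    if (best_err == 0) break
  }

  if (is.null(best_model)) {
    # no addition beat the empty panel; report the best single protein
    best_model <- fit_lda(x[, candidates[1], drop = FALSE], pm$labels, ridge)
  }
  if (!is.na(best_model$loo_errors) && best_model$loo_errors > 0) {
    warn(sprintf(
      "selected panel still misclassifies %d sample(s) under leave-one-out.",
      best_model$loo_errors
    ))
  }
  best_model
}

#' Classify a new sample with a fitted panel
#'
#' @param model A `panel_model`.
#' @param x Named numeric vector covering the panel's proteins (log2
#'   intensities).
#' @return List with `label` and `score`. A score exactly at the threshold
#'   classifies as the negative class ("control").
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "panel_model"))
  missing <- setdiff(model$proteins, names(x))
  if (length(missing) > 0) {
    abort(
      sprintf("sample lacks panel protein(s): %s", paste(missing, collapse = ", ")),
      class = "protlfq_data_error"
    )
  }
  score <- sum(x[model$proteins] * model$weights[model$proteins])
  label <- if (score > model$threshold) {
    unname(model$classes["positive"])
  } else {
    unname(model$classes["negative"])
  }
  list(label = label, score = unname(score))
}
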
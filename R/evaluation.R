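#' Q16 accuracy of a predicted PB sequence
#'
#' Percentage of residues whose predicted PB (out of 16) matches the
#' structure-derived PB. Positions that are `Z` in either sequence (termini,
#' unassignable windows, no-hit predictions) are excluded from numerator and
#' denominator; `n_total` variants counting no-prediction positions as errors
#' are available from [evaluate_prediction()].
#'
#' @param true_pb,pred_pb PB sequence strings of equal length.
#' @return Percentage in `[0, 100]` (`NaN` when no position is jointly
#'   defined).
#' @export
q16_accuracy <- function(true_pb, pred_pb) {
  al <- aligned_letters(true_pb, pred_pb)
  100 * mean(al$true == al$pred)
}

aligned_letters <- function(true_pb, pred_pb) {
  t <- pb_letters(true_pb)
  p <- pb_letters(pred_pb)
  if (length(t) != length(p)) {
    stop("true and predicted PB sequences differ in length")
  }
  keep <- t != "Z" & p != "Z"
  list(true = t[keep], pred = p[keep], n_excluded = sum(!keep))
}

#' Confusion matrix between true and predicted PB sequences
#'
#' @inheritParams q16_accuracy
#' @return A `pb_confusion`: 16 x 16 integer matrix (rows = true PB,
#'   columns = predicted PB) with attribute `n_excluded` (positions with `Z`
#'   in either sequence).
#' @export
pb_confusion <- function(true_pb, pred_pb) {
  al <- aligned_letters(true_pb, pred_pb)
  lv <- letters[1:16]
  m <- table(factor(al$true, levels = lv), factor(al$pred, levels = lv))
  m <- matrix(as.integer(m), 16L, 16L, dimnames = list(true = lv, pred = lv))
  structure(m, n_excluded = al$n_excluded, class = c("pb_confusion", "matrix"))
}

#' Per-PB one-vs-rest statistics from a confusion matrix
#'
#' Binarizes each PB against the other fifteen and reports accuracy (per-PB
#' recall: fraction of true occurrences predicted correctly), sensitivity,
#' specificity and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the convention that a zero denominator gives MCC 0. Specificity is
#' high almost by construction (a binary test against 15 negative classes);
#' sensitivity is the discriminating figure.
#'
#' @param cm A `pb_confusion` (or 16 x 16 count matrix, rows = true).
#' @return A tibble with one row per PB: `pb`, `n_true`, `frequency`,
#'   `accuracy`, `sensitivity`, `specificity`, `mcc`.
#' @export
per_pb_stats <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), all(dim(cm) == 16L))
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  purrr::map_dfr(seq_len(16L), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    tibble::tibble(
      pb = letters[i],
      n_true = tp + fn,
      frequency = (tp + fn) / total,
      accuracy = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    )
  })
}

#' Relaxed-equivalence accuracy
#'
#' Q16 with selected PB letters treated as interchangeable: a position counts
#' as correct when the true and predicted letters are equal or co-members of
#' an equivalence set. The default set `{c, d}` reflects the one well-known
#' confusion between two structurally adjacent extended-region PBs; further
#' sets (e.g. from a PB substitution matrix) can be supplied.
#'
#' @inheritParams q16_accuracy
#' @param equivalence_sets List of character vectors of PB letters.
#'   Overlapping sets are merged (with a warning).
#' @return Percentage in `[0, 100]`; always at least [q16_accuracy()].
#' @export
relaxed_accuracy <- function(true_pb, pred_pb,
                             equivalence_sets = list(c("c", "d"))) {
  al <- aligned_letters(true_pb, pred_pb)
  sets <- merge_overlapping_sets(equivalence_sets)
  class_of <- stats::setNames(letters[1:16], letters[1:16])
  for (s in sets) class_of[s] <- min(s)
  100 * mean(class_of[al$true] == class_of[al$pred])
}

merge_overlapping_sets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  merged <- list()
  for (s in sets) {
    hit <- which(vapply(merged, function(m) length(intersect(m, s)) > 0L,
                        logical(1)))
    if (length(hit) > 0L) {
      warning("overlapping equivalence sets merged")
      joined <- sort(unique(c(s, unlist(merged[hit]))))
      merged <- c(merged[-hit], list(joined))
    } else {
      merged <- c(merged, list(sort(unique(s))))
    }
  }
  merged
}

#' Candidate-list coverage of the true PB sequence
#'
#' Fraction of jointly defined positions at which the true PB appears in the
#' window's candidate list (regardless of what was eventually chosen). This
#' is the ceiling of any prediction built from the same profiles, so coverage
#' is always at least the Q16 of such a prediction.
#'
#' @param true_pb True PB sequence string.
#' @param profiles Output of [collect_profiles()] for the same query.
#' @return Percentage in `[0, 100]`.
#' @export
candidate_coverage <- function(true_pb, profiles) {
  t <- pb_letters(true_pb)
  pos <- profiles$position + 2L
  stopifnot(max(pos) <= length(t))
  truth <- t[pos]
  keep <- truth != "Z"
  hit <- purrr::map2_lgl(profiles$profile[keep], truth[keep],
                         ~ .y %in% .x$pb)
  100 * mean(hit)
}

#' Evaluate a prediction against the structure-derived PB sequence
#'
#' Bundles the evaluation battery: Q16 (both denominators), relaxed
#' accuracy, confusion matrix and per-PB one-vs-rest statistics.
#'
#' @param true_pb True PB sequence string.
#' @param prediction A `pb_prediction` (or a predicted PB string).
#' @param equivalence_sets Passed to [relaxed_accuracy()].
#' @return A list of class `pb_evaluation`: `summary` (one-row tibble with
#'   `q16`, `q16_strict_denominator`, `relaxed`, `n_positions`,
#'   `n_excluded`), `per_pb` (tibble from [per_pb_stats()]), `confusion`.
#' @export
evaluate_prediction <- function(true_pb, prediction,
                                equivalence_sets = list(c("c", "d"))) {
  pred_pb <- if (inherits(prediction, "pb_prediction")) prediction$pb else {
    prediction
  }
  t <- pb_letters(true_pb)
  p <- pb_letters(pred_pb)
  if (length(t) != length(p)) stop("sequence length mismatch")
  joint <- t != "Z" & p != "Z"
  n_true_def <- sum(t != "Z")
  cm <- pb_confusion(true_pb, pred_pb)
  matches <- sum(t[joint] == p[joint])
  summary <- tibble::tibble(
    q16 = 100 * matches / sum(joint),
    # counting positions with a true PB but no prediction as errors:
    q16_strict_denominator = 100 * matches / n_true_def,
    relaxed = relaxed_accuracy(true_pb, pred_pb, equivalence_sets),
    n_positions = sum(joint),
    n_excluded = attr(cm, "n_excluded")
  )
  structure(list(summary = summary, per_pb = per_pb_stats(cm),
                 confusion = cm),
            class = "pb_evaluation")
}

#' @export
print.pb_evaluation <- function(x, ...) {
  cat("PB prediction evaluation\n")
  cat(sprintf("  Q16: %.1f%%  (strict denominator: %.1f%%)  relaxed: %.1f%%\n",
              x$summary$q16, x$summary$q16_strict_denominator,
              x$summary$relaxed))
  cat("  positions scored:", x$summary$n_positions, "\n")
  invisible(x)
}

#' @export
tidy.pb_evaluation <- function(x, ...) x$per_pb

#' @export
glance.pb_evaluation <- function(x, ...) x$summary

#' Tidy a PB confusion matrix
#'
#' @param x A `pb_confusion`.
#' @param ... Unused.
#' @return A tibble with columns `true`, `pred`, `n`.
#' @export
tidy.pb_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    true = rep(rownames(m), times = 16L),
    pred = rep(colnames(m), each = 16L),
    n = as.integer(m[cbind(rep(1:16, times = 16L), rep(1:16, each = 16L))])
  )
}

#' Heatmap of a PB confusion matrix
#'
#' @param object A `pb_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pb_confusion <- function(object, ...) {
  d <- tidy.pb_confusion(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$true,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(letters[1:16])) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted PB", y = "true PB", fill = "count") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-PB prediction statistics
#'
#' @param evaluation A `pb_evaluation`.
#' @param metric Column of the per-PB table to display.
#' @return A ggplot object.
#' @export
plot_per_pb <- function(evaluation, metric = "mcc") {
  d <- evaluation$per_pb
  stopifnot(metric %in% names(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pb, y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Protein Block", y = metric) +
    ggplot2::theme_minimal()
}
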
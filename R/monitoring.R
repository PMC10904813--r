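# Performance monitoring: the baseline against which data-based drift
# detection is compared. Per-class and macro discrimination/calibration
# metrics with a class-exclusion rule for degenerate classes.

#' Rank-based AUROC with midrank tie handling
#'
#' @param gold binary vector.
#' @param prob numeric score vector.
#' @return AUROC, or `NA` if `gold` is single-class.
#' @export
auroc <- function(gold, prob) {
  n_pos <- sum(gold == 1)
  n_neg <- sum(gold == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[gold == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Class exclusion rule for degenerate classes
#'
#' A class is excluded from macro aggregation when its gold column has fewer
#' than `min_count` positives or negatives, or when the thresholded
#' predictions are single-class (not enough predicted positive or negative
#' instances to support the threshold metrics).
#'
#' @param gold binary gold vector for one class.
#' @param pred binarized prediction vector for the class.
#' @param min_count minimum count of each class required (default 1).
#' @return `TRUE` if the class should be excluded.
#' @export
class_exclusion <- function(gold, pred, min_count = 1L) {
  sum(gold == 1) < min_count || sum(gold == 0) < min_count ||
    sum(pred == 1) < min_count || sum(pred == 0) < min_count
}

#' Multi-label performance report
#'
#' Computes per-class AUROC (rank-based, midrank ties), precision, recall,
#' F1 at the binarization threshold, and Brier score (mean squared error of
#' the probabilities), plus unweighted macro averages over the non-excluded
#' classes.
#'
#' @param gold `n x L` binary matrix.
#' @param probs `n x L` probability matrix in `[0, 1]`.
#' @param threshold binarization threshold for precision/recall/F1.
#' @param min_count passed to [class_exclusion()].
#' @return a `performance_report`: list with `per_class` (data frame) and
#'   `macro` (named vector), plus the threshold used.
#' @export
compute_metrics <- function(gold, probs, threshold = 0.5, min_count = 1L) {
  gold <- as.matrix(gold); probs <- as.matrix(probs)
  stopifnot(all(dim(gold) == dim(probs)), all(probs >= 0 & probs <= 1))
  L <- ncol(gold)
  cls <- colnames(gold)
  if (is.null(cls)) cls <- sprintf("class_%02d", seq_len(L))
  per <- lapply(seq_len(L), function(j) {
    g <- gold[, j]; p <- probs[, j]
    pred <- as.integer(p >= threshold)
    tp <- sum(pred == 1 & g == 1)
    fp <- sum(pred == 1 & g == 0)
    fn <- sum(pred == 0 & g == 1)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else if (!is.na(precision) && !is.na(recall)) 0 else NA_real_
    data.frame(class = cls[j],
               auroc = auroc(g, p),
               f1 = f1, precision = precision, recall = recall,
               brier = mean((p - g)^2),
               n_pos = sum(g == 1), n_neg = sum(g == 0),
               excluded = class_exclusion(g, pred, min_count),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  inc <- !per$excluded
  macro <- c(auroc = mean(per$auroc[inc]), f1 = mean(per$f1[inc]),
             precision = mean(per$precision[inc]),
             recall = mean(per$recall[inc]), brier = mean(per$brier[inc]))
  structure(list(per_class = per, macro = macro, threshold = threshold),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> %d classes (%d excluded) | macro AUROC %.3f, F1 %.3f, Brier %.3f\n",
              nrow(x$per_class), sum(x$per_class$excluded),
              x$macro["auroc"], x$macro["f1"], x$macro["brier"]))
  invisible(x)
}

#' False-positive percentage of a sampled evaluation under a population mix
#'
#' Demonstrates the sampling-bias failure mode of performance monitoring:
#' per-group alert rates are taken from the observed correct/incorrect alert
#' counts, the counts are re-scaled to a specified population mix (total
#' normalized to 100 cases), and the false-positive percentage is returned
#' as `100 * sum(scaled incorrect) / sum(scaled correct)`. With fixed
#' per-group rates, a flip in the population mix changes this percentage
#' even though the sampled evaluation looks unchanged.
#'
#' @param alerts data frame with columns `group`, `correct`, `incorrect`
#'   (alert counts per group); each group needs `correct + incorrect > 0`.
#' @param population_mix named numeric vector of group fractions summing
#'   to 1.
#' @return false-positive percentage (full precision; no rounding).
#' @export
sampling_bias_fp_ratio <- function(alerts, population_mix) {
  stopifnot(all(c("group", "correct", "incorrect") %in% names(alerts)),
            abs(sum(population_mix) - 1) < 1e-9)
  tot <- alerts$correct + alerts$incorrect
  if (any(tot <= 0)) stop("each group needs correct + incorrect > 0", call. = FALSE)
  mix <- population_mix[alerts$group]
  if (any(is.na(mix))) stop("population_mix missing a group", call. = FALSE)
  scaled_correct <- 100 * mix * alerts$correct / tot
  scaled_incorrect <- 100 * mix * alerts$incorrect / tot
  if (sum(scaled_correct) == 0) {
    stop("no correct alerts after re-scaling", call. = FALSE)
  }
  100 * sum(scaled_incorrect) / sum(scaled_correct)
}
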
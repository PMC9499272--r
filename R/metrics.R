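#' Multi-label evaluation metrics
#'
#' The five set-theoretic multi-label metrics standard in therapeutic
#' peptide prediction. Writing \eqn{L_i} for the true label set of sample i
#' and \eqn{L_i^*} for the predicted set, with N samples and M labels:
#' \itemize{
#'   \item Precision: mean of \eqn{|L_i \cap L_i^*| / |L_i^*|}
#'   \item Coverage: mean of \eqn{|L_i \cap L_i^*| / |L_i|}
#'   \item Accuracy: mean of \eqn{|L_i \cap L_i^*| / |L_i \cup L_i^*|}
#'     (Jaccard index)
#'   \item Absolute true: fraction of samples with \eqn{L_i^* = L_i}
#'     exactly (the strictest metric)
#'   \item Absolute false: mean of
#'     \eqn{(|L_i \cup L_i^*| - |L_i \cap L_i^*|) / M} — the per-sample
#'     symmetric-difference size over M (lower is better)
#' }
#' Empty-set conventions: a sample whose predicted set is empty contributes
#' 0 to precision (1 if the true set is also empty); the same convention
#' applies to coverage and accuracy for empty true/union sets. On curated
#' data true sets are never empty.
#'
#' @param truth N x M binary matrix of true labels (or a list of character
#'   label sets plus `vocab`).
#' @param pred N x M binary matrix of predicted labels (same alternative).
#' @param vocab Required when `truth`/`pred` are lists of label sets.
#' @return Named numeric of class `metric_report`: `precision`, `coverage`,
#'   `accuracy`, `absolute_true`, `absolute_false`, with attribute `n`.
#' @examples
#' truth <- rbind(c(1, 1, 0), c(0, 0, 1))
#' pred  <- rbind(c(1, 0, 0), c(0, 0, 1))
#' multilabel_metrics(truth, pred)
#' @export
multilabel_metrics <- function(truth, pred, vocab = NULL) {
  if (is.list(truth) || is.list(pred)) {
    if (is.null(vocab)) stop("vocab required for label-set list input")
    truth <- sets_to_matrix(truth, vocab)
    pred <- sets_to_matrix(pred, vocab)
  }
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!all(dim(truth) == dim(pred))) stop("truth/pred shape mismatch")
  if (ncol(truth) == 0L) stop("need at least one label column")
  if (nrow(truth) == 0L) stop("need at least one sample")
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1)) {
    stop("truth and pred must be binary (apply a threshold first)")
  }
  M <- ncol(truth)
  inter <- rowSums(truth * pred)
  uni <- rowSums(pmax(truth, pred))
  nt <- rowSums(truth)
  np <- rowSums(pred)
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, 1)
  out <- c(
    precision = mean(safe_ratio(inter, np) * (np > 0 | nt == 0)),
    coverage = mean(safe_ratio(inter, nt) * (nt > 0 | np == 0)),
    accuracy = mean(safe_ratio(inter, uni)),
    absolute_true = mean(inter == uni),
    absolute_false = mean((uni - inter) / M)
  )
  structure(out, class = "metric_report", n = nrow(truth))
}

sets_to_matrix <- function(sets, vocab) {
  m <- matrix(0L, length(sets), length(vocab),
              dimnames = list(NULL, unclass(vocab)))
  for (i in seq_along(sets)) {
    j <- label_index(vocab, sets[[i]])
    m[i, j[!is.na(j)]] <- 1L
  }
  m
}

#' @export
print.metric_report <- function(x, digits = 3L, ...) {
  lab <- c("Precision ↑", "Coverage ↑", "Accuracy ↑",
           "Absolute true ↑", "Absolute false ↓")
  v <- formatC(unclass(x), digits = digits, format = "f")
  cat(sprintf("Multi-label metrics (n = %d)\n", attr(x, "n")))
  for (i in seq_along(lab)) {
    cat(sprintf("  %-17s %s\n", lab[i], v[i]))
  }
  invisible(x)
}

#' Per-class coverage (recall)
#'
#' Fraction of true occurrences of each label that were predicted —
#' coverage restricted to one label column. Useful for inspecting how a
#' model treats minority classes under imbalance.
#'
#' @inheritParams multilabel_metrics
#' @return Named numeric vector over label columns (`NaN` for classes with
#'   no true occurrences).
#' @export
per_class_coverage <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  colSums(truth * pred) / colSums(truth)
}

#' Repeated-subsample evaluation
#'
#' Evaluation protocol for comparing models on a shared test set: draw
#' `reps` random subsets of `floor(fraction * N)` test samples, compute
#' [multilabel_metrics()] on each, and report per-replicate values plus
#' their mean. Replicates drawn under the same seed are identical across
#' calls, so two models evaluated with the same seed are scored on the same
#' subsets — the pairing exploited by [compare_methods_ttest()].
#'
#' @param probs N x M probability matrix (or an already-thresholded binary
#'   matrix).
#' @param truth N x M binary truth matrix.
#' @param fraction Subsample fraction in (0, 1]; default 0.8.
#' @param reps Number of replicates; default 5.
#' @param seed Integer seed.
#' @param threshold Probability threshold (default 0.5).
#' @return List with `mean` (a `metric_report` of column means), `reps`
#'   (reps x 5 matrix of per-replicate metrics) and `indices` (list of the
#'   subsample index vectors).
#' @export
subsample_evaluate <- function(probs, truth, fraction = 0.8, reps = 5L,
                               seed = 1L, threshold = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (reps < 1L) stop("reps must be >= 1")
  n <- nrow(truth)
  k <- floor(fraction * n)
  if (k < 1L) stop("subsample size is 0; increase fraction or sample size")
  pred <- predict_labels(probs, threshold)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- lapply(seq_len(reps), function(r) sort(sample.int(n, k)))
  per <- t(vapply(idx, function(i) {
    unclass(multilabel_metrics(truth[i, , drop = FALSE],
                               pred[i, , drop = FALSE]))
  }, numeric(5)))
  m <- colMeans(per)
  list(mean = structure(m, class = "metric_report", n = k),
       reps = per, indices = idx)
}

#' Threshold probabilities into label calls
#'
#' A label is called present when its probability is at or above the
#' threshold (default 0.5). Rows may come out all-zero; downstream metrics
#' handle empty predicted sets explicitly.
#'
#' @param probs Matrix of probabilities in \[0, 1\].
#' @param threshold Scalar in \[0, 1\].
#' @return Binary matrix of the same shape.
#' @export
predict_labels <- function(probs, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  (probs >= threshold) + 0L
}

#' Compare two methods' scores with a t-test
#'
#' Two-sided t-test on per-replicate metric values from two methods,
#' paired by default (the subsample protocol scores both methods on the
#' same subsets). Significance stars follow the usual convention:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param scores_a,scores_b Numeric vectors of per-replicate scores.
#' @param paired Paired test? Default `TRUE` (requires equal lengths).
#' @return List with `t`, `p_value`, `stars`.
#' @export
compare_methods_ttest <- function(scores_a, scores_b, paired = TRUE) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("need at least 2 observations per method")
  }
  if (paired && length(scores_a) != length(scores_b)) {
    stop("paired comparison requires equal-length score vectors")
  }
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    return(list(t = 0, p_value = 1, stars = ""))
  }
  res <- tryCatch(
    stats::t.test(scores_a, scores_b, paired = paired),
    error = function(e) {
      stop("degenerate comparison: ", conditionMessage(e), call. = FALSE)
    })
  list(t = unname(res$statistic), p_value = res$p.value,
       stars = significance_stars(res$p.value))
}

#' @rdname compare_methods_ttest
#' @param p A p-value.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("")
  cuts <- c(1e-4, 1e-3, 1e-2, 5e-2)
  strrep("*", sum(p < cuts))
}
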
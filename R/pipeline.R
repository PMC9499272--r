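#' Train an ensemble of independently initialized models
#'
#' Trains `n_models` copies of the same configuration that differ only in
#' their random seed (initialization, shuffling, dropout), to average out
#' initialization noise. Prediction averages the per-model probability
#' matrices; thresholding is applied after averaging.
#'
#' @inheritParams mfpnet
#' @param n_models Number of ensemble members (default 10).
#' @param seeds Integer vector of member seeds (default `seed + 0:(n-1)`).
#' @param ... Further arguments passed to [mfpnet()].
#' @return An object of class `mfpnet_ensemble` (list of fits).
#' @export
train_ensemble <- function(records, vocab, config = NULL, n_models = 10L,
                           seed = 1L, seeds = seed + seq_len(n_models) - 1L,
                           ...) {
  fits <- lapply(seeds, function(s) {
    mfpnet(records, vocab, config = config, seed = s, ...)
  })
  structure(list(fits = fits, vocab = vocab, seeds = seeds),
            class = "mfpnet_ensemble")
}

#' @export
print.mfpnet_ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$fits), "mfpnet models (seeds:",
      paste(x$seeds, collapse = ", "), ")\n")
  invisible(x)
}

#' @rdname train_ensemble
#' @param object A fitted `mfpnet_ensemble`.
#' @inheritParams predict.mfpnet
#' @export
predict.mfpnet_ensemble <- function(object, newdata,
                                    type = c("prob", "label"),
                                    threshold = 0.5, ...) {
  type <- match.arg(type)
  vocabs <- lapply(object$fits, function(f) unclass(f$vocab))
  if (!all(vapply(vocabs, identical, TRUE, vocabs[[1]]))) {
    stop("ensemble members have mismatched vocabularies")
  }
  probs <- Reduce(`+`, lapply(object$fits, predict, newdata = newdata,
                              type = "prob", ...)) / length(object$fits)
  if (type == "label") predict_labels(probs, threshold) else probs
}

#' Grid-search hyperparameters with k-fold cross-validation
#'
#' Evaluates every grid point by k-fold cross-validation on the training
#' records: for each fold, a model is fitted on the remaining folds and
#' scored with [multilabel_metrics()] on the held-out fold. Grid points are
#' ranked by mean CV accuracy (Jaccard), with absolute true as tie-breaker —
#' the two metrics most informative for multi-label selection. Class weights
#' inside each fold are computed from that fold's training portion only; a
#' fold whose training portion misses a class entirely is kept with a
#' warning.
#'
#' @param records Training [peptide_set()].
#' @param vocab A [label_vocab()].
#' @param grid A list of named lists; each element is a set of [mfpnet()] /
#'   [model_config()] overrides (e.g. `list(lr = 1e-2, hidden = 32)`).
#'   Recognized config names go to [model_config()], the rest to
#'   [mfpnet()].
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment and fold-level fits.
#' @param metric Selection metric: `"accuracy"` (default) or
#'   `"absolute_true"`.
#' @param ... Common [mfpnet()] arguments applied to every grid point.
#' @return List of class `grid_search` with `best` (the winning override
#'   list), `table` (data frame: one row per grid point with mean CV
#'   accuracy and absolute true), and `fold_reports` (per-point list of
#'   per-fold `metric_report`s).
#' @export
grid_search_cv <- function(records, vocab, grid, folds = 5L, seed = 1L,
                           metric = c("accuracy", "absolute_true"), ...) {
  metric <- match.arg(metric)
  if (!length(grid)) stop("grid must contain at least one point")
  if (folds < 2L) stop("folds must be >= 2")
  n <- nrow(records)
  old <- local_seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  restore_seed(old)
  common <- list(...)
  cfg_names <- setdiff(names(formals(model_config)), c("n_labels", "variant"))

  fold_reports <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    over <- utils::modifyList(common, as.list(grid[[gi]]))
    cfg_over <- over[intersect(names(over), cfg_names)]
    fit_over <- over[setdiff(names(over), cfg_names)]
    cfg <- do.call(model_config,
                   c(list(n_labels = length(vocab)), cfg_over))
    reports <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- records[fold_id != f, ]
      te <- records[fold_id == f, ]
      fit <- do.call(mfpnet, c(list(records = tr, vocab = vocab,
                                    config = cfg, seed = seed + f),
                               fit_over))
      pred <- predict(fit, te, type = "label")
      truth <- encode_peptides(te, vocab, L = cfg$L)$labels
      reports[[f]] <- multilabel_metrics(truth, pred)
    }
    per <- t(vapply(reports, unclass, numeric(5)))
    rows[[gi]] <- data.frame(
      point = gi,
      label = paste(names(grid[[gi]]),
                    vapply(grid[[gi]], function(v) paste(v, collapse = "/"),
                           ""),
                    sep = "=", collapse = " "),
      accuracy = mean(per[, "accuracy"]),
      absolute_true = mean(per[, "absolute_true"]))
    fold_reports[[gi]] <- reports
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab[[metric]],
               -tab[[setdiff(c("accuracy", "absolute_true"), metric)]])
  best_i <- tab$point[ord[1]]
  structure(list(best = grid[[best_i]], best_index = best_i, table = tab,
                 fold_reports = fold_reports, metric = metric),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat("Grid search (", nrow(x$table), " points, selection by ", x$metric,
      ")\n", sep = "")
  tab <- x$table
  tab$accuracy <- round(tab$accuracy, 4)
  tab$absolute_true <- round(tab$absolute_true, 4)
  print(tab, row.names = FALSE)
  cat("Best: point", x$best_index, "\n")
  invisible(x)
}

#' Ablation study over network components
#'
#' Trains the full model and the requested single-component ablations under
#' identical data, configuration and seed, evaluates each with the
#' repeated-subsample protocol on the same test subsets, and reports a
#' paired t-test of each variant against the full model on per-replicate
#' accuracy, with significance stars.
#'
#' Variants: `"no_cnn"`, `"no_bilstm"`, `"no_mhsa"` remove one stage from
#' the forward path; `"no_cw"` keeps the full architecture but trains with
#' uniform (all-ones) class weights.
#'
#' @param train,test [peptide_set()]s (curated).
#' @param vocab A [label_vocab()].
#' @param variants Character subset of
#'   `c("no_cnn", "no_bilstm", "no_mhsa", "no_cw")`.
#' @param config A [model_config()] for the full model; ablated configs are
#'   derived from it.
#' @param seed Shared training seed.
#' @param fraction,reps Subsample protocol (defaults 0.8 and 5).
#' @param ... Further [mfpnet()] arguments shared by every variant.
#' @return List of class `ablation`: `table` (one row per model: the five
#'   metrics, accuracy t-test vs full, stars), `reports` (per-model
#'   subsample results), `fits`.
#' @export
run_ablation <- function(train, test, vocab,
                         variants = c("no_cnn", "no_bilstm", "no_mhsa",
                                      "no_cw"),
                         config = NULL, seed = 1L, fraction = 0.8,
                         reps = 5L, ...) {
  known <- c("no_cnn", "no_bilstm", "no_mhsa", "no_cw")
  bad <- setdiff(variants, known)
  if (length(bad)) {
    stop("unknown variant(s): ", paste(bad, collapse = ", "),
         "; choose from ", paste(known, collapse = ", "))
  }
  if (is.null(config)) config <- model_config(n_labels = length(vocab))
  models <- c("full", variants)
  truth <- encode_peptides(test, vocab, L = config$L)$labels
  fits <- list(); reports <- list()
  for (m in models) {
    cfg <- config
    scheme <- "cw"
    if (m %in% c("no_cnn", "no_bilstm", "no_mhsa")) {
      args <- unclass(config)
      keep <- setdiff(intersect(names(args), names(formals(model_config))),
                      "variant")
      cfg <- do.call(model_config, c(args[keep], list(variant = m)))
    } else if (m == "no_cw") {
      scheme <- "uniform"
    }
    fits[[m]] <- mfpnet(train, vocab, config = cfg, weight_scheme = scheme,
                        seed = seed, ...)
    probs <- predict(fits[[m]], test, type = "prob")
    reports[[m]] <- subsample_evaluate(probs, truth, fraction = fraction,
                                       reps = reps, seed = seed)
  }
  tab <- do.call(rbind, lapply(models, function(m) {
    r <- reports[[m]]
    row <- as.data.frame(as.list(unclass(r$mean)))
    row <- cbind(model = m, row)
    if (m == "full" || reps < 2L) {
      row$p_accuracy <- NA_real_; row$stars <- ""
    } else {
      tt <- compare_methods_ttest(reports[["full"]]$reps[, "accuracy"],
                                  r$reps[, "accuracy"], paired = TRUE)
      row$p_accuracy <- tt$p_value; row$stars <- tt$stars
    }
    row
  }))
  structure(list(table = tab, reports = reports, fits = fits),
            class = "ablation")
}

#' @export
print.ablation <- function(x, digits = 3L, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
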
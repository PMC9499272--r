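#' Fit a multi-label peptide function classifier
#'
#' Trains the attention network described in [model_config()] on a curated
#' multi-label peptide set, minimizing a class-weighted binary cross-entropy
#' with mini-batch Adam. The class weights are computed from the training
#' split only, by default with the logarithmic scheme of [cw_weights()],
#' which up-weights rare function classes to counter label imbalance.
#'
#' Training is deterministic given `seed`: parameter initialization, batch
#' shuffling and dropout all draw from a seeded generator, so two fits with
#' identical inputs and seed produce identical parameters.
#'
#' @param records A curated [peptide_set()] (training split).
#' @param vocab A [label_vocab()] fixing the output label order.
#' @param config A [model_config()]; default builds one for
#'   `length(vocab)` labels with package defaults.
#' @param weight_scheme `"cw"` (default), `"uniform"` or
#'   `"inverse_frequency"` — see [cw_weights()] and [baseline_weights()].
#' @param weight_mode How the class weights enter the loss (see
#'   [weighted_bce()]): `"positive"` (default) up-weights the label-present
#'   terms of rare classes, which raises their operating probability and
#'   hence minority recall; `"both"` scales whole label columns.
#' @param phi,theta,log_base Passed to [cw_weights()] when
#'   `weight_scheme = "cw"`.
#' @param epochs Training epochs (default 60).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param verbose Print a loss line every 10 epochs?
#' @return An object of class `mfpnet`: list with `params`, `config`,
#'   `vocab`, `class_weights`, `weight_scheme`, `loss` (per-epoch mean
#'   training loss), `counts` (training label counts), `seed`, `call`.
#' @seealso [predict.mfpnet()], [train_ensemble()], [grid_search_cv()],
#'   [run_ablation()]
#' @examples
#' ds <- generate_peptides(synth_spec(c(A = 30, B = 30), seed = 7))
#' cfg <- model_config(n_labels = 2, L = 30, embed_dim = 8, filters = 4,
#'                     hidden = 8, heads = 2, d_k = 4, dropout = 0)
#' fit <- mfpnet(ds$records, ds$vocab, cfg, epochs = 2, seed = 1)
#' predict(fit, ds$records[1:3, ])
#' @export
mfpnet <- function(records, vocab, config = NULL,
                   weight_scheme = c("cw", "uniform", "inverse_frequency"),
                   weight_mode = c("positive", "both"),
                   phi = 1, theta = NULL, log_base = 10,
                   epochs = 60L, batch_size = 64L, lr = 1e-3,
                   seed = 1L, verbose = FALSE) {
  weight_scheme <- match.arg(weight_scheme)
  weight_mode <- match.arg(weight_mode)
  if (epochs < 0L) stop("epochs must be >= 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (is.null(config)) config <- model_config(n_labels = length(vocab))
  if (config$n_labels != length(vocab)) {
    stop("config$n_labels (", config$n_labels,
         ") does not match vocabulary size (", length(vocab), ")")
  }
  enc <- encode_peptides(records, vocab, L = config$L)
  n <- nrow(enc$tokens)
  counts <- colSums(enc$labels)
  w <- training_class_weights(counts, n, weight_scheme, phi, theta, log_base)

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  params <- init_params(config, seed = stats::runif(1, 1, 2^30))
  opt <- adam_init(params)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    bl <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      tok <- enc$tokens[idx, , drop = FALSE]
      y <- enc$labels[idx, , drop = FALSE]
      fwd <- nn_forward(params, tok, config, train = TRUE)
      loss <- weighted_bce(fwd$probs, y, w, mode = weight_mode)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep,
             "; try a lower learning rate, or check for all-zero class ",
             "weights")
      }
      dLogits <- if (weight_mode == "both") {
        sweep(fwd$probs - y, 2L, w, `*`) / length(y)
      } else {
        (sweep(y * (fwd$probs - 1), 2L, w, `*`) +
           (1 - y) * fwd$probs) / length(y)
      }
      grads <- nn_backward(params, fwd$cache, dLogits, config)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params; opt <- upd$opt
      bl <- bl + loss; nb <- nb + 1L
    }
    losses[ep] <- bl / nb
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("epoch %3d  loss %.5f", ep, losses[ep]))
    }
  }
  structure(list(params = params, config = config, vocab = vocab,
                 class_weights = w, weight_scheme = weight_scheme,
                 weight_mode = weight_mode, loss = losses, counts = counts,
                 seed = seed, n_train = n, call = match.call()),
            class = "mfpnet")
}

# class weights from training counts only; classes absent from the training
# split get weight 0 (they have no positive loss term anyway)
training_class_weights <- function(counts, n, scheme, phi, theta, log_base) {
  present <- counts > 0
  if (!all(present)) {
    warning("class(es) with no training instances: ",
            paste(names(counts)[!present], collapse = ", "),
            "; their loss weight is set to 0")
  }
  w <- numeric(length(counts))
  names(w) <- names(counts)
  if (any(present)) {
    wp <- switch(scheme,
      cw = cw_weights(counts[present], n, phi = phi, theta = theta,
                      base = log_base),
      uniform = baseline_weights(counts[present], n, "uniform"),
      inverse_frequency = baseline_weights(counts[present], n,
                                           "inverse_frequency"))
    w[present] <- wp
    for (a in c("phi", "theta", "base")) attr(w, a) <- attr(wp, a)
  }
  w
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zero, v = zero, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Predict peptide function probabilities or labels
#'
#' Runs the forward pass of a fitted [mfpnet()] model (dropout disabled) on
#' new peptides and returns either per-label probabilities or thresholded
#' binary calls (a label is called at probability >= `threshold`).
#'
#' @param object A fitted `mfpnet`.
#' @param newdata A [peptide_set()] or an encoded token matrix.
#' @param type `"prob"` (default) or `"label"`.
#' @param threshold Decision threshold for `type = "label"` (default 0.5).
#' @param batch_size Forward-pass chunk size (default 256).
#' @param ... Unused.
#' @return N x M matrix of probabilities or 0/1 calls, columns named by the
#'   vocabulary.
#' @export
predict.mfpnet <- function(object, newdata, type = c("prob", "label"),
                           threshold = 0.5, batch_size = 256L, ...) {
  type <- match.arg(type)
  tokens <- if (inherits(newdata, "peptide_set")) {
    encode_peptides(newdata, object$vocab, L = object$config$L)$tokens
  } else {
    as.matrix(newdata)
  }
  n <- nrow(tokens)
  probs <- matrix(0, n, object$config$n_labels,
                  dimnames = list(NULL, unclass(object$vocab)))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[idx, ] <- nn_forward(object$params,
                               tokens[idx, , drop = FALSE],
                               object$config, train = FALSE)$probs
  }
  if (type == "label") predict_labels(probs, threshold) else probs
}

#' @export
print.mfpnet <- function(x, ...) {
  cat("Multi-label peptide function classifier (mfpnet)\n")
  cat(sprintf("  %d training peptides, %d classes, variant '%s'\n",
              x$n_train, length(x$vocab), x$config$variant))
  cat(sprintf("  weight scheme: %s [%s mode]", x$weight_scheme,
              x$weight_mode %||% "positive"))
  if (x$weight_scheme == "cw") {
    cat(sprintf(" (phi = %g, theta = %.3f, log base %g)",
                attr(x$class_weights, "phi") %||% 1,
                attr(x$class_weights, "theta") %||% 1,
                attr(x$class_weights, "base") %||% 10))
  }
  cat("\n")
  if (length(x$loss)) {
    cat(sprintf("  training loss: %.5f (epoch 1) -> %.5f (epoch %d)\n",
                x$loss[1], x$loss[length(x$loss)], length(x$loss)))
  }
  invisible(x)
}

#' @method summary mfpnet
#' @export
summary.mfpnet <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$config)
  cat("\nPer-class training counts and loss weights:\n")
  print(data.frame(class = names(object$counts),
                   count = as.integer(object$counts),
                   weight = round(as.numeric(object$class_weights), 4)),
        row.names = FALSE)
  invisible(object)
}

#' @method coef mfpnet
#' @export
coef.mfpnet <- function(object, ...) object$params

#' Plot the training loss curve
#'
#' @param x A fitted `mfpnet`.
#' @param ... Passed to [graphics::plot()].
#' @method plot mfpnet
#' @export
plot.mfpnet <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}
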
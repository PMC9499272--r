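#' Class weights for imbalanced multi-label loss
#'
#' Computes the logarithmic class-weight scheme
#' \deqn{W_i = \varphi \cdot [\log_b(N / n_i)]^\theta}
#' where \eqn{N} is the number of training instances, \eqn{n_i} the number
#' of instances carrying class \eqn{i} (a multi-label instance counts once
#' for every class it carries), \eqn{\varphi > 0} a global scale and
#' \eqn{\theta \ge 1} an exponent that sharpens the contrast between rare
#' and frequent classes. Rarer classes receive strictly larger weights; a
#' class carried by every instance receives weight exactly 0, which silences
#' its loss — a warning is emitted (set `floor` to a small positive value to
#' avoid this).
#'
#' `theta` is constrained to \eqn{[1, \theta_{max}]} with the upper bound
#' given by [theta_upper_bound()]; by default it is set to the midpoint of
#' that interval (or 1 when the bound is undefined because all counts are
#' equal).
#'
#' @param counts Per-class instance counts (all >= 1).
#' @param N Total number of training instances (>= max(counts)).
#' @param phi Positive scale hyperparameter (default 1).
#' @param theta Exponent >= 1, or `NULL` to use the midpoint of the valid
#'   interval.
#' @param base Logarithm base for the weight formula (default 10).
#' @param floor Lower bound applied to the weights (default 0, i.e. the
#'   formula is used exactly).
#' @return Numeric weight vector (named like `counts`), with the `phi`,
#'   `theta` and `base` used attached as attributes.
#' @examples
#' cw_weights(c(ABP = 2154, AEP = 58), N = 7872, phi = 1, theta = 1)
#' @export
cw_weights <- function(counts, N, phi = 1, theta = NULL, base = 10,
                       floor = 0) {
  if (any(counts < 1)) stop("all class counts must be >= 1")
  if (any(counts > N)) stop("class count exceeds N")
  if (phi <= 0) stop("phi must be positive")
  if (is.null(theta)) {
    # midpoint of the valid interval [1, bound]; the bound is the
    # logarithmic mean of ln X and ln Y and drops below 1 when one class
    # dominates (max(n) > N/e), in which case the interval collapses to {1}
    theta <- if (min(counts) == max(counts)) 1 else {
      max(1, (1 + theta_upper_bound(counts, N)) / 2)
    }
  }
  if (theta < 1) stop("theta must be >= 1")
  w <- phi * (log(N / counts, base = base))^theta
  if (any(counts == N)) {
    warning("class with n_i = N receives weight 0; its loss term is ",
            "silenced (consider a positive weight floor)")
  }
  w <- pmax(w, floor)
  names(w) <- names(counts)
  attr(w, "phi") <- phi
  attr(w, "theta") <- theta
  attr(w, "base") <- base
  w
}

#' Upper bound of the class-weight exponent
#'
#' With \eqn{X = N/\min(n_i)} and \eqn{Y = N/\max(n_i)}, the exponent
#' \eqn{\theta} of [cw_weights()] is constrained to
#' \deqn{1 \le \theta \le \frac{\ln X - \ln Y}{\ln(\log_Y X)}}
#' which keeps the spread between the largest and smallest class weight in
#' a controlled range. The bound is undefined for balanced counts
#' (\eqn{X = Y}).
#'
#' @inheritParams cw_weights
#' @return The upper bound (a scalar >= 1).
#' @examples
#' theta_upper_bound(c(10, 500), N = 1000) # X = 100, Y = 2 -> about 2.066
#' @export
theta_upper_bound <- function(counts, N) {
  if (any(counts < 1)) stop("all class counts must be >= 1")
  if (any(counts > N)) stop("class count exceeds N")
  X <- N / min(counts)
  Y <- N / max(counts)
  if (X == Y) stop("bound undefined for balanced counts (X = Y)")
  (log(X) - log(Y)) / log(log(X, base = Y))
}

#' Baseline class-weight schemes
#'
#' Simple reference schemes for comparison with [cw_weights()]:
#' `"uniform"` gives every class weight 1 (the unweighted loss);
#' `"inverse_frequency"` gives class i the weight \eqn{N / (M \cdot n_i)}.
#' These are generic textbook baselines, not re-implementations of any
#' published weighting variant.
#'
#' @inheritParams cw_weights
#' @param scheme One of `"uniform"`, `"inverse_frequency"`.
#' @return Numeric weight vector.
#' @export
baseline_weights <- function(counts, N,
                             scheme = c("uniform", "inverse_frequency")) {
  scheme <- match.arg(scheme)
  w <- switch(scheme,
              uniform = rep(1, length(counts)),
              inverse_frequency = N / (length(counts) * counts))
  names(w) <- names(counts)
  w
}

#' Class-weighted binary cross-entropy
#'
#' Two ways of letting per-class weights enter the multi-label BCE:
#' \describe{
#'   \item{`mode = "both"`}{mean over samples and labels of
#'     \eqn{w_j [-y \log p - (1-y) \log(1-p)]} — the whole column of class j
#'     is scaled. With all weights 1 this is the standard multi-label BCE.}
#'   \item{`mode = "positive"`}{mean of
#'     \eqn{-w_j\, y \log p - (1-y) \log(1-p)} — only the label-present
#'     terms are up-weighted. This shifts the within-class balance between
#'     positive and negative evidence, raising the operating probability of
#'     rare classes; it is the form [mfpnet()] trains with by default.}
#' }
#' Both modes coincide at all-ones weights. Probabilities are clipped to
#' `[eps, 1 - eps]` before taking logs.
#'
#' @param probs N x M matrix of predicted probabilities.
#' @param targets N x M binary matrix of true labels.
#' @param weights Length-M non-negative class weights (default all 1).
#' @param mode `"both"` (default) or `"positive"`; see Details.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
weighted_bce <- function(probs, targets, weights = rep(1, ncol(probs)),
                         mode = c("both", "positive"), eps = 1e-7) {
  mode <- match.arg(mode)
  if (!all(dim(probs) == dim(targets))) stop("probs/targets shape mismatch")
  if (length(weights) != ncol(probs)) {
    stop("weights must have one entry per label column")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  p <- pmin(pmax(probs, eps), 1 - eps)
  pos <- -targets * log(p)
  neg <- -(1 - targets) * log(1 - p)
  if (mode == "both") {
    mean(sweep(pos + neg, 2L, weights, `*`))
  } else {
    mean(sweep(pos, 2L, weights, `*`) + neg)
  }
}
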
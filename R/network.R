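#' Network architecture configuration
#'
#' Hyperparameters of the multi-label peptide classifier. The forward path
#' is: token embedding -> multi-scale 1-D convolutions (one branch per
#' kernel size, ReLU, max pooling) -> feature concatenation -> bidirectional
#' LSTM -> multi-head self-attention -> global max pooling over sequence
#' positions -> dropout -> fully connected sigmoid scorer with one output
#' per label. The attention feature width is \eqn{d_m}: twice the LSTM
#' hidden size on the full path, or the convolutional channel count when the
#' recurrent stage is ablated.
#'
#' @param n_labels Number of output labels M.
#' @param L Fixed input length in tokens (default 50).
#' @param embed_dim Embedding dimension (default 128).
#' @param kernel_sizes Convolution window sizes (default `c(2, 3, 8)`).
#' @param filters Filters per kernel size (default 64).
#' @param pool_size Max-pooling width/stride after convolution (default 2).
#' @param hidden LSTM hidden units per direction (default 64, so
#'   \eqn{d_m = 128}).
#' @param heads Number of attention heads h (default 8).
#' @param d_k Per-head query/key/value dimension (default 16).
#' @param dropout Dropout rate on the pooled feature vector during training
#'   (default 0.5).
#' @param variant Architecture variant: `"full"` or one of the ablations
#'   `"no_cnn"`, `"no_bilstm"`, `"no_mhsa"` that remove exactly one stage
#'   from the forward path.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_labels, L = 50L, embed_dim = 128L,
                         kernel_sizes = c(2L, 3L, 8L), filters = 64L,
                         pool_size = 2L, hidden = 64L, heads = 8L,
                         d_k = 16L, dropout = 0.5,
                         variant = c("full", "no_cnn", "no_bilstm",
                                     "no_mhsa")) {
  variant <- match.arg(variant)
  if (n_labels < 1L) stop("n_labels must be >= 1")
  if (any(kernel_sizes > L)) stop("kernel sizes must not exceed L")
  if (heads < 1L) stop("need at least one attention head")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  cfg <- list(n_labels = as.integer(n_labels), L = as.integer(L),
              embed_dim = as.integer(embed_dim),
              kernel_sizes = as.integer(kernel_sizes),
              filters = as.integer(filters),
              pool_size = as.integer(pool_size),
              hidden = as.integer(hidden), heads = as.integer(heads),
              d_k = as.integer(d_k), dropout = dropout, variant = variant,
              vocab_size = 21L)
  cfg$use_cnn <- variant != "no_cnn"
  cfg$use_bilstm <- variant != "no_bilstm"
  cfg$use_mhsa <- variant != "no_mhsa"
  # sequence length and feature width entering each stage
  cfg$conv_channels <- cfg$filters * length(cfg$kernel_sizes)
  cfg$T <- if (cfg$use_cnn) cfg$L %/% cfg$pool_size else cfg$L
  cfg$lstm_in <- if (cfg$use_cnn) cfg$conv_channels else cfg$embed_dim
  cfg$d_m <- if (cfg$use_bilstm) 2L * cfg$hidden else cfg$lstm_in
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration (variant:", x$variant, ")\n")
  cat(sprintf("  input      L = %d tokens, vocab %d (20 aa + pad)\n",
              x$L, x$vocab_size))
  cat(sprintf("  embedding  %d\n", x$embed_dim))
  if (x$use_cnn) {
    cat(sprintf("  conv       kernels {%s} x %d filters, pool %d -> T = %d\n",
                paste(x$kernel_sizes, collapse = ","), x$filters,
                x$pool_size, x$T))
  }
  if (x$use_bilstm) {
    cat(sprintf("  BiLSTM     hidden %d per direction -> d_m = %d\n",
                x$hidden, x$d_m))
  }
  if (x$use_mhsa) {
    cat(sprintf("  attention  %d heads, d_k = %d\n", x$heads, x$d_k))
  }
  cat(sprintf("  head       dropout %.2f -> dense %d -> sigmoid, M = %d\n",
              x$dropout, x$d_m, x$n_labels))
  invisible(x)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network parameters
#'
#' Glorot-uniform initialization for all projection matrices, zero biases
#' (LSTM forget-gate bias 1), and a zero row for the padding token, which
#' stays frozen at zero throughout training.
#'
#' Convolution weights for kernel size k are stored as a
#' `(k * embed_dim) x filters` matrix whose row block j holds the weights of
#' window position j; per-head attention projections are stored
#' column-blocked as `d_m x (heads * d_k)`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(config, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  p <- list()
  p$E <- rbind(0, glorot(config$vocab_size - 1L, config$embed_dim))
  if (config$use_cnn) {
    for (k in config$kernel_sizes) {
      p[[paste0("conv", k, "_W")]] <- glorot(k * config$embed_dim,
                                             config$filters)
      p[[paste0("conv", k, "_b")]] <- numeric(config$filters)
    }
  }
  if (config$use_bilstm) {
    H <- config$hidden
    for (dir in c("f", "b")) {
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget gate bias
      p[[paste0("lstm", dir, "_Wx")]] <- glorot(config$lstm_in, 4L * H)
      p[[paste0("lstm", dir, "_Wh")]] <- glorot(H, 4L * H)
      p[[paste0("lstm", dir, "_b")]] <- b
    }
  }
  if (config$use_mhsa) {
    hk <- config$heads * config$d_k
    p$att_Wq <- glorot(config$d_m, hk)
    p$att_Wk <- glorot(config$d_m, hk)
    p$att_Wv <- glorot(config$d_m, hk)
    p$att_Wo <- glorot(hk, config$d_m)
  }
  p$out_W <- glorot(config$d_m, config$n_labels)
  p$out_b <- numeric(config$n_labels)
  p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Scaled dot-product self-attention (one head)
#'
#' Projects an input feature matrix to queries, keys and values and applies
#' scaled dot-product attention:
#' \deqn{\mathrm{Attention}(Q,K,V) = \mathrm{softmax}(QK^T/\sqrt{d_k})\,V}
#' with a row-wise softmax, where \eqn{Q = F W^Q}, \eqn{K = F W^K},
#' \eqn{V = F W^V}.
#'
#' @param F_in L x d_m input feature matrix.
#' @param Wq,Wk,Wv d_m x d_k projection matrices.
#' @return L x d_k attention output.
#' @export
self_attention <- function(F_in, Wq, Wk, Wv) {
  if (!all(is.finite(F_in))) stop("non-finite attention input")
  Q <- F_in %*% Wq
  K <- F_in %*% Wk
  V <- F_in %*% Wv
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Wq)))
  A %*% V
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Multi-head self-attention
#'
#' Runs [self_attention()] for each of h heads, concatenates the per-head
#' outputs along the feature axis and projects back to \eqn{d_m} with
#' \eqn{W^O}.
#'
#' @param F_in L x d_m input feature matrix.
#' @param Wq,Wk,Wv Either d_m x d_k x h arrays of per-head projections, or
#'   column-blocked d_m x (h d_k) matrices as stored by [init_params()].
#' @param Wo (h d_k) x d_m output projection.
#' @param heads Number of heads h; required for the column-blocked form
#'   (inferred from the third array dimension otherwise).
#' @return L x d_m matrix.
#' @export
multi_head_attention <- function(F_in, Wq, Wk, Wv, Wo, heads = NULL) {
  as_blocked <- function(W) {
    if (length(dim(W)) == 3L) {
      matrix(W, dim(W)[1], dim(W)[2] * dim(W)[3])
    } else {
      as.matrix(W)
    }
  }
  if (is.null(heads)) {
    if (length(dim(Wq)) != 3L) stop("heads must be given for matrix input")
    heads <- dim(Wq)[3]
  }
  Wq <- as_blocked(Wq); Wk <- as_blocked(Wk); Wv <- as_blocked(Wv)
  if (!all(dim(Wq) == dim(Wk)) || !all(dim(Wq) == dim(Wv))) {
    stop("head projection shape mismatch")
  }
  d_k <- ncol(Wq) / heads
  if (d_k != round(d_k)) stop("projection width is not a multiple of heads")
  if (nrow(Wo) != heads * d_k) stop("Wo rows must equal heads * d_k")
  out <- lapply(seq_len(heads), function(i) {
    cols <- (i - 1L) * d_k + seq_len(d_k)
    self_attention(F_in, Wq[, cols, drop = FALSE],
                   Wk[, cols, drop = FALSE], Wv[, cols, drop = FALSE])
  })
  do.call(cbind, out) %*% Wo
}

# ---- batched forward/backward ---------------------------------------------
#
# All sequence activations are flat (B*T) x C matrices with the sample index
# fastest: row b + (t-1)*B holds sample b at position t, so a time slice is
# the contiguous row block ((t-1)*B + 1):(t*B).

nn_forward <- function(params, tokens, config, train = FALSE,
                       dropout_mask = NULL) {
  B <- nrow(tokens); L <- config$L
  if (ncol(tokens) != L) stop("token matrix must have L = ", L, " columns")
  if (any(tokens < 0L | tokens >= config$vocab_size)) {
    stop("token out of range 0..", config$vocab_size - 1L)
  }
  cache <- list(tokens = tokens, B = B)

  X <- params$E[as.vector(tokens) + 1L, , drop = FALSE]  # (B*L) x embed

  if (config$use_cnn) {
    branches <- vector("list", length(config$kernel_sizes))
    pooled <- vector("list", length(config$kernel_sizes))
    for (bi in seq_along(config$kernel_sizes)) {
      k <- config$kernel_sizes[bi]
      cb <- conv_forward(X, B, L, k, params[[paste0("conv", k, "_W")]],
                         params[[paste0("conv", k, "_b")]])
      pb <- maxpool_forward(cb$A, B, L, config$pool_size)
      branches[[bi]] <- list(conv = cb, pool = pb)
      pooled[[bi]] <- pb$P
    }
    cache$branches <- branches
    Tn <- config$T
    C <- do.call(cbind, pooled)
  } else {
    Tn <- L
    C <- X
  }
  cache$C <- C

  if (config$use_bilstm) {
    fwd <- lstm_forward(C, B, Tn, params$lstmf_Wx, params$lstmf_Wh,
                        params$lstmf_b, reverse = FALSE)
    bwd <- lstm_forward(C, B, Tn, params$lstmb_Wx, params$lstmb_Wh,
                        params$lstmb_b, reverse = TRUE)
    cache$lstm <- list(fwd = fwd, bwd = bwd)
    S <- cbind(fwd$H, bwd$H)
  } else {
    S <- C
  }
  cache$S <- S

  if (config$use_mhsa) {
    att <- mhsa_forward(S, B, Tn, params$att_Wq, params$att_Wk,
                        params$att_Wv, params$att_Wo, config)
    cache$att <- att
    Y <- att$Y
  } else {
    Y <- S
  }

  gm <- seqmax_forward(Y, B, Tn)
  cache$gmax <- gm
  G <- gm$G

  if (train && config$dropout > 0) {
    if (is.null(dropout_mask)) {
      keep <- 1 - config$dropout
      dropout_mask <- matrix(stats::rbinom(length(G), 1L, keep) / keep,
                             nrow(G), ncol(G))
    }
    cache$drop <- dropout_mask
    G <- G * dropout_mask
  }
  cache$G <- G

  logits <- G %*% params$out_W +
    matrix(params$out_b, B, config$n_labels, byrow = TRUE)
  probs <- sigmoid(logits)
  list(probs = probs, cache = cache)
}

# "same"-padded 1-D convolution via an unfolded window matrix: U row
# (b, t) holds the k*Cin window entries, so the whole branch is one matmul.
conv_forward <- function(X, B, L, k, W, b) {
  Cin <- ncol(X)
  lp <- (k - 1L) %/% 2L
  Xp <- matrix(0, (L + k - 1L) * B, Cin)
  Xp[lp * B + seq_len(L * B), ] <- X
  U <- matrix(0, B * L, k * Cin)
  for (j in seq_len(k)) {
    U[, (j - 1L) * Cin + seq_len(Cin)] <- Xp[(j - 1L) * B + seq_len(L * B), ]
  }
  Z <- U %*% W
  Z <- Z + matrix(b, nrow(Z), ncol(Z), byrow = TRUE)
  list(U = U, Z = Z, A = pmax(Z, 0), k = k, lp = lp, Cin = Cin)
}

conv_backward <- function(cb, dA, B, L, W) {
  dZ <- dA * (cb$Z > 0)
  dW <- crossprod(cb$U, dZ)
  db <- colSums(dZ)
  dU <- tcrossprod(dZ, W)
  Cin <- cb$Cin
  dXp <- matrix(0, (L + cb$k - 1L) * B, Cin)
  for (j in seq_len(cb$k)) {
    rows <- (j - 1L) * B + seq_len(L * B)
    dXp[rows, ] <- dXp[rows, ] + dU[, (j - 1L) * Cin + seq_len(Cin)]
  }
  list(dW = dW, db = db, dX = dXp[cb$lp * B + seq_len(L * B), , drop = FALSE])
}

# non-overlapping max pooling of width/stride p along the time axis
maxpool_forward <- function(A, B, L, p) {
  Tn <- L %/% p
  Fo <- ncol(A)
  # row indices of window offset o (1..p) for all (b, pooled t)
  ridx <- matrix(0L, B * Tn, p)
  base <- as.vector(outer(seq_len(B), (seq_len(Tn) - 1L) * p * B, `+`))
  for (o in seq_len(p)) ridx[, o] <- base + (o - 1L) * B
  P <- A[ridx[, 1L], , drop = FALSE]
  amax <- matrix(1L, B * Tn, Fo)
  if (p > 1L) {
    for (o in 2L:p) {
      cand <- A[ridx[, o], , drop = FALSE]
      upd <- cand > P
      P[upd] <- cand[upd]
      amax[upd] <- o
    }
  }
  list(P = P, amax = amax, ridx = ridx, p = p, L = L, Fo = Fo)
}

maxpool_backward <- function(pb, dP, B) {
  n <- nrow(dP)
  src <- matrix(pb$ridx[cbind(rep(seq_len(n), pb$Fo), as.vector(pb$amax))],
                n, pb$Fo)
  dA <- matrix(0, B * pb$L, pb$Fo)
  dA[as.vector(src) + (rep(seq_len(pb$Fo), each = n) - 1L) * B * pb$L] <-
    as.vector(dP)
  dA
}

lstm_forward <- function(Xin, B, Tn, Wx, Wh, b, reverse = FALSE) {
  H <- nrow(Wh)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hout <- matrix(0, B * Tn, H)
  steps <- vector("list", Tn)
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  ii <- seq_len(H); ff <- H + ii; oo <- 2L * H + ii; gg <- 3L * H + ii
  for (s in seq_len(Tn)) {
    t <- ord[s]
    rows <- (t - 1L) * B + seq_len(B)
    x_t <- Xin[rows, , drop = FALSE]
    z <- x_t %*% Wx + h %*% Wh + bmat
    gi <- sigmoid(z[, ii, drop = FALSE])
    gf <- sigmoid(z[, ff, drop = FALSE])
    go <- sigmoid(z[, oo, drop = FALSE])
    ga <- tanh(z[, gg, drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- gf * c_prev + gi * ga
    tc <- tanh(cc)
    h <- go * tc
    Hout[rows, ] <- h
    steps[[s]] <- list(rows = rows, i = gi, f = gf, o = go, g = ga,
                       c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(H = Hout, steps = steps, Cin = ncol(Xin), Hdim = H)
}

lstm_backward <- function(fw, Xin, dH, B, Tn, Wx, Wh) {
  H <- fw$Hdim
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dXin <- matrix(0, B * Tn, fw$Cin)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (s in rev(seq_len(Tn))) {
    st <- fw$steps[[s]]
    dh <- dH[st$rows, , drop = FALSE] + dh_next
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + crossprod(Xin[st$rows, , drop = FALSE], dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dXin[st$rows, ] <- tcrossprod(dz, Wx)
    dh_next <- tcrossprod(dz, Wh)
    dc_next <- dc * st$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dXin)
}

mhsa_forward <- function(S, B, Tn, Wq, Wk, Wv, Wo, config) {
  h <- config$heads; dk <- config$d_k
  Q <- S %*% Wq
  K <- S %*% Wk
  V <- S %*% Wv
  O <- matrix(0, B * Tn, h * dk)
  Amats <- array(0, c(Tn, Tn, h, B))
  sq <- sqrt(dk)
  tidx <- (seq_len(Tn) - 1L) * B
  for (b in seq_len(B)) {
    rows <- b + tidx
    for (i in seq_len(h)) {
      cols <- (i - 1L) * dk + seq_len(dk)
      A <- softmax_rows(tcrossprod(Q[rows, cols, drop = FALSE],
                                   K[rows, cols, drop = FALSE]) / sq)
      Amats[, , i, b] <- A
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  list(Y = O %*% Wo, O = O, A = Amats, Q = Q, K = K, V = V)
}

mhsa_backward <- function(att, S, dY, B, Tn, Wq, Wk, Wv, Wo, config) {
  h <- config$heads; dk <- config$d_k
  dWo <- crossprod(att$O, dY)
  dO <- tcrossprod(dY, Wo)
  dQ <- matrix(0, B * Tn, h * dk); dK <- dQ; dV <- dQ
  sq <- sqrt(dk)
  tidx <- (seq_len(Tn) - 1L) * B
  for (b in seq_len(B)) {
    rows <- b + tidx
    for (i in seq_len(h)) {
      cols <- (i - 1L) * dk + seq_len(dk)
      A <- matrix(att$A[, , i, b], Tn, Tn)
      dOb <- dO[rows, cols, drop = FALSE]
      dV[rows, cols] <- crossprod(A, dOb)
      dA <- tcrossprod(dOb, att$V[rows, cols, drop = FALSE])
      dSc <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dSc %*% att$K[rows, cols, drop = FALSE] / sq
      dK[rows, cols] <- crossprod(dSc, att$Q[rows, cols, drop = FALSE]) / sq
    }
  }
  dS <- tcrossprod(dQ, Wq) + tcrossprod(dK, Wk) + tcrossprod(dV, Wv)
  list(dS = dS, dWq = crossprod(S, dQ), dWk = crossprod(S, dK),
       dWv = crossprod(S, dV), dWo = dWo)
}

# global max over time positions: (B*Tn) x C -> B x C
seqmax_forward <- function(Y, B, Tn) {
  C <- ncol(Y)
  G <- Y[seq_len(B), , drop = FALSE]
  amax <- matrix(1L, B, C)
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      cand <- Y[(t - 1L) * B + seq_len(B), , drop = FALSE]
      upd <- cand > G
      G[upd] <- cand[upd]
      amax[upd] <- t
    }
  }
  list(G = G, amax = amax, Tn = Tn)
}

seqmax_backward <- function(gm, dG, B) {
  C <- ncol(dG)
  dY <- matrix(0, B * gm$Tn, C)
  rows <- rep(seq_len(B), C) + (as.vector(gm$amax) - 1L) * B
  dY[rows + (rep(seq_len(C), each = B) - 1L) * B * gm$Tn] <- as.vector(dG)
  dY
}

# Full backward pass: takes d loss / d logits, returns gradients for every
# parameter array (same names/shapes as params).
nn_backward <- function(params, cache, dLogits, config) {
  B <- cache$B
  Tn <- if (config$use_cnn) config$T else config$L
  grads <- list()
  grads$out_W <- crossprod(cache$G, dLogits)
  grads$out_b <- colSums(dLogits)
  dG <- tcrossprod(dLogits, params$out_W)
  if (!is.null(cache$drop)) dG <- dG * cache$drop
  dY <- seqmax_backward(cache$gmax, dG, B)

  if (config$use_mhsa) {
    mb <- mhsa_backward(cache$att, cache$S, dY, B, Tn, params$att_Wq,
                        params$att_Wk, params$att_Wv, params$att_Wo, config)
    grads$att_Wq <- mb$dWq; grads$att_Wk <- mb$dWk
    grads$att_Wv <- mb$dWv; grads$att_Wo <- mb$dWo
    dS <- mb$dS
  } else {
    dS <- dY
  }

  if (config$use_bilstm) {
    H <- config$hidden
    bf <- lstm_backward(cache$lstm$fwd, cache$C,
                        dS[, seq_len(H), drop = FALSE], B, Tn,
                        params$lstmf_Wx, params$lstmf_Wh)
    bb <- lstm_backward(cache$lstm$bwd, cache$C,
                        dS[, H + seq_len(H), drop = FALSE], B, Tn,
                        params$lstmb_Wx, params$lstmb_Wh)
    grads$lstmf_Wx <- bf$dWx; grads$lstmf_Wh <- bf$dWh; grads$lstmf_b <- bf$db
    grads$lstmb_Wx <- bb$dWx; grads$lstmb_Wh <- bb$dWh; grads$lstmb_b <- bb$db
    dC <- bf$dX + bb$dX
  } else {
    dC <- dS
  }

  if (config$use_cnn) {
    dX <- matrix(0, B * config$L, config$embed_dim)
    for (bi in seq_along(config$kernel_sizes)) {
      k <- config$kernel_sizes[bi]
      cols <- (bi - 1L) * config$filters + seq_len(config$filters)
      br <- cache$branches[[bi]]
      dA <- maxpool_backward(br$pool, dC[, cols, drop = FALSE], B)
      cbk <- conv_backward(br$conv, dA, B, config$L,
                           params[[paste0("conv", k, "_W")]])
      grads[[paste0("conv", k, "_W")]] <- cbk$dW
      grads[[paste0("conv", k, "_b")]] <- cbk$db
      dX <- dX + cbk$dX
    }
  } else {
    dX <- dC
  }

  rs <- rowsum(dX, as.vector(cache$tokens) + 1L)
  dE <- matrix(0, config$vocab_size, config$embed_dim)
  dE[as.integer(rownames(rs)), ] <- rs
  dE[1L, ] <- 0  # pad embedding stays frozen
  grads$E <- dE
  grads[names(params)]
}
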
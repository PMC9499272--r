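# Independent brute-force oracles used across tests. These deliberately use
# naive set arithmetic and scalar loops, sharing no code with the package's
# vectorized implementations.

# multi-label metrics from explicit label sets
oracle_metrics <- function(true_sets, pred_sets, M) {
  n <- length(true_sets)
  prec <- cov <- acc <- atrue <- afalse <- numeric(n)
  for (i in seq_len(n)) {
    L <- true_sets[[i]]
    P <- pred_sets[[i]]
    inter <- length(intersect(L, P))
    uni <- length(union(L, P))
    prec[i] <- if (length(P) == 0) as.numeric(length(L) == 0) else {
      inter / length(P)
    }
    cov[i] <- if (length(L) == 0) as.numeric(length(P) == 0) else {
      inter / length(L)
    }
    acc[i] <- if (uni == 0) 1 else inter / uni
    atrue[i] <- as.numeric(setequal(L, P))
    afalse[i] <- (uni - inter) / M
  }
  c(precision = mean(prec), coverage = mean(cov), accuracy = mean(acc),
    absolute_true = mean(atrue), absolute_false = mean(afalse))
}

matrix_to_sets <- function(m) {
  lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1))
}

# scalar-loop scaled dot-product attention for one head
oracle_attention <- function(F_in, Wq, Wk, Wv) {
  L <- nrow(F_in); dk <- ncol(Wq)
  Q <- matrix(0, L, dk); K <- matrix(0, L, dk); V <- matrix(0, L, dk)
  for (a in seq_len(L)) for (b in seq_len(dk)) {
    for (c in seq_len(ncol(F_in))) {
      Q[a, b] <- Q[a, b] + F_in[a, c] * Wq[c, b]
      K[a, b] <- K[a, b] + F_in[a, c] * Wk[c, b]
      V[a, b] <- V[a, b] + F_in[a, c] * Wv[c, b]
    }
  }
  out <- matrix(0, L, dk)
  for (a in seq_len(L)) {
    s <- numeric(L)
    for (b in seq_len(L)) {
      for (c in seq_len(dk)) s[b] <- s[b] + Q[a, c] * K[b, c]
      s[b] <- s[b] / sqrt(dk)
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    for (b in seq_len(L)) for (c in seq_len(dk)) {
      out[a, c] <- out[a, c] + w[b] * V[b, c]
    }
  }
  out
}

# a tiny but complete architecture for fast unit tests
tiny_config <- function(n_labels = 3, L = 12, variant = "full",
                        dropout = 0) {
  model_config(n_labels = n_labels, L = L, embed_dim = 5,
               kernel_sizes = c(2, 3, 4), filters = 4, pool_size = 2,
               hidden = 4, heads = 2, d_k = 3, dropout = dropout,
               variant = variant)
}

random_records <- function(n, seed = 1, min_len = 5, max_len = 20,
                           codes = c("ABP", "ACP", "AFP")) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(mfpep::AA_ALPHABET, sample(min_len:max_len, 1),
                   replace = TRUE), collapse = "")
    }, "")
    labs <- lapply(seq_len(n), function(i) {
      sample(codes, sample(1:2, 1))
    })
    peptide_set(sprintf("r%03d", seq_len(n)), seqs, labs)
  })
}
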
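# Shared fixtures and independent oracles used across the suite.

# a random profile with occasional non-canonical residues
random_profile <- function(n = NULL, id = "p", p_unknown = 0.03) {
  if (is.null(n)) n <- sample(1:30, 1L)
  res <- sample(c(AA_ALPHABET, "X"), n, replace = TRUE,
                prob = c(rep(1, 20L), 20 * p_unknown / (1 - p_unknown)))
  pssm_profile(id, res,
               matrix(sample(-10:12, n * 20L, replace = TRUE), n, 20L))
}

tiny_model_config <- function(conv_filters = c(3L, 4L), conv_kernel = 3L,
                              gru_hidden = 3L, fc_size = 4L, dropout = 0,
                              ...) {
  model_config(conv_filters = conv_filters, conv_kernel = conv_kernel,
               gru_hidden = gru_hidden, fc_size = fc_size,
               dropout = dropout, ...)
}

# GRU step evaluated scalar by scalar with plain arithmetic: the
# independent oracle for the gate equations
scalar_gru_oracle <- function(x, h, p) {
  H <- length(h); D <- length(x)
  out <- numeric(H)
  for (i in seq_len(H)) {
    az <- p$b_iz[i] + p$b_hz[i]
    ar <- p$b_ir[i] + p$b_hr[i]
    an <- p$b_in[i]
    ah <- p$b_hn[i]
    for (j in seq_len(D)) {
      az <- az + p$W_iz[i, j] * x[j]
      ar <- ar + p$W_ir[i, j] * x[j]
      an <- an + p$W_in[i, j] * x[j]
    }
    for (j in seq_len(H)) {
      az <- az + p$W_hz[i, j] * h[j]
      ar <- ar + p$W_hr[i, j] * h[j]
      ah <- ah + p$W_hn[i, j] * h[j]
    }
    z <- 1 / (1 + exp(-az))
    r <- 1 / (1 + exp(-ar))
    n <- tanh(an + r * ah)
    out[i] <- (1 - z) * n + z * h[i]
  }
  out
}

random_gru_params <- function(H, D) {
  m <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.5), nr, nc)
  list(W_iz = m(H, D), W_ir = m(H, D), W_in = m(H, D),
       W_hz = m(H, H), W_hr = m(H, H), W_hn = m(H, H),
       b_iz = rnorm(H), b_ir = rnorm(H), b_in = rnorm(H),
       b_hz = rnorm(H), b_hr = rnorm(H), b_hn = rnorm(H))
}

# full forward pass re-implemented with explicit loops in R, built on
# gru_cell_step(); checks the compiled path end to end
r_forward_oracle <- function(X, par, cfg) {
  k <- cfg$conv_kernel
  pad <- (k - 1L) / 2L
  conv <- function(A, W, b) {
    N <- ncol(A); ch <- nrow(A)
    Z <- matrix(0, nrow(W), N)
    for (i in seq_len(N)) {
      patch <- matrix(0, ch, k)
      for (o in seq_len(k)) {
        src <- i + o - 1L - pad
        if (src >= 1L && src <= N) patch[, o] <- A[, src]
      }
      Z[, i] <- W %*% as.vector(patch) + b
    }
    Z
  }
  pool <- function(A) {
    pk <- cfg$pool_kernel; ps <- cfg$pool_stride
    m <- (ncol(A) - pk) %/% ps + 1L
    out <- matrix(0, nrow(A), m)
    for (j in seq_len(m)) {
      win <- A[, ((j - 1L) * ps + 1L):((j - 1L) * ps + pk), drop = FALSE]
      out[, j] <- if (cfg$pool == "max") apply(win, 1L, max)
                  else rowMeans(win)
    }
    out
  }
  A0 <- t(X)
  if (cfg$input_squash) A0 <- plogis(A0)
  O1 <- pool(pmax(conv(A0, par$conv1_W, par$conv1_b), 0))
  S <- pool(pmax(conv(O1, par$conv2_W, par$conv2_b), 0))
  Xseq <- S
  for (l in seq_len(cfg$gru_layers)) {
    h <- numeric(cfg$gru_hidden)
    Hs <- matrix(0, cfg$gru_hidden, ncol(Xseq))
    for (t in seq_len(ncol(Xseq))) {
      h <- gru_cell_step(Xseq[, t], h, par$gru[[l]])
      Hs[, t] <- h
    }
    Xseq <- Hs
  }
  fc <- pmax(drop(par$fc_W %*% Xseq[, ncol(Xseq)]) + drop(par$fc_b), 0)
  plogis(drop(par$out_W %*% fc) + par$out_b[1L])
}

# AUC as the normalised Mann-Whitney U statistic, by exhaustive pairwise
# comparison with ties counted one half
u_statistic_auc <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# small synthetic dataset shortcut
quick_dataset <- function(n_pos, n_neg, mode = "order", seed = 7L,
                          lens = c(30L, 60L), motif = 6L, effect = 4) {
  generate_dataset(synthetic_config(
    n_positive = n_pos, n_negative = n_neg, length_range = lens,
    signal_mode = mode, motif_length = motif, effect_size = effect,
    seed = seed))
}
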
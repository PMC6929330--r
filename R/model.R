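#' Configuration of the convolutional-recurrent classifier
#'
#' The architecture: the N x 20 profile enters with the 20 amino-acid
#' columns as channels; two (1-D convolution -> ReLU -> pooling) stages
#' shorten the position axis, with the default kernel = stride = 3 pooling
#' giving an output length of floor(floor(N/3)/3) — a 9-fold reduction
#' (N = 900 emits exactly 100 steps). The remaining steps drive a stacked
#' GRU; the final hidden state passes through a fully connected ReLU layer
#' (with dropout during training) and a sigmoid that emits the probability
#' that the profile belongs to the positive (adaptor) class.
#'
#' @param conv_filters integer vector of length 2: channels of the two
#'   convolution stages.
#' @param conv_kernel odd convolution width in positions (zero padding
#'   preserves length before pooling).
#' @param pool_kernel,pool_stride pooling window and stride; the 3/3
#'   default is the only equal two-stage factorisation of a 9-fold
#'   reduction.
#' @param pool `"max"` or `"avg"`. Both are implemented because
#'   descriptions of this architecture use either; max is the default.
#' @param gru_hidden GRU hidden size (tuned value 256).
#' @param gru_layers number of stacked GRU layers.
#' @param fc_size fully connected layer width (tuned value 512).
#' @param dropout dropout probability applied after the fully connected
#'   layer during training only.
#' @param input_squash if `TRUE`, squash raw integer scores elementwise
#'   through `1/(1+exp(-x))` before the network; default feeds raw scores.
#' @param pad_short if `TRUE`, profiles shorter than 9 positions are
#'   zero-padded to length 9; by default they are rejected with an error.
#' @return An object of class `model_config` (a validated list).
#' @export
model_config <- function(conv_filters = c(64L, 128L), conv_kernel = 7L,
                         pool_kernel = 3L, pool_stride = 3L,
                         pool = c("max", "avg"),
                         gru_hidden = 256L, gru_layers = 1L,
                         fc_size = 512L, dropout = 0.5,
                         input_squash = FALSE, pad_short = FALSE) {
  pool <- match.arg(pool)
  stopifnot(length(conv_filters) == 2L, all(conv_filters >= 1L),
            conv_kernel >= 1L, conv_kernel %% 2L == 1L,
            pool_kernel >= 1L, pool_stride >= 1L,
            pool_kernel >= pool_stride,
            gru_hidden >= 1L, gru_layers >= 1L, fc_size >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_kernel = as.integer(pool_kernel),
                 pool_stride = as.integer(pool_stride),
                 pool = pool,
                 gru_hidden = as.integer(gru_hidden),
                 gru_layers = as.integer(gru_layers),
                 fc_size = as.integer(fc_size),
                 dropout = dropout,
                 input_squash = isTRUE(input_squash),
                 pad_short = isTRUE(pad_short),
                 input_channels = 20L),
            class = "model_config")
}

min_profile_length <- function(config) {
  # smallest N for which both pooling stages see a complete window
  l1 <- config$pool_kernel  # need >= pool_kernel after conv1
  (l1 - 1L) * config$pool_stride + config$pool_kernel
}

runif_mat <- function(nr, nc, bound) {
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}

#' Initialise model parameters
#'
#' Weights are drawn uniformly from \[-1/sqrt(fan_in), 1/sqrt(fan_in)\];
#' biases start at zero.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @return A named list of parameter arrays (`conv1_W`, `conv1_b`,
#'   `conv2_W`, `conv2_b`, `gru` — one sublist of the twelve GRU arrays per
#'   layer —, `fc_W`, `fc_b`, `out_W`, `out_b`).
#' @export
init_model_params <- function(config, seed = 7L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k <- config$conv_kernel
  c1 <- config$conv_filters[1L]; c2 <- config$conv_filters[2L]
  H <- config$gru_hidden; Fc <- config$fc_size
  gru <- vector("list", config$gru_layers)
  for (l in seq_len(config$gru_layers)) {
    D <- if (l == 1L) c2 else H
    gru[[l]] <- list(
      W_iz = runif_mat(H, D, 1 / sqrt(D)),
      W_ir = runif_mat(H, D, 1 / sqrt(D)),
      W_in = runif_mat(H, D, 1 / sqrt(D)),
      W_hz = runif_mat(H, H, 1 / sqrt(H)),
      W_hr = runif_mat(H, H, 1 / sqrt(H)),
      W_hn = runif_mat(H, H, 1 / sqrt(H)),
      b_iz = matrix(0, H, 1L), b_ir = matrix(0, H, 1L),
      b_in = matrix(0, H, 1L), b_hz = matrix(0, H, 1L),
      b_hr = matrix(0, H, 1L), b_hn = matrix(0, H, 1L))
  }
  list(conv1_W = runif_mat(c1, 20L * k, 1 / sqrt(20L * k)),
       conv1_b = matrix(0, c1, 1L),
       conv2_W = runif_mat(c2, c1 * k, 1 / sqrt(c1 * k)),
       conv2_b = matrix(0, c2, 1L),
       gru = gru,
       fc_W = runif_mat(Fc, H, 1 / sqrt(H)),
       fc_b = matrix(0, Fc, 1L),
       out_W = runif_mat(1L, Fc, 1 / sqrt(Fc)),
       out_b = matrix(0, 1L, 1L))
}

#' One GRU cell step
#'
#' The gated recurrent unit update, written exactly as its defining
#' equations: update gate
#' `z = sigmoid(W_iz x + b_iz + W_hz h + b_hz)`, reset gate
#' `r = sigmoid(W_ir x + b_ir + W_hr h + b_hr)`, candidate memory
#' `n = tanh(W_in x + b_in + r * (W_hn h + b_hn))` (elementwise `*`), and
#' new hidden state `h' = (1 - z) * n + z * h`.
#'
#' @param x input vector at the current step.
#' @param h_prev hidden state from the previous step.
#' @param params list with the twelve GRU arrays `W_iz`, `W_ir`, `W_in`,
#'   `W_hz`, `W_hr`, `W_hn`, `b_iz`, `b_ir`, `b_in`, `b_hz`, `b_hr`,
#'   `b_hn` (one layer of `init_model_params()$gru`).
#' @return The new hidden state, a numeric vector of length `hidden_size`.
#' @examples
#' H <- 3
#' z <- matrix(0, H, H); b <- numeric(H)
#' p <- list(W_iz = matrix(0, H, 2), W_ir = matrix(0, H, 2),
#'           W_in = matrix(0, H, 2), W_hz = z, W_hr = z, W_hn = z,
#'           b_iz = b, b_ir = b, b_in = b, b_hz = b, b_hr = b, b_hn = b)
#' gru_cell_step(c(1, -1), c(0.4, 0, -0.2), p)  # 0.5 * h_prev
#' @export
gru_cell_step <- function(x, h_prev, params) {
  x <- as.numeric(x); h_prev <- as.numeric(h_prev)
  H <- length(h_prev)
  for (nm in c("W_hz", "W_hr", "W_hn"))
    if (!all(dim(params[[nm]]) == c(H, H)))
      stop(nm, " must be ", H, " x ", H)
  for (nm in c("W_iz", "W_ir", "W_in"))
    if (ncol(params[[nm]]) != length(x) || nrow(params[[nm]]) != H)
      stop(nm, " must be ", H, " x ", length(x))
  z <- plogis(drop(params$W_iz %*% x) + drop(params$b_iz) +
              drop(params$W_hz %*% h_prev) + drop(params$b_hz))
  r <- plogis(drop(params$W_ir %*% x) + drop(params$b_ir) +
              drop(params$W_hr %*% h_prev) + drop(params$b_hr))
  n <- tanh(drop(params$W_in %*% x) + drop(params$b_in) +
            r * (drop(params$W_hn %*% h_prev) + drop(params$b_hn)))
  (1 - z) * n + z * h_prev
}

# Convert profiles to the double matrices the compiled code consumes,
# enforcing the minimum admissible length (or zero-padding when allowed).
profile_scores_list <- function(profiles, config) {
  min_n <- min_profile_length(config)
  lapply(profiles, function(p) {
    x <- if (inherits(p, "pssm_profile")) p$scores else p
    x <- matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
    if (nrow(x) < min_n) {
      if (!config$pad_short)
        stop(sprintf(paste0(
          "profile of length %d is shorter than the minimum admissible ",
          "length %d; reject it or opt into zero-padding with ",
          "model_config(pad_short = TRUE)"), nrow(x), min_n))
      x <- rbind(x, matrix(0, min_n - nrow(x), ncol(x)))
    }
    x
  })
}

#' Convolutional front-end of the model
#'
#' Applies the two (convolution -> ReLU -> pooling) stages along the
#' position axis with the 20 PSSM columns as input channels, and returns
#' the downsampled feature sequence fed to the GRU. With the default
#' kernel = stride = 3 pooling the output length is floor(floor(N/3)/3).
#'
#' @param profile a [pssm_profile] or an N x 20 numeric score matrix.
#' @param params model parameters ([init_model_params()]).
#' @param config a [model_config()].
#' @return A T x C matrix: T downsampled steps, C = `conv_filters[2]`
#'   channels.
#' @export
cnn_front_end <- function(profile, params, config) {
  stopifnot(inherits(config, "model_config"))
  x <- profile_scores_list(list(profile), config)[[1L]]
  cpp_front_end(x, params, unclass(config))
}

#' Forward pass: probability that a profile is positive
#'
#' Runs the full model (front-end, GRU, fully connected layer, sigmoid) in
#' evaluation mode (dropout disabled); the result is deterministic given
#' the parameters.
#'
#' @inheritParams cnn_front_end
#' @return A scalar probability in \[0, 1\].
#' @export
model_forward <- function(profile, params, config) {
  stopifnot(inherits(config, "model_config"))
  x <- profile_scores_list(list(profile), config)
  as.numeric(cpp_predict(x, params, unclass(config)))
}

#' @export
print.pssm_gru_model <- function(x, ...) {
  cat(sprintf(paste0("<pssm_gru_model> conv %d/%d (kernel %d), GRU %dx%d,",
                     " FC %d\n"),
              x$config$conv_filters[1L], x$config$conv_filters[2L],
              x$config$conv_kernel, x$config$gru_layers,
              x$config$gru_hidden, x$config$fc_size))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final weighted BCE %.4f\n",
                length(x$history), tail(x$history, 1L)))
  invisible(x)
}

#' Predict with a trained model
#'
#' @param object a `pssm_gru_model` from [train_model()].
#' @param newdata a `labeled_dataset`, a list of [pssm_profile]s / score
#'   matrices, or a single profile.
#' @param ... unused.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.pssm_gru_model <- function(object, newdata, ...) {
  profiles <- if (inherits(newdata, "labeled_dataset")) newdata$profiles
              else if (inherits(newdata, "pssm_profile") ||
                       is.matrix(newdata)) list(newdata)
              else newdata
  xs <- profile_scores_list(profiles, object$config)
  as.numeric(cpp_predict(xs, object$params, unclass(object$config)))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the parameters with their
#' embedded [model_config()] (and the training history when present).
#'
#' @param model a `pssm_gru_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pssm_gru_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pssm_gru_model"))
  model
}
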
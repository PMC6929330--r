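# 2-D CNN comparator: treats the 20 x 20 summed-PSSM matrix as a
# one-channel image. One convolution (valid, square kernel) -> ReLU ->
# 2 x 2 max pooling -> fully connected sigmoid output, trained with Adam
# on the weighted binary cross-entropy (the same loss and optimizer as
# the recurrent model). The compute lives in src/cnn2d_net.cpp; entries
# are z-score standardized here (fitted on the training data) so the
# optimiser sees comparably scaled inputs.

fit_cnn2d <- function(x, y, config) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  n <- nrow(xs)
  w <- ifelse(y == 1, n / (2 * max(1, sum(y == 1))),
              n / (2 * max(1, sum(y == 0))))

  k <- config$cnn2d_kernel
  Fn <- config$cnn2d_filters
  out <- 20L - k + 1L
  nq <- (out %/% 2L)^2
  params0 <- list(W = runif_mat(Fn, k * k, 1 / k),
                  b = numeric(Fn),
                  Wf = runif(nq * Fn, -1, 1) / sqrt(nq * Fn),
                  bf = 0)
  fit <- cpp_cnn2d_train(xs, as.numeric(y), w, params0, k,
                         epochs = config$cnn2d_epochs,
                         lr = config$cnn2d_lr,
                         batch_size = config$cnn2d_batch,
                         seed = config$seed)
  c(fit$params,
    list(history = as.numeric(fit$history), mu = mu, sd = sdv, kernel = k))
}

predict_cnn2d <- function(net, x) {
  xs <- sweep(sweep(x, 2L, net$mu), 2L, net$sd, "/")
  as.numeric(cpp_cnn2d_predict(xs, net, net$kernel))
}
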
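test_that("zero-parameter GRU cell halves the hidden state", {
  H <- 4L
  p <- list(W_iz = matrix(0, H, 2L), W_ir = matrix(0, H, 2L),
            W_in = matrix(0, H, 2L), W_hz = matrix(0, H, H),
            W_hr = matrix(0, H, H), W_hn = matrix(0, H, H),
            b_iz = numeric(H), b_ir = numeric(H), b_in = numeric(H),
            b_hz = numeric(H), b_hr = numeric(H), b_hn = numeric(H))
  h <- c(0.8, -0.4, 0, 2)
  expect_identical(gru_cell_step(c(1, -3), h, p), 0.5 * h)
  expect_identical(gru_cell_step(c(1, -3), numeric(H), p), numeric(H))
})

test_that("GRU cell matches the scalar oracle on random parameters", {
  set.seed(20)
  for (rep in 1:100) {
    H <- sample(1:8, 1L)
    D <- sample(1:6, 1L)
    p <- random_gru_params(H, D)
    x <- rnorm(D)
    h <- rnorm(H)
    expect_equal(gru_cell_step(x, h, p), scalar_gru_oracle(x, h, p),
                 tolerance = 1e-10)
  }
})

test_that("GRU cell validates dimensions", {
  p <- random_gru_params(3L, 2L)
  expect_error(gru_cell_step(c(1, 2, 3), c(0, 0, 0), p), "W_iz")
  expect_error(gru_cell_step(c(1, 2), c(0, 0), p), "W_hz")
})

test_that("front-end emits floor(floor(N/3)/3) steps", {
  cfg <- tiny_model_config()
  par <- init_model_params(cfg, seed = 1L)
  expect_identical(nrow(cnn_front_end(matrix(0, 900L, 20L), par, cfg)), 100L)
  expect_identical(nrow(cnn_front_end(matrix(0, 9L, 20L), par, cfg)), 1L)
  expect_identical(nrow(cnn_front_end(matrix(0, 100L, 20L), par, cfg)), 11L)
  set.seed(21)
  for (N in c(9:14, sample(15:2000, 30L))) {
    S <- cnn_front_end(matrix(rnorm(N * 20L), N, 20L), par, cfg)
    expect_identical(nrow(S), as.integer((N %/% 3L) %/% 3L))
    expect_identical(ncol(S), cfg$conv_filters[2L])
  }
})

test_that("profiles shorter than 9 are rejected unless padding is chosen", {
  cfg <- tiny_model_config()
  par <- init_model_params(cfg, seed = 1L)
  expect_error(model_forward(matrix(0, 8L, 20L), par, cfg), "zero-padding")
  cfg_pad <- tiny_model_config(pad_short = TRUE)
  expect_length(model_forward(matrix(0, 8L, 20L), par, cfg_pad), 1L)
})

test_that("forward pass emits probabilities; zero output head gives 0.5", {
  cfg <- tiny_model_config()
  par <- init_model_params(cfg, seed = 2L)
  set.seed(22)
  probs <- replicate(200L, {
    N <- sample(9:60, 1L)
    model_forward(matrix(rnorm(N * 20L, sd = 3), N, 20L), par, cfg)
  })
  expect_true(all(probs >= 0 & probs <= 1))
  par0 <- par
  par0$out_W[] <- 0
  par0$out_b[] <- 0
  expect_identical(model_forward(matrix(rnorm(300L), 15L, 20L), par0, cfg),
                   0.5)
})

test_that("compiled forward equals the looped R oracle", {
  set.seed(23)
  for (cfg in list(tiny_model_config(gru_layers = 2L),
                   tiny_model_config(pool = "avg"),
                   tiny_model_config(input_squash = TRUE))) {
    par <- init_model_params(cfg, seed = 3L)
    par$fc_b <- par$fc_b + 0.3  # keep some ReLU units active
    for (rep in 1:5) {
      N <- sample(9:50, 1L)
      X <- matrix(rnorm(N * 20L, sd = 2), N, 20L)
      expect_equal(model_forward(X, par, cfg), r_forward_oracle(X, par, cfg),
                   tolerance = 1e-10)
    }
  }
})

test_that("analytic gradients match a directional finite difference", {
  cfg <- tiny_model_config(gru_layers = 2L)
  par <- init_model_params(cfg, seed = 4L)
  par$fc_b <- par$fc_b + 0.3
  set.seed(24)
  X <- matrix(rnorm(31L * 20L), 31L, 20L)
  lg <- pssmGRU:::cpp_loss_grad(X, 1, 1.7, par, unclass(cfg))
  flat <- function(x) if (is.list(x)) unlist(lapply(x, flat)) else as.numeric(x)
  nudge <- function(par, d, h) {
    idx <- 0L
    rec <- function(x) {
      if (is.list(x)) return(lapply(x, rec))
      n <- length(x)
      y <- x + h * d[(idx + 1L):(idx + n)]
      idx <<- idx + n
      y
    }
    rec(par)
  }
  d <- rnorm(length(flat(par)))
  d <- d / sqrt(sum(d^2))
  h <- 1e-5
  num <- (pssmGRU:::cpp_loss_grad(X, 1, 1.7, nudge(par, d, h),
                                  unclass(cfg))$loss -
          pssmGRU:::cpp_loss_grad(X, 1, 1.7, nudge(par, d, -h),
                                  unclass(cfg))$loss) / (2 * h)
  ana <- sum(flat(lg$grads) * d)
  expect_equal(ana, num, tolerance = 1e-6)
})

test_that("inference is deterministic but not row-permutation invariant", {
  cfg <- tiny_model_config(conv_filters = c(4L, 6L), gru_hidden = 5L)
  par <- init_model_params(cfg, seed = 5L)
  set.seed(25)
  X <- matrix(rnorm(40L * 20L, sd = 3), 40L, 20L)
  expect_identical(model_forward(X, par, cfg), model_forward(X, par, cfg))
  # contrast with the summed representation: reordering rows changes the
  # model's view of the profile for the vast majority of permutations
  changed <- 0L
  for (rep in 1:100) {
    N <- sample(12:60, 1L)
    X <- matrix(rnorm(N * 20L, sd = 3), N, 20L)
    perm <- sample(N)
    if (abs(model_forward(X, par, cfg) -
            model_forward(X[perm, ], par, cfg)) > 1e-8)
      changed <- changed + 1L
  }
  expect_gt(changed, 90L)
})

test_that("checkpoints round-trip through disk", {
  ds <- quick_dataset(4L, 8L, lens = c(12L, 20L), motif = 3L)
  fit <- train_model(ds, tiny_model_config(dropout = 0.2),
                     train_config(epochs = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, ds), predict(fit, ds))
})
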
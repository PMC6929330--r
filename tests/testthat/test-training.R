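test_that("inverse class frequency weights equalise class totals", {
  expect_equal(inverse_class_frequency_weights(c(1, 1, 0, 0)),
               c(positive = 1, negative = 1))
  w <- inverse_class_frequency_weights(c(1, 0, 0, 0, 0))
  expect_equal(unname(w["positive"] / w["negative"]), 4)
  set.seed(30)
  for (rep in 1:20) {
    y <- c(rep(1, sample(1:30, 1L)), rep(0, sample(1:30, 1L)))
    w <- inverse_class_frequency_weights(y)
    expect_equal(w["positive"] * sum(y == 1), w["negative"] * sum(y == 0),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(inverse_class_frequency_weights(c(1, 1)), "both classes")
})

test_that("weighted BCE matches closed forms", {
  # single sample, y = 1, p = 0.5, w = 2 -> 2 ln 2
  expect_equal(weighted_bce_loss(0.5, 1, c(positive = 2, negative = 1)),
               2 * log(2), tolerance = 1e-12)
  set.seed(31)
  p <- runif(50)
  y <- rbinom(50, 1, 0.3)
  expect_equal(weighted_bce_loss(p, y),
               mean(-(y * log(p) + (1 - y) * log(1 - p))),
               tolerance = 1e-9)
  # near-perfect predictions cost at most the clipping floor
  expect_lte(weighted_bce_loss(y, y), -log(1 - 1e-7) + 1e-12)
  expect_error(weighted_bce_loss(c(0.1, 0.9), 1), "length")
})

test_that("duplicating negatives while halving their weight is a no-op", {
  set.seed(32)
  p <- runif(40)
  y <- rep(c(1, 0), each = 20L)
  w <- inverse_class_frequency_weights(y)
  base <- weighted_bce_loss(p, y, w) * 40
  dup <- weighted_bce_loss(c(p, p[y == 0]), c(y, rep(0, 20L)),
                           c(positive = unname(w["positive"]),
                             negative = unname(w["negative"]) / 2)) * 60
  expect_equal(base, dup, tolerance = 1e-7)
})

test_that("stratified folds partition the data proportionally", {
  folds <- stratified_kfold(rep(c(1, 0), each = 5L), k = 5L)
  for (f in folds) {
    expect_length(f$validation, 2L)
    expect_equal(sum(f$validation <= 5L), 1L)  # one positive per fold
  }
  set.seed(33)
  y <- rbinom(83, 1, 0.3)
  while (min(table(y)) < 5L) y <- rbinom(83, 1, 0.3)
  folds <- stratified_kfold(y, k = 5L, seed = 2L)
  vals <- unlist(lapply(folds, `[[`, "validation"))
  expect_identical(sort(vals), seq_along(y))  # disjoint and exhaustive
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    for (cl in c(0, 1)) {
      got <- sum(y[f$validation] == cl)
      expect_lt(abs(got - sum(y == cl) / 5), 1)
    }
  }
  expect_error(stratified_kfold(c(1, 0, 0, 0, 0, 0), k = 5L), "at least")
})

test_that("training defaults follow the reference protocol", {
  tc <- train_config()
  expect_equal(tc$learning_rate, 1e-4)
  expect_equal(tc$epochs, 30L)
  expect_equal(tc$optimizer, "adam")
  expect_equal(tc$class_weighting, "inverse_frequency")
  expect_equal(tc$k_folds, 5L)
  expect_equal(tc$seed, 7L)
})

test_that("training is reproducible bit for bit under a fixed seed", {
  ds <- quick_dataset(6L, 12L, lens = c(15L, 30L), motif = 4L)
  cfg <- tiny_model_config(dropout = 0.5)
  tc <- train_config(epochs = 3L, seed = 7L)
  f1 <- train_model(ds, cfg, tc)
  f2 <- train_model(ds, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- train_model(ds, cfg, train_config(epochs = 3L, seed = 8L))
  expect_false(identical(f3$params, f1$params))
})

test_that("loss decreases on learnable order-mode data", {
  ds <- generate_dataset(synthetic_config(
    n_positive = 40L, n_negative = 160L, length_range = c(30L, 60L),
    motif_length = 6L, effect_size = 4, seed = 7L))
  fit <- train_model(ds, tiny_model_config(conv_filters = c(8L, 12L),
                                           gru_hidden = 8L, fc_size = 8L),
                     train_config(epochs = 6L))
  expect_length(fit$history, 6L)
  expect_lt(tail(fit$history, 1L), fit$history[1L])
})

test_that("degenerate training inputs raise errors", {
  cfg <- tiny_model_config()
  expect_error(train_model(labeled_dataset(list(), character(0)), cfg),
               "empty")
  ds <- quick_dataset(0L, 4L, lens = c(12L, 20L), motif = 3L)
  expect_error(train_model(ds, cfg), "both positive and negative")
})

test_that("cross-validation returns one report per fold with fold support", {
  ds <- quick_dataset(9L, 18L, lens = c(12L, 24L), motif = 3L)
  cv <- cross_validate(ds, tiny_model_config(),
                       train_config(epochs = 2L, k_folds = 3L))
  expect_length(cv$folds, 3L)
  splits <- stratified_kfold(ds$labels, k = 3L, seed = 7L)
  for (i in 1:3)
    expect_equal(sum(cv$folds[[i]]$support),
                 length(splits[[i]]$validation))
  expect_named(cv$summary,
               c("sensitivity", "specificity", "accuracy", "mcc", "auc"))
})
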
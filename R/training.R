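#' Training configuration
#'
#' Defaults follow the reference training protocol for this architecture:
#' Adam with the learning rate fixed at 1e-4 for all 30 epochs, weighted
#' binary cross-entropy with inverse-class-frequency weights to counter
#' class imbalance, decision threshold 0.5, 5-fold cross-validation, and
#' seed 7.
#'
#' @param learning_rate Adam learning rate (fixed for the whole run).
#' @param epochs number of passes over the training set.
#' @param optimizer only `"adam"` (beta1 = 0.9, beta2 = 0.999,
#'   eps = 1e-8).
#' @param class_weighting `"inverse_frequency"` or `"none"`.
#' @param threshold decision cutoff on the predicted probability.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param k_folds folds for [cross_validate()].
#' @param batch_size samples per optimizer step (gradients are averaged
#'   over the batch; each sequence is still processed at its own length,
#'   so predictions never depend on batching).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 30L,
                         optimizer = "adam",
                         class_weighting = c("inverse_frequency", "none"),
                         threshold = 0.5, seed = 7L, k_folds = 5L,
                         batch_size = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  class_weighting <- match.arg(class_weighting)
  stopifnot(learning_rate > 0, epochs >= 1L, threshold > 0, threshold < 1,
            k_folds >= 2L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, class_weighting = class_weighting,
                 threshold = threshold, seed = as.integer(seed),
                 k_folds = as.integer(k_folds),
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

#' Inverse-class-frequency loss weights
#'
#' `w_c = n_total / (2 * n_c)` for each class, so `w_pos / w_neg =
#' n_neg / n_pos` (the inverse class frequency ratio) and the weighted
#' total count of each class is the same. The normalisation keeps the loss
#' magnitude comparable across imbalance levels; only the ratio affects
#' the optimum.
#'
#' @param labels binary labels (any form accepted by [labeled_dataset()]).
#' @return Named numeric vector `c(positive = w_pos, negative = w_neg)`.
#' @export
inverse_class_frequency_weights <- function(labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute class weights")
  n <- n_pos + n_neg
  c(positive = n / (2 * n_pos), negative = n / (2 * n_neg))
}

#' Weighted binary cross-entropy loss
#'
#' Mean over samples of `-w(y) * (y * log p + (1 - y) * log(1 - p))`,
#' with probabilities clipped to `[eps, 1 - eps]`. With unit weights this
#' is plain binary cross-entropy.
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param labels binary labels.
#' @param weights either a length-2 named vector
#'   `c(positive = , negative = )` (e.g. from
#'   [inverse_class_frequency_weights()]) or one weight per sample.
#'   Defaults to unit weights.
#' @param eps clipping constant.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(probabilities, labels,
                              weights = c(positive = 1, negative = 1),
                              eps = 1e-7) {
  labels <- as_binary_labels(labels)
  y <- as.numeric(labels == "positive")
  if (length(probabilities) != length(y))
    stop("probabilities and labels must have the same length")
  w <- if (length(weights) == 2L && !is.null(names(weights)))
    unname(weights[ifelse(y == 1, "positive", "negative")])
  else if (length(weights) == length(y)) as.numeric(weights)
  else stop("weights must be a named length-2 vector or one per sample")
  p <- pmin(1 - eps, pmax(eps, probabilities))
  mean(-w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Stratified k-fold split
#'
#' Shuffles each class independently (seeded) and deals its members
#' round-robin across folds, so per-fold class counts differ from perfect
#' proportionality by less than one. Validation sets are disjoint and
#' jointly exhaustive.
#'
#' @param labels binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of `k` fold objects, each with elements `k` (fold index),
#'   `train` and `validation` (integer index vectors).
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 7L) {
  labels <- as_binary_labels(labels)
  k <- as.integer(k)
  if (min(table(labels)) < k)
    stop("each class must have at least k = ", k, " members")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  assignment <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    assignment[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(k = f,
         train = which(assignment != f),
         validation = which(assignment == f)))
}

#' Train the convolutional-recurrent classifier
#'
#' Runs `epochs` passes of Adam over the dataset with per-sample weighted
#' binary cross-entropy. Initialisation, epoch shuffling and dropout are
#' all driven by `train_cfg$seed`, so a rerun with the same seed
#' reproduces the parameters and the loss history bit for bit.
#'
#' @param dataset a `labeled_dataset` containing both classes; all
#'   profiles must be admissible for the front-end (length >= 9 with the
#'   default pooling).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @return A `pssm_gru_model`: list with `params`, `config`,
#'   `train_config`, `class_weights` and `history` (per-epoch mean
#'   weighted loss, length `epochs`).
#' @export
train_model <- function(dataset, model_cfg = model_config(),
                        train_cfg = train_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(model_cfg, "model_config"),
            inherits(train_cfg, "train_config"))
  if (length(dataset) == 0L) stop("cannot train on an empty dataset")
  y <- labels01(dataset)
  if (length(unique(y)) < 2L)
    stop("training requires both positive and negative examples")
  cw <- if (train_cfg$class_weighting == "inverse_frequency")
    inverse_class_frequency_weights(dataset$labels)
  else c(positive = 1, negative = 1)
  w <- unname(cw[ifelse(y == 1, "positive", "negative")])
  xs <- profile_scores_list(dataset$profiles, model_cfg)
  params0 <- init_model_params(model_cfg, seed = train_cfg$seed)
  fit <- cpp_train(xs, as.numeric(y), w, params0, unclass(model_cfg),
                   epochs = train_cfg$epochs,
                   lr = train_cfg$learning_rate,
                   beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                   batch_size = train_cfg$batch_size,
                   seed = train_cfg$seed)
  structure(list(params = fit$params, config = model_cfg,
                 train_config = train_cfg, class_weights = cw,
                 history = as.numeric(fit$history)),
            class = "pssm_gru_model")
}

#' Stratified cross-validation of the classifier
#'
#' Splits the dataset with [stratified_kfold()], trains one model per fold
#' on the training indices and evaluates it on the held-out validation
#' indices with [evaluate_predictions()].
#'
#' @inheritParams train_model
#' @return An object of class `cv_result`: list with `folds` (one
#'   [evaluate_predictions()] report per fold, each also carrying the
#'   fitted model), and `summary` (mean of sensitivity, specificity,
#'   accuracy, MCC and AUC over folds).
#' @export
cross_validate <- function(dataset, model_cfg = model_config(),
                           train_cfg = train_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  splits <- stratified_kfold(dataset$labels, k = train_cfg$k_folds,
                             seed = train_cfg$seed)
  folds <- lapply(splits, function(sp) {
    fit <- train_model(dataset[sp$train], model_cfg, train_cfg)
    prob <- predict(fit, dataset[sp$validation])
    rep <- evaluate_predictions(prob, dataset$labels[sp$validation],
                                threshold = train_cfg$threshold)
    rep$fold <- sp$k
    rep$model <- fit
    rep
  })
  metrics <- c("sensitivity", "specificity", "accuracy", "mcc", "auc")
  summ <- vapply(metrics, function(m)
    mean(vapply(folds, `[[`, numeric(1L), m)), numeric(1L))
  structure(list(folds = folds, summary = summ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", length(x$folds)))
  print(round(x$summary, 4L))
  invisible(x)
}
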
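#' Configuration of the order-destroying comparator models
#'
#' Four conventional classifiers consuming the 400-dimensional summed-PSSM
#' representation ([summed_pssm_features()]): k-nearest neighbours, random
#' forest, a radial-kernel SVM, and a small 2-D CNN that treats the 20 x 20
#' summed matrix as an image. Hyperparameter defaults are the tuned values
#' reported for this task: k = 10, 500 trees, SVM cost 8 and gamma 0.5,
#' 128 filters of size 3 x 3.
#'
#' @param method one of `"knn"`, `"rf"`, `"svm"`, `"cnn2d"`.
#' @param knn_k neighbours for k-NN.
#' @param rf_trees trees for the random forest.
#' @param svm_c,svm_gamma radial-kernel SVM cost and gamma.
#' @param cnn2d_filters,cnn2d_kernel 2-D CNN filter count and (square)
#'   kernel width.
#' @param cnn2d_lr,cnn2d_epochs,cnn2d_batch Adam settings for the 2-D CNN
#'   comparator (same optimizer and weighted loss as the recurrent model;
#'   the steeper default rate suits its small fixed-size input).
#' @param standardize rescale features before distance/kernel methods
#'   (k-NN, SVM): min-max to \[0, 1\], fitted on the training data only —
#'   the conventional preprocessing for radial-kernel SVMs, and the one
#'   under which the stated gamma is meaningful. The forest consumes raw
#'   features; the CNN standardizes internally.
#' @param seed integer seed (forest bootstrap, CNN initialisation and
#'   shuffling, k-NN tie-breaks).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(method = c("knn", "rf", "svm", "cnn2d"),
                            knn_k = 10L, rf_trees = 500L,
                            svm_c = 8.0, svm_gamma = 0.5,
                            cnn2d_filters = 128L, cnn2d_kernel = 3L,
                            cnn2d_lr = 1e-3, cnn2d_epochs = 30L,
                            cnn2d_batch = 32L,
                            standardize = TRUE, seed = 7L) {
  method <- match.arg(method)
  stopifnot(knn_k >= 1L, rf_trees >= 1L, svm_c > 0, svm_gamma > 0,
            cnn2d_filters >= 1L, cnn2d_kernel >= 1L, cnn2d_lr > 0,
            cnn2d_epochs >= 1L, cnn2d_batch >= 1L)
  structure(list(method = method, knn_k = as.integer(knn_k),
                 rf_trees = as.integer(rf_trees),
                 svm_c = svm_c, svm_gamma = svm_gamma,
                 cnn2d_filters = as.integer(cnn2d_filters),
                 cnn2d_kernel = as.integer(cnn2d_kernel),
                 cnn2d_lr = cnn2d_lr,
                 cnn2d_epochs = as.integer(cnn2d_epochs),
                 cnn2d_batch = as.integer(cnn2d_batch),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

# min-max scaler fitted on training features
fit_minmax <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}
apply_minmax <- function(x, s) sweep(sweep(x, 2L, s$lo), 2L, s$rng, "/")

baseline_features <- function(x) {
  if (inherits(x, "labeled_dataset")) x <- summed_feature_matrix(x)
  if (!is.matrix(x) || ncol(x) != 400L)
    stop("baseline input must be an n x 400 summed-feature matrix ",
         "(or a labeled_dataset); got ", paste(dim(x), collapse = " x "))
  x
}

#' Fit a comparator model on summed-PSSM features
#'
#' @param x an n x 400 summed-feature matrix ([summed_feature_matrix()])
#'   or a `labeled_dataset` (features are computed on the fly). The 2-D
#'   CNN internally reshapes each row back to its 20 x 20 matrix form.
#' @param labels binary labels (taken from `x` when it is a dataset).
#' @param config a [baseline_config()].
#' @return An object of class `pssm_baseline` exposing probability scores
#'   through [predict_baseline()].
#' @export
fit_baseline <- function(x, labels = NULL, config = baseline_config()) {
  stopifnot(inherits(config, "baseline_config"))
  if (inherits(x, "labeled_dataset") && is.null(labels)) labels <- x$labels
  x <- baseline_features(x)
  labels <- as_binary_labels(labels)
  if (nrow(x) != length(labels))
    stop("feature rows and labels differ in length")
  if (length(unique(labels)) < 2L)
    stop("training labels must contain both classes")

  obj <- list(method = config$method, config = config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  if (config$method %in% c("knn", "svm") && config$standardize) {
    obj$scaler <- fit_minmax(x)
    x <- apply_minmax(x, obj$scaler)
  }
  obj <- switch(config$method,
    knn = {
      obj$train_x <- x
      obj$train_y <- labels
      obj
    },
    rf = {
      obj$fit <- randomForest::randomForest(x, labels,
                                            ntree = config$rf_trees)
      obj
    },
    svm = {
      obj$fit <- e1071::svm(x, labels, kernel = "radial",
                            cost = config$svm_c, gamma = config$svm_gamma,
                            scale = FALSE)
      # orientation of decision values: "A/B" in the column name means
      # positive decision value -> class A
      dv <- attr(predict(obj$fit, x[1:2, , drop = FALSE],
                         decision.values = TRUE), "decision.values")
      obj$flip <- !startsWith(colnames(dv)[1L], "positive")
      obj
    },
    cnn2d = {
      obj$fit <- fit_cnn2d(x, as.numeric(labels == "positive"), config)
      obj
    })
  class(obj) <- "pssm_baseline"
  obj
}

#' Probability scores from a fitted comparator
#'
#' k-NN scores are the fraction of positive neighbours; forest scores the
#' fraction of positive votes; SVM decision values are mapped through the
#' logistic function `plogis` (a documented monotone link — ROC/AUC only
#' require a correctly ordered score); the 2-D CNN emits its sigmoid
#' output.
#'
#' @param model a `pssm_baseline` from [fit_baseline()].
#' @param x an n x 400 feature matrix or `labeled_dataset`.
#' @return Numeric vector of scores in \[0, 1\], one per row.
#' @export
predict_baseline <- function(model, x) {
  stopifnot(inherits(model, "pssm_baseline"))
  x <- baseline_features(x)
  if (!is.null(model$scaler)) x <- apply_minmax(x, model$scaler)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(model$config$seed)  # fixes k-NN distance tie-breaks
  switch(model$method,
    knn = {
      pred <- class::knn(model$train_x, x, model$train_y,
                         k = model$config$knn_k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "positive", win, 1 - win)
    },
    rf = unname(predict(model$fit, x, type = "prob")[, "positive"]),
    svm = {
      dv <- attr(predict(model$fit, x, decision.values = TRUE),
                 "decision.values")[, 1L]
      unname(plogis(if (model$flip) -dv else dv))
    },
    cnn2d = predict_cnn2d(model$fit, x))
}
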
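# Uniform interface over the six classification backends. Each fit returns a
# `petromics_classifier` whose `predict_prob()` emits the positive-class
# probability, which is what average precision and soft voting consume.

.classifier_names <- function() c("logistic", "svm", "random_forest",
                                  "naive_bayes", "neural_net", "knn")

#' Hyperparameter grids for the classifier sweep
#'
#' `preset = "default"` is the full desk-scale grid (SVM cost x kernel,
#' random-forest trees x depth, KNN k, neural-net hidden width); `"reduced"`
#' is a one-point-per-classifier grid used for large repeated sweeps such as
#' multi-seed null-cohort calibration.
#'
#' @param preset `"default"` or `"reduced"`.
#' @return Named list of data frames, one per classifier.
#' @export
classifier_grids <- function(preset = c("default", "reduced")) {
  preset <- match.arg(preset)
  if (preset == "default") {
    list(
      logistic = data.frame(dummy = NA),
      svm = expand.grid(cost = c(0.1, 1, 10), kernel = c("radial", "linear"),
                        stringsAsFactors = FALSE),
      random_forest = expand.grid(num_trees = c(100, 300), max_depth = c(3, 0)),
      naive_bayes = data.frame(dummy = NA),
      neural_net = expand.grid(size = c(8, 32), decay = 0.1, maxit = 150),
      knn = data.frame(k = c(3, 5, 11))
    )
  } else {
    list(
      logistic = data.frame(dummy = NA),
      svm = data.frame(cost = 1, kernel = "radial", stringsAsFactors = FALSE),
      random_forest = data.frame(num_trees = 50, max_depth = 0),
      naive_bayes = data.frame(dummy = NA),
      neural_net = data.frame(size = 4, decay = 0.1, maxit = 60),
      knn = data.frame(k = 5)
    )
  }
}

#' Selection and classifier grids for the pipeline sweep
#'
#' Bundles the filter cut grid (`k_features`; `Inf` means "all") with the
#' per-classifier hyperparameter grids.
#' @param preset `"default"` or `"reduced"`.
#' @return List with `k_grid` and `classifiers`.
#' @export
pipeline_grids <- function(preset = c("default", "reduced")) {
  preset <- match.arg(preset)
  list(k_grid = if (preset == "default") c(2, 5, 10, 20, Inf) else c(5, Inf),
       classifiers = classifier_grids(preset))
}

#' Fit one classifier
#'
#' @param name One of `"logistic"`, `"svm"`, `"random_forest"`,
#'   `"naive_bayes"`, `"neural_net"`, `"knn"`.
#' @param X Data frame / matrix of numeric features (rows = samples).
#' @param y Binary labels (0/1).
#' @param hyper One-row data frame (or list) of hyperparameters from
#'   [classifier_grids()].
#' @param seed Integer seed for stochastic learners.
#' @return A `petromics_classifier`.
#' @export
fit_classifier <- function(name, X, y, hyper = list(), seed = 1L) {
  name <- match.arg(name, .classifier_names())
  X <- as.data.frame(X)
  .audit_record(rownames(X))
  y <- as.integer(y)
  yf <- factor(y, levels = c(0, 1))
  hyper <- as.list(hyper)
  set.seed(seed)
  fit <- switch(name,
    logistic = suppressWarnings(stats::glm(yf ~ ., data = cbind(X, yf = yf),
                                           family = stats::binomial())),
    svm = e1071::svm(x = as.matrix(X), y = yf, probability = TRUE,
                     kernel = if (is.null(hyper$kernel)) "radial" else as.character(hyper$kernel),
                     cost = if (is.null(hyper$cost)) 1 else hyper$cost,
                     scale = FALSE),
    random_forest = ranger::ranger(
      x = X, y = yf, probability = TRUE,
      num.trees = if (is.null(hyper$num_trees)) 100 else hyper$num_trees,
      max.depth = if (is.null(hyper$max_depth)) 0 else hyper$max_depth,
      seed = seed, num.threads = 1),
    naive_bayes = e1071::naiveBayes(x = X, y = yf),
    neural_net = {
      utils::capture.output(nn <- nnet::nnet(
        x = as.matrix(X), y = y,
        size = if (is.null(hyper$size)) 8 else hyper$size,
        decay = if (is.null(hyper$decay)) 0.1 else hyper$decay,
        maxit = if (is.null(hyper$maxit)) 150 else hyper$maxit,
        entropy = TRUE, trace = FALSE))
      nn
    },
    knn = caret::knn3(as.matrix(X), yf, k = min(if (is.null(hyper$k)) 5 else hyper$k,
                                                nrow(X))))
  structure(list(name = name, fit = fit, features = names(X), hyper = hyper),
            class = "petromics_classifier")
}

#' Positive-class probability predictions
#'
#' @param clf A `petromics_classifier`.
#' @param X New data containing the training feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(clf, X) {
  stopifnot(inherits(clf, "petromics_classifier"))
  X <- as.data.frame(X)[, clf$features, drop = FALSE]
  p <- switch(clf$name,
    logistic = {
      pr <- stats::predict(clf$fit, newdata = X, type = "response")
      as.numeric(pr)
    },
    svm = {
      pr <- stats::predict(clf$fit, newdata = as.matrix(X), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    random_forest = stats::predict(clf$fit, data = X, num.threads = 1)$predictions[, "1"],
    naive_bayes = stats::predict(clf$fit, newdata = X, type = "raw")[, "1"],
    neural_net = as.numeric(stats::predict(clf$fit, newdata = as.matrix(X))),
    knn = stats::predict(clf$fit, newdata = as.matrix(X), type = "prob")[, "1"])
  pmin(pmax(as.numeric(p), 0), 1)
}
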
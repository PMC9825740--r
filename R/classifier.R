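#' Probabilistic-classifier contract
#'
#' An AL classifier is any object of class `al_classifier` with two closures:
#' `fit(x, y, seed)` returning a fitted model, and
#' `predict_posteriors(model, x)` returning a matrix of class posteriors with
#' one row per item and columns ordered by `levels(y)` (rows sum to 1). Any
#' model satisfying this contract — a random forest on feature vectors, an
#' SVM with probability outputs, a neural network on padded raw vectors —
#' can drive the AL loop.
#'
#' @param fit function(x, y, seed) -> model.
#' @param predict_posteriors function(model, x) -> posterior matrix.
#' @param label short descriptive name.
#' @return an `al_classifier`.
#' @export
al_classifier <- function(fit, predict_posteriors, label = "custom") {
  stopifnot(is.function(fit), is.function(predict_posteriors))
  structure(list(fit = fit, predict_posteriors = predict_posteriors,
                 label = label),
            class = "al_classifier")
}

#' Random-forest classifier adapter (default)
#'
#' Wraps [randomForest::randomForest()] on the 11-feature event vectors.
#' Classes absent from the (initially tiny) labeled pool are handled by
#' fitting on the observed classes and padding their posterior columns with
#' zeros, so posterior matrices always span the full label space. A
#' degenerate single-class labeled pool yields a trivial model that predicts
#' that class with probability 1. `ntree = 100` is plenty for an 11-feature
#' space and keeps the retrain inside the AL loop fast.
#'
#' @param ntree number of trees.
#' @param ... passed on to [randomForest::randomForest()].
#' @return an [al_classifier()].
#' @export
rf_classifier <- function(ntree = 100L, ...) {
  dots <- list(...)
  fit <- function(x, y, seed = 1L) {
    x <- as.matrix(x)
    y <- as.factor(y)
    lv <- levels(y)
    yd <- droplevels(y)
    if (nlevels(yd) < 2L) {
      return(structure(list(rf = NULL, levels = lv, only = levels(yd)),
                       class = "nanoal_rf_model"))
    }
    rf <- local_seed(seed, do.call(randomForest::randomForest,
                                   c(list(x = x, y = yd, ntree = ntree),
                                     dots)))
    structure(list(rf = rf, levels = lv, only = NULL),
              class = "nanoal_rf_model")
  }
  predict_posteriors <- function(model, x) {
    x <- as.matrix(x)
    out <- matrix(0, nrow = nrow(x), ncol = length(model$levels),
                  dimnames = list(NULL, model$levels))
    if (is.null(model$rf)) {
      out[, model$only] <- 1
      return(out)
    }
    p <- predict(model$rf, x, type = "prob")
    out[, colnames(p)] <- p
    out
  }
  al_classifier(fit, predict_posteriors, label = "random_forest")
}
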
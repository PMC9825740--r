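#' SavedRate: fraction of labeling effort saved
#'
#' `SR = 1 - EA/FS`, where `EA` is the number of expert-annotated samples the
#' AL run consumed before reaching the target performance and `FS` is the
#' full number of labels the dataset could provide. `SR = 0` means AL saved
#' nothing (every label was bought); `SR = 1` means the target was met with
#' no labels at all.
#'
#' @param EA expert-annotated count, `0 <= EA <= FS`.
#' @param FS full sample count, > 0.
#' @return object of class `saved_rate`: list with `EA`, `FS`, `SR`.
#' @examples
#' saved_rate(160, 1020)  # SR ~ 0.843
#' @export
saved_rate <- function(EA, FS) {
  if (!is.numeric(FS) || length(FS) != 1L || FS <= 0)
    stop("`FS` must be a single positive count", call. = FALSE)
  if (!is.numeric(EA) || length(EA) != 1L || EA < 0 || EA > FS)
    stop("`EA` must lie in [0, FS]", call. = FALSE)
  structure(list(EA = EA, FS = FS, SR = 1 - EA / FS), class = "saved_rate")
}

#' @export
print.saved_rate <- function(x, ...) {
  cat(sprintf("SavedRate: EA = %d, FS = %d, SR = %.4f\n",
              as.integer(x$EA), as.integer(x$FS), x$SR))
  invisible(x)
}

#' Empirical risk of predictions
#'
#' Mean loss over the evaluated points, `(1/M) sum_m L(y_m, f(x_m))`. With
#' zero-one loss this is the error rate of the argmax prediction (first index
#' wins ties); with log loss it is the mean negative log posterior of the
#' true class. Note that when the M points were *actively* sampled this is a
#' biased estimator of the population risk — actively queried points are by
#' construction the hard ones.
#'
#' @param true_labels factor/character truth of length M >= 1.
#' @param posteriors posterior matrix, M rows, columns named by class.
#' @param loss `"zero_one"` or `"log"`.
#' @return mean loss (scalar).
#' @export
empirical_risk <- function(true_labels, posteriors,
                           loss = c("zero_one", "log")) {
  loss <- match.arg(loss)
  p <- as_posterior_matrix(posteriors)
  y <- as.character(true_labels)
  if (length(y) != nrow(p))
    stop("labels and posteriors have different lengths", call. = FALSE)
  if (is.null(colnames(p)))
    stop("posterior columns must be named by class", call. = FALSE)
  if (!all(y %in% colnames(p)))
    stop("true labels outside the posterior label space", call. = FALSE)
  if (loss == "zero_one") {
    pred <- colnames(p)[apply(p, 1L, which.max)]
    mean(pred != y)
  } else {
    p_true <- p[cbind(seq_len(nrow(p)), match(y, colnames(p)))]
    mean(-log(pmax(p_true, 1e-15)))
  }
}

#' Accuracy, macro one-vs-rest AUC and confusion matrix
#'
#' Accuracy uses the argmax prediction (ties broken by first class index).
#' AUC is the macro average of one-vs-rest AUCs over the classes present in
#' the truth; it is `NA` when fewer than two classes are present. Confusion
#' matrix rows are true classes, columns predicted classes.
#'
#' @param posteriors posterior matrix with class-named columns.
#' @param true_labels truth, length = rows of `posteriors`.
#' @return list with `accuracy`, `macro_auc`, `confusion`.
#' @export
evaluate_posteriors <- function(posteriors, true_labels) {
  p <- as_posterior_matrix(posteriors)
  if (is.null(colnames(p)))
    stop("posterior columns must be named by class", call. = FALSE)
  y <- factor(as.character(true_labels), levels = colnames(p))
  if (any(is.na(y)))
    stop("true labels outside the posterior label space", call. = FALSE)
  pred <- factor(colnames(p)[apply(p, 1L, which.max)], levels = colnames(p))
  acc <- mean(pred == y)
  present <- levels(y)[tabulate(y, nbins = nlevels(y)) > 0L]
  auc <- NA_real_
  if (length(present) >= 2L) {
    aucs <- vapply(present, function(cls) {
      resp <- factor(y == cls, levels = c(FALSE, TRUE))
      as.numeric(pROC::auc(pROC::roc(resp, p[, cls], quiet = TRUE,
                                     levels = c(FALSE, TRUE),
                                     direction = "<")))
    }, numeric(1L))
    auc <- mean(aucs)
  }
  list(accuracy = acc, macro_auc = auc, confusion = table(true = y, pred = pred))
}

#' Evaluate a fitted classifier on a test set
#'
#' @param classifier an [al_classifier()].
#' @param model a model fitted by `classifier$fit`.
#' @param test list with feature matrix `x` and labels `y` (as produced by
#'   [make_dataset()]).
#' @return list with `accuracy`, `macro_auc`, `confusion`.
#' @export
evaluate_model <- function(classifier, model, test) {
  if (length(test$y) == 0L) stop("test set is empty", call. = FALSE)
  evaluate_posteriors(classifier$predict_posteriors(model, test$x), test$y)
}

#' Per-feature importance of a fitted feature-based classifier
#'
#' `method = "impurity"` reads the mean decrease in Gini impurity off a
#' fitted random-forest model. `method = "permutation"` measures, for each
#' feature in turn, the drop in accuracy on `(x, y)` when that feature's
#' column is permuted (averaged over `n_repeats` permutations) — a
#' model-agnostic alternative that needs held-out data. Importances are
#' floored at 0 and normalized to sum to 1.
#'
#' @param model a model fitted by [rf_classifier()]'s `fit` (impurity), or
#'   any model usable with `classifier` (permutation).
#' @param method `"impurity"` or `"permutation"`.
#' @param classifier,x,y required for `"permutation"`.
#' @param n_repeats permutations per feature.
#' @param seed integer seed for the permutations.
#' @return data.frame with `feature` and `importance` (sums to 1), sorted
#'   decreasing.
#' @export
feature_importance_report <- function(model, method = c("impurity",
                                                        "permutation"),
                                      classifier = NULL, x = NULL, y = NULL,
                                      n_repeats = 5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "impurity") {
    if (!inherits(model, "nanoal_rf_model") || is.null(model$rf))
      stop("impurity importances need a fitted random-forest model",
           call. = FALSE)
    imp <- randomForest::importance(model$rf)[, "MeanDecreaseGini"]
  } else {
    if (is.null(classifier) || is.null(x) || is.null(y))
      stop("permutation importances need `classifier`, `x` and `y`",
           call. = FALSE)
    x <- as.matrix(x)
    base <- 1 - empirical_risk(y, classifier$predict_posteriors(model, x))
    imp <- local_seed(seed, vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        base - (1 - empirical_risk(y, classifier$predict_posteriors(model, xp)))
      }, numeric(1L))
      mean(drops)
    }, numeric(1L)))
    names(imp) <- colnames(x)
  }
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot <= 0) imp[] <- 1 / length(imp) else imp <- imp / tot
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out[order(-out$importance), , drop = FALSE]
}

#' Summarize AL runs per strategy
#'
#' Aggregates the SavedRate of repeated runs: mean, sample (n-1) standard
#' deviation and mean iteration count per strategy.
#'
#' @param records list of [run_al()] records.
#' @return data.frame: `strategy`, `n_runs`, `sr_mean`, `sr_sd`,
#'   `mean_iterations`.
#' @export
report_run <- function(records) {
  if (length(records) == 0L) stop("no run records", call. = FALSE)
  strat <- vapply(records, function(r) r$strategy, character(1L))
  sr <- vapply(records, function(r) saved_rate(r$EA, r$FS)$SR, numeric(1L))
  iters <- vapply(records, function(r) max(r$history$iteration), numeric(1L))
  out <- do.call(rbind, lapply(unique(strat), function(s) {
    i <- strat == s
    data.frame(strategy = s, n_runs = sum(i), sr_mean = mean(sr[i]),
               sr_sd = if (sum(i) > 1L) sd(sr[i]) else 0,
               mean_iterations = mean(iters[i]))
  }))
  rownames(out) <- NULL
  out
}
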
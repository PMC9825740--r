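#' Simulated supervisor: label pool items from ground truth
#'
#' Returns the ground-truth label of every requested id; with
#' `mislabel_rate > 0` each label is independently replaced by a uniformly
#' random *wrong* label with that probability, emulating annotator error.
#'
#' @param ids character ids to label.
#' @param ground_truth named factor/character vector of true labels.
#' @param mislabel_rate probability in `[0, 1)` of corrupting each label.
#' @param seed integer seed.
#' @return factor of labels aligned with `ids`, with the full level set.
#' @export
simulated_oracle <- function(ids, ground_truth, mislabel_rate = 0,
                             seed = 1L) {
  if (mislabel_rate < 0 || mislabel_rate >= 1)
    stop("`mislabel_rate` must lie in [0, 1)", call. = FALSE)
  if (is.null(names(ground_truth)))
    stop("`ground_truth` must be named by id", call. = FALSE)
  missing <- setdiff(ids, names(ground_truth))
  if (length(missing) > 0L)
    stop("unknown ids: ", paste(head(missing, 5L), collapse = ", "),
         call. = FALSE)
  lv <- if (is.factor(ground_truth)) levels(ground_truth)
        else sort(unique(as.character(ground_truth)))
  lab <- as.character(ground_truth[ids])
  if (mislabel_rate > 0) {
    lab <- local_seed(seed, {
      flip <- runif(length(lab)) < mislabel_rate
      lab[flip] <- vapply(lab[flip], function(tr)
        sample(setdiff(lv, tr), 1L), character(1L))
      lab
    })
  }
  factor(lab, levels = lv)
}

#' Center and radius of the embedded labeled pool
#'
#' Fits the embedding on the labeled features, takes the centroid `O` of the
#' embedded points and sets the radius `r` to the `radius_quantile` quantile
#' of their distances to `O`. The returned state also carries the fitted
#' projection, so newly queried points can be mapped into the same plane.
#'
#' @param labeled_features feature matrix, >= 2 rows.
#' @param embedding embedding constructor ([pca_embedding()] signature).
#' @param radius_quantile quantile of labeled distances defining `r`.
#' @param seed passed to stochastic embeddings.
#' @return object of class `stopping_state`: list with `center` (length-2),
#'   `radius`, `project` and `radius_quantile`.
#' @export
compute_center_radius <- function(labeled_features,
                                  embedding = pca_embedding,
                                  radius_quantile = 0.95, seed = NULL) {
  x <- as.matrix(labeled_features)
  if (nrow(x) < 2L) stop("need >= 2 labeled items", call. = FALSE)
  if (radius_quantile <= 0 || radius_quantile > 1)
    stop("`radius_quantile` must lie in (0, 1]", call. = FALSE)
  emb <- embedding(x, seed = seed)
  O <- colMeans(emb$points)
  d <- sqrt(rowSums(sweep(emb$points, 2L, O)^2))
  structure(list(center = O,
                 radius = as.numeric(quantile(d, radius_quantile)),
                 project = emb$project, radius_quantile = radius_quantile),
            class = "stopping_state")
}

#' Geometric stopping decision for one queried batch
#'
#' Counts how many of the newly queried points fall *outside* the circle
#' (center `O`, radius `r`) around the embedded labeled pool. A count above
#' the threshold `T = n_classes / 2` means the batch still differs from what
#' the model has seen — keep training. A count below `T` means the queries
#' have converged onto known territory — stop. An exact tie (`count == T`,
#' possible only for even class counts since `T` is fractional otherwise)
#' continues: training more is the safe side of the tie.
#'
#' @param state a `stopping_state` from [compute_center_radius()].
#' @param batch_points 2-D coordinates of the queried batch (already
#'   projected via `state$project`).
#' @param n_classes number of classes `n`; the threshold is `n/2`.
#' @param T_override explicit threshold, replacing `n/2`.
#' @return list with `stop` (logical), `n_outside` and `threshold`.
#' @export
should_stop <- function(state, batch_points, n_classes, T_override = NULL) {
  if (!inherits(state, "stopping_state"))
    stop("`state` must come from compute_center_radius()", call. = FALSE)
  pts <- matrix(as.numeric(batch_points), ncol = 2L)
  if (nrow(pts) == 0L) stop("batch must be non-empty", call. = FALSE)
  Tt <- if (is.null(T_override)) n_classes / 2 else T_override
  if (Tt <= 0) stop("threshold must be > 0", call. = FALSE)
  d <- sqrt(rowSums(sweep(pts, 2L, state$center)^2))
  n_out <- sum(d > state$radius)
  list(stop = n_out < Tt, n_outside = n_out, threshold = Tt)
}

#' Configuration of an AL run
#'
#' @param batch_size samples queried per iteration (default 10).
#' @param max_iterations cap on query iterations (default: until the pool
#'   cannot fill another batch).
#' @param stop_mode `"none"` (run to exhaustion, recording the stopping
#'   diagnostics), `"threshold"` (geometric stopping evaluator), or
#'   `"oracle_best"` (stop when test accuracy first reaches
#'   `target_accuracy`; requires knowing the full-data ceiling, so it is a
#'   benchmarking mode, not a field mode).
#' @param target_accuracy accuracy target for `"oracle_best"`.
#' @param radius_quantile quantile defining the stopping radius.
#' @param T_override explicit stopping threshold instead of `n/2`.
#' @param patience consecutive sub-threshold batches required to stop.
#' @param mislabel_rate supervisor corruption rate.
#' @param compute_auc whether to compute macro AUC each iteration.
#' @param seed integer seed driving classifier fits, query randomness and the
#'   oracle.
#' @return list of class `al_config`.
#' @export
al_config <- function(batch_size = 10L, max_iterations = Inf,
                      stop_mode = c("none", "threshold", "oracle_best"),
                      target_accuracy = NULL, radius_quantile = 0.95,
                      T_override = NULL, patience = 1L, mislabel_rate = 0,
                      compute_auc = TRUE, seed = 1L) {
  stop_mode <- match.arg(stop_mode)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (stop_mode == "oracle_best" && is.null(target_accuracy))
    stop("`oracle_best` mode needs `target_accuracy`", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 max_iterations = max_iterations, stop_mode = stop_mode,
                 target_accuracy = target_accuracy,
                 radius_quantile = radius_quantile, T_override = T_override,
                 patience = as.integer(patience),
                 mislabel_rate = mislabel_rate, compute_auc = compute_auc,
                 seed = as.integer(seed)),
            class = "al_config")
}

#' Run the active-learning loop
#'
#' Implements the (L, C, Q, U, S) cycle: train the classifier on the labeled
#' pool, score the unlabeled pool with the query strategy (reweighted by the
#' bias constraint when enabled), query a batch, obtain labels from the
#' simulated supervisor, move the batch from `U` to `L`, retrain and
#' evaluate. Every iteration also embeds the current labeled pool, projects
#' the queried batch and records how many batch points fall outside the
#' stopping radius, so threshold stopping can be applied live
#' (`stop_mode = "threshold"`) or analyzed after the fact
#' ([apply_threshold_stop()]).
#'
#' When the threshold rule fires, the pending batch is *not* sent to the
#' supervisor — those labels are the ones the rule saves — so `EA` is the
#' labeled count before that batch.
#'
#' @param dataset an `al_dataset` from [make_dataset()].
#' @param classifier an [al_classifier()] (default [rf_classifier()]).
#' @param strategy query strategy, see [select_batch()].
#' @param bias_constraint recompute [compute_bias_weights()] before every
#'   query round and multiply them into the score?
#' @param config an [al_config()].
#' @param embedding embedding constructor for weights and stopping.
#' @param committee_size committee size for `qbc`.
#' @param density_bandwidth bandwidth for `density_weighted`; default is the
#'   median pairwise Manhattan distance of the pool features.
#' @return object of class `al_run`: list with `history` (one row per
#'   iteration: `iteration`, `labeled_count`, `test_accuracy`,
#'   `test_macro_auc`, `n_outside`), `selected` (ids per iteration), `EA`,
#'   `FS`, `stopped_at` (`NA` if no rule fired), `strategy`,
#'   `bias_constraint` and the `config`.
#' @export
run_al <- function(dataset, classifier = rf_classifier(),
                   strategy = "margin", bias_constraint = FALSE,
                   config = al_config(), embedding = pca_embedding,
                   committee_size = 5L, density_bandwidth = NULL) {
  stopifnot(inherits(dataset, "al_dataset"), inherits(config, "al_config"))
  L <- dataset$labeled
  U <- dataset$pool
  test <- dataset$test
  lv <- levels(L$y)
  n_classes <- length(lv)
  FS <- length(L$ids) + length(U$ids)
  truth <- c(stats::setNames(as.character(L$y), L$ids),
             stats::setNames(as.character(U$y), U$ids))
  truth <- factor(truth, levels = lv)

  fit_and_eval <- function(iter) {
    model <- classifier$fit(L$x, L$y, seed = derive_seed(config$seed, iter))
    ev <- evaluate_model(classifier, model, test)
    list(model = model, ev = ev)
  }

  st <- fit_and_eval(0L)
  history <- data.frame(iteration = 0L, labeled_count = length(L$ids),
                        test_accuracy = st$ev$accuracy,
                        test_macro_auc = if (config$compute_auc)
                          st$ev$macro_auc else NA_real_,
                        n_outside = NA_real_)
  selected <- list()
  stopped_at <- NA_integer_
  consec_below <- 0L
  iter <- 0L

  if (config$stop_mode == "oracle_best" &&
      st$ev$accuracy >= config$target_accuracy) {
    stopped_at <- 0L
  } else {
    while (length(U$ids) >= config$batch_size &&
           iter < config$max_iterations) {
      iter <- iter + 1L
      it_seed <- derive_seed(config$seed, 1000L + iter)

      geo <- compute_center_radius(L$x, embedding = embedding,
                                   radius_quantile = config$radius_quantile,
                                   seed = it_seed)
      post <- NULL; votes <- NULL; dens <- NULL
      if (strategy %in% c("least_confident", "margin", "entropy",
                          "density_weighted"))
        post <- classifier$predict_posteriors(st$model, U$x)
      if (strategy == "qbc")
        votes <- committee_votes(classifier, L, U, committee_size, it_seed, lv)
      if (strategy == "density_weighted") {
        bw <- density_bandwidth
        if (is.null(bw)) {
          bw <- median(dist(U$x, method = "manhattan"))
          if (!is.finite(bw) || bw <= 0) bw <- 1
        }
        dens <- density_weight(U$x, bw)
      }
      w <- if (bias_constraint)
        compute_bias_weights(L$x, U$x, embedding = embedding, seed = it_seed)
      else NULL

      sel <- select_batch(strategy, U$ids, posteriors = post, votes = votes,
                          n_classes = n_classes,
                          batch_size = config$batch_size, weights = w,
                          density = dens, seed = it_seed)
      idx <- match(sel$selected_ids, U$ids)
      geo_check <- should_stop(geo, geo$project(U$x[idx, , drop = FALSE]),
                               n_classes, T_override = config$T_override)
      consec_below <- if (geo_check$stop) consec_below + 1L else 0L

      if (config$stop_mode == "threshold" &&
          consec_below >= config$patience) {
        stopped_at <- iter
        # record the decision; the pending batch is never labeled
        history <- rbind(history,
                         data.frame(iteration = iter,
                                    labeled_count = length(L$ids),
                                    test_accuracy = st$ev$accuracy,
                                    test_macro_auc = tail(history$test_macro_auc, 1L),
                                    n_outside = geo_check$n_outside))
        break
      }

      lab <- simulated_oracle(sel$selected_ids, truth,
                              mislabel_rate = config$mislabel_rate,
                              seed = it_seed)
      L$x <- rbind(L$x, U$x[idx, , drop = FALSE])
      L$y <- factor(c(as.character(L$y), as.character(lab)), levels = lv)
      L$ids <- c(L$ids, sel$selected_ids)
      U$x <- U$x[-idx, , drop = FALSE]
      U$y <- U$y[-idx]
      U$ids <- U$ids[-idx]
      selected[[iter]] <- sel$selected_ids

      st <- fit_and_eval(iter)
      history <- rbind(history,
                       data.frame(iteration = iter,
                                  labeled_count = length(L$ids),
                                  test_accuracy = st$ev$accuracy,
                                  test_macro_auc = if (config$compute_auc)
                                    st$ev$macro_auc else NA_real_,
                                  n_outside = geo_check$n_outside))
      if (config$stop_mode == "oracle_best" &&
          st$ev$accuracy >= config$target_accuracy) {
        stopped_at <- iter
        break
      }
    }
  }

  EA <- if (config$stop_mode == "threshold" && !is.na(stopped_at))
    history$labeled_count[history$iteration == stopped_at][1L]
  else length(L$ids)
  structure(list(history = history, selected = selected, EA = EA, FS = FS,
                 stopped_at = stopped_at, strategy = strategy,
                 bias_constraint = bias_constraint, config = config),
            class = "al_run")
}

committee_votes <- function(classifier, L, U, committee_size, seed, lv) {
  if (committee_size < 2L) stop("committee needs >= 2 members", call. = FALSE)
  n <- length(L$ids)
  votes <- local_seed(seed, {
    vapply(seq_len(committee_size), function(m) {
      idx <- sample.int(n, n, replace = TRUE)  # query by bagging
      mdl <- classifier$fit(L$x[idx, , drop = FALSE], L$y[idx],
                            seed = sample.int(.Machine$integer.max, 1L))
      p <- classifier$predict_posteriors(mdl, U$x)
      colnames(p)[apply(p, 1L, which.max)]
    }, character(length(U$ids)))
  })
  t(votes)  # members x items
}

#' @export
print.al_run <- function(x, ...) {
  cat(sprintf(
    "<al_run> strategy = %s%s | %d iterations | EA = %d / FS = %d (SR = %.3f)%s\n",
    x$strategy, if (x$bias_constraint) " + bias constraint" else "",
    max(x$history$iteration), x$EA, x$FS, 1 - x$EA / x$FS,
    if (!is.na(x$stopped_at)) sprintf(" | stopped at iteration %d", x$stopped_at)
    else ""))
  invisible(x)
}

#' Labels needed to first reach a target accuracy
#'
#' @param run an `al_run` (any `stop_mode`).
#' @param target target test accuracy.
#' @return the `labeled_count` at the first iteration whose accuracy is >=
#'   `target`; if never reached, the count at the best iteration (with a
#'   warning).
#' @export
labels_to_target <- function(run, target) {
  h <- run$history
  hit <- which(h$test_accuracy >= target)
  if (length(hit) > 0L) return(h$labeled_count[hit[1L]])
  warning("target accuracy never reached; returning labels at best iteration")
  h$labeled_count[which.max(h$test_accuracy)]
}

#' Apply the geometric stopping rule to a recorded run
#'
#' Replays the threshold evaluator on the `n_outside` diagnostics a
#' `stop_mode = "none"` run recorded, returning where a live
#' `stop_mode = "threshold"` run would have stopped and the labels it would
#' have spent. The batch queried at the stopping iteration is not counted:
#' the rule fires before those labels are bought.
#'
#' @param run an `al_run` with recorded `n_outside`.
#' @param n_classes class count (threshold `T = n/2`).
#' @param T_override explicit threshold.
#' @param patience consecutive sub-threshold batches required.
#' @return list with `stopped_at` (iteration, `NA` if the rule never fired),
#'   `EA` (labels spent) and `accuracy` at the stop.
#' @export
apply_threshold_stop <- function(run, n_classes, T_override = NULL,
                                 patience = 1L) {
  h <- run$history
  Tt <- if (is.null(T_override)) n_classes / 2 else T_override
  below <- h$n_outside < Tt  # NA at iteration 0
  consec <- 0L
  for (i in seq_len(nrow(h))) {
    if (isTRUE(below[i])) consec <- consec + 1L else consec <- 0L
    if (consec >= patience) {
      return(list(stopped_at = h$iteration[i],
                  EA = h$labeled_count[i] - run$config$batch_size,
                  accuracy = h$test_accuracy[i - 1L]))
    }
  }
  list(stopped_at = NA_integer_, EA = tail(h$labeled_count, 1L),
       accuracy = tail(h$test_accuracy, 1L))
}
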
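as_posterior_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  p <- as.matrix(p)
  if (ncol(p) < 2L)
    stop("posteriors need at least 2 classes", call. = FALSE)
  if (any(!is.finite(p)) || any(p < -1e-12) ||
      any(abs(rowSums(p) - 1) > 1e-9))
    stop("invalid posterior: entries must be >= 0 and rows sum to 1",
         call. = FALSE)
  pmax(p, 0)
}

#' Least-confident informativeness
#'
#' `1 - max_i p_i`: high when even the model's best guess is improbable.
#' Batch selection takes the largest values.
#'
#' @param p posterior vector, or matrix with one posterior per row.
#' @return numeric score(s) in `[0, 1 - 1/k]`.
#' @export
score_least_confident <- function(p) {
  p <- as_posterior_matrix(p)
  unname(1 - apply(p, 1L, max))
}

#' Margin between the two most probable classes
#'
#' `P(y_hat1 | x) - P(y_hat2 | x)`, the gap between the largest and
#' second-largest posterior. Batch selection takes the *smallest* margins.
#'
#' @inheritParams score_least_confident
#' @return numeric margin(s) in `[0, 1]`.
#' @export
score_margin <- function(p) {
  p <- as_posterior_matrix(p)
  unname(apply(p, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    s[1L] - s[2L]
  }))
}

#' Shannon entropy of the posterior (nats)
#'
#' `-sum_i p_i ln p_i` with `0 ln 0 = 0`. Unlike least-confident and margin,
#' entropy weighs every class. Batch selection takes the largest values.
#'
#' @inheritParams score_least_confident
#' @return numeric entropy in `[0, ln k]` nats.
#' @export
score_entropy <- function(p) {
  p <- as_posterior_matrix(p)
  unname(apply(p, 1L, function(r) {
    r <- r[r > 0]
    -sum(r * log(r))
  }))
}

#' Vote entropy of a committee (query-by-bagging disagreement)
#'
#' For one pool item, committee members trained on bootstrap resamples of the
#' labeled pool each cast a predicted label; disagreement is the entropy of
#' the vote shares, `-sum_y (V(y)/C) ln(V(y)/C)`. Largest = most disagreement.
#'
#' @param votes vector of predicted labels, one per committee member, or a
#'   matrix (members x items).
#' @param k number of classes (used only for validation of the label space).
#' @return disagreement in nats (scalar, or one value per item column).
#' @export
qbc_vote_entropy <- function(votes, k = NULL) {
  if (is.matrix(votes))
    return(apply(votes, 2L, qbc_vote_entropy, k = k))
  if (length(votes) < 2L)
    stop("committee must have >= 2 members", call. = FALSE)
  if (!is.null(k) && length(unique(votes)) > k)
    stop("more distinct votes than classes", call. = FALSE)
  shares <- table(votes) / length(votes)
  -sum(shares * log(shares))
}

#' Kernel density of each pool item (Manhattan metric, Gaussian kernel)
#'
#' `dens_i = mean_j exp(-d(i,j)^2 / (2 h^2))` with `d` the pairwise Manhattan
#' (L1) distance and `h` the bandwidth. In density-weighted selection the
#' density multiplies the informativeness, steering queries toward items that
#' are both uncertain and representative.
#'
#' @param pool_features numeric matrix, rows = pool items.
#' @param bandwidth kernel bandwidth `h` > 0.
#' @return numeric density per item (unitless, positive).
#' @export
density_weight <- function(pool_features, bandwidth) {
  x <- as.matrix(pool_features)
  if (nrow(x) == 0L) stop("pool must be non-empty", call. = FALSE)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be > 0", call. = FALSE)
  d <- as.matrix(dist(x, method = "manhattan"))
  unname(rowMeans(exp(-d^2 / (2 * bandwidth^2))))
}

#' Bias-constraint weights for the unlabeled pool
#'
#' Embeds labeled and pool items jointly in 2-D, takes the centroid `O` of the
#' embedded *labeled* points, measures each pool item's Euclidean distance to
#' `O`, then min-max-normalizes and inverts: `w = 1 - minmax(d)`. The pool
#' item nearest `O` gets weight 1 and the farthest gets 0, so sequences far
#' from everything already labeled — typically heterogeneous noise events that
#' are hard to label and learn — are suppressed in the query score. Weights
#' must be recomputed before every query round as `L` grows.
#'
#' If all pool distances coincide (a degenerate pool), every weight is 1 and
#' bias-constrained selection reduces to unconstrained selection.
#'
#' @param labeled_features feature matrix of the labeled pool (non-empty).
#' @param pool_features feature matrix of the unlabeled pool (non-empty).
#' @param embedding embedding constructor with the [pca_embedding()]
#'   signature.
#' @param seed passed to stochastic embeddings; the default PCA ignores it.
#' @return numeric vector of weights in `[0, 1]`, aligned with pool rows.
#' @export
compute_bias_weights <- function(labeled_features, pool_features,
                                 embedding = pca_embedding, seed = NULL) {
  lab <- as.matrix(labeled_features)
  pool <- as.matrix(pool_features)
  if (nrow(lab) == 0L || nrow(pool) == 0L)
    stop("labeled and pool sets must both be non-empty", call. = FALSE)
  emb <- embedding(rbind(lab, pool), seed = seed)
  pts <- emb$points
  O <- colMeans(pts[seq_len(nrow(lab)), , drop = FALSE])
  pp <- pts[nrow(lab) + seq_len(nrow(pool)), , drop = FALSE]
  d <- sqrt(rowSums(sweep(pp, 2L, O)^2))
  rng <- max(d) - min(d)
  if (!is.finite(rng) || rng < 1e-12) return(rep(1, nrow(pool)))
  1 - (d - min(d)) / rng
}

strategy_names <- function() {
  c("random", "least_confident", "margin", "entropy", "qbc",
    "density_weighted")
}

# Informativeness on a common [0, 1] scale so bias weights compose uniformly.
informativeness <- function(strategy, posteriors = NULL, votes = NULL,
                            n_classes = NULL, density = NULL) {
  need_post <- function() {
    if (is.null(posteriors)) stop("strategy needs posteriors", call. = FALSE)
    as_posterior_matrix(posteriors)
  }
  switch(strategy,
    least_confident = score_least_confident(need_post()),
    margin = 1 - score_margin(need_post()),
    entropy = {
      p <- need_post()
      score_entropy(p) / log(ncol(p))
    },
    qbc = {
      if (is.null(votes) || is.null(n_classes))
        stop("qbc needs committee votes and n_classes", call. = FALSE)
      qbc_vote_entropy(votes, k = n_classes) / log(n_classes)
    },
    density_weighted = {
      p <- need_post()
      if (is.null(density))
        stop("density_weighted needs per-item densities", call. = FALSE)
      (1 - score_margin(p)) * density / max(density)
    },
    stop("unknown strategy: ", strategy, call. = FALSE))
}

#' Select a query batch from the unlabeled pool
#'
#' Converts the chosen strategy into a maximize-informativeness score
#' `I(x)` in `[0, 1]` (margin becomes `1 - margin`, entropy is normalized by
#' `ln k`, vote entropy likewise; density weighting multiplies `1 - margin`
#' by the normalized density). With bias-constraint weights `w` the final
#' score is `w * I(x)`, so with all weights 1 the selection is identical to
#' the unconstrained one. Ties are broken by smallest pool index; the
#' `random` strategy ignores scores and samples uniformly under `seed`.
#'
#' @param strategy one of `random`, `least_confident`, `margin`, `entropy`,
#'   `qbc`, `density_weighted`.
#' @param pool_ids character ids of the unlabeled pool, in pool order.
#' @param posteriors posterior matrix (pool rows) for posterior-based
#'   strategies.
#' @param votes committee vote matrix (members x pool items) for `qbc`.
#' @param n_classes class count (needed by `qbc` and entropy normalization of
#'   vote entropy).
#' @param batch_size number of items to query (default 10).
#' @param weights optional bias-constraint weights from
#'   [compute_bias_weights()].
#' @param density optional densities from [density_weight()] for
#'   `density_weighted`.
#' @param seed integer seed (used by `random` only).
#' @return object of class `query_selection`: list with `selected_ids`
#'   (ordered, length `batch_size`) and `scores` (per-pool-item final score;
#'   `NA` for `random`).
#' @export
select_batch <- function(strategy = strategy_names(), pool_ids,
                         posteriors = NULL, votes = NULL, n_classes = NULL,
                         batch_size = 10L, weights = NULL, density = NULL,
                         seed = 1L) {
  strategy <- match.arg(strategy)
  n <- length(pool_ids)
  if (batch_size < 1L || batch_size > n)
    stop("`batch_size` must lie in [1, pool size]", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != n || any(weights < 0 | weights > 1))
      stop("`weights` must align with the pool and lie in [0, 1]",
           call. = FALSE)
  }
  if (strategy == "random") {
    ids <- local_seed(seed, sample(pool_ids, batch_size))
    return(structure(list(selected_ids = ids, scores = rep(NA_real_, n)),
                     class = "query_selection"))
  }
  info <- informativeness(strategy, posteriors = posteriors, votes = votes,
                          n_classes = n_classes, density = density)
  if (length(info) != n)
    stop("scores do not align with `pool_ids`", call. = FALSE)
  score <- if (is.null(weights)) info else weights * info
  ord <- order(-score, seq_len(n))
  structure(list(selected_ids = pool_ids[ord[seq_len(batch_size)]],
                 scores = score),
            class = "query_selection")
}
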
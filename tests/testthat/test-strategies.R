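test_that("uncertainty scores agree with direct formula oracles", {
  pools <- list(
    c(1, 0, 0),                       # one-hot
    rep(1 / 7, 7),                    # uniform, 7 classes
    c(0.5, 0.5, 0),
    c(0.6, 0.3, 0.1),
    c(0.8, 0.2),
    c(0.25, 0.25, 0.25, 0.25)
  )
  for (p in pools) {
    expect_equal(score_least_confident(p), oracle_least_confident(p),
                 tolerance = 1e-12)
    expect_equal(score_margin(p), oracle_margin(p), tolerance = 1e-12)
    expect_equal(score_entropy(p), oracle_entropy(p), tolerance = 1e-12)
  }
  expect_equal(score_least_confident(c(1, 0, 0)), 0)
  expect_equal(score_least_confident(rep(1 / 7, 7)), 1 - 1 / 7)
  expect_equal(score_margin(c(0.5, 0.5, 0)), 0)
  expect_equal(score_margin(c(1, 0, 0)), 1)
  expect_equal(score_margin(c(0.6, 0.3, 0.1)), 0.3)
  expect_equal(score_entropy(c(1, 0, 0)), 0)
  expect_equal(score_entropy(rep(0.2, 5)), log(5))
  expect_error(score_margin(c(0.6, 0.6)), "posterior")
  expect_error(score_entropy(c(1.2, -0.2)), "posterior")
})

test_that("pool rankings equal exhaustive enumeration", {
  pool <- rbind(c(0.90, 0.05, 0.05),
                c(0.40, 0.35, 0.25),
                c(0.34, 0.33, 0.33),
                c(0.70, 0.20, 0.10),
                c(0.50, 0.45, 0.05),
                c(0.98, 0.01, 0.01))
  lc <- apply(pool, 1, oracle_least_confident)
  mg <- apply(pool, 1, oracle_margin)
  en <- apply(pool, 1, oracle_entropy)
  expect_equal(order(-score_least_confident(pool)), order(-lc))
  expect_equal(order(score_margin(pool)), order(mg))      # smallest margin first
  expect_equal(order(-score_entropy(pool)), order(-en))
})

test_that("binary posteriors rank identically under all three scores", {
  p1 <- withr::with_seed(2, runif(25, 0.5, 1))
  pool <- cbind(p1, 1 - p1)
  expect_equal(order(-score_least_confident(pool)),
               order(-(1 - score_margin(pool))))
  expect_equal(order(-score_entropy(pool)),
               order(-(1 - score_margin(pool))))
})

test_that("vote entropy measures committee disagreement", {
  expect_equal(qbc_vote_entropy(rep("a", 5)), 0)
  expect_equal(qbc_vote_entropy(c("a", "b")), log(2))
  votes <- c("a", "a", "a", "b", "c")
  expect_equal(qbc_vote_entropy(votes, k = 3), oracle_vote_entropy(votes),
               tolerance = 1e-12)
  expect_error(qbc_vote_entropy("a"), "committee")
})

test_that("density weighting favors clustered points", {
  x <- matrix(rep(c(0.5, 0.5), 5), ncol = 2, byrow = TRUE)
  expect_true(all(abs(diff(density_weight(x, 1))) < 1e-12))
  sym <- rbind(c(-1, 0), c(1, 0))
  d <- density_weight(sym, 1)
  expect_equal(d[1], d[2])
  clustered <- rbind(matrix(withr::with_seed(1, rnorm(20, 0, 0.05)),
                            ncol = 2), c(5, 5))
  dens <- density_weight(clustered, 1)
  expect_equal(which.min(dens), 11L)
  expect_error(density_weight(clustered, 0), "bandwidth")
})

test_that("bias weights invert min-max-normalized distance from the centroid", {
  # labeled mass sits at the origin; pool is collinear and equally spaced
  lab <- matrix(rep(c(0, 0), 6), ncol = 2, byrow = TRUE)
  pool <- cbind(0:4, 0)
  w <- compute_bias_weights(lab, pool)
  expect_equal(w, c(1, 0.75, 0.5, 0.25, 0), tolerance = 1e-9)
  # endpoints: nearest 1, farthest 0; all within [0, 1]; monotone in distance
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) < 0))
})

test_that("bias weights handle degenerate pools and random geometry", {
  lab <- matrix(withr::with_seed(3, rnorm(20)), ncol = 2)
  same <- matrix(rep(c(9, 9), 4), ncol = 2, byrow = TRUE)
  expect_equal(compute_bias_weights(lab, same), rep(1, 4))
  pool <- matrix(withr::with_seed(4, rnorm(60)), ncol = 2)
  w <- compute_bias_weights(lab, pool)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(min(w), 0)
  expect_equal(max(w), 1)
  # monotone non-increasing in distance from the embedded labeled centroid
  emb <- pca_embedding(rbind(lab, pool))
  O <- colMeans(emb$points[1:10, ])
  d <- sqrt(rowSums(sweep(emb$points[11:40, ], 2, O)^2))
  expect_equal(order(d), order(-w))
})

test_that("select_batch composes weights with informativeness", {
  pool_ids <- sprintf("p%d", 1:8)
  post <- rbind(c(0.9, 0.05, 0.05), c(0.34, 0.33, 0.33), c(0.5, 0.3, 0.2),
                c(0.4, 0.4, 0.2), c(0.98, 0.01, 0.01), c(0.6, 0.25, 0.15),
                c(0.45, 0.35, 0.2), c(0.7, 0.2, 0.1))
  w <- c(0.1, 0.9, 1, 0.2, 0.5, 0.8, 0.6, 0)
  sel <- select_batch("margin", pool_ids, posteriors = post, batch_size = 3,
                      weights = w)
  # brute-force oracle over all items: score = w * (1 - margin)
  info <- w * (1 - apply(post, 1, oracle_margin))
  expect_equal(sel$selected_ids, pool_ids[order(-info, 1:8)][1:3])

  # weights all zero except one item: that item comes first
  w1 <- c(0, 0, 0, 0, 0, 1, 0, 0)
  sel1 <- select_batch("entropy", pool_ids, posteriors = post,
                       batch_size = 1, weights = w1)
  expect_equal(sel1$selected_ids, "p6")

  # weights of 1 reduce to the unconstrained selection (ablation identity)
  su <- select_batch("margin", pool_ids, posteriors = post, batch_size = 4)
  sw <- select_batch("margin", pool_ids, posteriors = post, batch_size = 4,
                     weights = rep(1, 8))
  expect_identical(su$selected_ids, sw$selected_ids)

  # batch = pool returns everything, in score order
  sall <- select_batch("margin", pool_ids, posteriors = post, batch_size = 8)
  expect_setequal(sall$selected_ids, pool_ids)
  expect_error(select_batch("margin", pool_ids, posteriors = post,
                            batch_size = 9), "batch_size")
})

test_that("ties break toward the smallest pool index and random is seeded", {
  post <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.9, 0.1))
  ids <- c("a", "b", "c")
  sel <- select_batch("margin", ids, posteriors = post, batch_size = 2)
  expect_identical(sel$selected_ids, c("a", "b"))
  r1 <- select_batch("random", ids, posteriors = NULL, batch_size = 2,
                     seed = 7)
  r2 <- select_batch("random", ids, posteriors = NULL, batch_size = 2,
                     seed = 7)
  expect_identical(r1$selected_ids, r2$selected_ids)
})
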
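test_that("the simulated supervisor returns truth and seeded corruptions", {
  truth <- factor(setNames(rep(c("a", "b", "c"), each = 4),
                           sprintf("id%02d", 1:12)))
  expect_identical(simulated_oracle(names(truth), truth),
                   factor(unname(truth), levels = levels(truth)))
  expect_error(simulated_oracle("nope", truth), "unknown ids")
  expect_error(simulated_oracle("id01", truth, mislabel_rate = 1),
               "mislabel_rate")

  big <- factor(setNames(sample(c("a", "b"), 10000, replace = TRUE),
                         sprintf("x%05d", 1:10000)))
  lab <- simulated_oracle(names(big), big, mislabel_rate = 0.1, seed = 5)
  flips <- sum(lab != big)
  iv <- binom99(10000, 0.1)
  expect_gte(flips, iv["lo"])
  expect_lte(flips, iv["hi"])
  # near-total corruption flips almost everything in the binary case
  lab99 <- simulated_oracle(names(big), big, mislabel_rate = 0.99, seed = 5)
  expect_gt(mean(lab99 != big), 0.95)
})

test_that("run length and pool bookkeeping follow the batch arithmetic", {
  ds <- make_dataset(n_labeled = 10, n_pool = 90, n_test = 105, seed = 2)
  run <- run_al(ds, config = al_config(seed = 2, compute_auc = FALSE))
  expect_equal(max(run$history$iteration), 9)
  expect_equal(tail(run$history$labeled_count, 1), 100)
  expect_equal(run$FS, 100)
  expect_equal(run$EA, 100)
  expect_equal(run$history$labeled_count, seq(10, 100, by = 10))
  # no id queried twice, all queried ids came from the pool
  sel <- unlist(run$selected)
  expect_length(sel, 90)
  expect_false(any(duplicated(sel)))
  expect_setequal(sel, ds$pool$ids)
})

test_that("identical config and seed reproduce the run record exactly", {
  ds <- make_dataset(n_labeled = 10, n_pool = 60, n_test = 105, seed = 4)
  cfg <- al_config(seed = 4, max_iterations = 4)
  r1 <- run_al(ds, strategy = "entropy", config = cfg)
  r2 <- run_al(ds, strategy = "entropy", config = cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$selected, r2$selected)
})

test_that("all query strategies drive the loop", {
  ds <- make_dataset(n_labeled = 12, n_pool = 50, n_test = 105, seed = 6)
  for (strat in c("least_confident", "entropy", "qbc", "density_weighted",
                  "random")) {
    run <- run_al(ds, strategy = strat,
                  config = al_config(max_iterations = 2, seed = 6,
                                     compute_auc = FALSE))
    expect_equal(max(run$history$iteration), 2)
    expect_equal(tail(run$history$labeled_count, 1), 32)
  }
})

test_that("a degenerate embedding makes the bias constraint a no-op", {
  ds <- make_dataset(n_labeled = 10, n_pool = 50, n_test = 105, seed = 8)
  collapse_embedding <- function(x, seed = NULL) {
    pts <- matrix(0, nrow = nrow(as.matrix(x)), ncol = 2)
    structure(list(points = pts,
                   project = function(newx)
                     matrix(0, nrow = nrow(matrix(as.numeric(newx),
                                                  ncol = ncol(x))), ncol = 2)),
              class = "nanoal_embedding")
  }
  cfg <- al_config(max_iterations = 3, seed = 8, compute_auc = FALSE)
  r_off <- run_al(ds, bias_constraint = FALSE, config = cfg)
  r_on <- run_al(ds, bias_constraint = TRUE, config = cfg,
                 embedding = collapse_embedding)
  expect_identical(r_off$selected, r_on$selected)
  expect_identical(r_off$history$test_accuracy, r_on$history$test_accuracy)
})

test_that("center and radius match a direct centroid and quantile oracle", {
  identity_embedding <- function(x, seed = NULL) {
    x <- as.matrix(x)
    structure(list(points = x,
                   project = function(newx) matrix(as.numeric(newx),
                                                   ncol = 2)),
              class = "nanoal_embedding")
  }
  # coincident labeled points: radius 0
  same <- matrix(rep(c(2, 3), 5), ncol = 2, byrow = TRUE)
  st0 <- compute_center_radius(same, embedding = identity_embedding)
  expect_equal(st0$radius, 0)
  expect_equal(unname(st0$center), c(2, 3))
  # points on the unit circle, quantile 1: center origin, radius 1
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- cbind(cos(th), sin(th))
  st1 <- compute_center_radius(circ, embedding = identity_embedding,
                               radius_quantile = 1)
  expect_equal(unname(st1$center), c(0, 0), tolerance = 1e-12)
  expect_equal(st1$radius, 1, tolerance = 1e-12)
  # random cloud vs brute-force distances
  cloud <- matrix(withr::with_seed(9, rnorm(60)), ncol = 2)
  st <- compute_center_radius(cloud, embedding = identity_embedding,
                              radius_quantile = 0.95)
  O <- c(mean(cloud[, 1]), mean(cloud[, 2]))
  d <- sqrt((cloud[, 1] - O[1])^2 + (cloud[, 2] - O[2])^2)
  expect_equal(unname(st$center), O)
  expect_equal(st$radius, unname(quantile(d, 0.95)))
  expect_error(compute_center_radius(cloud[1, , drop = FALSE]), ">= 2")
})

test_that("the threshold decision counts points outside the circle", {
  identity_embedding <- function(x, seed = NULL) {
    x <- as.matrix(x)
    structure(list(points = x, project = function(newx)
      matrix(as.numeric(newx), ncol = 2)), class = "nanoal_embedding")
  }
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  st <- compute_center_radius(cbind(cos(th), sin(th)),
                              embedding = identity_embedding,
                              radius_quantile = 1)
  # T = 7/2 = 3.5; 4 points outside -> continue
  batch4 <- rbind(cbind(2 * cos(1:4), 2 * sin(1:4)), matrix(0, 6, 2))
  dec <- should_stop(st, batch4, n_classes = 7)
  expect_false(dec$stop)
  expect_equal(dec$n_outside, 4)
  expect_equal(dec$threshold, 3.5)
  # batch entirely at the center -> 0 outside -> stop
  expect_true(should_stop(st, matrix(0, 10, 2), n_classes = 7)$stop)
  # whole batch at 2r -> 10 outside -> continue for any n <= 19
  far <- cbind(2 * cos(th[1:10]), 2 * sin(th[1:10]))
  for (n in c(7, 19)) expect_false(should_stop(st, far, n_classes = n)$stop)
  # exact tie continues (even class count)
  batch_tie <- rbind(cbind(2 * cos(1:3), 2 * sin(1:3)), matrix(0, 7, 2))
  expect_false(should_stop(st, batch_tie, n_classes = 6)$stop)
})

test_that("live threshold stopping matches the post-hoc replay", {
  ds <- make_dataset(n_labeled = 10, n_pool = 80, n_test = 105, seed = 10)
  r_none <- run_al(ds, config = al_config(stop_mode = "none", seed = 10,
                                          compute_auc = FALSE))
  replay <- apply_threshold_stop(r_none, n_classes = 7)
  r_live <- run_al(ds, config = al_config(stop_mode = "threshold", seed = 10,
                                          compute_auc = FALSE))
  expect_equal(r_live$stopped_at, replay$stopped_at)
  expect_equal(r_live$EA, replay$EA)
})

test_that("accuracy improves from the initial model on almost every seed", {
  gains <- vapply(1:10, function(s) {
    ds <- make_dataset(n_labeled = 10, n_pool = 150, n_test = 150, seed = s)
    run <- run_al(ds, config = al_config(max_iterations = 8, seed = s,
                                         compute_auc = FALSE))
    tail(run$history$test_accuracy, 1) - run$history$test_accuracy[1]
  }, numeric(1))
  expect_gte(sum(gains >= 0), 9)
})
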
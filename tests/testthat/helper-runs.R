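# Memoized AL runs shared by the acceptance blocks: the benchmark conditions
# (7 classes, 600-item pool, 600-item test, init 10, batch 10, seeds 1-10)
# take minutes, so each configuration is computed once per test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE))
    assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache, inherits = FALSE)
}

benchmark_seeds <- 1:10

# margin/random runs to 95%-of-ceiling target on the default dataset
benchmark_target_runs <- function() {
  cached("target_runs", {
    lapply(benchmark_seeds, function(s) {
      ds <- make_dataset(seed = s)
      fa <- full_data_accuracy(ds, seed = s)
      cfg <- al_config(stop_mode = "oracle_best", target_accuracy = 0.95 * fa,
                       seed = s, compute_auc = FALSE, max_iterations = 59)
      list(seed = s, full_accuracy = fa,
           margin = run_al(ds, strategy = "margin", config = cfg),
           random = run_al(ds, strategy = "random", config = cfg))
    })
  })
}

# margin runs with/without the bias constraint at 20% noise contamination
benchmark_bias_runs <- function() {
  cached("bias_runs", {
    lapply(benchmark_seeds, function(s) {
      ds <- make_dataset(noise_fraction = 0.2, seed = s)
      fa <- full_data_accuracy(ds, seed = s)
      cfg <- al_config(stop_mode = "oracle_best", target_accuracy = 0.95 * fa,
                       seed = s, compute_auc = FALSE, max_iterations = 59)
      list(seed = s, full_accuracy = fa,
           bias = run_al(ds, strategy = "margin", bias_constraint = TRUE,
                         config = cfg),
           plain = run_al(ds, strategy = "margin", config = cfg))
    })
  })
}

# full margin learning curves (no stopping) with recorded stop diagnostics
benchmark_full_curves <- function() {
  cached("full_curves", {
    lapply(benchmark_seeds, function(s) {
      ds <- make_dataset(seed = s)
      fa <- full_data_accuracy(ds, seed = s)
      cfg <- al_config(stop_mode = "none", seed = s, compute_auc = FALSE,
                       max_iterations = 59)
      list(seed = s, full_accuracy = fa,
           run = run_al(ds, strategy = "margin", config = cfg))
    })
  })
}
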
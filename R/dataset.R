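#' Build a labeled-seed / unlabeled-pool / test split of simulated events
#'
#' Generates events from `profiles`, assigns each training event the noise
#' class with probability `noise_fraction` (signal classes uniform in the
#' remainder), and splits:
#' \itemize{
#'   \item a labeled seed set of `n_labeled` events drawn uniformly at random
#'     from the training events (the initial pool `L` of an AL run is a plain
#'     random draw, not stratified);
#'   \item the remaining training events as the unlabeled pool `U`;
#'   \item a test set stratified to the same expected class proportions.
#' }
#' Splits are disjoint and the whole dataset is reproducible from
#' (`profiles`, sizes, `seed`).
#'
#' @param profiles list of [class_profile()]s (default [default_rna_profiles()]).
#' @param n_labeled initial labeled pool size (default 10).
#' @param n_pool unlabeled pool size.
#' @param n_test test set size.
#' @param noise_fraction probability a training event is noise-class; the
#'   default gives all classes (noise included) equal weight.
#' @param n_total,props alternative sizing: total event count split by
#'   proportions `c(labeled, pool, test)`, which must sum to 1.
#' @param seed integer seed.
#' @return an `al_dataset`: list with components `labeled`, `pool`, `test`
#'   (each a list of `events`, feature matrix `x`, factor labels `y` and
#'   character `ids`), plus `profiles` and the generating configuration.
#' @export
make_dataset <- function(profiles = default_rna_profiles(),
                         n_labeled = 10L, n_pool = 600L, n_test = 600L,
                         noise_fraction = NULL, n_total = NULL, props = NULL,
                         seed = 1L) {
  if (!is.null(n_total) || !is.null(props)) {
    if (is.null(n_total) || is.null(props) || length(props) != 3L)
      stop("supply both `n_total` and 3 `props`", call. = FALSE)
    if (abs(sum(props) - 1) > 1e-9)
      stop("split proportions must sum to 1", call. = FALSE)
    n_labeled <- round(n_total * props[1L])
    n_pool <- round(n_total * props[2L])
    n_test <- n_total - n_labeled - n_pool
  }
  shapes <- vapply(profiles, `[[`, "", "shape")
  has_noise <- any(shapes == "noise-heterogeneous")
  if (is.null(noise_fraction))
    noise_fraction <- if (has_noise) sum(shapes == "noise-heterogeneous") /
                        length(profiles) else 0
  if (noise_fraction > 0 && !has_noise)
    stop("noise_fraction > 0 but no noise-heterogeneous profile", call. = FALSE)
  class_ids <- vapply(profiles, `[[`, "", "class_id")
  # expected class proportions: noise_fraction to noise, uniform on the rest
  p_class <- ifelse(shapes == "noise-heterogeneous",
                    noise_fraction / max(1, sum(shapes == "noise-heterogeneous")),
                    (1 - noise_fraction) / sum(shapes != "noise-heterogeneous"))
  n_train <- n_labeled + n_pool
  if (n_train < 1L || n_test < 1L)
    stop("all split sizes must be >= 1", call. = FALSE)

  local_seed(seed, {
    train_cls <- sample(seq_along(profiles), n_train, replace = TRUE,
                        prob = p_class)
    # stratified test counts at the same proportions, largest-remainder rounding
    raw <- n_test * p_class
    cnt <- floor(raw)
    rem <- n_test - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    if (any(cnt[p_class > 0] < 2L))
      stop("stratification error: a class would get < 2 test instances",
           call. = FALSE)
    test_cls <- sample(rep(seq_along(profiles), cnt))

    make_events <- function(cls, prefix) {
      ev <- lapply(cls, function(k) nanopore_event(gen_event(profiles[[k]]),
                                                   true_label = class_ids[k]))
      names(ev) <- sprintf("%s%05d", prefix, seq_along(ev))
      ev
    }
    train_ev <- make_events(train_cls, "tr")
    test_ev <- make_events(test_cls, "te")

    lab_idx <- sample.int(n_train, n_labeled)
    bundle <- function(ev, cls) {
      list(events = ev, x = feature_matrix(ev),
           y = factor(class_ids[cls], levels = class_ids),
           ids = names(ev))
    }
    structure(list(
      labeled = bundle(train_ev[lab_idx], train_cls[lab_idx]),
      pool = bundle(train_ev[-lab_idx], train_cls[-lab_idx]),
      test = bundle(test_ev, test_cls),
      profiles = profiles,
      config = list(n_labeled = n_labeled, n_pool = n_pool, n_test = n_test,
                    noise_fraction = noise_fraction, seed = seed)
    ), class = "al_dataset")
  })
}

#' @export
print.al_dataset <- function(x, ...) {
  cat(sprintf("<al_dataset> labeled %d | pool %d | test %d | classes: %s\n",
              length(x$labeled$ids), length(x$pool$ids), length(x$test$ids),
              paste(levels(x$labeled$y), collapse = ", ")))
  invisible(x)
}

#' Write events as one-record-per-event columnar text
#'
#' Format: tab-separated `id`, `label` (`.` when unknown) and the samples as
#' one comma-separated field. A JSON manifest with the generating
#' configuration can be written alongside via [write_manifest()].
#'
#' @param events named list of [nanopore_event()]s.
#' @param path output file.
#' @export
write_events <- function(events, path) {
  ids <- names(events)
  if (is.null(ids)) ids <- sprintf("ev%05d", seq_along(events))
  lines <- vapply(seq_along(events), function(i) {
    e <- events[[i]]
    lab <- if (is.null(e$true_label)) "." else as.character(e$true_label)
    paste(ids[i], lab, paste(sprintf("%.8g", e$samples), collapse = ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read events written by [write_events()]
#'
#' @param path input file.
#' @return named list of [nanopore_event()]s (label `.` read as `NULL`).
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ev <- lapply(parts, function(p) {
    if (length(p) != 3L) stop("malformed event record", call. = FALSE)
    nanopore_event(as.numeric(strsplit(p[3L], ",", fixed = TRUE)[[1L]]),
                   true_label = if (p[2L] == ".") NULL else p[2L])
  })
  names(ev) <- vapply(parts, `[[`, "", 1L)
  ev
}

#' Write a JSON manifest of configuration + seed next to a dataset or run
#'
#' @param config named list (must be JSON-representable).
#' @param path output file.
#' @export
write_manifest <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
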
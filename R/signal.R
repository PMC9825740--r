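#' Normalize a raw current trace by the open-pore current
#'
#' @param raw numeric vector of raw currents.
#' @param open_pore_current the open-pore current in the same units, > 0.
#' @param source_id optional identifier carried onto the trace.
#' @return a [signal_trace()] of blockade fractions, clipped to \[0, 1.2\]
#'   (transient overshoots above the open-pore level are retained up to 20%).
#' @export
normalize_trace <- function(raw, open_pore_current, source_id = NULL) {
  if (!is.numeric(open_pore_current) || length(open_pore_current) != 1L ||
      open_pore_current <= 0)
    stop("`open_pore_current` must be a single positive number", call. = FALSE)
  signal_trace(pmin(pmax(as.numeric(raw) / open_pore_current, 0), 1.2),
               source_id = source_id)
}

#' Segment a trace into blockade events by thresholding
#'
#' Extracts the maximal runs of consecutive samples strictly below
#' `open_pore_threshold`; runs shorter than `min_event_len` are discarded.
#' Coordinates are 0-based and half-open, so an event's length equals
#' `end - start` and abutting events never share a sample.
#'
#' @param trace a [signal_trace()] or numeric vector.
#' @param open_pore_threshold threshold in (0, 1); samples below it count as
#'   blocked.
#' @param min_event_len minimum run length kept, >= 1.
#' @return list of [nanopore_event()]s in trace order (possibly empty).
#' @export
segment_trace <- function(trace, open_pore_threshold = 0.985,
                          min_event_len = 10L) {
  x <- event_samples(trace)
  if (length(x) == 0L) stop("cannot segment an empty trace", call. = FALSE)
  if (open_pore_threshold <= 0 || open_pore_threshold >= 1)
    stop("`open_pore_threshold` must lie in (0, 1)", call. = FALSE)
  if (min_event_len < 1L) stop("`min_event_len` must be >= 1", call. = FALSE)
  src <- if (inherits(trace, "signal_trace")) trace$source_id else NULL
  r <- rle(x < open_pore_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_event_len
  lapply(which(keep), function(i)
    nanopore_event(x[(starts[i] + 1L):ends[i]],
                   parent_id = if (is.null(src)) "trace" else src,
                   start = starts[i], end = ends[i]))
}

#' Pad (or truncate) an event to a fixed-length model input
#'
#' Events shorter than `target_len` are padded at the end with i.i.d.
#' Gaussian noise (`mu = 0`, `sigma = 0.072` by default); the copied prefix is
#' bit-identical to the event samples. Events longer than `target_len` keep
#' their first `target_len` samples — the head is kept because the identity
#' of a barcode train is front-loaded (the start delimiter peak comes first).
#'
#' @param event a [nanopore_event()] or numeric vector.
#' @param target_len output length, >= 1 (default 700).
#' @param mu,sigma parameters of the Gaussian padding noise.
#' @param seed integer seed for the padding tail.
#' @return numeric vector of length exactly `target_len`.
#' @export
pad_to_length <- function(event, target_len = 700L, mu = 0, sigma = 0.072,
                          seed = 1L) {
  x <- event_samples(event)
  if (target_len < 1L) stop("`target_len` must be >= 1", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  n <- length(x)
  if (n >= target_len) return(x[seq_len(target_len)])
  c(x, local_seed(seed, rnorm(target_len - n, mu, sigma)))
}
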
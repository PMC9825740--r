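#' Construct a signal trace
#'
#' A trace is a raw, uninterrupted sequence of normalized blockade-current
#' samples (1 = open pore, 0 = fully blocked).
#'
#' @param samples numeric vector of blockade fractions; non-empty, finite.
#' @param source_id optional identifier.
#' @return object of class `signal_trace`.
#' @export
signal_trace <- function(samples, source_id = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("trace samples must all be finite", call. = FALSE)
  structure(list(samples = samples, source_id = source_id),
            class = "signal_trace")
}

#' Construct an event (one molecule translocation)
#'
#' An event is a contiguous sub-sequence of blockade samples. When it came out
#' of a parent trace, `start`/`end` locate it there with 0-based, half-open
#' coordinates, so `end - start == length(samples)` always holds.
#'
#' @param samples numeric blockade samples.
#' @param parent_id identifier of the parent trace, or `NULL`.
#' @param start,end 0-based half-open coordinates in the parent (or `NA`).
#' @param true_label ground-truth class label, or `NULL` when unknown.
#' @return object of class `nanopore_event`.
#' @export
nanopore_event <- function(samples, parent_id = NULL, start = NA_integer_,
                           end = NA_integer_, true_label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("event must be non-empty", call. = FALSE)
  if (!is.null(parent_id)) {
    if (is.na(start) || is.na(end) || end <= start)
      stop("events with a parent need 0-based half-open [start, end), end > start",
           call. = FALSE)
    if (end - start != length(samples))
      stop("event length must equal end - start", call. = FALSE)
  }
  structure(list(samples = samples, parent_id = parent_id,
                 start = as.integer(start), end = as.integer(end),
                 true_label = true_label),
            class = "nanopore_event")
}

#' @export
print.nanopore_event <- function(x, ...) {
  cat(sprintf("<nanopore_event> %d samples, label = %s\n",
              length(x$samples),
              if (is.null(x$true_label)) "<none>" else x$true_label))
  invisible(x)
}

#' @export
length.nanopore_event <- function(x) length(x$samples)

event_samples <- function(x) {
  if (inherits(x, "nanopore_event")) x$samples
  else if (inherits(x, "signal_trace")) x$samples
  else as.numeric(x)
}
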
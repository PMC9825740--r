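#' Names of the 11 per-event features, in their fixed column order
#'
#' The feature set is declared centrally so every producer and consumer (the
#' extractor, feature tables on disk, importance reports) agrees on order:
#' `length`, `mean`, `median`, `std`, `min`, `max`, `range`, `skewness`,
#' `kurtosis`, `noise`, `area`. `noise` is the standard deviation of
#' consecutive-sample first differences (a high-frequency noise proxy);
#' `area` is the plain sum of samples (blockade x samples); `kurtosis` is
#' excess kurtosis (normal -> 0). Moments use population (n) denominators.
#'
#' @return character vector of length 11.
#' @export
feature_names <- function() {
  c("length", "mean", "median", "std", "min", "max", "range",
    "skewness", "kurtosis", "noise", "area")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract the 11-statistic feature vector of one event
#'
#' Statistics are computed on the raw (unpadded) event samples. For constant
#' signals the standardized moments are 0/0; they are defined as 0 there so
#' every field is finite for any event of length >= 2.
#'
#' @param event a [nanopore_event()], [signal_trace()] or numeric vector of
#'   length >= 2.
#' @return named numeric vector of length 11, ordered as [feature_names()].
#' @export
extract_features <- function(event) {
  x <- event_samples(event)
  if (length(x) < 2L)
    stop("feature extraction needs events of length >= 2", call. = FALSE)
  if (!all(is.finite(x)))
    stop("event samples must all be finite", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 1e-24) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-24) mean((x - m)^4) / m2^2 - 3 else 0
  d <- diff(x)
  out <- c(length(x), m, median(x), sqrt(m2), min(x), max(x),
           max(x) - min(x), skew, kurt, pop_sd(d), sum(x))
  names(out) <- feature_names()
  out
}

#' Feature matrix for a list of events
#'
#' @param events list of events acceptable to [extract_features()].
#' @return numeric matrix, `length(events)` x 11, rows in input order,
#'   columns ordered as [feature_names()]. Invalid events are reported
#'   together, by position (and id, when events carry one).
#' @export
feature_matrix <- function(events) {
  if (length(events) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = 11L)
    colnames(m) <- feature_names()
    return(m)
  }
  rows <- vector("list", length(events))
  bad <- character(0)
  for (i in seq_along(events)) {
    r <- tryCatch(extract_features(events[[i]]), error = function(e) e)
    if (inherits(r, "error")) {
      id <- names(events)[i]
      bad <- c(bad, if (!is.null(id) && nzchar(id)) id else as.character(i))
    } else rows[[i]] <- r
  }
  if (length(bad) > 0L)
    stop("invalid events: ", paste(bad, collapse = ", "), call. = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- names(events)
  m
}
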
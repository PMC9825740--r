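# Shape generators draw from the RNG stream of the caller; public entry
# points wrap them in local_seed() so a (profile, seed) pair is reproducible.

gen_dwell <- function(profile) {
  n <- round(rlnorm(1L, meanlog = log(profile$dwell_mean),
                    sdlog = profile$dwell_dispersion))
  max(10L, as.integer(n))
}

gen_flat <- function(profile, n) {
  rnorm(n, profile$level_mean, profile$level_sd)
}

gen_multilevel <- function(profile, n) {
  k <- sample(2:3, 1L)
  offsets <- rnorm(k, 0, profile$sublevel_spread)
  # random segment lengths summing to n (each >= 1)
  cuts <- sort(sample(seq_len(n - 1L), k - 1L))
  lens <- diff(c(0L, cuts, n))
  unlist(lapply(seq_len(k), function(j)
    rnorm(lens[j], profile$level_mean + offsets[j], profile$level_sd)))
}

# "strange shapes": spike train, drifting ramp, or bounded random walk
gen_noise <- function(profile, n) {
  kind <- sample(c("spike", "ramp", "walk"), 1L)
  switch(kind,
    spike = {
      base <- runif(1L, 0.6, 0.9)
      x <- rnorm(n, base, 0.02)
      n_spikes <- rpois(1L, lambda = max(1, n / 30))
      if (n_spikes > 0L) {
        pos <- sample.int(n, min(n_spikes, n))
        for (p in pos) {
          w <- sample(2:6, 1L)
          idx <- p:min(n, p + w - 1L)
          x[idx] <- x[idx] - runif(1L, 0.1, 0.7)
        }
      }
      x
    },
    ramp = {
      a <- runif(1L, 0.05, 0.95)
      b <- runif(1L, 0.05, 0.95)
      seq(a, b, length.out = n) + rnorm(n, 0, 0.03)
    },
    walk = {
      x <- runif(1L, 0.1, 0.9) + cumsum(rnorm(n, 0, 0.03))
      # reflect into [0.05, 0.95]
      x <- 0.05 + abs((x - 0.05) %% 1.8)
      x[x > 0.95] <- 1.9 - x[x > 0.95]
      x
    })
}

gen_event <- function(profile) {
  n <- gen_dwell(profile)
  s <- switch(profile$shape,
              "flat"                = gen_flat(profile, n),
              "multi-level"         = gen_multilevel(profile, n),
              "noise-heterogeneous" = gen_noise(profile, n))
  pmax(s, 0)
}

#' Simulate one blockade event from a class profile
#'
#' Draws a dwell length from the profile's log-normal dwell distribution and
#' fills it with samples from the profile's shape generator (see
#' [class_profile()]). Noise-class events pick one of three heterogeneous
#' shape generators per event. Samples are floored at 0 (a blockade cannot be
#' deeper than a fully occluded pore).
#'
#' @param profile a [class_profile()].
#' @param seed integer; fixes all randomness of this event.
#' @return a [nanopore_event()] carrying `true_label = profile$class_id`.
#' @export
simulate_rna_event <- function(profile, seed) {
  if (!inherits(profile, "class_profile"))
    stop("`profile` must be a class_profile", call. = FALSE)
  s <- local_seed(seed, gen_event(profile))
  nanopore_event(s, true_label = profile$class_id)
}

#' Simulate a long trace of events separated by open-pore baseline
#'
#' Concatenates open-pore baseline stretches (level `baseline_level`, noise
#' `baseline_sd`) with blockade events drawn from `profiles`. Each event is a
#' noise-class event with probability `noise_fraction`, otherwise a uniformly
#' chosen signal class. Event samples are capped at `event_ceiling` so the
#' events stay strictly below the open-pore level and the returned boundary
#' list is exactly recoverable by thresholding.
#'
#' @param profiles list of [class_profile()]s; must contain exactly one
#'   `noise-heterogeneous` profile when `noise_fraction > 0`.
#' @param n_events number of events, >= 1.
#' @param noise_fraction probability an event is noise-class, in \[0, 1\].
#' @param baseline_level open-pore level (blockade fraction, near 1).
#' @param baseline_sd baseline noise sd; 0 gives a noiseless baseline.
#' @param gap_mean median baseline gap length in samples.
#' @param event_ceiling upper cap applied to event samples.
#' @param seed integer seed.
#' @return list with `trace` (a [signal_trace()]) and `events`, a data.frame
#'   of 0-based half-open `(start, end, label)` ground-truth boundaries.
#' @export
simulate_long_trace <- function(profiles, n_events, noise_fraction = 0,
                                baseline_level = 1.0, baseline_sd = 0,
                                gap_mean = 60, event_ceiling = 0.97,
                                seed = 1L) {
  if (n_events < 1) stop("`n_events` must be >= 1", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("`noise_fraction` must lie in [0, 1]", call. = FALSE)
  shapes <- vapply(profiles, `[[`, "", "shape")
  signal <- profiles[shapes != "noise-heterogeneous"]
  noisep <- profiles[shapes == "noise-heterogeneous"]
  if (noise_fraction > 0 && length(noisep) != 1L)
    stop("need exactly one noise-heterogeneous profile when noise_fraction > 0",
         call. = FALSE)
  if (length(signal) == 0L) stop("need at least one signal profile", call. = FALSE)

  local_seed(seed, {
    is_noise <- rbinom(n_events, 1L, noise_fraction) == 1L
    pieces <- vector("list", 2L * n_events + 1L)
    bounds <- data.frame(start = integer(n_events), end = integer(n_events),
                         label = character(n_events))
    pos <- 0L
    gap <- function() {
      n <- max(5L, as.integer(round(rlnorm(1L, log(gap_mean), 0.3))))
      rnorm(n, baseline_level, baseline_sd)
    }
    for (i in seq_len(n_events)) {
      g <- gap()
      prof <- if (is_noise[i]) noisep[[1L]]
              else signal[[sample.int(length(signal), 1L)]]
      ev <- pmin(gen_event(prof), event_ceiling)
      pieces[[2L * i - 1L]] <- g
      pieces[[2L * i]] <- ev
      pos <- pos + length(g)
      bounds$start[i] <- pos
      pos <- pos + length(ev)
      bounds$end[i] <- pos
      bounds$label[i] <- prof$class_id
    }
    pieces[[2L * n_events + 1L]] <- gap()
    list(trace = signal_trace(unlist(pieces)), events = bounds)
  })
}

#' Simulate a 3-bit barcode peak train
#'
#' Builds the trace as: start delimiter peak, then one slot per bit (a peak
#' for '1', baseline for '0'), then an end delimiter peak — so the first peak
#' marks the beginning and the last peak the end of the code. Gap and peak
#' widths are jittered by +/-20% per molecule, giving variable-length traces
#' that are guaranteed to fit in 700 samples before padding.
#'
#' @param spec a [barcode_spec()].
#' @param seed integer seed.
#' @param baseline baseline (inter-peak) level, blockade fraction.
#' @param noise_sd sample noise sd; 0 gives a noiseless trace.
#' @return a [nanopore_event()] with `true_label = spec$bits`.
#' @export
simulate_barcode_trace <- function(spec, seed, baseline = 0.2,
                                   noise_sd = 0.02) {
  if (!inherits(spec, "barcode_spec"))
    stop("`spec` must be a barcode_spec", call. = FALSE)
  # worst case: 5 peaks + 4 gaps at +20% jitter + 20 samples lead/tail
  worst <- ceiling(5 * 1.2 * spec$peak_width + 4 * 1.2 * spec$gap) + 20L
  if (worst > 700L)
    stop("spec peaks/gaps cannot exceed 700 samples before padding",
         call. = FALSE)
  local_seed(seed, {
    jit <- function(w) max(1L, as.integer(round(w * runif(1L, 0.8, 1.2))))
    peak <- function() rnorm(jit(spec$peak_width), spec$peak_height, noise_sd)
    flat <- function(w) rnorm(w, baseline, noise_sd)
    slots <- strsplit(spec$bits, "")[[1L]]
    pieces <- list(flat(10L), peak())
    for (b in slots) {
      w <- jit(spec$gap)
      pieces <- c(pieces, list(flat(w)),
                  if (b == "1") list(peak()) else list(flat(jit(spec$peak_width))))
    }
    pieces <- c(pieces, list(flat(jit(spec$gap))), list(peak()), list(flat(10L)))
    s <- pmin(pmax(unlist(pieces), 0), 1)
    nanopore_event(s[seq_len(min(length(s), 700L))], true_label = spec$bits)
  })
}
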
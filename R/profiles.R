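#' Describe one simulated signal class
#'
#' A class profile fixes the class-conditional distribution of blockade events:
#' where the blockade level sits (as a fraction of the open-pore current, 0 =
#' fully blocked, 1 = open pore), how noisy the level is, and how long the
#' molecule dwells in the pore. The `shape` selects the generator:
#' \describe{
#'   \item{`flat`}{i.i.d. Gaussian samples around `level_mean`.}
#'   \item{`multi-level`}{2-3 sub-levels around `level_mean` (offsets of scale
#'     `sublevel_spread`), visited in random-length segments; the event mean
#'     then varies event-to-event, which makes classes with nearby levels
#'     genuinely confusable.}
#'   \item{`noise-heterogeneous`}{one of three strange-shape generators per
#'     event: a spike train, a drifting ramp, or a bounded random walk.}
#' }
#'
#' @param class_id character label attached to simulated events.
#' @param level_mean blockade fraction in \[0, 1\].
#' @param level_sd within-event sample noise (blockade fraction), > 0.
#' @param dwell_mean typical event length in samples (>= 10). Dwell lengths are
#'   log-normal (positive, right-skewed, the standard model for pore dwell
#'   times) with median `dwell_mean` and log-scale spread `dwell_dispersion`.
#' @param dwell_dispersion sdlog of the dwell distribution.
#' @param shape generator, see above.
#' @param sublevel_spread sd of the sub-level offsets used by `multi-level`.
#' @return an object of class `class_profile`.
#' @seealso [default_rna_profiles()], [simulate_rna_event()]
#' @export
class_profile <- function(class_id, level_mean, level_sd, dwell_mean,
                          dwell_dispersion = 0.3,
                          shape = c("flat", "multi-level",
                                    "noise-heterogeneous"),
                          sublevel_spread = 0.08) {
  shape <- match.arg(shape)
  if (!is.character(class_id) || length(class_id) != 1L || !nzchar(class_id))
    stop("`class_id` must be a non-empty string", call. = FALSE)
  if (!is.numeric(level_mean) || level_mean < 0 || level_mean > 1)
    stop("`level_mean` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(level_sd) || level_sd <= 0)
    stop("`level_sd` must be > 0", call. = FALSE)
  if (!is.numeric(dwell_mean) || dwell_mean < 10)
    stop("`dwell_mean` must be >= 10 samples", call. = FALSE)
  if (!is.numeric(dwell_dispersion) || dwell_dispersion < 0)
    stop("`dwell_dispersion` must be >= 0", call. = FALSE)
  structure(list(class_id = class_id, level_mean = level_mean,
                 level_sd = level_sd, dwell_mean = dwell_mean,
                 dwell_dispersion = dwell_dispersion, shape = shape,
                 sublevel_spread = sublevel_spread),
            class = "class_profile")
}

#' Default 7-class profile set (6 signal classes + 1 noise class)
#'
#' Six blockade-level classes at level means 0.2, 0.35, 0.5, 0.6, 0.75, 0.9
#' plus a heterogeneous noise class. The 0.5 and 0.6 classes are deliberately
#' close and use the `multi-level` shape, so their event means overlap and the
#' classifier has a genuinely confusable pair to learn — the situation where
#' uncertainty sampling earns its keep.
#'
#' @return named list of seven [class_profile()] objects; the noise class is
#'   named `"noise"`.
#' @export
default_rna_profiles <- function() {
  p <- list(
    class_profile("t1",    0.20, 0.050, 120),
    class_profile("t2",    0.35, 0.050, 150),
    class_profile("t3",    0.50, 0.060, 180, shape = "multi-level"),
    class_profile("t4",    0.60, 0.060, 180, shape = "multi-level"),
    class_profile("t5",    0.75, 0.050, 140),
    class_profile("t6",    0.90, 0.040, 100),
    class_profile("noise", 0.50, 0.060, 150, shape = "noise-heterogeneous")
  )
  names(p) <- vapply(p, `[[`, "", "class_id")
  p
}

#' Describe one 3-bit barcode molecule
#'
#' A barcode trace is a train of upward current peaks between a start and an
#' end delimiter peak; each of the three bit slots carries a peak for a '1'
#' and stays at baseline for a '0', so the eight codes '000'-'111' are
#' distinguishable by counting peaks and their slots.
#'
#' @param bits 3-character string over `{0,1}`.
#' @param peak_height peak level as a blockade fraction.
#' @param peak_width nominal peak width in samples.
#' @param gap nominal baseline gap between peaks, samples.
#' @return an object of class `barcode_spec`.
#' @export
barcode_spec <- function(bits, peak_height = 0.8, peak_width = 20, gap = 80) {
  if (!is.character(bits) || length(bits) != 1L ||
      !grepl("^[01]{3}$", bits))
    stop("`bits` must be a 3-character string over {0,1}", call. = FALSE)
  if (peak_height <= 0 || peak_height > 1)
    stop("`peak_height` must lie in (0, 1]", call. = FALSE)
  if (peak_width < 1 || gap < 1)
    stop("`peak_width` and `gap` must be >= 1 sample", call. = FALSE)
  structure(list(bits = bits, peak_height = peak_height,
                 peak_width = peak_width, gap = gap),
            class = "barcode_spec")
}
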
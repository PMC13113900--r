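#' Construct a waveform object
#'
#' A waveform is a single-channel transient recording (typically a
#' light-adapted electroretinogram epoch, ~200-300 ms at 2 kHz) together
#' with its acquisition metadata. Amplitudes are in microvolts for raw
#' input and dimensionless after [normalize()].
#'
#' @param samples Numeric vector of amplitudes, ordered by time.
#' @param sampling_rate Sampling rate in Hz (default 2000).
#' @param subject_id Subject identifier.
#' @param group Diagnostic group, one of `"ASD"`, `"ADHD"`, `"ASD_ADHD"`,
#'   `"CONTROL"`, `"UNKNOWN"`.
#' @param sex `"M"`, `"F"` or `"UNKNOWN"`.
#' @param eye `"RIGHT"`, `"LEFT"` or `"UNKNOWN"`.
#' @param flash_td Flash strength in Troland-seconds, or `NA`.
#' @param recording_index Integer >= 1 distinguishing repeat recordings of
#'   the same subject/eye/flash combination.
#' @param normalized Logical; `TRUE` once samples lie in `[0, 1]`.
#' @param degenerate Logical; set by [normalize()] when the raw signal was
#'   flat (max equal to min).
#' @return An object of class `erg_waveform`.
#' @export
waveform <- function(samples, sampling_rate = 2000, subject_id = "S1",
                     group = "UNKNOWN", sex = "UNKNOWN", eye = "UNKNOWN",
                     flash_td = NA_real_, recording_index = 1L,
                     normalized = FALSE, degenerate = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform needs at least one sample")
  if (anyNA(samples)) stop("waveform samples must not contain NA")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  group <- match.arg(group, c("ASD", "ADHD", "ASD_ADHD", "CONTROL", "UNKNOWN"))
  sex <- match.arg(sex, c("M", "F", "UNKNOWN"))
  eye <- match.arg(eye, c("RIGHT", "LEFT", "UNKNOWN"))
  recording_index <- as.integer(recording_index)
  if (is.na(recording_index) || recording_index < 1L)
    stop("recording_index must be an integer >= 1")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         n_samples = length(samples), subject_id = as.character(subject_id),
         group = group, sex = sex, eye = eye,
         flash_td = as.numeric(flash_td),
         recording_index = recording_index,
         normalized = isTRUE(normalized), degenerate = isTRUE(degenerate)),
    class = "erg_waveform"
  )
}

#' @exportS3Method base::print
print.erg_waveform <- function(x, ...) {
  cat(sprintf(
    "<erg_waveform> %s [%s] %s eye, flash %s Td.s, recording %d\n",
    x$subject_id, x$group, tolower(x$eye),
    ifelse(is.na(x$flash_td), "?", format(x$flash_td)), x$recording_index))
  cat(sprintf("  %d samples @ %g Hz (%.1f ms)%s%s\n", x$n_samples,
              x$sampling_rate, 1000 * x$n_samples / x$sampling_rate,
              if (x$normalized) ", normalized" else "",
              if (x$degenerate) ", degenerate (flat input)" else ""))
  invisible(x)
}

is_waveform <- function(x) inherits(x, "erg_waveform")

#' Min-max normalize a waveform to [0, 1]
#'
#' Rescales the samples to `x(t) = (x~(t) - min x~) / (max x~ - min x~)` so
#' that graph topology reflects relative amplitude dynamics rather than
#' absolute voltage scale (gain- and impedance-independent). Normalization
#' is strictly per waveform.
#'
#' A flat signal (max equal to min) has no well-defined rescaling; it is
#' mapped to the constant 0.5 and flagged `degenerate`, which downstream
#' graph construction turns into a single-node self-loop graph rather than
#' an error.
#'
#' @param w An `erg_waveform`.
#' @return The waveform with samples in `[0, 1]`, `normalized = TRUE`, and
#'   both bounds attained unless the flat-signal rule fired.
#' @export
normalize <- function(w) {
  stopifnot(is_waveform(w))
  rng <- range(w$samples)
  if (rng[1] == rng[2]) {
    w$samples <- rep(0.5, w$n_samples)
    w$degenerate <- TRUE
  } else {
    w$samples <- (w$samples - rng[1]) / (rng[2] - rng[1])
  }
  w$normalized <- TRUE
  w
}

#' Quantize a normalized waveform into Q amplitude levels
#'
#' Maps each normalized sample to the nearest of `Q` equally spaced levels
#' `{0, 1/(Q-1), ..., 1}`: `q(t) = round(x(t) * (Q-1)) / (Q-1)`. The level
#' spacing `epsilon = 1/(Q-1)` is carried along because it also serves as
#' the self-loop regularizer of the quantization graph's edge weights.
#'
#' Rounding ties (`x * (Q-1)` exactly halfway between integers) are broken
#' half-away-from-zero (0.5 rounds to 1), fixed explicitly so that outputs
#' do not depend on the platform's banker's rounding.
#'
#' @param w A normalized `erg_waveform` (all samples in `[0, 1]`).
#' @param Q Integer >= 2, number of quantization levels.
#' @return An object of class `erg_quantized` with fields `levels`, `Q`,
#'   `epsilon` and `source` (the input waveform).
#' @export
quantize <- function(w, Q) {
  stopifnot(is_waveform(w))
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 2L) stop("Q must be an integer >= 2")
  x <- w$samples
  if (any(x < 0 | x > 1)) stop("quantize() expects a normalized waveform; call normalize() first")
  # round-half-away-from-zero; x*(Q-1) >= 0 so floor(. + 0.5) suffices
  k <- floor(x * (Q - 1) + 0.5)
  structure(
    list(levels = k / (Q - 1), Q = Q, epsilon = 1 / (Q - 1), source = w),
    class = "erg_quantized"
  )
}

#' @exportS3Method base::print
print.erg_quantized <- function(x, ...) {
  cat(sprintf("<erg_quantized> Q = %d (epsilon = %.4g), %d samples, %d distinct levels\n",
              x$Q, x$epsilon, length(x$levels), length(unique(x$levels))))
  invisible(x)
}

is_quantized <- function(x) inherits(x, "erg_quantized")
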
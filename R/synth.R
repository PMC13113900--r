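#' Morphology parameters for the synthetic photopic waveform generator
#'
#' The generator emulates the light-adapted flash electroretinogram as a
#' sum of Gaussian bumps plus a windowed sinusoid: a negative a-wave trough
#' (photoreceptors, ~15 ms), a dominant positive b-wave peak (bipolar
#' cells, ~32 ms), high-frequency oscillatory potentials riding the b-wave
#' rising limb, a late photopic negative response (ganglion cells), and
#' additive Gaussian noise (recordings are averages of band-limited sweeps,
#' so white Gaussian noise at a few percent of the b-wave is a reasonable
#' stand-in).
#'
#' @param a_amp a-wave trough depth, microvolts (> 0).
#' @param a_time,a_width Trough latency and Gaussian width, ms.
#' @param b_amp b-wave peak amplitude, microvolts (> 0, dominant).
#' @param b_time,b_width Peak latency and width, ms.
#' @param op_amp Oscillatory-potential ripple amplitude, microvolts (>= 0).
#' @param op_freq Ripple frequency, Hz (must stay below Nyquist; 120 Hz is
#'   inside the 0.1-300 Hz acquisition band).
#' @param op_time,op_width Centre and width of the ripple window, ms
#'   (defaults place it on the b-wave rising limb).
#' @param phnr_amp,phnr_time,phnr_width Photopic negative response
#'   amplitude (>= 0), latency and width, ms.
#' @param noise_sd Additive Gaussian noise SD, microvolts.
#' @param duration_ms Epoch length, ms (default 250).
#' @param sampling_rate Hz (default 2000).
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(a_amp = 20, a_time = 15, a_width = 4,
                              b_amp = 45, b_time = 32, b_width = 10,
                              op_amp = 6, op_freq = 120, op_time = 22,
                              op_width = 6, phnr_amp = 6, phnr_time = 70,
                              phnr_width = 18, noise_sd = 2,
                              duration_ms = 250, sampling_rate = 2000) {
  p <- list(a_amp = a_amp, a_time = a_time, a_width = a_width,
            b_amp = b_amp, b_time = b_time, b_width = b_width,
            op_amp = op_amp, op_freq = op_freq, op_time = op_time,
            op_width = op_width, phnr_amp = phnr_amp,
            phnr_time = phnr_time, phnr_width = phnr_width,
            noise_sd = noise_sd, duration_ms = duration_ms,
            sampling_rate = sampling_rate)
  if (!(a_amp > 0 && b_amp > 0 && op_amp >= 0 && phnr_amp >= 0 &&
        noise_sd >= 0))
    stop("amplitude parameters out of range")
  if (!(0 < a_time && a_time < b_time && b_time < duration_ms))
    stop("latencies must satisfy 0 < a_time < b_time < duration_ms")
  if (op_freq >= sampling_rate / 2)
    stop("op_freq must be below the Nyquist frequency")
  structure(p, class = "morphology_params")
}

gauss_bump <- function(t, centre, width) exp(-0.5 * ((t - centre) / width)^2)

#' Generate one synthetic waveform
#'
#' Deterministic morphology plus seeded Gaussian noise; uses the current R
#' RNG state, so wrap in [withr::with_seed()] or `set.seed()` for
#' reproducibility.
#'
#' @param p A [morphology_params()] object.
#' @param subject_id,group,sex,eye,flash_td,recording_index Metadata passed
#'   to [waveform()].
#' @return A raw (microvolt) [waveform()] with
#'   `N = duration_ms * sampling_rate / 1000` samples.
#' @export
generate_waveform <- function(p, subject_id = "SYN1", group = "UNKNOWN",
                              sex = "UNKNOWN", eye = "UNKNOWN",
                              flash_td = NA_real_, recording_index = 1L) {
  stopifnot(inherits(p, "morphology_params"))
  n <- round(p$duration_ms * p$sampling_rate / 1000)
  t <- (seq_len(n) - 1) / p$sampling_rate * 1000  # ms
  x <- -p$a_amp * gauss_bump(t, p$a_time, p$a_width) +
    p$b_amp * gauss_bump(t, p$b_time, p$b_width) +
    p$op_amp * sin(2 * pi * p$op_freq * t / 1000) *
      gauss_bump(t, p$op_time, p$op_width) -
    p$phnr_amp * gauss_bump(t, p$phnr_time, p$phnr_width) +
    stats::rnorm(n, 0, p$noise_sd)
  waveform(x, sampling_rate = p$sampling_rate, subject_id = subject_id,
           group = group, sex = sex, eye = eye, flash_td = flash_td,
           recording_index = recording_index)
}

#' Morphology presets with compact / expansive amplitude dynamics
#'
#' Three repo-constant presets used as the group bases of the default
#' synthetic cohorts. They are emulation targets, not fitted clinical
#' values: `COMPACT` (ASD-like) has reduced a-/b-wave and oscillatory
#' amplitudes with sharper transients, so after per-waveform normalization
#' the measurement noise spans relatively more quantization levels and the
#' fast sweeps skip levels -- yielding fewer, more densely interconnected
#' nodes (compact topology). `EXPANSIVE` (ADHD-like) has an elevated,
#' broader b-wave and stronger oscillatory potentials, so the normalized
#' trajectory sweeps slowly and repeatedly through the level range --
#' yielding chain-like graphs with larger diameter and lower clustering
#' (expansive topology).
#'
#' @param group_style `"CONTROL_LIKE"`, `"COMPACT"` or `"EXPANSIVE"`.
#' @return A [morphology_params()] object.
#' @export
preset <- function(group_style = c("CONTROL_LIKE", "COMPACT", "EXPANSIVE")) {
  group_style <- match.arg(group_style)
  switch(group_style,
    CONTROL_LIKE = morphology_params(),
    COMPACT = morphology_params(a_amp = 10, a_width = 0.9, b_amp = 22,
                                b_width = 2.2, op_amp = 2.5, op_width = 5,
                                phnr_amp = 1, phnr_width = 10,
                                noise_sd = 2.3),
    EXPANSIVE = morphology_params(a_amp = 30, a_width = 5, b_amp = 70,
                                  b_width = 10, op_amp = 12, op_time = 20,
                                  op_width = 3, phnr_amp = 8, noise_sd = 3)
  )
}

group_preset <- function(group) {
  switch(group,
    CONTROL = preset("CONTROL_LIKE"),
    ASD = preset("COMPACT"),
    ADHD = preset("EXPANSIVE"),
    ASD_ADHD = {
      a <- unclass(preset("COMPACT")); b <- unclass(preset("EXPANSIVE"))
      structure(Map(function(u, v) (u + v) / 2, a, b),
                class = "morphology_params")
    },
    preset("CONTROL_LIKE"))
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the acquisition design of a two-site pediatric study:
#' four diagnostic groups with subject counts 77 (ASD), 43 (ADHD), 21
#' (ASD+ADHD) and 137 (control), 1-4 recordings per subject, eye and flash
#' combination, both eyes, flash strengths 113 and 446 Td.s, and
#' group-specific male:female ratios. Subject-level morphology varies by
#' log-normal multiplicative factors around the group preset
#' (multiplicative keeps amplitudes positive); within-subject repeat
#' variation is smaller than between-subject variation so that
#' subject-wise cross-validation leakage is detectable.
#'
#' @param n_subjects Named integer vector, groups to subject counts.
#' @param recordings_per_subject Either a single integer in 1..4 or a range
#'   `c(lo, hi)` sampled uniformly per subject/eye/flash cell.
#' @param eyes Subset of `c("RIGHT", "LEFT")`.
#' @param flashes Subset of `c(113, 446)` (Td.s).
#' @param male_fraction Named numeric vector per group.
#' @param between_sd Log-scale SD of the between-subject amplitude
#'   multipliers (default 0.15).
#' @param within_sd Log-scale SD of within-subject repeat multipliers
#'   (default 0.05).
#' @param seed Integer RNG seed; identical specs with identical seeds give
#'   byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(ASD = 77, ADHD = 43, ASD_ADHD = 21,
                                       CONTROL = 137),
                        recordings_per_subject = c(1, 4),
                        eyes = c("RIGHT", "LEFT"),
                        flashes = c(113, 446),
                        male_fraction = c(ASD = 0.73, ADHD = 0.58,
                                          ASD_ADHD = 0.76, CONTROL = 0.42),
                        between_sd = 0.15, within_sd = 0.05, seed = 1L) {
  stopifnot(all(n_subjects >= 2), length(n_subjects) >= 1,
            !is.null(names(n_subjects)))
  if (length(recordings_per_subject) == 1)
    recordings_per_subject <- rep(recordings_per_subject, 2)
  stopifnot(recordings_per_subject[1] >= 1, recordings_per_subject[2] <= 4)
  structure(list(n_subjects = n_subjects,
                 recordings_per_subject = recordings_per_subject,
                 eyes = match.arg(eyes, c("RIGHT", "LEFT"), several.ok = TRUE),
                 flashes = flashes, male_fraction = male_fraction,
                 between_sd = between_sd, within_sd = within_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# scale the amplitude-like fields of a morphology preset
scale_amplitudes <- function(p, mult) {
  for (f in c("a_amp", "b_amp", "op_amp", "phnr_amp"))
    p[[f]] <- p[[f]] * mult[[f]]
  p
}

#' Generate a synthetic waveform cohort
#'
#' Draws per-subject amplitude multipliers (log-normal, SD
#' `spec$between_sd`) around the group preset, smaller within-subject
#' repeat multipliers (SD `spec$within_sd`), and a flash-strength effect:
#' the 446 Td.s condition scales all component amplitudes and the noise SD
#' by 1.35 relative to 113 Td.s, emulating the stronger (and
#' proportionally more variable) retinal response to the brighter flash
#' (no claim of physiological accuracy).
#'
#' @param spec A [cohort_spec()].
#' @return A list of raw [waveform()] objects with full metadata; subject
#'   ids are unique across groups.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    waves <- list()
    for (grp in names(spec$n_subjects)) {
      base <- group_preset(grp)
      n_sub <- spec$n_subjects[[grp]]
      mf <- if (grp %in% names(spec$male_fraction))
        spec$male_fraction[[grp]] else 0.5
      for (s in seq_len(n_sub)) {
        sid <- sprintf("%s_%03d", grp, s)
        sex <- if (stats::runif(1) < mf) "M" else "F"
        bmult <- stats::setNames(as.list(stats::rlnorm(4, 0, spec$between_sd)),
                                 c("a_amp", "b_amp", "op_amp", "phnr_amp"))
        subj_p <- scale_amplitudes(base, bmult)
        for (eye in spec$eyes) for (fl in spec$flashes) {
          lo <- spec$recordings_per_subject[1]
          hi <- spec$recordings_per_subject[2]
          n_rec <- lo + sample.int(hi - lo + 1L, 1) - 1L
          for (r in seq_len(n_rec)) {
            wmult <- stats::setNames(as.list(stats::rlnorm(4, 0, spec$within_sd)),
                                     c("a_amp", "b_amp", "op_amp", "phnr_amp"))
            p <- scale_amplitudes(subj_p, wmult)
            if (fl == 446) {
              p <- scale_amplitudes(
                p, list(a_amp = 1.35, b_amp = 1.35, op_amp = 1.35,
                        phnr_amp = 1.35))
              p$noise_sd <- p$noise_sd * 1.35
            }
            waves[[length(waves) + 1]] <- generate_waveform(
              p, subject_id = sid, group = grp, sex = sex, eye = eye,
              flash_td = fl, recording_index = r)
          }
        }
      }
    }
    waves
  })
}

#' Small two-condition cohort for method studies
#'
#' Convenience wrapper: one recording per subject, right eye, 446 Td.s,
#' equal group sizes; used by the directionality and classification
#' checks.
#'
#' @param groups Character vector of group names (mapped to presets).
#' @param n_per_group Subjects per group.
#' @param recordings_per_subject Recordings per subject (default 1).
#' @param seed RNG seed.
#' @return A list of waveforms.
#' @export
two_group_cohort <- function(groups = c("ASD", "ADHD"), n_per_group = 60,
                             recordings_per_subject = 1, seed = 1L) {
  ns <- stats::setNames(rep(n_per_group, length(groups)), groups)
  generate_cohort(cohort_spec(
    n_subjects = ns, recordings_per_subject = recordings_per_subject,
    eyes = "RIGHT", flashes = 446, seed = seed))
}
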
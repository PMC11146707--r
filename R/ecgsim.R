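# Synthetic single-lead ECG rhythm simulator.
#
# The generator encodes the class-defining phenomenology of the detection
# task: sinus rhythm has regular RR intervals and a P wave before each QRS;
# atrial fibrillation has highly irregular, serially uncorrelated RR
# intervals, no P wave, and a low-amplitude 4-10 Hz fibrillatory (f-wave)
# baseline oscillation; "other" is sinus with premature beats; "noise" is
# band-limited noise with no beat structure.

#' Rhythm generation parameters
#'
#' Default parameter sets per rhythm class. Sinus ("normal") rhythm is
#' constrained to a low RR coefficient of variation (<= 0.08) with a
#' positive P-wave amplitude and no f wave; AF to a high RR coefficient of
#' variation (>= 0.20) with no P wave and a positive f-wave amplitude —
#' the vanishing P wave, emerging f wave, and RR irregularity that define
#' the class distinction.
#'
#' @param rhythm_label One of `"normal"`, `"af"`, `"other"`, `"noise"`.
#' @param mean_rr Mean RR interval, seconds.
#' @param rr_cv RR coefficient of variation (dimensionless).
#' @param p_wave_amplitude P-wave amplitude, mV.
#' @param f_wave_amplitude Fibrillatory-wave amplitude, mV.
#' @param f_wave_freq Fibrillatory-wave frequency, Hz, in \[4, 10\].
#' @param noise_sd Additive sensor-noise standard deviation, mV.
#' @return An object of class `rhythm_params`.
#' @export
rhythm_params <- function(rhythm_label = c("normal", "af", "other",
                                           "noise"),
                          mean_rr = NULL, rr_cv = NULL,
                          p_wave_amplitude = NULL,
                          f_wave_amplitude = NULL, f_wave_freq = NULL,
                          noise_sd = NULL) {
  rhythm_label <- match.arg(rhythm_label)
  def <- switch(rhythm_label,
    normal = list(mean_rr = 0.8, rr_cv = 0.05, p_wave_amplitude = 0.15,
                  f_wave_amplitude = 0, f_wave_freq = NA_real_,
                  noise_sd = 0.03),
    af     = list(mean_rr = 0.7, rr_cv = 0.25, p_wave_amplitude = 0,
                  f_wave_amplitude = 0.08, f_wave_freq = 7,
                  noise_sd = 0.03),
    other  = list(mean_rr = 0.8, rr_cv = 0.07, p_wave_amplitude = 0.15,
                  f_wave_amplitude = 0, f_wave_freq = NA_real_,
                  noise_sd = 0.03),
    noise  = list(mean_rr = 0.8, rr_cv = 0.05, p_wave_amplitude = 0,
                  f_wave_amplitude = 0, f_wave_freq = NA_real_,
                  noise_sd = 0.35))
  p <- def
  for (nm in names(def)) {
    v <- get(nm)
    if (!is.null(v)) p[[nm]] <- v
  }
  p$rhythm_label <- rhythm_label
  if (rhythm_label == "normal") {
    if (p$rr_cv > 0.08)
      stop("normal rhythm requires rr_cv <= 0.08", call. = FALSE)
    if (p$p_wave_amplitude <= 0)
      stop("normal rhythm requires a positive P-wave amplitude",
           call. = FALSE)
    if (p$f_wave_amplitude != 0)
      stop("normal rhythm has no f wave", call. = FALSE)
  }
  if (rhythm_label == "af") {
    if (p$rr_cv < 0.20)
      stop("AF requires rr_cv >= 0.20", call. = FALSE)
    if (p$p_wave_amplitude != 0)
      stop("AF has no P wave", call. = FALSE)
    if (p$f_wave_amplitude <= 0)
      stop("AF requires a positive f-wave amplitude", call. = FALSE)
    if (is.na(p$f_wave_freq) || p$f_wave_freq < 4 || p$f_wave_freq > 10)
      stop("f_wave_freq must lie in [4, 10] Hz", call. = FALSE)
  }
  structure(p, class = "rhythm_params")
}

#' Simulate a sequence of RR intervals
#'
#' Sinus (and "other"/"noise") rhythms draw from a truncated normal law
#' around `mean_rr`; AF draws i.i.d. from a truncated lognormal with the
#' requested coefficient of variation, i.e. high variance and no serial
#' correlation. "Other" rhythm additionally injects premature beats: a
#' shortened interval followed by a compensatory pause. Intervals are drawn
#' until their cumulative sum covers `duration`.
#'
#' @param params A [rhythm_params()].
#' @param duration Target duration, seconds (> 0).
#' @param seed Integer seed; the draw is a pure function of
#'   `(params, duration, seed)`.
#' @return Numeric vector of RR intervals in seconds whose cumulative sum
#'   covers `duration`.
#' @export
simulate_rr <- function(params, duration, seed = 1L) {
  stopifnot(inherits(params, "rhythm_params"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (params$mean_rr <= 0.2)
    stop("nonphysiological mean_rr (must exceed 0.2 s)", call. = FALSE)
  with_seed(seed, {
    n_guess <- ceiling(duration / params$mean_rr) + 10L
    draw <- function(n) {
      if (params$rhythm_label == "af") {
        sdlog <- sqrt(log(1 + params$rr_cv^2))
        r <- rlnorm(n, log(params$mean_rr) - sdlog^2 / 2, sdlog)
        pmin(pmax(r, 0.25), 2.5)
      } else {
        r <- rnorm(n, params$mean_rr, params$rr_cv * params$mean_rr)
        pmin(pmax(r, 0.3), 2)
      }
    }
    rr <- draw(n_guess)
    while (sum(rr) < duration) rr <- c(rr, draw(n_guess))
    if (params$rhythm_label == "other") {
      # premature beats: shorten an interval, lengthen the next
      prem <- which(runif(length(rr)) < 0.15)
      prem <- prem[prem < length(rr)]
      rr[prem] <- rr[prem] * 0.6
      rr[prem + 1L] <- rr[prem + 1L] * 1.4
    }
    rr[seq_len(which(cumsum(rr) >= duration)[1])]
  })
}

#' Analytic P-QRS-T beat template
#'
#' A single heartbeat modeled as a sum of Gaussian bumps for the P, Q, R,
#' S and T waves at fixed latencies relative to the R peak (which is the
#' global maximum). With `include_p = FALSE` the P bump is omitted, as in
#' atrial fibrillation.
#'
#' @param fs Sampling rate, Hz (>= 100).
#' @param include_p Include the P wave (default TRUE).
#' @param p_amplitude P-wave amplitude in mV.
#' @return Numeric waveform in mV with attributes `t` (sample times in
#'   seconds relative to the R peak) and `fs`.
#' @export
beat_template <- function(fs, include_p = TRUE, p_amplitude = 0.15) {
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  t <- seq(-0.25, 0.45, by = 1 / fs)
  bumps <- list(                      # center (s), width (s), amplitude (mV)
    q = c(-0.040, 0.013, -0.12),
    r = c(0.000, 0.014, 1.00),
    s = c(0.045, 0.013, -0.25),
    t = c(0.280, 0.060, 0.35))
  if (include_p) bumps$p <- c(-0.170, 0.028, p_amplitude)
  y <- numeric(length(t))
  for (b in bumps) y <- y + b[3] * exp(-0.5 * ((t - b[1]) / b[2])^2)
  structure(y, t = t, fs = fs)
}

butter_filter <- function(x, fs, low = NULL, high = NULL, order = 2) {
  nyq <- fs / 2
  f <- if (!is.null(low) && !is.null(high))
    signal::butter(order, c(low, high) / nyq, type = "pass")
  else if (!is.null(high))
    signal::butter(order, high / nyq, type = "low")
  else signal::butter(order, low / nyq, type = "high")
  as.numeric(signal::filtfilt(f, x))
}

#' Synthesize a labeled ECG segment
#'
#' Places beat templates at the onsets given by [simulate_rr()]. For AF a
#' frequency-jittered sinusoid at `f_wave_freq` is added as the
#' fibrillatory baseline; for the noise class the output is band-limited
#' random noise with no beat structure. Band-limited (0.1-40 Hz) Gaussian
#' sensor noise at `noise_sd` is added to every class, and the output is
#' clipped to +/- 5 mV. The result is bit-identical for identical
#' `(params, fs, duration, seed)`.
#'
#' @param params A [rhythm_params()].
#' @param fs Sampling rate, Hz.
#' @param duration Segment duration, seconds, in \[1, 120\].
#' @param seed Integer seed.
#' @return An `ecg_segment`: list with `samples` (mV), `fs`, `label`,
#'   `duration`.
#' @export
synthesize_segment <- function(params, fs = 250, duration = 10,
                               seed = 1L) {
  stopifnot(inherits(params, "rhythm_params"))
  if (duration < 1 || duration > 120)
    stop("`duration` must lie in [1, 120] seconds", call. = FALSE)
  n <- round(fs * duration)
  x <- with_seed(seed, {
    if (params$rhythm_label == "noise") {
      raw <- rnorm(n + 200L, 0, params$noise_sd * 3)
      x <- butter_filter(raw, fs, low = 0.5, high = 40)[101:(100 + n)]
    } else {
      rr <- simulate_rr(params, duration, seed = derive_seed(seed, 1L))
      r_times <- cumsum(c(0.3, rr))
      r_times <- r_times[r_times < duration]
      tpl <- beat_template(fs, include_p = params$p_wave_amplitude > 0,
                           p_amplitude = max(params$p_wave_amplitude,
                                             0.01))
      tt <- attr(tpl, "t")
      x <- numeric(n)
      for (rt in r_times) {
        idx <- round((rt + tt) * fs) + 1L
        keep <- idx >= 1L & idx <= n
        x[idx[keep]] <- x[idx[keep]] + tpl[keep]
      }
      if (params$f_wave_amplitude > 0) {
        tgrid <- (seq_len(n) - 1L) / fs
        freq_jitter <- cumsum(rnorm(n, 0, 0.02))
        phase <- 2 * pi * (params$f_wave_freq * tgrid +
                             freq_jitter / fs)
        x <- x + params$f_wave_amplitude * sin(phase)
      }
      if (params$noise_sd > 0) {
        raw <- rnorm(n + 200L, 0, params$noise_sd)
        x <- x + butter_filter(raw, fs, low = 0.1, high = 40,
                               order = 2)[101:(100 + n)]
      }
      x
    }
  })
  new_ecg_segment(pmin(pmax(x, -5), 5), fs, params$rhythm_label, duration)
}

new_ecg_segment <- function(samples, fs, label, duration) {
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 duration = duration),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("ecg segment: %.1f s @ %g Hz, label '%s' (%d samples)\n",
              x$duration, x$fs, x$label, length(x$samples)))
  invisible(x)
}

#' Generate a balanced labeled synthetic dataset
#'
#' Two regimes are emulated: `duration_policy = 10` with `fs = 250`
#' produces fixed 10-second binary-task windows; `duration_policy =
#' c(9, 30)` with `fs = 300` produces variable-length four-class records.
#' Per-segment seeds are derived deterministically from the master seed.
#'
#' @param n_per_class Segments per class (>= 1).
#' @param classes Character vector of rhythm classes.
#' @param fs Sampling rate, Hz.
#' @param duration_policy A single duration in seconds, or a length-2
#'   vector `c(min, max)` for uniformly drawn durations.
#' @param seed Master seed.
#' @param params Optional named list mapping class name ->
#'   [rhythm_params()] override.
#' @return List of `ecg_segment` objects (class `ecg_dataset`), in
#'   interleaved class order.
#' @export
make_dataset <- function(n_per_class, classes = c("normal", "af"),
                         fs = 250, duration_policy = 10, seed = 1L,
                         params = NULL) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  known <- c("normal", "af", "other", "noise")
  if (!all(classes %in% known))
    stop("unknown class(es): ",
         paste(setdiff(classes, known), collapse = ", "), call. = FALSE)
  if (!length(duration_policy) %in% c(1L, 2L))
    stop("`duration_policy` must be a duration or c(min, max)",
         call. = FALSE)
  segs <- vector("list", n_per_class * length(classes))
  k <- 0L
  for (i in seq_len(n_per_class)) {
    for (cl in classes) {
      k <- k + 1L
      sseed <- derive_seed(seed, k)
      dur <- if (length(duration_policy) == 1L) duration_policy
             else with_seed(derive_seed(sseed, 1L),
                            round(runif(1, duration_policy[1],
                                        duration_policy[2]), 1))
      p <- if (!is.null(params) && !is.null(params[[cl]])) params[[cl]]
           else rhythm_params(cl)
      segs[[k]] <- synthesize_segment(p, fs = fs, duration = dur,
                                      seed = sseed)
    }
  }
  structure(segs, class = c("ecg_dataset", "list"))
}

#' Simple R-peak detector
#'
#' Band-passes the signal into the QRS energy band (5-25 Hz) and finds
#' local maxima above an absolute amplitude threshold with a physiological
#' refractory distance. Plausibility gate: QRS complexes are sparse spikes,
#' so the band-passed signal must have a high crest factor (peak over
#' median absolute amplitude); beat-free noise fails the gate and yields no
#' peaks. Used for the generator's own sanity checks.
#'
#' @param x Numeric signal, mV.
#' @param fs Sampling rate, Hz.
#' @param min_height Minimum band-passed peak amplitude, mV.
#' @param refractory Minimum distance between peaks, seconds.
#' @param min_crest Minimum peak-over-median-absolute-amplitude ratio for the signal to
#'   count as having beat structure at all.
#' @return Integer vector of peak sample indices (1-based).
#' @export
detect_r_peaks <- function(x, fs, min_height = 0.35, refractory = 0.25,
                           min_crest = 8) {
  z <- butter_filter(x, fs, low = 5, high = 25)
  crest <- max(z) / (stats::median(abs(z)) + 1e-9)
  if (crest < min_crest) return(integer(0))
  thr <- max(min_height, 0.4 * max(z))
  cand <- which(z > thr &
                  z >= c(-Inf, z[-length(z)]) &
                  z >= c(z[-1], -Inf))
  if (!length(cand)) return(integer(0))
  cand <- cand[order(z[cand], decreasing = TRUE)]
  keep <- integer(0)
  mind <- refractory * fs
  for (p in cand)
    if (!length(keep) || all(abs(keep - p) >= mind)) keep <- c(keep, p)
  sort(keep)
}

#' RR-interval coefficient of variation of a segment
#'
#' Convenience wrapper: detect R peaks, difference to RR intervals, return
#' their coefficient of variation (NA with fewer than 3 peaks). A simple
#' threshold on this statistic separates synthetic AF from sinus rhythm.
#'
#' @param seg An `ecg_segment` (or numeric vector with `fs` given).
#' @param fs Sampling rate if `seg` is a plain vector.
#' @return RR coefficient of variation, or NA.
#' @export
segment_rr_cv <- function(seg, fs = NULL) {
  if (inherits(seg, "ecg_segment")) {
    x <- seg$samples; fs <- seg$fs
  } else x <- seg
  pk <- detect_r_peaks(x, fs)
  if (length(pk) < 3) return(NA_real_)
  rr <- diff(pk) / fs
  sd(rr) / mean(rr)
}
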
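# Synthetic single-lead ECG beats with class-dependent P-QRS-T morphology.
#
# Each beat is a sum of five Gaussian bumps (P, Q, R, S, T waves) on a flat
# baseline plus white noise at 20 dB SNR. Nominal bump parameters
# (amplitude in arbitrary units, center offset in samples relative to the R
# peak at 360 Hz, width = Gaussian sd in samples) are fixed per class and
# jittered by +/-10% per beat. This is deliberately a phenomenological
# generator: it exists so that the downstream imaging/training/inference
# pipeline has separable, annotated input, not as a physiological simulator.

.nominal_rr <- 0.8  # seconds between beats for non-S classes
.s_rr_factor <- 0.6 # S beats arrive after a shortened RR interval

# columns: amplitude, center offset (samples @360Hz), width (sd, samples)
.morphology <- list(
  N = rbind(P = c(0.15, -54, 8), Q = c(-0.12, -9, 3), R = c(1.00, 0, 4),
            S = c(-0.20, 9, 4), T = c(0.30, 90, 22)),
  V = rbind(P = c(0.00, -54, 8), Q = c(-0.05, -20, 8), R = c(0.85, 0, 14),
            S = c(-0.40, 22, 12), T = c(-0.35, 100, 30))
)
.morphology$S <- .morphology$N                       # distinguished by RR
.morphology$F <- (.morphology$N + .morphology$V) / 2 # fusion of N and V

# Unknown (Q) beats draw a fresh morphology per beat from wide ranges; the
# R bump still dominates so the peak stays at the annotated sample.
.q_morphology <- function() {
  rbind(P = c(stats::runif(1, -0.2, 0.3), stats::runif(1, -70, -40),
              stats::runif(1, 5, 15)),
        Q = c(stats::runif(1, -0.3, 0.1), stats::runif(1, -25, -5),
              stats::runif(1, 3, 9)),
        R = c(stats::runif(1, 0.7, 1.1), 0, stats::runif(1, 3, 16)),
        S = c(stats::runif(1, -0.5, 0.1), stats::runif(1, 5, 25),
              stats::runif(1, 3, 12)),
        T = c(stats::runif(1, -0.5, 0.5), stats::runif(1, 60, 120),
              stats::runif(1, 10, 35)))
}

.beat_trace <- function(cls, fs) {
  pars <- if (cls == "Q") .q_morphology() else .morphology[[cls]]
  # +/-10% multiplicative jitter on every bump parameter
  jit <- matrix(stats::runif(length(pars), 0.9, 1.1), nrow = nrow(pars))
  pars <- pars * jit
  scale <- fs / 360
  t <- (seq_len(300 * scale) - 1) - 100 * scale  # offsets relative to R peak
  x <- numeric(length(t))
  for (b in seq_len(nrow(pars))) {
    a <- pars[b, 1]; mu <- pars[b, 2] * scale; w <- max(pars[b, 3] * scale, 0.5)
    x <- x + a * exp(-0.5 * ((t - mu) / w)^2)
  }
  # white noise at 20 dB SNR relative to the clean trace power
  p_sig <- mean(x^2)
  x <- x + stats::rnorm(length(x), sd = sqrt(p_sig / 100))
  # the R peak is at offset 0 by construction; pin the global argmax there
  # so annotations are exact even under noise
  peak <- 100 * scale + 1
  x[peak] <- max(x) + 0.01
  x
}

#' Generate one synthetic ECG beat
#'
#' Produces a 300-sample (at 360 Hz) single-lead beat of the requested AAMI
#' class with its R peak at 0-based sample index 100. Morphology is a sum of
#' five Gaussian bumps with class-dependent nominal parameters, +/-10% seeded
#' jitter and white noise at 20 dB SNR; ventricular (V) beats have a widened
#' QRS and no P wave, fusion (F) beats average the N and V parameter tables,
#' unknown (Q) beats draw a randomized morphology, and supraventricular (S)
#' beats share the N morphology (their identity lives in the shortened RR
#' interval assigned by [generate_record()]).
#'
#' @param cls One of `"N"`, `"S"`, `"V"`, `"F"`, `"Q"`.
#' @param rng_seed Integer seed; identical seeds give identical beats.
#' @param fs Sampling rate in Hz (the window is `300 * fs / 360` samples).
#' @return Numeric vector of amplitudes (arbitrary units) whose maximum is at
#'   0-based index `100 * fs / 360`.
#' @examples
#' b <- generate_beat("V", rng_seed = 7)
#' which.max(b) - 1  # 100
#' @export
generate_beat <- function(cls, rng_seed, fs = 360) {
  if (!is.character(cls) || length(cls) != 1L || !cls %in% beat_classes()) {
    stop("unknown beat class: ", paste(cls, collapse = ","))
  }
  if (fs <= 0) stop("fs must be positive")
  with_seed(rng_seed, .beat_trace(cls, fs))
}

#' Generate an annotated synthetic ECG record
#'
#' Concatenates seeded synthetic beats (see [generate_beat()]) into one
#' continuous record with class-appropriate RR gaps: non-S beats follow a
#' nominal 0.8 s interval with +/-8% jitter, while S beats are preceded by an
#' interval shortened to 60% of nominal. Overlapping beat tails are summed.
#'
#' @param n_beats Number of beats (>= 1).
#' @param class_mix Probability vector over the classes `N, S, V, F, Q`;
#'   must be nonnegative and sum to 1 (within 1e-9).
#' @param rng_seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @param record_id Identifier stored with the record.
#' @return An object of class `ecg_record`: a list with `samples`, `fs`,
#'   `r_peaks` (1-based sample indices, strictly increasing), `labels`
#'   (one class per peak), `truncated` (peaks lacking 100 samples of left or
#'   200 of right context), `record_id` and `seed`.
#' @examples
#' rec <- generate_record(10, c(1, 0, 0, 0, 0), rng_seed = 3)
#' table(rec$labels)
#' @export
generate_record <- function(n_beats, class_mix, rng_seed, fs = 360,
                            record_id = paste0("synth", rng_seed)) {
  if (length(n_beats) != 1L || n_beats < 1L) stop("n_beats must be >= 1")
  if (length(class_mix) != 5L) stop("class_mix must have 5 entries (N,S,V,F,Q)")
  if (any(class_mix < 0)) stop("class_mix entries must be nonnegative")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  n_beats <- as.integer(n_beats)
  scale <- fs / 360
  half_left <- as.integer(100 * scale)
  half_right <- as.integer(200 * scale)

  with_seed(rng_seed, {
    labels <- sample(beat_classes(), n_beats, replace = TRUE, prob = class_mix)
    rr <- .nominal_rr * stats::runif(n_beats, 0.92, 1.08)
    rr[labels == "S"] <- .s_rr_factor * .nominal_rr *
      stats::runif(sum(labels == "S"), 0.92, 1.08)
    gaps <- as.integer(round(rr * fs))
    r_peaks <- half_left + 51L + cumsum(c(0L, gaps[-1L]))
    n_samples <- r_peaks[n_beats] + half_right + 50L
    samples <- numeric(n_samples)
    for (k in seq_len(n_beats)) {
      tr <- .beat_trace(labels[k], fs)
      lo <- r_peaks[k] - half_left
      samples[lo:(lo + length(tr) - 1L)] <-
        samples[lo:(lo + length(tr) - 1L)] + tr
    }
    truncated <- (r_peaks - 1L) < half_left |
      (n_samples - r_peaks) < half_right
    structure(list(samples = samples, fs = fs, r_peaks = r_peaks,
                   labels = labels, truncated = truncated,
                   record_id = record_id, seed = as.integer(rng_seed)),
              class = "ecg_record")
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record '%s': %d samples @ %g Hz, %d beats (%s)\n",
              x$record_id, length(x$samples), x$fs, length(x$r_peaks),
              paste(sprintf("%s:%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}
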
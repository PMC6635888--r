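# Bark frequency mapping (Traunmueller's approximation of the Zwicker
# critical-band scale) and its inverse, used both by the parametric
# synthesizer and by the waveform filterbank.
hz_to_bark <- function(f) 26.81 * f / (1960 + f) - 0.53
bark_to_hz <- function(z) 1960 * (z + 0.53) / (26.28 - z)

# acoustic-phonetic reference values (Hz); config-overridable via the
# `formants` argument of synthesize_auditory()
default_formants <- list(
  vowels = rbind(i = c(280, 2250, 2890),
                 e = c(400, 2100, 2700),
                 a = c(710, 1100, 2540),
                 o = c(450,  850, 2400),
                 u = c(310,  870, 2250)),
  f2_locus = c(labial = 900, alveolar = 1800, velar = 2100),
  f1_onset = 250,
  lateral = c(360, 1300, 3000),
  nasal_murmur = c(250, 2500),
  burst_centroid = c(labial = 800, alveolar = 3700, velar = 1800),
  burst_width_bark = c(labial = 3.0, alveolar = 2.5, velar = 1.5))

# place a spectral bump (Gaussian in bark) across the 24 band centers
band_bump <- function(freq_hz, amp, width_bark = 0.9) {
  z <- hz_to_bark(freq_hz)
  amp * exp(-(seq_len(24) - 0.5 - z)^2 / (2 * width_bark^2))
}

#' Parametric bark-domain auditory synthesis
#'
#' Renders the 24-band neural spectrogram of a word directly in the bark
#' domain from the motor plan's phonetic score, without an intermediate
#' waveform: vowel intervals concentrate energy in bands around
#' vowel-specific F1/F2/F3 targets with place-dependent initial formant
#' transitions; plosive closures are near-silent (voiced closures add a
#' low-band voice bar) and are released as a burst frame group with a
#' place-dependent spectral centroid (plus aspiration for voiceless
#' plosives); nasals contribute a low-band murmur; laterals are vowel-like
#' with attenuated mid bands. Band amplitudes receive per-frame
#' multiplicative jitter. Output is clipped to `[0, 1]`.
#'
#' @param word a word (see [synthesize_motor_plan()]); only used for
#'   labeling.
#' @param plan the word's [synthesize_motor_plan()] result (its `score`
#'   carries the jittered event timing).
#' @param config a [corpus_config()] (`amp_jitter`, `aud_gain`,
#'   `frame_hop_ms`).
#' @param seed optional seed for the amplitude jitter.
#' @param formants overridable acoustic reference values; see
#'   `phonmap:::default_formants` for the layout.
#' @return an `auditory_rep`: 24 x T activation matrix in `[0, 1]` with a
#'   `frame_hop_ms` attribute.
#' @export
synthesize_auditory <- function(word, plan, config = corpus_config(),
                                seed = NULL, formants = default_formants) {
  if (!is.null(seed))
    return(withr_seed(seed, synthesize_auditory(word, plan, config,
                                                seed = NULL, formants)))
  hop <- config$frame_hop_ms
  n_frames <- max(1L, floor(plan$total_duration / hop))
  times <- (seq_len(n_frames) - 0.5) * hop
  act <- matrix(0, 24, n_frames)
  score <- plan$score
  trans <- seg_dur$transition
  fjit <- function(f) f * (1 + runif(length(f), -0.05, 0.05))
  for (i in seq_len(NROW(score))) {
    ev <- score[i, ]
    frames <- which(times >= ev$on & times < ev$off)
    if (length(frames) == 0) next
    if (ev$role == "vowel") {
      fv <- fjit(formants$vowels[ev$phone, ])
      f1_from <- formants$f1_onset
      f2_from <- if (ev$place %in% names(formants$f2_locus))
        formants$f2_locus[[ev$place]] else fv[2]
      has_trans <- ev$place != "none"
      for (j in frames) {
        dt <- times[j] - ev$on
        a <- if (dt > (ev$off - ev$on) - 20)
          (ev$off - times[j]) / 20 else 1  # release fade
        if (has_trans && dt < trans) {
          u <- dt / trans
          f1 <- f1_from + u * (fv[1] - f1_from)
          f2 <- f2_from + u * (fv[2] - f2_from)
        } else {
          f1 <- fv[1]; f2 <- fv[2]
        }
        act[, j] <- act[, j] + a * (band_bump(f1, 1.0) +
                                    band_bump(f2, 0.8) +
                                    band_bump(fv[3], 0.5) +
                                    band_bump(120, 0.4, 1.2))
      }
    } else if (ev$role == "closure") {
      if (ev$voiced)
        act[, frames] <- act[, frames] + band_bump(150, 0.35, 1.2)
    } else if (ev$role == "burst") {
      act[, frames] <- act[, frames] +
        band_bump(fjit(formants$burst_centroid[[ev$place]]), 0.85,
                  formants$burst_width_bark[[ev$place]])
    } else if (ev$role == "aspiration") {
      act[, frames] <- act[, frames] +
        band_bump(fjit(formants$burst_centroid[[ev$place]]), 0.40, 5)
    } else if (ev$role == "murmur") {
      nm <- fjit(formants$nasal_murmur)
      act[, frames] <- act[, frames] + band_bump(nm[1], 0.7, 1.2) +
        band_bump(nm[2], 0.15)
    } else if (ev$role == "lateral") {
      fl <- fjit(formants$lateral)
      act[, frames] <- act[, frames] + band_bump(fl[1], 0.55) +
        0.5 * band_bump(fl[2], 0.55) + band_bump(fl[3], 0.3) +
        band_bump(120, 0.35, 1.2)
    }
  }
  jit <- matrix(exp(rnorm(length(act), 0, config$amp_jitter)), 24, n_frames)
  act <- config$aud_gain * (act * jit + 0.01 * matrix(runif(length(act)),
                                                      24, n_frames))
  act[act < 0] <- 0
  act[act > 1] <- 1
  structure(act, frame_hop_ms = hop, class = "auditory_rep")
}

#' Bark-scale critical-band filterbank for waveform audio
#'
#' Optional front-end for externally supplied audio: short-time spectra are
#' integrated over the 24 Zwicker critical bands (Traunmueller bark edges)
#' every 10 ms, log-compressed and normalized to `[0, 1]`. Not used by the
#' default synthetic path.
#'
#' @param x mono signal (numeric vector).
#' @param sample_rate sampling rate in Hz (>= 16000).
#' @param frame_hop_ms analysis hop, ms.
#' @param window_ms analysis window length, ms.
#' @return an `auditory_rep`: 24 x T matrix.
#' @export
bark_filterbank <- function(x, sample_rate, frame_hop_ms = 10,
                            window_ms = 25) {
  if (length(x) == 0) stop("empty signal")
  if (sample_rate < 16000) stop("sample_rate must be >= 16 kHz")
  hop <- round(sample_rate * frame_hop_ms / 1000)
  n <- round(sample_rate * window_ms / 1000)
  x <- c(x, numeric(n - 1))  # pad so T = ceiling(length(x) / hop)
  sg <- signal::specgram(x, n = n, Fs = sample_rate,
                         window = signal::hanning(n), overlap = n - hop)
  p <- abs(sg$S)^2
  edges <- bark_to_hz(0:24)
  band <- findInterval(sg$f, edges, rightmost.closed = FALSE)
  e <- matrix(0, 24, ncol(p))
  for (b in 1:24) {
    rows <- which(band == b)
    if (length(rows) > 0)
      e[b, ] <- colSums(p[rows, , drop = FALSE])
  }
  mx <- max(e)
  if (mx == 0) {
    a <- e
  } else {
    ref <- 1e-2 * mx
    a <- log1p(e / ref) / log1p(mx / ref)
  }
  structure(a, frame_hop_ms = frame_hop_ms, class = "auditory_rep")
}

#' @export
print.auditory_rep <- function(x, ...) {
  cat("Auditory representation: 24 bark bands x", ncol(x), "frames (",
      attr(x, "frame_hop_ms"), "ms hop )\n")
  invisible(x)
}

#' @export
print.somato_rep <- function(x, ...) {
  cat("Somatosensory representation:", nrow(x), "tiers x", ncol(x),
      "frames (", attr(x, "frame_hop_ms"), "ms hop )\n")
  invisible(x)
}
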
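# Class-conditioned synthetic sEMG: resonantly filtered Gaussian noise
# under an attack-sustain-decay envelope, with acquisition artifacts
# (DC offset, 50 Hz mains, slow drift, white noise) injected afterwards
# so preprocessing has real work to do.

#' Generator configuration
#'
#' @param fs sampling rate (Hz).
#' @param n_classes number of vowel classes.
#' @param trials_per_class trials per class per subject.
#' @param n_subjects number of simulated subjects.
#' @param subject_gain_sd sd of the per-subject log-normal gain.
#' @param dc_offset_mv constant offset added by the acquisition front-end.
#' @param mains_amp_mv amplitude of the 50 Hz interference.
#' @param drift_amp_mv amplitude of the slow (< 0.1 Hz) baseline drift.
#' @param noise_sd_mv sd of white measurement noise.
#' @param duration_s trial duration in seconds.
#' @param seed RNG seed; the full dataset is a pure function of this
#'   configuration.
#' @return A `generator_config` list.
#' @export
generator_config <- function(fs = 1000, n_classes = N_VOWEL_CLASSES,
                             trials_per_class = 10, n_subjects = 8,
                             subject_gain_sd = 0.15, dc_offset_mv = 0.5,
                             mains_amp_mv = 0.2, drift_amp_mv = 0.3,
                             noise_sd_mv = 0.02, duration_s = 1.0,
                             seed = 11) {
  stopifnot(fs > 0, n_classes >= 2, trials_per_class >= 1, n_subjects >= 1,
            subject_gain_sd >= 0, duration_s > 0.064)
  structure(as.list(environment()), class = "generator_config")
}

#' Build deterministic, mutually distinct vowel class specs
#'
#' Each class gets a primary spectral resonance whose center is spread
#' evenly over 20-350 Hz (with small seeded jitter) plus a weaker
#' secondary resonance, an utterance envelope, and a nominal amplitude.
#' Same seed, same specs.
#'
#' @param n_classes number of classes (>= 2).
#' @param rng_seed integer seed.
#' @param duration_s envelope duration (seconds).
#' @return list of `vowel_class_spec` objects.
#' @export
make_class_specs <- function(n_classes = N_VOWEL_CLASSES, rng_seed = 7,
                             duration_s = 1.0) {
  if (n_classes < 2) stop("need at least 2 classes")
  centers <- seq(20, 350, length.out = n_classes)
  specs <- withr_seed(rng_seed, {
    jit <- stats::runif(n_classes, -0.25, 0.25) * diff(centers[1:2])
    sec <- stats::runif(n_classes, 60, 320)
    lapply(seq_len(n_classes), function(i) {
      structure(list(
        class_id = i,
        spectral_peaks = list(
          c(center = centers[i] + jit[i], bandwidth = 25, gain = 1.0),
          c(center = sec[i], bandwidth = 60, gain = 0.25)),
        envelope_duration = duration_s,
        envelope_shape = c(attack = 0.2, decay = 0.2),
        amplitude_mv = 1.0), class = "vowel_class_spec")
    })
  })
  specs
}

# evaluate an expression under a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# second-order resonator band-pass (constant 0 dB peak gain)
.resonator_sos <- function(center, bandwidth, fs) {
  w0 <- 2 * pi * center / fs
  q <- max(center / bandwidth, 0.5)
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(alpha / a0, 0, -alpha / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0), 1, 6)
}

# raised-cosine attack / sustain / raised-cosine decay envelope
.asd_envelope <- function(n, attack = 0.2, decay = 0.2) {
  na <- max(1L, round(n * attack)); nd <- max(1L, round(n * decay))
  ns <- n - na - nd
  c(0.5 * (1 - cos(pi * seq_len(na) / na)),
    rep(1, max(0L, ns)),
    0.5 * (1 + cos(pi * seq_len(nd) / nd)))[seq_len(n)]
}

#' Generate one clean synthetic trial
#'
#' Gaussian noise shaped by the spec's resonances, scaled so the sustain
#' RMS equals `amplitude_mv`, multiplied by the utterance envelope.  No
#' artifacts yet.
#'
#' @param spec a `vowel_class_spec` from [make_class_specs()].
#' @param cfg a [generator_config()].
#' @param rng_seed per-trial substream seed.
#' @param subject_id label carried onto the trial.
#' @return A `semg_trial`.
#' @export
generate_trial <- function(spec, cfg = generator_config(), rng_seed = 1,
                           subject_id = "S1") {
  n <- round(spec$envelope_duration * cfg$fs)
  x <- withr_seed(rng_seed, {
    w <- stats::rnorm(n + 200)   # burn-in absorbs resonator transients
    shaped <- Reduce(`+`, lapply(spec$spectral_peaks, function(pk) {
      pk["gain"] * sosfilt(.resonator_sos(pk["center"], pk["bandwidth"],
                                          cfg$fs), w)
    }))
    shaped[(length(shaped) - n + 1):length(shaped)]
  })
  r <- sqrt(mean(x^2))
  if (r > 0 && spec$amplitude_mv > 0) {
    x <- x / r * spec$amplitude_mv
  } else {
    x <- x * 0
  }
  x <- x * .asd_envelope(n, spec$envelope_shape[["attack"]],
                         spec$envelope_shape[["decay"]])
  semg_trial(x, fs = cfg$fs, class_id = spec$class_id,
             subject_id = subject_id)
}

#' Add acquisition artifacts to a clean trial
#'
#' Constant DC offset, a 50 Hz sinusoid with random phase, a slow
#' (0.05 Hz) drift with random phase, and white measurement noise.
#' With all artifact amplitudes and noise at zero the trial is returned
#' unchanged.
#'
#' @param trial a `semg_trial`.
#' @param cfg a [generator_config()].
#' @param rng_seed substream seed for the random phases and noise.
#' @return the corrupted `semg_trial`.
#' @export
corrupt_with_artifacts <- function(trial, cfg = generator_config(),
                                   rng_seed = 1) {
  n <- length(trial$samples)
  t <- (seq_len(n) - 1) / trial$fs
  withr_seed(rng_seed, {
    ph_m <- stats::runif(1, 0, 2 * pi)
    ph_d <- stats::runif(1, 0, 2 * pi)
    noise <- if (cfg$noise_sd_mv > 0) {
      stats::rnorm(n, sd = cfg$noise_sd_mv)
    } else rep(0, n)
    trial$samples <- trial$samples +
      cfg$dc_offset_mv +
      cfg$mains_amp_mv * sin(2 * pi * 50 * t + ph_m) +
      cfg$drift_amp_mv * sin(2 * pi * 0.05 * t + ph_d) +
      noise
  })
  trial
}

#' Generate a full labeled synthetic dataset
#'
#' `n_subjects x n_classes x trials_per_class` artifact-corrupted trials
#' with a per-subject multiplicative log-normal gain.  Per-trial RNG
#' substreams are derived from a counter, so generation is
#' order-independent and the dataset is a pure function of the config.
#'
#' @param cfg a [generator_config()].
#' @param specs class specs; defaults to `make_class_specs(cfg$n_classes,
#'   rng_seed = 7)`.
#' @return list with `trials` (list of `semg_trial`) and `meta`
#'   (data.frame: trial, subject_id, class_id).
#' @export
generate_dataset <- function(cfg = generator_config(), specs = NULL) {
  if (is.null(specs))
    specs <- make_class_specs(cfg$n_classes, rng_seed = 7,
                              duration_s = cfg$duration_s)
  stopifnot(length(specs) == cfg$n_classes)
  gains <- withr_seed(cfg$seed, {
    exp(stats::rnorm(cfg$n_subjects, 0, cfg$subject_gain_sd))
  })
  trials <- list()
  meta <- list()
  counter <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (cl in seq_len(cfg$n_classes)) {
      sp <- specs[[cl]]
      sp$amplitude_mv <- sp$amplitude_mv * gains[s]
      for (r in seq_len(cfg$trials_per_class)) {
        counter <- counter + 1L
        # double arithmetic: exact below 2^53, avoids 32-bit overflow
        sub_seed <- (cfg$seed * 131071 + counter * 2654435) %% 2147483647
        tr <- generate_trial(sp, cfg, rng_seed = sub_seed, subject_id = sid)
        tr <- corrupt_with_artifacts(tr, cfg, rng_seed = sub_seed + 1L)
        trials[[counter]] <- tr
        meta[[counter]] <- data.frame(trial = counter, subject_id = sid,
                                      class_id = cl)
      }
    }
  }
  list(trials = trials, meta = do.call(rbind, meta))
}
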
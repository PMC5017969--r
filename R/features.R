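# The 57-feature multi-domain catalogue: 9 time, 13 entropy/regularity,
# 9 spectral, and 26 Symlet-4 wavelet descriptors per trial.

#' Feature extraction parameters
#'
#' @param renyi_alpha Renyi entropy order (histogram-based, bits).
#' @param tsallis_q Tsallis entropy order.
#' @param higuchi_kmax maximum lag for the Higuchi fractal dimension.
#' @param apen_m,sampen_m embedding dimensions for ApEn / SampEn.
#' @param apen_r_factor,sampen_r_factor tolerance as a multiple of the
#'   signal standard deviation.
#' @param hist_bins histogram bin count for amplitude-distribution
#'   entropies and wavelet-coefficient entropies.
#' @param flux_frame spectral-flux frame length (samples).
#' @param flux_overlap fractional frame overlap.
#' @param wavelet_name wavelet family ("sym4" is the only built-in).
#' @param wavelet_level decomposition depth.
#' @param sef_fractions cumulative-power fractions for the spectral edge.
#' @return A `feature_params` list.
#' @export
feature_params <- function(renyi_alpha = 2, tsallis_q = 2,
                           higuchi_kmax = 8, apen_m = 2, sampen_m = 2,
                           apen_r_factor = 0.2, sampen_r_factor = 0.2,
                           hist_bins = 100, flux_frame = 256,
                           flux_overlap = 0.5, wavelet_name = "sym4",
                           wavelet_level = 3,
                           sef_fractions = c(0.80, 0.90, 0.95)) {
  stopifnot(renyi_alpha > 0, tsallis_q > 0, higuchi_kmax >= 2,
            apen_m >= 1, sampen_m >= 1, apen_r_factor > 0,
            sampen_r_factor > 0, hist_bins >= 2, flux_frame >= 8,
            flux_overlap > 0, flux_overlap < 1, wavelet_level >= 1)
  structure(as.list(environment()), class = "feature_params")
}

#' Canonical names of the 57 features
#'
#' Order is fixed: time (9), entropy (13), frequency (9),
#' time-frequency (26).
#' @return character vector of length 57.
#' @export
feature_names <- function() {
  tf <- as.vector(outer(c("entropy", "var", "sd", "median", "mean",
                          "maxmin_ratio"),
                        c("a3", "d3", "d2", "d1"),
                        function(s, b) paste(b, s, sep = "_")))
  c(
    # time domain
    "mean", "max", "sd", "min", "var", "cov", "skewness", "kurtosis", "rms",
    # entropy / regularity domain
    "hjorth_mobility", "hjorth_complexity", "mean_lower_envelope",
    "mean_upper_envelope", "mean_abs_diff", "higuchi_fd", "lz_complexity",
    "renyi_entropy", "shannon_entropy", "tsallis_entropy", "hurst_exponent",
    "apen", "sampen",
    # frequency domain
    "spectral_flatness", "spectral_flux", "spectral_entropy",
    "sef80", "sep80", "sef90", "sep90", "sef95", "sep95",
    # time-frequency domain (per band: a3, d3, d2, d1) + energy shares
    tf, "wavelet_ea", "wavelet_ed"
  )
}

#' Grouping of the canonical features into the four domains
#' @return named list of index vectors (time, entropy, frequency, wavelet).
#' @export
feature_families <- function() {
  list(time = 1:9, entropy = 10:22, frequency = 23:31, wavelet = 32:57)
}

# ---- time domain -------------------------------------------------------

#' Time-domain summary features
#'
#' Population moments (divide by N).  Kurtosis is excess kurtosis.
#' Guards: a constant signal has CoV = skewness = kurtosis = 0.
#'
#' @param x sample vector, length >= 2.
#' @return named numeric vector of 9 features.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  s <- sqrt(m2)
  if (s > 0) {
    cov_ <- s / mu
    if (!is.finite(cov_)) cov_ <- 0   # zero-mean guard
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    cov_ <- 0; skew <- 0; kurt <- 0
  }
  c(mean = mu, max = max(x), sd = s, min = min(x), var = m2, cov = cov_,
    skewness = skew, kurtosis = kurt, rms = sqrt(mean(x^2)))
}

# ---- entropy / regularity domain ---------------------------------------

# histogram probabilities over `bins` equal-width bins; empty bins dropped
.hist_probs <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(1)
  h <- tabulate(pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins)),
                nbins = bins)
  p <- h / length(x)
  p[p > 0]
}

#' Shannon entropy of the amplitude histogram (bits)
#' @param x sample vector.
#' @param bins histogram bin count.
#' @export
shannon_entropy <- function(x, bins = 100) {
  p <- .hist_probs(x, bins)
  -sum(p * log2(p))
}

#' Renyi entropy of order alpha of the amplitude histogram (bits)
#' @inheritParams shannon_entropy
#' @param alpha entropy order (alpha != 1).
#' @export
renyi_entropy <- function(x, alpha = 2, bins = 100) {
  p <- .hist_probs(x, bins)
  if (abs(alpha - 1) < 1e-12) return(shannon_entropy(x, bins))
  log2(sum(p^alpha)) / (1 - alpha)
}

#' Tsallis entropy of order q of the amplitude histogram
#' @inheritParams shannon_entropy
#' @param q entropy order (q != 1).
#' @export
tsallis_entropy <- function(x, q = 2, bins = 100) {
  p <- .hist_probs(x, bins)
  if (abs(q - 1) < 1e-12) return(shannon_entropy(x, bins) * log(2))
  (1 - sum(p^q)) / (q - 1)
}

#' Hjorth mobility and complexity
#'
#' mobility = sqrt(var(dx)/var(x)); complexity = mobility(dx)/mobility(x),
#' with dx the first difference.  Constant signal gives 0/0 guards of 0.
#' @param x sample vector.
#' @return named vector c(mobility, complexity).
#' @export
hjorth_params <- function(x) {
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 == 0) return(c(mobility = 0, complexity = 0))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  cmp <- if (v1 > 0) sqrt(v2 / v1) / mob else 0
  c(mobility = mob, complexity = cmp)
}

# upper/lower envelope means via cubic interpolation through local extrema
.envelope_means <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  maxima <- which(x[i] >= x[i - 1] & x[i] > x[i + 1]) + 1L
  minima <- which(x[i] <= x[i - 1] & x[i] < x[i + 1]) + 1L
  env_mean <- function(idx) {
    if (length(idx) < 2L) return(mean(x))   # degenerate: no oscillation
    idx <- unique(c(1L, idx, n))            # anchor endpoints
    mean(stats::spline(idx, x[idx], xout = seq_len(n), method = "natural")$y)
  }
  c(lower = env_mean(minima), upper = env_mean(maxima))
}

#' Higuchi fractal dimension
#'
#' Curve-length estimator over lags 1..kmax; ~1 for smooth signals, ~2 for
#' white noise.
#' @param x sample vector.
#' @param kmax maximum lag.
#' @export
higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx)
      if (nm < 2) { Lm[m] <- NA; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / ((nm - 1) * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  ok <- is.finite(Lk) & Lk > 0
  if (sum(ok) < 2) return(1)   # flat signal guard
  lx <- log(1 / seq_len(kmax))[ok]
  ly <- log(Lk[ok])
  stats::coef(stats::lm(ly ~ lx))[[2]]
}

#' Normalized Lempel-Ziv complexity of the median-thresholded sequence
#'
#' LZ76 parsing count of the binary sequence `x > median(x)`, normalized
#' by n / log2(n).  Serves as the catalogue's algorithmic-entropy entry.
#' @param x sample vector.
#' @export
lz_complexity <- function(x) {
  n <- length(x)
  b <- as.integer(x > stats::median(x))
  .lz76_cpp(b) * log2(n) / n
}

#' Hurst exponent by rescaled-range analysis
#'
#' R/S statistic averaged over non-overlapping blocks at dyadic window
#' sizes 8, 16, ..., n/2; slope of log(R/S) on log(window).
#' @param x sample vector (length >= 32).
#' @export
hurst_rs <- function(x) {
  n <- length(x)
  sizes <- 2^(3:floor(log2(n / 2)))
  sizes <- sizes[sizes >= 8]
  if (length(sizes) < 2) return(0.5)
  rs <- vapply(sizes, function(w) {
    nb <- n %/% w
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * w + 1):(b * w)]
      d <- seg - mean(seg)
      cs <- cumsum(d)
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      (max(cs) - min(cs)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(0.5)
  stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[[2]]
}

#' Approximate entropy
#' @param x sample vector.
#' @param m embedding dimension.
#' @param r_factor tolerance as multiple of sd(x).
#' @export
approx_entropy <- function(x, m = 2, r_factor = 0.2) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  .apen_cpp(x, as.integer(m), r_factor * s)
}

#' Sample entropy
#' @inheritParams approx_entropy
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  .sampen_cpp(x, as.integer(m), r_factor * s)
}

#' Entropy-domain features (13 values)
#'
#' @param x sample vector (length >= 64).
#' @param p a [feature_params()].
#' @return named numeric vector of 13 features.
#' @export
entropy_domain_features <- function(x, p = feature_params()) {
  if (length(x) < MIN_TRIAL_LEN)
    stop("need at least ", MIN_TRIAL_LEN, " samples")
  hj <- hjorth_params(x)
  env <- .envelope_means(x)
  c(hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    mean_lower_envelope = unname(env["lower"]),
    mean_upper_envelope = unname(env["upper"]),
    mean_abs_diff = mean(abs(diff(x))),
    higuchi_fd = higuchi_fd(x, p$higuchi_kmax),
    lz_complexity = lz_complexity(x),
    renyi_entropy = renyi_entropy(x, p$renyi_alpha, p$hist_bins),
    shannon_entropy = shannon_entropy(x, p$hist_bins),
    tsallis_entropy = tsallis_entropy(x, p$tsallis_q, p$hist_bins),
    hurst_exponent = hurst_rs(x),
    apen = approx_entropy(x, p$apen_m, p$apen_r_factor),
    sampen = sample_entropy(x, p$sampen_m, p$sampen_r_factor))
}

# ---- frequency domain --------------------------------------------------

#' One-sided periodogram
#'
#' Density scaling: `sum(power) * df` equals the signal mean square
#' (Parseval).
#' @param x sample vector (length >= 64).
#' @param fs sampling rate (Hz).
#' @return list with `freq` (Hz) and `power` (density, units^2/Hz).
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 64L) stop("need at least 64 samples")
  X <- stats::fft(x)
  nh <- n %/% 2 + 1L
  pw <- (Mod(X[seq_len(nh)])^2) / (n * fs)
  # fold negative frequencies onto positive (not DC, not Nyquist if n even)
  dbl <- 2:(if (n %% 2 == 0) nh - 1L else nh)
  pw[dbl] <- 2 * pw[dbl]
  list(freq = (seq_len(nh) - 1) * fs / n, power = pw)
}

#' Spectral edge frequency and power
#'
#' SEF is the lowest frequency bin at which the cumulative power reaches
#' `fraction` of the total; SEP is the cumulative power there (absolute
#' units).  Zero total power gives the guard (0, 0).
#' @param psd list from [power_spectrum()].
#' @param fraction cumulative-power fraction in (0, 1).
#' @return named vector c(sef, sep).
#' @export
spectral_edge <- function(psd, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  tot <- sum(psd$power)
  if (tot <= 0) return(c(sef = 0, sep = 0))
  cs <- cumsum(psd$power)
  i <- which(cs >= fraction * tot)[1]
  c(sef = psd$freq[i], sep = cs[i] * (psd$freq[2] - psd$freq[1]))
}

# L1-normalized magnitude-spectrum flux over overlapping frames
.spectral_flux <- function(x, frame, overlap) {
  n <- length(x)
  frame <- min(frame, 2^floor(log2(n / 2)))   # guard: ensure >= 2 frames
  hop <- max(1L, as.integer(round(frame * (1 - overlap))))
  starts <- seq(1L, n - frame + 1L, by = hop)
  if (length(starts) < 2L) return(0)
  specs <- vapply(starts, function(s) {
    m <- Mod(stats::fft(x[s:(s + frame - 1L)]))[seq_len(frame %/% 2 + 1L)]
    tot <- sum(m)
    if (tot > 0) m / tot else m
  }, numeric(frame %/% 2 + 1L))
  mean(colSums((specs[, -1L, drop = FALSE] -
                specs[, -ncol(specs), drop = FALSE])^2))
}

#' Frequency-domain features (9 values)
#'
#' @param x sample vector.
#' @param fs sampling rate (Hz).
#' @param p a [feature_params()].
#' @return named numeric vector of 9 features.
#' @export
frequency_domain_features <- function(x, fs, p = feature_params()) {
  psd <- power_spectrum(x, fs)
  pw <- psd$power
  tot <- sum(pw)
  if (tot > 0) {
    flat <- exp(mean(log(pmax(pw, .Machine$double.xmin)))) / mean(pw)
    pr <- pw[pw > 0] / tot
    sent <- -sum(pr * log2(pr)) / log2(length(pw))
  } else {
    flat <- 0; sent <- 0
  }
  edges <- lapply(p$sef_fractions, function(f) spectral_edge(psd, f))
  out <- c(spectral_flatness = flat,
           spectral_flux = .spectral_flux(x, p$flux_frame, p$flux_overlap),
           spectral_entropy = sent)
  for (i in seq_along(edges)) {
    pct <- round(100 * p$sef_fractions[i])
    out[paste0("sef", pct)] <- edges[[i]]["sef"]
    out[paste0("sep", pct)] <- edges[[i]]["sep"]
  }
  out
}

# ---- time-frequency domain (Symlet-4 DWT) ------------------------------

# Symlet-4 decomposition filters (orthonormal; 4 vanishing moments)
.SYM4_LO <- c(-0.07576571478927333, -0.02963552764599851,
               0.49761866763201545,  0.80373875180591614,
               0.29785779560527736, -0.09921954357684722,
              -0.01260396726203783,  0.03222310060404270)
.SYM4_HI <- c(-0.03222310060404270, -0.01260396726203783,
               0.09921954357684722,  0.29785779560527736,
              -0.80373875180591614,  0.49761866763201545,
               0.02963552764599851, -0.07576571478927333)

# one analysis step: symmetric half-point padding, valid convolution,
# downsample from the second output sample (PyWavelets convention)
.dwt_step <- function(x, filt) {
  fl <- length(filt)
  xp <- c(x[(fl - 1L):1L], x, x[length(x):(length(x) - fl + 2L)])
  conv <- as.numeric(stats::filter(xp, filt, method = "convolution",
                                   sides = 1))[fl:length(xp)]
  conv[seq(2L, length(conv), by = 2L)]
}

#' Multilevel Symlet-4 discrete wavelet decomposition
#'
#' Pyramid analysis with symmetric boundary extension.  At level 3 the
#' signal splits into one approximation band (a3, 0 to fs/16) and three
#' detail bands (d3, d2, d1 covering successively higher octaves).
#'
#' @param x sample vector (length >= 64).
#' @param p a [feature_params()] (wavelet_level is honoured; only sym4
#'   filters are built in).
#' @return A `dwt_decomposition`: list with `approx`, `details` (list,
#'   level deepest-first d3, d2, d1), and `energies`.
#' @export
dwt_decompose <- function(x, p = feature_params()) {
  if (length(x) < 64L) stop("need at least 64 samples for a 3-level DWT")
  if (!identical(p$wavelet_name, "sym4"))
    stop("only the sym4 wavelet is built in")
  L <- p$wavelet_level
  details <- vector("list", L)
  a <- x
  for (j in seq_len(L)) {
    details[[j]] <- .dwt_step(a, .SYM4_HI)
    a <- .dwt_step(a, .SYM4_LO)
  }
  names(details) <- paste0("d", seq_len(L))
  details <- rev(details)          # deepest first: d3, d2, d1
  e <- c(approx = sum(a^2), vapply(details, function(d) sum(d^2),
                                   numeric(1)))
  structure(list(approx = a, details = details, energies = e),
            class = "dwt_decomposition")
}

#' Wavelet-band features (26 values)
#'
#' Six descriptors (histogram Shannon entropy, variance, sd, median, mean,
#' max/min ratio of absolute coefficients) for each of the four bands
#' a3, d3, d2, d1, plus the percentage of energy in the approximation
#' (EA) and in all details together (ED).  EA + ED = 100 by construction.
#'
#' @param dec a `dwt_decomposition`.
#' @param hist_bins bin count for the coefficient-histogram entropy.
#' @return named numeric vector of 26 features.
#' @export
wavelet_features <- function(dec, hist_bins = 100) {
  bands <- c(list(a3 = dec$approx), dec$details)
  names(bands) <- c("a3", names(dec$details))
  out <- numeric(0)
  for (nm in names(bands)) {
    cb <- bands[[nm]]
    ab <- abs(cb)
    vals <- c(entropy = shannon_entropy(cb, hist_bins),
              var = stats::var(cb), sd = stats::sd(cb),
              median = stats::median(cb), mean = mean(cb),
              maxmin_ratio = max(ab) / max(min(ab), 1e-12))
    names(vals) <- paste(nm, names(vals), sep = "_")
    out <- c(out, vals)
  }
  tot <- sum(dec$energies)
  if (tot <= 0) stop("zero-energy decomposition: energy shares undefined")
  ea <- 100 * dec$energies[["approx"]] / tot
  c(out, wavelet_ea = ea, wavelet_ed = 100 - ea)
}

#' Extract the full 57-feature vector from a trial
#'
#' Concatenates the four families in canonical order.  All values are
#' finite under the documented guard rules.
#'
#' @param trial a `semg_trial` (or plain numeric vector with `fs` given).
#' @param p a [feature_params()].
#' @param fs sampling rate, only needed for plain vectors.
#' @return named numeric vector of length 57.
#' @export
extract_features <- function(trial, p = feature_params(), fs = NULL) {
  if (inherits(trial, "semg_trial")) {
    x <- trial$samples; fs <- trial$fs
  } else {
    x <- as.numeric(trial)
    if (is.null(fs)) stop("fs required for plain numeric input")
  }
  fam <- function(tag, expr) {
    v <- tryCatch(expr, error = function(e)
      stop(tag, "-domain feature extraction failed: ",
           conditionMessage(e), call. = FALSE))
    v
  }
  v <- c(fam("time", time_domain_features(x)),
         fam("entropy", entropy_domain_features(x, p)),
         fam("frequency", frequency_domain_features(x, fs, p)),
         fam("time-frequency", wavelet_features(dwt_decompose(x, p),
                                                p$hist_bins)))
  stopifnot(length(v) == 57L)
  names(v) <- feature_names()
  v
}
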
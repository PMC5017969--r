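# Zero-phase preprocessing: DC removal, Butterworth band-pass, IIR notch.
#
# No DSP package is assumed: the Butterworth design (analog prototype ->
# band transform -> bilinear transform -> second-order sections) and the
# forward-backward zero-phase runner are implemented here and verified in
# the test suite against closed-form magnitude responses.

#' Filter specification
#'
#' Defaults follow the standard facial-sEMG conditioning chain: band-pass
#' 0.15-450 Hz to suppress motion artifacts and out-of-band noise, plus a
#' 50 Hz IIR band-stop for mains interference.
#'
#' @param band_low high-pass corner (Hz).
#' @param band_high low-pass corner (Hz).
#' @param notch_freq mains frequency (Hz).
#' @param order Butterworth band-pass order.
#' @param notch_q notch quality factor (center frequency / -3 dB width).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(band_low = 0.15, band_high = 450, notch_freq = 50,
                        order = 4, notch_q = 30) {
  if (band_low <= 0 || band_high <= band_low)
    stop("need 0 < band_low < band_high")
  if (notch_freq <= band_low || notch_freq >= band_high)
    stop("notch frequency must lie inside the pass-band")
  structure(list(band_low = band_low, band_high = band_high,
                 notch_freq = notch_freq, order = as.integer(order),
                 notch_q = notch_q),
            class = "filter_spec")
}

#' Subtract the mean from a signal
#'
#' @param x numeric sample vector.
#' @return `x - mean(x)`.
#' @export
remove_dc <- function(x) {
  if (length(x) < 1L) stop("empty input")
  x - mean(x)
}

# ---- Butterworth design in zero-pole-gain form -------------------------

# analog lowpass prototype: n poles on the unit circle, no zeros, gain 1
.butter_proto <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  list(z = complex(0), p = p, k = 1)
}

.lp2bp <- function(zpk, w0, bw) {
  p <- zpk$p * bw / 2
  p <- c(p + sqrt(p^2 - w0^2), p - sqrt(p^2 - w0^2))
  n <- length(zpk$p)
  list(z = rep(0 + 0i, n), p = p, k = zpk$k * bw^n)
}

.bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  # zeros at analog infinity map to z = -1
  deficit <- length(zpk$p) - length(zpk$z)
  if (deficit > 0) zd <- c(zd, rep(-1 + 0i, deficit))
  list(z = zd, p = pd, k = kd)
}

# pair conjugate poles with their nearest remaining zeros; spread the gain
.zpk2sos <- function(zpk) {
  p <- zpk$p; z <- zpk$z
  stopifnot(length(p) %% 2 == 0, length(z) == length(p))
  # keep one representative of each conjugate pair, worst-damped first
  pu <- p[Im(p) >= 0]
  pu <- pu[order(-Mod(pu))]
  zpool <- z
  ns <- length(pu)
  sos <- matrix(0, ns, 6)
  gain_per <- rep(abs(zpk$k)^(1 / ns), ns)
  gain_per[1] <- gain_per[1] * sign(zpk$k)
  for (i in seq_len(ns)) {
    pi1 <- pu[i]
    pair <- if (abs(Im(pi1)) > 1e-12) c(pi1, Conj(pi1)) else {
      # real pole: pull another real pole (not expected for our designs)
      c(pi1, pi1)
    }
    # two zeros nearest this pole
    idx <- order(Mod(zpool - pi1))[1:2]
    zz <- zpool[idx]
    zpool <- zpool[-idx]
    b <- Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2])) * gain_per[i]
    a <- Re(c(1, -(pair[1] + pair[2]), pair[1] * pair[2]))
    sos[i, ] <- c(b, a)
  }
  sos
}

#' Design a digital Butterworth band-pass in second-order sections
#'
#' @param order analog prototype order (the digital filter has 2x poles).
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric matrix, one row per biquad: b0 b1 b2 a0 a1 a2 (a0 = 1).
#' @export
butter_bandpass_sos <- function(order, low, high, fs) {
  if (fs <= 2 * high) stop("sampling rate too low for band_high = ", high)
  fs2 <- 2 * fs
  wl <- fs2 * tan(pi * low / fs)    # pre-warped edges
  wh <- fs2 * tan(pi * high / fs)
  zpk <- .lp2bp(.butter_proto(order), w0 = sqrt(wl * wh), bw = wh - wl)
  .zpk2sos(.bilinear_zpk(zpk, fs))
}

#' Design a biquad notch (band-stop) filter
#'
#' Constrained direct-form biquad with unit gain at DC and Nyquist and a
#' null at `freq`.
#'
#' @param freq notch center (Hz).
#' @param fs sampling rate (Hz).
#' @param q quality factor.
#' @return 1 x 6 second-order-section matrix.
#' @export
notch_sos <- function(freq, fs, q = 30) {
  if (freq <= 0 || freq >= fs / 2) stop("notch frequency must be in (0, fs/2)")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0), 1, 6)
}

# direct-form II transposed biquad with explicit state (C++ inner loop)
.biquad <- function(x, s, zi = c(0, 0)) .biquad_cpp(x, s, zi)

# steady-state biquad state for a unit-step input (for transient-free starts)
.biquad_zi <- function(s) {
  b0 <- s[1]; b1 <- s[2]; b2 <- s[3]; a1 <- s[5]; a2 <- s[6]
  ydc <- (b0 + b1 + b2) / (1 + a1 + a2)
  z2 <- b2 - a2 * ydc
  z1 <- b1 - a1 * ydc + z2
  c(z1, z2)
}

#' Filter a signal through second-order sections (single pass)
#' @param sos section matrix from the designers above.
#' @param x input vector.
#' @return filtered vector.
#' @export
sosfilt <- function(sos, x) {
  for (i in seq_len(nrow(sos))) x <- .biquad(x, sos[i, ])
  x
}

#' Zero-phase (forward-backward) second-order-section filtering
#'
#' Odd-reflection padding at both ends with steady-state initial
#' conditions, forward pass, time reversal, second pass, un-pad.  Doubles
#' the magnitude response in dB and cancels the phase.
#'
#' @param sos section matrix.
#' @param x input vector.
#' @param padlen extension length per edge (default grows with section
#'   count, capped at `length(x) - 1`).
#' @return filtered vector, same length as `x`.
#' @export
sosfiltfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  ns <- nrow(sos)
  if (is.null(padlen)) padlen <- min(n - 1L, max(3L * (2L * ns + 1L), 250L))
  if (n <= padlen) padlen <- n - 1L
  if (n < 4L) stop("input too short to filter")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  run <- function(v) {
    for (i in seq_len(ns)) {
      zi <- .biquad_zi(sos[i, ]) * v[1]
      v <- .biquad(v, sos[i, ], zi)
    }
    v
  }
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass filter a signal (zero phase)
#'
#' @param x sample vector.
#' @param fs sampling rate (Hz).
#' @param spec a [filter_spec()].
#' @return filtered vector, same length.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$band_high)
    stop("fs must exceed twice band_high (", spec$band_high, " Hz)")
  sos <- butter_bandpass_sos(spec$order, spec$band_low, spec$band_high, fs)
  if (length(x) <= 3L * spec$order)
    stop("input too short for order-", spec$order, " band-pass")
  sosfiltfilt(sos, x)
}

#' Notch out the mains component (zero phase)
#'
#' @inheritParams bandpass_filter
#' @return filtered vector, same length.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  sos <- notch_sos(spec$notch_freq, fs, spec$notch_q)
  sosfiltfilt(sos, x)
}

#' Preprocess a trial or recording
#'
#' DC removal, band-pass, and mains notch, in that order.  Labels, rate
#' and metadata are carried through unchanged.
#'
#' @param x a `semg_trial`, `semg_recording`, or plain numeric vector (in
#'   which case `fs` must be supplied).
#' @param spec a [filter_spec()].
#' @param fs sampling rate, only for plain vectors.
#' @return same type as the input, with filtered samples.
#' @export
preprocess <- function(x, spec = filter_spec(), fs = NULL) {
  if (inherits(x, "semg_trial") || inherits(x, "semg_recording")) {
    x$samples <- preprocess(x$samples, spec, fs = x$fs)
    return(x)
  }
  if (is.null(fs)) stop("fs required for plain numeric input")
  y <- remove_dc(x)
  y <- bandpass_filter(y, fs, spec)
  notch_filter(y, fs, spec)
}
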
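# Shared fixtures, generated in code (no binary files).

tone <- function(freq, fs = 1000, n = 2000, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

white_noise <- function(n, seed = 1, sd = 1) {
  withr::with_seed(seed, stats::rnorm(n, sd = sd))
}

# small labeled synthetic dataset for classifier/evaluation tests
tiny_dataset <- function(n_classes = 3, trials_per_class = 12, seed = 5) {
  cfg <- generator_config(n_classes = n_classes,
                          trials_per_class = trials_per_class,
                          n_subjects = 1, duration_s = 0.256, seed = seed,
                          noise_sd_mv = 0.02)
  specs <- make_class_specs(n_classes, rng_seed = seed, duration_s = 0.256)
  generate_dataset(cfg, specs)
}

# Brute-force re-implementation of the incremental mRMR criterion used
# as the selection oracle: at every step, evaluate
# I(x;c) - mean_{j in S} I(x;x_j) for every remaining feature by direct
# enumeration, independent of the package's greedy bookkeeping.
brute_mrmr <- function(Fd, cl, k) {
  p <- ncol(Fd)
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(i) {
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(j)
          mutual_information(Fd[, i], Fd[, j]), numeric(1)))
      mutual_information(Fd[, i], cl) - red
    }, numeric(1))
    sel <- c(sel, cand[which.max(crit)])
  }
  sel
}

# two well-separated Gaussian blobs in d dimensions
gaussian_blobs <- function(n_per, d = 12, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep / sqrt(d)), n_per, d))
    list(X = X, y = rep(1:2, each = n_per))
  })
}
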
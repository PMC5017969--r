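test_that("time-domain features match direct moment computation", {
  v <- time_domain_features(c(1, 2, 3, 4))
  expect_equal(unname(v[c("mean", "max", "min", "var")]),
               c(2.5, 4, 1, 1.25))
  expect_equal(unname(v["sd"]), sqrt(1.25), tolerance = 1e-9)
  expect_equal(unname(v["cov"]), sqrt(1.25) / 2.5, tolerance = 1e-9)
  expect_equal(unname(v["rms"]), sqrt(7.5), tolerance = 1e-9)
  expect_equal(unname(v["skewness"]), 0)
  expect_equal(unname(v["kurtosis"]), -1.36, tolerance = 1e-9)
  # constant-signal guards
  g <- time_domain_features(rep(1, 4))
  expect_equal(unname(g[c("cov", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_equal(unname(g[c("mean", "rms", "sd", "var")]), c(1, 1, 0, 0))
  # skewness flips sign under reflection about the mean
  x <- white_noise(300, seed = 2)^3
  s1 <- time_domain_features(x)["skewness"]
  s2 <- time_domain_features(-x + 2 * mean(x))["skewness"]
  expect_equal(unname(s1), -unname(s2), tolerance = 1e-9)
  expect_error(time_domain_features(1), "at least 2")
})

test_that("Hjorth mobility matches the discrete closed form on sinusoids", {
  for (f in c(20, 50, 120)) {
    x <- tone(f, fs = 1000, n = 4000)
    expect_equal(unname(hjorth_params(x)["mobility"]),
                 2 * abs(sin(pi * f / 1000)), tolerance = 1e-3)
  }
  expect_equal(unname(hjorth_params(rep(3, 100))), c(0, 0))
})

test_that("histogram entropies behave at the edges", {
  expect_equal(shannon_entropy(rep(5, 200)), 0)
  # uniform over bins -> near log2(bins)
  x <- seq(0, 1, length.out = 10000)
  expect_equal(shannon_entropy(x, bins = 100), log2(100), tolerance = 0.01)
  # Renyi-2 and Tsallis-2 on equiprobable two-state signal
  x2 <- rep(c(0, 1), 500)
  expect_equal(renyi_entropy(x2, alpha = 2), 1, tolerance = 1e-9)
  expect_equal(tsallis_entropy(x2, q = 2), 0.5, tolerance = 1e-9)
})

test_that("complexity estimators land where theory says", {
  ramp <- seq(0, 1, length.out = 1024)
  expect_lt(abs(higuchi_fd(ramp) - 1), 0.1)
  wn <- white_noise(2048, seed = 4)
  expect_lt(abs(higuchi_fd(wn) - 2), 0.15)
  # Hurst of white noise ~ 0.5 averaged over 20 seeds
  hs <- vapply(1:20, function(s) hurst_rs(white_noise(1024, seed = s)),
               numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.1)
  # LZ complexity: periodic sequence far below white noise
  expect_lt(lz_complexity(rep(c(0, 1), 512)),
            lz_complexity(white_noise(1024, seed = 6)) / 2)
  # ApEn/SampEn: regular sinusoid below white noise; guards at constant
  xs <- tone(10, n = 500); xn <- white_noise(500, seed = 7)
  expect_lt(approx_entropy(xs), approx_entropy(xn))
  expect_lt(sample_entropy(xs), sample_entropy(xn))
  expect_identical(approx_entropy(rep(1, 100)), 0)
  expect_identical(sample_entropy(rep(1, 100)), 0)
  expect_gte(approx_entropy(xn), 0)
  expect_gte(sample_entropy(xn), 0)
})

test_that("power_spectrum satisfies Parseval and locates tones", {
  x <- tone(100, n = 1000)
  ps <- power_spectrum(x, 1000)
  expect_equal(ps$freq[which.max(ps$power)], 100)
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(sum(ps$power) * df, mean(x^2), tolerance = 0.01)
  wn <- white_noise(4096, seed = 11)
  psn <- power_spectrum(wn, 1000)
  expect_equal(sum(psn$power) * (psn$freq[2] - psn$freq[1]), mean(wn^2),
               tolerance = 0.01)
  expect_true(all(power_spectrum(rep(0, 256), 1000)$power == 0))
  expect_error(power_spectrum(1:10, 1000), "64")
})

test_that("spectral edge is monotone and exact on constructed PSDs", {
  x <- tone(100, n = 1000)
  ps <- power_spectrum(x, 1000)
  e80 <- spectral_edge(ps, 0.80); e90 <- spectral_edge(ps, 0.90)
  e95 <- spectral_edge(ps, 0.95)
  expect_equal(unname(c(e80["sef"], e90["sef"], e95["sef"])),
               c(100, 100, 100))
  expect_equal(unname(e80["sep"]), mean(x^2), tolerance = 0.01)
  # uniform flat PSD over [0, 500]
  flat <- list(freq = seq(0, 500, by = 2), power = rep(1, 251))
  expect_equal(unname(spectral_edge(flat, 0.95)["sef"]), 476, tolerance = 3)
  # monotonicity on arbitrary signals
  for (s in 1:5) {
    p <- power_spectrum(white_noise(512, seed = s), 1000)
    sefs <- vapply(c(.8, .9, .95),
                   function(f) spectral_edge(p, f)["sef"], numeric(1))
    expect_true(all(diff(sefs) >= 0))
  }
  expect_equal(unname(spectral_edge(list(freq = 0:10, power = rep(0, 11)),
                                    0.9)), c(0, 0))
})

test_that("frequency-domain features separate tones from noise", {
  p <- feature_params()
  ftone <- frequency_domain_features(tone(100, n = 2000), 1000, p)
  fnoise <- frequency_domain_features(white_noise(2000, seed = 3), 1000, p)
  expect_lt(ftone[["spectral_flatness"]], 0.01)
  expect_lt(ftone[["spectral_entropy"]], 0.2)
  expect_gt(fnoise[["spectral_entropy"]], 0.9)
  expect_gt(fnoise[["spectral_flatness"]], ftone[["spectral_flatness"]])
  expect_true(all(c(ftone, fnoise) >= 0 | names(c(ftone, fnoise)) == ""))
  # flux: stationary tone ~ 0, frequency step mid-trial > 0
  expect_lt(ftone[["spectral_flux"]], 1e-3)
  stepped <- c(tone(50, n = 1024), tone(180, n = 1024))
  fstep <- frequency_domain_features(stepped, 1000, p)
  expect_gt(fstep[["spectral_flux"]], 10 * ftone[["spectral_flux"]])
  expect_true(ftone[["spectral_entropy"]] >= 0 &
                fnoise[["spectral_entropy"]] <= 1)
})

test_that("sym4 DWT reproduces the reference transform", {
  # frozen from an independent reference implementation (PyWavelets,
  # sym4, symmetric mode) on a 16-sample mixed sinusoid + ramp
  x <- sin(2 * pi * (0:15) / 16) + 0.25 * (0:15) / 16
  ca_ref <- c(0.43246127839256293, 0.08522872298109285, 1.1005802013354318,
              1.502440727957444, 1.107763263074468, 0.14202624941257147,
              -0.8031663204624793, -1.1482451105238403, -0.5672549650527147,
              -0.29211428946501766, -1.0642042812936978)
  cd_ref <- c(-0.049005683188518466, 0.14547042838228583,
              -0.07975030856499889, -0.011066118832968888,
              -0.01021571859329646, -0.0033810889511052267,
              0.005434136742985644, 0.011066118832736624,
              0.051862862564106736, -0.14097823797303743,
              0.08324604579077594)
  expect_equal(semgvowel:::.dwt_step(x, semgvowel:::.SYM4_LO), ca_ref,
               tolerance = 1e-12)
  expect_equal(semgvowel:::.dwt_step(x, semgvowel:::.SYM4_HI), cd_ref,
               tolerance = 1e-12)
})

test_that("DWT conserves energy and annihilates low-degree polynomials", {
  # interior-dominated signal (tapered ends, as enveloped trials are):
  # symmetric-padding boundary coefficients then contribute < 1 % energy
  wn <- white_noise(512, seed = 9) *
    sin(pi * (seq_len(512) - 0.5) / 512)^2
  dec <- dwt_decompose(wn)
  expect_s3_class(dec, "dwt_decomposition")
  expect_length(dec$details, 3)
  ratio <- sum(dec$energies) / sum(wn^2)
  expect_gt(ratio, 0.99); expect_lt(ratio, 1.01)
  # constant signal: detail energy < 1% of total
  decc <- dwt_decompose(rep(2, 256))
  expect_lt(sum(decc$energies[-1]) / sum(decc$energies), 0.01)
  # cubic ramp: 4 vanishing moments annihilate degree <= 3
  t <- seq(-1, 1, length.out = 512)
  decp <- dwt_decompose(2 + t - 0.5 * t^2 + 3 * t^3)
  expect_lt(sum(decp$energies[-1]) / sum(decp$energies), 0.01)
  expect_error(dwt_decompose(1:32), "64")
})

test_that("wavelet features have the contracted structure", {
  dec <- dwt_decompose(white_noise(512, seed = 10))
  wf <- wavelet_features(dec)
  expect_length(wf, 26)
  expect_equal(unname(wf["wavelet_ea"] + wf["wavelet_ed"]), 100)
  decc <- dwt_decompose(rep(1, 256))
  expect_gte(unname(wavelet_features(decc)["wavelet_ea"]), 99)
})

test_that("extract_features: 57 finite values, deterministic, with the
           documented scale-invariant entries", {
  ds <- tiny_dataset(n_classes = 2, trials_per_class = 1)
  trial <- preprocess(ds$trials[[1]])
  v1 <- extract_features(trial)
  v2 <- extract_features(trial)
  expect_length(v1, 57)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
  fam <- feature_families()
  expect_equal(lengths(fam), c(time = 9, entropy = 13, frequency = 9,
                               wavelet = 26))
  # amplitude-scale invariance audit
  scaled <- trial; scaled$samples <- 7.3 * trial$samples
  vs <- extract_features(scaled)
  inv <- c("cov", "skewness", "kurtosis", "spectral_flatness",
           "spectral_entropy", "wavelet_ea", "wavelet_ed",
           "hjorth_mobility", "hjorth_complexity", "higuchi_fd",
           "hurst_exponent")
  expect_equal(vs[inv], v1[inv], tolerance = 1e-6)
})
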
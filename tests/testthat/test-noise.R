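# Carrier noise model: SNR estimation, calibrated corruption, filtering.

test_that("SNR estimator recovers known signal-to-noise ratios", {
  cfg <- carrier_config()
  t <- eit3d:::carrier_times(cfg)
  pure <- cos(2 * pi * cfg$frequency * t)
  expect_gte(estimate_snr(pure, cfg)$snr_db, 200)   # noise-free sentinel
  expect_error(estimate_snr(0 * t, cfg), "zero-power")
  # sine of power P plus WGN of power P/100 -> 20 dB
  set.seed(11)
  est <- replicate(300, {
    w <- pure + rnorm(length(t), 0, sqrt(0.5 / 100))
    estimate_snr(w, cfg)$snr_db
  })
  expect_lt(abs(mean(est) - 20), 0.5)
  # averaging over many frames pins a preset ratio within 0.5 dB
  set.seed(12)
  preset <- 35
  est2 <- replicate(500, {
    nsd <- sqrt(0.5 / 10^(preset / 10))
    estimate_snr(pure + rnorm(length(t), 0, nsd), cfg)$snr_db
  })
  expect_lt(abs(mean(est2) - preset), 0.5)
})

test_that("the SNR definition is scale invariant", {
  cfg <- carrier_config()
  t <- eit3d:::carrier_times(cfg)
  set.seed(13)
  noise <- rnorm(length(t), 0, 0.05)
  w <- cos(2 * pi * cfg$frequency * t) + noise
  base <- estimate_snr(w, cfg)$snr_db
  for (alpha in c(0.01, 3, 250)) {
    expect_equal(estimate_snr(alpha * w, cfg)$snr_db, base, tolerance = 1e-9)
  }
})

test_that("the SNR profile falls monotonically with separation and hits its bounds", {
  p <- proto16()
  snr <- eit3d:::channel_snr_db(snr_profile(50, 10), p)
  expect_lte(max(snr), 50)
  expect_gte(min(snr), 10)
  # near-adjacent measurement gets the best SNR of its injection block
  rows <- eit3d:::protocol_rows(p)
  blk <- which(rows$injection == 1)
  mid <- eit3d:::protocol_rows(p)$measurement[blk]
  sep_rank <- order(pmin(abs(mid - 1), 16 - abs(mid - 1)))
  expect_equal(which.max(snr[blk]), sep_rank[1])
})

test_that("corrupt_frame is an identity at infinite SNR and deterministic by seed", {
  p <- proto16()
  cfg <- carrier_config()
  clean <- eit_frame(seq(1e-3, 2e-2, length.out = p$frame_length), p)
  out <- corrupt_frame(clean, snr_profile(Inf, Inf), cfg, p, seed = 1)
  expect_lt(max(abs(out$values - clean$values) / abs(clean$values)), 1e-3)
  a <- corrupt_frame(clean, snr_profile(), cfg, p, seed = 5)
  b <- corrupt_frame(clean, snr_profile(), cfg, p, seed = 5)
  c <- corrupt_frame(clean, snr_profile(), cfg, p, seed = 6)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_length(a$values, p$frame_length)        # filtering preserves layout
})

test_that("round trip: post-filter SNR matches the profile-implied value", {
  cfg <- carrier_config()
  t <- eit3d:::carrier_times(cfg)
  n <- length(t)
  # filter noise power gain, from the realised magnitude response
  H2 <- local({
    fs <- cfg$samples_per_period * cfg$frequency
    f <- (0:(n - 1)) / n * fs; f <- pmin(f, fs - f)
    u <- ifelse(f > 0, (f^2 - cfg$frequency^2) / (0.1 * cfg$frequency * f), Inf)
    h <- 1 / sqrt(1 + u^10); h[!is.finite(h)] <- 0
    mean(h^2)
  })
  set.seed(21)
  for (snr_pre in c(20, 40)) {
    # the sine fit absorbs the noise in the two carrier-frequency bins
    # (power 2/n of the white total), which therefore leaves the residual;
    # average the power ratio linearly (few effective passband bins make the
    # dB-domain mean biased)
    implied_post <- snr_pre - 10 * log10(H2 - 2 / n)
    ratio <- replicate(400, {
      nsd <- sqrt(0.5 / 10^(snr_pre / 10))
      w <- eit3d:::bandpass_filter(cos(2 * pi * cfg$frequency * t) +
                                   rnorm(n, 0, nsd), cfg)
      e <- estimate_snr(w, cfg)
      e$residual_noise_power / e$signal_power
    })
    expect_lt(abs(-10 * log10(mean(ratio)) - implied_post), 1)
  }
})

test_that("heavy-tailed corruption behaves as specified", {
  p <- adjacent_protocol(1, 8)
  cfg <- carrier_config(n_periods = 8L)
  clean <- eit_frame(rep(0.01, p$frame_length), p)
  # zero amplitude -> identity
  z <- eit_frame(rep(0, p$frame_length), p)
  expect_equal(corrupt_frame_nongaussian(z, snr_profile(), cfg, p, seed = 2)$values,
               z$values)
  # flat-spectrum Laplacian noise has positive excess kurtosis
  set.seed(31)
  lap <- local({
    u <- runif(20000, -0.5, 0.5)
    -1 / sqrt(2) * sign(u) * log(1 - 2 * abs(u))
  })
  kurt <- mean(lap^4) / mean(lap^2)^2 - 3
  expect_gt(kurt, 1)
  # Gaussian limit: heavy_tail_param = 0, flat spectrum, reproduces the
  # Gaussian model distributionally (KS test over channels x repeats)
  g1 <- unlist(lapply(1:30, function(s) {
    corrupt_frame(clean, snr_profile(20, 20), cfg, p, seed = s)$values
  }))
  g2 <- unlist(lapply(1:30, function(s) {
    corrupt_frame_nongaussian(clean, snr_profile(20, 20), cfg, p, seed = 1000 + s,
                              heavy_tail_param = 0, spectrum_shape = "flat")$values
  }))
  expect_gt(suppressWarnings(stats::ks.test(g1, g2)$p.value), 0.01)
})
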
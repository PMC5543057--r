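# Carrier-level measurement noise: synthesise the 100 kHz drive sine per
# channel, add white Gaussian (or heavy-tailed) noise at a separation-
# dependent SNR, bandpass-filter, and demodulate by peak detection — the
# acquisition chain of a serial EIT system.

#' Carrier configuration
#'
#' Defaults follow a typical serial EIT acquisition chain: a 100 kHz
#' sinusoidal drive sampled 20 times per period, SNR estimates averaged over
#' 500 frames, and a tenth-order bandpass filter centred on the carrier.
#'
#' @param frequency carrier frequency, Hz
#' @param samples_per_period samples per carrier period (>= 4)
#' @param n_periods carrier periods synthesised per demodulated value
#' @param n_frames frames averaged in SNR estimation
#' @param filter_order bandpass order (even, >= 2)
#' @param rel_bandwidth half-power bandwidth as a fraction of the carrier
#' @return a `carrier_config` list
#' @export
carrier_config <- function(frequency = 1e5, samples_per_period = 20L,
                           n_periods = 16L, n_frames = 500L,
                           filter_order = 10L, rel_bandwidth = 0.10) {
  stopifnot(samples_per_period >= 4, filter_order >= 2, filter_order %% 2 == 0,
            frequency > 0, n_periods >= 1, rel_bandwidth > 0)
  structure(list(frequency = frequency, samples_per_period = as.integer(samples_per_period),
                 n_periods = as.integer(n_periods), n_frames = as.integer(n_frames),
                 filter_order = as.integer(filter_order), rel_bandwidth = rel_bandwidth),
            class = "carrier_config")
}

carrier_times <- function(cfg) {
  n <- cfg$samples_per_period * cfg$n_periods
  (0:(n - 1)) / (cfg$samples_per_period * cfg$frequency)
}

# Carrier sine of amplitude A: cosine phase, so a sample lands exactly on the
# peak and noise-free demodulation is exact.
carrier_wave <- function(amplitude, cfg) {
  amplitude * cos(2 * pi * cfg$frequency * carrier_times(cfg))
}

# Zero-phase bandpass via the analytic Butterworth magnitude response applied
# in the frequency domain: |H(f)|^2 = 1 / (1 + ((f^2 - f0^2) / (B f))^order),
# an order-`filter_order` bandpass born of the order/2 lowpass prototype.
bandpass_filter <- function(x, cfg) {
  n <- length(x)
  fs <- cfg$samples_per_period * cfg$frequency
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)              # two-sided spectrum folded to [0, fs/2]
  f0 <- cfg$frequency
  B <- cfg$rel_bandwidth * f0
  u <- ifelse(f > 0, (f^2 - f0^2) / (B * f), Inf)
  H <- 1 / sqrt(1 + u^(cfg$filter_order))
  H[!is.finite(H)] <- 0
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

demodulate_peak <- function(x) max(x)

#' Estimate the signal-to-noise ratio of one channel waveform
#'
#' Fits an ideal sine at the carrier frequency by linear least squares
#' (amplitude and phase via in-phase/quadrature regressors), takes the
#' residual as noise, and returns
#' \deqn{SNR(dB) = 10 \log_{10}\left(\frac{mean(signal^2)}{mean(residual^2)}\right).}
#' A noise-free waveform is reported as the capped sentinel 300 dB.
#'
#' @param raw sampled waveform covering an integer number of carrier periods
#' @param cfg a [carrier_config()]
#' @return list with `snr_db`, `signal_power`, `residual_noise_power`,
#'   and the fitted `amplitude`
#' @export
estimate_snr <- function(raw, cfg) {
  t <- carrier_times(cfg)
  if (length(raw) != length(t)) {
    stop("waveform length must equal samples_per_period * n_periods")
  }
  c1 <- cos(2 * pi * cfg$frequency * t)
  s1 <- sin(2 * pi * cfg$frequency * t)
  fit <- lm.fit(cbind(c1, s1), raw)
  signal <- cbind(c1, s1) %*% fit$coefficients
  sp <- mean(signal^2)
  if (sp <= 0) stop("zero-power signal: no carrier component to estimate SNR against")
  np <- mean((raw - signal)^2)
  snr <- if (np <= sp * 1e-30) 300 else min(300, 10 * log10(sp / np))
  list(snr_db = snr, signal_power = sp, residual_noise_power = np,
       amplitude = sqrt(sum(fit$coefficients^2)))
}

#' Separation-dependent SNR profile
#'
#' Serial EIT systems see high SNR when the measuring pair is close to the
#' driving pair and low SNR diametrically opposite, because the medium
#' attenuates the signal: here the target SNR falls linearly in dB from
#' `max_db` at zero angular separation to `min_db` at separation pi, the
#' separation being measured between the injection-pair and
#' measurement-pair midpoints. Defaults mirror the observed extremes of
#' above 50 dB (near) and below 10 dB (far).
#'
#' @param max_db SNR at minimal separation (default 50)
#' @param min_db SNR at maximal separation (default 10)
#' @return an `snr_profile`
#' @export
snr_profile <- function(max_db = 50, min_db = 10) {
  stopifnot(max_db >= min_db)
  structure(list(max_db = max_db, min_db = min_db), class = "snr_profile")
}

# Target SNR (dB) per kept measurement of a protocol: angular separation of
# pair midpoints within a ring (electrode angle = slot / per_ring * 2*pi).
channel_snr_db <- function(profile, protocol) {
  if (is.infinite(profile$max_db)) return(rep(Inf, protocol$frame_length))
  m <- protocol$electrodes_per_ring
  slot <- function(e) (e - 1L) %% m          # angular slot, ring-independent
  midang <- function(pairs) {
    a <- 2 * pi * slot(pairs[, 1]) / m
    b <- 2 * pi * slot(pairs[, 2]) / m
    a + (((b - a + pi) %% (2 * pi)) - pi) / 2  # circular midpoint
  }
  rows <- protocol_rows(protocol)
  ai <- midang(protocol$injections)[rows$injection]
  am <- midang(protocol$measurements)[rows$measurement]
  sep <- abs(((am - ai + pi) %% (2 * pi)) - pi)   # 0..pi
  profile$max_db - (profile$max_db - profile$min_db) * sep / pi
}

#' Corrupt a frame with calibrated carrier noise
#'
#' For every kept measurement: synthesise the carrier sine with amplitude
#' equal to the clean voltage, add white Gaussian noise scaled to the
#' channel's target pre-filter SNR, apply the zero-phase order-10 bandpass
#' centred on the carrier, and demodulate by taking the highest filtered
#' peak. The per-channel SNR comes from the [snr_profile()]; the operation
#' is deterministic given `seed`.
#'
#' @param clean an absolute `eit_frame`
#' @param profile an [snr_profile()]; use `snr_profile(Inf, Inf)` for a
#'   noise-free pass-through
#' @param cfg a [carrier_config()]
#' @param protocol the protocol the frame belongs to
#' @param seed integer seed
#' @return an absolute `eit_frame` of demodulated noisy voltages
#' @export
corrupt_frame <- function(clean, profile, cfg, protocol, seed = NULL) {
  stopifnot(clean$kind == "absolute")
  corrupt_impl(clean, profile, cfg, protocol, seed, noise_fun = function(n, nsd) rnorm(n, 0, nsd))
}

#' Corrupt a frame with heavy-tailed coloured noise
#'
#' Variant of [corrupt_frame()] for channels whose disturbances are not
#' white Gaussian (physiological sources such as organ movement): the
#' additive term is Laplacian (heavier-tailed than Gaussian at the same
#' power) shaped by a `1/f`-type spectral envelope below the carrier.
#'
#' @inheritParams corrupt_frame
#' @param heavy_tail_param mixing parameter in [0, 1]: 1 = pure Laplacian,
#'   0 recovers the Gaussian model of [corrupt_frame()]
#' @param spectrum_shape `"one_over_f"` or `"flat"`
#' @export
corrupt_frame_nongaussian <- function(clean, profile, cfg, protocol, seed = NULL,
                                      heavy_tail_param = 1, spectrum_shape = c("one_over_f", "flat")) {
  stopifnot(clean$kind == "absolute", heavy_tail_param >= 0, heavy_tail_param <= 1)
  spectrum_shape <- match.arg(spectrum_shape)
  nf <- function(n, nsd) {
    g <- rnorm(n, 0, nsd)
    # Laplace with the same power: scale b = nsd / sqrt(2)
    u <- runif(n, -0.5, 0.5)
    lap <- -nsd / sqrt(2) * sign(u) * log(1 - 2 * abs(u))
    x <- sqrt(1 - heavy_tail_param) * g + sqrt(heavy_tail_param) * lap
    if (spectrum_shape == "one_over_f" && n > 2) {
      fs <- (0:(n - 1)) / n
      fs <- pmin(fs, 1 - fs)
      env <- ifelse(fs > 0, 1 / sqrt(pmax(fs, 1 / n)), 1)
      xc <- Re(fft(fft(x) * env, inverse = TRUE)) / n
      x <- xc * (nsd / max(stats::sd(xc), 1e-300))   # renormalise to target power
    }
    x
  }
  corrupt_impl(clean, profile, cfg, protocol, seed, noise_fun = nf)
}

corrupt_impl <- function(clean, profile, cfg, protocol, seed, noise_fun) {
  snr <- channel_snr_db(profile, protocol)
  n <- cfg$samples_per_period * cfg$n_periods
  with_seed(seed, {
    out <- vapply(seq_along(clean$values), function(i) {
      v <- clean$values[i]
      wave <- carrier_wave(abs(v), cfg)
      if (is.finite(snr[i]) && abs(v) > 0) {
        sig_p <- mean(wave^2)
        noise_sd <- sqrt(sig_p / 10^(snr[i] / 10))
        wave <- wave + noise_fun(n, noise_sd)
      }
      sign(v) * demodulate_peak(bandpass_filter(wave, cfg))
    }, numeric(1))
    f <- clean
    f$values <- out
    f
  })
}
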
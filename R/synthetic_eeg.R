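#' Parameters of the synthetic EEG epoch generator
#'
#' Synthetic epochs are a sum of spectrally shaped (1/f^x) Gaussian background
#' noise and planted, covariate-scaled components: a frontocentral deflection
#' in the 275-350 ms window (feedback-related negativity; `frn_gain` microvolts
#' per unit scaled discrepancy, negative for a negativity), a centroparietal
#' late positivity over 350-700 ms (`late_pos_gain`, scaled by discrepancy),
#' and theta/alpha/beta oscillatory bursts over 180-500 ms whose *power* is
#' multiplied by `(1 + gain * covariate)` — theta follows the scaled
#' adjustment, alpha and beta the scaled discrepancy. Deflection kernels are
#' fixed-shape windowed half-cosines, so window integrals have closed forms.
#'
#' @param sampling_rate Hz (default 1024, the acquisition rate).
#' @param epoch_window Length-2 seconds relative to feedback onset; must cover
#'   all analysis windows and the time-frequency baseline (`[-0.4, 0.7]` s).
#' @param channels Ordered channel labels; only Fz/Cz/Pz carry planted
#'   components, extra channels receive background noise only.
#' @param frn_gain,late_pos_gain Deflection amplitudes in microvolts per unit
#'   scaled discrepancy.
#' @param theta_gain,alpha_gain,beta_gain Multiplicative band-power modulation
#'   per unit covariate (must keep `1 + gain * covariate >= 0` over \[0, 1\]).
#' @param osc_base_uv Baseline amplitudes (microvolts) of the three oscillatory
#'   bursts, named `theta`, `alpha`, `beta`.
#' @param noise_exponent Spectral slope x of the 1/f^x background.
#' @param noise_scale Background noise standard deviation in microvolts.
#' @param seed Integer seed.
#' @return An object of class `eeg_gen_params`.
#' @export
eeg_gen_params <- function(sampling_rate = 1024, epoch_window = c(-2, 2),
                           channels = c("Fz", "Cz", "Pz"),
                           frn_gain = -4, late_pos_gain = 5,
                           theta_gain = 0.5, alpha_gain = -0.4, beta_gain = -0.4,
                           osc_base_uv = c(theta = 2, alpha = 2, beta = 1),
                           noise_exponent = 1, noise_scale = 5, seed = 1L) {
  if (sampling_rate <= 0) stop_config("sampling_rate must be > 0")
  if (epoch_window[1] > -0.4 || epoch_window[2] < 0.7) {
    stop_config("epoch_window must contain [-0.4, 0.7] s")
  }
  structure(list(sampling_rate = sampling_rate, epoch_window = epoch_window,
                 channels = channels, frn_gain = frn_gain,
                 late_pos_gain = late_pos_gain, theta_gain = theta_gain,
                 alpha_gain = alpha_gain, beta_gain = beta_gain,
                 osc_base_uv = osc_base_uv, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, seed = seed),
            class = "eeg_gen_params")
}

# fixed scalp weighting of the planted components at the analysis electrodes
topo_weight <- function(channels, where = c("frontocentral", "centroparietal", "midline")) {
  where <- match.arg(where)
  w <- switch(where,
              frontocentral = c(Fz = 1, Cz = 0.8, Pz = 0.3),
              centroparietal = c(Fz = 0.3, Cz = 0.8, Pz = 1),
              midline = c(Fz = 1, Cz = 1, Pz = 1))
  out <- w[channels]
  out[is.na(out)] <- 0
  unname(out)
}

#' Windowed half-cosine deflection kernel
#'
#' `k(t) = 1 - cos(2 * pi * (t - t0) / (t1 - t0))` inside `[t0, t1)` and 0
#' outside: a raised-cosine bump normalized to unit mean over its own support
#' (peak 2), so that a planted component `gain * k(t)` shifts the window-mean
#' feature of its window by exactly `gain` microvolts — the gains are
#' calibrated in feature units.
#'
#' @param times Sample times in seconds.
#' @param window Length-2 window `c(t0, t1)` in seconds.
#' @return Numeric vector of kernel values at `times`.
#' @export
erp_kernel <- function(times, window) {
  inside <- times >= window[1] & times < window[2]
  k <- numeric(length(times))
  k[inside] <- 1 - cos(2 * pi * (times[inside] - window[1]) / diff(window))
  k
}

# 1/f^x shaped Gaussian noise, unit variance, length n
one_over_f_noise <- function(n, exponent, sfreq) {
  freqs <- seq(0, sfreq / 2, length.out = floor(n / 2) + 1)
  amp <- c(0, freqs[-1]^(-exponent / 2))
  re <- stats::rnorm(length(freqs))
  im <- stats::rnorm(length(freqs))
  half <- complex(real = re, imaginary = im) * amp
  # hermitian-symmetric spectrum -> real signal
  if (n %% 2 == 0) {
    spec <- c(half, Conj(rev(half[2:(length(half) - 1)])))
  } else {
    spec <- c(half, Conj(rev(half[2:length(half)])))
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else (x - mean(x)) / s
}

erp_windows_gen <- list(frn = c(0.275, 0.350), late_pos = c(0.350, 0.700))
osc_freqs_gen <- c(theta = 6, alpha = 10, beta = 20)
osc_window_gen <- c(0.180, 0.500)

#' Synthesize EEG epochs for a behavior table
#'
#' Generates one epoch per behavior row (participant x trial x feedback) with
#' planted components scaled by that row's covariates. Scaled discrepancy and
#' adjustment are computed on the fly when absent; missing covariates plant
#' nothing (treated as 0).
#'
#' @param behavior Behavior table (see [simulate_dyad_behavior()]).
#' @param gen An [eeg_gen_params()] object.
#' @return An `epoch_set` whose events carry the behavior columns.
#' @export
simulate_eeg_epochs <- function(behavior, gen = eeg_gen_params()) {
  stopifnot(inherits(gen, "eeg_gen_params"))
  if (!"scaled_discrepancy" %in% names(behavior)) {
    behavior <- scale_discrepancy(compute_discrepancy(behavior))
  }
  if (!"scaled_adjustment" %in% names(behavior)) {
    behavior <- compute_adjustment(behavior)
  }
  sfreq <- gen$sampling_rate
  times <- seq(round(gen$epoch_window[1] * sfreq),
               round(gen$epoch_window[2] * sfreq)) / sfreq
  n_s <- length(times)
  n_e <- nrow(behavior)
  n_c <- length(gen$channels)
  sdisc <- ifelse(is.na(behavior$scaled_discrepancy), 0, behavior$scaled_discrepancy)
  sadj <- ifelse(is.na(behavior$scaled_adjustment), 0, behavior$scaled_adjustment)

  k_frn <- erp_kernel(times, erp_windows_gen$frn)
  k_lp <- erp_kernel(times, erp_windows_gen$late_pos)
  env <- erp_kernel(times, osc_window_gen) / 2  # unit-peak burst envelope
  w_fc <- topo_weight(gen$channels, "frontocentral")
  w_cp <- topo_weight(gen$channels, "centroparietal")
  w_mid <- topo_weight(gen$channels, "midline")
  osc_cov <- list(theta = sadj, alpha = sdisc, beta = sdisc)
  osc_gain <- c(theta = gen$theta_gain, alpha = gen$alpha_gain, beta = gen$beta_gain)

  with_seed(gen$seed, {
    dat <- array(0, dim = c(n_e, n_c, n_s))
    for (e in seq_len(n_e)) {
      for (ch in seq_len(n_c)) {
        x <- if (gen$noise_scale > 0) {
          gen$noise_scale * one_over_f_noise(n_s, gen$noise_exponent, sfreq)
        } else {
          numeric(n_s)
        }
        x <- x + gen$frn_gain * sdisc[e] * w_fc[ch] * k_frn +
          gen$late_pos_gain * sdisc[e] * w_cp[ch] * k_lp
        for (b in names(osc_freqs_gen)) {
          amp2 <- max(0, 1 + osc_gain[[b]] * osc_cov[[b]][e])
          amp <- gen$osc_base_uv[[b]] * sqrt(amp2) * w_mid[ch]
          if (amp > 0) {
            phase <- stats::runif(1, 0, 2 * pi)
            x <- x + amp * env * sin(2 * pi * osc_freqs_gen[[b]] * times + phase)
          }
        }
        dat[e, ch, ] <- x
      }
    }
    events <- behavior
    events$epoch_index <- seq_len(n_e)
    epoch_set(dat, sfreq, times, gen$channels, events)
  })
}

#' Inject spike artifacts into a fraction of epochs
#'
#' Exactly `round(fraction * n_epochs)` randomly chosen epochs receive a spike
#' of `+/- amplitude_uv` on one random channel at a random sample inside
#' -100 ms to 1000 ms; injected epochs are flagged in
#' `events$artifact_injected`.
#'
#' @param epochs An `epoch_set`.
#' @param fraction Fraction of epochs in \[0, 1\].
#' @param amplitude_uv Spike amplitude in microvolts.
#' @param seed Integer seed.
#' @export
inject_artifacts <- function(epochs, fraction, amplitude_uv = 150, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop_config("fraction must be in [0, 1]")
  n <- n_epochs(epochs)
  n_bad <- round(fraction * n)
  epochs$events$artifact_injected <- rep(FALSE, n)
  if (n_bad == 0) return(epochs)
  window_idx <- which(epochs$times >= -0.1 & epochs$times <= 1.0)
  with_seed(seed, {
    bad <- sample(n, n_bad)
    for (e in bad) {
      ch <- sample(length(epochs$channels), 1)
      s <- sample(window_idx, 1)
      epochs$data[e, ch, s] <- sample(c(-1, 1), 1) * amplitude_uv
    }
    epochs$events$artifact_injected[bad] <- TRUE
    epochs
  })
}
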
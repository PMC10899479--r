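test_that("band-pass keeps the passband, rejects the stopband, and removes DC", {
  sfreq <- 512
  t <- seq(0, 4, by = 1 / sfreq)
  mid <- t > 1 & t < 3
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(x10, sfreq, 0.5, 30)
  expect_lt(abs(max(abs(y10[mid])) - 1), 0.01)
  y60 <- bandpass_filter(sin(2 * pi * 60 * t), sfreq, 0.5, 30)
  expect_lt(20 * log10(max(abs(y60[mid]))), -20)
  ydc <- bandpass_filter(rep(3, length(t)) + x10, sfreq, 0.5, 30)
  expect_lt(abs(mean(ydc[mid])), 0.05)
  expect_error(bandpass_filter(x10, sfreq, 30, 0.5), class = "dyadconv_config_error")
})

test_that("white-noise output spectrum follows the filter's magnitude response", {
  set.seed(3)
  sfreq <- 256
  x <- rnorm(sfreq * 16)
  y <- bandpass_filter(x, sfreq, 1, 30)
  spec_in <- Mod(fft(x))^2
  spec_out <- Mod(fft(y))^2
  freqs <- (seq_along(x) - 1) * sfreq / length(x)
  pass <- freqs > 5 & freqs < 25
  stopb <- freqs > 60 & freqs < 120
  expect_lt(abs(10 * log10(mean(spec_out[pass]) / mean(spec_in[pass]))), 1)
  expect_lt(10 * log10(mean(spec_out[stopb]) / mean(spec_in[stopb])), -25)
})

test_that("epoching slices the record and subtracts the baseline mean", {
  sfreq <- 100
  rec <- matrix(7, nrow = 1, ncol = 10 * sfreq)
  ev <- data.frame(id = 1:2)
  ep <- epoch_and_baseline(rec, sfreq, onsets = c(3, 6), events = ev,
                           channels = "Fz", tmin = -1, tmax = 1)
  expect_true(all(abs(ep$data) < 1e-12))

  rec2 <- matrix(0, 1, 10 * sfreq)
  rec2[1, (5 * sfreq + 1):(10 * sfreq)] <- 5  # +5 uV step at t = 5 s
  ep2 <- epoch_and_baseline(rec2, sfreq, onsets = 5, events = ev[1, , drop = FALSE],
                            channels = "Fz", tmin = -1, tmax = 1)
  expect_true(all(ep2$data[1, 1, ep2$times >= 0] == 5))
  expect_true(all(ep2$data[1, 1, ep2$times < 0] == 0))

  set.seed(4)
  rec3 <- matrix(rnorm(2 * 10 * sfreq), nrow = 2)
  ep3 <- epoch_and_baseline(rec3, sfreq, onsets = 4.5, events = ev[1, , drop = FALSE],
                            channels = c("Fz", "Cz"), tmin = -0.5, tmax = 0.5)
  rel <- seq(round(-0.5 * sfreq), round(0.5 * sfreq))
  for (ch in 1:2) {
    sl <- rec3[ch, round(4.5 * sfreq) + 1 + rel]
    bl <- mean(sl[rel / sfreq >= -0.1 & rel / sfreq < 0])
    expect_equal(as.numeric(ep3$data[1, ch, ]), sl - bl)
  }
  expect_warning(epoch_and_baseline(rec, sfreq, onsets = 0.1, events = ev[1, , drop = FALSE],
                                    channels = "Fz", tmin = -1, tmax = 1),
                 "skipped")
})

test_that("amplitude rejection honors the inspection window and is monotone", {
  dat <- array(0, c(3, 1, 300))
  ep <- fixture_epochs(dat, sfreq = 100, tmin = -0.5)  # times -0.5 .. 2.49
  ep$data[1, 1, which.min(abs(ep$times - 0.5))] <- 150   # inside window
  ep$data[2, 1, which.min(abs(ep$times - 1.5))] <- 150   # outside window
  ep$data[3, 1, ] <- 99
  out <- reject_artifacts(ep, 100, window = c(-0.1, 1))
  expect_identical(out$rejected, c(TRUE, FALSE, FALSE))
  lower <- reject_artifacts(ep, 90, window = c(-0.1, 1))
  expect_true(all(out$rejected <= lower$rejected |
                    which(out$rejected) %in% which(lower$rejected)))
})

test_that("ERP window means equal masked means, are linear, and conserve counts", {
  sfreq <- 200
  n <- 1 + 2 * sfreq
  const <- fixture_epochs(array(5, c(1, 1, n)), sfreq, tmin = -0.5)
  const$channels <- "Fz"
  f <- erp_window_means(const, electrodes = "Fz")
  expect_equal(f$value, rep(5, 4))

  # linear ramp 0 -> 10 over 0..1000 ms: window mean = ramp at window midpoint
  ramp <- fixture_epochs(array(0, c(1, 1, n)), sfreq, tmin = -0.5)
  ramp$channels <- "Fz"
  tt <- ramp$times
  ramp$data[1, 1, ] <- ifelse(tt >= 0 & tt <= 1, 10 * tt, 0)
  fr <- erp_window_means(ramp, electrodes = "Fz")
  for (w in names(erp_windows_ms())) {
    wint <- erp_windows_ms()[[w]] / 1000
    expect_lt(abs(fr$value[fr$window == w] - 10 * mean(wint)), 10 / sfreq)
  }

  set.seed(9)
  x <- fixture_epochs(array(rnorm(2 * 2 * n), c(2, 2, n)), sfreq, tmin = -0.5)
  x$channels <- c("Fz", "Cz")
  fx <- erp_window_means(x, electrodes = c("Fz", "Cz"))
  expect_equal(nrow(fx), 2 * 2 * 4)  # epochs x electrodes x windows
  for (i in sample(nrow(fx), 8)) {
    sel <- x$times >= erp_windows_ms()[[fx$window[i]]][1] / 1000 &
      x$times < erp_windows_ms()[[fx$window[i]]][2] / 1000
    expect_equal(fx$value[i],
                 mean(x$data[fx$trial_index[i], match(fx$electrode[i], x$channels), sel]))
  }
  # linearity
  y <- fixture_epochs(array(rnorm(2 * 2 * n), c(2, 2, n)), sfreq, tmin = -0.5)
  y$channels <- c("Fz", "Cz")
  z <- x; z$data <- 2 * x$data + 3 * y$data
  fy <- erp_window_means(y, electrodes = c("Fz", "Cz"))
  fz <- erp_window_means(z, electrodes = c("Fz", "Cz"))
  expect_equal(fz$value, 2 * fx$value + 3 * fy$value)
  expect_error(erp_window_means(x, electrodes = "Oz"), class = "dyadconv_config_error")
})

test_that("Morlet power: stationary plateau, quadratic amplitude scaling, leakage", {
  sfreq <- 256
  n <- 4 * sfreq + 1
  tt <- seq(-2, 2, by = 1 / sfreq)
  for (A in c(1, 2)) {
    ep <- fixture_epochs(array(A * sin(2 * pi * 10 * tt), c(1, 1, n)), sfreq, tmin = -2)
    p <- morlet_power(ep, freqs = c(6, 10, 20))
    valid <- attr(p, "edge_valid")[2, ]
    plateau <- p[1, 1, 2, valid]
    expect_lt(sd(plateau) / mean(plateau), 0.01)
    if (A == 1) p1 <- mean(plateau) else expect_equal(mean(plateau) / p1, 4, tolerance = 0.01)
  }
  # power at 6 Hz insensitive to the 20 Hz component's amplitude
  ep_a <- fixture_epochs(array(sin(2 * pi * 6 * tt), c(1, 1, n)), sfreq, tmin = -2)
  ep_b <- fixture_epochs(array(sin(2 * pi * 6 * tt) + 3 * sin(2 * pi * 20 * tt),
                               c(1, 1, n)), sfreq, tmin = -2)
  pa <- morlet_power(ep_a, freqs = 6); pb <- morlet_power(ep_b, freqs = 6)
  v <- attr(pa, "edge_valid")[1, ]
  expect_lt(max(abs(pb[1, 1, 1, v] - pa[1, 1, 1, v])) / mean(pa[1, 1, 1, v]), 0.02)
})

test_that("FFT-based Morlet convolution matches direct time-domain convolution", {
  set.seed(12)
  sfreq <- 128
  n <- 2 * sfreq + 1
  x <- rnorm(n)
  ep <- fixture_epochs(array(x, c(1, 1, n)), sfreq, tmin = -1)
  p <- morlet_power(ep, freqs = c(5, 11))
  for (fi in 1:2) {
    w <- morlet_wavelet(c(5, 11)[fi], sfreq, 7, max_samples = n)
    half <- (length(w) - 1) %/% 2
    direct <- vapply(seq_len(n), function(i) {
      m <- seq(max(1, i - half), min(n, i + half))
      Mod(sum(x[m] * w[i - m + half + 1]))^2
    }, numeric(1))
    expect_lt(max(abs(direct - p[1, 1, fi, ])) / max(direct), 1e-6)
  }
  expect_error(morlet_wavelet(1, sfreq = 100, max_samples = 51),
               class = "dyadconv_config_error")
})

test_that("baseline-ratio normalization self-normalizes and scales with power", {
  sfreq <- 128
  tt <- seq(-2, 2, by = 1 / sfreq)
  n <- length(tt)
  # amplitude doubles well after the baseline so wavelet smearing (about
  # +/- 0.42 s for a 7-cycle 8 Hz wavelet) cannot leak into it
  amp <- ifelse(tt >= 0.8, 2, 1)
  ep <- fixture_epochs(array(amp * sin(2 * pi * 8 * tt), c(1, 1, n)), sfreq, tmin = -2)
  p <- morlet_power(ep, freqs = 8)
  np <- baseline_ratio(p, baseline = c(-0.4, -0.1))
  interior_pre <- tt > -1.2 & tt < -0.5
  interior_post <- tt > 1.3 & tt < 1.55
  expect_equal(mean(np[1, 1, 1, interior_pre]), 1, tolerance = 0.02)
  expect_equal(mean(np[1, 1, 1, interior_post]), 4, tolerance = 0.05)
  # brute-force division oracle
  set.seed(2)
  ep2 <- fixture_epochs(array(rnorm(2 * 1 * n), c(2, 1, n)), sfreq, tmin = -2)
  p2 <- morlet_power(ep2, freqs = c(6, 12))
  np2 <- baseline_ratio(p2)
  bsel <- ep2$times >= -0.4 & ep2$times < -0.1
  for (e in 1:2) for (fi in 1:2) {
    expect_equal(np2[e, 1, fi, ], p2[e, 1, fi, ] / mean(p2[e, 1, fi, bsel]))
  }
  zero <- fixture_epochs(array(0, c(1, 1, n)), sfreq, tmin = -2)
  pz <- morlet_power(zero, freqs = 8)
  expect_error(baseline_ratio(pz), class = "dyadconv_config_error")
})

test_that("band/window means respect band edges and match a masked-mean oracle", {
  sfreq <- 128
  tt <- seq(-2, 2, by = 1 / sfreq)
  n <- length(tt)
  set.seed(6)
  ep <- fixture_epochs(array(rnorm(n, sd = 3), c(1, 1, n)), sfreq, tmin = -2)
  ep$channels <- "Fz"
  p <- morlet_power(ep, freqs = 1:30)
  np <- baseline_ratio(p)
  f <- band_window_means(np, ep, electrodes = "Fz")
  freqs <- 1:30
  for (i in seq_len(nrow(f))) {
    b <- freq_bands()[[f$band[i]]]
    fsel <- if (b[1] == 4) freqs >= b[1] & freqs <= b[2] else freqs > b[1] & freqs <= b[2]
    wint <- tf_windows_ms()[[f$window[i]]] / 1000
    tsel <- ep$times >= wint[1] & ep$times < wint[2]
    expect_equal(f$value[i], mean(np[1, 1, fsel, tsel]))
  }
  # 8 Hz belongs to theta, not alpha
  theta_mask <- freqs >= 4 & freqs <= 8
  alpha_mask <- freqs > 8 & freqs <= 12
  expect_true(8 %in% freqs[theta_mask] && !(8 %in% freqs[alpha_mask]))

  ones <- np; ones[] <- 1
  attr(ones, "times") <- attr(np, "times")
  f1 <- band_window_means(ones, ep, electrodes = "Fz")
  expect_true(all(f1$value == 1))

  single <- morlet_power(ep, freqs = 10)
  nps <- baseline_ratio(single)
  fs <- band_window_means(nps, ep, bands = list(alpha = c(8, 12)), electrodes = "Fz")
  wint <- tf_windows_ms()[["180-230"]] / 1000
  tsel <- ep$times >= wint[1] & ep$times < wint[2]
  expect_equal(fs$value[fs$window == "180-230"], mean(nps[1, 1, 1, tsel]))
})

test_that("rejected epochs are excluded from every feature table", {
  sfreq <- 128
  n <- 2 * sfreq + 1
  dat <- array(rnorm(3 * 1 * n), c(3, 1, n))
  ep <- fixture_epochs(dat, sfreq, tmin = -1)
  ep$channels <- "Fz"
  ep$times <- seq(-1, 1, by = 1 / sfreq)
  ep$rejected <- c(FALSE, TRUE, FALSE)
  f <- erp_window_means(ep, windows = list("275-350" = c(275, 350)), electrodes = "Fz")
  expect_equal(sort(unique(f$trial_index)), c(1, 3))
})
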
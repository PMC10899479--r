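# shared fixtures and independent oracles, all built in code

tiny_settings <- function(seed = 1L, chains = 2, iterations = 700, warmup = 250) {
  sampler_settings(chains = chains, iterations = iterations, warmup = warmup,
                   seed = seed)
}

# hand-built two-dyad behavior table (one trial each, three repetitions)
fixture_behavior <- function() {
  data.frame(
    dyad_id = rep(c(1, 2), each = 6),
    participant_id = rep(c("a1", "a2", "b1", "b2"), each = 3),
    group = "Cooperative",
    trial_index = 1,
    block_index = 1,
    feedback_index = rep(1:3, 4),
    estimate = c(50, 44, 47,   # dyad 1, member 1
                 42, 47, 47,   # dyad 1, member 2
                 63, 63, 63,   # dyad 2, member 1
                 63, 63, 63)   # dyad 2, member 2
  )
}

# independent re-implementation of the dyad generative rule (per-trial loop,
# own RNG stream) used as a Monte-Carlo oracle for distributional statistics
oracle_simulate <- function(n_trials, true_pos, pa, pb, seed) {
  set.seed(seed)
  est <- array(NA_real_, c(n_trials, 2, 3))
  prm <- list(pa, pb)
  rnd <- function(x, p) if (p$response_rounding == "integer") round(x) else x
  for (tr in seq_len(n_trials)) {
    for (p in 1:2) {
      est[tr, p, 1] <- rnd(true_pos + rnorm(1, 0, prm[[p]]$perceptual_noise_sd), prm[[p]])
    }
    for (k in 1:2) {
      for (p in 1:2) {
        own <- est[tr, p, k]; partner <- est[tr, 3 - p, k]
        if (runif(1) < prm[[p]]$p_match) {
          est[tr, p, k + 1] <- partner
        } else {
          est[tr, p, k + 1] <- rnd(own + prm[[p]]$lambda * (partner - own) +
                                     rnorm(1, 0, prm[[p]]$update_noise_sd), prm[[p]])
        }
      }
    }
  }
  est
}

# small epoch set with arbitrary data
fixture_epochs <- function(data, sfreq = 100, tmin = -0.5) {
  n <- dim(data)[3]
  times <- seq(tmin, by = 1 / sfreq, length.out = n)
  epoch_set(data, sfreq, times, paste0("ch", seq_len(dim(data)[2]))[seq_len(dim(data)[2])],
            data.frame(dyad_id = 1, participant_id = "p1",
                       trial_index = seq_len(dim(data)[1]), feedback_index = 1))
}

# minimal posterior_samples object for contrast-arithmetic tests
fixture_samples <- function(draws_list, covariate = NULL) {
  nm <- names(draws_list)
  n <- length(draws_list[[1]])
  arr <- array(NA_real_, c(1, n, length(nm)), dimnames = list(NULL, NULL, nm))
  for (i in seq_along(nm)) arr[1, , i] <- draws_list[[i]]
  spec <- model_spec("feedback-simple")
  spec$covariate <- covariate
  structure(list(draws = arr, parameters = nm, warmup_discarded = 0,
                 settings = sampler_settings(chains = 1),
                 diagnostics = list(divergences = 0L, treedepth_exceeded = 0L),
                 meta = list(X_cols = sub("^b_", "", nm[startsWith(nm, "b_")]),
                             spec = spec, response = numeric(0), cell = NULL)),
            class = "posterior_samples")
}

# batch-means Monte-Carlo standard error for correlated draws
mcse_batch <- function(x, batch = 50) {
  nb <- floor(length(x) / batch)
  bm <- colMeans(matrix(x[seq_len(nb * batch)], nrow = batch))
  sd(bm) / sqrt(nb)
}
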
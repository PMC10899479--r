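test_that("design construction: nesting counts, treatment coding, interactions", {
  beh <- compute_discrepancy(fixture_behavior())
  spec <- model_spec("group-interaction")
  des <- build_design(beh, spec)
  expect_equal(des$blocks[[1]]$n, 2)   # dyads
  expect_equal(des$blocks[[2]]$n, 4)   # participants within dyads
  expect_true(all(c("(Intercept)", "feedbackfb2", "feedbackfb3") %in% colnames(des$X)))
  expect_equal(unname(des$X[, "feedbackfb2"]),
               as.numeric(des$data$feedback_index == 2))

  # interaction columns are elementwise products of the main-effect columns
  feat <- data.frame(dyad_id = rep(1:2, each = 12), participant_id = rep(1:4, each = 6),
                     trial_index = rep(1:2, 12), feedback_index = rep(1:3, 8),
                     value = rnorm(24), scaled_discrepancy = runif(24),
                     cell = rep(c("w:Fz", "w:Cz"), 12))
  des2 <- build_design(feat, model_spec("discrepancy-fb"))
  X <- des2$X
  for (f in 2:3) {
    expect_equal(unname(X[, paste0("feedbackfb", f, ":scaled_discrepancy")]),
                 unname(X[, paste0("feedbackfb", f)] * X[, "scaled_discrepancy"]))
  }
  # one independent effect block per fixed column per cell grouping
  cell_blocks <- Filter(function(b) startsWith(b$name, "cell:"), des2$blocks)
  expect_equal(length(cell_blocks), ncol(X))
  expect_error(build_design(beh[, setdiff(names(beh), "group")], spec),
               class = "dyadconv_structure_error")
})

test_that("hurdle-gamma density integrates to one and contributes log(pi) at zero", {
  pi0 <- 0.3; mu <- 2.5; shape <- 1.7
  expect_equal(dhurdle_gamma(0, pi0, mu, shape, log = TRUE), log(pi0))
  total <- pi0 + integrate(function(y) dhurdle_gamma(y, pi0, mu, shape),
                           0, Inf, rel.tol = 1e-9)$value
  expect_lt(abs(total - 1), 1e-6)
  expect_error(dhurdle_gamma(-1, pi0, mu, shape), class = "dyadconv_config_error")
})

test_that("log density: support errors, finiteness at zero init, student-t normal limit", {
  beh <- compute_discrepancy(fixture_behavior())
  des <- build_design(beh, model_spec("feedback-simple"))
  theta <- setNames(rep(0, length(dyadconv:::param_names(des))),
                    dyadconv:::param_names(des))
  expect_true(is.finite(log_density(des, theta)))
  # continuity in a parameter
  eps <- 1e-6
  th2 <- theta; th2[1] <- th2[1] + eps
  expect_lt(abs(log_density(des, th2) - log_density(des, theta)), 1e-2)

  neg <- beh; neg$discrepancy[1] <- -1
  expect_error(build_design(neg, model_spec("feedback-simple")),
               class = "dyadconv_config_error")
  zero_tf <- data.frame(dyad_id = 1, participant_id = "p", trial_index = 1,
                        feedback_index = 1, value = 0, cell = "a")
  spec_tf <- model_spec("feedback-signal", family = "gamma_log")
  expect_error(build_design(zero_tf, spec_tf), class = "dyadconv_config_error")

  # student-t likelihood approaches the normal at huge degrees of freedom
  y <- c(-1.3, 0.2, 2.1)
  aux <- c(lsigma = log(1.4), lnu = log(1e6 - 1))
  des_t <- list(family = "student_t", y = y, spec = list(sigma_fixed = NULL))
  ll_t <- dyadconv:::family_loglik(des_t, rep(0.3, 3), aux)
  ll_n <- sum(dnorm(y, 0.3, 1.4, log = TRUE))
  expect_lt(abs(ll_t - ll_n), 1e-4)
})

test_that("cumulative probit category probabilities sum to one", {
  aux <- c(thr1 = -0.7, ldelta2 = 0.1, ldelta3 = -0.4, ldelta4 = 0.6)
  th <- dyadconv:::probit_thresholds(aux, 5)
  expect_equal(length(th), 4)
  expect_true(all(diff(th) > 0))
  for (eta in c(-1, 0, 1.2)) {
    p <- pnorm(c(th, Inf) - eta) - pnorm(c(-Inf, th) - eta)
    expect_equal(sum(p), 1)
  }
})

test_that("posterior matches the conjugate closed form for a gaussian model", {
  set.seed(1)
  n <- 50; sigma <- 2
  y <- rnorm(n, 1.5, sigma)
  df <- data.frame(dyad_id = 1, participant_id = "p1", trial_index = seq_len(n),
                   feedback_index = 3, group = "Cooperative", accuracy = y)
  spec <- model_spec("accuracy", family = "gaussian", sigma_fixed = sigma)
  spec$random <- list()
  spec$formula <- ~ 1
  fit <- sample_posterior(spec, df, sampler_settings(chains = 4, iterations = 3000,
                                                     warmup = 500, seed = 5))
  d <- parameter_draws(fit, "b_(Intercept)")
  post_prec <- 1 + n / sigma^2
  expect_lt(abs(mean(d) - (sum(y) / sigma^2) / post_prec), 3 * mcse_batch(d))
  expect_equal(sd(d), sqrt(1 / post_prec), tolerance = 0.05)
  expect_true(check_convergence(fit)$converged)
})

test_that("prior-only sampling recovers the prior moments", {
  beh <- compute_discrepancy(fixture_behavior())
  fit <- sample_posterior(model_spec("feedback-simple"), beh,
                          sampler_settings(chains = 2, iterations = 4200, warmup = 200,
                                           seed = 3),
                          prior_only = TRUE)
  b <- parameter_draws(fit, "b_(Intercept)")
  expect_equal(mean(b), 0, tolerance = 0.05)
  expect_equal(sd(b), 1, tolerance = 0.05)
  sd_dyad <- parameter_draws(fit, "sd_dyad:(Intercept)")
  expect_equal(mean(sd_dyad), 0.1, tolerance = 0.01)  # Gamma(1, 10) prior mean
})

test_that("sampling is deterministic in the seed and decisions are seed-robust", {
  sim <- simulate_study(6, 40, 2, agent_params(2, 0.35, 0.1), seed = 17)
  beh <- clean_responses(compute_discrepancy(sim$behavior), "discrepancy", 95, "na")
  s <- function(seed) sample_posterior(model_spec("feedback-simple"), beh,
                                       tiny_settings(seed, iterations = 1100, warmup = 350))
  f1 <- s(1)
  expect_identical(s(1)$draws, f1$draws)
  f2 <- s(2)
  rope <- build_rope(f1$meta$response, 0.05)
  d1 <- decide(hdi(contrast(f1, "fb2-fb1")), rope, 2)
  d2 <- decide(hdi(contrast(f2, "fb2-fb1")), rope, 2)
  expect_identical(d1$decision, d2$decision)
  expect_identical(d1$decision, "credible_effect")
})

test_that("feedback contrasts recover the planted convergence on synthetic dyads", {
  sim <- simulate_study(8, 50, 2, agent_params(2, 0.4, 0.1), seed = 23)
  beh <- clean_responses(compute_discrepancy(sim$behavior), "discrepancy", 95, "na")
  fit <- sample_posterior(model_spec("feedback-simple"), beh,
                          tiny_settings(7, iterations = 1200, warmup = 400))
  h <- hdi(contrast(fit, "fb2-fb1"))
  expect_lt(h[2], 0)  # 95% HDI excludes zero, in the convergence direction
  # FB3-FB2 equals the brute-force per-draw subtraction
  expect_equal(contrast(fit, "fb3-fb2"),
               parameter_draws(fit, "b_feedbackfb3") - parameter_draws(fit, "b_feedbackfb2"))
})

test_that("permuting dyad labels leaves the posterior unchanged up to MC error", {
  sim <- simulate_study(6, 30, 2, agent_params(2, 0.35, 0.1), seed = 29)
  beh <- compute_discrepancy(sim$behavior)
  perm <- beh
  relabel <- setNames(sample(unique(beh$dyad_id)), unique(beh$dyad_id))
  perm$dyad_id <- relabel[as.character(beh$dyad_id)]
  f1 <- sample_posterior(model_spec("feedback-simple"), beh,
                         tiny_settings(5, iterations = 1500, warmup = 400))
  f2 <- sample_posterior(model_spec("feedback-simple"), perm,
                         tiny_settings(5, iterations = 1500, warmup = 400))
  c1 <- contrast(f1, "fb2-fb1"); c2 <- contrast(f2, "fb2-fb1")
  tol <- 3 * sqrt(mcse_batch(c1)^2 + mcse_batch(c2)^2)
  expect_lt(abs(mean(c1) - mean(c2)), max(tol, 0.02))
})

test_that("doubling the slope prior barely moves a well-identified contrast", {
  sim <- simulate_study(6, 40, 2, agent_params(2, 0.35, 0.1), seed = 31)
  beh <- compute_discrepancy(sim$behavior)
  f1 <- sample_posterior(model_spec("feedback-simple"), beh,
                         tiny_settings(3, iterations = 1200, warmup = 400))
  f2 <- sample_posterior(model_spec("feedback-simple", priors = list(b_sd = 2)), beh,
                         tiny_settings(3, iterations = 1200, warmup = 400))
  c1 <- contrast(f1, "fb2-fb1"); c2 <- contrast(f2, "fb2-fb1")
  expect_lt(abs(mean(c1) - mean(c2)), 0.1 * sd(c1) + 3 * mcse_batch(c1))
})

test_that("split R-hat flags designed failures and matches the textbook formula", {
  set.seed(8)
  same <- matrix(rnorm(4 * 1000), nrow = 4)
  expect_lt(split_rhat(same), 1.01)
  shifted <- rbind(rnorm(500), rnorm(500) + 3)
  expect_gt(split_rhat(shifted), 1.01)

  draws <- matrix(rnorm(2 * 400, sd = 2), nrow = 2)
  # literal split-chain variance-ratio implementation
  halves <- list(draws[1, 1:200], draws[1, 201:400], draws[2, 1:200], draws[2, 201:400])
  m <- 4; nn <- 200
  W <- mean(vapply(halves, var, numeric(1)))
  B <- nn * var(vapply(halves, mean, numeric(1)))
  oracle <- sqrt(((nn - 1) / nn * W + B / nn) / W)
  expect_equal(split_rhat(draws), oracle)

  fake <- fixture_samples(list(`b_(Intercept)` = rnorm(100)))
  expect_error(check_convergence(fake), class = "dyadconv_config_error")
})

test_that("contrast arithmetic follows the sign-permuted reporting convention", {
  b2 <- rnorm(200); b3 <- rnorm(200); cov <- rnorm(200); int2 <- rnorm(200)
  s <- fixture_samples(list(`b_(Intercept)` = rnorm(200), b_feedbackfb2 = b2,
                            b_feedbackfb3 = b3, b_scaled_discrepancy = cov,
                            `b_feedbackfb2:scaled_discrepancy` = int2),
                       covariate = "scaled_discrepancy")
  expect_identical(contrast(s, "fb2-fb1"), b2)
  expect_equal(contrast(s, "fb3-fb2"), b3 - b2)
  expect_identical(contrast(s, "covariate-max-vs-min", feedback = 1), cov)
  expect_equal(contrast(s, "covariate-max-vs-min", feedback = 2), cov + int2)
  # zero interaction draws degenerate to the main effect
  s0 <- fixture_samples(list(b_scaled_discrepancy = cov,
                             `b_feedbackfb2:scaled_discrepancy` = rep(0, 200)),
                        covariate = "scaled_discrepancy")
  expect_equal(contrast(s0, "covariate-max-vs-min", feedback = 2), cov)
  expect_error(contrast(s, "group-at-fb", feedback = 3), class = "dyadconv_config_error")
})

test_that("accuracy and adjustment models build their stated designs and fit", {
  sim <- simulate_study(4, 20, 2, agent_params(2, 0.4, 0.1), seed = 41)
  beh <- compute_adjustment(scale_discrepancy(compute_discrepancy(sim$behavior)))
  beh <- compute_accuracy(beh, sim$stimuli)

  des_acc <- build_design(beh, model_spec("accuracy"))
  expect_equal(unique(des_acc$data$feedback_index), 3)  # one row set per trial
  fit <- sample_posterior(model_spec("accuracy"), beh, tiny_settings(2))
  expect_true(all(is.finite(parameter_draws(fit, "b_(Intercept)"))))

  feat <- data.frame(beh[!is.na(beh$scaled_adjustment), ],
                     value = rnorm(sum(!is.na(beh$scaled_adjustment))),
                     cell = "275-350:Fz")
  des_adj <- build_design(feat, model_spec("adjustment-fb"))
  # the adjustment model pairs epochs at FB1/FB2 with the following adjustment
  expect_true(all(des_adj$data$feedback_index %in% 1:2))
  expect_true("feedbackfb2:scaled_adjustment" %in% colnames(des_adj$X))
})
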
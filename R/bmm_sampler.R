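#' MCMC settings
#'
#' Default test-scale settings (4 chains, 1,500 iterations with 500 discarded
#' as warmup); [paper_settings()] gives the full-scale run (4 chains, 10,000
#' iterations, 1,000 warmup, acceptance target 0.9, maximum tree depth 10).
#' Chains are initialized at zero on the unconstrained scale. The
#' `target_accept` and `max_tree_depth` fields describe tree-based gradient
#' samplers and are carried in the settings for interface compatibility; the
#' package's adaptive Metropolis-within-Gibbs sampler records them but tunes
#' its own proposal scales during warmup.
#'
#' @param chains Number of chains (>= 2 for convergence checks).
#' @param iterations Total iterations per chain (including warmup).
#' @param warmup Iterations discarded (and used for adaptation).
#' @param target_accept,max_tree_depth Recorded settings (see above).
#' @param init Initial value on the unconstrained scale (0).
#' @param seed Integer seed.
#' @export
sampler_settings <- function(chains = 4, iterations = 1500, warmup = 500,
                             target_accept = 0.9, max_tree_depth = 10,
                             init = 0, seed = 1L) {
  stopifnot(iterations > warmup, chains >= 1)
  list(chains = chains, iterations = iterations, warmup = warmup,
       target_accept = target_accept, max_tree_depth = max_tree_depth,
       init = init, seed = seed)
}

#' @rdname sampler_settings
#' @export
paper_settings <- function(seed = 1L) {
  sampler_settings(chains = 4, iterations = 10000, warmup = 1000, seed = seed)
}

# ---------------------------------------------------------------------------
# Likelihood kernels over the support rows (positive rows for hurdle-gamma,
# all rows otherwise). `sup` is the integer vector of support rows; per-row
# values are cached by the chain so each Metropolis step costs one kernel
# evaluation on the rows it touches.

support_rows <- function(design) {
  if (design$family == "hurdle_gamma") design$pos else seq_along(design$y)
}

# per-row log likelihood at linear predictor eta_s for support positions s
kernel_ll <- function(design, eta_s, aux, s) {
  y <- design$y_sup[s]
  switch(design$family,
    gamma_log = ,
    hurdle_gamma = {
      shape <- exp(aux[["lshape"]])
      shape * base::log(shape) - lgamma(shape) - shape * eta_s +
        (shape - 1) * design$ly_sup[s] - shape * y * exp(-eta_s)
    },
    student_t = {
      sigma <- exp(aux[["lsigma"]])
      nu <- 1 + exp(aux[["lnu"]])
      z2 <- ((y - eta_s) / sigma)^2
      lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * base::log(nu * pi) -
        base::log(sigma) - (nu + 1) / 2 * log1p(z2 / nu)
    },
    gaussian = {
      sigma <- design$spec$sigma_fixed %||% exp(aux[["lsigma"]])
      stats::dnorm(y, eta_s, sigma, log = TRUE)
    },
    cumulative_probit = {
      th <- probit_thresholds(aux, design$n_categories)
      base::log(stats::pnorm(c(th, Inf)[y] - eta_s) -
                  stats::pnorm(c(-Inf, th)[y] - eta_s))
    }
  )
}

# count-part of the hurdle likelihood (independent of eta)
hurdle_count_ll <- function(design, hu) {
  pi <- stats::plogis(hu)
  design$n_zero * base::log(pi) + length(design$pos) * log1p(-pi)
}

run_chain <- function(design, iterations, warmup, seed, prior_only = FALSE) {
  set.seed(seed)
  P <- ncol(design$X)
  nb <- length(design$blocks)
  anames <- aux_names(design)
  st <- list(b = numeric(P),
             r = lapply(design$blocks, function(bl) numeric(bl$n)),
             lsd = numeric(nb),
             aux = stats::setNames(numeric(length(anames)), anames))
  n_par <- P + sum(vapply(design$blocks, `[[`, 0L, "n")) + nb + length(anames)
  kept <- iterations - warmup
  draws <- matrix(NA_real_, kept, n_par)

  if (prior_only) {
    for (i in seq_len(kept)) {
      st$b <- stats::rnorm(P, 0, design$spec$b_sd)
      for (j in seq_len(nb)) {
        st$lsd[j] <- if (design$spec$sd_prior == "gamma") {
          base::log(stats::rgamma(1, 1, 10))
        } else {
          base::log(abs(stats::rt(1, 3) * 2.5))
        }
        st$r[[j]] <- stats::rnorm(design$blocks[[j]]$n, 0, exp(st$lsd[j]))
      }
      st$aux[] <- sample_aux_prior(design)
      draws[i, ] <- flatten_state(design, st)
    }
    return(list(draws = draws, accept = NULL))
  }

  sup <- support_rows(design)
  design$y_sup <- design$y[sup]
  if (design$family %in% c("gamma_log", "hurdle_gamma")) {
    design$ly_sup <- base::log(design$y_sup)
  }
  X_sup <- design$X[sup, , drop = FALSE]
  # per-block active rows, expressed as positions within the support vector
  blk <- lapply(design$blocks, function(bl) {
    s <- which(bl$z[sup] != 0)
    list(s = s, idx = bl$idx[sup][s], z = bl$z[sup][s])
  })
  aux_ll_free <- if (design$family == "hurdle_gamma") "hu" else character()

  eta_s <- as.numeric(X_sup %*% st$b)
  for (j in seq_len(nb)) {
    eta_s[blk[[j]]$s] <- eta_s[blk[[j]]$s] + blk[[j]]$z * st$r[[j]][blk[[j]]$idx]
  }
  cur <- kernel_ll(design, eta_s, st$aux, seq_along(sup))

  ls_aux <- stats::setNames(rep(base::log(0.2), length(anames)), anames)
  ls_beta <- base::log(0.1 / sqrt(P))
  chol_beta <- diag(P)
  ls_block <- lapply(design$blocks, function(bl) rep(base::log(0.3), bl$n))
  ls_lsd <- rep(base::log(0.4), nb)
  ls_sc <- rep(base::log(0.3), nb)
  ls_tr <- lapply(design$blocks, function(bl)
    rep(base::log(0.2), length(bl$translations)))
  beta_hist <- matrix(NA_real_, warmup, P)
  acc_count <- c(beta = 0)

  for (t in seq_len(iterations)) {
    adapting <- t <= warmup
    gam <- min(0.25, 2 / sqrt(t))

    # --- auxiliary family parameters (scalar random walks)
    for (a in anames) {
      prop <- st$aux
      prop[[a]] <- prop[[a]] + stats::rnorm(1, 0, exp(ls_aux[[a]]))
      dprior <- log_prior_aux(design, prop) - log_prior_aux(design, st$aux)
      if (a %in% aux_ll_free) {
        dlp <- hurdle_count_ll(design, prop[["hu"]]) -
          hurdle_count_ll(design, st$aux[["hu"]]) + dprior
        acc <- is.finite(dlp) && base::log(stats::runif(1)) < dlp
        if (acc) st$aux <- prop
      } else {
        prop_row <- kernel_ll(design, eta_s, prop, seq_along(sup))
        dlp <- sum(prop_row) - sum(cur) + dprior
        acc <- is.finite(dlp) && base::log(stats::runif(1)) < dlp
        if (acc) { st$aux <- prop; cur <- prop_row }
      }
      if (adapting) ls_aux[[a]] <- ls_aux[[a]] + gam * (acc - 0.44)
    }

    # --- fixed effects (joint random walks with adapted covariance; a few
    #     sub-steps per iteration since correlated interaction terms are the
    #     slowest-mixing directions and each step costs one kernel pass)
    for (bstep in 1:3) {
      db <- exp(ls_beta) * as.numeric(chol_beta %*% stats::rnorm(P))
      eta_prop <- eta_s + as.numeric(X_sup %*% db)
      prop_row <- kernel_ll(design, eta_prop, st$aux, seq_along(sup))
      dlp <- sum(prop_row) - sum(cur) +
        sum(stats::dnorm(st$b + db, 0, design$spec$b_sd, log = TRUE)) -
        sum(stats::dnorm(st$b, 0, design$spec$b_sd, log = TRUE))
      if (is.finite(dlp) && base::log(stats::runif(1)) < dlp) {
        st$b <- st$b + db; eta_s <- eta_prop; cur <- prop_row
        acc_beta <- TRUE
      } else acc_beta <- FALSE
      if (adapting) ls_beta <- ls_beta + gam * (acc_beta - 0.25)
      else acc_count["beta"] <- acc_count["beta"] + acc_beta
    }
    if (adapting) {
      beta_hist[t, ] <- st$b
      if (t >= 150 && t %% 50 == 0) {
        S <- stats::cov(beta_hist[max(1, t - 500):t, , drop = FALSE]) + diag(1e-8, P)
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(ch)) chol_beta <- t(ch)
      }
    }

    # --- random-effect blocks
    for (j in seq_len(nb)) {
      bl <- blk[[j]]
      n_g <- design$blocks[[j]]$n

      # vectorized per-group single-site update
      dr <- stats::rnorm(n_g, 0, exp(ls_block[[j]]))
      deta <- bl$z * dr[bl$idx]
      prop_sub <- kernel_ll(design, eta_s[bl$s] + deta, st$aux, bl$s)
      dll_g <- numeric(n_g)
      agg <- rowsum(prop_sub - cur[bl$s], bl$idx)
      dll_g[as.integer(rownames(agg))] <- agg
      sdj <- exp(st$lsd[j])
      dpr_g <- stats::dnorm(st$r[[j]] + dr, 0, sdj, log = TRUE) -
        stats::dnorm(st$r[[j]], 0, sdj, log = TRUE)
      acc_g <- base::log(stats::runif(n_g)) < dll_g + dpr_g
      acc_g[!is.finite(dll_g)] <- FALSE
      if (any(acc_g)) {
        st$r[[j]][acc_g] <- st$r[[j]][acc_g] + dr[acc_g]
        sub_acc <- acc_g[bl$idx]
        eta_s[bl$s[sub_acc]] <- eta_s[bl$s[sub_acc]] + deta[sub_acc]
        cur[bl$s[sub_acc]] <- prop_sub[sub_acc]
      }
      if (adapting) ls_block[[j]] <- ls_block[[j]] + gam * (acc_g - 0.44)

      # group SD (conditional involves the prior terms only)
      lsd_prop <- st$lsd[j] + stats::rnorm(1, 0, exp(ls_lsd[j]))
      dlp <- sum(stats::dnorm(st$r[[j]], 0, exp(lsd_prop), log = TRUE)) -
        sum(stats::dnorm(st$r[[j]], 0, exp(st$lsd[j]), log = TRUE)) +
        log_prior_sd(lsd_prop, design$spec$sd_prior) -
        log_prior_sd(st$lsd[j], design$spec$sd_prior)
      acc_sd <- is.finite(dlp) && base::log(stats::runif(1)) < dlp
      if (acc_sd) st$lsd[j] <- lsd_prop
      if (adapting) ls_lsd[j] <- ls_lsd[j] + gam * (acc_sd - 0.44)

      # joint scale move (r, sd) -> (c r, c sd): breaks the funnel coupling
      delta <- stats::rnorm(1, 0, exp(ls_sc[j]))
      cfac <- exp(delta)
      deta <- bl$z * (cfac - 1) * st$r[[j]][bl$idx]
      prop_sub <- kernel_ll(design, eta_s[bl$s] + deta, st$aux, bl$s)
      lsd_prop <- st$lsd[j] + delta
      dlp <- sum(prop_sub) - sum(cur[bl$s]) +
        sum(stats::dnorm(cfac * st$r[[j]], 0, exp(lsd_prop), log = TRUE)) -
        sum(stats::dnorm(st$r[[j]], 0, exp(st$lsd[j]), log = TRUE)) +
        log_prior_sd(lsd_prop, design$spec$sd_prior) -
        log_prior_sd(st$lsd[j], design$spec$sd_prior) +
        n_g * delta
      acc_sc <- is.finite(dlp) && base::log(stats::runif(1)) < dlp
      if (acc_sc) {
        st$r[[j]] <- cfac * st$r[[j]]
        st$lsd[j] <- lsd_prop
        eta_s[bl$s] <- eta_s[bl$s] + deta
        cur[bl$s] <- prop_sub
      }
      if (adapting) ls_sc[j] <- ls_sc[j] + gam * (acc_sc - 0.44)

      # translation moves along the likelihood-invariant flat directions
      # between fixed effects and this block's effects
      trs <- design$blocks[[j]]$translations
      for (ti in seq_along(trs)) {
        tr <- trs[[ti]]
        delta <- stats::rnorm(1, 0, exp(ls_tr[[j]][ti]))
        r_prop <- st$r[[j]] - delta * tr$coef
        dlp <- stats::dnorm(st$b[tr$col] + delta, 0, design$spec$b_sd, log = TRUE) -
          stats::dnorm(st$b[tr$col], 0, design$spec$b_sd, log = TRUE) +
          sum(stats::dnorm(r_prop, 0, exp(st$lsd[j]), log = TRUE)) -
          sum(stats::dnorm(st$r[[j]], 0, exp(st$lsd[j]), log = TRUE))
        acc_tr <- base::log(stats::runif(1)) < dlp
        if (acc_tr) {
          st$b[tr$col] <- st$b[tr$col] + delta
          st$r[[j]] <- r_prop
        }
        if (adapting) ls_tr[[j]][ti] <- ls_tr[[j]][ti] + gam * (acc_tr - 0.44)
      }
    }

    if (t %% 200 == 0) {
      # guard against numerical drift in the cached row likelihoods
      cur <- kernel_ll(design, eta_s, st$aux, seq_along(sup))
    }
    if (t > warmup) draws[t - warmup, ] <- flatten_state(design, st)
  }
  list(draws = draws, accept = acc_count)
}

sample_aux_prior <- function(design) {
  switch(design$family,
    hurdle_gamma = c(stats::rnorm(1, 0, 1.5), stats::rnorm(1, 0, 1.5)),
    gamma_log = stats::rnorm(1, 0, 1.5),
    student_t = c(stats::rnorm(1, base::log(design$scale_y), 1.5),
                  base::log(stats::rgamma(1, 2, 0.1))),
    gaussian = if (is.null(design$spec$sigma_fixed))
      stats::rnorm(1, base::log(design$scale_y), 1.5) else numeric(),
    cumulative_probit = c(stats::rnorm(1, 0, 2),
                          if (design$n_categories > 2)
                            stats::rnorm(design$n_categories - 2, 0, 1))
  )
}

# natural-scale draw vector (group SDs, shape, sigma, nu, hurdle probability)
flatten_state <- function(design, st) {
  out <- st$b
  for (j in seq_along(design$blocks)) {
    out <- c(out, st$r[[j]], exp(st$lsd[j]))
  }
  aux <- st$aux
  nat <- switch(design$family,
    hurdle_gamma = c(exp(aux[["lshape"]]), stats::plogis(aux[["hu"]])),
    gamma_log = exp(aux[["lshape"]]),
    student_t = c(exp(aux[["lsigma"]]), 1 + exp(aux[["lnu"]])),
    gaussian = if (is.null(design$spec$sigma_fixed)) exp(aux[["lsigma"]]) else numeric(),
    cumulative_probit = probit_thresholds(aux, design$n_categories)
  )
  c(out, nat)
}

natural_param_names <- function(design) {
  nm <- paste0("b_", colnames(design$X))
  for (bl in design$blocks) {
    nm <- c(nm, paste0("r_", bl$name, "[", bl$levels, "]"), paste0("sd_", bl$name))
  }
  nat <- switch(design$family,
    hurdle_gamma = c("shape", "hu_prob"),
    gamma_log = "shape",
    student_t = c("sigma", "nu"),
    gaussian = if (is.null(design$spec$sigma_fixed)) "sigma" else character(),
    cumulative_probit = paste0("threshold", seq_len(design$n_categories - 1))
  )
  c(nm, nat)
}

#' Draw from the posterior of a multilevel model
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler on the joint posterior
#' defined by [log_density()]: a joint random walk with adapted covariance on
#' the fixed effects, vectorized per-group single-site updates for every
#' random-effect block, conditional updates for group SDs and family
#' parameters, a joint scale move per block that decouples effects from their
#' SD, and likelihood-invariant translation moves along intercept/random-
#' effect flat directions. Proposal scales adapt during warmup only. Chains
#' start at zero on the unconstrained scale.
#'
#' @param spec A [model_spec()].
#' @param data Model data (behavior or feature table).
#' @param settings A [sampler_settings()] list.
#' @param prior_only If `TRUE`, sample from the priors (no likelihood), used
#'   for prior-recovery checks.
#' @return A `posterior_samples` object: `draws` array
#'   `[chains x iterations x parameters]` on the natural scale,
#'   `warmup_discarded`, per-chain acceptance counters, sampler diagnostics
#'   (`divergences` and `treedepth_exceeded`, both structurally 0 for this
#'   sampler), and metadata used by [contrast()] and [build_rope()].
#' @export
sample_posterior <- function(spec, data, settings = sampler_settings(),
                             prior_only = FALSE) {
  design <- build_design(data, spec)
  theta0 <- stats::setNames(rep(settings$init, length(param_names(design))),
                            param_names(design))
  if (!prior_only) {
    lp0 <- log_density(design, theta0)
    if (!is.finite(lp0)) stop_config("log density not finite at the zero initialization")
  }
  kept <- settings$iterations - settings$warmup
  nm <- natural_param_names(design)
  draws <- array(NA_real_, dim = c(settings$chains, kept, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  accept <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    res <- run_chain(design, settings$iterations, settings$warmup,
                     seed = (settings$seed * 7919 + ch) %% .Machine$integer.max,
                     prior_only = prior_only)
    draws[ch, , ] <- res$draws
    accept[[ch]] <- res$accept
  }
  structure(list(
    draws = draws,
    parameters = nm,
    warmup_discarded = settings$warmup,
    settings = settings,
    accept = accept,
    diagnostics = list(divergences = 0L, treedepth_exceeded = 0L,
                       sampler = "adaptive Metropolis-within-Gibbs"),
    meta = list(X_cols = colnames(design$X),
                blocks = lapply(design$blocks, function(bl)
                  bl[c("name", "levels", "fixed_col")]),
                spec = design$spec,
                response = design$y,
                cell = if ("cell" %in% names(design$data)) design$data$cell,
                scale_y = design$scale_y,
                n = nrow(design$X))
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_samples> %d chains x %d draws x %d parameters (%s)\n",
              d[1], d[2], d[3], x$meta$spec$model))
  invisible(x)
}

#' Extract per-draw values of a named parameter (chains stacked)
#' @param samples A `posterior_samples` object.
#' @param parameter Parameter name.
#' @export
parameter_draws <- function(samples, parameter) {
  if (!parameter %in% samples$parameters) {
    stop_config("unknown parameter: ", parameter)
  }
  as.numeric(samples$draws[, , parameter])
}
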
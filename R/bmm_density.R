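#' Hurdle-gamma density
#'
#' Two-part distribution: probability mass `pi` at zero and, for `y > 0`,
#' `(1 - pi)` times a gamma density with shape `shape` and mean `mu`.
#'
#' @param y Non-negative values.
#' @param pi Zero probability in (0, 1).
#' @param mu Mean of the positive part (> 0).
#' @param shape Gamma shape (> 0).
#' @param log Return log density?
#' @export
dhurdle_gamma <- function(y, pi, mu, shape, log = FALSE) {
  if (any(y < 0)) stop_config("hurdle-gamma support is [0, Inf)")
  ld <- ifelse(y == 0, base::log(pi),
               log1p(-pi) + stats::dgamma(y, shape = shape, rate = shape / mu,
                                          log = TRUE))
  if (log) ld else exp(ld)
}

# --- parameter layout -------------------------------------------------------

aux_names <- function(design) {
  switch(design$family,
    hurdle_gamma = c("lshape", "hu"),
    gamma_log = "lshape",
    student_t = c("lsigma", "lnu"),
    gaussian = if (is.null(design$spec$sigma_fixed)) "lsigma" else character(),
    cumulative_probit = c("thr1",
                          if (design$n_categories > 2)
                            paste0("ldelta", 2:(design$n_categories - 1)))
  )
}

param_names <- function(design) {
  nm <- paste0("b_", colnames(design$X))
  for (bl in design$blocks) {
    nm <- c(nm, paste0("r_", bl$name, "[", bl$levels, "]"), paste0("lsd_", bl$name))
  }
  c(nm, aux_names(design))
}

unpack_params <- function(design, theta) {
  P <- ncol(design$X)
  pos <- P
  b <- unname(theta[seq_len(P)])
  r <- list(); lsd <- numeric(length(design$blocks))
  for (j in seq_along(design$blocks)) {
    bl <- design$blocks[[j]]
    r[[j]] <- unname(theta[pos + seq_len(bl$n)])
    lsd[j] <- unname(theta[pos + bl$n + 1])
    pos <- pos + bl$n + 1
  }
  aux <- theta[pos + seq_len(length(theta) - pos)]
  names(aux) <- aux_names(design)
  list(b = b, r = r, lsd = lsd, aux = aux)
}

compute_eta <- function(design, st) {
  eta <- as.numeric(design$X %*% st$b)
  for (j in seq_along(design$blocks)) {
    bl <- design$blocks[[j]]
    eta <- eta + bl$z * st$r[[j]][bl$idx]
  }
  eta
}

# --- likelihoods ------------------------------------------------------------

family_loglik <- function(design, eta, aux) {
  y <- design$y
  switch(design$family,
    gamma_log = {
      shape <- exp(aux[["lshape"]])
      sum(stats::dgamma(y, shape = shape, rate = shape / exp(eta), log = TRUE))
    },
    hurdle_gamma = {
      shape <- exp(aux[["lshape"]])
      pi <- stats::plogis(aux[["hu"]])
      yp <- y[design$pos]
      design$n_zero * base::log(pi) + length(design$pos) * log1p(-pi) +
        sum(stats::dgamma(yp, shape = shape, rate = shape / exp(eta[design$pos]),
                          log = TRUE))
    },
    student_t = {
      sigma <- exp(aux[["lsigma"]])
      nu <- 1 + exp(aux[["lnu"]])
      sum(stats::dt((y - eta) / sigma, df = nu, log = TRUE)) - length(y) * base::log(sigma)
    },
    gaussian = {
      sigma <- design$spec$sigma_fixed %||% exp(aux[["lsigma"]])
      sum(stats::dnorm(y, eta, sigma, log = TRUE))
    },
    cumulative_probit = {
      th <- probit_thresholds(aux, design$n_categories)
      upper <- c(th, Inf)[y]
      lower <- c(-Inf, th)[y]
      sum(base::log(stats::pnorm(upper - eta) - stats::pnorm(lower - eta)))
    }
  )
}

probit_thresholds <- function(aux, n_cat) {
  th <- aux[["thr1"]]
  if (n_cat > 2) {
    th <- cumsum(c(th, exp(aux[paste0("ldelta", 2:(n_cat - 1))])))
  }
  unname(th)
}

# --- priors -----------------------------------------------------------------

log_prior_sd <- function(lsd, kind) {
  sd <- exp(lsd)
  # density on the SD scale plus the log-scale Jacobian
  if (kind == "gamma") {
    stats::dgamma(sd, shape = 1, rate = 10, log = TRUE) + lsd
  } else {
    base::log(2) + stats::dt(sd / 2.5, df = 3, log = TRUE) - base::log(2.5) + lsd
  }
}

log_prior_aux <- function(design, aux) {
  lp <- 0
  fam <- design$family
  if (fam %in% c("gamma_log", "hurdle_gamma")) {
    lp <- lp + stats::dnorm(aux[["lshape"]], 0, 1.5, log = TRUE)
  }
  if (fam == "hurdle_gamma") {
    lp <- lp + stats::dnorm(aux[["hu"]], 0, 1.5, log = TRUE)
  }
  if (fam == "student_t" || (fam == "gaussian" && is.null(design$spec$sigma_fixed))) {
    lp <- lp + stats::dnorm(aux[["lsigma"]], base::log(design$scale_y), 1.5, log = TRUE)
  }
  if (fam == "student_t") {
    lp <- lp + stats::dgamma(exp(aux[["lnu"]]), 2, 0.1, log = TRUE) + aux[["lnu"]]
  }
  if (fam == "cumulative_probit") {
    lp <- lp + stats::dnorm(aux[["thr1"]], 0, 2, log = TRUE)
    nd <- grep("^ldelta", names(aux))
    if (length(nd)) lp <- lp + sum(stats::dnorm(aux[nd], 0, 1, log = TRUE))
  }
  unname(lp)
}

#' Joint log posterior density on the unconstrained scale
#'
#' Fixed effects carry independent normal(0, `b_sd`) priors; group-level
#' effects are normal with per-term SDs under either a Gamma(1, 10) prior
#' (simple models) or half-Student-t(3, 0, 2.5) (hierarchical choice for
#' interaction models); SDs, shapes, and scales are parameterized on the log
#' scale with the Jacobian included, the hurdle probability on the logit
#' scale, and the Student-t degrees of freedom as `1 + exp(lnu)`.
#'
#' @param design A [build_design()] bundle.
#' @param theta Named numeric vector over [param_names()] order.
#' @return The scalar joint log posterior (likelihood + priors).
#' @export
log_density <- function(design, theta) {
  st <- unpack_params(design, theta)
  eta <- compute_eta(design, st)
  lp <- family_loglik(design, eta, st$aux)
  lp <- lp + sum(stats::dnorm(st$b, 0, design$spec$b_sd, log = TRUE))
  for (j in seq_along(design$blocks)) {
    sdj <- exp(st$lsd[j])
    lp <- lp + sum(stats::dnorm(st$r[[j]], 0, sdj, log = TRUE)) +
      log_prior_sd(st$lsd[j], design$spec$sd_prior)
  }
  lp + log_prior_aux(design, st$aux)
}
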
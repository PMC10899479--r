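#' Split-chain R-hat
#'
#' Each chain is split in half; the potential scale reduction factor compares
#' between- and within-half-chain variances:
#' `R-hat = sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B = n * var(chain means)`.
#'
#' @param draws Numeric matrix `[chains x iterations]` for one parameter.
#' @return The split R-hat value (NA if a split chain has zero variance in a
#'   constant-parameter corner case).
#' @export
split_rhat <- function(draws) {
  stopifnot(is.matrix(draws))
  n <- ncol(draws)
  half <- n %/% 2
  splits <- rbind(draws[, seq_len(half), drop = FALSE],
                  draws[, half + seq_len(half), drop = FALSE])
  m <- nrow(splits)
  nn <- ncol(splits)
  means <- rowMeans(splits)
  vars <- apply(splits, 1, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Convergence report for posterior samples
#'
#' Computes split R-hat for every parameter plus the sampler's divergence and
#' tree-depth counters, and flags the fit at the 1.01 threshold.
#'
#' @param samples A `posterior_samples` object (>= 2 chains).
#' @param threshold Pass/fail threshold (default 1.01).
#' @return A list with `per_parameter` (data frame of R-hat values),
#'   `max_rhat`, `divergences`, `treedepth_exceeded`, and `converged`.
#' @export
check_convergence <- function(samples, threshold = 1.01) {
  if (dim(samples$draws)[1] < 2) {
    stop_config("convergence checks need at least 2 chains")
  }
  rhat <- vapply(seq_along(samples$parameters), function(p) {
    split_rhat(samples$draws[, , p, drop = TRUE])
  }, numeric(1))
  per <- data.frame(parameter = samples$parameters, rhat = rhat)
  list(per_parameter = per,
       max_rhat = max(rhat, na.rm = TRUE),
       divergences = samples$diagnostics$divergences,
       treedepth_exceeded = samples$diagnostics$treedepth_exceeded,
       converged = all(is.na(rhat) | rhat < threshold))
}

block_level_param <- function(samples, term, cell) {
  nm <- paste0("r_cell:", term, "[", cell, "]")
  if (!nm %in% samples$parameters) {
    stop_config("no cell-level effect ", nm, " in this model")
  }
  nm
}

#' Posterior draws of a reported contrast
#'
#' Contrasts follow the reporting convention in which a negative value means a
#' reduction at the later feedback (or at maximum discrepancy/adjustment):
#' under treatment coding with the first feedback as reference,
#' `fb2-fb1` is the FB2 coefficient, `fb3-fb2` the difference of the FB3 and
#' FB2 coefficients, `group-at-fb` the Individual-minus-Cooperative difference
#' at a given feedback, and `covariate-max-vs-min` the difference between the
#' linear predictor at covariate 1 and covariate 0 at a given feedback (the
#' covariate main effect plus any interaction active there). For signal models
#' a `cell` adds that time-window x electrode cell's random slopes, giving the
#' per-cell contrast that is reported with its own HDI.
#'
#' @param samples A `posterior_samples` object.
#' @param which One of `"fb2-fb1"`, `"fb3-fb2"`, `"group-at-fb"`,
#'   `"covariate-max-vs-min"`.
#' @param feedback Feedback index for the conditional contrasts.
#' @param cell Optional cell label (e.g. `"275-350:Fz"`).
#' @return Numeric vector of per-draw contrast values.
#' @export
contrast <- function(samples, which = c("fb2-fb1", "fb3-fb2", "group-at-fb",
                                        "covariate-max-vs-min"),
                     feedback = NULL, cell = NULL) {
  which <- match.arg(which)
  cols <- samples$meta$X_cols
  get_b <- function(term) parameter_draws(samples, paste0("b_", term))
  add_cell <- function(val, term) {
    if (is.null(cell)) return(val)
    val + parameter_draws(samples, block_level_param(samples, term, cell))
  }
  if (which == "fb2-fb1") {
    if (!"feedbackfb2" %in% cols) stop_config("model has no FB2 term")
    return(add_cell(get_b("feedbackfb2"), "feedbackfb2"))
  }
  if (which == "fb3-fb2") {
    if (!all(c("feedbackfb2", "feedbackfb3") %in% cols)) {
      stop_config("model has no FB3/FB2 terms")
    }
    val <- get_b("feedbackfb3") - get_b("feedbackfb2")
    if (!is.null(cell)) {
      val <- val + parameter_draws(samples, block_level_param(samples, "feedbackfb3", cell)) -
        parameter_draws(samples, block_level_param(samples, "feedbackfb2", cell))
    }
    return(val)
  }
  if (which == "group-at-fb") {
    if (is.null(feedback)) stop_config("group-at-fb needs a feedback index")
    if (!"groupIndividual" %in% cols) stop_config("model has no group term")
    val <- get_b("groupIndividual")
    if (feedback > 1) {
      inter <- paste0("feedbackfb", feedback, ":groupIndividual")
      if (inter %in% cols) val <- val + get_b(inter)
    }
    return(val)
  }
  # covariate-max-vs-min
  covar <- samples$meta$spec$covariate
  if (is.null(covar)) stop_config("model has no continuous covariate")
  if (is.null(feedback)) stop_config("covariate-max-vs-min needs a feedback index")
  val <- add_cell(get_b(covar), covar)
  if (feedback > 1) {
    inter <- paste0("feedbackfb", feedback, ":", covar)
    if (inter %in% cols) val <- val + add_cell(get_b(inter), inter)
  }
  val
}
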
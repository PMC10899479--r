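#' Highest density interval of posterior draws
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws (exact for unimodal empirical distributions; no density
#' smoothing).
#'
#' @param draws Numeric vector of at least 100 draws (unless `min_draws`
#'   lowered for exhaustive small-sample checks).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @param min_draws Minimum number of draws required.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95, min_draws = 100) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < min_draws) {
    stop_config("hdi needs at least ", min_draws, " draws")
  }
  if (mass <= 0 || mass >= 1) stop_config("mass must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Region of practical equivalence from response variability
#'
#' The ROPE is `[-m * sd(y), +m * sd(y)]` with `sd` the sample standard
#' deviation of the model's response data for the relevant cell; `m = 0.05`
#' for behavioral and ERP contrasts and `0.01` for time-frequency power, whose
#' scale (and variability) is much smaller.
#'
#' @param response_values Numeric vector (>= 2 values) of the response data.
#' @param multiplier Positive ROPE multiplier.
#' @return Length-2 numeric; `[0, 0]` with a warning under zero variance.
#' @export
build_rope <- function(response_values, multiplier = 0.05) {
  response_values <- response_values[!is.na(response_values)]
  if (length(response_values) < 2) stop_config("ROPE needs at least 2 response values")
  if (multiplier <= 0) stop_config("multiplier must be > 0")
  sdy <- stats::sd(response_values)
  if (sdy == 0) {
    warning("zero response variance: degenerate ROPE [0, 0]")
    return(c(0, 0))
  }
  c(-multiplier * sdy, multiplier * sdy)
}

#' HDI + ROPE decision
#'
#' HDI endpoints are rounded to `decimals` places (2 for behavioral/ERP
#' contrasts, 3 for time-frequency) before the comparison; the ROPE is never
#' rounded. A contrast is a `credible_effect` when the rounded HDI and the
#' ROPE are disjoint, a `practical_equivalence` when the rounded HDI lies
#' inside the ROPE, and `undecided` otherwise.
#'
#' @param hdi_interval Length-2 HDI.
#' @param rope_interval Length-2 ROPE (symmetric about 0).
#' @param decimals Rounding applied to the HDI at decision time.
#' @param contrast_name,cell Optional labels carried into the result.
#' @param sdy Optional response SD carried into the result.
#' @return A `contrast_decision` (list/data-frame row) with the rounded HDI,
#'   ROPE, and the three-way `decision`.
#' @export
decide <- function(hdi_interval, rope_interval, decimals = 2,
                   contrast_name = NA_character_, cell = NA_character_,
                   sdy = NA_real_) {
  lo <- round(hdi_interval[1], decimals)
  hi <- round(hdi_interval[2], decimals)
  if (lo > hi) stop_config("invalid HDI")
  decision <- if (hi < rope_interval[1] || lo > rope_interval[2]) {
    "credible_effect"
  } else if (lo >= rope_interval[1] && hi <= rope_interval[2]) {
    "practical_equivalence"
  } else {
    "undecided"
  }
  structure(list(contrast = contrast_name, cell = cell,
                 hdi_low = lo, hdi_high = hi,
                 rope_low = rope_interval[1], rope_high = rope_interval[2],
                 sdy = sdy, decision = decision,
                 rounding_decimals = decimals),
            class = "contrast_decision")
}

#' Assemble contrast decisions into a report table
#'
#' @param decisions List of `contrast_decision` objects.
#' @param model Optional model label.
#' @return Long-format data frame (one row per decision) with per-model
#'   `sdy_min` / `sdy_max` columns summarizing the response variability range
#'   used for the ROPEs.
#' @export
summarize_decisions <- function(decisions, model = NA_character_) {
  cols <- c("contrast", "cell", "hdi_low", "hdi_high", "rope_low", "rope_high",
            "sdy", "decision", "rounding_decimals")
  if (length(decisions) == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(character()), rep(list(numeric()), 6), list(character()), list(numeric())),
      cols))
    out$model <- character()
    out$sdy_min <- numeric()
    out$sdy_max <- numeric()
    return(out[, c("model", cols, "sdy_min", "sdy_max")])
  }
  rows <- lapply(decisions, function(d) as.data.frame(unclass(d)[cols]))
  out <- do.call(rbind, rows)
  out$model <- model
  sdys <- out$sdy[!is.na(out$sdy)]
  out$sdy_min <- if (length(sdys)) min(sdys) else NA_real_
  out$sdy_max <- if (length(sdys)) max(sdys) else NA_real_
  rownames(out) <- NULL
  out[, c("model", cols, "sdy_min", "sdy_max")]
}

#' Per-cell response SD for ROPE construction
#'
#' @param samples A `posterior_samples` object.
#' @param cell Optional cell label; `NULL` uses the whole response vector.
#' @export
response_sd <- function(samples, cell = NULL) {
  y <- samples$meta$response
  if (!is.null(cell)) {
    if (is.null(samples$meta$cell)) stop_config("model has no cell structure")
    y <- y[samples$meta$cell == cell]
  }
  stats::sd(y)
}
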
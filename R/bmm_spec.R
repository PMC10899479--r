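#' Specify one of the study's multilevel models
#'
#' The model catalogue mirrors the analysis plan: behavioral discrepancy
#' models (hurdle-gamma), a per-trial accuracy model, cumulative-probit
#' questionnaire models, and single-trial signal models (Student-t for ERP
#' amplitudes, gamma with log link for baseline-normalized power) with
#' participants nested in dyads and, for signal models, uncorrelated random
#' slopes per time-window x electrode cell.
#'
#' @param model One of `"group-interaction"`, `"feedback-simple"`,
#'   `"accuracy"`, `"question"`, `"feedback-signal"`, `"discrepancy-fb"`,
#'   `"adjustment-fb"`.
#' @param family Likelihood family; defaults to the model's standard choice.
#'   Signal models take `"student_t"` (ERP) or `"gamma_log"` (time-frequency).
#'   `"gaussian"` (optionally with `sigma_fixed`) is available for validation
#'   studies.
#' @param response Response column; defaults to the model's standard column.
#' @param sigma_fixed Known residual SD for the gaussian family (`NULL` to
#'   estimate).
#' @param priors Optional overrides: `b_sd` (SD of the normal prior on fixed
#'   effects), `sd_prior` (`"gamma"` for Gamma(1, 10) on group SDs —
#'   the simple-model choice — or `"half_t"` for half-Student-t(3, 0, 2.5),
#'   the hierarchical choice used by interaction models).
#' @return A `model_spec` object.
#' @export
model_spec <- function(model = c("group-interaction", "feedback-simple",
                                 "accuracy", "question", "feedback-signal",
                                 "discrepancy-fb", "adjustment-fb"),
                       family = NULL, response = NULL, sigma_fixed = NULL,
                       priors = list()) {
  model <- match.arg(model)
  def <- switch(model,
    "group-interaction" = list(response = "discrepancy", family = "hurdle_gamma",
      formula = ~ feedback * group, covariate = NULL,
      random = list(list(group = "dyad", terms = "(Intercept)"),
                    list(group = "participant", terms = "(Intercept)")),
      cell_slopes = FALSE, sd_prior = "half_t", fb_levels = 1:3),
    "feedback-simple" = list(response = "discrepancy", family = "hurdle_gamma",
      formula = ~ feedback, covariate = NULL,
      random = list(list(group = "dyad", terms = c("(Intercept)", "feedbackfb2", "feedbackfb3")),
                    list(group = "participant", terms = c("(Intercept)", "feedbackfb2", "feedbackfb3"))),
      cell_slopes = FALSE, sd_prior = "gamma", fb_levels = 1:3),
    "accuracy" = list(response = "accuracy", family = "hurdle_gamma",
      formula = ~ group, covariate = NULL,
      random = list(list(group = "dyad", terms = "(Intercept)"),
                    list(group = "participant", terms = "(Intercept)")),
      cell_slopes = FALSE, sd_prior = "gamma", fb_levels = 3),
    "question" = list(response = "answer", family = "cumulative_probit",
      formula = ~ group, covariate = NULL, random = list(),
      cell_slopes = FALSE, sd_prior = "gamma", fb_levels = NULL),
    "feedback-signal" = list(response = "value", family = "student_t",
      formula = ~ feedback, covariate = NULL,
      random = list(list(group = "dyad", terms = "(Intercept)"),
                    list(group = "participant", terms = "(Intercept)")),
      cell_slopes = TRUE, sd_prior = "gamma", fb_levels = 1:3),
    "discrepancy-fb" = list(response = "value", family = "student_t",
      formula = ~ feedback * scaled_discrepancy, covariate = "scaled_discrepancy",
      random = list(list(group = "dyad", terms = "(Intercept)"),
                    list(group = "participant", terms = "(Intercept)")),
      cell_slopes = TRUE, sd_prior = "half_t", fb_levels = 1:3),
    "adjustment-fb" = list(response = "value", family = "student_t",
      formula = ~ feedback * scaled_adjustment, covariate = "scaled_adjustment",
      random = list(list(group = "dyad", terms = "(Intercept)"),
                    list(group = "participant", terms = "(Intercept)")),
      cell_slopes = TRUE, sd_prior = "half_t", fb_levels = 1:2)
  )
  if (!is.null(family)) def$family <- match.arg(family,
    c("hurdle_gamma", "student_t", "gamma_log", "cumulative_probit", "gaussian"))
  if (!is.null(response)) def$response <- response
  def$model <- model
  def$sigma_fixed <- sigma_fixed
  def$b_sd <- priors$b_sd %||% 1
  if (!is.null(priors$sd_prior)) def$sd_prior <- match.arg(priors$sd_prior, c("gamma", "half_t"))
  class(def) <- "model_spec"
  def
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s | family %s | response %s\n",
              x$model, x$family, x$response))
  cat("  fixed:", deparse(x$formula), "\n")
  if (length(x$random)) {
    cat("  random intercept/slope groups:",
        paste(vapply(x$random, function(r)
          paste0(r$group, "(", length(r$terms), ")"), character(1)), collapse = ", "),
        if (x$cell_slopes) "+ uncorrelated slopes by cell", "\n")
  }
  invisible(x)
}

#' Build the design bundle for a model specification
#'
#' Assembles the response vector, treatment-coded fixed-effect matrix (first
#' feedback as reference level), and random-effect index maps: dyad-level and
#' participant-within-dyad intercepts (participants are indexed within dyads,
#' so the nesting is explicit) and, for signal models, one independent effect
#' block per fixed-effect column per time-window x electrode cell. Rows with a
#' missing response or covariate are dropped, as is any feedback level outside
#' the model's scope. For the hurdle-gamma family the gamma part of the design
#' keeps only positive responses; the zero count feeds the hurdle probability.
#'
#' @param data A behavior or feature table.
#' @param spec A [model_spec()].
#' @return A list of class `bmm_design` with elements `y`, `X`, `blocks`,
#'   family bookkeeping (`n_zero`, `n_categories`, `scale_y`) and factor
#'   metadata.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  assert_columns(data, spec$response, "model data")
  df <- as.data.frame(data)
  if (!is.null(spec$fb_levels) && "feedback_index" %in% names(df)) {
    df <- df[df$feedback_index %in% spec$fb_levels, , drop = FALSE]
  }
  vars <- all.vars(spec$formula)
  if ("feedback" %in% vars) {
    assert_columns(df, "feedback_index", "model data")
    df$feedback <- factor(paste0("fb", df$feedback_index),
                          levels = paste0("fb", sort(unique(df$feedback_index))))
  }
  if ("group" %in% vars) {
    assert_columns(df, "group", "model data")
    bad <- setdiff(unique(df$group), c("Cooperative", "Individual"))
    if (length(bad)) stop_structure("unknown group level(s): ", paste(bad, collapse = ", "))
    df$group <- factor(df$group, levels = c("Cooperative", "Individual"))
  }
  needed <- c(spec$response, intersect(vars, names(df)))
  missing_vars <- setdiff(vars, c(names(df), "feedback", "group"))
  if (length(missing_vars)) {
    stop_structure("model data is missing column(s): ",
                   paste(missing_vars, collapse = ", "))
  }
  keep <- stats::complete.cases(df[, needed, drop = FALSE])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop_config("no complete rows left for the model")

  y <- df[[spec$response]]
  if (spec$family == "hurdle_gamma" && any(y < 0)) {
    stop_config("hurdle-gamma requires non-negative responses")
  }
  if (spec$family == "gamma_log" && any(y <= 0)) {
    stop_config("gamma with log link requires strictly positive responses")
  }
  if (spec$family == "cumulative_probit" && (!all(y == round(y)) || any(y < 1))) {
    stop_config("cumulative probit requires integer categories >= 1")
  }
  X <- stats::model.matrix(spec$formula, df)
  if (spec$family == "cumulative_probit") {
    # ordinal thresholds absorb the intercept
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  }

  blocks <- list()
  add_block <- function(name, z, idx, levels, fixed_col) {
    z <- as.numeric(z)
    idx <- as.integer(idx)
    # flat directions: fixed columns whose ratio to z is constant within each
    # group (and zero off the block's rows); shifting such a coefficient while
    # counter-shifting the group effects leaves the linear predictor unchanged
    translations <- list()
    on_rows <- z != 0
    for (k in seq_len(ncol(X))) {
      xk <- X[, k]
      if (any(xk[!on_rows] != 0)) next
      ratio <- xk[on_rows] / z[on_rows]
      per_group <- tapply(ratio, idx[on_rows], function(v) {
        if (diff(range(v)) < 1e-12) v[1] else NA_real_
      })
      if (anyNA(per_group)) next
      coef_g <- numeric(length(levels))
      coef_g[as.integer(names(per_group))] <- as.numeric(per_group)
      if (all(coef_g == 0)) next
      translations[[length(translations) + 1]] <- list(col = k, coef = coef_g)
    }
    blocks[[length(blocks) + 1]] <<- list(
      name = name, z = z, idx = idx,
      n = length(levels), levels = levels, fixed_col = fixed_col,
      translations = translations)
  }
  term_column <- function(term) {
    if (term == "(Intercept)") rep(1, nrow(df))
    else if (term %in% colnames(X)) X[, term]
    else stop_config("random term ", term, " is not a fixed-effect column")
  }
  group_index <- function(group) {
    if (group == "dyad") {
      f <- factor(df$dyad_id)
    } else if (group == "participant") {
      f <- factor(paste(df$dyad_id, df$participant_id, sep = "/"))
    } else {
      f <- factor(df[[group]])
    }
    f
  }
  for (r in spec$random) {
    f <- group_index(r$group)
    for (term in r$terms) {
      if (term != "(Intercept)" && !term %in% colnames(X)) next  # absent level
      add_block(paste(r$group, term, sep = ":"), term_column(term),
                as.integer(f), levels(f),
                fixed_col = match(term, colnames(X)))
    }
  }
  if (isTRUE(spec$cell_slopes)) {
    assert_columns(df, "cell", "model data (signal models need a 'cell' column)")
    f <- factor(df$cell)
    for (term in colnames(X)) {
      add_block(paste("cell", term, sep = ":"), term_column(term),
                as.integer(f), levels(f), fixed_col = match(term, colnames(X)))
    }
  }

  des <- list(y = y, X = X, blocks = blocks, family = spec$family,
              spec = spec, data = df, scale_y = stats::sd(y))
  if (spec$family == "hurdle_gamma") {
    des$pos <- which(y > 0)
    des$n_zero <- sum(y == 0)
  } else if (spec$family == "cumulative_probit") {
    des$n_categories <- max(y)
  }
  class(des) <- "bmm_design"
  des
}

#' Add a time-window x electrode cell label to a feature table
#'
#' @param features Long feature table from [erp_window_means()] or
#'   [tf_band_features()].
#' @return The table with a `cell` column (`window:electrode`, with the band
#'   prefixed for time-frequency features).
#' @export
add_cell_column <- function(features) {
  assert_columns(features, c("window", "electrode"), "feature table")
  cell <- paste(features$window, features$electrode, sep = ":")
  if ("band" %in% names(features)) cell <- paste(features$band, cell, sep = ":")
  features$cell <- cell
  features
}
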
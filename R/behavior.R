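#' Trial-level behavioral measures and cleaning rules
#'
#' These functions attach the task's behavioral quantities to a long behavior
#' table (one row per dyad x participant x trial x feedback repetition):
#' discrepancy between the two members' estimates, its min-max scaled version,
#' the participant's adjustment between consecutive repetitions, and per-trial
#' accuracy of the dyad's final midpoint. All of them leave `estimate`
#' untouched and are idempotent.
#'
#' @name behavior-measures
NULL

behavior_key_cols <- c("dyad_id", "participant_id", "trial_index", "feedback_index")

#' Compute interpersonal discrepancy
#'
#' Discrepancy is the absolute difference between the estimates of the two
#' dyad members at the same trial and feedback repetition; it is attached to
#' both members' rows and is missing when either estimate is missing.
#'
#' @param table Behavior table with the key columns and `estimate`.
#' @return The table with a `discrepancy` column.
#' @export
compute_discrepancy <- function(table) {
  assert_columns(table, c(behavior_key_cols, "estimate"), "behavior table")
  key <- interaction(table$dyad_id, table$trial_index, table$feedback_index,
                     drop = TRUE)
  n_members <- tapply(table$participant_id, table$dyad_id,
                      function(p) length(unique(p)))
  if (any(n_members != 2)) {
    stop_structure("every dyad must have exactly 2 participants; offending dyad(s): ",
                   paste(names(n_members)[n_members != 2], collapse = ", "))
  }
  disc <- tapply(table$estimate, key, function(e) {
    if (length(e) != 2 || anyNA(e)) NA_real_ else abs(e[1] - e[2])
  })
  table$discrepancy <- as.numeric(disc[as.character(key)])
  table
}

#' Min-max scale discrepancy against the first-feedback distribution
#'
#' Scaling constants are the minimum and maximum of all first-feedback
#' discrepancies in the dataset (or per dyad with `scaling = "per-dyad"`), and
#' the same constants are applied to all repetitions, so the covariate stays
#' comparable across feedbacks. Values that exceed the first-feedback maximum
#' (possible at later repetitions) are clipped into \[0, 1\]; the number of
#' clipped values is reported as an attribute `n_clipped`.
#'
#' @param table Behavior table with `discrepancy` (see [compute_discrepancy()]).
#' @param scaling `"global"` (default) or `"per-dyad"`.
#' @return The table with a `scaled_discrepancy` column.
#' @export
scale_discrepancy <- function(table, scaling = c("global", "per-dyad")) {
  scaling <- match.arg(scaling)
  assert_columns(table, c("discrepancy", "feedback_index"), "behavior table")
  if (nrow(table) == 0) stop_config("cannot scale an empty table")
  scale_one <- function(idx) {
    d1 <- table$discrepancy[idx & table$feedback_index == 1]
    d1 <- d1[!is.na(d1)]
    rng <- if (length(d1)) range(d1) else c(0, 0)
    if (diff(rng) == 0) {
      ifelse(is.na(table$discrepancy[idx]), NA_real_, 0)
    } else {
      (table$discrepancy[idx] - rng[1]) / (rng[2] - rng[1])
    }
  }
  scaled <- rep(NA_real_, nrow(table))
  if (scaling == "global") {
    scaled <- scale_one(rep(TRUE, nrow(table)))
  } else {
    for (d in unique(table$dyad_id)) {
      idx <- table$dyad_id == d
      scaled[idx] <- scale_one(idx)
    }
  }
  n_clipped <- sum(scaled > 1 | scaled < 0, na.rm = TRUE)
  table$scaled_discrepancy <- pmin(pmax(scaled, 0), 1)
  attr(table, "n_clipped") <- n_clipped
  table
}

#' Compute the adjustment after each feedback
#'
#' The adjustment at repetition k (k in 1, 2) is the absolute change in the
#' participant's own estimate from repetition k to k+1 — the behavioral
#' consequence of processing feedback k — so it is stored on the repetition-k
#' row, ready to be paired with the EEG epoch of that feedback. A min-max
#' scaled version (`scaled_adjustment`) uses constants from the
#' first-adjustment (k = 1) distribution, mirroring the discrepancy scaling.
#'
#' @param table Behavior table with `estimate`.
#' @return The table with `adjustment` and `scaled_adjustment` columns.
#' @export
compute_adjustment <- function(table) {
  assert_columns(table, c(behavior_key_cols, "estimate"), "behavior table")
  ord <- order(table$participant_id, table$trial_index, table$feedback_index)
  tbl <- table[ord, ]
  nxt <- c(tbl$estimate[-1], NA_real_)
  same_series <- c(tbl$participant_id[-1] == tbl$participant_id[-nrow(tbl)] &
                     tbl$trial_index[-1] == tbl$trial_index[-nrow(tbl)], FALSE)
  adj <- ifelse(same_series & tbl$feedback_index < 3, abs(nxt - tbl$estimate), NA_real_)
  tbl$adjustment <- adj
  a1 <- adj[tbl$feedback_index == 1]
  a1 <- a1[!is.na(a1)]
  rng <- if (length(a1)) range(a1) else c(0, 0)
  if (diff(rng) == 0) {
    tbl$scaled_adjustment <- ifelse(is.na(adj), NA_real_, 0)
  } else {
    tbl$scaled_adjustment <- pmin(pmax((adj - rng[1]) / (rng[2] - rng[1]), 0), 1)
  }
  # restore the caller's row order
  out <- tbl[match(seq_len(nrow(table)), ord), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute per-trial accuracy of the dyad's final estimate
#'
#' Accuracy is the absolute difference between the midpoint of the two
#' members' third-repetition estimates and the true point position, attached
#' to all rows of the trial.
#'
#' @param table Behavior table.
#' @param stimuli Stimulus table with `true_position`; if it carries a
#'   `dyad_id` column, matching is per dyad x trial, otherwise per trial.
#' @return The table with an `accuracy` column.
#' @export
compute_accuracy <- function(table, stimuli) {
  assert_columns(table, c(behavior_key_cols, "estimate"), "behavior table")
  assert_columns(stimuli, c("trial_index", "true_position"), "stimulus table")
  per_dyad <- "dyad_id" %in% names(stimuli)
  fb3 <- table[table$feedback_index == 3, ]
  key3 <- paste(fb3$dyad_id, fb3$trial_index)
  mid <- tapply(fb3$estimate, key3, function(e) {
    if (length(e) != 2 || anyNA(e)) NA_real_ else mean(e)
  })
  tkey <- paste(table$dyad_id, table$trial_index)
  skey <- if (per_dyad) paste(stimuli$dyad_id, stimuli$trial_index) else
    as.character(stimuli$trial_index)
  lookup_key <- if (per_dyad) tkey else as.character(table$trial_index)
  srow <- match(lookup_key, skey)
  if (anyNA(srow)) {
    stop_structure("stimulus missing for trial(s): ",
                   paste(unique(tkey[is.na(srow)]), collapse = ", "))
  }
  table$accuracy <- abs(as.numeric(mid[tkey]) - stimuli$true_position[srow])
  table
}

#' Remove upper-percentile outliers from a response column
#'
#' Values strictly greater than the empirical percentile (type-7 linear
#' interpolation between order statistics) are replaced by `NA`
#' (`action = "na"`, used for behavioral responses) or their rows dropped
#' (`action = "drop"`, used for signal features). The number of affected rows
#' is attached as attribute `n_removed`.
#'
#' @param table A data frame.
#' @param column Name of the response column.
#' @param percentile Percentile threshold in (0, 100); default 95.
#' @param action `"na"` or `"drop"`.
#' @export
clean_responses <- function(table, column = "discrepancy", percentile = 95,
                            action = c("na", "drop")) {
  action <- match.arg(action)
  if (percentile <= 0 || percentile >= 100) {
    stop_config("percentile must be strictly between 0 and 100")
  }
  assert_columns(table, column, "table")
  x <- table[[column]]
  if (all(is.na(x))) {
    attr(table, "n_removed") <- 0L
    return(table)
  }
  cut <- stats::quantile(x, percentile / 100, na.rm = TRUE, names = FALSE, type = 7)
  bad <- !is.na(x) & x > cut
  if (action == "na") {
    table[[column]][bad] <- NA_real_
  } else {
    table <- table[!bad, , drop = FALSE]
    rownames(table) <- NULL
  }
  attr(table, "n_removed") <- sum(bad)
  table
}

#' Drop trials that already agreed at the first feedback
#'
#' Trials whose first-feedback discrepancy is exactly zero carry no
#' convergence information for the discrepancy- and adjustment-by-feedback
#' signal models, so all their rows are removed.
#'
#' @param table Behavior table with `discrepancy`.
#' @return The filtered table; attribute `n_trials_removed` counts dropped trials.
#' @export
filter_converged_trials <- function(table) {
  assert_columns(table, c("dyad_id", "trial_index", "feedback_index", "discrepancy"),
                 "behavior table")
  fb1 <- table[table$feedback_index == 1, ]
  zero <- !is.na(fb1$discrepancy) & fb1$discrepancy == 0
  zero_key <- unique(paste(fb1$dyad_id, fb1$trial_index)[zero])
  keep <- !(paste(table$dyad_id, table$trial_index) %in% zero_key)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trials_removed") <- length(zero_key)
  out
}
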
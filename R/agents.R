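#' Agent parameters for the dyadic convergence simulator
#'
#' The generative model of a participant is deliberately simple: the first
#' estimate is the true point position plus Gaussian perceptual noise; on each
#' later repetition the agent either copies the partner's previous estimate
#' exactly (probability `p_match`, the source of an exact-agreement mass that
#' motivates a hurdle likelihood downstream) or closes a fraction `lambda` of
#' the gap to the partner's previous estimate, again with Gaussian noise.
#' Responses are typed on a numeric keypad, so they are rounded to integers by
#' default and clamped to the displayed endpoint range.
#'
#' @param perceptual_noise_sd Standard deviation (stimulus units) of the
#'   Gaussian noise on the initial, perception-driven estimate. Must be >= 0.
#' @param lambda Fraction of the gap to the partner closed per adjustment,
#'   in \[0, 1\].
#' @param p_match Probability of copying the partner's last estimate exactly,
#'   in \[0, 1\].
#' @param update_noise_sd Execution noise of the deliberate adjustments at
#'   repetitions 2 and 3. Later responses are anchored on two known numbers
#'   rather than a percept, so this defaults to a quarter of
#'   `perceptual_noise_sd`; that separation is what makes expected
#'   discrepancy non-increasing over repetitions for `lambda` in (0, 1).
#' @param response_rounding `"integer"` (keypad entry) or `"none"`.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(perceptual_noise_sd = 2, lambda = 0.3,
                         p_match = 0.1,
                         update_noise_sd = perceptual_noise_sd / 4,
                         response_rounding = c("integer", "none")) {
  response_rounding <- match.arg(response_rounding)
  if (perceptual_noise_sd < 0) stop_config("perceptual_noise_sd must be >= 0")
  if (update_noise_sd < 0) stop_config("update_noise_sd must be >= 0")
  if (lambda < 0 || lambda > 1) stop_config("lambda must be in [0, 1]")
  if (p_match < 0 || p_match > 1) stop_config("p_match must be in [0, 1]")
  structure(list(perceptual_noise_sd = perceptual_noise_sd, lambda = lambda,
                 p_match = p_match, update_noise_sd = update_noise_sd,
                 response_rounding = response_rounding),
            class = "agent_params")
}

finalize_response <- function(x, params, low, high) {
  if (params$response_rounding == "integer") x <- round(x)
  pmin(pmax(x, low), high)
}

#' Simulate one dyad's estimates across three feedback repetitions
#'
#' Both members first estimate the point independently. After each of the two
#' feedback displays, both agents update simultaneously from the repetition-k
#' estimates: with probability `p_match` an agent adopts the partner's previous
#' estimate verbatim, otherwise it moves `lambda` of the way towards it plus
#' perceptual noise.
#'
#' @param stimuli Stimulus table from [generate_stimuli()]; must be non-empty.
#' @param params_a,params_b [agent_params()] for the two members.
#' @param seed Integer seed.
#' @param dyad_id Identifier for this dyad.
#' @param group `"Cooperative"` or `"Individual"` label carried into the table.
#' @return A behavior table in long format: one row per participant x trial x
#'   feedback repetition with columns `dyad_id`, `participant_id`, `group`,
#'   `trial_index`, `block_index`, `feedback_index`, `estimate`.
#' @examples
#' stim <- generate_stimuli(10, n_blocks = 2, seed = 1)
#' beh <- simulate_dyad_behavior(stim, agent_params(), agent_params(), seed = 2)
#' head(beh)
#' @export
simulate_dyad_behavior <- function(stimuli, params_a, params_b, seed = 1L,
                                   dyad_id = 1L, group = "Cooperative") {
  if (!is.data.frame(stimuli) || nrow(stimuli) == 0) {
    stop_config("stimuli must be a non-empty stimulus table")
  }
  stopifnot(inherits(params_a, "agent_params"), inherits(params_b, "agent_params"))
  n <- nrow(stimuli)
  low <- stimuli$endpoint_low
  high <- stimuli$endpoint_high

  with_seed(seed, {
    est <- array(NA_real_, dim = c(n, 2L, 3L))  # trial x participant x repetition
    prm <- list(params_a, params_b)
    for (p in 1:2) {
      noise <- stats::rnorm(n, 0, prm[[p]]$perceptual_noise_sd)
      est[, p, 1] <- finalize_response(stimuli$true_position + noise, prm[[p]], low, high)
    }
    for (k in 1:2) {
      own <- est[, , k]
      for (p in 1:2) {
        partner <- own[, 3 - p]
        copy <- stats::runif(n) < prm[[p]]$p_match
        noise <- stats::rnorm(n, 0, prm[[p]]$update_noise_sd)
        upd <- own[, p] + prm[[p]]$lambda * (partner - own[, p]) + noise
        upd <- finalize_response(upd, prm[[p]], low, high)
        est[, p, k + 1] <- ifelse(copy, partner, upd)
      }
    }
    out <- expand.grid(feedback_index = 1:3, participant_index = 1:2,
                       trial_index = stimuli$trial_index)
    out <- out[order(out$participant_index, out$trial_index, out$feedback_index), ]
    trial_row <- match(out$trial_index, stimuli$trial_index)
    data.frame(
      dyad_id = dyad_id,
      participant_id = paste0("d", dyad_id, "_p", out$participant_index),
      group = group,
      trial_index = out$trial_index,
      block_index = stimuli$block_index[trial_row],
      feedback_index = out$feedback_index,
      estimate = est[cbind(trial_row, out$participant_index, out$feedback_index)],
      row.names = NULL
    )
  })
}

#' Simulate a multi-dyad study
#'
#' Convenience wrapper running [generate_stimuli()] and
#' [simulate_dyad_behavior()] per dyad, with per-dyad seeds derived from the
#' study seed.
#'
#' @param n_dyads Number of dyads.
#' @param n_trials Trials per dyad.
#' @param n_blocks Blocks per dyad.
#' @param params_a,params_b Agent parameters shared by all dyads (member 1 / 2).
#' @param group Group label, recycled to `n_dyads`.
#' @param seed Study seed.
#' @param dyad_offset Added to dyad numbering (useful when binding groups).
#' @return A list with `behavior` (row-bound behavior table) and `stimuli`
#'   (stimulus tables with a `dyad_id` column).
#' @export
simulate_study <- function(n_dyads, n_trials, n_blocks = 4L,
                           params_a = agent_params(), params_b = params_a,
                           group = "Cooperative", seed = 1L, dyad_offset = 0L) {
  group <- rep_len(group, n_dyads)
  beh <- vector("list", n_dyads)
  stim <- vector("list", n_dyads)
  for (d in seq_len(n_dyads)) {
    id <- d + dyad_offset
    s <- (seed * 1000L + id * 2L) %% .Machine$integer.max
    stim[[d]] <- generate_stimuli(n_trials, n_blocks, seed = s)
    stim[[d]]$dyad_id <- id
    beh[[d]] <- simulate_dyad_behavior(stim[[d]], params_a, params_b,
                                       seed = s + 1L, dyad_id = id,
                                       group = group[d])
  }
  list(behavior = do.call(rbind, beh), stimuli = do.call(rbind, stim))
}
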
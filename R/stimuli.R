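#' Generate line-and-point stimuli for the estimation task
#'
#' Each trial presents a horizontal or vertical line whose two endpoints are
#' integers drawn between 0 and 150 and between 40 and 50 units apart, with a
#' target point at a uniformly random position strictly between the endpoints.
#' Trials are divided evenly into blocks.
#'
#' @param n_trials Number of trials (>= 0). Must be divisible by `n_blocks`
#'   when `n_blocks > 0`.
#' @param n_blocks Number of blocks.
#' @param seed Integer seed; identical seeds give identical stimulus tables.
#' @return A data frame with one row per trial: `trial_index`, `block_index`,
#'   `orientation`, `endpoint_low`, `endpoint_high`, `true_position`.
#' @examples
#' stim <- generate_stimuli(100, n_blocks = 4, seed = 7)
#' range(stim$endpoint_high - stim$endpoint_low)  # within [40, 50]
#' @export
generate_stimuli <- function(n_trials, n_blocks = 4L, seed = 1L) {
  n_trials <- as.integer(n_trials)
  n_blocks <- as.integer(n_blocks)
  if (n_trials < 0) stop_config("n_trials must be >= 0")
  if (n_trials == 0) {
    return(data.frame(trial_index = integer(), block_index = integer(),
                      orientation = character(), endpoint_low = integer(),
                      endpoint_high = integer(), true_position = numeric()))
  }
  if (n_blocks <= 0 || n_trials %% n_blocks != 0) {
    stop_config("n_trials (", n_trials, ") must be divisible by n_blocks (",
                n_blocks, ")")
  }
  with_seed(seed, {
    span <- sample(40:50, n_trials, replace = TRUE)
    low <- vapply(span, function(s) sample(0:(150L - s), 1L), integer(1))
    high <- low + span
    # strictly interior point; at least half a unit from either end so that
    # integer responses can bracket it
    true_pos <- low + 0.5 + stats::runif(n_trials) * (span - 1)
    data.frame(
      trial_index = seq_len(n_trials),
      block_index = rep(seq_len(n_blocks), each = n_trials %/% n_blocks),
      orientation = sample(c("horizontal", "vertical"), n_trials, replace = TRUE),
      endpoint_low = low,
      endpoint_high = high,
      true_position = true_pos
    )
  })
}
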
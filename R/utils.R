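#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("dyadconv_config_error", "error")))
}

stop_structure <- function(...) {
  stop(errorCondition(paste0(...), class = c("dyadconv_structure_error", "error")))
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_structure(what, " is missing required column(s): ",
                   paste(missing, collapse = ", "))
  }
  invisible(df)
}
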
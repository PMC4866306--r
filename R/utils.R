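# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stream label
#'
#' All stochastic functions in the package draw their randomness from a single
#' integer seed. Sub-tasks (each segregant panel, each cross-validation fold,
#' each scenario redraw) use seeds derived deterministically from the master
#' seed and a short label, so that any part of a run can be reproduced in
#' isolation and unrelated parts stay statistically independent.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or integer) identifying the stream.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  tags <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(tags)
  # polynomial rolling hash in the positive signed 32-bit range
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Coefficient of determination on a held-out set
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed against the
#' mean of the evaluation set itself. Can be negative when predictions are
#' worse than the constant mean predictor.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return A single number.
#' @export
r2_score <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ok <- !is.na(y) & !is.na(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss_tot
}

# population variance (denominator n, not n-1)
pvar <- function(x) mean((x - mean(x))^2)

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min),
          class = "dgp_argument_error")
  }
}

abort_arg <- function(msg) abort(msg, class = "dgp_argument_error")
abort_consistency <- function(msg) abort(msg, class = "dgp_consistency_error")
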
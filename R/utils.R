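#' Evaluate an expression with a local, restorable RNG state
#'
#' All stochastic functions in the package route their draws through one
#' seeded generator per call and leave the caller's RNG state untouched.
#'
#' @param seed integer seed, or `NULL` to use (and advance) the current state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## scalar validators used across constructors
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name))
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper)
    stop(sprintf("'%s' = %g outside allowed range", name, x))
  invisible(x)
}

#' Moving-average smoothing with shrinking windows at the edges
#'
#' Centered moving average of window `w`; near the series ends the window
#' shrinks to the available samples, so a linear trend is reproduced exactly
#' in the interior and with only O(slope * w) bias at the edges. NA values
#' are ignored within each window.
#'
#' @param x numeric vector.
#' @param w window width in samples.
#' @return smoothed vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n <= 1L) return(x)
  half <- floor(w / 2)
  miss <- is.na(x)
  x0 <- ifelse(miss, 0, x)
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(!miss))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

## stage-tagged error used by the pipeline orchestrator
stage_error <- function(stage, message) {
  stop(structure(
    class = c("memquant_stage_error", "error", "condition"),
    list(message = sprintf("[stage:%s] %s", stage, message),
         call = sys.call(-1), stage = stage)
  ))
}
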
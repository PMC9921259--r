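# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state, so seeded package internals never disturb
#' the user's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a named substream seed from a base seed. Keeps results < 2^31 and
# decorrelates streams that share a base seed (split, cnn, cv folds, per
# subject, ...).
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(as.character(stream)) * 131^(seq_along(utf8ToInt(as.character(stream))) %% 7L))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + as.numeric(index) * 7919) %% 2147483647)
}

stop_cuffbp <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cuffbp(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_cuffbp(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

# Simple timestamped logger used by the pipeline; collects lines when a
# collector environment is supplied.
log_line <- function(fmt, ..., collector = NULL, verbose = TRUE) {
  msg <- sprintf(fmt, ...)
  if (!is.null(collector)) collector$lines <- c(collector$lines, msg)
  if (isTRUE(verbose)) message("[cuffbp] ", msg)
  invisible(msg)
}
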
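#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; published clinical tables almost
#' always round half away from zero, so yield percentages use this rule.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared consequence vocabulary; LOF classes per LOFTEE-style annotation
.lof_consequences <- c("stop_gained", "splice", "frameshift")
.known_consequences <- c(.lof_consequences, "missense", "synonymous", "other")

.check_flag <- function(x, name) {
  if (!is.logical(x) || anyNA(x)) stop(sprintf("'%s' must be logical without NA", name))
  invisible(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1, na.rm = TRUE))
    stop(sprintf("'%s' must lie in [0, 1]", name))
  invisible(x)
}
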
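# Internal validation helpers. All user-facing errors funnel through these so
# messages are consistent and testable.

.check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("%s must be non-negative", what), call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop(sprintf("%s must be strictly positive", what), call. = FALSE)
  }
  invisible(x)
}

# The two rearing regimes used throughout the package.
.REGIMES <- c("conventional", "welfare_friendly")

.check_regime <- function(regime) {
  match.arg(regime, .REGIMES)
}

# A length-2 numeric named by regime; accepts unnamed pairs in
# (conventional, welfare_friendly) order.
.regime_pair <- function(x, what) {
  if (length(x) != 2L) stop(sprintf("%s must have one value per regime", what),
                            call. = FALSE)
  if (is.null(names(x))) names(x) <- .REGIMES
  if (!setequal(names(x), .REGIMES)) {
    stop(sprintf("%s must be named 'conventional' and 'welfare_friendly'", what),
         call. = FALSE)
  }
  x[.REGIMES]
}
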
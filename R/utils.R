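#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef confint glm lm median plogis predict rbinom
#'   resid rnorm runif sd setNames binomial isoreg mad quantile var
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# derived sub-seeds stay within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483629L)
}

# trapezoidal integral; x must be sorted increasing
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

stop_dropsol <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dropsol_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
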
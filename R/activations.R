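## Activation registry.  Each activation is phi(x) = base(b * x) with an
## input-slope ("curvature") multiplier b; the linear kind has gain a.
## SELU constants are the standard self-normalising values.
SELU_LAMBDA <- 1.0507
SELU_ALPHA  <- 1.6732

#' Activation function specification
#'
#' @param kind one of \code{"sigmoid"}, \code{"tanh"}, \code{"linear"},
#'   \code{"relu"}, \code{"threshold"}, \code{"selu"}.
#' @param curvature input-slope multiplier \code{b} in
#'   \eqn{\phi(x) = base(bx)}; default 1.  The hidden layers of the
#'   retention blocks use \code{tanh} with curvature 0.7.
#' @param gain output gain \code{a} of the \code{linear} kind; default 1.
#' @return object of class \code{"activation_spec"}.
#' @export
activation_spec <- function(kind = c("tanh", "sigmoid", "linear", "relu",
                                     "threshold", "selu"),
                            curvature = 1, gain = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(curvature), length(curvature) == 1L, curvature > 0)
  structure(list(kind = kind, curvature = curvature, gain = gain),
            class = "activation_spec")
}

#' Evaluate an activation function and its derivative
#'
#' @param spec an [activation_spec()].
#' @param x numeric vector or matrix of pre-activations (finite).
#' @return list with \code{value} and analytic \code{deriv}, same shape as
#'   \code{x}.  The threshold kind has derivative 0 almost everywhere.
#' @export
activation_eval <- function(spec, x) {
  stopifnot(inherits(spec, "activation_spec"))
  if (any(!is.finite(x))) stop("non-finite pre-activation", call. = FALSE)
  b <- spec$curvature
  z <- b * x
  switch(spec$kind,
    tanh = {
      t <- tanh(z)
      list(value = t, deriv = b * (1 - t^2))
    },
    sigmoid = {
      s <- 1 / (1 + exp(-z))
      list(value = s, deriv = b * s * (1 - s))
    },
    linear = list(value = spec$gain * z,
                  deriv = array(spec$gain * b, dim = dim(x) %||% length(x))),
    relu = list(value = pmax(z, 0), deriv = b * (z > 0)),
    threshold = list(value = (z > 0) + 0, deriv = 0 * z),
    selu = {
      pos <- z > 0
      v <- ifelse(pos, SELU_LAMBDA * z, SELU_LAMBDA * SELU_ALPHA * (exp(z) - 1))
      d <- ifelse(pos, SELU_LAMBDA * b, SELU_LAMBDA * SELU_ALPHA * exp(z) * b)
      list(value = v, deriv = d)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
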
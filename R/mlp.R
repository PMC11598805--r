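#' Initialise a single-hidden-layer perceptron block
#'
#' The retention blocks are feed-forward networks with one hidden layer of
#' \code{tanh(0.7 x)} neurons and a linear output neuron.  Weights are drawn
#' uniformly from \eqn{[-0.5, 0.5]} under the given seed ("small random
#' values"); biases start at zero.
#'
#' @param n_inputs number of input neurons (7 for the long-term block,
#'   6 for the short-term block; other sizes allowed).
#' @param n_hidden number of hidden neurons (default 5).
#' @param seed integer seed (required for reproducibility).
#' @param hidden hidden-layer [activation_spec()]; default tanh with
#'   curvature 0.7.
#' @param output output-neuron [activation_spec()]; default linear, gain 1.
#' @return object of class \code{"mlp_block"} with weight matrices
#'   \code{w1} (hidden x inputs), \code{b1}, \code{w2} (1 x hidden),
#'   \code{b2}, the activation specs, layer sizes and the seed.
#' @export
mlp_init <- function(n_inputs, n_hidden = 5, seed,
                     hidden = activation_spec("tanh", curvature = 0.7),
                     output = activation_spec("linear")) {
  if (n_inputs < 1L || n_hidden < 1L)
    stop("layer sizes must be positive", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  w <- local_seed(seed, stats::runif(n_hidden * n_inputs + n_hidden, -0.5, 0.5))
  structure(
    list(w1 = matrix(w[seq_len(n_hidden * n_inputs)], n_hidden, n_inputs),
         b1 = numeric(n_hidden),
         w2 = matrix(w[n_hidden * n_inputs + seq_len(n_hidden)], 1L, n_hidden),
         b2 = 0,
         hidden = hidden, output = output,
         n_inputs = n_inputs, n_hidden = n_hidden, seed = seed),
    class = "mlp_block")
}

#' Forward pass of an MLP block
#'
#' @param model an \code{mlp_block}.
#' @param x input matrix (rows = examples, columns = features) or a single
#'   input vector; column count must equal \code{model$n_inputs}.
#' @return numeric vector of scalar outputs, one per row.
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_block"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_inputs)
    stop("input has ", ncol(x), " columns; model expects ", model$n_inputs,
         call. = FALSE)
  s1 <- x %*% t(model$w1)
  s1 <- sweep(s1, 2L, model$b1, "+")
  h <- activation_eval(model$hidden, s1)$value
  s2 <- drop(h %*% t(model$w2)) + model$b2
  activation_eval(model$output, s2)$value
}

#' Mean-squared-error gradient by backpropagation
#'
#' Gradient of \eqn{\frac{1}{N}\sum_i (y^{model}_i - y^{ref}_i)^2} with
#' respect to every weight and bias, by the chain rule, over the full batch.
#'
#' @param model an \code{mlp_block}.
#' @param x input matrix, rows = examples.
#' @param y reference outputs, length \code{nrow(x)}.
#' @return list with \code{grad} (named list \code{w1}, \code{b1},
#'   \code{w2}, \code{b2} matching the model shapes) and \code{loss}.
#' @export
mlp_gradient <- function(model, x, y) {
  stopifnot(inherits(model, "mlp_block"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- nrow(x)
  if (n == 0L) stop("empty batch", call. = FALSE)
  if (length(y) != n) stop("'y' length must match rows of 'x'", call. = FALSE)

  s1 <- sweep(x %*% t(model$w1), 2L, model$b1, "+")
  a1 <- activation_eval(model$hidden, s1)
  s2 <- drop(a1$value %*% t(model$w2)) + model$b2
  a2 <- activation_eval(model$output, s2)

  resid <- a2$value - y
  loss <- mean(resid^2)
  delta2 <- (2 / n) * resid * a2$deriv              # dL/ds2, length n
  g_w2 <- matrix(delta2 %*% a1$value, 1L)           # 1 x hidden
  g_b2 <- sum(delta2)
  delta1 <- (delta2 %*% model$w2) * a1$deriv        # n x hidden
  g_w1 <- t(delta1) %*% x                           # hidden x inputs
  g_b1 <- colSums(delta1)

  list(grad = list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2), loss = loss)
}

#' Resilient-backpropagation configuration
#'
#' RPROP adapts a per-weight step size: grown by the split factor
#' \code{eta_plus} when the gradient keeps its sign, shrunk by the descent
#' step \code{eta_minus} on a sign flip (with the direction update skipped
#' once — the variant without weight backtracking).
#'
#' @param eta_minus step-shrink factor on sign change (default 0.5).
#' @param eta_plus step-growth factor on sign agreement (default 1.2).
#' @param delta_init initial per-weight step size (default 0.5).
#' @param delta_min,delta_max step-size bounds (defaults 1e-6 and 50).
#' @param epochs number of full-batch training epochs (default 10000).
#' @return object of class \code{"rprop_config"}.
#' @export
rprop_config <- function(eta_minus = 0.5, eta_plus = 1.2, delta_init = 0.5,
                         delta_min = 1e-6, delta_max = 50, epochs = 10000) {
  stopifnot(eta_minus < 1, eta_plus > 1, delta_init > 0,
            delta_min > 0, delta_max >= delta_init, epochs >= 1)
  structure(list(eta_minus = eta_minus, eta_plus = eta_plus,
                 delta_init = delta_init, delta_min = delta_min,
                 delta_max = delta_max, epochs = as.integer(epochs)),
            class = "rprop_config")
}

#' One RPROP step on a flat parameter vector
#'
#' Per weight: if the gradient sign agrees with the previous step's, the
#' step size grows by \code{eta_plus} (capped at \code{delta_max}); on a
#' sign flip it shrinks by \code{eta_minus} (floored at \code{delta_min})
#' and the direction update is skipped once, with the stored gradient
#' zeroed.  The weight then moves by \code{-sign(grad) * delta}.
#'
#' @param w numeric parameter vector.
#' @param grad gradient vector, same length.
#' @param state list with \code{delta} and \code{prev_grad} vectors;
#'   \code{NULL} initialises both from the config.
#' @param config an [rprop_config()].
#' @return list with updated \code{w} and \code{state}.
#' @export
rprop_step <- function(w, grad, state = NULL, config = rprop_config()) {
  if (any(!is.finite(grad))) {
    bad <- which(!is.finite(grad))[1L]
    stop("non-finite gradient at weight ", bad, call. = FALSE)
  }
  if (is.null(state))
    state <- list(delta = rep(config$delta_init, length(w)),
                  prev_grad = numeric(length(w)))
  sgn_prod <- state$prev_grad * grad
  grew <- sgn_prod > 0
  flip <- sgn_prod < 0
  delta <- state$delta
  delta[grew] <- pmin(delta[grew] * config$eta_plus, config$delta_max)
  delta[flip] <- pmax(delta[flip] * config$eta_minus, config$delta_min)
  g_eff <- grad
  g_eff[flip] <- 0
  list(w = w - sign(g_eff) * delta,
       state = list(delta = delta, prev_grad = g_eff))
}

flatten_block <- function(model)
  c(as.vector(model$w1), model$b1, as.vector(model$w2), model$b2)

unflatten_block <- function(model, w) {
  nh <- model$n_hidden; ni <- model$n_inputs
  i <- 0L
  model$w1 <- matrix(w[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  model$b1 <- w[i + seq_len(nh)];                      i <- i + nh
  model$w2 <- matrix(w[i + seq_len(nh)], 1L, nh);      i <- i + nh
  model$b2 <- w[i + 1L]
  model
}

#' Train an MLP block with full-batch RPROP
#'
#' Runs \code{config$epochs} full-batch epochs of resilient
#' backpropagation on inputs normalised to \eqn{[-1,1]}.  The per-epoch
#' training error (the mean squared deviation on the normalised scale) is
#' recorded; because RPROP does not guarantee monotone descent, the weights
#' with the best training error seen are retained and returned.
#'
#' @param model an \code{mlp_block} from [mlp_init()].
#' @param x training input matrix.
#' @param y training targets (normalised scale).
#' @param config an [rprop_config()].
#' @return list with \code{model} (best-so-far weights), \code{history}
#'   (per-epoch training error, length \code{epochs}), \code{best_epoch}
#'   and \code{final_loss} (error at the last epoch's weights, for
#'   auditing the retention of best weights).
#' @export
mlp_train <- function(model, x, y, config = rprop_config()) {
  stopifnot(inherits(model, "mlp_block"), inherits(config, "rprop_config"))
  if (is.null(dim(x))) x <- matrix(x, nrow = length(x))
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  w <- flatten_block(model)
  state <- NULL
  history <- numeric(config$epochs)
  best_loss <- Inf
  best_w <- w
  for (epoch in seq_len(config$epochs)) {
    g <- mlp_gradient(unflatten_block(model, w), x, y)
    if (!is.finite(g$loss))
      stop("non-finite training loss at epoch ", epoch, "; aborting",
           call. = FALSE)
    history[epoch] <- g$loss
    if (g$loss < best_loss) {
      best_loss <- g$loss
      best_w <- w
      best_epoch <- epoch
    }
    st <- rprop_step(w, c(as.vector(g$grad$w1), g$grad$b1,
                          as.vector(g$grad$w2), g$grad$b2),
                     state, config)
    w <- st$w
    state <- st$state
  }
  final_loss <- mlp_gradient(unflatten_block(model, w), x, y)$loss
  if (final_loss < best_loss) {
    best_loss <- final_loss
    best_w <- w
    best_epoch <- config$epochs + 1L
  }
  list(model = unflatten_block(model, best_w), history = history,
       best_epoch = best_epoch, best_loss = best_loss,
       final_loss = final_loss)
}

#' Squared-error report for a prediction batch
#'
#' Per-example squared deviations of model output from reference on the
#' normalised scale, with their mean (the block's aggregate error), minimum
#' and maximum — the three columns reported for each block.
#'
#' @param predicted model outputs (normalised scale).
#' @param reference reference values, same length.
#' @return object of class \code{"error_report"} with \code{per_example},
#'   \code{mean}, \code{min}, \code{max} and \code{n}.
#' @export
error_report <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) == 0L)
    stop("'predicted' and 'reference' must be non-empty and equal length",
         call. = FALSE)
  e <- (predicted - reference)^2
  structure(list(per_example = e, mean = mean(e), min = min(e), max = max(e),
                 n = length(e)),
            class = "error_report")
}

#' Evaluate a trained block on a normalised dataset
#'
#' @param model an \code{mlp_block}.
#' @param x normalised input matrix.
#' @param y normalised reference outputs.
#' @return an [error_report()].
#' @export
mlp_evaluate <- function(model, x, y)
  error_report(mlp_forward(model, x), y)

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "Squared-error report over %d examples: min %.4g | max %.4g | mean %.4g\n",
    x$n, x$min, x$max, x$mean))
  invisible(x)
}

#' @export
print.mlp_block <- function(x, ...) {
  cat(sprintf("MLP block %d-%d-1, hidden %s(curvature %g), output %s\n",
              x$n_inputs, x$n_hidden, x$hidden$kind, x$hidden$curvature,
              x$output$kind))
  invisible(x)
}
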
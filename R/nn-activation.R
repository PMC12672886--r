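#' Clamp the negative-branch slope parameter
#'
#' The element-wise learned sign attention (ELSA) module clamps its
#' learnable negative-branch parameter into [0.01, 0.99] so negative
#' pre-activations are always suppressed but never zeroed.
#'
#' @param alpha numeric value(s); must be finite.
#' @return \code{min(max(alpha, 0.01), 0.99)}, elementwise.
#' @examples
#' elsaClamp(c(0.5, 5, -3)) # 0.5, 0.99, 0.01
#' @export
elsaClamp <- function(alpha) {
  if (any(!is.finite(alpha))) stop("alpha must be finite")
  pmin(0.99, pmax(0.01, alpha))
}

#' ELSA sign-dependent attention weight
#'
#' Elements of the pre-activation volume receive an attention weight
#' depending only on their sign: \code{C(alpha)} (clamped) for negative
#' elements, \code{sigmoid(beta)} for non-negative ones (zero is assigned
#' to the non-negative branch).
#'
#' @param v pre-activation value(s).
#' @param alpha,beta learnable parameters.
#' @return attention weight(s) in (0, 1).
#' @examples
#' elsaAttention(c(-1, 2), alpha = 0.5, beta = 0) # 0.5, 0.5
#' @export
elsaAttention <- function(v, alpha, beta) {
  ifelse(v < 0, elsaClamp(alpha), stats::plogis(beta))
}

#' AReLU learnable activation
#'
#' Combines ReLU with ELSA residual attention: negative inputs are scaled
#' by the clamped slope \code{C(alpha)} (in [0.01, 0.99], so their
#' magnitude shrinks), non-negative inputs by \code{1 + sigmoid(beta)}
#' (ReLU passes them through and the attention adds a residual
#' amplification, so the slope is at least 1). Applied elementwise to
#' inputs of any shape; the shape is preserved.
#'
#' @param x input value(s), vector or array.
#' @param alpha,beta learnable parameters.
#' @return activated values, same shape as \code{x}.
#' @examples
#' arelu(c(-1, 0, 2), alpha = 5, beta = 0) # -0.99, 0, 3
#' @export
arelu <- function(x, alpha, beta) {
  y <- ifelse(x < 0, elsaClamp(alpha) * x, (1 + stats::plogis(beta)) * x)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Analytic partial derivatives of AReLU
#'
#' Returns the partials of \code{\link{arelu}} with respect to the input
#' and both learnable parameters, demonstrating that the activation is
#' trainable end to end: \code{d/dx} is the branch slope;
#' \code{d/dalpha = x} on the negative branch while \code{alpha} is
#' strictly inside the clamp (and 0 where the clamp saturates);
#' \code{d/dbeta = x * sigmoid(beta) * (1 - sigmoid(beta))} on the
#' non-negative branch. \code{d/dx} is undefined at \code{x = 0}; the
#' non-negative branch slope is reported there.
#'
#' @param x input value(s).
#' @param alpha,beta learnable parameters.
#' @return list with elementwise \code{dx}, \code{dalpha}, \code{dbeta}.
#' @export
areluGradients <- function(x, alpha, beta) {
  sb <- stats::plogis(beta)
  neg <- x < 0
  inside <- alpha > 0.01 & alpha < 0.99
  list(dx = ifelse(neg, elsaClamp(alpha), 1 + sb),
       dalpha = ifelse(neg & inside, x, 0),
       dbeta = ifelse(neg, 0, x * sb * (1 - sb)))
}

#' Fit AReLU slopes to activation pairs by gradient descent
#'
#' Small demonstration that the two AReLU parameters are recoverable by
#' first-order optimisation: given pre-activation inputs \code{x} and
#' target outputs \code{y} produced by some AReLU, minimises mean squared
#' error over \code{(alpha, beta)} with plain gradient descent using the
#' analytic partials.
#'
#' @param x,y paired pre-/post-activation values.
#' @param alpha0,beta0 initial parameter values.
#' @param lr learning rate.
#' @param iters iteration count.
#' @return list with fitted \code{alpha} (clamped), \code{beta}, and the
#'   final mean squared error \code{mse}.
#' @export
fitArelu <- function(x, y, alpha0 = 0.5, beta0 = 0, lr = 0.05,
                     iters = 500L) {
  a <- alpha0; b <- beta0
  for (it in seq_len(iters)) {
    pred <- arelu(x, a, b)
    res <- pred - y
    g <- areluGradients(x, a, b)
    a <- a - lr * mean(2 * res * g$dalpha)
    b <- b - lr * mean(2 * res * g$dbeta)
    # stay strictly inside the clamp so the alpha gradient never dies
    a <- min(max(a, 0.011), 0.989)
  }
  list(alpha = elsaClamp(a), beta = b,
       mse = mean((arelu(x, a, b) - y)^2))
}
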
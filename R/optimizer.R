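# Loop controller: an Adam-like update that turns the classifier's test
# accuracy into the next cycle's window fraction P.

#' Create the loop-controller state
#'
#' Holds the exponential moment accumulators and hyperparameters of the
#' Adam-like rule that drives the shuffle window fraction `P` (called
#' `omega` inside the state). Defaults are the loop's operating point:
#' learning rate 1, `beta1 = 0.95`, `beta2 = 0.99`, `epsilon = 1e-4`.
#'
#' Two sign conventions are exposed. `"standard"` (the default) accumulates
#' the moments with plus signs, `v' = beta1 * v + (1 - beta1) * g` and
#' `s' = beta2 * s + (1 - beta2) * g^2`, so `s` is a true non-negative
#' second moment. `"as_printed"` uses minus signs in both accumulators (and
#' floors `s` at zero before the square root) for fidelity experiments with
#' the update as typeset.
#'
#' @param P Initial window fraction (`omega`), default 0.1.
#' @param eta Learning rate, default 1.
#' @param beta1,beta2 Moment decay rates, defaults 0.95 and 0.99.
#' @param epsilon Denominator guard, default 1e-4.
#' @param convention `"standard"` or `"as_printed"`.
#' @param keep_trailing_g Keep the trailing `g` factor in the step
#'   `delta = eta * v / (sqrt(s) + epsilon) * g` (default `TRUE`); set
#'   `FALSE` for the plain Adam-style step without it.
#' @return An object of class `loop_optimizer`.
#' @export
optimizer_state <- function(P = 0.1, eta = 1, beta1 = 0.95, beta2 = 0.99,
                            epsilon = 1e-4,
                            convention = c("standard", "as_printed"),
                            keep_trailing_g = TRUE) {
  convention <- match.arg(convention)
  structure(
    list(v = 0, s = 0, t = 0L, eta = eta, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, omega = P, convention = convention,
         keep_trailing_g = keep_trailing_g),
    class = "loop_optimizer"
  )
}

#' @export
print.loop_optimizer <- function(x, ...) {
  cat(sprintf(
    "<loop_optimizer> t = %d, P = %.4f, v = %.4g, s = %.4g (%s convention)\n",
    x$t, x$omega, x$v, x$s, x$convention))
  invisible(x)
}

#' Gradient signal from test accuracy
#'
#' The controller's driving signal is the classification error
#' `g = 1 - test_accuracy`: shuffling pressure decays to zero as the
#' classes become perfectly separable.
#'
#' @param test_accuracy Fraction in `[0, 1]`.
#' @return The gradient `g`.
#' @export
accuracy_gradient <- function(test_accuracy) {
  stopifnot(is_scalar_number(test_accuracy),
            test_accuracy >= 0, test_accuracy <= 1)
  1 - test_accuracy
}

#' One controller step: update the window fraction P
#'
#' Standard convention: `v' = beta1 * v + (1 - beta1) * g`,
#' `s' = beta2 * s + (1 - beta2) * g^2`,
#' `delta = eta * v' / (sqrt(s') + epsilon) * g`, and
#' `P' = clip(P + delta, 0.01, 1)` so the window is never empty nor larger
#' than the table. The `"as_printed"` convention substitutes minus signs in
#' both accumulators and floors `s'` at zero before the square root.
#'
#' @param state A [optimizer_state()].
#' @param g Gradient from [accuracy_gradient()].
#' @return The updated `loop_optimizer`; the step taken is in attribute
#'   `delta`.
#' @export
update_P <- function(state, g) {
  stopifnot(inherits(state, "loop_optimizer"), is_scalar_number(g))
  sgn <- if (state$convention == "standard") 1 else -1
  v <- state$beta1 * state$v + sgn * (1 - state$beta1) * g
  s <- state$beta2 * state$s + sgn * (1 - state$beta2) * g^2
  if (state$convention == "as_printed") s <- max(s, 0)
  delta <- state$eta * v / (sqrt(s) + state$epsilon)
  if (state$keep_trailing_g) delta <- delta * g
  if (!is.finite(delta)) {
    stop("non-finite controller step: g = ", g, ", v = ", v, ", s = ", s,
         ", t = ", state$t, call. = FALSE)
  }
  state$v <- v
  state$s <- s
  state$t <- state$t + 1L
  state$omega <- min(max(state$omega + delta, 0.01), 1)
  attr(state, "delta") <- delta
  state
}
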
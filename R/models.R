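#' Growth rate of the single-species Verhulst model
#'
#' Right-hand side of the logistic equation, \eqn{r x (1 - x/N)}.
#' Vectorised over `x`.
#'
#' @param p A [single_params()] object.
#' @param x Population (nonnegative), individuals.
#' @return Rate of change in individuals per month.
#' @examples
#' p <- single_params(0.8, 780500, 6000)
#' rhs_single(p, 390250)  # maximal growth rate r*N/4
#' @export
rhs_single <- function(p, x) {
  p$r * x * (1 - x / p$N)
}

#' Closed-form solution of the single-species Verhulst model
#'
#' The logistic growth function
#' \deqn{x(t) = \frac{x_0 N}{(N - x_0) e^{-r t} + x_0}.}
#' Vectorised over `t`.  When `x0 = 0` the solution is identically zero.
#'
#' @param p A [single_params()] object.
#' @param t Time in months (nonnegative), may be a vector.
#' @return Population at each time in `t`.
#' @examples
#' p <- single_params(0.8, 780500, 6000)
#' solution_single(p, c(0, 6, 12))
#' @export
solution_single <- function(p, t) {
  if (p$x0 == 0) return(rep(0, length(t)))
  p$x0 * p$N / ((p$N - p$x0) * exp(-p$r * t) + p$x0)
}

#' Growth rate of the Verhulst model coupled to an exogenous signal
#'
#' Right-hand side \eqn{r x (1 - x/N + \alpha v / N)}.  A negative
#' coupling (`alpha < 0`) makes the signal inhibit growth (harvesting);
#' a positive coupling makes it enhance growth.
#'
#' @param p A [coupled_params()] object.
#' @param x Population (nonnegative).
#' @param v Signal level (nonnegative).
#' @param alpha Coupling parameter; defaults to the one stored in `p`.
#'   Supplied explicitly by the closed-loop simulator, where the coupling
#'   is the manipulated variable.
#' @return Rate of change in individuals per month.
#' @export
rhs_coupled <- function(p, x, v, alpha = p$alpha) {
  p$r * x * (1 - x / p$N + alpha * v / p$N)
}

#' Closed-form solution of the coupled Verhulst model under constant signal
#'
#' \deqn{x(t) = \frac{x_0 N + x_0 \alpha v}{(N + \alpha v - x_0)
#'       e^{-r t (1 + \alpha v/N)} + x_0}}
#' valid only while `v` (and `alpha`) are constant on `[0, t]` and the
#' effective capacity `N + alpha*v` is positive.  In the extinction regime
#' `N + alpha*v <= 0` the expression is not a positive sigmoid and the
#' function signals an error; use the numeric integrator there.
#'
#' @inheritParams rhs_coupled
#' @param t Time in months (nonnegative), may be a vector.
#' @return Population at each time in `t`.
#' @examples
#' p <- coupled_params(0.8, 780500, -390.25, 10000)
#' solution_coupled(p, v = 1000, t = c(0, 12, 60))  # tends to N + alpha*v
#' @export
solution_coupled <- function(p, v, t, alpha = p$alpha) {
  Neff <- p$N + alpha * v
  if (Neff <= 0)
    stop("extinction regime: N + alpha*v <= 0 has no positive sigmoid ",
         "solution; integrate numerically", call. = FALSE)
  if (p$x0 == 0) return(rep(0, length(t)))
  reff <- p$r * (1 + alpha * v / p$N)
  p$x0 * Neff / ((Neff - p$x0) * exp(-reff * t) + p$x0)
}

#' Growth rates of the two-species coexistence model
#'
#' Right-hand side pair of the coupled logistic system; see
#' [coexist_params()] for the equations.
#'
#' @param p A [coexist_params()] object.
#' @param x1,x2 Current populations (nonnegative).
#' @param alpha1 Coupling of species 1 to species 2; defaults to the value
#'   stored in `p` and is overridden by the closed-loop simulator.
#' @return Numeric vector `c(dx1, dx2)` in individuals per month.
#' @examples
#' p <- coexist_params(1, 1, 100, 200, 0.5, 0.5, 10, 10)
#' rhs_coexist(p, 266.6667, 333.3333)  # ~0 at the non-trivial equilibrium
#' @export
rhs_coexist <- function(p, x1, x2, alpha1 = p$alpha1) {
  c(p$r1 * x1 * (1 - x1 / p$N1 + alpha1 * x2 / p$N1),
    p$r2 * x2 * (1 - x2 / p$N2 + p$alpha2 * x1 / p$N2))
}
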
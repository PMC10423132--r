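#' Parameter set for the single-species Verhulst model
#'
#' Bundles the parameters of the logistic (Verhulst) growth equation
#' \deqn{\dot x = r x (1 - x/N)}
#' together with the initial population.
#'
#' @param r Intrinsic growth rate per month (nonnegative).
#' @param N Maximum carrying capacity in individuals (positive).
#' @param x0 Initial population in individuals (nonnegative).
#'
#' @return An object of class `"single_params"`: a list with elements
#'   `r`, `N`, `x0`.
#' @examples
#' single_params(r = 0.8, N = 780500, x0 = 6000)
#' @export
single_params <- function(r, N, x0) {
  check_scalar(r, "r", min = 0)
  check_scalar(N, "N", min = 0, strict = TRUE)
  check_scalar(x0, "x0", min = 0)
  structure(list(r = r, N = N, x0 = x0), class = "single_params")
}

#' Parameter set for the Verhulst model coupled to an exogenous signal
#'
#' Parameters of the coupled growth equation
#' \deqn{\dot x = r x (1 - x/N + \alpha v / N)}
#' where `v` is an exogenous signal (e.g. number of fishermen) and
#' `alpha` is the signed coupling parameter scaling its influence.
#' The signal level itself is supplied to each operation separately, so
#' one parameter set can be evaluated under several signal levels.
#'
#' @param r Intrinsic growth rate per month (nonnegative).
#' @param N Maximum carrying capacity in individuals (positive).
#' @param alpha Coupling parameter, individuals of `x` per unit of signal
#'   (any sign; negative values model inhibition such as harvesting).
#' @param x0 Initial population in individuals (nonnegative).
#'
#' @return An object of class `"coupled_params"`.
#' @examples
#' coupled_params(r = 0.8, N = 780500, alpha = -780.5, x0 = 10000)
#' @export
coupled_params <- function(r, N, alpha, x0) {
  check_scalar(r, "r", min = 0)
  check_scalar(N, "N", min = 0, strict = TRUE)
  check_scalar(alpha, "alpha")
  check_scalar(x0, "x0", min = 0)
  structure(list(r = r, N = N, alpha = alpha, x0 = x0),
            class = "coupled_params")
}

#' Parameter set for the two-species Verhulst coexistence model
#'
#' Parameters of the coupled pair
#' \deqn{\dot x_1 = r_1 x_1 (1 - x_1/N_1 + \alpha_1 x_2/N_1)}
#' \deqn{\dot x_2 = r_2 x_2 (1 - x_2/N_2 + \alpha_2 x_1/N_2)}
#' The signs of `alpha1` and `alpha2` select the ecological regime
#' (see [classify_regime()]).
#'
#' @param r1,r2 Intrinsic growth rates per month (nonnegative).
#' @param N1,N2 Maximum carrying capacities in individuals (positive).
#' @param alpha1,alpha2 Signed coupling (interaction) parameters.
#' @param x01,x02 Initial populations (nonnegative).
#'
#' @return An object of class `"coexist_params"`.
#' @examples
#' # amensalism: species 2 grows independently and inhibits species 1
#' coexist_params(r1 = 0.8, r2 = 0.11, N1 = 780500, N2 = 5000,
#'                alpha1 = -78.05, alpha2 = 0, x01 = 10000, x02 = 500)
#' @export
coexist_params <- function(r1, r2, N1, N2, alpha1, alpha2, x01, x02) {
  check_scalar(r1, "r1", min = 0)
  check_scalar(r2, "r2", min = 0)
  check_scalar(N1, "N1", min = 0, strict = TRUE)
  check_scalar(N2, "N2", min = 0, strict = TRUE)
  check_scalar(alpha1, "alpha1")
  check_scalar(alpha2, "alpha2")
  check_scalar(x01, "x01", min = 0)
  check_scalar(x02, "x02", min = 0)
  structure(list(r1 = r1, r2 = r2, N1 = N1, N2 = N2,
                 alpha1 = alpha1, alpha2 = alpha2,
                 x01 = x01, x02 = x02),
            class = "coexist_params")
}

# scalar validation used by every constructor; `strict` demands > min
check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) x > min else x >= min
  if (!ok)
    stop(sprintf("'%s' must be %s %g (got %g)", name,
                 if (strict) ">" else ">=", min, x), call. = FALSE)
  invisible(x)
}

#' @export
print.single_params <- function(x, ...) {
  cat("Single-species Verhulst parameters\n")
  cat(sprintf("  r = %g /month, N = %g individuals, x0 = %g\n",
              x$r, x$N, x$x0))
  invisible(x)
}

#' @export
print.coupled_params <- function(x, ...) {
  cat("Coupled Verhulst parameters (exogenous signal)\n")
  cat(sprintf("  r = %g /month, N = %g, alpha = %g, x0 = %g\n",
              x$r, x$N, x$alpha, x$x0))
  invisible(x)
}

#' @export
print.coexist_params <- function(x, ...) {
  cat("Two-species coexistence parameters\n")
  cat(sprintf("  species 1: r = %g, N = %g, alpha = %g, x0 = %g\n",
              x$r1, x$N1, x$alpha1, x$x01))
  cat(sprintf("  species 2: r = %g, N = %g, alpha = %g, x0 = %g\n",
              x$r2, x$N2, x$alpha2, x$x02))
  cat(sprintf("  regime: %s\n", classify_regime(x)$regime))
  invisible(x)
}
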
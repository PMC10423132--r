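#' Settings for the coupling-parameter regulation laws
#'
#' The regulation laws steer a population to a desired final value
#' `x_d` by manipulating its (negative) coupling parameter.  The
#' commanded coupling is saturated into `[alpha_min, alpha_max]`; the
#' lower bound must stay above the extinction threshold of the model in
#' use (`-N/v` for the exogenous-signal model, `-N_j/N_i` for the
#' coexistence model), which is what the defaults enforce.
#'
#' @param x_d Desired population in individuals (positive).
#' @param K Control gain (positive, dimensionless).  Changes the
#'   settling speed, not the steady state.
#' @param alpha_min Lower saturation bound for the commanded coupling.
#'   `NULL` (default) means "just inside the extinction bound", computed
#'   at call time as `-N/v * (1 - 1e-6)` or `-N_j/N_i * (1 - 1e-6)`.
#' @param alpha_max Upper bound, at most 0 (the laws only withdraw
#'   individuals; a positive coupling cannot regulate).
#' @param x_floor Small positive population used to guard the divisions
#'   inside the laws (default 1 individual).
#'
#' @return An object of class `"control_spec"`.
#' @examples
#' control_spec(x_d = 0.65 * 780500, K = 1)
#' @export
control_spec <- function(x_d, K = 1, alpha_min = NULL, alpha_max = 0,
                         x_floor = 1) {
  check_scalar(x_d, "x_d", min = 0, strict = TRUE)
  check_scalar(K, "K", min = 0, strict = TRUE)
  check_scalar(alpha_max, "alpha_max")
  if (alpha_max > 0) stop("alpha_max must be <= 0", call. = FALSE)
  if (!is.null(alpha_min)) {
    check_scalar(alpha_min, "alpha_min")
    if (alpha_min >= alpha_max)
      stop("alpha_min must be < alpha_max", call. = FALSE)
  }
  check_scalar(x_floor, "x_floor", min = 0, strict = TRUE)
  structure(list(x_d = x_d, K = K, alpha_min = alpha_min,
                 alpha_max = alpha_max, x_floor = x_floor),
            class = "control_spec")
}

# shared saturation; default lower bound sits just inside the extinction
# threshold `bound` so a large transient can never command extinction
saturate_alpha <- function(alpha, spec, bound) {
  lo <- if (is.null(spec$alpha_min)) bound * (1 - 1e-6) else spec$alpha_min
  min(max(alpha, lo), spec$alpha_max)
}

#' Regulation law for the exogenous-signal model
#'
#' Computes the manipulated coupling
#' \deqn{\alpha(t) = \frac{1}{v}\left(-\frac{K N (x - x_d)}{r x}
#'       - N + x\right)}
#' and saturates it into `[alpha_min, alpha_max]`.  At zero tracking
#' error the unsaturated command is `(x_d - N)/v`, which places the
#' model's non-trivial equilibrium `N + alpha v` exactly at `x_d`;
#' substituting the unsaturated law into the model reduces the
#' closed-loop dynamics to `dx/dt = -K (x - x_d)`.
#'
#' @param p A [coupled_params()] object.
#' @param spec A [control_spec()] object.
#' @param x Current population (guarded below by `spec$x_floor`).
#' @param v Current signal level (positive; the law is undefined at
#'   `v = 0`, where there is no coupling channel).
#' @return The saturated coupling value to apply.
#' @examples
#' p <- coupled_params(0.8, 780500, 0, 10000)
#' s <- control_spec(x_d = 0.65 * 780500)
#' control_alpha_coupled(p, s, x = 0.65 * 780500, v = 1000)  # -273.175
#' @export
control_alpha_coupled <- function(p, spec, x, v) {
  if (v <= 0)
    stop("no coupling channel: the regulation law requires v > 0",
         call. = FALSE)
  x <- max(x, spec$x_floor)
  raw <- (1 / v) * (-spec$K * p$N * (x - spec$x_d) / (p$r * x) - p$N + x)
  saturate_alpha(raw, spec, -p$N / v)
}

#' Regulation law for the coexistence model
#'
#' Regulates species `j` through its coupling to species `i = 3 - j`:
#' \deqn{\alpha_j(t) = \frac{1}{x_i}\left(-\frac{K_j N_j (x_j - x_{jd})}
#'       {r_j x_j} - N_j + x_j\right)}
#' saturated into the regulable band `(-N_j/N_i, 0]`.  When the partner
#' population `x_i` falls below `spec$x_floor` the law has no authority
#' and the previous coupling is held (with a warning).
#'
#' @param p A [coexist_params()] object.
#' @param spec A [control_spec()] object.
#' @param j Index of the controlled species (1 or 2).
#' @param xj Current population of the controlled species.
#' @param xi Current population of the partner species.
#' @param alpha_prev Coupling applied at the previous step, returned
#'   unchanged when the partner population is below the floor.
#' @return The saturated coupling value to apply.
#' @export
control_alpha_coexist <- function(p, spec, j, xj, xi, alpha_prev = 0) {
  stopifnot(j %in% 1:2)
  Nj <- if (j == 1L) p$N1 else p$N2
  Ni <- if (j == 1L) p$N2 else p$N1
  rj <- if (j == 1L) p$r1 else p$r2
  if (xi < spec$x_floor) {
    warning("partner population below floor: holding previous coupling",
            call. = FALSE)
    return(alpha_prev)
  }
  xj <- max(xj, spec$x_floor)
  raw <- (1 / xi) * (-spec$K * Nj * (xj - spec$x_d) / (rj * xj) - Nj + xj)
  saturate_alpha(raw, spec, -Nj / Ni)
}
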
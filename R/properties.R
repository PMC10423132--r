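# Closed-form dynamic properties of the three model families:
# equilibria, final values, inflection points, characteristic times,
# and the six-regime classification of the two-species couplings.
#
# Conventions used throughout:
#   * an "absent" or "undefined" quantity is returned as NA_real_, never
#     as a complex or negative time;
#   * qualitative conditions (extinction branch, violated lemma
#     preconditions, unstable overgrowth) are reported in a "flags"
#     attribute, retrievable with property_flags().

with_flags <- function(x, flags) {
  if (length(flags)) attr(x, "flags") <- flags
  x
}

#' Qualitative flags attached to a property result
#'
#' Several property functions annotate their numeric result with
#' qualitative flags such as `"extinction"` or `"unstable_overgrowth"`.
#'
#' @param x A result returned by one of the property functions.
#' @return A character vector of flags (empty if none).
#' @export
property_flags <- function(x) {
  f <- attr(x, "flags", exact = TRUE)
  if (is.null(f)) character(0) else f
}

# ---- single species ------------------------------------------------------

#' Equilibria of the single-species Verhulst model
#'
#' The trivial equilibrium 0 and the non-trivial equilibrium at the
#' carrying capacity `N`.
#'
#' @param p A [single_params()] object with `r > 0`.
#' @return Named numeric vector `c(trivial = 0, nontrivial = N)`.
#' @examples
#' equilibria_single(single_params(0.8, 780500, 6000))
#' @export
equilibria_single <- function(p) {
  stopifnot(p$r > 0)
  c(trivial = 0, nontrivial = p$N)
}

#' Final value of the single-species Verhulst model
#'
#' The limit of the trajectory as `t -> Inf`, equal to the carrying
#' capacity `N` for any nonzero start (growth branch for `x0 < N`,
#' decline branch for `x0 > N`); independent of `r`.
#'
#' @inheritParams equilibria_single
#' @return The limiting population `N`.
#' @export
final_value_single <- function(p) {
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  p$N
}

#' Inflection point of the single-species Verhulst model
#'
#' The population at which the growth rate is maximal, `N/2`.  The
#' sigmoid only passes through it when the start lies below it: for
#' `x0 >= N/2` the inflection is absent and `NA` is returned.
#'
#' @inheritParams equilibria_single
#' @return `N/2`, or `NA` when the trajectory has no inflection.
#' @examples
#' inflection_single(single_params(0.8, 780500, 6000))    # 390250
#' inflection_single(single_params(0.8, 780500, 400000))  # NA (absent)
#' @export
inflection_single <- function(p) {
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  if (p$x0 >= p$N / 2) return(NA_real_)
  p$N / 2
}

#' Transitory time duration of the single-species model
#'
#' Time for the trajectory to come within 1% of its final value:
#' `x(t*) = 0.99 N` on the growth branch (`x0 < N`) and `x(t*) = 1.01 N`
#' on the decline branch (`x0 > N`).  After `t*` the population is
#' effectively at equilibrium, so any regulation must act before it.
#'
#' @inheritParams equilibria_single
#' @return Time in months.
#' @examples
#' transitory_time_single(single_params(0.8, 780500, 6000))  # ~11.8
#' @export
transitory_time_single <- function(p) {
  stopifnot(p$r > 0)
  if (p$x0 == p$N) stop("already at equilibrium: x0 = N", call. = FALSE)
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  if (p$x0 < p$N) log(99 * (p$N - p$x0) / p$x0) / p$r
  else            log(101 * (p$x0 - p$N) / p$x0) / p$r
}

#' Time to inflection of the single-species model
#'
#' The instant at which the trajectory crosses `N/2` and the growth rate
#' peaks: `(1/r) log((N - x0)/x0)`, defined for `0 < x0 < N/2`.
#'
#' @inheritParams equilibria_single
#' @return Time in months, or `NA` when the inflection is absent
#'   (`x0 >= N/2`).
#' @examples
#' time_to_inflection_single(single_params(0.8, 780500, 6000))  # ~6.08
#' @export
time_to_inflection_single <- function(p) {
  stopifnot(p$r > 0)
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  if (p$x0 >= p$N / 2) return(NA_real_)
  log((p$N - p$x0) / p$x0) / p$r
}

#' Recover the intrinsic growth rate from a characteristic time
#'
#' Inverts the transitory-time or time-to-inflection formula: given `N`,
#' `x0` and an observed characteristic time, returns the `r` that
#' reproduces it.  Used to calibrate a logistic sub-model when the time
#' to maturity or to saturation is known but the growth rate is not.
#'
#' @param N Carrying capacity (positive).
#' @param x0 Initial population (positive).
#' @param target_time The observed characteristic time in months
#'   (positive).
#' @param which `"transitory"` (time to 99%/101% of the final value) or
#'   `"inflection"` (time to `N/2`).
#' @return The intrinsic growth rate per month.
#' @examples
#' rate_from_time(N = 5000, x0 = 500, target_time = 60, "transitory")
#' @export
rate_from_time <- function(N, x0, target_time,
                           which = c("transitory", "inflection")) {
  which <- match.arg(which)
  check_scalar(N, "N", min = 0, strict = TRUE)
  check_scalar(x0, "x0", min = 0, strict = TRUE)
  check_scalar(target_time, "target_time", min = 0, strict = TRUE)
  arg <- switch(which,
    transitory = if (x0 < N) 99 * (N - x0) / x0
                 else if (x0 > N) 101 * (x0 - N) / x0
                 else stop("x0 = N: no transitory phase", call. = FALSE),
    inflection = {
      if (x0 >= N / 2)
        stop("x0 >= N/2: trajectory has no inflection", call. = FALSE)
      (N - x0) / x0
    })
  r <- log(arg) / target_time
  if (r <= 0)
    stop("infeasible inversion: implied growth rate is not positive",
         call. = FALSE)
  r
}

# ---- coupled with exogenous signal ---------------------------------------

#' Equilibria of the coupled Verhulst model under constant signal
#'
#' Trivial equilibrium 0 and non-trivial equilibrium `N + alpha*v`.
#' The closed-form lemma assumes `|alpha*v| < N`; outside that range the
#' result carries a `"lemma_condition_violated"` flag, and when the
#' effective capacity is non-positive the non-trivial equilibrium is
#' floored at 0 with an `"extinction"` flag.
#'
#' @param p A [coupled_params()] object.
#' @param v Constant signal level (nonzero).
#' @return Named vector `c(trivial, nontrivial)` with optional flags
#'   (see [property_flags()]).
#' @export
equilibria_coupled <- function(p, v) {
  stopifnot(v != 0)
  Neff <- p$N + p$alpha * v
  flags <- character(0)
  if (abs(p$alpha * v) >= p$N) flags <- "lemma_condition_violated"
  if (Neff <= 0) flags <- c(flags, "extinction")
  with_flags(c(trivial = 0, nontrivial = max(Neff, 0)), flags)
}

#' Final value of the coupled Verhulst model
#'
#' `N + alpha*v` when `alpha > -N/v` and 0 (extinction, flagged) when
#' `alpha <= -N/v`.  A positive coupling pushes the final value above
#' the carrying capacity, a negative one below it.
#'
#' @inheritParams equilibria_coupled
#' @return The limiting population, flagged `"extinction"` on the zero
#'   branch.
#' @examples
#' p <- coupled_params(0.8, 780500, -390.25, 10000)
#' final_value_coupled(p, v = 1000)  # 390250
#' @export
final_value_coupled <- function(p, v) {
  stopifnot(v != 0)
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  if (p$alpha <= -p$N / v) return(with_flags(0, "extinction"))
  p$N + p$alpha * v
}

#' Inflection point of the coupled Verhulst model
#'
#' Half the effective capacity, `(N + alpha*v)/2`; absent (`NA`) when
#' the start lies at or above it, or in the extinction regime.
#'
#' @inheritParams equilibria_coupled
#' @return Population at maximal growth rate, or `NA`.
#' @export
inflection_coupled <- function(p, v) {
  stopifnot(v != 0)
  Neff <- p$N + p$alpha * v
  if (Neff <= 0) return(with_flags(NA_real_, "extinction"))
  if (p$x0 >= Neff / 2) return(NA_real_)
  Neff / 2
}

#' Characteristic times of the coupled Verhulst model
#'
#' Same 99%/101% and inflection-crossing definitions as the single-species
#' versions, with the carrying capacity replaced by the effective capacity
#' `N + alpha*v` and the rate scaled to `r (1 + alpha*v/N)`.  In the
#' extinction regime (`1 + alpha*v/N <= 0`) there is no finite sigmoid
#' time and `NA` is returned.
#'
#' @inheritParams equilibria_coupled
#' @return Time in months, or `NA` when undefined.
#' @export
transitory_time_coupled <- function(p, v) {
  stopifnot(p$r > 0, v != 0)
  reff <- p$r * (1 + p$alpha * v / p$N)
  Neff <- p$N + p$alpha * v
  if (reff <= 0) return(with_flags(NA_real_, "extinction"))
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  if (p$x0 == Neff) stop("already at equilibrium", call. = FALSE)
  if (p$x0 < Neff) log(99 * (Neff - p$x0) / p$x0) / reff
  else             log(101 * (p$x0 - Neff) / p$x0) / reff
}

#' @rdname transitory_time_coupled
#' @export
time_to_inflection_coupled <- function(p, v) {
  stopifnot(p$r > 0, v != 0)
  reff <- p$r * (1 + p$alpha * v / p$N)
  Neff <- p$N + p$alpha * v
  if (reff <= 0) return(with_flags(NA_real_, "extinction"))
  if (p$x0 == 0)
    stop("x0 = 0 starts at the trivial equilibrium; no growth", call. = FALSE)
  if (p$x0 >= Neff / 2) return(NA_real_)
  log((Neff - p$x0) / p$x0) / reff
}

# ---- two-species coexistence ---------------------------------------------

#' Equilibria of the two-species coexistence model
#'
#' The trivial pair (0, 0) and the non-trivial pair
#' \deqn{x_j^* = \frac{N_j + \alpha_j N_i}{1 - \alpha_1 \alpha_2},
#'       \quad i = 3 - j,}
#' which exists only when `alpha1*alpha2 != 1`.
#'
#' @param p A [coexist_params()] object.
#' @return A list with elements `trivial = c(0, 0)` and `nontrivial`
#'   (length-2 numeric).
#' @examples
#' equilibria_coexist(coexist_params(1, 1, 100, 200, 0.5, 0.5, 10, 10))
#' @export
equilibria_coexist <- function(p) {
  prod <- p$alpha1 * p$alpha2
  if (prod == 1)
    stop("alpha1*alpha2 = 1: no real solution for the non-trivial ",
         "equilibrium", call. = FALSE)
  list(trivial = c(0, 0),
       nontrivial = c((p$N1 + p$alpha1 * p$N2) / (1 - prod),
                      (p$N2 + p$alpha2 * p$N1) / (1 - prod)))
}

#' Final values of the two-species coexistence model
#'
#' Per-species limiting populations, with four branches for species `j`
#' (partner `i`):
#' unbounded overgrowth (`Inf`, flagged `"unstable_overgrowth"`) when
#' `alpha_j > 0` and `alpha_1*alpha_2 >= 1`; the non-trivial equilibrium
#' `(N_j + alpha_j N_i)/(1 - alpha_1 alpha_2)` when the product is below
#' 1 and `alpha_j > -N_j/N_i`; extinction (0, flagged) when
#' `alpha_j <= -N_j/N_i`.  When one species goes extinct the survivor no
#' longer feels any coupling and settles at its own carrying capacity.
#' If both couplings lie at or below their extinction bounds the outcome
#' depends on the initial conditions and `NA` is returned with a
#' `"strong_competition_bistable"` flag.
#'
#' @param p A [coexist_params()] object with positive initial conditions.
#' @return Length-2 numeric vector of final populations (may contain
#'   `Inf` or `NA`), with flags (see [property_flags()]).
#' @examples
#' p <- coexist_params(1, 1, 100, 100, -0.5, -0.5, 10, 10)
#' final_value_coexist(p)  # c(66.67, 66.67)
#' @export
final_value_coexist <- function(p) {
  if (p$x01 <= 0 || p$x02 <= 0)
    stop("final values require positive initial conditions", call. = FALSE)
  prod <- p$alpha1 * p$alpha2
  if (prod == 1)
    stop("alpha1*alpha2 = 1: no real solution", call. = FALSE)
  extinct <- c(p$alpha1 <= -p$N1 / p$N2, p$alpha2 <= -p$N2 / p$N1)
  if (all(extinct))
    return(with_flags(c(NA_real_, NA_real_), "strong_competition_bistable"))
  if (any(extinct)) {
    j <- which(extinct)                       # loser
    i <- 3L - j                               # survivor, freed of coupling
    out <- numeric(2)
    out[j] <- 0
    out[i] <- if (i == 1L) p$N1 else p$N2
    return(with_flags(out, paste0("extinction_species", j)))
  }
  flags <- character(0)
  alphas <- c(p$alpha1, p$alpha2)
  Ns <- c(p$N1, p$N2)
  out <- numeric(2)
  for (j in 1:2) {
    i <- 3L - j
    if (alphas[j] > 0 && prod >= 1) {
      out[j] <- Inf
      flags <- union(flags, "unstable_overgrowth")
    } else {
      out[j] <- (Ns[j] + alphas[j] * Ns[i]) / (1 - prod)
    }
  }
  with_flags(out, flags)
}

#' Inflection points of the two-species coexistence model
#'
#' \deqn{x_{ip,j} = \frac{2 N_j + \alpha_j N_i}{4 - \alpha_1 \alpha_2}}
#' reported as stated by the closed form; undefined when
#' `alpha1*alpha2 = 4`.
#'
#' @param p A [coexist_params()] object with positive initial conditions.
#' @return Length-2 numeric vector of inflection populations.
#' @export
inflection_coexist <- function(p) {
  prod <- p$alpha1 * p$alpha2
  if (prod == 4)
    stop("alpha1*alpha2 = 4: inflection points undefined", call. = FALSE)
  c((2 * p$N1 + p$alpha1 * p$N2) / (4 - prod),
    (2 * p$N2 + p$alpha2 * p$N1) / (4 - prod))
}

#' Classify the ecological regime of a two-species coupling
#'
#' Maps the sign pattern of `(alpha1, alpha2)` to one of the six
#' ecological regimes — neutralism, commensalism, amensalism, mutualism,
#' competition, predation — across their nine coupling configurations,
#' and evaluates feasibility and stability:
#' \itemize{
#'   \item mutualism with `alpha1*alpha2 >= 1` is flagged unstable
#'     (unbounded overgrowth, the non-trivial equilibrium is never
#'     reached);
#'   \item any negatively coupled species `j` with
#'     `alpha_j <= -N_j/N_i` is driven extinct, so amensalism,
#'     competition and predation violating that bound are flagged
#'     infeasible (prey/inhibited-species extermination).
#' }
#'
#' @param p A [coexist_params()] object (only the signs of the couplings
#'   and the capacity ratio are used).
#' @return An object of class `"regime_label"`: a list with elements
#'   `regime`, `configuration`, `product`, `feasible`, `stable`, `flags`.
#' @examples
#' classify_regime(coexist_params(1, 1, 100, 200, 0.5, 0.5, 1, 1))
#' @export
classify_regime <- function(p) {
  a1 <- p$alpha1; a2 <- p$alpha2
  s <- function(a) sign(a)
  key <- paste(s(a1), s(a2))
  regime <- switch(key,
    "0 0"   = "neutralism",
    "0 1"   = "commensalism",
    "1 0"   = "commensalism",
    "0 -1"  = "amensalism",
    "-1 0"  = "amensalism",
    "1 1"   = "mutualism",
    "-1 -1" = "competition",
    "-1 1"  = "predation",
    "1 -1"  = "predation")
  configuration <- switch(key,
    "0 0"   = "no interaction",
    "0 1"   = "species 1 independent, species 2 benefits",
    "1 0"   = "species 2 independent, species 1 benefits",
    "0 -1"  = "species 1 independent, species 2 inhibited",
    "-1 0"  = "species 2 independent, species 1 inhibited",
    "1 1"   = "both species benefit",
    "-1 -1" = "both species inhibited",
    "-1 1"  = "species 1 prey, species 2 predator",
    "1 -1"  = "species 2 prey, species 1 predator")
  prod <- a1 * a2
  flags <- character(0)
  stable <- TRUE
  if (regime == "mutualism" && prod >= 1) {
    stable <- FALSE
    flags <- c(flags, "unstable_overgrowth")
  }
  feasible <- TRUE
  if (a1 < 0 && a1 < -p$N1 / p$N2) {
    feasible <- FALSE
    flags <- c(flags, if (regime == "predation")
      "prey_extermination" else "extinction_species1")
  }
  if (a2 < 0 && a2 < -p$N2 / p$N1) {
    feasible <- FALSE
    flags <- c(flags, if (regime == "predation")
      "prey_extermination" else "extinction_species2")
  }
  structure(list(regime = regime, configuration = configuration,
                 product = prod, feasible = feasible, stable = stable,
                 flags = flags),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s (%s)\n", x$regime, x$configuration))
  cat(sprintf("  alpha1*alpha2 = %g; feasible: %s; stable: %s\n",
              x$product, x$feasible, x$stable))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# ---- consolidated report --------------------------------------------------

#' Property report for a model parameter set
#'
#' Evaluates all closed-form dynamic properties of a parameter set and
#' assembles them into a list ready for JSON serialisation:
#' equilibria, final value(s), inflection point(s), transitory time,
#' time to inflection, regime classification (two-species case) and
#' qualitative flags.
#'
#' @param p A [single_params()], [coupled_params()] or
#'   [coexist_params()] object.
#' @param ... Further arguments: `v` (signal level) for the coupled
#'   model.
#' @return A list with elements `model`, `params`, `equilibria`,
#'   `final_value`, `inflection`, `t_star`, `t_ip`, `regime` (two-species
#'   only) and `flags`.
#' @examples
#' property_report(single_params(0.8, 780500, 6000))
#' @export
property_report <- function(p, ...) UseMethod("property_report")

#' @export
property_report.single_params <- function(p, ...) {
  list(model = "single",
       params = unclass(p),
       equilibria = as.list(equilibria_single(p)),
       final_value = final_value_single(p),
       inflection = inflection_single(p),
       t_star = if (p$x0 %in% c(0, p$N)) NA_real_ else
         transitory_time_single(p),
       t_ip = time_to_inflection_single(p),
       flags = character(0))
}

#' @export
property_report.coupled_params <- function(p, v, ...) {
  eq <- equilibria_coupled(p, v)
  fv <- final_value_coupled(p, v)
  ip <- inflection_coupled(p, v)
  ts <- transitory_time_coupled(p, v)
  ti <- time_to_inflection_coupled(p, v)
  flags <- unique(c(property_flags(eq), property_flags(fv),
                    property_flags(ip), property_flags(ts)))
  list(model = "coupled",
       params = c(unclass(p), list(v = v)),
       equilibria = list(trivial = eq[["trivial"]],
                         nontrivial = eq[["nontrivial"]]),
       final_value = as.numeric(fv),
       inflection = as.numeric(ip),
       t_star = as.numeric(ts),
       t_ip = as.numeric(ti),
       flags = flags)
}

#' @export
property_report.coexist_params <- function(p, ...) {
  reg <- classify_regime(p)
  prod <- p$alpha1 * p$alpha2
  if (prod == 1) {
    eq <- list(trivial = c(0, 0), nontrivial = c(NA_real_, NA_real_))
    fv <- c(NA_real_, NA_real_)
    flags <- "no_real_solution"
  } else {
    eq <- equilibria_coexist(p)
    fv <- final_value_coexist(p)
    flags <- property_flags(fv)
  }
  ip <- if (prod == 4) c(NA_real_, NA_real_) else inflection_coexist(p)
  list(model = "coexist",
       params = unclass(p),
       equilibria = eq,
       final_value = as.numeric(fv),
       inflection = as.numeric(ip),
       t_star = NA_real_,
       t_ip = NA_real_,
       regime = unclass(reg),
       flags = unique(c(flags, reg$flags)))
}
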
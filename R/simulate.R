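# Fixed-step RK4 integration of the growth models under piecewise
# scenarios: open-loop coupling schedules, piecewise-constant exogenous
# signals, and closed-loop regulation with the coupling recomputed at
# every step.  Fixed step => bit-reproducible trajectories.

#' Season of a simulation scenario
#'
#' A scenario is an ordered list of seasons.  Within a season the
#' exogenous signal is constant and the coupling is either zero
#' (`"decoupled"`), a fixed value (`"open_loop"`), or recomputed every
#' integration step by the regulation law (`"closed_loop"`).
#'
#' @param duration Season length in months (positive).
#' @param mode One of `"decoupled"`, `"open_loop"`, `"closed_loop"`.
#' @param alpha Coupling value applied in open-loop mode.
#' @param reference_fraction Desired population as a fraction of the
#'   controlled species' carrying capacity, in (0, 1); closed-loop mode
#'   only.
#' @param v_level Signal level during the season (coupled model only);
#'   falls back to the scenario-level `v_level`.
#' @return A list of class `"season"`.
#' @examples
#' season(6, "closed_loop", reference_fraction = 0.65)
#' @export
season <- function(duration, mode = c("decoupled", "open_loop", "closed_loop"),
                   alpha = NULL, reference_fraction = NULL, v_level = NULL) {
  mode <- match.arg(mode)
  check_scalar(duration, "duration", min = 0, strict = TRUE)
  if (mode == "open_loop" && is.null(alpha))
    stop("open_loop season needs an 'alpha'", call. = FALSE)
  if (mode == "closed_loop") {
    if (is.null(reference_fraction))
      stop("closed_loop season needs a 'reference_fraction'", call. = FALSE)
    check_scalar(reference_fraction, "reference_fraction")
    if (reference_fraction <= 0 || reference_fraction >= 1)
      stop("reference_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(duration = duration, mode = mode, alpha = alpha,
                 reference_fraction = reference_fraction,
                 v_level = v_level),
            class = "season")
}

#' Simulation scenario
#'
#' Bundles a model family, its parameter set, an ordered season list,
#' the solver step and the control settings into a runnable scenario.
#'
#' @param model `"single"`, `"coupled"` or `"coexist"`.
#' @param params The matching parameter object ([single_params()],
#'   [coupled_params()] or [coexist_params()]).
#' @param seasons A list of [season()] objects; their durations define
#'   the total horizon.
#' @param step Solver step in months (default 0.01).
#' @param v_level Default signal level for coupled-model seasons that do
#'   not set their own.
#' @param control List of control settings for closed-loop seasons:
#'   `K` (gain, default 1), `alpha_min`, `alpha_max`, `x_floor`; see
#'   [control_spec()].  The per-season reference supplies `x_d`.
#' @param controlled_species For the coexistence model, which species
#'   the closed-loop seasons regulate (default 1).
#' @param name Optional scenario name (used in logs and CSV output).
#' @return A list of class `"scenario"` with a computed `horizon`.
#' @examples
#' sc <- scenario("single", single_params(0.8, 780500, 6000),
#'                list(season(12, "decoupled")))
#' @export
scenario <- function(model = c("single", "coupled", "coexist"), params,
                     seasons, step = 0.01, v_level = NULL,
                     control = list(), controlled_species = 1L,
                     name = NULL) {
  model <- match.arg(model)
  expected <- switch(model, single = "single_params",
                     coupled = "coupled_params", coexist = "coexist_params")
  if (!inherits(params, expected))
    stop(sprintf("'params' must be a %s object for model '%s'",
                 expected, model), call. = FALSE)
  if (!length(seasons) || !all(vapply(seasons, inherits, TRUE, "season")))
    stop("'seasons' must be a non-empty list of season() objects",
         call. = FALSE)
  check_scalar(step, "step", min = 0, strict = TRUE)
  ctrl_defaults <- list(K = 1, alpha_min = NULL, alpha_max = 0, x_floor = 1)
  control <- utils::modifyList(ctrl_defaults, control)
  if (model == "coupled") {
    for (s in seasons)
      if (s$mode != "decoupled" && is.null(s$v_level) && is.null(v_level))
        stop("coupled seasons need a v_level (season- or scenario-level)",
             call. = FALSE)
  }
  structure(list(model = model, params = params, seasons = seasons,
                 step = step, v_level = v_level, control = control,
                 controlled_species = as.integer(controlled_species),
                 horizon = sum(vapply(seasons, `[[`, 0, "duration")),
                 name = name %||% model),
            class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixed-step 4th-order Runge-Kutta integrator with per-step control
#'
#' Integrates `deriv` from `state0` over `[0, horizon]` with a constant
#' step.  A callback is evaluated at the start of every step to refresh
#' the control inputs (coupling, signal, reference), which is how the
#' closed-loop laws are discretised.  After each step the state is
#' floored at zero, and any component that falls below `extinct_tol`
#' is clamped to exactly 0 (extinction is absorbing).  Non-finite or
#' explosively growing states abort the run with an error of class
#' `"growthreg_unstable"` (unstable overgrowth).
#'
#' @param deriv `function(state, ctrl)` returning the state derivative;
#'   `ctrl` is whatever the callback returned for the current step.
#' @param state0 Numeric initial state (length 1 or 2).
#' @param horizon Total time in months.
#' @param step Step size in months.
#' @param callback `function(t, state, prev_ctrl)` returning a list with
#'   elements `alpha`, `v`, `reference` (any may be `NA`), or `NULL` for
#'   autonomous models.
#' @param extinct_tol Absorbing-zero threshold per state component
#'   (same length as `state0`, or scalar).
#' @param blowup Abort threshold: any state component exceeding it is
#'   treated as unstable overgrowth.
#' @return A list with `t` (time grid), `states` (matrix, one row per
#'   grid point), `alpha` and `reference` (vectors of the control inputs
#'   in effect during the step starting at each grid point).
#' @export
rk4_integrate <- function(deriv, state0, horizon, step, callback = NULL,
                          extinct_tol = 0, blowup = 1e15) {
  stopifnot(step > 0, horizon >= step)
  n <- round(horizon / step)
  t <- seq(0, by = step, length.out = n + 1)
  d <- length(state0)
  extinct_tol <- rep_len(extinct_tol, d)
  states <- matrix(NA_real_, n + 1, d)
  alpha <- numeric(n + 1)
  reference <- numeric(n + 1)
  state <- as.numeric(state0)
  states[1, ] <- state
  ctrl <- NULL
  for (i in seq_len(n)) {
    ti <- t[i]
    if (!is.null(callback)) ctrl <- callback(ti, state, ctrl)
    alpha[i] <- ctrl$alpha %||% NA_real_
    reference[i] <- ctrl$reference %||% NA_real_
    h <- step
    k1 <- deriv(state, ctrl)
    k2 <- deriv(state + h / 2 * k1, ctrl)
    k3 <- deriv(state + h / 2 * k2, ctrl)
    k4 <- deriv(state + h * k3, ctrl)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state)) || any(state > blowup))
      stop(structure(class = c("growthreg_unstable", "error", "condition"),
                     list(message = sprintf(
                       "unstable overgrowth: state non-finite or above %g at t = %g",
                       blowup, ti + h), call = NULL)))
    state[state < 0] <- 0
    state[state < extinct_tol] <- 0
    states[i + 1, ] <- state
  }
  alpha[n + 1] <- alpha[n]
  reference[n + 1] <- reference[n]
  list(t = t, states = states, alpha = alpha, reference = reference)
}

# per-season control callback factory for a scenario
season_callback <- function(sc, sn) {
  p <- sc$params
  ctl <- sc$control
  switch(sc$model,
    single = NULL,
    coupled = {
      v <- sn$v_level %||% sc$v_level %||% 0
      switch(sn$mode,
        decoupled = function(t, state, prev)
          list(alpha = 0, v = v, reference = NA_real_),
        open_loop = function(t, state, prev)
          list(alpha = sn$alpha, v = v, reference = NA_real_),
        closed_loop = {
          spec <- control_spec(x_d = sn$reference_fraction * p$N,
                               K = ctl$K, alpha_min = ctl$alpha_min,
                               alpha_max = ctl$alpha_max,
                               x_floor = ctl$x_floor)
          function(t, state, prev)
            list(alpha = control_alpha_coupled(p, spec, state[1], v),
                 v = v, reference = spec$x_d)
        })
    },
    coexist = {
      j <- sc$controlled_species
      Nj <- if (j == 1L) p$N1 else p$N2
      switch(sn$mode,
        decoupled = function(t, state, prev)
          list(alpha = 0, v = NA_real_, reference = NA_real_),
        open_loop = function(t, state, prev)
          list(alpha = sn$alpha, v = NA_real_, reference = NA_real_),
        closed_loop = {
          spec <- control_spec(x_d = sn$reference_fraction * Nj,
                               K = ctl$K, alpha_min = ctl$alpha_min,
                               alpha_max = ctl$alpha_max,
                               x_floor = ctl$x_floor)
          function(t, state, prev) {
            prev_alpha <- (prev$alpha %||% 0)
            if (is.na(prev_alpha)) prev_alpha <- 0
            a <- control_alpha_coexist(p, spec, j, state[j], state[3L - j],
                                       alpha_prev = prev_alpha)
            list(alpha = a, v = NA_real_, reference = spec$x_d)
          }
        })
    })
}

season_deriv <- function(sc) {
  p <- sc$params
  switch(sc$model,
    single = function(state, ctrl) rhs_single(p, state),
    coupled = function(state, ctrl)
      rhs_coupled(p, state, ctrl$v, alpha = ctrl$alpha),
    coexist = {
      j <- sc$controlled_species
      if (j == 1L)
        function(state, ctrl)
          rhs_coexist(p, state[1], state[2], alpha1 = ctrl$alpha)
      else
        function(state, ctrl) {
          a2 <- ctrl$alpha
          c(p$r1 * state[1] * (1 - state[1] / p$N1 +
                                 p$alpha1 * state[2] / p$N1),
            p$r2 * state[2] * (1 - state[2] / p$N2 + a2 * state[1] / p$N2))
        }
    })
}

#' Run a simulation scenario
#'
#' Integrates the scenario season by season with the fixed-step RK4
#' solver, carrying the state across season boundaries (the state is
#' continuous; the coupling, signal and reference may jump).  Each step
#' records the coupling actually applied and the active reference.
#'
#' @param sc A [scenario()] object.
#' @return A `data.frame` of class `"growthreg_trajectory"` with columns
#'   `t`, `x1` (and `x2` for the coexistence model), `alpha_applied`,
#'   `reference`, `season_index`.  The scenario is attached as attribute
#'   `"scenario"`.
#' @examples
#' sc <- scenario("single", single_params(0.8, 780500, 6000),
#'                list(season(12, "decoupled")))
#' tail(run_scenario(sc), 1)
#' @export
run_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  p <- sc$params
  state <- switch(sc$model,
                  single = p$x0,
                  coupled = p$x0,
                  coexist = c(p$x01, p$x02))
  caps <- switch(sc$model, single = p$N, coupled = p$N,
                 coexist = c(p$N1, p$N2))
  deriv <- season_deriv(sc)
  pieces <- vector("list", length(sc$seasons))
  t_off <- 0
  for (k in seq_along(sc$seasons)) {
    sn <- sc$seasons[[k]]
    cb <- season_callback(sc, sn)
    seg <- rk4_integrate(deriv, state, sn$duration, sc$step,
                         callback = cb, extinct_tol = 1e-9 * caps)
    state <- seg$states[nrow(seg$states), ]
    df <- data.frame(t = t_off + seg$t)
    if (ncol(seg$states) == 1L) df$x1 <- seg$states[, 1]
    else { df$x1 <- seg$states[, 1]; df$x2 <- seg$states[, 2] }
    df$alpha_applied <- seg$alpha
    df$reference <- seg$reference
    df$season_index <- k
    # drop the duplicated boundary point of every season after the first
    if (k > 1L) df <- df[-1L, ]
    pieces[[k]] <- df
    t_off <- t_off + sn$duration
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "scenario") <- sc
  class(out) <- c("growthreg_trajectory", "data.frame")
  out
}

#' Write a trajectory to CSV
#'
#' Plain CSV with a header row and full floating-point precision
#' (15 significant digits), so identical scenarios produce byte-identical
#' files.
#'
#' @param traj A trajectory returned by [run_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) {
    out <- trimws(formatC(col, digits = 15, format = "g"))
    out[is.na(col)] <- ""
    out
  })
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
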
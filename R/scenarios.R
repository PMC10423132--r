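# Built-in fishery scenarios: a fish population (r = 0.8 /month,
# N = 780500) growing freely, harvested by fishermen modelled as an
# exogenous signal, and finally coexisting with a logistically growing
# fishermen population (amensalism).  Parameter values are the fixture
# constants used throughout the tests and the CLI.

#' Built-in scenario: uncoupled fish population
#'
#' Single-species logistic growth of the fish population
#' (r = 0.8 /month, N = 780500 fish) over 12 months with no harvesting.
#' The documented initial conditions of this study are 800, 1000 and
#' 6000 fish; `x0` selects one of them (or any other positive start).
#'
#' @param x0 Initial population (default 6000 fish).
#' @param step Solver step in months.
#' @return A [scenario()] object.
#' @examples
#' tail(run_scenario(fixture_single()), 1)
#' @export
fixture_single <- function(x0 = 6000, step = 0.01) {
  scenario("single", single_params(r = 0.8, N = 780500, x0 = x0),
           list(season(12, "decoupled")), step = step,
           name = "single_fish")
}

#' Built-in scenario: fish population harvested by fishermen
#'
#' The fish population coupled to a fishermen head-count `v` as an
#' exogenous signal (r = 0.8, N = 780500, x0 = 10000).  The nominal
#' maximum harvest capacity per fisherman that avoids extinction is
#' `alpha0 = -N/1000`, computed for the nominal crew of 1000; the
#' scenario can then be run with larger crews (`v_level` of 2000 or
#' 3000) to study overharvesting.
#'
#' Modes:
#' \describe{
#'   \item{`"closed_loop"`}{12 months of free growth, then alternating
#'     6-month fishing / growing seasons to 60 months with the
#'     regulation law holding the population at 65% of `N` while
#'     fishing and 90% of `N` while growing.}
#'   \item{`"open_loop"`}{12 months of free growth, then the coupling
#'     held at `alpha0` for the remaining 48 months — the
#'     maximum-capacity harvesting study, which extinguishes the stock
#'     for `v_level` of 2000 or 3000 but not for 1000.}
#'   \item{`"open_loop_seasonal"`}{12 months free, then `alpha0` during
#'     fishing seasons and no coupling during growing seasons.}
#' }
#'
#' @param v_level Number of fishermen (default 1000).
#' @param mode See above.
#' @param K Control gain for closed-loop seasons.
#' @param alpha0_v Crew size used to compute the nominal capacity
#'   `alpha0 = -N/alpha0_v` (default 1000).
#' @param step Solver step in months.
#' @return A [scenario()] object.
#' @examples
#' sc <- fixture_coupled(v_level = 1000, mode = "open_loop")
#' tail(run_scenario(sc), 1)
#' @export
fixture_coupled <- function(v_level = 1000,
                            mode = c("closed_loop", "open_loop",
                                     "open_loop_seasonal"),
                            K = 1, alpha0_v = 1000, step = 0.01) {
  mode <- match.arg(mode)
  N <- 780500
  alpha0 <- -N / alpha0_v
  p <- coupled_params(r = 0.8, N = N, alpha = alpha0, x0 = 10000)
  seasons <- switch(mode,
    closed_loop = c(list(season(12, "decoupled")),
                    rep(list(
                      season(6, "closed_loop", reference_fraction = 0.65),
                      season(6, "closed_loop", reference_fraction = 0.90)),
                      4)),
    open_loop = list(season(12, "decoupled"),
                     season(48, "open_loop", alpha = alpha0)),
    open_loop_seasonal = c(list(season(12, "decoupled")),
                           rep(list(
                             season(6, "open_loop", alpha = alpha0),
                             season(6, "decoupled")),
                             4)))
  scenario("coupled", p, seasons, step = step, v_level = v_level,
           control = list(K = K),
           name = paste0("coupled_fish_", mode))
}

#' Built-in scenario: fish and fishermen in amensal coexistence
#'
#' The fishermen are now a logistic population of their own
#' (N2 = 5000, x02 = 500) growing independently of the fish
#' (`alpha2 = 0`, amensalism), while the fish (r1 = 0.8, N1 = 780500,
#' x01 = 10000) are inhibited through the manipulated coupling
#' `alpha1`.  The fishermen's growth rate is calibrated so they reach
#' 99% of their capacity in 60 months (transitory-time inversion, ~0.1132
#' /month); `use_printed_r2 = TRUE` substitutes the alternative tabled
#' value 0.1166 instead.  After 12 months of free growth the regulation
#' law alternates 6-month fishing seasons (reference 45% of N1) and
#' growing seasons (reference 65% of N1) up to 60 months.
#'
#' @param K Control gain.
#' @param use_printed_r2 Use the tabled fishermen growth rate 0.1166
#'   instead of the transitory-time-derived default.
#' @param step Solver step in months.
#' @return A [scenario()] object.
#' @export
fixture_coexist <- function(K = 1, use_printed_r2 = FALSE, step = 0.01) {
  r2 <- if (use_printed_r2) 0.1166
        else rate_from_time(N = 5000, x0 = 500, target_time = 60,
                            which = "transitory")
  p <- coexist_params(r1 = 0.8, r2 = r2, N1 = 780500, N2 = 5000,
                      alpha1 = -780500 / 5000, alpha2 = 0,
                      x01 = 10000, x02 = 500)
  seasons <- c(list(season(12, "decoupled")),
               rep(list(
                 season(6, "closed_loop", reference_fraction = 0.45),
                 season(6, "closed_loop", reference_fraction = 0.65)),
                 4))
  scenario("coexist", p, seasons, step = step, control = list(K = K),
           controlled_species = 1L, name = "coexist_amensalism")
}

#' List the built-in scenarios
#'
#' @return A `data.frame` with one row per fixture: name, model family
#'   and a short description.
#' @export
list_fixtures <- function() {
  data.frame(
    name = c("single", "coupled", "coexist"),
    model = c("single", "coupled", "coexist"),
    description = c(
      "Fish population growing freely for 12 months (r = 0.8, N = 780500)",
      "Fish harvested by v fishermen; open-loop max capacity or closed-loop regulation between 65% and 90% of N over 60 months",
      "Fish and logistically growing fishermen (amensalism); fish regulated between 45% and 65% of N1 over 60 months"),
    stringsAsFactors = FALSE)
}

get_fixture <- function(name, v_level = 1000, mode = NULL, K = 1,
                        step = 0.01) {
  switch(name,
    single = fixture_single(step = step),
    coupled = fixture_coupled(v_level = v_level,
                              mode = mode %||% "closed_loop",
                              K = K, step = step),
    coexist = fixture_coexist(K = K, step = step),
    stop(sprintf("unknown fixture '%s'; see list_fixtures()", name),
         call. = FALSE))
}

# ---- YAML scenario configs ------------------------------------------------

#' Read a scenario from a YAML config file
#'
#' The config schema mirrors [scenario()]: keys `name`, `model`
#' (single | coupled | coexist), `params` (the fields of the matching
#' parameter constructor; months and individuals), `step` (months),
#' `v_level`, `control` (`K`, `alpha_min`, `alpha_max`, `x_floor`),
#' `controlled_species`, and a `seasons` list whose entries carry
#' `duration` (months), `mode`, and `alpha` / `reference_fraction` /
#' `v_level` as the mode requires.  The shipped fixture configs under
#' `system.file("fixtures", package = "growthreg")` follow this schema.
#'
#' @param path Path to the YAML file.
#' @return A [scenario()] object.
#' @examples
#' cfg <- system.file("fixtures", "single_fish.yaml", package = "growthreg")
#' read_scenario_config(cfg)
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("model", "params", "seasons"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config is missing required key '%s'", key),
           call. = FALSE)
  params <- switch(cfg$model,
    single = do.call(single_params, cfg$params),
    coupled = do.call(coupled_params, cfg$params),
    coexist = do.call(coexist_params, cfg$params),
    stop(sprintf("unknown model '%s'", cfg$model), call. = FALSE))
  seasons <- lapply(cfg$seasons, function(s) do.call(season, s))
  scenario(cfg$model, params, seasons,
           step = cfg$step %||% 0.01,
           v_level = cfg$v_level,
           control = cfg$control %||% list(),
           controlled_species = cfg$controlled_species %||% 1L,
           name = cfg$name)
}
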
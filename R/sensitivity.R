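#' Monte-Carlo sensitivity specification
#'
#' The protocol varies the designated parameters independently and uniformly
#' within +/- `half_width` (default 20 percent) of their base values, re-runs
#' the full model `n_runs` times (default 1000) and reports the mean with a
#' central 95 percent interval. The designated parameters are the proportion
#' of families with an FDW and the two surveyed primary-caregiver hours
#' blocks (without services/FDW; with services, no FDW), each severity cell
#' drawn independently.
#'
#' @param parameters character subset of `"fdw_proportion"`,
#'   `"hours_no_services"`, `"hours_services"`.
#' @param half_width half-width of the uniform band as a fraction of the
#'   base value (in (0, 1); 0 allowed as the degenerate no-variation case).
#' @param n_runs number of model runs.
#' @param seed integer master seed; each run uses a substream keyed by its
#'   run index, so results do not depend on execution order.
#' @param interval_level central interval coverage (default 0.95).
#' @return a named list (class `sensitivity_spec`).
#' @export
sensitivity_spec <- function(parameters = c("fdw_proportion",
                                            "hours_no_services",
                                            "hours_services"),
                             half_width = 0.20, n_runs = 1000, seed = 1,
                             interval_level = 0.95) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (half_width < 0 || half_width >= 1)
    stop("sensitivity_spec: half_width must lie in [0, 1)")
  if (n_runs < 1) stop("sensitivity_spec: n_runs must be at least 1")
  structure(list(parameters = parameters, half_width = half_width,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 interval_level = interval_level),
            class = "sensitivity_spec")
}

run_substream_seed <- function(seed, run_index) {
  # cheap integer hash keeping the derived seed inside 32-bit range
  as.integer((as.numeric(seed) * 48271 + as.numeric(run_index) * 69621) %%
               2147483647)
}

#' Draw one parameter-override set
#'
#' Each designated parameter is drawn independently from
#' `Uniform(base * (1 - half_width), base * (1 + half_width))`; the draw is
#' reproducible from `(spec$seed, run_index)` alone.
#'
#' @param spec a [sensitivity_spec()].
#' @param run_index 1-based run index (`<= spec$n_runs`).
#' @param config the base configuration supplying the central values.
#' @return named list of overrides understood by [run_scenario()]:
#'   `fdw_proportion_factor` (a multiplier, so ramped FDW levers scale with
#'   the drawn proportion), `hours_no_services`, `hours_services` (absolute
#'   hours), plus `fdw_proportion` (the drawn base-proportion value, for
#'   logging).
#' @export
draw_parameter_set <- function(spec, run_index,
                               config = make_fixture_config()) {
  if (run_index < 1 || run_index > spec$n_runs)
    stop("draw_parameter_set: run_index out of range")
  set.seed(run_substream_seed(spec$seed, run_index))
  hw <- spec$half_width
  u <- function(base) runif(length(base), base * (1 - hw), base * (1 + hw))
  out <- list()
  if ("fdw_proportion" %in% spec$parameters) {
    base <- config$care$fdw_proportion
    drawn <- u(base)
    out$fdw_proportion <- drawn
    out$fdw_proportion_factor <- drawn / base
  }
  if ("hours_no_services" %in% spec$parameters)
    out$hours_no_services <- u(config$care$hours_no_services)
  if ("hours_services" %in% spec$parameters)
    out$hours_services <- u(config$care$hours_services)
  out
}

#' Monte-Carlo sensitivity analysis over the policy scenarios
#'
#' Runs the scenario set under `spec$n_runs` independent parameter draws and
#' summarizes each (scenario, metric, year) with its mean and central
#' interval bounds (2.5th / 97.5th percentile across runs at the default
#' level).
#'
#' @param spec a [sensitivity_spec()].
#' @param scenarios character vector of scenario names.
#' @param config base configuration.
#' @param years report years (default 2020 and 2030).
#' @param metrics outcome columns to summarize.
#' @return data frame (class `sensitivity_result`) with columns `scenario`,
#'   `metric`, `year`, `mean`, `lower`, `upper`.
#' @export
run_sensitivity <- function(spec = sensitivity_spec(),
                            scenarios = c("no_ltc", "current"),
                            config = make_fixture_config(),
                            years = c(2020, 2030),
                            metrics = c("caregivers_in_market",
                                        "increase_in_caregivers_working",
                                        "new_paid_labor",
                                        "percent_dropping_out",
                                        "labor_requirement_ratio")) {
  sc <- config$scenario
  demo <- make_demography(config$synthetic_demography)
  rates <- demo$rates
  rates$fertility_rate <- config$demography$fertility_rate
  pyramids <- project_population(demo$pyramid, rates,
                                 sc$start_year, sc$end_year)
  draws <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    ov <- draw_parameter_set(spec, r, config)
    runs <- run_scenarios(scenarios, config, pyramids = pyramids,
                          overrides = ov)
    draws[[r]] <- do.call(rbind, lapply(names(runs), function(nm) {
      oc <- runs[[nm]][runs[[nm]]$year %in% years, , drop = FALSE]
      data.frame(run = r, scenario = nm, year = oc$year,
                 oc[, metrics, drop = FALSE], row.names = NULL)
    }))
  }
  long <- do.call(rbind, draws)
  alpha <- (1 - spec$interval_level) / 2
  rows <- list()
  for (nm in unique(long$scenario)) {
    for (met in metrics) {
      for (y in years) {
        v <- long[[met]][long$scenario == nm & long$year == y]
        v <- v[!is.na(v)]   # comparison metrics are undefined for no_ltc
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = nm, metric = met, year = y,
          mean = if (length(v)) mean(v) else NA_real_,
          lower = if (length(v)) quantile(v, alpha, names = FALSE)
                  else NA_real_,
          upper = if (length(v)) quantile(v, 1 - alpha, names = FALSE)
                  else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' One-at-a-time (tornado) sensitivity
#'
#' Evaluates each designated parameter alone at the low and high edge of its
#' +/- `half_width` band, holding everything else at base values — the
#' standard tornado-diagram companion to the joint Monte-Carlo protocol.
#'
#' @inheritParams run_sensitivity
#' @param scenario single scenario name.
#' @param metric single outcome column.
#' @param year report year.
#' @return data frame with columns `parameter`, `edge`, `value`.
#' @export
run_sensitivity_oat <- function(spec = sensitivity_spec(),
                                scenario = "current",
                                config = make_fixture_config(),
                                metric = "percent_dropping_out",
                                year = 2030) {
  edges <- c(low = 1 - spec$half_width, high = 1 + spec$half_width)
  rows <- list()
  for (par in spec$parameters) {
    for (e in names(edges)) {
      ov <- switch(par,
        fdw_proportion = list(fdw_proportion_factor = edges[[e]]),
        hours_no_services = list(
          hours_no_services = config$care$hours_no_services * edges[[e]]),
        hours_services = list(
          hours_services = config$care$hours_services * edges[[e]]))
      oc <- run_scenario(scenario, config, overrides = ov)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, edge = e, value = oc[[metric]][oc$year == year])
    }
  }
  do.call(rbind, rows)
}
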
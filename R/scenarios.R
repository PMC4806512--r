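#' Piecewise-linear time ramp
#'
#' Policy levers are described by their values at a few calendar years;
#' between knots the lever moves linearly, outside the knot range it is held
#' at the nearest knot value.
#'
#' @param years knot years (strictly increasing).
#' @param values lever values at the knots (finite).
#' @return an object of class `ramp`.
#' @export
ramp <- function(years, values) {
  if (length(years) != length(values) || length(years) < 1)
    stop("ramp: years and values must have equal positive length")
  if (any(diff(years) <= 0))
    stop("ramp: knot years must be strictly increasing")
  if (!all(is.finite(values)))
    stop("ramp: knot values must be finite")
  structure(list(years = as.numeric(years), values = as.numeric(values)),
            class = "ramp")
}

#' Evaluate a ramp at a calendar year
#'
#' @param r a [ramp()].
#' @param year calendar year (vectorized).
#' @return interpolated lever value(s); constant beyond the first/last knot.
#' @export
eval_ramp <- function(r, year) {
  if (length(r$years) == 1) return(rep(r$values, length(year)))
  approx(r$years, r$values, xout = year, rule = 2)$y
}

#' Build one of the six policy scenarios
#'
#' * `no_ltc` — counterfactual with all formal services absent; the care
#'   burden falls entirely on the family.
#' * `current` — beds ramp along the published plan (9,750 in 2012 to
#'   22,400 in 2030 through 14,900 in 2020); HCBS uptake 0.20 (2013) to
#'   0.30 (2030); FDW proportion 0.49 (2013) to 0.60 (2030).
#' * `pro_hcbs` — as `current` but uptake rises to 0.80 by 2030.
#' * `pro_fdw` — as `current` but FDW proportion rises to 0.80 by 2030.
#' * `pro_nh` — from the policy start, capacity covers all high-severity
#'   (>=5 ADL) elderly (held over the simulation); uptake and FDW as
#'   `current`.
#' * `all_in` — the three enhanced levers simultaneously.
#'
#' @param name one of `"no_ltc"`, `"current"`, `"pro_hcbs"`, `"pro_fdw"`,
#'   `"pro_nh"`, `"all_in"`.
#' @param config an `ltc_config`; supplies the bed knots, the policy start
#'   year and the optional `bed_start_override` (an alternative opening bed
#'   count placed at the policy start year).
#' @return an object of class `scenario_spec` with elements `name`,
#'   `nh_beds` (a [ramp()] or the string `"all_high_severity_in_nh"`),
#'   `hcbs_uptake` and `fdw_proportion` (ramps).
#' @export
build_scenario <- function(name, config = make_fixture_config()) {
  names_ok <- c("no_ltc", "current", "pro_hcbs", "pro_fdw", "pro_nh", "all_in")
  if (!name %in% names_ok)
    stop("build_scenario: unknown scenario '", name, "'; expected one of ",
         paste(names_ok, collapse = ", "))
  sc <- config$scenario
  ps <- sc$policy_start
  knots <- sc$nh_bed_knots
  beds_ramp <- if (!is.null(sc$bed_start_override)) {
    ramp(c(ps, max(knots$years)),
         c(sc$bed_start_override, knots$beds[length(knots$beds)]))
  } else {
    ramp(knots$years, knots$beds)
  }
  uptake_cur <- ramp(c(ps, 2030), c(0.20, 0.30))
  uptake_hi <- ramp(c(ps, 2030), c(0.20, 0.80))
  fdw_cur <- ramp(c(ps, 2030), c(0.49, 0.60))
  fdw_hi <- ramp(c(ps, 2030), c(0.49, 0.80))
  spec <- switch(name,
    no_ltc = list(nh_beds = ramp(ps, 0), hcbs_uptake = ramp(ps, 0),
                  fdw_proportion = ramp(ps, 0)),
    current = list(nh_beds = beds_ramp, hcbs_uptake = uptake_cur,
                   fdw_proportion = fdw_cur),
    pro_hcbs = list(nh_beds = beds_ramp, hcbs_uptake = uptake_hi,
                    fdw_proportion = fdw_cur),
    pro_fdw = list(nh_beds = beds_ramp, hcbs_uptake = uptake_cur,
                   fdw_proportion = fdw_hi),
    pro_nh = list(nh_beds = "all_high_severity_in_nh",
                  hcbs_uptake = uptake_cur, fdw_proportion = fdw_cur),
    all_in = list(nh_beds = "all_high_severity_in_nh",
                  hcbs_uptake = uptake_hi, fdw_proportion = fdw_hi))
  structure(c(list(name = name), spec, list(pre_policy_beds = beds_ramp)),
            class = "scenario_spec")
}

scenario_beds <- function(spec, year, stocks, policy_start) {
  if (identical(spec$nh_beds, "all_high_severity_in_nh")) {
    if (year >= policy_start) return(list(beds = unname(stocks[["high"]]),
                                          bypass_delay = TRUE))
    return(list(beds = eval_ramp(spec$pre_policy_beds, year),
                bypass_delay = FALSE))
  }
  list(beds = eval_ramp(spec$nh_beds, year), bypass_delay = FALSE)
}

#' Run a policy scenario through the full model
#'
#' Pipeline per simulated year: project the population, advance the
#' ADL-disability stocks, update nursing-home occupancy toward its
#' bed-limited target, partition home-dwelling disabled elderly across the
#' home-care arrangements, convert primary caregiver hours to expected
#' labor-market withdrawal, and count the paid LTC workforce. Comparison
#' columns (increase in caregivers working, new paid labor, the
#' labor-requirement ratio) are measured against the no-LTC counterfactual
#' run on identical inputs.
#'
#' @param spec a `scenario_spec` from [build_scenario()], or a scenario
#'   name.
#' @param config an `ltc_config` (default [make_fixture_config()]).
#' @param pyramids optional precomputed population trajectory (list of
#'   [age_pyramid()] named by year), e.g. to share across sensitivity runs.
#' @param overrides optional named list of parameter overrides from
#'   [draw_parameter_set()]: `fdw_proportion_factor`, `hours_no_services`,
#'   `hours_services`.
#' @param comparator optional precomputed no-LTC outcome data frame on the
#'   same inputs; computed internally when omitted.
#' @param keep_caremix logical; attach the yearly care-mix matrices and
#'   disability stocks as attributes `"caremix"` and `"stocks"` (lists named
#'   by year) for diagnostics.
#' @return a `policy_outcome` data frame with one row per year and columns
#'   `scenario, year, dyads, employable, dropouts, caregivers_in_market,
#'   percent_dropping_out, paid_labor, nh_occupancy,
#'   increase_in_caregivers_working, new_paid_labor,
#'   labor_requirement_ratio` (comparison columns are `NA` for the
#'   counterfactual itself, as in the published table's dashes).
#' @export
run_scenario <- function(spec, config = make_fixture_config(),
                         pyramids = NULL, overrides = NULL,
                         comparator = NULL, keep_caremix = FALSE) {
  if (is.character(spec)) spec <- build_scenario(spec, config)
  sc <- config$scenario
  years <- sc$start_year:sc$end_year
  if (is.null(pyramids)) {
    demo <- make_demography(config$synthetic_demography)
    rates <- demo$rates
    rates$fertility_rate <- config$demography$fertility_rate
    rates$sex_ratio_at_birth <- config$demography$sex_ratio_at_birth
    pyramids <- project_population(demo$pyramid, rates,
                                   sc$start_year, sc$end_year)
  }
  dis_par <- config_disability_params(config)
  care_par <- config_care_params(config)
  curve <- config_dropout_curve(config)
  ratios <- config_staff_ratios(config)
  ef <- config$labor$employable_fraction
  if (!is.null(overrides)) {
    if (!is.null(overrides$hours_no_services))
      care_par$hours_no_services[] <- overrides$hours_no_services
    if (!is.null(overrides$hours_services))
      care_par$hours_services[] <- overrides$hours_services
  }
  fdw_factor <- if (is.null(overrides$fdw_proportion_factor)) 1
                else overrides$fdw_proportion_factor

  # initialization: community prevalence plus residents already in homes
  bed0 <- scenario_beds(spec, sc$start_year,
                        disability_stocks(0, 0, Inf), sc$policy_start)
  p0 <- pyramids[[1]]
  comm0 <- initialize_disability_stocks(p0, dis_par, nh_residents = 0)
  occ0_total <- if (!is.na(care_par$initial_occupancy))
    care_par$initial_occupancy
  else min(bed0$beds, unname(comm0[["high"]]))
  stocks <- initialize_disability_stocks(p0, dis_par,
                                         nh_residents = occ0_total)
  occupancy <- c(low = 0, medium = 0, high = occ0_total)

  rows <- vector("list", length(years))
  mixes <- if (keep_caremix) vector("list", length(years))
  stock_trace <- if (keep_caremix) vector("list", length(years))
  for (i in seq_along(years)) {
    yr <- years[i]
    pyr <- pyramids[[i]]
    bd <- scenario_beds(spec, yr, stocks, sc$policy_start)
    occupancy <- if (bd$bypass_delay) {
      nursing_home_target(stocks, bd$beds)
    } else {
      update_nursing_home(occupancy, stocks, bd$beds,
                          adj_time = care_par$capacity_adjustment_time)
    }
    home <- pmax(as.numeric(stocks) - occupancy[severity_levels], 0)
    home <- disability_stocks(home[1], home[2], home[3], year = yr)
    u <- eval_ramp(spec$hcbs_uptake, yr)
    p <- min(max(eval_ramp(spec$fdw_proportion, yr) * fdw_factor, 0), 1)
    mix <- partition_home_care(home, u, p, nh_occupancy = occupancy,
                               year = yr)
    dyads <- sum(stocks)
    employable <- ef * dyads
    dropouts <- count_dropouts(mix, care_par, ef, curve)
    rows[[i]] <- data.frame(
      scenario = spec$name, year = yr, dyads = dyads,
      employable = employable, dropouts = dropouts,
      caregivers_in_market = employable - dropouts,
      percent_dropping_out = if (dyads > 0) 100 * dropouts / dyads else 0,
      paid_labor = paid_labor_required(mix, ratios),
      nh_occupancy = sum(occupancy))
    if (keep_caremix) {
      mixes[[i]] <- mix
      stock_trace[[i]] <- stocks
    }
    stocks <- step_disability(stocks, pyr, dis_par,
                              nh_residents = sum(occupancy))
  }
  out <- do.call(rbind, rows)
  if (keep_caremix) {
    names(mixes) <- years
    names(stock_trace) <- years
    attr(out, "caremix") <- mixes
    attr(out, "stocks") <- stock_trace
  }

  if (spec$name == "no_ltc") {
    out$increase_in_caregivers_working <- NA_real_
    out$new_paid_labor <- NA_real_
    out$labor_requirement_ratio <- NA_real_
  } else {
    if (is.null(comparator))
      comparator <- run_scenario(build_scenario("no_ltc", config), config,
                                 pyramids = pyramids, overrides = overrides)
    out$increase_in_caregivers_working <-
      out$caregivers_in_market - comparator$caregivers_in_market
    out$new_paid_labor <- out$paid_labor
    out$labor_requirement_ratio <- ifelse(
      out$increase_in_caregivers_working > 0,
      out$new_paid_labor / out$increase_in_caregivers_working, NA_real_)
  }
  class(out) <- c("policy_outcome", class(out))
  out
}

#' Run several scenarios on shared inputs
#'
#' @param scenarios character vector of scenario names (default: all six).
#' @inheritParams run_scenario
#' @return named list of `policy_outcome` data frames; the no-LTC
#'   counterfactual is always run (first) and used as the shared comparator.
#' @export
run_scenarios <- function(scenarios = c("no_ltc", "current", "pro_hcbs",
                                        "pro_fdw", "pro_nh", "all_in"),
                          config = make_fixture_config(), pyramids = NULL,
                          overrides = NULL) {
  sc <- config$scenario
  if (is.null(pyramids)) {
    demo <- make_demography(config$synthetic_demography)
    rates <- demo$rates
    rates$fertility_rate <- config$demography$fertility_rate
    pyramids <- project_population(demo$pyramid, rates,
                                   sc$start_year, sc$end_year)
  }
  base <- run_scenario("no_ltc", config, pyramids, overrides)
  out <- lapply(setdiff(scenarios, "no_ltc"), function(nm)
    run_scenario(nm, config, pyramids, overrides, comparator = base))
  names(out) <- setdiff(scenarios, "no_ltc")
  if ("no_ltc" %in% scenarios) out <- c(list(no_ltc = base), out)
  out[scenarios]
}

#' Summarize scenario outcomes in the published table layout
#'
#' One row per (scenario, metric) with a column per requested year. Counts
#' are rounded to the nearest hundred, percentages and ratios to one
#' decimal, matching the published rounding.
#'
#' @param outcomes named list of `policy_outcome` data frames (from
#'   [run_scenarios()]) or a single outcome data frame.
#' @param years report years (default 2020 and 2030).
#' @return a tidy data frame with columns `scenario`, `metric` and one
#'   `y<year>` column per requested year.
#' @export
summarize_outcomes <- function(outcomes, years = c(2020, 2030)) {
  if (is.data.frame(outcomes))
    outcomes <- setNames(list(outcomes), outcomes$scenario[1])
  metrics <- c(caregivers_in_market = "count",
               increase_in_caregivers_working = "count",
               new_paid_labor = "count",
               percent_dropping_out = "decimal",
               labor_requirement_ratio = "decimal")
  rows <- list()
  for (nm in names(outcomes)) {
    oc <- outcomes[[nm]]
    missing_years <- setdiff(years, oc$year)
    if (length(missing_years))
      stop("summarize_outcomes: outcome '", nm, "' lacks year(s) ",
           paste(missing_years, collapse = ", "))
    for (met in names(metrics)) {
      vals <- sapply(years, function(y) {
        v <- oc[[met]][oc$year == y]
        if (metrics[[met]] == "count") round(v / 100) * 100
        else round(v, 1)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = nm, metric = met,
        as.list(setNames(vals, paste0("y", years))))
    }
  }
  do.call(rbind, rows)
}
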
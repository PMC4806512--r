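#' Full model configuration with survey-based defaults
#'
#' Returns the nested parameter list that drives [run_scenario()], populated
#' with the study's published input values: HCBS uptake 0.20, capacity
#' adjustment time 1.5 years, FDW proportion 0.491, weekly primary caregiver
#' hours 31/36/42 (no services) and 25/48/37 (with HCBS), employable fraction
#' 0.65, patient-to-staff ratios 5 (nursing home) / 7 (HCBS) / 1 (FDW),
#' nursing-home bed ramp 9,750 (2012) - 14,900 (2020) - 22,400 (2030), ADL
#' incidence 0.00768/y, disabled mortality 0.1134/y and the age-band
#' prevalence table — plus a synthetic demography spec (see
#' [make_demography()]) so end-to-end runs need no external data.
#'
#' @return a nested named list of class `ltc_config`.
#' @export
make_fixture_config <- function() {
  structure(list(
    demography = list(
      fertility_rate = 0.043,
      sex_ratio_at_birth = 0.487,
      time_step = 1L),
    synthetic_demography = list(
      total_population = 3900000L,
      growth_rate = 0.015,
      mortality_model = "gompertz_makeham",
      gompertz_a = 3e-05,
      gompertz_b = 0.095,
      makeham_c = 3e-04,
      bulge_scale = 8,
      bulge_center = 55L,
      bulge_sd = 10L,
      net_migration_level = 19500L,
      max_age = 100L,
      seed = 1L),
    disability = list(
      mode = "stock_flow",
      incidence = 0.00768,
      mortality = 0.1134,
      severity_shares = c(0.36, 0.24, 0.4),
      overall_prevalence_60plus = 0.0478),
    care = list(
      hcbs_uptake = 0.2,
      fdw_proportion = 0.491,
      capacity_adjustment_time = 1.5,
      fdw_share_of_hours = 0.7,
      hours_no_services = c(31, 36, 42),
      hours_services = c(25, 48, 37),
      family_friends_share = c(0.43, 0.36, 0.29)),
    labor = list(
      employable_fraction = 0.65,
      dropout_anchors = list(hours = c(0, 10, 20, 40),
                             reduction = c(0, 11, 22, 55)),
      staff_ratios = list(nh = 5, hcbs = 7, fdw = 1)),
    scenario = list(
      start_year = 2010L,
      end_year = 2030L,
      policy_start = 2013L,
      nh_bed_knots = list(years = c(2012L, 2020L, 2030L),
                          beds = c(9750L, 14900L, 22400L)),
      bed_start_override = NULL)),
    class = "ltc_config")
}

#' Read / write a model configuration as YAML
#'
#' @param config an `ltc_config` list (e.g. from [make_fixture_config()]).
#' @param path file path of the YAML configuration.
#' @return `read_ltc_config()` returns the `ltc_config`;
#'   `write_ltc_config()` returns `path` invisibly.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_ltc_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname config_io
#' @export
read_ltc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "ltc_config")
}

# helpers building module parameter objects from a config list
config_disability_params <- function(config) {
  d <- config$disability
  disability_params(severity_shares = d$severity_shares,
                    incidence = d$incidence, mortality = d$mortality,
                    overall_prevalence_60plus = d$overall_prevalence_60plus,
                    mode = d$mode)
}

config_care_params <- function(config) {
  cc <- config$care
  care_params(hcbs_uptake = cc$hcbs_uptake,
              fdw_proportion = cc$fdw_proportion,
              capacity_adjustment_time = cc$capacity_adjustment_time,
              fdw_share_of_hours = cc$fdw_share_of_hours,
              hours_no_services = cc$hours_no_services,
              hours_services = cc$hours_services,
              family_friends_share = cc$family_friends_share,
              initial_occupancy = if (is.null(cc$initial_occupancy)) NA
                                  else cc$initial_occupancy)
}

config_dropout_curve <- function(config) {
  a <- config$labor$dropout_anchors
  dropout_curve(data.frame(hours = a$hours, reduction = a$reduction))
}

config_staff_ratios <- function(config) {
  r <- config$labor$staff_ratios
  staff_ratios(nh = r$nh, hcbs = r$hcbs, fdw = r$fdw)
}
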
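arrangement_levels <- c("nursing_home", "home_services", "home_fdw",
                        "home_services_fdw", "home_unpaid")

#' Care-arrangement parameters
#'
#' Governs how ADL-disabled elderly are partitioned across the five care
#' arrangements (nursing home; home with HCBS; home with FDW; home with both;
#' home with no paid services) and how many hours per week the primary
#' informal family caregiver provides in each cell.
#'
#' @param hcbs_uptake probability that a home-dwelling disabled elder uses
#'   home- and community-based services (default 0.20).
#' @param fdw_proportion probability that the household employs a foreign
#'   domestic worker for eldercare (default 0.491).
#' @param capacity_adjustment_time first-order time constant (years) with
#'   which nursing-home occupancy approaches its bed-limited target (1.5).
#' @param fdw_share_of_hours share of total eldercare hours an FDW provides
#'   when present (0.70); the primary caregiver keeps the remainder.
#' @param hours_no_services weekly primary caregiver hours by severity
#'   (low, medium, high) for home care without HCBS and without FDW
#'   (31, 36, 42).
#' @param hours_services same, with HCBS but no FDW (25, 48, 37).
#' @param family_friends_share share of total informal hours from other
#'   family and friends, by severity (0.43, 0.36, 0.29; the medium value is a
#'   linear interpolation between the surveyed low and high values).
#'   Informational: primary-caregiver hours are given directly by the hours
#'   tables.
#' @param initial_occupancy optional nursing-home occupancy at the start year
#'   (`NA` = filled from beds and high-severity demand).
#' @return an object of class `care_params`.
#' @export
care_params <- function(hcbs_uptake = 0.20, fdw_proportion = 0.491,
                        capacity_adjustment_time = 1.5,
                        fdw_share_of_hours = 0.70,
                        hours_no_services = c(31, 36, 42),
                        hours_services = c(25, 48, 37),
                        family_friends_share = c(0.43, 0.36, 0.29),
                        initial_occupancy = NA) {
  for (p in c(hcbs_uptake, fdw_proportion, fdw_share_of_hours))
    if (p < 0 || p > 1) stop("care_params: probabilities must lie in [0, 1]")
  if (capacity_adjustment_time <= 0)
    stop("care_params: capacity_adjustment_time must be positive")
  if (any(c(hours_no_services, hours_services) < 0))
    stop("care_params: hours must be non-negative")
  structure(list(hcbs_uptake = hcbs_uptake, fdw_proportion = fdw_proportion,
                 capacity_adjustment_time = capacity_adjustment_time,
                 fdw_share_of_hours = fdw_share_of_hours,
                 hours_no_services = setNames(hours_no_services, severity_levels),
                 hours_services = setNames(hours_services, severity_levels),
                 family_friends_share = setNames(family_friends_share,
                                                 severity_levels),
                 initial_occupancy = initial_occupancy),
            class = "care_params")
}

#' Bed-limited nursing-home target, filled high-severity first
#'
#' Available beds go to the elderly with the highest number of ADL
#' limitations: demand is filled high, then medium, then low, until beds run
#' out.
#'
#' @param demand_by_severity a [disability_stocks()] (total demand eligible
#'   for placement).
#' @param beds available bed capacity (>= 0).
#' @return named numeric (low/medium/high) target occupancy; sums to
#'   `min(beds, total demand)`.
#' @export
nursing_home_target <- function(demand_by_severity, beds) {
  if (beds < 0) stop("nursing_home_target: beds must be non-negative")
  left <- beds
  out <- setNames(numeric(3), severity_levels)
  for (sev in c("high", "medium", "low")) {
    take <- min(left, demand_by_severity[[sev]])
    out[sev] <- take
    left <- left - take
  }
  out
}

#' First-order nursing-home occupancy update
#'
#' Occupancy moves toward the bed-limited, severity-prioritized target with
#' a first-order delay: `occupancy + (target - occupancy) / adj_time` per
#' year (capped so a short adjustment time cannot overshoot the target).
#'
#' @param occupancy current occupancy by severity (named numeric or scalar
#'   total; a scalar is allocated high-first against the target).
#' @param demand_by_severity a [disability_stocks()].
#' @param beds bed capacity.
#' @param adj_time capacity adjustment time in years (> 0).
#' @return named numeric (low/medium/high) occupancy after one year; never
#'   exceeds `beds`.
#' @export
update_nursing_home <- function(occupancy, demand_by_severity, beds,
                                adj_time = 1.5) {
  if (adj_time <= 0) stop("update_nursing_home: adj_time must be positive")
  target <- nursing_home_target(demand_by_severity, beds)
  if (length(occupancy) == 1)   # scalar total: allocate high-first over demand
    occupancy <- nursing_home_target(demand_by_severity, occupancy)
  occ <- setNames(as.numeric(occupancy[severity_levels]), severity_levels)
  frac <- min(1 / adj_time, 1)
  new <- pmax(occ + (target - occ) * frac, 0)
  if (sum(new) > beds && sum(new) > 0)   # beds shrank below occupancy
    new <- new * beds / sum(new)
  new
}

#' Partition home-dwelling disabled elderly across home-care arrangements
#'
#' HCBS uptake `u` and FDW employment `p` are applied as independent
#' fractions within each severity group, so the four home cells get
#' `u*p` (services + FDW), `u*(1-p)` (services only), `(1-u)*p` (FDW only)
#' and `(1-u)*(1-p)` (no paid services). The partition is exact.
#'
#' @param home_stocks [disability_stocks()] of home-dwelling (non-nursing
#'   home) disabled elderly.
#' @param hcbs_uptake,fdw_proportion probabilities in \[0, 1\].
#' @param nh_occupancy optional named numeric added as the `nursing_home`
#'   column of the returned mix (default 0).
#' @param year calendar year recorded on the mix.
#' @return a `care_mix`: 3 x 5 matrix (severity x arrangement) with a `year`
#'   attribute.
#' @export
partition_home_care <- function(home_stocks, hcbs_uptake, fdw_proportion,
                                nh_occupancy = NULL, year = NA) {
  u <- hcbs_uptake; p <- fdw_proportion
  if (u < 0 || u > 1 || p < 0 || p > 1)
    stop("partition_home_care: probabilities must lie in [0, 1]")
  m <- matrix(0, nrow = 3, ncol = 5,
              dimnames = list(severity_levels, arrangement_levels))
  h <- as.numeric(home_stocks[severity_levels])
  m[, "home_services_fdw"] <- h * u * p
  m[, "home_services"] <- h * u * (1 - p)
  m[, "home_fdw"] <- h * (1 - u) * p
  m[, "home_unpaid"] <- h * (1 - u) * (1 - p)
  if (!is.null(nh_occupancy))
    m[, "nursing_home"] <- as.numeric(nh_occupancy[severity_levels])
  structure(m, year = year, class = c("care_mix", class(m)))
}

#' Weekly primary informal family caregiver hours for one care cell
#'
#' Nursing homes provide all eldercare hours for residents, so the primary
#' caregiver contributes 0. At home, hours come from the severity-specific
#' survey tables (with or without HCBS); when an FDW is employed the FDW
#' provides `fdw_share_of_hours` (70 percent) of the care, leaving the
#' primary caregiver the remaining 30 percent of the tabulated hours.
#'
#' @param severity `"low"`, `"medium"` or `"high"`.
#' @param has_services,has_fdw logical indicators for the cell.
#' @param params a [care_params()].
#' @param in_nursing_home logical; overrides everything with 0 hours.
#' @return hours per week (numeric scalar).
#' @examples
#' primary_caregiver_hours("low", FALSE, FALSE)        # 31
#' primary_caregiver_hours("medium", TRUE, FALSE)      # 48
#' primary_caregiver_hours("high", FALSE, TRUE)        # 42 * 0.3 = 12.6
#' @export
primary_caregiver_hours <- function(severity, has_services, has_fdw,
                                    params = care_params(),
                                    in_nursing_home = FALSE) {
  if (!severity %in% severity_levels)
    stop("primary_caregiver_hours: unknown severity '", severity, "'")
  if (in_nursing_home) return(0)
  base <- if (has_services) params$hours_services[[severity]]
          else params$hours_no_services[[severity]]
  if (has_fdw) base * (1 - params$fdw_share_of_hours) else base
}

#' Tidy a care mix into a long data frame
#'
#' @param mix a `care_mix` matrix from [partition_home_care()].
#' @return data frame with columns `year`, `severity`, `arrangement`,
#'   `count`.
#' @export
care_mix_tidy <- function(mix) {
  data.frame(year = attr(mix, "year"),
             severity = rep(rownames(mix), times = ncol(mix)),
             arrangement = rep(colnames(mix), each = nrow(mix)),
             count = as.vector(unclass(mix)))
}
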
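severity_levels <- c("low", "medium", "high")

#' Parameters of the ADL-disability projection
#'
#' Severity groups follow the number of activities-of-daily-living (ADL)
#' limitations needing human assistance: low (1-2), medium (3-4), high (>=5).
#'
#' @param prevalence data frame with columns `age_band` (`"60-64"`, `"65-69"`,
#'   `"70-74"`, `"75-79"`, `"80-84"`, `"85+"`), `severity`
#'   (`"low"/"medium"/"high"`) and `prevalence` (probability that a
#'   community-dwelling person in the band has that severity). Default: the
#'   survey-based table in [default_prevalence_table()].
#' @param severity_shares probabilities that a newly disabled person falls in
#'   each severity group; must sum to 1. Default `c(0.36, 0.24, 0.40)`.
#' @param incidence annual probability that a non-disabled 60+ person becomes
#'   ADL-disabled (calibrated value 0.00768).
#' @param mortality annual death probability of ADL-disabled elderly
#'   (0.1134).
#' @param overall_prevalence_60plus overall prevalence of >=1 ADL limitation
#'   needing assistance among 60+ (0.0478); informational, used by the
#'   prevalence-mode shortcut when no age-band table is given.
#' @param mode `"stock_flow"` (default: explicit incidence/mortality flows)
#'   or `"prevalence"` (re-apply the age-band prevalence each year).
#' @return an object of class `disability_params`.
#' @export
disability_params <- function(prevalence = default_prevalence_table(),
                              severity_shares = c(0.36, 0.24, 0.40),
                              incidence = 0.00768,
                              mortality = 0.1134,
                              overall_prevalence_60plus = 0.0478,
                              mode = c("stock_flow", "prevalence")) {
  severity_shares <- as.numeric(severity_shares)
  if (length(severity_shares) != 3 || abs(sum(severity_shares) - 1) > 1e-9)
    stop("disability_params: severity_shares must be 3 probabilities summing to 1")
  if (any(severity_shares < 0))
    stop("disability_params: severity_shares must be non-negative")
  for (p in c(incidence, mortality, overall_prevalence_60plus))
    if (p < 0 || p > 1) stop("disability_params: probabilities must lie in [0, 1]")
  if (!is.null(prevalence)) {
    need <- c("age_band", "severity", "prevalence")
    if (!all(need %in% names(prevalence)))
      stop("disability_params: prevalence table needs columns ",
           paste(need, collapse = ", "))
    if (any(prevalence$prevalence < 0 | prevalence$prevalence > 1))
      stop("disability_params: prevalence values must lie in [0, 1]")
  }
  structure(list(prevalence = prevalence,
                 severity_shares = setNames(severity_shares, severity_levels),
                 incidence = incidence, mortality = mortality,
                 overall_prevalence_60plus = overall_prevalence_60plus,
                 mode = match.arg(mode)),
            class = "disability_params")
}

#' Age-band prevalence of ADL limitations needing human assistance
#'
#' Community prevalence by five-year age band and severity group, from a
#' nationally representative survey of community-dwelling Singaporeans 60+
#' (counts in nursing homes are added back separately at initialization).
#'
#' @return a data frame with columns `age_band`, `severity`, `prevalence`.
#' @export
default_prevalence_table <- function() {
  bands <- c("60-64", "65-69", "70-74", "75-79", "80-84", "85+")
  low <- c(0.0042, 0.0080, 0.0078, 0.0190, 0.0525, 0.1270)
  medium <- c(0.0069, 0.0109, 0.0230, 0.0427, 0.0892, 0.1432)
  high <- c(0.0042, 0.0156, 0.0262, 0.0464, 0.0785, 0.1744)
  data.frame(age_band = rep(bands, 3),
             severity = rep(severity_levels, each = length(bands)),
             prevalence = c(low, medium, high))
}

band_ages <- function(band) {
  if (band == "85+") return(85:200)
  r <- as.integer(strsplit(band, "-", fixed = TRUE)[[1]])
  r[1]:r[2]
}

#' Disability stocks by severity group
#'
#' @param low,medium,high counts of ADL-disabled elderly with 1-2, 3-4 and
#'   >=5 limitations needing human assistance.
#' @param year calendar year.
#' @return an object of class `disability_stocks`: a named numeric vector
#'   with a `year` attribute.
#' @export
disability_stocks <- function(low = 0, medium = 0, high = 0, year = NA) {
  x <- c(low = unname(low), medium = unname(medium), high = unname(high))
  if (any(x < 0)) stop("disability_stocks: counts must be non-negative")
  structure(x, year = year, class = "disability_stocks")
}

#' @export
print.disability_stocks <- function(x, ...) {
  cat("<disability_stocks>", if (!is.na(attr(x, "year"))) paste("year", attr(x, "year")),
      sprintf("low %.1f, medium %.1f, high %.1f (total %.1f)\n",
              x["low"], x["medium"], x["high"], sum(x)))
  invisible(x)
}

#' Initialize disability stocks from a pyramid
#'
#' Applies the age-band prevalence to the 60+ population and adds back
#' nursing-home residents, who are excluded from community prevalence surveys
#' and are assigned to the high-severity group.
#'
#' @param pyramid an [age_pyramid()] covering ages >= 60.
#' @param params a [disability_params()] with a prevalence table.
#' @param nh_residents count of elderly residing in nursing homes at the
#'   initialization year.
#' @return a [disability_stocks()].
#' @export
initialize_disability_stocks <- function(pyramid, params, nh_residents = 0) {
  if (is.null(params$prevalence))
    stop("initialize_disability_stocks: params carry no prevalence table")
  if (nh_residents < 0)
    stop("initialize_disability_stocks: nh_residents must be non-negative")
  tab <- params$prevalence
  bands <- c("60-64", "65-69", "70-74", "75-79", "80-84", "85+")
  out <- setNames(numeric(3), severity_levels)
  for (sev in severity_levels) {
    for (b in bands) {
      row <- tab[tab$age_band == b & tab$severity == sev, ]
      if (nrow(row) == 0)
        stop("initialize_disability_stocks: prevalence table missing band ",
             b, " x ", sev)
      out[sev] <- out[sev] +
        row$prevalence[1] * pyramid_total(pyramid, ages = band_ages(b))
    }
  }
  out["high"] <- out["high"] + nh_residents
  disability_stocks(out["low"], out["medium"], out["high"], year = pyramid$year)
}

#' Split a disabled total across severity groups
#'
#' @param total_disabled total count of ADL-disabled elderly (>= 0).
#' @param params a [disability_params()]; `severity_shares` is used.
#' @return a [disability_stocks()].
#' @examples
#' split_by_severity(100000, disability_params())  # 36000 / 24000 / 40000
#' @export
split_by_severity <- function(total_disabled, params = disability_params()) {
  if (total_disabled < 0)
    stop("split_by_severity: total must be non-negative")
  s <- params$severity_shares
  disability_stocks(total_disabled * s["low"], total_disabled * s["medium"],
                    total_disabled * s["high"])
}

#' Advance disability stocks one year
#'
#' Stock-flow mode: the inflow is `incidence` times the non-disabled 60+
#' population, split across severity by `severity_shares` (severity is fixed
#' at onset; no transitions between groups); the outflow is the disabled
#' mortality applied to each stock. Prevalence mode re-derives stocks from
#' the age-band prevalence applied to the current pyramid.
#'
#' @param stocks current [disability_stocks()].
#' @param pyramid the [age_pyramid()] for the same year.
#' @param params a [disability_params()].
#' @param nh_residents passed through to the prevalence-mode re-initialization
#'   (ignored in stock-flow mode).
#' @return updated [disability_stocks()] for the following year.
#' @export
step_disability <- function(stocks, pyramid, params, nh_residents = 0) {
  pop60 <- pyramid_total(pyramid, ages = 60:200)
  if (sum(stocks) > pop60 * (1 + 1e-9) + 1e-9)
    stop("step_disability: disabled stocks exceed the 60+ population")
  if (params$mode == "prevalence") {
    out <- initialize_disability_stocks(pyramid, params, nh_residents)
    attr(out, "year") <- attr(stocks, "year") + 1
    return(out)
  }
  at_risk <- max(pop60 - sum(stocks), 0)
  inflow <- params$incidence * at_risk * params$severity_shares
  new <- pmax(as.numeric(stocks) * (1 - params$mortality) + inflow, 0)
  disability_stocks(new[1], new[2], new[3],
                    year = if (is.na(attr(stocks, "year"))) NA
                           else attr(stocks, "year") + 1)
}
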
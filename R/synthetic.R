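#' Specification of a synthetic demography
#'
#' Describes a stable-population age structure: counts at age `a` are
#' proportional to `l(a) * exp(-r a)`, where `l` is the survivorship of the
#' chosen mortality schedule and `r` the stable growth rate. The default
#' schedule is Gompertz-Makeham, `m(a) = c + a_g * exp(b * a)` capped at
#' 0.95.
#'
#' @param total_population total count the pyramid is normalized to.
#' @param growth_rate stable-population growth rate `r` (per year).
#' @param mortality_model `"gompertz_makeham"` or `"flat"`.
#' @param gompertz_a,gompertz_b,makeham_c schedule parameters (ignored for
#'   `"flat"`).
#' @param flat_rate mortality used by the `"flat"` model.
#' @param bulge_scale,bulge_center,bulge_sd optional Gaussian cohort bulge
#'   multiplying the stable shape by
#'   `1 + bulge_scale * exp(-(age - bulge_center)^2 / (2 bulge_sd^2))` —
#'   a baby-boom generation part-way through the age range, which produces
#'   the population-aging wave as it crosses 60 during the simulation.
#'   `bulge_scale = 0` disables it.
#' @param fertility_rate annual births per woman 15-44 attached to the
#'   returned vital rates.
#' @param net_migration_level target annual net migration (persons/year);
#'   emigration is set so the schedule hits this level exactly.
#' @param sex_ratio_at_birth fraction female, applied at every age.
#' @param max_age top (open-ended) age.
#' @param seed integer kept for interface determinism (the construction is
#'   closed-form).
#' @return a named list (class `synthetic_demography_spec`).
#' @export
synthetic_demography_spec <- function(total_population = 3900000,
                                      growth_rate = 0.015,
                                      mortality_model = "gompertz_makeham",
                                      gompertz_a = 3e-05, gompertz_b = 0.095,
                                      makeham_c = 3e-04, flat_rate = 0.01,
                                      bulge_scale = 8, bulge_center = 55,
                                      bulge_sd = 10,
                                      fertility_rate = 0.043,
                                      net_migration_level = 19500,
                                      sex_ratio_at_birth = 0.487,
                                      max_age = 100, seed = 1) {
  if (total_population <= 0)
    stop("synthetic_demography_spec: total_population must be positive")
  structure(as.list(environment()), class = "synthetic_demography_spec")
}

#' Generate a synthetic age pyramid and vital rates
#'
#' Deterministic stable-population construction (see
#' [synthetic_demography_spec()]): survivorship from the mortality schedule
#' shapes the pyramid, discounted by the growth rate; migration schedules are
#' placed on working ages (20-44) with emigration balancing immigration to
#' hit the requested net level.
#'
#' @param spec a [synthetic_demography_spec()] or a compatible named list
#'   (e.g. `make_fixture_config()$synthetic_demography`).
#' @return list with elements `pyramid` ([age_pyramid()]) and `rates`
#'   ([vital_rates()]).
#' @export
make_demography <- function(spec = synthetic_demography_spec()) {
  defaults <- synthetic_demography_spec()
  for (nm in names(defaults))
    if (is.null(spec[[nm]])) spec[[nm]] <- defaults[[nm]]
  ages <- 0:spec$max_age
  m <- switch(spec$mortality_model,
    flat = rep(spec$flat_rate, length(ages)),
    gompertz_makeham = pmin(spec$makeham_c +
                              spec$gompertz_a * exp(spec$gompertz_b * ages),
                            0.95),
    stop("make_demography: unknown mortality model '",
         spec$mortality_model, "'"))
  if (any(m >= 1))
    stop("make_demography: mortality schedule reaches 1; infeasible")
  # survivorship to age a, then stable-population discounting by growth rate
  l <- cumprod(c(1, 1 - m[-length(m)]))
  shape <- l * exp(-spec$growth_rate * ages)
  if (spec$bulge_scale > 0)
    shape <- shape * (1 + spec$bulge_scale *
                        exp(-(ages - spec$bulge_center)^2 /
                              (2 * spec$bulge_sd^2)))
  if (!all(is.finite(shape)) || sum(shape) <= 0)
    stop("make_demography: infeasible growth/mortality combination")
  counts_age <- spec$total_population * shape / sum(shape)
  counts <- cbind(female = counts_age * spec$sex_ratio_at_birth,
                  male = counts_age * (1 - spec$sex_ratio_at_birth))
  rownames(counts) <- ages
  pyramid <- age_pyramid(counts, year = NA)

  mort <- cbind(female = m, male = m)
  rownames(mort) <- ages
  # gross in-migration on working ages, emigration balancing to the net level
  target_ages <- 20:44
  w <- counts_age[ages %in% target_ages]
  w <- w / sum(w)
  gross_in <- max(spec$net_migration_level, 0) + abs(spec$net_migration_level)
  imm_age <- setNames(numeric(length(ages)), ages)
  imm_age[as.character(target_ages)] <- gross_in * w
  emi_age <- setNames(numeric(length(ages)), ages)
  emi_age[as.character(target_ages)] <-
    (gross_in - spec$net_migration_level) * w
  to_mat <- function(v, srb) cbind(female = v * srb, male = v * (1 - srb))
  rates <- vital_rates(fertility_rate = spec$fertility_rate,
                       mortality = mort,
                       immigration = to_mat(imm_age, spec$sex_ratio_at_birth),
                       emigration = to_mat(emi_age, spec$sex_ratio_at_birth),
                       sex_ratio_at_birth = spec$sex_ratio_at_birth,
                       max_age = spec$max_age)
  list(pyramid = pyramid, rates = rates)
}

#' Specification of a synthetic caregiver survey
#'
#' The forward model of the two-stage system: caregiving hours follow the
#' Stage-1 linear model in the care recipient's severity category and the
#' caregiver covariates, and labor-force participation follows the Stage-2
#' probit in the *structural* (systematic) hours, so the severity instruments
#' affect participation only through hours and the exclusion restriction
#' holds by construction. In FDW households the hours effect on
#' participation is zero, matching the finding of no association there.
#'
#' @param n number of caregiver-care recipient dyads.
#' @param true_beta Stage-1 coefficients `beta0..beta7` (intercept, 3-4 ADL,
#'   >=5 ADL, x1..x5). Defaults put mean hours at the surveyed 31/36/42 by
#'   severity.
#' @param true_gamma Stage-2 coefficients `gamma0..gamma6` (intercept,
#'   hours, x1..x5). The default hours coefficient -0.035 reproduces
#'   participation reductions close to the published 11/22/55 percentage
#'   points at 10/20/40 hours.
#' @param severity_mix probabilities of low / medium / high severity
#'   (default the surveyed 0.36/0.24/0.40).
#' @param fdw_probability probability the household employs an FDW (0.491).
#' @param noise_sd standard deviation of the Stage-1 hours noise (15 h/week).
#' @param covariate_probs Bernoulli probabilities for x1..x5 (independent).
#' @param endogeneity_rho correlation between the Stage-1 and Stage-2 noise
#'   terms; 0 by default, 0.5 in the endogenous preset
#'   (`synthetic_survey_spec(endogeneity_rho = 0.5)`), which biases a naive
#'   probit on observed hours while the two-stage estimator stays consistent.
#' @param never_employed_prob,multi_recipient_prob rates of the two exclusion
#'   flags carried in the raw records.
#' @param seed RNG seed.
#' @return a named list (class `synthetic_survey_spec`).
#' @export
synthetic_survey_spec <- function(n = 20000,
                                  true_beta = c(31, 5, 11, 2, -1, 1.5, -2, 1),
                                  true_gamma = c(0.9, -0.035, 0.2, 0.1,
                                                 -0.1, 0.3, 0.1),
                                  severity_mix = c(0.36, 0.24, 0.40),
                                  fdw_probability = 0.491,
                                  noise_sd = 15,
                                  covariate_probs = rep(0.5, 5),
                                  endogeneity_rho = 0,
                                  never_employed_prob = 0.05,
                                  multi_recipient_prob = 0.03,
                                  seed = 1) {
  if (n <= 0) stop("synthetic_survey_spec: n must be positive")
  if (length(true_beta) != 8 || length(true_gamma) != 7)
    stop("synthetic_survey_spec: need 8 beta and 7 gamma coefficients")
  if (abs(sum(severity_mix) - 1) > 1e-9)
    stop("synthetic_survey_spec: severity_mix must sum to 1")
  if (abs(endogeneity_rho) > 1)
    stop("synthetic_survey_spec: endogeneity_rho must lie in [-1, 1]")
  structure(as.list(environment()), class = "synthetic_survey_spec")
}

#' Generate a synthetic caregiver survey with known ground truth
#'
#' @param spec a [synthetic_survey_spec()].
#' @return data frame with columns `cgh` (reported hours, truncated to
#'   \[0, 112\]), `cgh_struct` (the structural hours used in the outcome
#'   model), `adl1`, `adl2`, `x1`..`x5`, `lfp`, `has_fdw`, `never_employed`,
#'   `multi_recipient`. The generating spec is attached as attribute
#'   `"spec"`.
#' @export
make_caregiver_survey <- function(spec = synthetic_survey_spec()) {
  set.seed(spec$seed)
  n <- spec$n
  sev <- sample.int(3, n, replace = TRUE, prob = spec$severity_mix)
  adl1 <- as.integer(sev == 2)
  adl2 <- as.integer(sev == 3)
  X <- sapply(spec$covariate_probs, function(p) rbinom(n, 1, p))
  colnames(X) <- paste0("x", 1:5)
  b <- spec$true_beta
  struct <- b[1] + b[2] * adl1 + b[3] * adl2 + as.vector(X %*% b[4:8])
  z_eps <- rnorm(n)
  z_del <- rnorm(n)
  rho <- spec$endogeneity_rho
  eps <- spec$noise_sd * z_eps
  delta <- rho * z_eps + sqrt(1 - rho^2) * z_del
  cgh <- pmin(pmax(struct + eps, 0), 112)
  has_fdw <- rbinom(n, 1, spec$fdw_probability)
  g <- spec$true_gamma
  latent <- g[1] + g[2] * struct * (1 - has_fdw) +
    as.vector(X %*% g[3:7]) + delta
  lfp <- as.integer(latent > 0)
  out <- data.frame(cgh = cgh, cgh_struct = struct, adl1 = adl1, adl2 = adl2,
                    X, lfp = lfp, has_fdw = has_fdw,
                    never_employed = rbinom(n, 1, spec$never_employed_prob),
                    multi_recipient = rbinom(n, 1, spec$multi_recipient_prob))
  attr(out, "spec") <- spec
  out
}

#' Write a survey to the CSV layout consumed by the estimation module
#'
#' @param records survey data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
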
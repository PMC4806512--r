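#' Hours-to-dropout curve
#'
#' Piecewise-linear mapping from weekly primary eldercare hours to the
#' percentage-point reduction in labor-market participation, for caregivers
#' in households without an FDW (for FDW households no association was found,
#' so the reduction is identically zero). The default anchors encode the
#' instrumental-variable regression results: 11, 22 and 55 percentage points
#' at 10, 20 and 40 hours per week, through the origin. Beyond the last
#' anchor the curve continues at its mean slope over the anchor span, clamped
#' at 100.
#'
#' @param anchors data frame with columns `hours` and `reduction`
#'   (percentage points), non-decreasing in both.
#' @return an object of class `dropout_curve`.
#' @export
dropout_curve <- function(anchors = data.frame(
                            hours = c(0, 10, 20, 40),
                            reduction = c(0, 11, 22, 55))) {
  if (!all(c("hours", "reduction") %in% names(anchors)))
    stop("dropout_curve: anchors need columns hours, reduction")
  anchors <- anchors[order(anchors$hours), ]
  if (any(diff(anchors$hours) <= 0))
    stop("dropout_curve: anchor hours must be strictly increasing")
  if (any(diff(anchors$reduction) < 0))
    stop("dropout_curve: anchor reductions must be non-decreasing")
  if (any(anchors$reduction < 0 | anchors$reduction > 100))
    stop("dropout_curve: reductions are percentage points in [0, 100]")
  structure(list(anchors = anchors), class = "dropout_curve")
}

#' Reduction in labor-market participation at a given caregiving load
#'
#' @param hours weekly primary eldercare hours (>= 0; vectorized).
#' @param has_fdw logical; FDW households experience no reduction.
#' @param curve a [dropout_curve()].
#' @return the participation reduction as a fraction in \[0, 1\].
#' @examples
#' dropout_reduction(20, FALSE)  # 0.22
#' dropout_reduction(40, TRUE)   # 0 - no association for FDW households
#' @export
dropout_reduction <- function(hours, has_fdw = FALSE,
                              curve = dropout_curve()) {
  if (any(hours < 0)) stop("dropout_reduction: hours must be non-negative")
  a <- curve$anchors
  n <- nrow(a)
  pct <- approx(a$hours, a$reduction, xout = pmin(hours, a$hours[n]),
                rule = 2)$y
  # extrapolate past the last anchor at the mean slope of the anchor span
  slope <- (a$reduction[n] - a$reduction[1]) / (a$hours[n] - a$hours[1])
  over <- hours > a$hours[n]
  pct[over] <- a$reduction[n] + (hours[over] - a$hours[n]) * slope
  pct <- pmin(pmax(pct, 0), 100)
  pct[rep_len(has_fdw, length(pct))] <- 0
  pct / 100
}

#' Primary caregivers withdrawing from the labor market
#'
#' For every home-care cell without an FDW, the expected number of dropouts
#' is the cell count times the employable fraction times the participation
#' reduction at that cell's primary caregiver hours. FDW cells and nursing
#' homes contribute none (one caregiver per care recipient).
#'
#' @param caremix a `care_mix` matrix from [partition_home_care()].
#' @param params a [care_params()] (for the hours tables).
#' @param employable_fraction fraction of caregivers employed or employable
#'   (default 0.65).
#' @param curve a [dropout_curve()].
#' @return expected number of caregivers withdrawing (numeric scalar).
#' @export
count_dropouts <- function(caremix, params = care_params(),
                           employable_fraction = 0.65,
                           curve = dropout_curve()) {
  total <- 0
  for (sev in severity_levels) {
    for (arr in c("home_services", "home_unpaid")) {
      h <- primary_caregiver_hours(sev, has_services = arr == "home_services",
                                   has_fdw = FALSE, params = params)
      total <- total + caremix[sev, arr] * employable_fraction *
        dropout_reduction(h, has_fdw = FALSE, curve = curve)
    }
  }
  unname(total)
}

#' Staff ratios for the paid long-term care workforce
#'
#' @param nh patients per staff member in nursing homes (default 5).
#' @param hcbs patients per staff member for home- and community-based
#'   services (7).
#' @param fdw patients per FDW (1; live-in one-to-one care).
#' @return an object of class `staff_ratios`.
#' @export
staff_ratios <- function(nh = 5, hcbs = 7, fdw = 1) {
  if (any(c(nh, hcbs, fdw) <= 0))
    stop("staff_ratios: ratios must be positive")
  structure(list(nh = nh, hcbs = hcbs, fdw = fdw), class = "staff_ratios")
}

#' Paid LTC workforce required to serve a care mix
#'
#' Nursing-home residents divided by the nursing-home ratio, plus HCBS users
#' divided by the HCBS ratio, plus FDW-employing households at one worker
#' each. A household employing both an FDW and HCBS is counted once, under
#' its dominant paid arrangement (the live-in FDW, who provides 70 percent
#' of the care hours); set `double_count_fdw_hcbs = TRUE` to charge such
#' households for both kinds of labor instead.
#'
#' @param caremix a `care_mix` matrix.
#' @param ratios a [staff_ratios()].
#' @param double_count_fdw_hcbs logical; see above.
#' @return required staff count (numeric scalar).
#' @export
paid_labor_required <- function(caremix, ratios = staff_ratios(),
                                double_count_fdw_hcbs = FALSE) {
  nh <- sum(caremix[, "nursing_home"])
  hcbs <- sum(caremix[, "home_services"]) +
    if (double_count_fdw_hcbs) sum(caremix[, "home_services_fdw"]) else 0
  fdw <- sum(caremix[, "home_fdw"]) + sum(caremix[, "home_services_fdw"])
  nh / ratios$nh + hcbs / ratios$hcbs + fdw / ratios$fdw
}

#' Labor-requirement ratio of a policy
#'
#' Paid LTC workers needed to implement a policy per informal caregiver the
#' policy returns to (or keeps in) the labor market.
#'
#' @param new_paid_labor paid workers required under the policy (vs the
#'   no-LTC counterfactual, where none are required).
#' @param caregivers_returned increase in caregivers participating in the
#'   labor market relative to the counterfactual (> 0).
#' @return the ratio (numeric scalar, unrounded; reporting rounds to one
#'   decimal).
#' @examples
#' labor_requirement_ratio(35500, 20900)  # ~1.7
#' @export
labor_requirement_ratio <- function(new_paid_labor, caregivers_returned) {
  if (caregivers_returned <= 0)
    stop("labor_requirement_ratio: caregivers_returned must be positive")
  new_paid_labor / caregivers_returned
}

#' Clean a caregiver survey for estimation
#'
#' Caps reported caregiving hours at 112 per week (16 per day), drops
#' caregivers who were never employed (no labor-market attachment) and those
#' caring for more than one person (non-comparable load), and optionally
#' drops FDW households for the secondary analysis.
#'
#' @param records data frame with at least `cgh`, and optionally
#'   `never_employed`, `multi_recipient`, `has_fdw` indicator columns.
#' @param drop_fdw logical; also exclude FDW households.
#' @return the filtered, recoded data frame.
#' @export
prepare_survey <- function(records, drop_fdw = FALSE) {
  records$cgh <- pmin(records$cgh, 112)
  if ("never_employed" %in% names(records))
    records <- records[records$never_employed == 0, ]
  if ("multi_recipient" %in% names(records))
    records <- records[records$multi_recipient == 0, ]
  if (drop_fdw && "has_fdw" %in% names(records))
    records <- records[records$has_fdw == 0, ]
  records
}

#' Two-stage instrumental-variable probit of labor-force participation
#'
#' Stage 1 regresses weekly caregiving hours (`cgh`) on the care recipient's
#' ADL-severity category indicators (`adl1` = 3-4 limitations, `adl2` = >=5;
#' the instruments) and the exogenous covariates `x1`-`x5` by least squares.
#' Stage 2 fits a probit of labor-force participation (`lfp`) on the Stage-1
#' fitted hours and the same covariates by maximum likelihood. Severity
#' drives caregiving hours but affects participation only through them, which
#' is what identifies the hours effect despite the endogeneity of caregiving
#' time.
#'
#' @param records prepared survey data frame with columns `cgh`, `adl1`,
#'   `adl2`, `x1`..`x5`, `lfp`.
#' @param min_n minimum sample size (default 50).
#' @return an object of class `iv_probit_fit`: list with `beta` (Stage-1
#'   coefficients beta0..beta7), `gamma` (Stage-2 coefficients
#'   gamma0..gamma6), `stage1_residual_sd`, `predicted_cgh`, and the two
#'   underlying model fits.
#' @export
fit_iv_probit_tsls <- function(records, min_n = 50) {
  need <- c("cgh", "adl1", "adl2", paste0("x", 1:5), "lfp")
  if (!all(need %in% names(records)))
    stop("fit_iv_probit_tsls: records need columns ",
         paste(need, collapse = ", "))
  if (nrow(records) < min_n)
    stop("fit_iv_probit_tsls: need at least ", min_n, " records")
  if (length(unique(records$adl1)) < 2 && length(unique(records$adl2)) < 2)
    stop("fit_iv_probit_tsls: no variation in the ADL-severity instruments")
  if (length(unique(records$lfp)) < 2)
    stop("fit_iv_probit_tsls: labor-force participation does not vary ",
         "(complete separation); probit cannot be estimated")
  s1 <- lm(cgh ~ adl1 + adl2 + x1 + x2 + x3 + x4 + x5, data = records)
  records$cgh_hat <- unname(predict(s1))
  s2 <- suppressWarnings(
    glm(lfp ~ cgh_hat + x1 + x2 + x3 + x4 + x5, data = records,
        family = binomial(link = "probit")))
  if (!s2$converged)
    stop("fit_iv_probit_tsls: stage-2 probit did not converge (deviance ",
         format(s2$deviance), ", iterations ", s2$iter, ")")
  structure(list(beta = setNames(coef(s1), paste0("beta", 0:7)),
                 gamma = setNames(coef(s2), paste0("gamma", 0:6)),
                 stage1_residual_sd = summary(s1)$sigma,
                 predicted_cgh = records$cgh_hat,
                 stage1 = s1, stage2 = s2),
            class = "iv_probit_fit")
}

#' @export
print.iv_probit_fit <- function(x, ...) {
  cat("<iv_probit_fit> two-stage IV probit\n")
  cat("Stage 1 (hours ~ severity + covariates):\n")
  print(round(x$beta, 4))
  cat("Stage 2 (probit LFP ~ predicted hours + covariates):\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' Bootstrap standard errors for the two-stage fit
#'
#' Nonparametric bootstrap over survey records; both stages are refitted on
#' each resample, so the generated-regressor uncertainty of the Stage-1
#' prediction is reflected in the Stage-2 standard errors.
#'
#' @param records the prepared survey used for the fit.
#' @param n_boot number of resamples (default 500).
#' @param seed RNG seed for the resampling.
#' @return data frame with one row per Stage-2 coefficient: estimate, `se`,
#'   normal-theory 95 percent bounds.
#' @export
iv_probit_boot <- function(records, n_boot = 500, seed = 1) {
  fit <- fit_iv_probit_tsls(records)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(fit$gamma))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(records), replace = TRUE)
    fb <- try(fit_iv_probit_tsls(records[idx, ]), silent = TRUE)
    if (!inherits(fb, "try-error")) draws[b, ] <- fb$gamma
  }
  se <- apply(draws, 2, stats::sd, na.rm = TRUE)
  data.frame(term = names(fit$gamma), estimate = unname(fit$gamma),
             se = se, lower = unname(fit$gamma) - 1.96 * se,
             upper = unname(fit$gamma) + 1.96 * se)
}

#' Export a fitted IV probit as an hours-to-dropout curve
#'
#' Evaluates the fitted Stage-2 probit on an hours grid, holding covariates
#' at the sample mean, and anchors the curve at the predicted-probability
#' difference from zero hours (in percentage points).
#'
#' @param fit an `iv_probit_fit`.
#' @param hours grid of anchor hours (default 10, 20, 40).
#' @param covariate_means optional named numeric of x1..x5 means; defaults to
#'   the estimation-sample means.
#' @return a [dropout_curve()] through the origin and the evaluated anchors.
#' @export
as_dropout_curve <- function(fit, hours = c(10, 20, 40),
                             covariate_means = NULL) {
  g <- fit$gamma
  if (is.null(covariate_means)) {
    mm <- stats::model.matrix(fit$stage2)
    covariate_means <- colMeans(mm)[paste0("x", 1:5)]
  }
  base <- g["gamma0"] + sum(g[paste0("gamma", 2:6)] * covariate_means)
  p <- function(h) pnorm(base + g["gamma1"] * h)
  red <- pmin(pmax((p(0) - p(hours)) * 100, 0), 100)
  red <- cummax(red)   # enforce monotone anchors against MLE noise
  dropout_curve(data.frame(hours = c(0, hours), reduction = c(0, red)))
}
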
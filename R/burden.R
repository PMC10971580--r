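#' Remaining life expectancy at surgery
#'
#' Years of life remaining at the age of operation, computed by subtracting
#' the age from the catalog's average life expectancy.
#'
#' @param age_years Age(s) at operation, in years.
#' @param catalog A `"disease_catalog"` (carries the life expectancy).
#' @return Numeric vector of remaining years.
#' @export
remaining_life <- function(age_years, catalog) {
  le <- attr(catalog, "life_expectancy")
  check_nonneg(age_years, "age_years")
  if (any(age_years >= le))
    stopf("age (%s) must be below the life expectancy (%g)",
          paste(format(age_years[age_years >= le][1]), collapse = ""), le)
  le - age_years
}

#' Discounted years of healthy life
#'
#' Continuous time discounting of a stream of `L` years at annual rate `r`:
#' `(1 - exp(-r * L)) / r`, reducing to `L` at `r = 0`. No age weighting is
#' applied. This is the discount kernel for both years of life lost (YLL)
#' and years lived with disability (YLD).
#'
#' @param L Undiscounted years (non-negative).
#' @param rate Annual discount rate (non-negative; conventionally 0.03).
#' @return Discounted year equivalents, same length as `L`.
#' @export
discounted_years <- function(L, rate) {
  check_nonneg(L, "L")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stopf("'rate' must be a single non-negative number")
  if (rate == 0) return(L)
  (1 - exp(-rate * L)) / rate
}

# Composite untreated severity: probability-weighted mix of death (weight 1)
# and survival with the untreated disability weight. Untreated burden is
# severity * discounted remaining years.
untreated_severity <- function(entry) {
  entry$p_death_untreated + (1 - entry$p_death_untreated) * entry$dw_untreated
}

# residual-state burden per discounted year: full loss under the
# death_within_year convention, dw_residual under lifelong_disability
residual_weight <- function(entry) {
  ifelse(entry$residual_convention == "death_within_year", 1,
         entry$dw_residual)
}

#' Per-case DALYs under the natural (untreated) disease course
#'
#' Expected discounted DALYs accrued by an operable child who never reaches
#' surgery: with probability `p_death_untreated` the full discounted
#' remaining life is lost, otherwise the child lives it under the untreated
#' disability weight.
#'
#' @param records Registry `data.frame` (one or more rows).
#' @param catalog A `"disease_catalog"`.
#' @param discount Annual discount rate.
#' @return Numeric vector, one DALY value per record.
#' @export
daly_untreated <- function(records, catalog, discount = 0.03) {
  entry <- catalog_lookup(catalog, records$diagnosis)
  Y <- discounted_years(remaining_life(records$age_years, catalog), discount)
  untreated_severity(entry) * Y
}

#' Per-case DALYs under surgical treatment
#'
#' Expected discounted DALYs over the surgical branch of the decision tree:
#' death before discharge (`p_dbd`) loses the full discounted remaining
#' life; a surviving, successfully treated child (`p_st`) is fully cured
#' except with probability `p_residual_after_success`, which accrues the
#' residual-state burden under the entry's residual convention; treatment
#' failure reverts to the natural disease course.
#'
#' @inheritParams daly_untreated
#' @param treatment A [treatment_params()] object.
#' @return Numeric vector, one DALY value per record.
#' @export
daly_treated <- function(records, catalog, treatment, discount = 0.03) {
  if (!inherits(treatment, "treatment_params"))
    stopf("'treatment' must be built with treatment_params()")
  entry <- catalog_lookup(catalog, records$diagnosis)
  Y <- discounted_years(remaining_life(records$age_years, catalog), discount)
  s_u <- untreated_severity(entry)
  res <- entry$p_residual_after_success * residual_weight(entry) * Y
  treatment$p_dbd * Y +
    (1 - treatment$p_dbd) * (treatment$p_st * res +
                               (1 - treatment$p_st) * s_u * Y)
}

#' Per-case DALYs averted by surgery
#'
#' Difference between the natural-course and treated burdens,
#' [daly_untreated()] minus [daly_treated()]. Non-negative whenever
#' perioperative mortality does not exceed untreated mortality and residual
#' disability does not exceed untreated disability.
#'
#' @inheritParams daly_treated
#' @return Numeric vector, one value per record.
#' @export
dalys_averted <- function(records, catalog, treatment, discount = 0.03) {
  daly_untreated(records, catalog, discount) -
    daly_treated(records, catalog, treatment, discount)
}

#' Calibrate a disease catalog to published arm-level DALY totals
#'
#' The per-diagnosis severities shipped in a catalog are placeholders; this
#' operation rescales them so the two decision-tree arms reproduce published
#' annual DALY totals. The two linear arm equations identify the per-case
#' burdens: `d_t = target_or / n_or` for a treated case and
#' `d_u = (target_soc - n_soc * d_t) / (n_or - n_soc)` for an untreated one.
#' Two closed-form scale factors then carry the catalog onto those burdens:
#' `alpha` scales every entry's composite untreated severity (applied to
#' `p_death_untreated` and, consistently, to both disability weights), and
#' `beta` scales `p_residual_after_success` so the registry-mean treated
#' burden equals `d_t`. Infeasible targets (scaled probabilities or weights
#' escaping `[0, 1]`, or a treated target below the floor set by
#' perioperative mortality) raise a calibration error.
#'
#' @param catalog A `"disease_catalog"` to rescale.
#' @param registry Registry `data.frame` providing the empirical case mix
#'   and ages over which arm means are taken.
#' @param treatment A [treatment_params()] object.
#' @param discount Annual discount rate.
#' @param target_soc,target_or Annual DALYs accrued in the
#'   standard-of-care and intervention arms (calibration targets).
#' @param volumes Named vector `c(soc =, or =)` of annual treated volumes,
#'   `soc < or`.
#' @return The rescaled catalog; the solved quantities are attached as
#'   `attr(, "calibration")` (`d_t`, `d_u`, `alpha`, `beta`).
#' @export
calibrate_catalog <- function(catalog, registry, treatment, discount = 0.03,
                              target_soc = 840, target_or = 302,
                              volumes = c(soc = 226, or = 343)) {
  validate_registry(registry, catalog)
  n_soc <- volumes[["soc"]]; n_or <- volumes[["or"]]
  if (!(target_soc > 0 && target_or > 0))
    stopf("calibration targets must be positive")
  if (!(n_soc < n_or))
    stopf("'volumes' must satisfy soc < or")
  d_t <- target_or / n_or
  d_u <- (target_soc - n_soc * d_t) / (n_or - n_soc)
  if (d_u <= 0)
    stopf("calibration infeasible: implied untreated per-case burden %.3f <= 0",
          d_u)

  # alpha: match the registry-mean untreated burden to d_u
  u0 <- mean(daly_untreated(registry, catalog, discount))
  alpha <- d_u / u0
  new <- as.data.frame(catalog)
  p <- new$p_death_untreated
  if (any(alpha * p > 1 + 1e-12))
    stopf("calibration infeasible: scaled untreated death probability exceeds 1")
  dw_scale <- ifelse(new$dw_untreated > 0,
                     alpha * (1 - p) / pmax(1 - alpha * p, 1e-12), alpha)
  new$p_death_untreated <- pmin(alpha * p, 1)
  new$dw_untreated <- new$dw_untreated * dw_scale
  new$dw_residual <- new$dw_residual * dw_scale
  if (any(new$dw_untreated > 1 + 1e-9))
    stopf("calibration infeasible: scaled untreated disability weight exceeds 1")
  new$dw_untreated <- pmin(new$dw_untreated, 1)
  new$dw_residual <- pmin(new$dw_residual, 1)
  scaled <- disease_catalog(new,
                            life_expectancy = attr(catalog, "life_expectancy"))

  # beta: match the registry-mean treated burden to d_t, scaling the
  # residual-disability probability of the success branch
  entry <- catalog_lookup(scaled, registry$diagnosis)
  Y <- discounted_years(remaining_life(registry$age_years, scaled), discount)
  s_u <- untreated_severity(entry)
  a_term <- mean(treatment$p_dbd * Y +
                   (1 - treatment$p_dbd) * (1 - treatment$p_st) * s_u * Y)
  b_term <- mean((1 - treatment$p_dbd) * treatment$p_st *
                   entry$p_residual_after_success * residual_weight(entry) * Y)
  if (d_t < a_term - 1e-9)
    stopf(paste("calibration infeasible: treated target %.3f DALYs/case is below",
                "the %.3f floor set by mortality and treatment failure"),
          d_t, a_term)
  beta <- if (b_term > 0) (d_t - a_term) / b_term else 0
  if (b_term <= 0 && d_t > a_term + 1e-9)
    stopf("calibration infeasible: no residual-disability pathway to absorb the treated target")
  p_res <- scaled$p_residual_after_success * beta
  if (any(p_res > 1 + 1e-9))
    stopf("calibration infeasible: scaled residual probability exceeds 1")
  new2 <- as.data.frame(scaled)
  new2$p_residual_after_success <- pmin(p_res, 1)
  out <- disease_catalog(new2,
                         life_expectancy = attr(catalog, "life_expectancy"))
  attr(out, "calibration") <- list(d_t = d_t, d_u = d_u,
                                   alpha = alpha, beta = beta)
  out
}
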
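`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the two-arm pediatric operating-room cost-effectiveness model
#'
#' Central entry point of the package. Assembles the one-year, two-arm
#' decision tree comparing the pre-installation standard of care (226 of
#' 343 annual demand cases treated; the remaining 34% suffer the natural
#' disease course) with the dedicated pediatric OR scenario (all 343
#' treated), on an empirical case-mix registry. The pipeline is:
#' (1) generate or accept a perioperative registry; (2) take the
#' perioperative death probability from the registry's observed in-hospital
#' mortality; (3) calibrate the disease catalog so the two arms reproduce
#' the published annual DALY totals; (4) build the annualized incremental
#' cost ledger; (5) evaluate both arms and the incremental
#' cost-effectiveness ratio with threshold classification.
#'
#' The comparator arm's annual cost is a published total
#' (`soc_annual_cost`, default $117,514); its internal composition is not
#' modelled. The intervention arm costs the comparator plus the incremental
#' ledger total.
#'
#' @param registry Registry `data.frame`, or `NULL` to generate the default
#'   synthetic registry (1,068 cases, seeded by `seed`).
#' @param catalog A `"disease_catalog"`, or `NULL` for [default_catalog()].
#' @param costs Cost configuration list, see [default_costs()].
#' @param volumes Named annual treated volumes `c(soc =, or =)`.
#' @param discount Annual discount rate applied to future health.
#' @param life_expectancy Average life expectancy (years), used when the
#'   catalog is generated internally.
#' @param threshold Willingness-to-pay threshold, USD per DALY averted
#'   (default $1,043, half GDP per capita).
#' @param soc_annual_cost Comparator arm annual cost (USD).
#' @param calibration_targets Named annual DALY totals `c(soc =, or =)` the
#'   calibrated model must reproduce, or `NULL` to use the catalog as-is.
#' @param p_st Probability of successful treatment among survivors.
#' @param p_dbd Probability of death before discharge; default: the
#'   registry's observed in-hospital mortality.
#' @param seed Seed for the internally generated registry.
#' @return Object of class `"cea_model"` with components `arms` (both
#'   `"arm_result"`s), `ce` (the `"cea_result"`), `classification`,
#'   `ledger`, `catalog` (calibrated), `registry`, `treatment`, and the
#'   fitted configuration. Methods: `print`, `summary`, `simulate` (Monte
#'   Carlo probabilistic sensitivity analysis), [tornado()], [run_psa()].
#' @examples
#' m <- cea_model(seed = 1)
#' m
#' summary(m)
#' @export
cea_model <- function(registry = NULL, catalog = NULL,
                      costs = default_costs(),
                      volumes = c(soc = 226, or = 343),
                      discount = 0.03, life_expectancy = 54,
                      threshold = 1043, soc_annual_cost = 117514,
                      calibration_targets = c(soc = 840, or = 302),
                      p_st = 0.95, p_dbd = NULL, seed = 1L) {
  if (is.null(registry))
    registry <- generate_registry(registry_params(seed = seed))
  if (is.null(catalog)) catalog <- default_catalog(life_expectancy)
  validate_registry(registry, catalog)
  if (!all(c("soc", "or") %in% names(volumes)) ||
      volumes[["soc"]] >= volumes[["or"]])
    stopf("'volumes' must be c(soc =, or =) with soc < or")
  if (is.null(p_dbd)) p_dbd <- mean(registry$died_before_discharge)
  treatment <- treatment_params(p_dbd, p_st)

  if (!is.null(calibration_targets))
    catalog <- calibrate_catalog(catalog, registry, treatment, discount,
                                 target_soc = calibration_targets[["soc"]],
                                 target_or = calibration_targets[["or"]],
                                 volumes = volumes)

  n_inc <- volumes[["or"]] - volumes[["soc"]]
  ledger <- ledger_from_costs(costs, n_incremental_cases = n_inc)
  cost_components <- list(
    fixed = c(durable_equipment =
                sum(vapply(costs$durables, annualize, numeric(1))),
              shipping_installation = costs$shipping_installation,
              charity_overhead = costs$overhead,
              personnel = personnel_cost(costs$staff)),
    rates = unclass(costs$rates))

  soc <- evaluate_arm(
    scenario_spec("standard_of_care", volumes[["soc"]], soc_annual_cost,
                  treatment),
    registry, catalog, discount, demand_volume = volumes[["or"]])
  orr <- evaluate_arm(
    scenario_spec("pediatric_or", volumes[["or"]],
                  soc_annual_cost + attr(ledger, "total"), treatment),
    registry, catalog, discount, demand_volume = volumes[["or"]])
  ce <- icer(soc, orr)

  structure(list(arms = list(soc = soc, or = orr), ce = ce,
                 classification = classify_threshold(ce, threshold),
                 ledger = ledger, catalog = catalog, registry = registry,
                 treatment = treatment, discount = discount,
                 threshold = threshold, volumes = volumes,
                 soc_annual_cost = soc_annual_cost, costs = costs,
                 cost_components = cost_components, seed = seed),
            class = "cea_model")
}

#' Re-evaluate the model ICER under parameter overrides
#'
#' The re-evaluation engine behind the one-way and probabilistic
#' sensitivity analyses: recomputes both arms and the incremental results
#' with selected inputs replaced, everything else held at the fitted base
#' case. With no overrides it reproduces the base-case results exactly.
#'
#' Supported override names: `discount`, `life_expectancy`, `p_dbd`,
#' `p_st`, `soc_fraction` (comparator share of the intervention volume),
#' `or_volume`, the fixed cost components `durable_equipment`,
#' `shipping_installation`, `charity_overhead`, `personnel` (annual USD),
#' and the per-case rates `disposables_per_case`, `meds_per_case`,
#' `utilities_per_case`, `hospital_day_cost`, `mean_los_days`,
#' `oop_per_case`.
#'
#' @param model A fitted `"cea_model"`.
#' @param overrides Named list of replacement values.
#' @param registry,catalog Optional replacement registry / catalog (used by
#'   the probabilistic sensitivity analysis).
#' @return List with `delta_cost`, `dalys_averted`, `icer`, `soc_dalys`,
#'   `or_dalys`, `n_incremental`.
#' @export
icer_with <- function(model, overrides = list(), registry = NULL,
                      catalog = NULL) {
  known <- c("discount", "life_expectancy", "p_dbd", "p_st", "soc_fraction",
             "or_volume", "durable_equipment", "shipping_installation",
             "charity_overhead", "personnel", "disposables_per_case",
             "meds_per_case", "utilities_per_case", "hospital_day_cost",
             "mean_los_days", "oop_per_case")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stopf("unknown override parameter(s): %s", paste(bad, collapse = ", "))
  reg <- registry %||% model$registry
  cat0 <- catalog %||% model$catalog
  if (!is.null(overrides$life_expectancy))
    attr(cat0, "life_expectancy") <- overrides$life_expectancy
  disc <- overrides$discount %||% model$discount
  tp <- treatment_params(overrides$p_dbd %||% model$treatment$p_dbd,
                         overrides$p_st %||% model$treatment$p_st)
  orv <- overrides$or_volume %||% model$volumes[["or"]]
  frac <- overrides$soc_fraction %||%
    (model$volumes[["soc"]] / model$volumes[["or"]])
  check_prob(frac, "soc_fraction")
  socv <- frac * orv
  n_inc <- orv - socv
  if (n_inc <= 0) stopf("overrides leave no incremental caseload")

  f <- model$cost_components$fixed
  for (nm in intersect(names(overrides), names(f)))
    f[[nm]] <- overrides[[nm]]
  r <- model$cost_components$rates
  for (nm in intersect(names(overrides), names(r)))
    r[[nm]] <- overrides[[nm]]
  per_case <- r$disposables_per_case + r$meds_per_case +
    r$utilities_per_case + r$hospital_day_cost * r$mean_los_days +
    r$oop_per_case
  delta_cost <- sum(f) + per_case * n_inc

  t_bar <- mean(daly_treated(reg, cat0, tp, disc))
  u_bar <- mean(daly_untreated(reg, cat0, disc))
  averted <- n_inc * (u_bar - t_bar)
  list(delta_cost = delta_cost, dalys_averted = averted,
       icer = if (averted > 0) delta_cost / averted else NA_real_,
       soc_dalys = socv * t_bar + n_inc * u_bar,
       or_dalys = orv * t_bar,
       n_incremental = n_inc)
}

#' @export
print.cea_model <- function(x, ...) {
  soc <- x$arms$soc; orr <- x$arms$or; ce <- x$ce
  cat("Two-arm decision-tree cost-effectiveness model (annual)\n\n")
  tab <- data.frame(
    `Standard of care` = c(round_half_up(soc$expected_dalys),
                           round_half_up(soc$expected_cost)),
    `Pediatric OR` = c(round_half_up(orr$expected_dalys),
                       round_half_up(orr$expected_cost)),
    `Incremental` = c(-round_half_up(ce$dalys_averted),
                      round_half_up(ce$delta_cost)),
    check.names = FALSE,
    row.names = c("DALYs", "Total cost ($)"))
  print(format(tab, big.mark = ","))
  if (ce$classification == "tradeoff")
    cat(sprintf("\nICER: $%s per DALY averted",
                format(round_half_up(ce$icer), big.mark = ",")))
  else cat(sprintf("\nICER: %s", ce$classification))
  cat(sprintf(" [%s at a $%s/DALY threshold]\n",
              sub("_", "-", x$classification),
              format(x$threshold, big.mark = ",")))
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  structure(list(model = object), class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\n")
  print(m$ledger)
  cal <- attr(m$catalog, "calibration")
  if (!is.null(cal))
    cat(sprintf(paste0("\nCalibrated per-case burden: treated %.3f, ",
                       "untreated %.3f DALYs/case (severity scale %.3f, ",
                       "residual scale %.3f)\n"),
                cal$d_t, cal$d_u, cal$alpha, cal$beta))
  if (is.finite(m$ce$cost_per_life_saved))
    cat(sprintf("Cost per life saved: $%s (%.1f lives/yr)\n",
                format(round_half_up(m$ce$cost_per_life_saved),
                       big.mark = ","), m$ce$lives_saved))
  cat(sprintf("Discount rate %.0f%%, life expectancy %g y, registry n = %d\n",
              100 * m$discount, attr(m$catalog, "life_expectancy"),
              nrow(m$registry)))
  invisible(x)
}

#' Monte Carlo probabilistic sensitivity analysis of a fitted model
#'
#' `simulate()` on a `"cea_model"` runs [run_psa()]; `nsim` is the number
#' of Monte Carlo batches.
#'
#' @param object A fitted `"cea_model"`.
#' @param nsim Number of Monte Carlo batches.
#' @param seed Integer seed.
#' @param ... Passed on to [run_psa()].
#' @return A `"cea_psa"` object.
#' @export
simulate.cea_model <- function(object, nsim = 100, seed = NULL, ...) {
  run_psa(object, n_batches = nsim, seed = seed, ...)
}
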
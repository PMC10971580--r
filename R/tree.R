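#' Scenario specification for one decision-tree arm
#'
#' @param label Arm label (e.g. `"standard_of_care"`).
#' @param annual_volume Cases operated per year in this arm.
#' @param annual_cost Total annual cost of the arm (USD).
#' @param treatment A [treatment_params()] object.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(label, annual_volume, annual_cost, treatment) {
  if (!is.numeric(annual_volume) || length(annual_volume) != 1L ||
      is.na(annual_volume) || annual_volume < 0)
    stopf("'annual_volume' must be non-negative")
  check_nonneg(annual_cost, "annual_cost")
  if (!inherits(treatment, "treatment_params"))
    stopf("'treatment' must be built with treatment_params()")
  structure(list(label = label, annual_volume = annual_volume,
                 annual_cost = annual_cost, treatment = treatment),
            class = "scenario_spec")
}

# per-record probability of death on the treated branch: perioperative death
# or treatment failure followed by the natural-course death probability
treated_death_prob <- function(entry, treatment) {
  treatment$p_dbd + (1 - treatment$p_dbd) * (1 - treatment$p_st) *
    entry$p_death_untreated
}

#' Evaluate one decision-tree arm
#'
#' The demand registry represents the full annual surgical demand (the
#' intervention-arm volume); an arm treats `annual_volume` of
#' `demand_volume` cases and the remainder suffer the natural disease
#' course, so the fraction untreated is `pNoOR = 1 - volume/demand`. By
#' default (`method = "expected"`) the registry is used as an empirical
#' case-mix distribution and the arm is evaluated in expectation:
#' `volume * mean(daly_treated) + (demand - volume) * mean(daly_untreated)`,
#' which equals the exhaustive leaf-enumeration of the tree record by
#' record. `method = "draw"` instead assigns an explicit treated subset by a
#' seeded uniform draw (`method = "order"`: the first records in order),
#' requiring the registry size to equal the demand volume.
#'
#' @param spec A [scenario_spec()].
#' @param registry Demand registry `data.frame`.
#' @param catalog A `"disease_catalog"`.
#' @param discount Annual discount rate.
#' @param demand_volume Annual demand; defaults to `nrow(registry)`.
#' @param method Untreated-case selection: `"expected"`, `"draw"` or
#'   `"order"`.
#' @param seed Seed for `method = "draw"`.
#' @return Object of class `"arm_result"`: `expected_cost`,
#'   `expected_dalys`, `lives_saved`, plus the arm label and volumes.
#' @export
evaluate_arm <- function(spec, registry, catalog, discount = 0.03,
                         demand_volume = nrow(registry),
                         method = c("expected", "draw", "order"),
                         seed = NULL) {
  method <- match.arg(method)
  if (!inherits(spec, "scenario_spec"))
    stopf("'spec' must be built with scenario_spec()")
  validate_registry(registry, catalog)
  if (spec$annual_volume > demand_volume)
    stopf("arm volume (%g) exceeds annual demand (%g)",
          spec$annual_volume, demand_volume)
  treated <- daly_treated(registry, catalog, spec$treatment, discount)
  untreated <- daly_untreated(registry, catalog, discount)
  entry <- catalog_lookup(catalog, registry$diagnosis)
  p_dead_treated <- treated_death_prob(entry, spec$treatment)
  n_untreated <- demand_volume - spec$annual_volume
  if (method == "expected") {
    dalys <- spec$annual_volume * mean(treated) + n_untreated * mean(untreated)
    lives <- spec$annual_volume *
      (mean(entry$p_death_untreated) - mean(p_dead_treated))
  } else {
    if (nrow(registry) != demand_volume)
      stopf("method '%s' needs one registry record per demand case", method)
    idx <- if (method == "order") seq_len(spec$annual_volume) else
      with_seed(seed, sample.int(demand_volume, spec$annual_volume))
    sel <- seq_len(demand_volume) %in% idx
    dalys <- sum(treated[sel]) + sum(untreated[!sel])
    lives <- sum(entry$p_death_untreated[sel] - p_dead_treated[sel])
  }
  structure(list(label = spec$label, expected_cost = spec$annual_cost,
                 expected_dalys = dalys, lives_saved = lives,
                 annual_volume = spec$annual_volume,
                 demand_volume = demand_volume),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm '%s': %g/%g cases treated | cost $%s/yr | %.1f DALYs accrued | %.1f lives saved\n",
              x$label, x$annual_volume, x$demand_volume,
              format(round_half_up(x$expected_cost), big.mark = ","),
              x$expected_dalys, x$lives_saved))
  invisible(x)
}

#' Incremental cost-effectiveness of the intervention arm
#'
#' Computes the incremental cost, DALYs averted, the ICER (USD per DALY
#' averted), and cost per life saved of the intervention arm against the
#' comparator. Standard CEA dominance conventions apply: an intervention
#' that is no more costly and averts DALYs is `"dominant"` (no negative
#' ICER is reported); more costly and averting none is `"dominated"`; equal
#' effects yield an `"undefined"` classification rather than a division
#' error. No rounding is performed internally.
#'
#' @param soc Comparator (standard-of-care) `"arm_result"`.
#' @param orr Intervention `"arm_result"`.
#' @return Object of class `"cea_result"`.
#' @export
icer <- function(soc, orr) {
  delta_cost <- orr$expected_cost - soc$expected_cost
  averted <- soc$expected_dalys - orr$expected_dalys
  lives <- orr$lives_saved - soc$lives_saved
  ratio <- if (averted > 0 && delta_cost > 0) delta_cost / averted
           else NA_real_
  classification <-
    if (averted > 0 && delta_cost > 0) "tradeoff"
    else if (averted > 0) "dominant"
    else if (averted < 0 && delta_cost >= 0) "dominated"
    else "undefined"
  structure(list(delta_cost = delta_cost, dalys_averted = averted,
                 icer = ratio,
                 cost_per_life_saved = if (lives > 0) delta_cost / lives
                                       else NA_real_,
                 lives_saved = lives, classification = classification),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental cost-effectiveness\n")
  cat(sprintf("  incremental cost:  $%s per year\n",
              format(round_half_up(x$delta_cost), big.mark = ",")))
  cat(sprintf("  DALYs averted:     %.1f per year\n", x$dalys_averted))
  if (x$classification == "tradeoff") {
    cat(sprintf("  ICER:              $%s per DALY averted\n",
                format(round_half_up(x$icer), big.mark = ",")))
  } else {
    cat(sprintf("  ICER:              %s\n", x$classification))
  }
  if (is.finite(x$cost_per_life_saved))
    cat(sprintf("  cost per life saved: $%s (%.1f lives/yr)\n",
                format(round_half_up(x$cost_per_life_saved),
                       big.mark = ","), x$lives_saved))
  invisible(x)
}

#' Classify an ICER against a willingness-to-pay threshold
#'
#' Cost-effective iff the ICER is strictly below the threshold, or the
#' intervention is dominant (cost-saving and effective) outright.
#'
#' @param ce A `"cea_result"`.
#' @param threshold Willingness-to-pay in USD per DALY averted (positive);
#'   conventionally half the GDP per capita.
#' @return `"cost_effective"` or `"not_cost_effective"`.
#' @export
classify_threshold <- function(ce, threshold) {
  check_pos(threshold, "threshold")
  if (ce$classification == "dominant") return("cost_effective")
  if (ce$classification %in% c("dominated", "undefined"))
    return("not_cost_effective")
  if (ce$icer < threshold) "cost_effective" else "not_cost_effective"
}
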
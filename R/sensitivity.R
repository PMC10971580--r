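#' Uncertain-parameter specification
#'
#' Describes one uncertain model input for the probabilistic sensitivity
#' analysis: its base value, a plausible range, and the distribution family
#' it is drawn from (uniform over the range; beta or gamma moment-matched
#' so the sampler mean equals the base value and the 95% range spans
#' `low`-`high`; or an empirical resampling distribution over observed
#' per-case values). A zero-width range denotes a degenerate (fixed)
#' parameter.
#'
#' @param name Parameter name (an [icer_with()] override name, `"caseload"`,
#'   or a `"dw_untreated:<diagnosis>"` / `"dw_residual:<diagnosis>"`
#'   catalog field).
#' @param base_value Base-case value.
#' @param low,high Plausible range, `low <= base_value <= high`.
#' @param distribution `"uniform"`, `"beta"`, `"gamma"`, `"empirical"` or
#'   `"degenerate"`.
#' @param values Observed values for the empirical family.
#' @return Object of class `"param_spec"`.
#' @export
param_spec <- function(name, base_value, low = base_value,
                       high = base_value,
                       distribution = c("uniform", "beta", "gamma",
                                        "empirical", "degenerate"),
                       values = NULL) {
  distribution <- match.arg(distribution)
  if (!(low <= base_value && base_value <= high))
    stopf("'%s': need low <= base_value <= high (got %g, %g, %g)",
          name, low, base_value, high)
  if (distribution == "empirical" && is.null(values))
    stopf("'%s': empirical distribution needs 'values'", name)
  structure(list(name = name, base_value = base_value, low = low,
                 high = high, distribution = distribution, values = values),
            class = "param_spec")
}

#' Build a sampler for an uncertain parameter
#'
#' Returns a function of `n` drawing from the parameter's distribution
#' using the caller's RNG stream (seed management belongs to the caller, so
#' whole analyses are reproducible from one seed). Beta and gamma are
#' fitted by method of moments with mean equal to the base value and
#' standard deviation `(high - low) / 3.92` (the range read as a 95%
#' interval); uniform draws on `[low, high]` directly; a zero-width range
#' collapses to a constant. Infeasible moments (a variance the beta support
#' cannot carry) raise a fit error.
#'
#' @param p A [param_spec()].
#' @return A function `f(n)` returning `n` draws.
#' @export
build_distribution <- function(p) {
  if (!inherits(p, "param_spec"))
    stopf("'p' must be built with param_spec()")
  m <- p$base_value
  sdv <- (p$high - p$low) / 3.92
  if (p$distribution == "degenerate" ||
      (p$distribution != "empirical" && sdv == 0))
    return(function(n) rep(m, n))
  switch(p$distribution,
    uniform = {
      lo <- p$low; hi <- p$high
      function(n) stats::runif(n, lo, hi)
    },
    beta = {
      if (m <= 0 || m >= 1)
        stopf("'%s': beta fit needs a base value strictly inside (0, 1)",
              p$name)
      v <- sdv^2
      k <- m * (1 - m) / v - 1
      if (k <= 0)
        stopf("'%s': variance %.4g too large for the beta support at mean %.4g",
              p$name, v, m)
      a <- m * k; b <- (1 - m) * k
      function(n) stats::rbeta(n, a, b)
    },
    gamma = {
      if (m <= 0) stopf("'%s': gamma fit needs a positive mean", p$name)
      shape <- m^2 / sdv^2; rate <- m / sdv^2
      function(n) stats::rgamma(n, shape, rate)
    },
    empirical = {
      vals <- p$values
      function(n) vals[sample.int(length(vals), n, replace = TRUE)]
    })
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-evaluates the full model ICER with one parameter set to its low and
#' then its high endpoint, everything else at base. A model failure at an
#' endpoint is reported naming the parameter and endpoint.
#'
#' @param model A fitted `"cea_model"`.
#' @param name An [icer_with()] override name.
#' @param low,high Endpoint values.
#' @return One-row `data.frame`: `param`, `low`, `high`, `icer_low`,
#'   `icer_high`, `span`.
#' @export
one_way <- function(model, name, low, high) {
  at <- function(value, end) {
    res <- tryCatch(icer_with(model, stats::setNames(list(value), name)),
                    error = function(e)
                      stopf("one-way sweep of '%s' failed at the %s endpoint (%g): %s",
                            name, end, value, conditionMessage(e)))
    res$icer
  }
  icer_low <- at(low, "low")
  icer_high <- at(high, "high")
  data.frame(param = name, low = low, high = high, icer_low = icer_low,
             icer_high = icer_high, span = abs(icer_high - icer_low),
             stringsAsFactors = FALSE)
}

#' Default one-way sweep ranges
#'
#' The comparator volume share and the discount rate are swept over the
#' study's stated ranges (0-90% and 0-6%); perioperative mortality over the
#' observed elective-emergency span; remaining cost and demographic inputs
#' over +/-20%.
#'
#' @param model A fitted `"cea_model"`.
#' @return Named list of `c(low, high)` ranges.
#' @export
default_tornado_ranges <- function(model) {
  f <- model$cost_components$fixed
  r <- model$cost_components$rates
  le <- attr(model$catalog, "life_expectancy")
  list(soc_fraction = c(0, 0.90),
       discount = c(0, 0.06),
       life_expectancy = c(le - 10, le + 10),
       p_dbd = c(2 / 806, 16 / 242),
       durable_equipment = f[["durable_equipment"]] * c(0.8, 1.2),
       shipping_installation = f[["shipping_installation"]] * c(0.8, 1.2),
       charity_overhead = f[["charity_overhead"]] * c(0.8, 1.2),
       personnel = f[["personnel"]] * c(0.8, 1.2),
       hospital_day_cost = r$hospital_day_cost * c(0.8, 1.2),
       oop_per_case = r$oop_per_case * c(0.8, 1.2))
}

#' Tornado (one-way) sensitivity analysis
#'
#' Runs [one_way()] for each named range and returns the entries sorted by
#' decreasing ICER span, ready for a tornado diagram (see the `plot`
#' method).
#'
#' @param model A fitted `"cea_model"`.
#' @param ranges Named list of `c(low, high)` ranges; defaults to
#'   [default_tornado_ranges()].
#' @return `data.frame` of class `"cea_tornado"` with attribute
#'   `base_icer`.
#' @export
tornado <- function(model, ranges = default_tornado_ranges(model)) {
  rows <- lapply(names(ranges), function(nm)
    one_way(model, nm, ranges[[nm]][1], ranges[[nm]][2]))
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = model$ce$icer,
            class = c("cea_tornado", "data.frame"))
}

#' @export
plot.cea_tornado <- function(x, ...) {
  base <- attr(x, "base_icer")
  df <- x[nrow(x):1, , drop = FALSE]
  lo <- pmin(df$icer_low, df$icer_high)
  hi <- pmax(df$icer_low, df$icer_high)
  old <- graphics::par(mar = c(4.5, 11, 2.5, 1))
  on.exit(graphics::par(old))
  yy <- seq_len(nrow(df))
  graphics::plot(NA, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(df) + 0.5), yaxt = "n",
                 xlab = "ICER ($ per DALY averted)", ylab = "",
                 main = "One-way sensitivity (tornado)", ...)
  graphics::rect(lo, yy - 0.35, hi, yy + 0.35, col = "grey80")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = yy, labels = df$param, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Default uncertain-parameter set for the probabilistic analysis
#'
#' Mirrors the study's uncertainty table: annual caseload uniform on
#' 250-400; death-before-discharge, treatment success and every
#' disability weight as betas; equipment, shipping, personnel, disposables,
#' hospital-day and out-of-pocket costs as gammas; perioperative medication
#' cost as an empirical resampling distribution over a per-case cost sample
#' (represented by a deterministic gamma quantile grid at the base mean).
#' The death-before-discharge range spans the observed elective-emergency
#' mortality gap (the range the registry itself informs); the
#' treatment-success range is +/-0.2 absolute clipped to the unit
#' interval; disability-weight and cost ranges are +/-20% relative. All
#' families are moment-matched so every sampler's mean is its base-case
#' value.
#'
#' @param model A fitted `"cea_model"`.
#' @param caseload_range Annual caseload range for the uniform draw.
#' @param zero_variance If `TRUE`, every parameter is degenerate at its
#'   base value (the zero-variance limit of the analysis).
#' @return Named list of [param_spec()]s.
#' @export
psa_specs <- function(model, caseload_range = c(250, 400),
                      zero_variance = FALSE) {
  f <- model$cost_components$fixed
  r <- model$cost_components$rates
  orv <- model$volumes[["or"]]
  prob_range <- function(b) c(max(0, b - 0.2), min(1, b + 0.2))
  rel_range <- function(b) b * c(0.8, 1.2)
  dbd_range <- c(min(2 / 806, model$treatment$p_dbd),
                 max(16 / 242, model$treatment$p_dbd))
  specs <- list()
  add <- function(name, base, range, dist, values = NULL) {
    if (zero_variance) {
      range <- c(base, base)
      if (!is.null(values)) values <- base
      if (dist != "empirical") dist <- "degenerate"
    }
    specs[[name]] <<- param_spec(name, base, range[1], range[2], dist,
                                 values = values)
  }
  add("caseload", orv,
      if (zero_variance) c(orv, orv) else caseload_range, "uniform")
  add("p_dbd", model$treatment$p_dbd, dbd_range, "beta")
  add("p_st", model$treatment$p_st, prob_range(model$treatment$p_st), "beta")
  for (i in seq_len(nrow(model$catalog))) {
    dx <- model$catalog$diagnosis[i]
    if (model$catalog$dw_untreated[i] > 0)
      add(paste0("dw_untreated:", dx), model$catalog$dw_untreated[i],
          pmin(rel_range(model$catalog$dw_untreated[i]), 1), "beta")
    if (model$catalog$dw_residual[i] > 0)
      add(paste0("dw_residual:", dx), model$catalog$dw_residual[i],
          pmin(rel_range(model$catalog$dw_residual[i]), 1), "beta")
  }
  add("durable_equipment", f[["durable_equipment"]],
      rel_range(f[["durable_equipment"]]), "gamma")
  add("shipping_installation", f[["shipping_installation"]],
      rel_range(f[["shipping_installation"]]), "gamma")
  add("personnel", f[["personnel"]], rel_range(f[["personnel"]]), "gamma")
  add("disposables_per_case", r$disposables_per_case,
      rel_range(r$disposables_per_case), "gamma")
  add("hospital_day_cost", r$hospital_day_cost,
      rel_range(r$hospital_day_cost), "gamma")
  add("oop_per_case", r$oop_per_case, rel_range(r$oop_per_case), "gamma")
  # per-case medication costs resampled from a fixed empirical grid whose
  # mean is the base rate (gamma quantiles, deterministic by construction)
  med_values <- stats::qgamma(stats::ppoints(200), shape = 2,
                              rate = 2 / r$meds_per_case)
  med_values <- med_values * r$meds_per_case / mean(med_values)
  add("meds_per_case", r$meds_per_case, rel_range(r$meds_per_case),
      "empirical", values = med_values)
  specs
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Propagates parameter uncertainty through the fitted model over
#' `n_batches` Monte Carlo batches. Each batch simulates a new year of
#' service: the annual caseload is drawn (uniform 250-400 by default) and
#' that many cases are resampled with replacement from the model registry
#' to supply the year's empirical case mix and ages; every other uncertain
#' parameter is drawn from its assigned distribution; both arms are
#' re-evaluated and the
#' incremental triple (cost, DALYs averted, ICER) recorded. The decision
#' volumes stay at the fitted annual throughputs unless
#' `scale_volumes = TRUE`, in which case the intervention volume tracks the
#' drawn caseload. When the caseload specification is degenerate the
#' model's own registry is reused, so a fully degenerate parameter set
#' reproduces the base case exactly.
#'
#' The headline simulation ICER is the ratio of the mean incremental cost
#' to the mean DALYs averted; the mean of per-batch ratios is also
#' reported. The 95% uncertainty interval is a percentile bootstrap of the
#' mean per-batch ICER ([bootstrap_ui()]). The whole analysis, bootstrap
#' included, is reproducible from `seed`.
#'
#' @param model A fitted `"cea_model"`.
#' @param n_batches Number of Monte Carlo batches.
#' @param seed Integer seed.
#' @param specs Named list of [param_spec()]s; defaults to [psa_specs()].
#' @param scale_volumes Should the arm volumes track the drawn caseload?
#' @param n_boot Bootstrap replicates for the uncertainty interval.
#' @param level Uncertainty-interval level.
#' @return Object of class `"cea_psa"`: per-batch `samples`, `mean_icer`
#'   (ratio of means), `icer_mean_of_ratios`, `ui95`,
#'   `mean_dalys_averted`, `mean_delta_cost`, `prob_cost_effective`,
#'   `n_failed`.
#' @export
run_psa <- function(model, n_batches = 100, seed = NULL,
                    specs = psa_specs(model), scale_volumes = FALSE,
                    n_boot = 100, level = 0.95) {
  if (n_batches < 1) stopf("'n_batches' must be at least 1")
  samplers <- lapply(specs, build_distribution)
  cl_spec <- specs[["caseload"]]
  fixed_registry <- is.null(cl_spec) || cl_spec$low == cl_spec$high
  with_seed(seed, {
    rows <- vector("list", n_batches)
    failures <- 0L
    for (b in seq_len(n_batches)) {
      rows[[b]] <- tryCatch({
        n_b <- if (is.null(cl_spec)) model$volumes[["or"]] else
          max(1L, round(samplers[["caseload"]](1)))
        registry_b <- if (fixed_registry) model$registry else
          model$registry[sample.int(nrow(model$registry), n_b,
                                    replace = TRUE), , drop = FALSE]
        catalog_b <- model$catalog
        overrides <- list()
        for (nm in names(specs)) {
          if (nm == "caseload") next
          value <- if (specs[[nm]]$distribution == "empirical")
            mean(samplers[[nm]](n_b)) else samplers[[nm]](1)
          if (grepl("^dw_", nm)) {
            parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
            i <- match(parts[2], catalog_b$diagnosis)
            catalog_b[[parts[1]]][i] <- value
          } else {
            overrides[[nm]] <- value
          }
        }
        # keep the residual weight physical after independent draws
        catalog_b$dw_residual <- pmin(catalog_b$dw_residual,
                                      catalog_b$dw_untreated)
        if (scale_volumes) overrides$or_volume <- n_b
        res <- icer_with(model, overrides, registry = registry_b,
                         catalog = catalog_b)
        data.frame(batch = b, caseload = n_b, delta_cost = res$delta_cost,
                   dalys_averted = res$dalys_averted, icer = res$icer,
                   soc_dalys = res$soc_dalys, or_dalys = res$or_dalys)
      }, error = function(e) {
        warning(sprintf("PSA batch %d failed and was excluded: %s", b,
                        conditionMessage(e)), call. = FALSE)
        failures <<- failures + 1L
        NULL
      })
    }
    samples <- do.call(rbind, rows)
    if (is.null(samples) || nrow(samples) == 0L)
      stopf("every PSA batch failed")
    ok <- is.finite(samples$icer)
    mean_icer <- mean(samples$delta_cost) / mean(samples$dalys_averted)
    ui <- if (sum(ok) >= 2)
      bootstrap_ui(samples$icer[ok], n_boot = n_boot, level = level)
    else c(low = NA_real_, high = NA_real_)
    ce_flags <- (samples$dalys_averted > 0 & samples$delta_cost <= 0) |
      (ok & samples$icer < model$threshold)
    structure(list(samples = samples, mean_icer = mean_icer,
                   icer_mean_of_ratios = mean(samples$icer[ok]),
                   ui95 = ui,
                   mean_dalys_averted = mean(samples$dalys_averted),
                   mean_delta_cost = mean(samples$delta_cost),
                   mean_soc_dalys = mean(samples$soc_dalys),
                   mean_or_dalys = mean(samples$or_dalys),
                   prob_cost_effective = mean(ce_flags),
                   threshold = model$threshold, n_failed = failures,
                   seed = seed),
              class = "cea_psa")
  })
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis (%d batches%s)\n",
              nrow(x$samples),
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  cat(sprintf("  simulation ICER: $%.0f per DALY averted (95%% UI %.0f-%.0f)\n",
              x$mean_icer, x$ui95[1], x$ui95[2]))
  cat(sprintf("  mean of per-batch ICERs: $%.0f\n", x$icer_mean_of_ratios))
  cat(sprintf("  mean incremental: $%s, %.0f DALYs averted per year\n",
              format(round_half_up(x$mean_delta_cost), big.mark = ","),
              x$mean_dalys_averted))
  cat(sprintf("  P(cost-effective at $%s/DALY) = %.2f\n",
              format(x$threshold, big.mark = ","), x$prob_cost_effective))
  invisible(x)
}

#' Percentile bootstrap uncertainty interval for a mean ICER
#'
#' Resamples the per-batch ICERs with replacement, takes the mean of each
#' resample, and returns the percentile interval of those means.
#'
#' @param samples Numeric vector of per-batch ICERs (or a `"cea_psa"`
#'   object, whose finite ICERs are used). At least two values.
#' @param n_boot Number of bootstrap resamples (at least 2).
#' @param level Interval level.
#' @param seed Optional seed; by default the caller's RNG stream is used.
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_ui <- function(samples, n_boot = 100, level = 0.95, seed = NULL) {
  if (inherits(samples, "cea_psa"))
    samples <- samples$samples$icer[is.finite(samples$samples$icer)]
  if (!is.numeric(samples) || length(samples) < 2L)
    stopf("bootstrap needs at least 2 samples")
  if (n_boot < 2) stopf("'n_boot' must be at least 2")
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i)
      mean(sample(samples, replace = TRUE)), numeric(1))
    q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    c(low = q[1], high = q[2])
  })
}

#' Cost-effectiveness plane
#'
#' Plot-ready table of the per-batch incremental points
#' `(dalys_averted, delta_cost)`, with the simulation ICER ray slope and
#' the willingness-to-pay ray slope attached; the fraction of points on or
#' under the threshold ray is the probability of cost-effectiveness.
#'
#' @param psa A `"cea_psa"` object or a `data.frame` with columns
#'   `dalys_averted` and `delta_cost`.
#' @param threshold Willingness-to-pay (USD per DALY averted).
#' @return `data.frame` of class `"ce_plane"` with columns
#'   `dalys_averted`, `delta_cost`, `below_threshold`; attributes
#'   `icer_slope`, `threshold_slope`, `prob_cost_effective`.
#' @export
ce_plane <- function(psa, threshold) {
  check_pos(threshold, "threshold")
  df <- if (inherits(psa, "cea_psa")) psa$samples else psa
  if (!is.data.frame(df) || nrow(df) == 0L)
    stopf("no samples to place on the cost-effectiveness plane")
  df <- df[is.finite(df$dalys_averted) & is.finite(df$delta_cost), ,
           drop = FALSE]
  if (nrow(df) == 0L)
    stopf("no finite samples to place on the cost-effectiveness plane")
  below <- df$delta_cost <= threshold * df$dalys_averted
  out <- data.frame(dalys_averted = df$dalys_averted,
                    delta_cost = df$delta_cost, below_threshold = below)
  structure(out,
            icer_slope = mean(df$delta_cost) / mean(df$dalys_averted),
            threshold_slope = threshold,
            prob_cost_effective = mean(below),
            class = c("ce_plane", "data.frame"))
}

#' @export
plot.cea_psa <- function(x, threshold = x$threshold, ...) {
  pl <- ce_plane(x, threshold)
  graphics::plot(pl$dalys_averted, pl$delta_cost,
                 xlim = range(0, pl$dalys_averted),
                 ylim = range(0, pl$delta_cost),
                 xlab = "DALYs averted per year",
                 ylab = "Incremental cost ($ per year)",
                 main = "Cost-effectiveness plane", pch = 16,
                 col = "grey40", ...)
  graphics::abline(0, attr(pl, "icer_slope"), col = "grey30")
  graphics::abline(0, attr(pl, "threshold_slope"), col = "grey60", lty = 3)
  graphics::legend("bottomright",
                   legend = c(sprintf("ICER ray ($%.0f/DALY)",
                                      attr(pl, "icer_slope")),
                              sprintf("threshold ($%.0f/DALY)", threshold)),
                   lty = c(1, 3), col = c("grey30", "grey60"), bty = "n")
  invisible(x)
}
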
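test_that("method-of-moments samplers recover their target means within 3 SE at n = 10,000", {
  n <- 10000
  cases <- list(
    list(spec = param_spec("u", 325, 250, 400, "uniform"), mean = 325,
         sd = (400 - 250) / sqrt(12)),
    list(spec = param_spec("b", 0.017, 0, 0.217, "beta"), mean = 0.017,
         sd = 0.217 / 3.92),
    list(spec = param_spec("g", 57435, 0.8 * 57435, 1.2 * 57435, "gamma"),
         mean = 57435, sd = 0.4 * 57435 / 3.92))
  for (cs in cases) {
    draw <- build_distribution(cs$spec)
    x <- pedorcea:::with_seed(101, draw(n))
    expect_lt(abs(mean(x) - cs$mean), 3 * cs$sd / sqrt(n))
  }
})

test_that("beta samples respect the unit support even for a near-zero mean with a wide range", {
  draw <- build_distribution(param_spec("p", 0.017, 0, 0.217, "beta"))
  x <- pedorcea:::with_seed(5, draw(5000))
  expect_true(all(x >= 0 & x <= 1))
})

test_that("degenerate and empirical samplers behave as specified", {
  d <- build_distribution(param_spec("c", 7, 7, 7, "gamma"))
  expect_identical(d(4), rep(7, 4))
  e <- build_distribution(param_spec("m", 2, values = c(2, 4, 6),
                                     distribution = "empirical"))
  x <- pedorcea:::with_seed(1, e(500))
  expect_true(all(x %in% c(2, 4, 6)))
  # a single-value empirical distribution is constant, whatever the value
  e1 <- build_distribution(param_spec("m", 83, values = 83,
                                      distribution = "empirical"))
  expect_identical(pedorcea:::with_seed(1, e1(10)), rep(83, 10))
})

test_that("infeasible moment fits raise errors naming the parameter", {
  expect_error(build_distribution(param_spec("p", 0.5, -3, 3.5, "beta")),
               "variance")
  expect_error(build_distribution(param_spec("z", 0, 0, 1, "beta")),
               "beta")
  expect_error(param_spec("x", 5, 6, 7), "low")
})

test_that("one-way sweeps report endpoint ICERs, spans, and failures by name", {
  m <- cea_model(seed = 1)
  # a zero-width sweep leaves the ICER untouched
  inert <- one_way(m, "mean_los_days", m$cost_components$rates$mean_los_days,
                   m$cost_components$rates$mean_los_days)
  expect_equal(inert$span, 0)
  expect_equal(inert$icer_low, m$ce$icer, tolerance = 1e-12)
  disc <- one_way(m, "discount", 0, 0.06)
  expect_gt(disc$span, 0)
  expect_equal(disc$span, abs(disc$icer_high - disc$icer_low))
  expect_error(one_way(m, "soc_fraction", 0, 1), "soc_fraction")
})

test_that("the discount sweep rises over 0-6% and brackets the base-case ICER", {
  m <- cea_model(seed = 1)
  rates <- seq(0, 0.06, by = 0.01)
  icers <- vapply(rates, function(r)
    icer_with(m, list(discount = r))$icer, numeric(1))
  expect_true(all(diff(icers) > 0))
  expect_lt(icers[1], m$ce$icer)
  expect_gt(icers[length(icers)], m$ce$icer)
})

test_that("the tornado is sorted by span and led by the comparator volume share", {
  m <- cea_model(seed = 1)
  torn <- tornado(m)
  expect_true(all(diff(torn$span) <= 0))
  expect_identical(torn$param[1], "soc_fraction")
  expect_true("discount" %in% torn$param)
  # every entry's span matches its endpoints
  expect_equal(torn$span, abs(torn$icer_high - torn$icer_low))
})

test_that("the probabilistic analysis is reproducible from its seed, bootstrap included", {
  m <- cea_model(seed = 1)
  p1 <- run_psa(m, n_batches = 30, seed = 77)
  p2 <- run_psa(m, n_batches = 30, seed = 77)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$ui95, p2$ui95)
  p3 <- run_psa(m, n_batches = 30, seed = 78)
  expect_false(identical(p1$samples, p3$samples))
})

test_that("a zero-variance probabilistic analysis collapses to the base case exactly", {
  m <- cea_model(seed = 1)
  pz <- run_psa(m, n_batches = 10, seed = 3,
                specs = psa_specs(m, zero_variance = TRUE))
  expect_equal(unique(pz$samples$icer), m$ce$icer, tolerance = 1e-12)
  expect_equal(pz$mean_icer, m$ce$icer, tolerance = 1e-12)
  expect_equal(unique(pz$samples$dalys_averted), m$ce$dalys_averted,
               tolerance = 1e-9)
})

test_that("simulate() on the model runs the probabilistic analysis", {
  m <- cea_model(seed = 1)
  p <- simulate(m, nsim = 15, seed = 2)
  expect_s3_class(p, "cea_psa")
  expect_identical(nrow(p$samples), 15L)
  expect_identical(p$samples, run_psa(m, 15, seed = 2)$samples)
})

test_that("bootstrap intervals are percentile-based, degenerate for constant input, and guarded", {
  expect_error(bootstrap_ui(5), "at least 2")
  expect_error(bootstrap_ui(c(1, 2), n_boot = 1), "n_boot")
  ui <- bootstrap_ui(rep(42, 20), seed = 1)
  expect_equal(unname(ui), c(42, 42))
  x <- pedorcea:::with_seed(9, stats::rnorm(200, 100, 10))
  ui2 <- bootstrap_ui(x, n_boot = 500, seed = 2)
  expect_lt(ui2[["low"]], mean(x))
  expect_gt(ui2[["high"]], mean(x))
  # width of the interval on the mean shrinks roughly like the SE
  expect_lt(ui2[["high"]] - ui2[["low"]], 6 * stats::sd(x) / sqrt(200))
})

test_that("the cost-effectiveness plane classifies points against the threshold ray", {
  df <- data.frame(dalys_averted = c(10, 10, -1),
                   delta_cost = c(500, 20000, 100))
  pl <- ce_plane(df, threshold = 1043)
  expect_identical(pl$below_threshold, c(TRUE, FALSE, FALSE))
  expect_equal(attr(pl, "prob_cost_effective"), 1 / 3)
  expect_equal(attr(pl, "threshold_slope"), 1043)
  all_in <- ce_plane(data.frame(dalys_averted = c(5, 8),
                                delta_cost = c(100, 300)), 1043)
  expect_equal(attr(all_in, "prob_cost_effective"), 1)
  expect_error(ce_plane(df[0, ], 1043), "samples")
})

test_that("the calibrated simulation clusters under the threshold ray", {
  m <- cea_model(seed = 1)
  p <- run_psa(m, n_batches = 40, seed = 11)
  pl <- ce_plane(p, m$threshold)
  expect_gt(attr(pl, "prob_cost_effective"), 0.9)
  expect_equal(attr(pl, "icer_slope"), p$mean_icer)
})
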
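test_that("arm evaluation matches the exhaustive leaf-enumeration oracle on small registries", {
  tp <- treatment_params(0.05, 0.9)
  for (n in c(1, 7, 20)) {
    reg <- tiny_registry(n, ages = seq(0.5, 16, length.out = n))
    cat1 <- tiny_catalog()
    for (vol in unique(c(0, floor(n / 2), n))) {
      spec <- scenario_spec("arm", vol, 1000, tp)
      arm <- evaluate_arm(spec, reg, cat1, 0.03)
      oracle <- leaf_enum_dalys(reg, cat1, tp, 0.03, p_no_or = 1 - vol / n)
      expect_equal(arm$expected_dalys, oracle, tolerance = 1e-9)
    }
  }
})

test_that("explicit treated-subset selection agrees with the expectation form on average", {
  n <- 12
  reg <- tiny_registry(n)
  cat1 <- tiny_catalog()
  tp <- treatment_params(0.02, 0.95)
  spec <- scenario_spec("arm", 7, 1000, tp)
  by_order <- evaluate_arm(spec, reg, cat1, 0.03, method = "order")
  manual <- sum(daly_treated(reg[1:7, ], cat1, tp, 0.03)) +
    sum(daly_untreated(reg[8:12, ], cat1, 0.03))
  expect_equal(by_order$expected_dalys, manual, tolerance = 1e-12)
  by_draw <- evaluate_arm(spec, reg, cat1, 0.03, method = "draw", seed = 4)
  expect_equal(by_draw$expected_dalys,
               evaluate_arm(spec, reg, cat1, 0.03, method = "draw",
                            seed = 4)$expected_dalys)
  expect_error(evaluate_arm(scenario_spec("arm", 13, 0, tp), reg, cat1,
                            0.03), "demand")
})

test_that("a fully treated arm with a zero-burden catalog accrues nothing", {
  reg <- tiny_registry(5)
  cat0 <- disease_catalog(data.frame(
    diagnosis = c("hernia", "atresia"), p_death_untreated = 0,
    dw_untreated = 0, dw_residual = 0, p_residual_after_success = 0,
    residual_convention = "lifelong_disability"), 54)
  arm <- evaluate_arm(scenario_spec("or", 5, 0, treatment_params(0, 1)),
                      reg, cat0, 0.03)
  expect_equal(arm$expected_dalys, 0)
  expect_equal(arm$lives_saved, 0)
})

test_that("ICER arithmetic reproduces the published base case from Table-4 arm values", {
  soc <- structure(list(label = "soc", expected_cost = 117514,
                        expected_dalys = 840, lives_saved = 0),
                   class = "arm_result")
  orr <- structure(list(label = "or", expected_cost = 295041,
                        expected_dalys = 302, lives_saved = 0),
                   class = "arm_result")
  ce <- icer(soc, orr)
  expect_equal(ce$delta_cost, 177527)
  expect_equal(ce$dalys_averted, 538)
  expect_equal(round_half_up(ce$icer), 330)
  expect_identical(ce$classification, "tradeoff")
  expect_identical(classify_threshold(ce, 1043), "cost_effective")
})

test_that("dominance and undefined-ICER conventions follow standard CEA practice", {
  arm <- function(cost, dalys) structure(
    list(label = "x", expected_cost = cost, expected_dalys = dalys,
         lives_saved = 0), class = "arm_result")
  same <- icer(arm(100, 50), arm(100, 50))
  expect_identical(same$classification, "undefined")
  expect_true(is.na(same$icer))
  expect_identical(classify_threshold(same, 1000), "not_cost_effective")

  dom <- icer(arm(1000, 50), arm(900, 40))   # cheaper and more effective
  expect_identical(dom$classification, "dominant")
  expect_true(is.na(dom$icer))               # never a negative ICER
  expect_identical(classify_threshold(dom, 1), "cost_effective")

  bad <- icer(arm(100, 40), arm(200, 50))    # dearer, fewer DALYs averted
  expect_identical(bad$classification, "dominated")
  expect_identical(classify_threshold(bad, 1e6), "not_cost_effective")
})

test_that("threshold classification is strict at the boundary", {
  arm <- function(cost, dalys) structure(
    list(label = "x", expected_cost = cost, expected_dalys = dalys,
         lives_saved = 0), class = "arm_result")
  ce <- icer(arm(0, 1043), arm(1043, 1042))  # ICER exactly 1,043
  expect_equal(ce$icer, 1043)
  expect_identical(classify_threshold(ce, 1043), "not_cost_effective")
  expect_identical(classify_threshold(ce, 1044), "cost_effective")
})

test_that("identical arms give zero incremental cost and effect", {
  reg <- tiny_registry(10)
  cat1 <- tiny_catalog()
  tp <- treatment_params(0.02, 0.9)
  spec <- scenario_spec("a", 6, 5000, tp)
  a <- evaluate_arm(spec, reg, cat1, 0.03)
  ce <- icer(a, a)
  expect_equal(ce$delta_cost, 0)
  expect_equal(ce$dalys_averted, 0)
})

test_that("the fitted base-case model reproduces the published Table-4 row", {
  m <- cea_model(seed = 1)
  expect_equal(m$arms$soc$expected_dalys, 840, tolerance = 1e-6)
  expect_equal(m$arms$or$expected_dalys, 302, tolerance = 1e-6)
  expect_equal(m$ce$dalys_averted, 538, tolerance = 1e-6)
  expect_lt(abs(m$ce$delta_cost - 177527), 1.5)
  expect_equal(round_half_up(m$ce$icer), 330)
  expect_identical(m$classification, "cost_effective")
  expect_lt(abs(m$arms$or$expected_cost - 295041), 2)
})

test_that("shrinking the comparator share towards full coverage raises the ICER", {
  m <- cea_model(seed = 1)
  fracs <- seq(0.1, 0.9, by = 0.1)
  icers <- vapply(fracs, function(f)
    icer_with(m, list(soc_fraction = f))$icer, numeric(1))
  expect_true(all(diff(icers) > 0))
})
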
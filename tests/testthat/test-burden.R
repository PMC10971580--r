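test_that("remaining life subtracts age from life expectancy and rejects the boundary", {
  cat54 <- tiny_catalog()
  expect_equal(remaining_life(3.84, cat54), 50.16)
  expect_equal(remaining_life(0, cat54), 54)
  expect_error(remaining_life(54, cat54), "life expectancy")
})

test_that("discounting matches the closed form, its limits and monotonicity", {
  expect_identical(discounted_years(10, 0), 10)
  expect_equal(discounted_years(50.16, 0.03), 25.93, tolerance = 1e-3)
  expect_equal(discounted_years(50.16, 0.03), 25.931276609,
               tolerance = 1e-9)
  expect_identical(discounted_years(0, 0.05), 0)
  # continuity at r -> 0
  expect_equal(discounted_years(37, 1e-9), 37, tolerance = 1e-6)
  # strictly decreasing in the rate, strictly below L for r > 0
  rates <- c(0.01, 0.02, 0.03, 0.05, 0.08)
  vals <- vapply(rates, function(r) discounted_years(50, r), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 50))
  expect_error(discounted_years(-1, 0.03), "L")
  expect_error(discounted_years(10, -0.01), "rate")
})

test_that("untreated burden is the probability mix of death and disabled survival", {
  cat1 <- disease_catalog(data.frame(
    diagnosis = c("fatal", "silent", "mixed"),
    p_death_untreated = c(1, 0, 0.5),
    dw_untreated = c(0, 0, 0.5),
    dw_residual = 0, p_residual_after_success = 0,
    residual_convention = "lifelong_disability"), life_expectancy = 54)
  rec <- function(dx) data.frame(age_years = 3.84, sex = "male",
                                 diagnosis = dx, urgency = "elective",
                                 died_before_discharge = FALSE, oop_cost = 0)
  expect_equal(daly_untreated(rec("fatal"), cat1, 0.03), 25.931276609,
               tolerance = 1e-9)
  expect_equal(daly_untreated(rec("silent"), cat1, 0.03), 0)
  expect_equal(daly_untreated(rec("mixed"), cat1, 0.03),
               0.75 * 25.931276609, tolerance = 1e-9)
  expect_error(daly_untreated(rec("unknown"), cat1, 0.03), "catalog")
})

test_that("treated burden covers full cure, certain perioperative death, and the linear mix", {
  cat1 <- disease_catalog(data.frame(
    diagnosis = "dx", p_death_untreated = 0.8, dw_untreated = 0.4,
    dw_residual = 0, p_residual_after_success = 0,
    residual_convention = "lifelong_disability"), life_expectancy = 54)
  rec <- data.frame(age_years = 3.84, sex = "male", diagnosis = "dx",
                    urgency = "elective", died_before_discharge = FALSE,
                    oop_cost = 0)
  expect_equal(daly_treated(rec, cat1, treatment_params(0, 1), 0.03), 0)
  expect_equal(daly_treated(rec, cat1, treatment_params(1, 1), 0.03),
               25.931276609, tolerance = 1e-9)
  expect_equal(daly_treated(rec, cat1, treatment_params(0.017, 1), 0.03),
               0.017 * 25.931276609, tolerance = 1e-9)
})

test_that("per-record burdens equal the exhaustive leaf-enumeration of the tree", {
  for (conv in c("lifelong_disability", "death_within_year")) {
    cat1 <- tiny_catalog(convention = conv)
    reg <- tiny_registry(8, ages = c(0, 1, 2.5, 4, 7, 9.5, 13, 17.9))
    tp <- treatment_params(0.05, 0.9)
    for (disc in c(0, 0.03)) {
      # p_no_or = 1: every case untreated; p_no_or = 0: every case treated
      expect_equal(sum(daly_untreated(reg, cat1, disc)),
                   leaf_enum_dalys(reg, cat1, tp, disc, p_no_or = 1),
                   tolerance = 1e-12)
      expect_equal(sum(daly_treated(reg, cat1, tp, disc)),
                   leaf_enum_dalys(reg, cat1, tp, disc, p_no_or = 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("averted burden is non-negative, zero in the no-benefit case, and monotone in p_dbd", {
  cat1 <- tiny_catalog()
  reg <- tiny_registry(6)
  tp <- treatment_params(0.017, 0.95)
  expect_true(all(dalys_averted(reg, cat1, tp, 0.03) >= 0))
  # untreated certain death vs full cure recovers the discounted years
  cat2 <- disease_catalog(data.frame(
    diagnosis = "hernia", p_death_untreated = 1, dw_untreated = 0,
    dw_residual = 0, p_residual_after_success = 0,
    residual_convention = "lifelong_disability"), 54)
  rec <- tiny_registry(1, ages = 3.84); rec$diagnosis <- "hernia"
  expect_equal(dalys_averted(rec, cat2, treatment_params(0, 1), 0.03),
               25.931276609, tolerance = 1e-9)
  # no-benefit: treatment outcomes identical to natural course
  cat3 <- disease_catalog(data.frame(
    diagnosis = "hernia", p_death_untreated = 0.3, dw_untreated = 0.5,
    dw_residual = 0.5, p_residual_after_success = 1,
    residual_convention = "lifelong_disability"), 54)
  # certain failure with no perioperative risk puts the treated branch on
  # the natural course exactly
  expect_equal(dalys_averted(rec, cat3, treatment_params(0, 0), 0.03), 0,
               tolerance = 1e-12)
  # treated burden nondecreasing, averted nonincreasing in p_dbd
  grid <- seq(0, 1, by = 0.1)
  tr <- vapply(grid, function(p)
    daly_treated(rec, cat1, treatment_params(p, 0.95), 0.03), numeric(1))
  expect_true(all(diff(tr) >= 0))
  av <- vapply(grid, function(p)
    dalys_averted(rec, cat1, treatment_params(p, 0.95), 0.03), numeric(1))
  expect_true(all(diff(av) <= 0))
})

test_that("catalog calibration solves the published per-case burdens and recovers the targets", {
  reg <- generate_registry(registry_params(seed = 1))
  tp <- treatment_params(mean(reg$died_before_discharge), 0.95)
  cal <- calibrate_catalog(default_catalog(), reg, tp, 0.03,
                           target_soc = 840, target_or = 302,
                           volumes = c(soc = 226, or = 343))
  info <- attr(cal, "calibration")
  expect_equal(info$d_t, 302 / 343, tolerance = 1e-12)
  expect_equal(info$d_u, (840 - 226 * 302 / 343) / 117, tolerance = 1e-12)
  expect_equal(round(info$d_t, 3), 0.880)
  expect_equal(round(info$d_u, 2), 5.48)
  # re-evaluating both arms on the same registry reproduces the targets
  t_bar <- mean(daly_treated(reg, cal, tp, 0.03))
  u_bar <- mean(daly_untreated(reg, cal, 0.03))
  expect_equal(226 * t_bar + 117 * u_bar, 840, tolerance = 0.005 * 840)
  expect_equal(343 * t_bar, 302, tolerance = 0.005 * 302)
})

test_that("calibrating to the model's own output is the identity", {
  reg <- tiny_registry(10)
  cat1 <- tiny_catalog()
  tp <- treatment_params(0.02, 0.9)
  t_bar <- mean(daly_treated(reg, cat1, tp, 0.03))
  u_bar <- mean(daly_untreated(reg, cat1, 0.03))
  cal <- calibrate_catalog(cat1, reg, tp, 0.03,
                           target_soc = 226 * t_bar + 117 * u_bar,
                           target_or = 343 * t_bar,
                           volumes = c(soc = 226, or = 343))
  info <- attr(cal, "calibration")
  expect_equal(info$alpha, 1, tolerance = 1e-9)
  expect_equal(info$beta, 1, tolerance = 1e-9)
  expect_equal(cal$p_death_untreated, cat1$p_death_untreated,
               tolerance = 1e-9)
  expect_equal(cal$p_residual_after_success,
               cat1$p_residual_after_success, tolerance = 1e-9)
})

test_that("infeasible calibration targets raise calibration errors", {
  reg <- tiny_registry(10)
  cat1 <- tiny_catalog()
  tp <- treatment_params(0.02, 0.9)
  # untreated burden beyond certain death over the full remaining life
  expect_error(
    calibrate_catalog(cat1, reg, tp, 0.03, target_soc = 117 * 60 * 54,
                      target_or = 302, volumes = c(soc = 226, or = 343)),
    "infeasible")
  # treated target below the floor set by perioperative mortality
  expect_error(
    calibrate_catalog(cat1, reg, treatment_params(0.5, 0.9), 0.03,
                      target_soc = 840, target_or = 1,
                      volumes = c(soc = 226, or = 343)),
    "infeasible")
})

test_that("catalog CSV round-trips and rejects invalid entries", {
  cat1 <- tiny_catalog()
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat1, path)
  back <- read_catalog(path, life_expectancy = 54)
  expect_equal(as.data.frame(back), as.data.frame(cat1))
  expect_equal(attr(back, "life_expectancy"), 54)

  expect_error(disease_catalog(data.frame(
    diagnosis = "x", p_death_untreated = 1.4, dw_untreated = 0.1,
    dw_residual = 0, p_residual_after_success = 0,
    residual_convention = "lifelong_disability")), "p_death_untreated")
  expect_error(disease_catalog(data.frame(
    diagnosis = "x", p_death_untreated = 0.5, dw_untreated = 0.1,
    dw_residual = 0.3, p_residual_after_success = 0,
    residual_convention = "lifelong_disability")), "dw_residual")
  expect_error(disease_catalog(data.frame(
    diagnosis = "x", p_death_untreated = 0.5, dw_untreated = 0.1,
    dw_residual = 0.05, p_residual_after_success = 0,
    residual_convention = "sometimes")), "residual_convention")
})
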
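# Small deterministic fixtures and independent oracles used across tests.

# two-diagnosis catalog with hand-picked parameters
tiny_catalog <- function(life_expectancy = 54,
                         convention = "lifelong_disability") {
  disease_catalog(data.frame(
    diagnosis = c("hernia", "atresia"),
    p_death_untreated = c(0.2, 0.9),
    dw_untreated = c(0.3, 0.6),
    dw_residual = c(0.1, 0.2),
    p_residual_after_success = c(0.1, 0.3),
    residual_convention = convention,
    stringsAsFactors = FALSE), life_expectancy = life_expectancy)
}

# n-record registry cycling through the tiny catalog's diagnoses
tiny_registry <- function(n = 6, ages = seq(1, 10, length.out = n)) {
  data.frame(
    age_years = ages,
    sex = rep(c("male", "female"), length.out = n),
    diagnosis = rep(c("hernia", "atresia"), length.out = n),
    urgency = rep(c("elective", "emergency"), length.out = n),
    died_before_discharge = rep(FALSE, n),
    oop_cost = rep(50, n),
    stringsAsFactors = FALSE)
}

# Exhaustive leaf enumeration of the decision tree for one arm: for every
# record, walks all seven terminal branches (untreated death / untreated
# survival; perioperative death; success with / without residual
# disability; failure then death / survival) and sums path probability
# times leaf burden. Written independently of the package's vectorized
# burden arithmetic.
leaf_enum_dalys <- function(registry, catalog, treatment, discount,
                            p_no_or) {
  le <- attr(catalog, "life_expectancy")
  total <- 0
  for (i in seq_len(nrow(registry))) {
    e <- catalog[catalog$diagnosis == registry$diagnosis[i], ]
    L <- le - registry$age_years[i]
    Y <- if (discount == 0) L else (1 - exp(-discount * L)) / discount
    resw <- if (e$residual_convention == "death_within_year") 1 else
      e$dw_residual
    leaves <- rbind(
      c(p_no_or * e$p_death_untreated, Y),
      c(p_no_or * (1 - e$p_death_untreated), e$dw_untreated * Y),
      c((1 - p_no_or) * treatment$p_dbd, Y),
      c((1 - p_no_or) * (1 - treatment$p_dbd) * treatment$p_st *
          e$p_residual_after_success, resw * Y),
      c((1 - p_no_or) * (1 - treatment$p_dbd) * treatment$p_st *
          (1 - e$p_residual_after_success), 0),
      c((1 - p_no_or) * (1 - treatment$p_dbd) * (1 - treatment$p_st) *
          e$p_death_untreated, Y),
      c((1 - p_no_or) * (1 - treatment$p_dbd) * (1 - treatment$p_st) *
          (1 - e$p_death_untreated), e$dw_untreated * Y))
    total <- total + sum(leaves[, 1] * leaves[, 2])
  }
  total
}

# exact binomial central interval on the observed proportion
binom_bounds <- function(n, p, level = 0.95) {
  a <- (1 - level) / 2
  stats::qbinom(c(a, 1 - a), n, p) / n
}
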
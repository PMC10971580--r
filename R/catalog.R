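catalog_columns <- c("diagnosis", "p_death_untreated", "dw_untreated",
                     "dw_residual", "p_residual_after_success",
                     "residual_convention")
residual_conventions <- c("lifelong_disability", "death_within_year")

#' Construct a disease catalog
#'
#' A disease catalog holds, per diagnosis group, the natural-history and
#' treatment parameters needed to price disease burden: the probability of
#' death if untreated, the disability weight of the untreated survivor state,
#' the residual disability weight after successful surgery, the probability
#' of residual disability, and the convention under which residual morbidity
#' is portrayed (`"lifelong_disability"`: lived with `dw_residual` to life
#' expectancy; `"death_within_year"`: counted as full years of life lost).
#' The country life expectancy (default 54 y) is carried as an attribute.
#'
#' @param entries `data.frame` with columns `diagnosis`, `p_death_untreated`,
#'   `dw_untreated`, `dw_residual`, `p_residual_after_success`,
#'   `residual_convention`.
#' @param life_expectancy Average life expectancy in years.
#' @return Object of class `"disease_catalog"` (a `data.frame`).
#' @export
disease_catalog <- function(entries, life_expectancy = 54) {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stopf("'entries' must be a non-empty data.frame")
  missing_cols <- setdiff(catalog_columns, names(entries))
  if (length(missing_cols))
    stopf("catalog is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  check_pos(life_expectancy, "life_expectancy")
  for (col in c("p_death_untreated", "dw_untreated", "dw_residual",
                "p_residual_after_success")) {
    v <- entries[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
      stopf("catalog column '%s' must lie in [0, 1]", col)
  }
  if (any(entries$dw_residual > entries$dw_untreated + 1e-12))
    stopf("'dw_residual' must not exceed 'dw_untreated' (treatment never worsens steady-state disability)")
  if (any(!entries$residual_convention %in% residual_conventions))
    stopf("'residual_convention' must be one of: %s",
          paste(residual_conventions, collapse = ", "))
  if (anyDuplicated(entries$diagnosis))
    stopf("duplicate diagnosis codes in catalog")
  out <- entries[catalog_columns]
  attr(out, "life_expectancy") <- life_expectancy
  class(out) <- c("disease_catalog", "data.frame")
  out
}

#' Default disease catalog
#'
#' Ships one entry per default diagnosis group. The severity parameters are
#' synthetic placeholders in plausible ranges (untreated death probabilities
#' 0.15-0.60, disability weights 0.1-0.6): the per-diagnosis source values
#' are not reproducible from the published aggregates, so the catalog is
#' intended to be rescaled by [calibrate_catalog()] against the published
#' arm-level DALY totals before any base-case evaluation.
#'
#' @param life_expectancy Average life expectancy in years (default 54).
#' @return A `"disease_catalog"` object.
#' @export
default_catalog <- function(life_expectancy = 54) {
  entries <- data.frame(
    diagnosis = c("general_pediatric", "congenital_anomaly", "oncology",
                  "urology", "thoracic", "neurosurgical", "plastic_burn",
                  "other"),
    p_death_untreated = c(0.30, 0.45, 0.60, 0.15, 0.40, 0.35, 0.20, 0.25),
    dw_untreated = c(0.30, 0.40, 0.45, 0.25, 0.35, 0.40, 0.30, 0.25),
    dw_residual = c(0.10, 0.15, 0.20, 0.08, 0.12, 0.15, 0.10, 0.08),
    p_residual_after_success = c(0.10, 0.20, 0.15, 0.08, 0.12, 0.20, 0.10,
                                 0.08),
    residual_convention = "lifelong_disability",
    stringsAsFactors = FALSE)
  disease_catalog(entries, life_expectancy = life_expectancy)
}

#' Read / write a disease catalog CSV
#'
#' Comma-separated UTF-8 with a header row naming all catalog columns. The
#' life expectancy is a configuration value, not a CSV column.
#'
#' @param path File path.
#' @param life_expectancy Life expectancy attached to the catalog on read.
#' @param catalog A `"disease_catalog"` object.
#' @return `read_catalog()` returns a `"disease_catalog"`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path, life_expectancy = 54) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  entries <- utils::read.csv(path, stringsAsFactors = FALSE)
  disease_catalog(entries, life_expectancy = life_expectancy)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog)[catalog_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# entries matched to a vector of diagnosis codes, with a named error
catalog_lookup <- function(catalog, diagnosis) {
  idx <- match(diagnosis, catalog$diagnosis)
  if (anyNA(idx))
    stopf("diagnosis not in catalog: %s",
          paste(unique(diagnosis[is.na(idx)]), collapse = ", "))
  catalog[idx, , drop = FALSE]
}

#' Treatment-pathway probabilities
#'
#' The two chance-node probabilities of the surgical branch: `p_dbd`, the
#' probability of death before discharge (informed by the registry's
#' in-hospital mortality), and `p_st`, the probability that surgery is
#' curative-intent successful in a survivor.
#'
#' @param p_dbd Probability of death before discharge.
#' @param p_st Probability of successful treatment.
#' @return Object of class `"treatment_params"`.
#' @export
treatment_params <- function(p_dbd, p_st) {
  check_prob(p_dbd, "p_dbd")
  check_prob(p_st, "p_st")
  structure(list(p_dbd = p_dbd, p_st = p_st), class = "treatment_params")
}
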
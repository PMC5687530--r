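cohort_groups <- function() c("healthy", "asthma", "COPD")

qct_metrics <- function() {
  c("Cr", "WTstar", "Dhstar", "Emph", "fSAD", "beta_tissue",
    "dVairf", "Jacobian", "ADI")
}

airway_metrics <- function() c("Cr", "WTstar", "Dhstar")
lobar_metrics <- function() c("Emph", "fSAD", "beta_tissue", "dVairf",
                              "Jacobian", "ADI")

#' Default and null cohort effect tables
#'
#' Per-metric, per-group location shifts applied by
#' [generate_cohort_metrics()]. The default table is qualitative: shifts
#' follow the direction of the reported group differences (asthma and
#' COPD lose circularity and luminal calibre; COPD gains far more
#' emphysema and air trapping, loses tissue fraction and deformation;
#' both diseases shift air-volume change from the right lower to the
#' right upper lobe), with magnitudes of roughly one to a few
#' between-subject standard deviations. A `region` of `NA` applies the
#' shift everywhere the metric is defined.
#'
#' @return A tibble with columns `variable`, `group`, `region`, `shift`.
#' @export
default_effect_table <- function() {
  tibble::tribble(
    ~variable,      ~group,    ~region, ~shift,
    "Cr",           "asthma",  NA,      -0.030,
    "Cr",           "COPD",    NA,      -0.045,
    "WTstar",       "asthma",  NA,       0.040,
    "WTstar",       "COPD",    NA,       0.040,
    "Dhstar",       "asthma",  NA,      -0.080,
    "Dhstar",       "COPD",    NA,      -0.080,
    "Emph",         "asthma",  NA,       1.5,
    "Emph",         "COPD",    NA,       6.0,
    "fSAD",         "asthma",  NA,       6.0,
    "fSAD",         "COPD",    NA,      15.0,
    "beta_tissue",  "asthma",  NA,       0.000,
    "beta_tissue",  "COPD",    NA,      -0.025,
    "dVairf",       "asthma",  "RUL",    0.020,
    "dVairf",       "COPD",    "RUL",    0.020,
    "dVairf",       "asthma",  "RLL",   -0.020,
    "dVairf",       "COPD",    "RLL",   -0.030,
    "Jacobian",     "asthma",  NA,      -0.150,
    "Jacobian",     "COPD",    NA,      -0.350,
    "ADI",          "asthma",  NA,      -0.050,
    "ADI",          "COPD",    NA,      -0.090
  )
}

#' @rdname default_effect_table
#' @export
null_effect_table <- function() {
  dplyr::mutate(default_effect_table(), shift = 0)
}

#' Cohort configuration
#'
#' Study-condition container for the synthetic three-group cohort
#' (healthy, asthma, COPD). Defaults mirror the analysed study
#' populations: 94 healthy, 75 asthma and 215 COPD subjects.
#'
#' @param n_per_group Subjects per group: a single integer (>= 3) or a
#'   named vector over `healthy`, `asthma`, `COPD`.
#' @param effect_table Location shifts, as in [default_effect_table()].
#' @param seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(healthy = 94, asthma = 75, COPD = 215),
                          effect_table = default_effect_table(),
                          seed = 1L) {
  if (length(n_per_group) == 1L) {
    n_per_group <- setNames(rep(as.integer(n_per_group), 3L), cohort_groups())
  }
  n_per_group <- n_per_group[cohort_groups()]
  if (any(is.na(n_per_group)) || any(n_per_group < 3L)) {
    abort("`n_per_group` must provide at least 3 subjects for each of healthy, asthma and COPD.")
  }
  effect_table <- as_tibble(effect_table)
  needed <- c("variable", "group", "shift")
  if (!all(needed %in% names(effect_table))) {
    abort("`effect_table` needs columns variable, group, shift (and optionally region).")
  }
  if (!"region" %in% names(effect_table)) effect_table$region <- NA_character_
  bad <- setdiff(unique(effect_table$variable), qct_metrics())
  if (length(bad)) {
    abort(paste0("Unknown metric name(s) in effect_table: ",
                 paste(bad, collapse = ", "), "."))
  }
  if (!all(effect_table$group %in% cohort_groups())) {
    abort("effect_table groups must be healthy, asthma or COPD.")
  }
  structure(list(n_per_group = n_per_group, effect_table = effect_table,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Synthetic subject demographics
#'
#' Per-subject covariates (sex, age, height, BMI, lung function,
#' pack-years, race) drawn from group-independent distributions — the
#' generator emulates covariates as plain columns and deliberately does
#' not reproduce between-group demographic imbalance.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject.
#' @export
generate_demographics <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- sum(config$n_per_group)
  group <- factor(rep(cohort_groups(), times = config$n_per_group),
                  levels = cohort_groups())
  with_seed(config$seed, offset = 11L, {
    sex <- sample(c("F", "M"), n, replace = TRUE)
    tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      group = group,
      sex = sex,
      age = round(pmin(pmax(rnorm(n, 55, 12), 19), 85), 1),
      height = round(ifelse(sex == "F", rnorm(n, 163, 7), rnorm(n, 177, 7)), 1),
      bmi = round(pmax(rnorm(n, 28, 5), 16), 1),
      fev1_pct = round(pmax(rnorm(n, 65, 12), 20), 1),
      fev1_fvc = round(pmin(pmax(rnorm(n, 0.62, 0.10), 0.25), 0.95), 3),
      pack_years = round(stats::rgamma(n, shape = 1.5, scale = 12), 1),
      race = sample(c("white", "african_american", "other"), n,
                    replace = TRUE, prob = c(0.72, 0.18, 0.10))
    )
  })
}

# Effect-table lookup: additive shift for a metric/group, optionally
# region-specific (NA region rows apply everywhere).
effect_shift <- function(effect_table, variable, group, region) {
  rows <- effect_table[effect_table$variable == variable &
                         effect_table$group == group, , drop = FALSE]
  if (!nrow(rows)) return(0)
  s <- 0
  glob <- rows[is.na(rows$region), , drop = FALSE]
  if (nrow(glob)) s <- s + sum(glob$shift)
  loc <- rows[!is.na(rows$region) & rows$region == region, , drop = FALSE]
  if (nrow(loc)) s <- s + sum(loc$shift)
  s
}

# Healthy baseline mean for a metric in a region, and between-subject sd.
metric_baseline <- function(variable, region) {
  prof <- c(trachea = 1.00, RMB = 0.85, LMB = 0.82, BronInt = 0.80,
            TriLLB = 0.65, sLUL = 0.55, sRUL = 0.55, sRML = 0.52,
            sLLL = 0.55, sRLL = 0.55)
  switch(variable,
    Cr = list(mean = 0.88, sd = 0.04),
    WTstar = list(mean = unname(prof[region]), sd = 0.06),
    Dhstar = list(mean = unname(prof[region]) * 0.9, sd = 0.06),
    Emph = list(mean = 1.5, sd = 1.2),
    fSAD = list(mean = 5, sd = 3),
    beta_tissue = list(mean = 0.15, sd = 0.015),
    dVairf = list(mean = unname(c(LUL = 0.21, LLL = 0.24, RUL = 0.16,
                                  RML = 0.09, RLL = 0.30)[region]),
                  sd = 0.03),
    Jacobian = list(mean = unname(c(LUL = 1.70, LLL = 1.90, RUL = 1.65,
                                    RML = 1.75, RLL = 1.95,
                                    whole = 1.80)[region] %||% 1.80),
                    sd = 0.15),
    ADI = list(mean = 0.60, sd = 0.08),
    abort(paste0("Unknown metric: ", variable))
  )
}

metric_regions <- function(variable) {
  if (variable %in% airway_metrics()) return(airway_regions())
  if (variable == "dVairf") return(lobe_labels())
  c(lobe_labels(), "whole")
}

# Physical-range truncation, identical for every group so a null cohort
# stays exchangeable.
metric_clamp <- function(variable, x) {
  switch(variable,
    Cr = pmin(pmax(x, 0.05), 1),
    Emph = pmax(x, 0),
    fSAD = pmax(x, 0),
    beta_tissue = pmin(pmax(x, 0.01), 0.6),
    dVairf = x,
    Jacobian = pmax(x, 1.001),
    ADI = pmax(x, 0.01),
    pmax(x, 0.01)
  )
}

#' Synthetic per-subject imaging metrics
#'
#' Draws per-subject values of the nine analysed metrics — airway
#' circularity (Cr), normalised wall thickness (WTstar) and hydraulic
#' diameter (Dhstar) over the ten airway regions; emphysema percentage
#' (Emph), trapped-air percentage (fSAD), inspiratory tissue fraction
#' (beta_tissue), fractional air-volume change (dVairf), Jacobian and ADI
#' over the five lobes (plus a whole-lung value where meaningful) — from
#' Gaussian baselines with group shifts from the configured effect table.
#' With all shifts zero the three groups are exchangeable.
#'
#' @param config A [cohort_config()].
#' @return A long tibble: `subject_id`, `group`, `variable`, `region`,
#'   `value`.
#' @export
generate_cohort_metrics <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  demo <- generate_demographics(config)[, c("subject_id", "group")]
  n <- nrow(demo)
  combos <- purrr::map_dfr(qct_metrics(), function(v) {
    tibble(variable = v, region = metric_regions(v))
  })
  grp_chr <- as.character(demo$group)
  vals <- with_seed(config$seed, offset = 13L, {
    lapply(seq_len(nrow(combos)), function(i) {
      v <- combos$variable[i]; r <- combos$region[i]
      base <- metric_baseline(v, r)
      by_group <- vapply(cohort_groups(), function(g) {
        effect_shift(config$effect_table, v, g, r)
      }, numeric(1))
      metric_clamp(v, base$mean + unname(by_group[grp_chr]) +
                     rnorm(n, 0, base$sd))
    })
  })
  tibble(subject_id = rep(demo$subject_id, times = nrow(combos)),
         group = rep(demo$group, times = nrow(combos)),
         variable = rep(combos$variable, each = n),
         region = rep(combos$region, each = n),
         value = unlist(vals, use.names = FALSE))
}

#' Synthetic airway branch table
#'
#' One measured branch per subject per airway region, with lumen area,
#' perimeter and wall thickness generated so that region-level means of
#' Cr, Dh and WT carry the configured group effects: the `Cr` shift is
#' additive on circularity while `Dhstar` / `WTstar` shifts act as
#' relative changes of lumen calibre and wall thickness. Sex (and,
#' weakly, height) drives airway size, so tracheal normalisation has a
#' real signal to remove.
#'
#' @param config A [cohort_config()].
#' @return A tibble of branch records: `subject_id`, `group`, `region`,
#'   `lumen_area` (mm^2), `lumen_perimeter` (mm), `wall_thickness` (mm).
#' @export
generate_airway_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  demo <- generate_demographics(config)
  n <- nrow(demo)
  dh_base <- c(trachea = 18, RMB = 14, LMB = 12, BronInt = 11, TriLLB = 8,
               sLUL = 6.5, sRUL = 6.5, sRML = 6.0, sLLL = 6.5, sRLL = 6.5)
  wt_base <- c(trachea = 2.8, RMB = 2.3, LMB = 2.2, BronInt = 2.1,
               TriLLB = 1.7, sLUL = 1.4, sRUL = 1.4, sRML = 1.3,
               sLLL = 1.4, sRLL = 1.4)
  size_mult <- ifelse(demo$sex == "M", 1.15, 1.0) *
    (1 + 0.003 * (demo$height - 170))
  with_seed(config$seed, offset = 12L, {
    purrr::map_dfr(airway_regions(), function(r) {
      g <- as.character(demo$group)
      by_group <- function(v) {
        s <- vapply(cohort_groups(), function(gg) {
          effect_shift(config$effect_table, v, gg, r)
        }, numeric(1))
        unname(s[g])
      }
      cr_shift <- by_group("Cr")
      dh_rel <- by_group("Dhstar")
      wt_rel <- by_group("WTstar")
      cr <- pmin(pmax(0.88 + cr_shift + rnorm(n, 0, 0.03), 0.3), 0.995)
      dh <- dh_base[r] * size_mult * (1 + dh_rel) * exp(rnorm(n, 0, 0.06))
      wt <- wt_base[r] * size_mult * (1 + wt_rel) * exp(rnorm(n, 0, 0.08))
      tibble(subject_id = demo$subject_id, group = demo$group, region = r,
             lumen_area = pi * dh^2 / (4 * cr),
             lumen_perimeter = pi * dh / cr,
             wall_thickness = wt)
    })
  })
}
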
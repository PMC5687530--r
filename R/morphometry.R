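#' Airway lumen circularity
#'
#' Cr = 4 pi A / P^2 for a lumen cross-section of area A and perimeter P:
#' the squared ratio of the section's hydraulic diameter to the diameter
#' of the circle with the same perimeter. Cr = 1 exactly for a circle and
#' decreases as the lumen shape becomes heterogeneous (non-circular).
#' Inputs violating the isoperimetric inequality (P^2 < 4 pi A, impossible
#' for a plane curve) are rejected as inconsistent measurements.
#'
#' @param area Lumen area, mm^2 (> 0). Vectorised.
#' @param perimeter Lumen perimeter, mm (> 0). Vectorised.
#' @return Dimensionless circularity in (0, 1].
#' @export
#' @examples
#' circularity(pi, 2 * pi)      # unit circle: 1
#' circularity(9, 12)           # square of side 3
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    abort("`area` and `perimeter` must be finite and positive.")
  }
  cr <- 4 * pi * area / perimeter^2
  if (any(cr > 1 + 1e-9)) {
    bad <- which(cr > 1 + 1e-9)
    abort(paste0("Isoperimetric inequality violated (Cr > 1) for ",
                 length(bad), " record(s): area/perimeter pairs are ",
                 "inconsistent (no plane curve has P^2 < 4*pi*A)."))
  }
  pmin(cr, 1)
}

#' Hydraulic diameter of an airway lumen
#'
#' Dh = 4 A / P, the diameter of the circle with the same area-to-
#' perimeter ratio; equals the geometric diameter for a circular lumen
#' and the side length for a square one.
#'
#' @inheritParams circularity
#' @return Hydraulic diameter in mm.
#' @export
#' @examples
#' hydraulic_diameter(pi, 2 * pi)  # circle of radius 1: 2
#' hydraulic_diameter(9, 12)       # square of side 3: 3
hydraulic_diameter <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    abort("`area` and `perimeter` must be finite and positive.")
  }
  4 * area / perimeter
}

#' Healthy tracheal reference model
#'
#' Fits an ordinary-least-squares predictor of a tracheal airway size
#' (hydraulic diameter or wall thickness) from sex, age and height, on
#' healthy subjects. Subject-level predictions from this model are the
#' denominators of the normalised (starred) airway metrics, removing
#' inter-subject body-size variability — sex being the dominant
#' determinant of airway calibre.
#'
#' @param healthy A data frame of healthy subjects with columns `sex`
#'   (factor or character), `age` (years), `height` (cm) and the response
#'   named by `value`.
#' @param value Name of the response column (e.g. `"Dh"` or `"WT"`).
#' @return An object of class `trachea_ref` wrapping the [stats::lm()]
#'   fit, with [tidy()] / [glance()] / [predict()] methods.
#' @export
fit_trachea_reference <- function(healthy, value = "Dh") {
  healthy <- as_tibble(healthy)
  needed <- c("sex", "age", "height", value)
  missing_cols <- setdiff(needed, names(healthy))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  dat <- healthy[stats::complete.cases(healthy[needed]), needed]
  if (nrow(dat) < 4L) {
    abort(paste0("At least 4 healthy subjects with complete covariates are ",
                 "required to fit the 4-parameter reference (got ",
                 nrow(dat), ")."))
  }
  dat$sex <- as.factor(dat$sex)
  fml <- stats::reformulate(c("sex", "age", "height"), response = value)
  mm <- stats::model.matrix(fml[-2], data = dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    abort(paste0("Rank-deficient reference design: collinear covariate(s) ",
                 paste(dropped, collapse = ", "), "."))
  }
  fit <- lm(fml, data = dat)
  if (any(stats::fitted(fit) <= 0)) {
    warn("Reference model predicts non-positive values inside the fitting hull.")
  }
  structure(list(fit = fit, value = value, n = nrow(dat),
                 sigma = summary(fit)$sigma),
            class = "trachea_ref")
}

#' @export
print.trachea_ref <- function(x, ...) {
  cat("<trachea_ref> OLS predictor of tracheal ", x$value,
      " from sex + age + height (n = ", x$n, ", residual sd = ",
      format(x$sigma, digits = 4), ")\n", sep = "")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
predict.trachea_ref <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  newdata$sex <- factor(newdata$sex, levels = levels(object$fit$model$sex))
  as.double(predict(object$fit, newdata = newdata))
}

#' @rdname fit_trachea_reference
#' @param x,object A `trachea_ref` object.
#' @param ... Unused.
#' @method tidy trachea_ref
#' @export
tidy.trachea_ref <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_trachea_reference
#' @method glance trachea_ref
#' @export
glance.trachea_ref <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$fit$df.residual, nobs = x$n, response = x$value)
}

#' Normalise an airway value by a predicted tracheal value
#'
#' Starred metrics (WT*, Dh*) are plain ratios of the measured value to
#' the subject's healthy-predicted tracheal value, so a consistent
#' multiplicative body-size factor cancels.
#'
#' @param value Measured value, mm. Vectorised.
#' @param predicted_tracheal Subject-level predicted tracheal value, mm
#'   (> 0).
#' @return The dimensionless starred value.
#' @export
#' @examples
#' normalize_airway(15, 20)  # 0.75
normalize_airway <- function(value, predicted_tracheal) {
  if (any(!is.finite(predicted_tracheal)) || any(predicted_tracheal <= 0)) {
    abort("Predicted tracheal values must be positive.")
  }
  value / predicted_tracheal
}

#' Per-subject, per-region airway summaries
#'
#' Computes per-branch circularity, hydraulic diameter and wall thickness
#' and averages them (unweighted) over each subject's branches within each
#' of the ten named airway regions. Regions with no measured branch are
#' reported with `n_branches = 0` and `NA` values — absent, never zero.
#'
#' @param branches A data frame with columns `subject_id`, `region`
#'   (one of [airway_regions()]), `lumen_area` (mm^2), `lumen_perimeter`
#'   (mm) and `wall_thickness` (mm).
#' @return A tibble with one row per subject x region: `n_branches`,
#'   `Cr`, `Dh`, `WT`.
#' @export
summarize_regions <- function(branches) {
  branches <- as_tibble(branches)
  needed <- c("subject_id", "region", "lumen_area", "lumen_perimeter",
              "wall_thickness")
  missing_cols <- setdiff(needed, names(branches))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  unknown <- setdiff(unique(branches$region), airway_regions())
  if (length(unknown)) {
    abort(paste0("Unknown airway region label(s): ",
                 paste(unknown, collapse = ", "), "."))
  }
  summarised <- branches |>
    dplyr::mutate(
      Cr = circularity(.data$lumen_area, .data$lumen_perimeter),
      Dh = hydraulic_diameter(.data$lumen_area, .data$lumen_perimeter),
      WT = .data$wall_thickness
    ) |>
    dplyr::group_by(.data$subject_id, .data$region) |>
    dplyr::summarise(n_branches = dplyr::n(),
                     Cr = mean(.data$Cr), Dh = mean(.data$Dh),
                     WT = mean(.data$WT), .groups = "drop")
  grid <- tidyr::expand_grid(subject_id = unique(branches$subject_id),
                             region = airway_regions())
  grid |>
    dplyr::left_join(summarised, by = c("subject_id", "region")) |>
    dplyr::mutate(n_branches = dplyr::coalesce(.data$n_branches, 0L)) |>
    dplyr::arrange(.data$subject_id, match(.data$region, airway_regions()))
}

#' Full airway morphometry with tracheal normalisation
#'
#' The complete airway analysis for a cohort: per-branch Cr/Dh/WT,
#' regional aggregation, healthy tracheal reference fits for Dh and WT,
#' and the normalised metrics Dh* and WT* (each subject's regional value
#' divided by that subject's healthy-predicted tracheal value).
#'
#' @param branches Branch table as in [summarize_regions()].
#' @param demographics A data frame with columns `subject_id`, `group`
#'   (`"healthy"`, `"asthma"`, `"COPD"`), `sex`, `age`, `height`.
#' @param ref_dh,ref_wt Optional pre-fitted [fit_trachea_reference()]
#'   models; fitted on the healthy subjects' tracheal rows when `NULL`.
#' @return A tibble per subject x region with `Cr`, `Dh`, `WT`,
#'   `Dh_star`, `WT_star` and the subject's group; the reference models
#'   are attached as attributes `ref_dh` and `ref_wt`.
#' @export
airway_morphometry <- function(branches, demographics,
                               ref_dh = NULL, ref_wt = NULL) {
  demographics <- as_tibble(demographics)
  regional <- summarize_regions(branches)
  if (is.null(ref_dh) || is.null(ref_wt)) {
    healthy_ids <- demographics$subject_id[demographics$group == "healthy"]
    trac <- regional |>
      dplyr::filter(.data$region == "trachea",
                    .data$subject_id %in% healthy_ids,
                    .data$n_branches > 0) |>
      dplyr::inner_join(demographics, by = "subject_id")
    if (is.null(ref_dh)) ref_dh <- fit_trachea_reference(trac, value = "Dh")
    if (is.null(ref_wt)) ref_wt <- fit_trachea_reference(trac, value = "WT")
  }
  demographics$pred_dh <- predict(ref_dh, demographics)
  demographics$pred_wt <- predict(ref_wt, demographics)
  if (any(demographics$pred_dh <= 0, na.rm = TRUE) ||
      any(demographics$pred_wt <= 0, na.rm = TRUE)) {
    abort("Reference model produced non-positive tracheal predictions.")
  }
  out <- regional |>
    dplyr::left_join(
      dplyr::select(demographics, "subject_id", "group", "pred_dh", "pred_wt"),
      by = "subject_id") |>
    dplyr::mutate(
      Dh_star = normalize_airway(.data$Dh, .data$pred_dh),
      WT_star = normalize_airway(.data$WT, .data$pred_wt)
    ) |>
    dplyr::select("subject_id", "group", "region", "n_branches",
                  "Cr", "Dh", "WT", "Dh_star", "WT_star")
  attr(out, "ref_dh") <- ref_dh
  attr(out, "ref_wt") <- ref_wt
  out
}
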
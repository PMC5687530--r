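#' Reproducible end-to-end run configuration
#'
#' Settings for [run_pipeline()]: a small image cohort of per-subject
#' phantom scan pairs, the densitometry references, the statistics family
#' settings and one master seed. Every output file carries the
#' configuration hash and seed as provenance.
#'
#' @param out_dir Output directory.
#' @param n_img_per_group Subjects per group receiving a phantom scan
#'   pair (>= 4 so the healthy tracheal reference is identifiable;
#'   default 6 keeps the fit away from saturation).
#' @param grid_shape,spacing_mm Phantom grid (kept small by default so a
#'   full run stays laptop-scale).
#' @param refs A [densitometry_refs()].
#' @param q,family Statistics settings, as in [compare_groups()].
#' @param use_true_field Use the phantom's prescribed field (default);
#'   otherwise estimate one with [estimate_displacement()].
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, n_img_per_group = 6L,
                       grid_shape = c(24, 24, 24),
                       spacing_mm = c(1.5, 1.5, 1.5),
                       refs = densitometry_refs(), q = 0.01,
                       family = c("default", "all"),
                       use_true_field = TRUE, seed = 1L) {
  family <- match.arg(family)
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  if (n_img_per_group < 4L) abort("`n_img_per_group` must be >= 4 (the tracheal reference fit needs 4 healthy subjects).")
  structure(list(out_dir = out_dir, n_img_per_group = as.integer(n_img_per_group),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.double(spacing_mm), refs = refs, q = q,
                 family = family, use_true_field = isTRUE(use_true_field),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

# CSV with a provenance comment header (config hash + seed); read back
# with readr::read_csv(comment = "#").
write_csv_prov <- function(df, path, hash, seed) {
  hdr <- paste0("# lungqct config_hash=", hash, " seed=", seed)
  writeLines(c(paste0(hdr, "\n"), readr::format_csv(df)), path, sep = "")
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

# Per-subject phantom configuration for the image cohort: group effects
# enter through the per-lobe emphysema/trapping targets and the affine
# stretch (Jacobian), reusing the cohort effect directions.
subject_phantom_config <- function(config, group, subj_seed) {
  eff <- default_effect_table()
  draw <- with_seed(subj_seed, offset = 7L, {
    list(emph = rnorm(1, 0, 0.8), fsad = rnorm(1, 0, 2), jac = rnorm(1, 0, 0.08))
  })
  emph <- max(0, 1.5 + effect_shift(eff, "Emph", group, NA) + draw$emph)
  fsad <- max(0, 5 + effect_shift(eff, "fSAD", group, NA) + draw$fsad)
  jac <- max(1.05, 1.55 + effect_shift(eff, "Jacobian", group, NA) + draw$jac)
  phantom_config(grid_shape = config$grid_shape,
                 spacing_mm = config$spacing_mm,
                 target_emph_pct = emph, target_fsad_pct = fsad,
                 deformation = deformation_spec(affine = rep(jac^(1 / 3), 3),
                                                sin_amplitude_mm = 1,
                                                sin_period_mm = 2 * config$grid_shape[1] *
                                                  config$spacing_mm[1]),
                 refs = config$refs, noise_sd_hu = 5,
                 seed = subj_seed)
}

# All image-derived metrics for one phantom bundle, in long form.
image_metrics <- function(bundle, refs, use_true_field = TRUE) {
  insp_beta <- air_fraction(bundle$tlc_volume, refs)
  exp_beta <- air_fraction(bundle$exp_volume, refs)
  field <- if (use_true_field) {
    bundle$true_field
  } else {
    estimate_displacement(bundle$exp_volume, bundle$tlc_volume)
  }
  tens <- deformation_gradient(field)
  jac <- jacobian_determinant(tens, bundle$lobe_mask)
  adi_map <- adi(tens)
  warped <- warp_scalar(insp_beta, field)
  long <- function(df, variable, col) {
    tibble(variable = variable, region = df$region, value = df[[col]])
  }
  dplyr::bind_rows(
    long(emphysema_percent(insp_beta, bundle$lobe_mask, refs), "Emph", "emph_pct"),
    long(fsad_percent(exp_beta, warped, bundle$lobe_mask, refs), "fSAD", "fsad_pct"),
    long(lobar_tissue_fraction(tissue_fraction(insp_beta), bundle$lobe_mask),
         "beta_tissue", "beta_tissue"),
    long(lobar_means(jac, bundle$lobe_mask, exclude_boundary = TRUE,
                     value_name = "jacobian"), "Jacobian", "jacobian"),
    long(lobar_means(adi_map, bundle$lobe_mask, exclude_boundary = TRUE,
                     value_name = "adi"), "ADI", "adi"),
    long(fractional_air_volume_change(insp_beta, exp_beta, field, jac,
                                      bundle$lobe_mask) |>
           dplyr::rename(value = "delta_vair_frac") |>
           dplyr::mutate(dvairf = .data$value),
         "dVairf", "dvairf")
  )
}

#' Run the full phantom-to-report pipeline
#'
#' Chains the modules end to end on synthetic data: per-subject phantom
#' scan pairs, airway tables, densitometry and deformation metrics, and
#' the three-group comparison, writing per-subject metric tables, the
#' comparison report and a provenance manifest to `config$out_dir`.
#' Rerunning with an identical configuration reproduces the metric
#' tables exactly.
#'
#' @param config A [run_config()].
#' @param bundles Optional pre-built list of phantom bundles (one per
#'   subject row of the image cohort), replacing internal generation.
#' @return Invisibly, a list with the metric table, the airway table,
#'   the `qct_comparison` and the manifest.
#' @export
run_pipeline <- function(config, bundles = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))

  ccfg <- cohort_config(n_per_group = config$n_img_per_group,
                        seed = config$seed)
  demo <- run_stage("phantom_generator", generate_demographics(ccfg))

  if (is.null(bundles)) {
    bundles <- run_stage("phantom_generator", {
      purrr::map(seq_len(nrow(demo)), function(i) {
        generate_phantom_pair(subject_phantom_config(
          config, as.character(demo$group[i]),
          subj_seed = (config$seed * 131L + i) %% 2147480000L))
      })
    })
  }

  img <- run_stage("lung_densitometry", {
    purrr::map_dfr(seq_along(bundles), function(i) {
      m <- image_metrics(bundles[[i]], config$refs, config$use_true_field)
      dplyr::mutate(m, subject_id = demo$subject_id[i],
                    group = demo$group[i])
    })
  })

  branches <- run_stage("airway_morphometry", generate_airway_table(ccfg))
  airway <- run_stage("airway_morphometry", {
    airway_morphometry(branches, demo) |>
      dplyr::select("subject_id", "group", "region", Cr = "Cr",
                    Dhstar = "Dh_star", WTstar = "WT_star") |>
      tidyr::pivot_longer(c("Cr", "Dhstar", "WTstar"),
                          names_to = "variable", values_to = "value")
  })

  metrics <- dplyr::bind_rows(
    dplyr::select(img, "subject_id", "group", "variable", "region", "value"),
    dplyr::select(airway, "subject_id", "group", "variable", "region", "value")
  )

  comparison <- run_stage("cohort_statistics", {
    compare_groups(metrics, demographics = demo, q = config$q,
                   family = config$family)
  })

  write_csv_prov(metrics, file.path(config$out_dir, "metrics.csv"),
                 hash, config$seed)
  write_csv_prov(branches, file.path(config$out_dir, "airway_branches.csv"),
                 hash, config$seed)
  write_csv_prov(tidy(comparison),
                 file.path(config$out_dir, "comparison.csv"),
                 hash, config$seed)
  report <- report_markdown(comparison)
  writeLines(c(paste0("<!-- lungqct config_hash=", hash, " seed=",
                      config$seed, " -->"), report),
             file.path(config$out_dir, "report.md"))
  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("lungqct")),
                   n_subjects = nrow(demo),
                   family_size = comparison$family_size,
                   n_rejected = comparison$n_rejected,
                   outputs = c("metrics.csv", "airway_branches.csv",
                               "comparison.csv", "report.md"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, airway_branches = branches,
                 comparison = comparison, manifest = manifest))
}

#' Read a metric or branch table written by the pipeline
#'
#' @param path CSV path (provenance comment lines are skipped).
#' @return A tibble.
#' @export
read_metric_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
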
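#' Densitometry reference values and thresholds
#'
#' Reference attenuations and air-fraction thresholds for fraction-based
#' densitometry. A voxel's air fraction is interpolated between the
#' attenuation of pure air (`hu_air`) and of soft tissue (`hu_tissue`);
#' emphysema-like and air-trapped voxels are declared by thresholds on
#' that fraction rather than on raw HU, which removes scanner offset
#' (inter-site) variability. Defaults: air -1000 HU, tissue +55 HU,
#' emphysema at air fraction > 0.985, air trapping at > 0.90.
#'
#' @param hu_air Attenuation of pure air, HU.
#' @param hu_tissue Attenuation of pure (soft) tissue, HU.
#' @param emph_threshold Air-fraction threshold declaring emphysema on the
#'   inspiratory scan, in (0, 1).
#' @param fsad_threshold Air-fraction threshold declaring air trapping on
#'   the expiratory scan, in (0, 1); must be below `emph_threshold`.
#' @param expiration_state Lung volume at which the expiratory scan was
#'   acquired, `"FRC"` or `"RV"`. Recorded for reporting only; no
#'   correction is applied.
#' @return An object of class `densitometry_refs`.
#' @export
#' @examples
#' refs <- densitometry_refs()
#' hu_cutoff(refs, refs$emph_threshold)  # -984.175 HU
#' hu_cutoff(refs, refs$fsad_threshold)  # -894.5 HU
densitometry_refs <- function(hu_air = -1000, hu_tissue = 55,
                              emph_threshold = 0.985, fsad_threshold = 0.90,
                              expiration_state = c("FRC", "RV")) {
  expiration_state <- match.arg(expiration_state)
  if (!(hu_air < hu_tissue)) abort("`hu_air` must be below `hu_tissue`.")
  for (th in c(emph_threshold, fsad_threshold)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) {
      abort("Thresholds must lie strictly inside (0, 1).")
    }
  }
  if (!(fsad_threshold < emph_threshold)) {
    abort("`fsad_threshold` must be below `emph_threshold`.")
  }
  structure(list(hu_air = hu_air, hu_tissue = hu_tissue,
                 emph_threshold = emph_threshold,
                 fsad_threshold = fsad_threshold,
                 expiration_state = expiration_state),
            class = "densitometry_refs")
}

#' @export
print.densitometry_refs <- function(x, ...) {
  cat("<densitometry_refs> air ", x$hu_air, " HU, tissue ", x$hu_tissue,
      " HU; Emph at beta_air > ", x$emph_threshold,
      ", fSAD at beta_air > ", x$fsad_threshold,
      " (expiration at ", x$expiration_state, ")\n", sep = "")
  invisible(x)
}

#' HU cutoff equivalent to an air-fraction threshold
#'
#' Inverts the air-fraction model: a voxel has air fraction above
#' `threshold` exactly when its attenuation lies below the returned HU
#' value. With the default references, the 0.985 and 0.90 fraction
#' thresholds correspond to -984.175 HU and -894.5 HU.
#'
#' @param refs A [densitometry_refs()] object.
#' @param threshold Air-fraction threshold in (0, 1).
#' @return The equivalent HU cutoff.
#' @export
hu_cutoff <- function(refs, threshold) {
  stopifnot(inherits(refs, "densitometry_refs"))
  refs$hu_tissue - threshold * (refs$hu_tissue - refs$hu_air)
}

#' Per-voxel air fraction from attenuation
#'
#' Linear mixing model: a voxel at the air reference is all air
#' (fraction 1), at the tissue reference all tissue (fraction 0), and
#' attenuation interpolates linearly in between. Values are clamped to
#' \[0, 1\] so calibration overshoot cannot produce unphysical fractions.
#' The tissue fraction is the exact complement, `1 - beta_air`.
#'
#' @param volume A [qct_volume()] of attenuations in HU.
#' @param refs A [densitometry_refs()] object.
#' @param beta_air A [qct_volume()] of air fractions.
#' @return A [qct_volume()] with values in \[0, 1\].
#' @export
#' @examples
#' v <- qct_volume(array(c(-1000, 55, -895), c(3, 1, 1)))
#' air_fraction(v, densitometry_refs())$data
air_fraction <- function(volume, refs = densitometry_refs()) {
  stopifnot(inherits(refs, "densitometry_refs"))
  hu <- as_array(volume)
  beta <- (refs$hu_tissue - hu) / (refs$hu_tissue - refs$hu_air)
  beta <- pmin(pmax(beta, 0), 1)
  qct_volume(array(beta, dim(hu)),
             spacing = if (inherits(volume, "qct_volume")) volume$spacing else c(1, 1, 1))
}

#' @rdname air_fraction
#' @export
tissue_fraction <- function(beta_air) {
  b <- as_array(beta_air)
  qct_volume(array(1 - b, dim(b)),
             spacing = if (inherits(beta_air, "qct_volume")) beta_air$spacing else c(1, 1, 1))
}

# Convert an air-fraction map to HU under the same linear model (used by
# the phantom generator as the densitometry model inverse).
fraction_to_hu <- function(beta_air, refs = densitometry_refs()) {
  refs$hu_tissue - beta_air * (refs$hu_tissue - refs$hu_air)
}

#' Emphysema percentage per lobe and whole lung
#'
#' Percentage of lung voxels on the inspiratory scan whose air fraction
#' exceeds the emphysema threshold. Voxel-count based: with constant voxel
#' volume within an image this equals the volume percentage.
#'
#' @param insp_beta_air Inspiratory air-fraction map ([qct_volume()]).
#' @param lobe_mask A [qct_lobe_mask()] aligned to the map.
#' @param refs A [densitometry_refs()] object.
#' @return A tibble with columns `region` (five lobes and `"whole"`),
#'   `n_voxels` and `emph_pct`.
#' @export
emphysema_percent <- function(insp_beta_air, lobe_mask,
                              refs = densitometry_refs()) {
  stopifnot(inherits(refs, "densitometry_refs"))
  check_aligned(insp_beta_air, lobe_mask, what = "fraction map and lobe mask")
  if (!any(as_array(lobe_mask) > 0L)) abort("Lobe mask is empty: no lung voxels.")
  flag <- as_array(insp_beta_air) > refs$emph_threshold
  out <- lobar_means(array(100 * flag, dim(flag)), lobe_mask,
                     value_name = "emph_pct")
  out
}

#' Functional small-airways disease percentage with emphysema subtraction
#'
#' Percentage of lung voxels that are air-trapped on the expiratory scan
#' (expiratory air fraction above the trapping threshold) but not
#' emphysematous on the registered inspiratory scan (warped inspiratory
#' air fraction at or below the emphysema threshold). The subtraction is
#' the parametric-response-map idea: it removes voxels whose expiratory
#' hyperlucency reflects destroyed parenchyma rather than small-airway
#' obstruction. Voxels where the warp left the inspiration domain are
#' excluded from numerator and denominator.
#'
#' @param exp_beta_air Expiratory air-fraction map on the expiration grid.
#' @param warped_insp_beta_air Inspiratory air-fraction map resampled onto
#'   the expiration grid via [warp_scalar()].
#' @param lobe_mask A [qct_lobe_mask()] on the expiration grid.
#' @param refs A [densitometry_refs()] object.
#' @return A tibble with columns `region`, `n_voxels` and `fsad_pct`.
#' @export
fsad_percent <- function(exp_beta_air, warped_insp_beta_air, lobe_mask,
                         refs = densitometry_refs()) {
  stopifnot(inherits(refs, "densitometry_refs"))
  check_aligned(exp_beta_air, warped_insp_beta_air, lobe_mask,
                what = "fraction maps and lobe mask")
  if (!any(as_array(lobe_mask) > 0L)) abort("Lobe mask is empty: no lung voxels.")
  be <- as_array(exp_beta_air)
  bw <- as_array(warped_insp_beta_air)
  valid <- is.finite(bw)
  trapped <- be > refs$fsad_threshold & bw <= refs$emph_threshold
  trapped[!valid] <- FALSE
  lobar_means(array(100 * trapped, dim(be)), lobe_mask, valid = valid,
              value_name = "fsad_pct")
}

#' Mean lobar tissue fraction at inspiration
#'
#' Arithmetic mean of the per-voxel tissue fraction over each lobe of the
#' inspiratory scan — a direct measure of remaining parenchymal tissue,
#' sensitive to emphysematous destruction.
#'
#' @param insp_beta_tissue Inspiratory tissue-fraction map ([qct_volume()]).
#' @param lobe_mask A [qct_lobe_mask()] aligned to the map.
#' @return A tibble with columns `region`, `n_voxels` and `beta_tissue`.
#' @export
lobar_tissue_fraction <- function(insp_beta_tissue, lobe_mask) {
  check_aligned(insp_beta_tissue, lobe_mask, what = "fraction map and lobe mask")
  if (!any(as_array(lobe_mask) > 0L)) abort("Lobe mask is empty: no lung voxels.")
  lobar_means(insp_beta_tissue, lobe_mask, value_name = "beta_tissue")
}
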
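#' Prescribed deformation for the phantom
#'
#' The phantom's expiration-to-inspiration displacement is
#' `u(x) = (A - I)(x - c) + a * sin(2*pi*(x_i - c_i)/L + phase_i)`
#' per component: an affine stretch about the grid centre plus a smooth
#' diagonal sinusoidal perturbation whose deformation gradient (hence
#' Jacobian) is available in closed form. The specification is rejected
#' unless the displacement-gradient norm is bounded away from 1, which
#' guarantees the mapping is invertible.
#'
#' @param affine A length-3 vector of per-axis stretch factors, or a full
#'   3x3 matrix A.
#' @param sin_amplitude_mm Amplitude a of the sinusoidal perturbation, mm.
#' @param sin_period_mm Period L of the perturbation, mm.
#' @param phase Length-3 phase offsets (radians).
#' @return An object of class `deformation_spec`.
#' @export
#' @examples
#' deformation_spec(affine = c(1.2, 1.1, 0.9))
deformation_spec <- function(affine = c(1, 1, 1), sin_amplitude_mm = 0,
                             sin_period_mm = 64,
                             phase = c(0, 2 * pi / 3, 4 * pi / 3)) {
  A <- if (is.matrix(affine)) affine else diag(as.double(affine))
  if (!identical(dim(A), c(3L, 3L)) || any(!is.finite(A))) {
    abort("`affine` must be a 3x3 matrix or a length-3 stretch vector.")
  }
  if (sin_amplitude_mm < 0 || sin_period_mm <= 0) {
    abort("Sinusoid amplitude must be >= 0 and period > 0.")
  }
  k <- 2 * pi / sin_period_mm
  # Row-sum norm of grad u = (A - I) + diag(a k cos(.)) at its worst.
  gradnorm <- max(rowSums(abs(A - diag(3)))) + sin_amplitude_mm * k
  if (gradnorm >= 0.95) {
    abort(paste0("Deformation not invertible: max displacement-gradient ",
                 "norm ", format(gradnorm, digits = 3),
                 " must stay below 0.95. Reduce the affine stretch or the ",
                 "sinusoid amplitude."))
  }
  structure(list(A = A, amp = sin_amplitude_mm, k = k,
                 phase = as.double(phase), gradnorm = gradnorm),
            class = "deformation_spec")
}

# Displacement (mm) of the spec at world coordinates (arrays x, y, z),
# relative to centre `ctr`.
spec_displacement <- function(spec, x, y, z, ctr) {
  dx <- x - ctr[1]; dy <- y - ctr[2]; dz <- z - ctr[3]
  Ai <- spec$A - diag(3)
  list(
    u1 = Ai[1, 1] * dx + Ai[1, 2] * dy + Ai[1, 3] * dz +
      spec$amp * sin(spec$k * dx + spec$phase[1]),
    u2 = Ai[2, 1] * dx + Ai[2, 2] * dy + Ai[2, 3] * dz +
      spec$amp * sin(spec$k * dy + spec$phase[2]),
    u3 = Ai[3, 1] * dx + Ai[3, 2] * dy + Ai[3, 3] * dz +
      spec$amp * sin(spec$k * dz + spec$phase[3])
  )
}

# Analytic Jacobian determinant of x + u(x) for the spec, at world coords.
spec_jacobian <- function(spec, x, y, z, ctr) {
  A <- spec$A
  g1 <- spec$amp * spec$k * cos(spec$k * (x - ctr[1]) + spec$phase[1])
  g2 <- spec$amp * spec$k * cos(spec$k * (y - ctr[2]) + spec$phase[2])
  g3 <- spec$amp * spec$k * cos(spec$k * (z - ctr[3]) + spec$phase[3])
  d1 <- A[1, 1] + g1; d2 <- A[2, 2] + g2; d3 <- A[3, 3] + g3
  d1 * (d2 * d3 - A[2, 3] * A[3, 2]) -
    A[1, 2] * (A[2, 1] * d3 - A[2, 3] * A[3, 1]) +
    A[1, 3] * (A[2, 1] * A[3, 2] - d2 * A[3, 1])
}

# Invert y = x + u(x) by damped fixed-point iteration (the gradient-norm
# bound enforced at construction makes u a contraction).
spec_invert <- function(spec, y1, y2, y3, ctr, tol = 1e-9, maxit = 200L) {
  x1 <- y1; x2 <- y2; x3 <- y3
  for (it in seq_len(maxit)) {
    u <- spec_displacement(spec, x1, x2, x3, ctr)
    r1 <- x1 + u$u1 - y1; r2 <- x2 + u$u2 - y2; r3 <- x3 + u$u3 - y3
    err <- max(abs(r1), abs(r2), abs(r3))
    x1 <- x1 - r1; x2 <- x2 - r2; x3 <- x3 - r3
    if (err < tol) break
  }
  if (err >= tol) warn("Field inversion did not fully converge; residual > 1e-9 mm.")
  list(x1 = x1, x2 = x2, x3 = x3)
}

#' Phantom configuration
#'
#' Study-condition container for the synthetic paired-scan generator. The
#' lungs are five disjoint axis-aligned lobe blocks inside the grid (left
#' lung: upper/lower; right lung: upper/middle/lower), so every ground
#' truth is an exact count or closed-form value. Per-lobe targets
#' prescribe the inspiratory air-fraction baseline, the percentage of
#' emphysema-like voxels (inspiratory air fraction above the emphysema
#' threshold) and the percentage of purely air-trapped voxels.
#'
#' @param grid_shape Voxels per axis (each >= 8).
#' @param spacing_mm Voxel spacing, mm.
#' @param margin Voxels of air framing the lung region on every side.
#' @param beta_air_tlc Baseline inspiratory air fraction, one value or one
#'   per lobe.
#' @param target_emph_pct Percentage of lobe voxels made emphysematous,
#'   one value or one per lobe, in \[0, 100\].
#' @param target_fsad_pct Percentage made air-trapped-only, likewise.
#' @param emph_beta_air Inspiratory air fraction assigned to emphysematous
#'   voxels (must exceed the emphysema threshold).
#' @param fsad_beta_air_tlc Inspiratory air fraction assigned to
#'   air-trapped voxels (must not exceed the emphysema threshold).
#' @param deformation A [deformation_spec()].
#' @param noise_sd_hu Additive Gaussian HU noise, applied after all
#'   ground-truth bookkeeping.
#' @param refs A [densitometry_refs()] used to turn fractions into HU.
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 32),
                           spacing_mm = c(1, 1, 1),
                           margin = 4L,
                           beta_air_tlc = 0.85,
                           target_emph_pct = 0,
                           target_fsad_pct = 0,
                           emph_beta_air = 0.995,
                           fsad_beta_air_tlc = 0.96,
                           deformation = deformation_spec(),
                           noise_sd_hu = 0,
                           refs = densitometry_refs(),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    abort("`grid_shape` must be three integers >= 8.")
  }
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be three positive voxel sizes.")
  }
  if (2L * margin >= min(grid_shape) - 4L) abort("`margin` leaves no lung region.")
  rep5 <- function(v, what, lo, hi) {
    v <- as.double(v)
    if (length(v) == 1L) v <- rep(v, 5L)
    if (length(v) != 5L) abort(paste0("`", what, "` must have length 1 or 5."))
    if (any(v < lo | v > hi)) {
      abort(paste0("`", what, "` must lie in [", lo, ", ", hi, "]."))
    }
    setNames(v, lobe_labels())
  }
  beta_air_tlc <- rep5(beta_air_tlc, "beta_air_tlc", 0.2, 0.98)
  target_emph_pct <- rep5(target_emph_pct, "target_emph_pct", 0, 100)
  target_fsad_pct <- rep5(target_fsad_pct, "target_fsad_pct", 0, 100)
  if (any(target_emph_pct + target_fsad_pct > 100)) {
    abort("Per-lobe emphysema and air-trapping percentages must sum to <= 100.")
  }
  stopifnot(inherits(deformation, "deformation_spec"),
            inherits(refs, "densitometry_refs"))
  if (emph_beta_air <= refs$emph_threshold) {
    abort("`emph_beta_air` must exceed the emphysema threshold.")
  }
  if (fsad_beta_air_tlc > refs$emph_threshold) {
    abort("`fsad_beta_air_tlc` must not exceed the emphysema threshold (trapped-only voxels are not emphysematous at inspiration).")
  }
  if (noise_sd_hu < 0) abort("`noise_sd_hu` must be >= 0.")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 margin = as.integer(margin),
                 beta_air_tlc = beta_air_tlc,
                 target_emph_pct = target_emph_pct,
                 target_fsad_pct = target_fsad_pct,
                 emph_beta_air = emph_beta_air,
                 fsad_beta_air_tlc = fsad_beta_air_tlc,
                 deformation = deformation, noise_sd_hu = noise_sd_hu,
                 refs = refs, seed = as.integer(seed)),
            class = "phantom_config")
}

# Lobe label array for the block layout: left lung (x low half) split into
# LUL/LLL along z; right lung split into RUL/RML/RLL along z.
phantom_lobe_labels <- function(grid_shape, margin) {
  dm <- grid_shape
  lab <- array(0L, dm)
  xs <- (margin + 1L):(dm[1] - margin)
  ys <- (margin + 1L):(dm[2] - margin)
  zs <- (margin + 1L):(dm[3] - margin)
  xmid <- xs[seq_len(floor(length(xs) / 2))]
  xrgt <- setdiff(xs, xmid)
  nz <- length(zs)
  zlow <- zs[seq_len(floor(nz / 2))]
  zupp <- setdiff(zs, zlow)
  z3 <- split(zs, cut(seq_len(nz), 3, labels = FALSE))
  lab[xmid, ys, zupp] <- 1L  # LUL
  lab[xmid, ys, zlow] <- 2L  # LLL
  lab[xrgt, ys, z3[[3]]] <- 3L  # RUL
  lab[xrgt, ys, z3[[2]]] <- 4L  # RML
  lab[xrgt, ys, z3[[1]]] <- 5L  # RLL
  lab
}

#' Generate a paired inspiration/expiration phantom
#'
#' Builds a seeded synthetic scan pair with exact ground truth. Anatomy
#' (lobe blocks and lesion voxels) is laid out on the shared grid in the
#' expiration frame; every material point carries a prescribed
#' inspiratory tissue fraction. The expiration image is the
#' mass-consistent compression of that material (`beta_tissue_exp = J *
#' beta_tissue_insp` at the material point, with J the analytic Jacobian
#' of the prescribed field), and the inspiration image places each
#' material point at its deformed position via exact inversion of the
#' field. HU values follow from the air fractions through the
#' densitometry model inverse; Gaussian HU noise, if any, is added only
#' after all ground truth is recorded. Identical configurations (same
#' seed) reproduce the bundle bit for bit.
#'
#' With an identity deformation the prescribed per-lobe emphysema and
#' air-trapping percentages are exact voxel counts; with a non-trivial
#' field, lesion bookkeeping is exact on the expiration grid while
#' inspiration-grid counts acquire a small boundary-quantisation error.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_bundle`: `tlc_volume`,
#'   `exp_volume` ([qct_volume()] in HU), `lobe_mask`, `true_field`,
#'   `true_beta_air_tlc`, `true_beta_air_exp`, and `truth`, a tibble of
#'   per-lobe prescribed values (emphysema %, trapped %, mean tissue
#'   fraction, mean Jacobian, fractional air-volume change share).
#' @export
generate_phantom_pair <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dm <- config$grid_shape
  sp <- config$spacing_mm
  refs <- config$refs
  spec <- config$deformation
  ctr <- (dm - 1) * sp / 2

  lab <- phantom_lobe_labels(dm, config$margin)
  w <- grid_world(dm, sp)
  u <- spec_displacement(spec, w$x, w$y, w$z, ctr)
  J <- spec_jacobian(spec, w$x, w$y, w$z, ctr)
  if (any(J <= 0)) abort("Prescribed deformation has non-positive Jacobian.")

  # Material inspiratory tissue fraction, expiration-frame layout.
  t_mat <- array(0, dm)
  lesion <- array(0L, dm)  # 0 none, 1 emphysema, 2 trapped-only
  truth <- vector("list", 5L)
  for (l in 1:5) {
    idx <- which(lab == l)
    n_l <- length(idx)
    t_mat[idx] <- 1 - config$beta_air_tlc[[l]]
    k_e <- round(n_l * config$target_emph_pct[[l]] / 100)
    k_f <- round(n_l * config$target_fsad_pct[[l]] / 100)
    pick <- with_seed(config$seed, offset = l, {
      sample(idx, k_e + k_f)
    })
    if (k_e > 0) {
      t_mat[pick[seq_len(k_e)]] <- 1 - config$emph_beta_air
      lesion[pick[seq_len(k_e)]] <- 1L
    }
    if (k_f > 0) {
      t_mat[pick[k_e + seq_len(k_f)]] <- 1 - config$fsad_beta_air_tlc
      lesion[pick[k_e + seq_len(k_f)]] <- 2L
    }
    truth[[l]] <- tibble(
      region = lobe_labels()[l], n_voxels = n_l,
      emph_pct = 100 * k_e / n_l, fsad_pct = 100 * k_f / n_l,
      beta_tissue = mean(t_mat[idx])
    )
  }
  truth <- dplyr::bind_rows(truth)

  # Expiration image: mass-consistent compression of the material.
  bt_exp <- J * t_mat
  if (any(bt_exp > 1 + 1e-12)) {
    abort("Prescribed Jacobian and tissue fractions give beta_tissue > 1 at expiration; reduce the stretch or the baseline tissue fraction.")
  }
  beta_air_exp <- 1 - pmin(bt_exp, 1)
  beta_air_exp[lab == 0L] <- 1  # background air

  # Check the trapped-only prescription survives compression.
  f_idx <- which(lesion == 2L)
  if (length(f_idx)) {
    bad <- bt_exp[f_idx] >= (1 - refs$fsad_threshold)
    if (any(bad)) {
      warn(paste0(sum(bad), " trapped-only voxel(s) fail the expiratory ",
                  "trapping threshold after compression; the realised ",
                  "trapped percentage will undershoot the target."))
    }
  }

  # Inspiration image: material point of each inspiration-grid voxel.
  if (spec$amp == 0 && all(spec$A == diag(3))) {
    t_insp <- t_mat
    lab_insp <- lab
  } else {
    inv <- spec_invert(spec, w$x, w$y, w$z, ctr)
    ii <- pmin(pmax(round(inv$x1 / sp[1]) + 1, 1), dm[1])
    jj <- pmin(pmax(round(inv$x2 / sp[2]) + 1, 1), dm[2])
    kk <- pmin(pmax(round(inv$x3 / sp[3]) + 1, 1), dm[3])
    inside <- inv$x1 >= 0 & inv$x1 <= (dm[1] - 1) * sp[1] &
      inv$x2 >= 0 & inv$x2 <= (dm[2] - 1) * sp[2] &
      inv$x3 >= 0 & inv$x3 <= (dm[3] - 1) * sp[3]
    lin <- cbind(as.vector(ii), as.vector(jj), as.vector(kk))
    t_insp <- array(t_mat[lin], dm)
    lab_insp <- array(lab[lin], dm)
    t_insp[!inside] <- 0
    lab_insp[!inside] <- 0L
  }
  beta_air_tlc <- 1 - t_insp
  beta_air_tlc[lab_insp == 0L] <- 1

  hu_tlc <- fraction_to_hu(beta_air_tlc, refs)
  hu_exp <- fraction_to_hu(beta_air_exp, refs)
  if (config$noise_sd_hu > 0) {
    noise <- with_seed(config$seed, offset = 101L, {
      list(tlc = array(rnorm(prod(dm), 0, config$noise_sd_hu), dm),
           exp = array(rnorm(prod(dm), 0, config$noise_sd_hu), dm))
    })
    hu_tlc <- hu_tlc + noise$tlc
    hu_exp <- hu_exp + noise$exp
  }

  # Analytic per-lobe deformation truth (interior voxels, matching the
  # boundary-exclusion convention of the lobar summaries).
  keep <- lab > 0L & interior_mask(dm)
  dv <- J - 1  # per-voxel air-volume change per unit voxel volume
  def_truth <- purrr::map_dfr(1:5, function(l) {
    sel <- keep & lab == l
    tibble(region = lobe_labels()[l],
           mean_jacobian = mean(J[sel]),
           delta_vair = sum(dv[sel]))
  })
  def_truth <- dplyr::mutate(def_truth,
                             delta_vair_frac = .data$delta_vair / sum(.data$delta_vair),
                             delta_vair = NULL)
  truth <- dplyr::left_join(truth, def_truth, by = "region")

  ufield <- array(0, c(dm, 3))
  ufield[, , , 1] <- u$u1; ufield[, , , 2] <- u$u2; ufield[, , , 3] <- u$u3

  structure(list(
    tlc_volume = qct_volume(array(hu_tlc, dm), sp),
    exp_volume = qct_volume(array(hu_exp, dm), sp),
    lobe_mask = qct_lobe_mask(lab, sp),
    true_field = qct_field(ufield, sp),
    true_beta_air_tlc = qct_volume(array(beta_air_tlc, dm), sp),
    true_beta_air_exp = qct_volume(array(beta_air_exp, dm), sp),
    true_jacobian = qct_volume(array(J, dm), sp),
    truth = truth,
    config = config
  ), class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle> ", paste(dim(x$tlc_volume), collapse = " x "),
      " paired TLC/expiration phantom, seed ", x$config$seed, "\n", sep = "")
  print(x$truth)
  invisible(x)
}

#' Write a phantom bundle to disk
#'
#' Volumes, lobe mask and field as NIfTI, the ground-truth table as CSV
#' and the configuration summary as JSON.
#'
#' @param bundle A `phantom_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bundle$tlc_volume, file.path(dir, "tlc.nii.gz"))
  write_volume(bundle$exp_volume, file.path(dir, "exp.nii.gz"))
  write_volume(bundle$lobe_mask, file.path(dir, "lobes.nii.gz"))
  write_volume(bundle$true_field, file.path(dir, "field.nii.gz"))
  readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  cfg <- bundle$config
  jsonlite::write_json(
    list(grid_shape = cfg$grid_shape, spacing_mm = cfg$spacing_mm,
         margin = cfg$margin, beta_air_tlc = cfg$beta_air_tlc,
         target_emph_pct = cfg$target_emph_pct,
         target_fsad_pct = cfg$target_fsad_pct,
         noise_sd_hu = cfg$noise_sd_hu, seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
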
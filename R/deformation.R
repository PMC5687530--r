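# Finite-difference derivative of a scalar array along one grid axis,
# central differences interiorly and one-sided at the boundary faces,
# scaled by voxel spacing (per-mm derivative).
fd_axis <- function(a, ax, h) {
  dm <- dim(a)
  n <- dm[ax]
  if (n < 3L) abort("Gradient needs at least 3 voxels per axis.")
  g <- array(0, dm)
  if (ax == 1L) {
    g[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / (2 * h)
    g[1, , ] <- (a[2, , ] - a[1, , ]) / h
    g[n, , ] <- (a[n, , ] - a[n - 1, , ]) / h
  } else if (ax == 2L) {
    g[, 2:(n - 1), ] <- (a[, 3:n, ] - a[, 1:(n - 2), ]) / (2 * h)
    g[, 1, ] <- (a[, 2, ] - a[, 1, ]) / h
    g[, n, ] <- (a[, n, ] - a[, n - 1, ]) / h
  } else {
    g[, , 2:(n - 1)] <- (a[, , 3:n] - a[, , 1:(n - 2)]) / (2 * h)
    g[, , 1] <- (a[, , 2] - a[, , 1]) / h
    g[, , n] <- (a[, , n] - a[, , n - 1]) / h
  }
  g
}

fd_gradient <- function(a, spacing) {
  lapply(1:3, function(ax) fd_axis(a, ax, spacing[ax]))
}

#' Deformation gradient tensor field
#'
#' Computes F = I + du/dx at every voxel of a displacement field, using
#' central differences in the interior and one-sided stencils on the
#' boundary faces, scaled by the voxel spacing. F maps material line
#' elements on the expiration grid to their inspiration-space images.
#'
#' @param field A [qct_field()] of displacements in mm.
#' @return An object of class `qct_tensors`: a 5-D array `F[x, y, z, i, j]`
#'   with the grid spacing attached.
#' @export
#' @examples
#' u <- array(0, c(8, 8, 8, 3))
#' F <- deformation_gradient(qct_field(u))
#' F$data[4, 4, 4, , ]  # identity
deformation_gradient <- function(field) {
  stopifnot(inherits(field, "qct_field"))
  dm <- dim(field)
  if (any(dm < 3L)) abort("Grid must have at least 3 voxels per axis.")
  FF <- array(0, c(dm, 3, 3))
  for (i in 1:3) {
    g <- fd_gradient(field$data[, , , i], field$spacing)
    for (j in 1:3) {
      FF[, , , i, j] <- g[[j]] + as.double(i == j)
    }
  }
  structure(list(data = FF, spacing = field$spacing), class = "qct_tensors")
}

#' @export
dim.qct_tensors <- function(x) dim(x$data)[1:3]

#' @export
print.qct_tensors <- function(x, ...) {
  cat("<qct_tensors> deformation gradients on a ",
      paste(dim(x), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Jacobian determinant of the deformation
#'
#' det F per voxel: the local volume-change factor of the expiration-to-
#' inspiration mapping. Values above 1 indicate local expansion toward
#' inspiration. Non-positive values inside the lung mask indicate folding
#' of the mapping (a registration failure mode) and raise a warning; the
#' offending voxels are flagged in the `"folded"` attribute.
#'
#' @param tensors A `qct_tensors` object from [deformation_gradient()].
#' @param lobe_mask Optional [qct_lobe_mask()]; folding is only diagnosed
#'   inside the lung when given.
#' @return A [qct_volume()] of Jacobian determinants.
#' @export
jacobian_determinant <- function(tensors, lobe_mask = NULL) {
  stopifnot(inherits(tensors, "qct_tensors"))
  FF <- tensors$data
  J <- FF[, , , 1, 1] * (FF[, , , 2, 2] * FF[, , , 3, 3] - FF[, , , 2, 3] * FF[, , , 3, 2]) -
       FF[, , , 1, 2] * (FF[, , , 2, 1] * FF[, , , 3, 3] - FF[, , , 2, 3] * FF[, , , 3, 1]) +
       FF[, , , 1, 3] * (FF[, , , 2, 1] * FF[, , , 3, 2] - FF[, , , 2, 2] * FF[, , , 3, 1])
  out <- qct_volume(array(J, dim(tensors)), spacing = tensors$spacing)
  if (!is.null(lobe_mask)) {
    check_aligned(out, lobe_mask, what = "Jacobian and lobe mask")
    folded <- J <= 0 & as_array(lobe_mask) > 0L
    if (any(folded)) {
      warn(paste0("Non-positive Jacobian at ", sum(folded),
                  " lung voxel(s): the mapping folds there."))
      attr(out, "folded") <- which(folded)
    }
  }
  out
}

# Sorted principal stretches lambda1 >= lambda2 >= lambda3 at every voxel:
# square roots of the eigenvalues of C = F'F, computed with the closed-form
# trigonometric solution for symmetric 3x3 matrices (vectorised over voxels).
principal_stretches <- function(tensors) {
  stopifnot(inherits(tensors, "qct_tensors"))
  FF <- tensors$data
  dm <- dim(tensors)
  nv <- prod(dm)
  Fm <- array(FF, c(nv, 3, 3))
  C <- array(0, c(nv, 3, 3))
  for (j in 1:3) for (k in j:3) {
    C[, j, k] <- Fm[, 1, j] * Fm[, 1, k] + Fm[, 2, j] * Fm[, 2, k] + Fm[, 3, j] * Fm[, 3, k]
    if (k > j) C[, k, j] <- C[, j, k]
  }
  q <- (C[, 1, 1] + C[, 2, 2] + C[, 3, 3]) / 3
  p2 <- (C[, 1, 1] - q)^2 + (C[, 2, 2] - q)^2 + (C[, 3, 3] - q)^2 +
    2 * (C[, 1, 2]^2 + C[, 1, 3]^2 + C[, 2, 3]^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- C[, 1, 1] - q; b22 <- C[, 2, 2] - q; b33 <- C[, 3, 3] - q
  detB <- b11 * (b22 * b33 - C[, 2, 3]^2) -
    C[, 1, 2] * (C[, 1, 2] * b33 - C[, 2, 3] * C[, 1, 3]) +
    C[, 1, 3] * (C[, 1, 2] * C[, 2, 3] - b22 * C[, 1, 3])
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  lam <- cbind(e1, e2, e3)
  lam <- sqrt(pmax(lam, 0))
  array(lam, c(dm, 3))
}

#' Anisotropic deformation index
#'
#' ADI quantifies the magnitude of directional preference in local volume
#' change from the sorted principal stretches lambda1 >= lambda2 >= lambda3
#' of the deformation:
#' \deqn{ADI = \sqrt{((\lambda_1-\lambda_2)/\lambda_2)^2 +
#'                   ((\lambda_2-\lambda_3)/\lambda_3)^2}}
#' Isotropic scaling and rigid motion give ADI = 0.
#'
#' @param tensors A `qct_tensors` object from [deformation_gradient()].
#' @return A [qct_volume()] of ADI values (dimensionless, >= 0).
#' @export
adi <- function(tensors) {
  lam <- principal_stretches(tensors)
  l1 <- lam[, , , 1]; l2 <- lam[, , , 2]; l3 <- lam[, , , 3]
  if (any(l3 <= 0)) {
    abort("Non-positive principal stretch: the deformation is degenerate.")
  }
  val <- sqrt(((l1 - l2) / l2)^2 + ((l2 - l3) / l3)^2)
  qct_volume(array(val, dim(tensors)), spacing = tensors$spacing)
}

# Trilinear interpolation of `a` at continuous 1-based voxel coordinates.
# Returns list(values, valid); samples outside the grid are NA/invalid.
trilinear_sample <- function(a, ci, cj, ck) {
  dm <- dim(a)
  valid <- ci >= 1 & ci <= dm[1] & cj >= 1 & cj <= dm[2] & ck >= 1 & ck <= dm[3] &
    is.finite(ci) & is.finite(cj) & is.finite(ck)
  i0 <- pmin(pmax(floor(ci), 1), dm[1] - 1)
  j0 <- pmin(pmax(floor(cj), 1), dm[2] - 1)
  k0 <- pmin(pmax(floor(ck), 1), dm[3] - 1)
  fx <- ci - i0; fy <- cj - j0; fz <- ck - k0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  lin <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- lin(i0, j0, k0);     v100 <- lin(i0 + 1, j0, k0)
  v010 <- lin(i0, j0 + 1, k0); v110 <- lin(i0 + 1, j0 + 1, k0)
  v001 <- lin(i0, j0, k0 + 1); v101 <- lin(i0 + 1, j0, k0 + 1)
  v011 <- lin(i0, j0 + 1, k0 + 1); v111 <- lin(i0 + 1, j0 + 1, k0 + 1)
  vals <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                        fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
            fy * ((1 - fx) * v011 + fx * v111))
  vals[!valid] <- NA_real_
  list(values = vals, valid = valid)
}

# World coordinates (mm) of every voxel centre, as three arrays.
grid_world <- function(dm, spacing) {
  list(
    x = array(rep((seq_len(dm[1]) - 1) * spacing[1], times = dm[2] * dm[3]), dm),
    y = array(rep(rep((seq_len(dm[2]) - 1) * spacing[2], each = dm[1]), times = dm[3]), dm),
    z = array(rep((seq_len(dm[3]) - 1) * spacing[3], each = dm[1] * dm[2]), dm)
  )
}

#' Pull an inspiration-grid scalar map back onto the expiration grid
#'
#' Samples a scalar map defined on the inspiration grid at the deformed
#' positions x + u(x) of every expiration-grid voxel, by trilinear
#' interpolation. Samples falling outside the inspiration domain are
#' returned as `NA` and marked invalid, so downstream voxel counts can
#' exclude them.
#'
#' @param map_on_insp A [qct_volume()] on the inspiration grid.
#' @param field A [qct_field()] mapping expiration-grid points into
#'   inspiration space (displacements in mm).
#' @return A [qct_volume()] on the expiration grid, with a logical
#'   `"valid"` attribute.
#' @export
warp_scalar <- function(map_on_insp, field) {
  stopifnot(inherits(field, "qct_field"))
  a <- as_array(map_on_insp)
  check_aligned(map_on_insp, field, what = "map and field")
  dm <- dim(a)
  sp <- field$spacing
  w <- grid_world(dm, sp)
  ci <- (w$x + field$data[, , , 1]) / sp[1] + 1
  cj <- (w$y + field$data[, , , 2]) / sp[2] + 1
  ck <- (w$z + field$data[, , , 3]) / sp[3] + 1
  s <- trilinear_sample(a, ci, cj, ck)
  out <- qct_volume(array(s$values, dm), spacing = sp)
  attr(out, "valid") <- array(s$valid, dm)
  out
}

#' Fractional lobar air-volume change
#'
#' Distributes the whole-lung air-volume change between expiration and
#' inspiration over the lobes. Per voxel (on the expiration grid), the air
#' volume change is `v * (J * beta_air_insp(x + u(x)) - beta_air_exp(x))`
#' with `v` the voxel volume: the Jacobian carries the inspiratory air of
#' the corresponding material region back to the expiration grid. Each
#' lobe's share of the summed change is reported; the shares sum to 1.
#'
#' @param insp_beta_air Inspiratory air-fraction map on the inspiration grid.
#' @param exp_beta_air Expiratory air-fraction map on the expiration grid.
#' @param field A [qct_field()] (expiration to inspiration).
#' @param jac Optional precomputed Jacobian [qct_volume()]; computed from
#'   `field` when `NULL`.
#' @param lobe_mask A [qct_lobe_mask()] on the expiration grid.
#' @param exclude_boundary Drop the one-voxel grid shell, where one-sided
#'   difference stencils are less accurate (default `TRUE`).
#' @return A tibble with one row per lobe: `region`, `n_voxels`,
#'   `delta_vair_ml` (air-volume change in ml) and `delta_vair_frac`
#'   (share of the whole-lung change).
#' @export
fractional_air_volume_change <- function(insp_beta_air, exp_beta_air, field,
                                         jac = NULL, lobe_mask,
                                         exclude_boundary = TRUE) {
  stopifnot(inherits(field, "qct_field"))
  check_aligned(insp_beta_air, exp_beta_air, field, lobe_mask,
                what = "maps, field and lobe mask")
  if (is.null(jac)) jac <- jacobian_determinant(deformation_gradient(field))
  check_aligned(jac, field, what = "Jacobian and field")
  warped <- warp_scalar(insp_beta_air, field)
  vvox <- prod(field$spacing) / 1000  # mm^3 -> ml
  dv <- vvox * (as_array(jac) * as_array(warped) - as_array(exp_beta_air))
  lab <- as_array(lobe_mask)
  keep <- lab > 0L & attr(warped, "valid")
  if (exclude_boundary) keep <- keep & interior_mask(dim(lab))
  per_lobe <- purrr::map_dfr(seq_along(lobe_labels()), function(l) {
    sel <- keep & lab == l
    tibble(region = lobe_labels()[l], n_voxels = sum(sel),
           delta_vair_ml = sum(dv[sel]))
  })
  total <- sum(per_lobe$delta_vair_ml)
  if (!is.finite(total) || total <= 0) {
    abort(paste0("Total air-volume change is not positive (", format(total),
                 " ml): inspiration and expiration inputs are likely swapped."))
  }
  dplyr::mutate(per_lobe, delta_vair_frac = .data$delta_vair_ml / total)
}

# ---- displacement-field estimation (demons-style) -------------------------

# Separable Gaussian smoothing of a 3-D array, sigma in voxels, with
# replicate padding at the edges.
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  dm <- dim(a)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    m <- prod(dim(ap)[-1])
    X <- matrix(ap, n, m)
    Xp <- rbind(X[rep(1L, r), , drop = FALSE], X, X[rep(n, r), , drop = FALSE])
    Y <- matrix(0, n, m)
    for (t in seq_along(k)) {
      Y <- Y + k[t] * Xp[t:(t + n - 1L), , drop = FALSE]
    }
    a <- aperm(array(Y, dim(ap)), order(perm))
  }
  a
}

# Block-mean downsampling by a factor of 2 (truncating odd trailing voxels).
downsample2 <- function(a) {
  dm <- dim(a)
  nd <- pmax(dm %/% 2L, 1L)
  a <- a[seq_len(nd[1] * 2), seq_len(nd[2] * 2), seq_len(nd[3] * 2), drop = FALSE]
  b <- array(a, c(2L, nd[1], 2L, nd[2], 2L, nd[3]))
  s <- b[1, , 1, , 1, ] + b[2, , 1, , 1, ] + b[1, , 2, , 1, ] + b[2, , 2, , 1, ] +
    b[1, , 1, , 2, ] + b[2, , 1, , 2, ] + b[1, , 2, , 2, ] + b[2, , 2, , 2, ]
  array(s / 8, nd)
}

# Trilinear resampling of a coarse array onto a finer grid of dim `target`,
# matching voxel-centre world coordinates (same physical extent).
upsample_to <- function(a, target, spacing_coarse, spacing_fine) {
  dm <- dim(a)
  w <- grid_world(target, spacing_fine)
  ci <- w$x / spacing_coarse[1] + 1
  cj <- w$y / spacing_coarse[2] + 1
  ck <- w$z / spacing_coarse[3] + 1
  ci <- pmin(pmax(ci, 1), dm[1]); cj <- pmin(pmax(cj, 1), dm[2]); ck <- pmin(pmax(ck, 1), dm[3])
  array(trilinear_sample(a, ci, cj, ck)$values, target)
}

#' Estimate a displacement field from an image pair
#'
#' A deliberately simple multi-resolution, diffusion-regularised
#' (demons-style) deformable registration: at each pyramid level the
#' moving image is warped by the current field, a Thirion demons force is
#' computed from the intensity difference and the warped-image gradient,
#' and the accumulated field is smoothed with a Gaussian. Deterministic
#' given its parameters. Any externally estimated field in the same
#' format can be substituted for its output.
#'
#' @param fixed The fixed image (expiration scan), a [qct_volume()].
#' @param moving The moving image (inspiration scan), same grid.
#' @param levels Number of pyramid levels (coarsest is
#'   `2^(levels-1)`-fold downsampled).
#' @param iterations Iterations per level (scalar or one per level,
#'   coarsest first).
#' @param smooth_sigma Gaussian regularisation sigma in voxels.
#' @param step_max Maximum per-iteration displacement update, in voxels.
#' @return A [qct_field()] mapping expiration-grid points to inspiration
#'   space.
#' @export
estimate_displacement <- function(fixed, moving, levels = 3L,
                                  iterations = 30L, smooth_sigma = 1.0,
                                  step_max = 2.0) {
  stopifnot(inherits(fixed, "qct_volume"), inherits(moving, "qct_volume"))
  check_aligned(fixed, moving, what = "fixed and moving images")
  if (length(iterations) == 1L) iterations <- rep(iterations, levels)
  stopifnot(length(iterations) == levels)
  dm_full <- dim(fixed)
  sp_full <- fixed$spacing

  pyr_f <- list(as_array(fixed))
  pyr_m <- list(as_array(moving))
  sps <- list(sp_full)
  for (l in seq_len(levels - 1L)) {
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
    sps[[l + 1L]] <- sps[[l]] * dim(pyr_f[[l]]) / dim(pyr_f[[l + 1L]])
  }

  u <- NULL
  for (l in rev(seq_len(levels))) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]; sp <- sps[[l]]
    dm <- dim(f)
    if (is.null(u)) {
      u <- array(0, c(dm, 3))
    } else {
      uo <- u
      u <- array(0, c(dm, 3))
      for (c3 in 1:3) {
        u[, , , c3] <- upsample_to(uo[, , , c3], dm, sps[[l + 1L]], sp)
      }
    }
    scale_hu <- max(1e-8, stats::sd(f))
    fn <- f / scale_hu
    mn <- m / scale_hu
    w <- grid_world(dm, sp)
    diss0 <- NA_real_
    for (it in seq_len(iterations[l])) {
      ci <- (w$x + u[, , , 1]) / sp[1] + 1
      cj <- (w$y + u[, , , 2]) / sp[2] + 1
      ck <- (w$z + u[, , , 3]) / sp[3] + 1
      mw <- trilinear_sample(mn, ci, cj, ck)
      mwv <- array(mw$values, dm)
      mwv[!mw$valid] <- fn[!mw$valid]  # zero force outside the domain
      diff <- mwv - fn
      diss <- mean(abs(diff))
      if (it == 1L) diss0 <- diss
      g <- fd_gradient(mwv, sp)
      g2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
      denom <- g2 + diff^2
      denom[denom < 1e-12] <- Inf
      for (c3 in 1:3) {
        du <- -diff * g[[c3]] / denom
        lim <- step_max * sp[c3]
        du <- pmin(pmax(du, -lim), lim)
        u[, , , c3] <- gaussian_smooth3(u[, , , c3] + du, smooth_sigma)
      }
    }
    ci <- (w$x + u[, , , 1]) / sp[1] + 1
    cj <- (w$y + u[, , , 2]) / sp[2] + 1
    ck <- (w$z + u[, , , 3]) / sp[3] + 1
    mw <- trilinear_sample(mn, ci, cj, ck)
    mwv <- array(mw$values, dm); mwv[!mw$valid] <- fn[!mw$valid]
    if (mean(abs(mwv - fn)) > diss0 * 1.5 + 1e-12) {
      abort(paste0("Registration diverged at pyramid level ", l,
                   ": dissimilarity increased during iteration."))
    }
  }
  qct_field(u, spacing = sp_full)
}
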
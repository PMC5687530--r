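test_that("deformation gradient reproduces identity, affine and rotation fields", {
  dm <- c(12, 12, 12)
  int <- lungqct:::interior_mask(dm)
  # zero displacement: F = I everywhere (including boundaries)
  F0 <- deformation_gradient(qct_field(array(0, c(dm, 3))))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(F0$data[, , , i, j], array(as.double(i == j), dm))
  }
  # affine: exact at every voxel (linear field, exact finite differences)
  A <- diag(c(1.2, 1.1, 0.9))
  FA <- deformation_gradient(affine_field(dm, A))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(max(abs(FA$data[, , , i, j] - A[i, j])), 0, tolerance = 1e-12)
  }
  # rotation: unit principal stretches, ADI 0, J 1
  th <- 20 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  FR <- deformation_gradient(affine_field(dm, R))
  lam <- lungqct:::principal_stretches(FR)
  expect_equal(max(abs(lam - 1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(adi(FR)$data)), 0, tolerance = 1e-6)
  expect_equal(max(abs(jacobian_determinant(FR)$data - 1)), 0, tolerance = 1e-10)
})

test_that("Jacobian matches det(A) for affine fields and analytic values for smooth fields", {
  dm <- c(32, 32, 32)
  int <- lungqct:::interior_mask(dm)
  J <- jacobian_determinant(deformation_gradient(
    affine_field(dm, diag(c(1.2, 1.1, 0.9)))))
  expect_equal(max(abs(J$data[int] - 1.188)), 0, tolerance = 1e-6)
  # smooth sinusoidal field vs analytic det(I + grad u)
  spec <- deformation_spec(affine = c(1.15, 1.1, 1.05), sin_amplitude_mm = 1.5,
                           sin_period_mm = 64)
  w <- lungqct:::grid_world(dm, c(1, 1, 1))
  ctr <- (dm - 1) / 2
  us <- lungqct:::spec_displacement(spec, w$x, w$y, w$z, ctr)
  uf <- array(0, c(dm, 3))
  uf[, , , 1] <- us$u1; uf[, , , 2] <- us$u2; uf[, , , 3] <- us$u3
  Jfd <- jacobian_determinant(deformation_gradient(qct_field(uf)))$data
  Jan <- lungqct:::spec_jacobian(spec, w$x, w$y, w$z, ctr)
  expect_lt(max(abs(Jfd - Jan)[int]), 1e-3)
})

test_that("non-positive Jacobians inside the lung are flagged as folding", {
  dm <- c(8, 8, 8)
  w <- lungqct:::grid_world(dm, c(1, 1, 1))
  u <- array(0, c(dm, 3))
  u[, , , 1] <- -1.5 * w$x  # reflects the x axis: J < 0
  tens <- deformation_gradient(qct_field(u))
  expect_warning(J <- jacobian_determinant(tens, full_lung_mask(dm)),
                 "folds")
  expect_true(length(attr(J, "folded")) > 0)
})

test_that("ADI is zero for isotropic stretch and matches the hand-computed value", {
  dm <- c(10, 10, 10)
  iso <- deformation_gradient(affine_field(dm, diag(c(1.3, 1.3, 1.3))))
  expect_equal(max(abs(adi(iso)$data)), 0, tolerance = 1e-6)
  aniso <- deformation_gradient(affine_field(dm, diag(c(1.2, 1.1, 0.9))))
  hand <- sqrt(((1.2 - 1.1) / 1.1)^2 + ((1.1 - 0.9) / 0.9)^2)
  expect_equal(hand, 0.2401, tolerance = 5e-4)
  expect_equal(max(abs(adi(aniso)$data - hand)), 0, tolerance = 1e-8)
  # collapsing an axis is degenerate
  flat <- deformation_gradient(affine_field(dm, diag(c(1, 1, 0))))
  expect_error(adi(flat), "degenerate")
})

test_that("det F equals the product of principal stretches", {
  dm <- c(16, 16, 16)
  A <- rbind(c(1.10, 0.05, 0.00), c(0.02, 1.05, 0.03), c(0.00, 0.01, 0.95))
  spec <- deformation_spec(affine = A, sin_amplitude_mm = 1, sin_period_mm = 48)
  w <- lungqct:::grid_world(dm, c(1, 1, 1))
  ctr <- (dm - 1) / 2
  us <- lungqct:::spec_displacement(spec, w$x, w$y, w$z, ctr)
  uf <- array(0, c(dm, 3))
  uf[, , , 1] <- us$u1; uf[, , , 2] <- us$u2; uf[, , , 3] <- us$u3
  tens <- deformation_gradient(qct_field(uf))
  J <- jacobian_determinant(tens)$data
  lam <- lungqct:::principal_stretches(tens)
  expect_equal(J, lam[, , , 1] * lam[, , , 2] * lam[, , , 3],
               tolerance = 1e-10)
})

test_that("Jacobian error decreases second-order under grid refinement", {
  errs <- vapply(c(17, 33, 65), function(n) {
    dm <- c(n, n, n)
    h <- 32 / (n - 1)
    sp <- c(h, h, h)
    spec <- deformation_spec(sin_amplitude_mm = 2, sin_period_mm = 32)
    w <- lungqct:::grid_world(dm, sp)
    ctr <- (dm - 1) * sp / 2
    us <- lungqct:::spec_displacement(spec, w$x, w$y, w$z, ctr)
    uf <- array(0, c(dm, 3))
    uf[, , , 1] <- us$u1; uf[, , , 2] <- us$u2; uf[, , , 3] <- us$u3
    Jfd <- jacobian_determinant(deformation_gradient(qct_field(uf, sp)))$data
    Jan <- lungqct:::spec_jacobian(spec, w$x, w$y, w$z, ctr)
    max(abs(Jfd - Jan)[lungqct:::interior_mask(dm)])
  }, numeric(1))
  expect_lt(errs[2], 0.35 * errs[1])
  expect_lt(errs[3], 0.35 * errs[2])
})

test_that("warping handles identity, constants and integer translations", {
  dm <- c(12, 12, 12)
  set.seed(3)
  m <- qct_volume(array(runif(prod(dm)), dm))
  u0 <- qct_field(array(0, c(dm, 3)))
  expect_equal(warp_scalar(m, u0)$data, m$data)
  # constant scalar stays constant wherever valid
  cst <- qct_volume(array(7, dm))
  ut <- array(0, c(dm, 3)); ut[, , , 1] <- 2
  wc <- warp_scalar(cst, qct_field(ut))
  expect_true(all(wc$data[attr(wc, "valid")] == 7))
  # a delta spike relocates by the integer offset (direct index oracle)
  spike <- array(0, dm); spike[9, 6, 6] <- 1
  ws <- warp_scalar(qct_volume(spike), qct_field(ut))
  oracle <- array(0, dm); oracle[7, 6, 6] <- 1  # output(x) = input(x + 2)
  oracle[11:12, , ] <- NA  # samples beyond the grid are invalid
  expect_equal(ws$data, oracle)
  expect_equal(attr(ws, "valid"), !is.na(oracle))
})

test_that("lobar air-volume shares are exact for constructed inputs and sum to one", {
  dm <- c(10, 10, 10)
  lab <- array(0L, dm)
  lab[2:5, 2:9, 2:9] <- 1L  # two equal interior lobes
  lab[6:9, 2:9, 2:9] <- 2L
  mask <- qct_lobe_mask(lab)
  u0 <- qct_field(array(0, c(dm, 3)))
  insp <- qct_volume(array(0.5, dm))
  eb <- array(0.5, dm)
  eb[lab == 1L] <- 0.2  # voxel change 0.3 v
  eb[lab == 2L] <- 0.4  # voxel change 0.1 v: exactly 3x smaller
  out <- fractional_air_volume_change(insp, qct_volume(eb), u0,
                                      lobe_mask = mask)
  expect_equal(out$delta_vair_frac[1:2], c(0.75, 0.25))
  expect_equal(sum(out$delta_vair_frac), 1, tolerance = 1e-12)
  # swapped phases are caught
  expect_error(
    fractional_air_volume_change(qct_volume(array(0.2, dm)),
                                 qct_volume(array(0.8, dm)), u0,
                                 lobe_mask = mask),
    "swapped")
})

test_that("phantom lobar air-volume shares and Jacobians are recovered from images", {
  spec <- deformation_spec(affine = c(1.18, 1.15, 1.12), sin_amplitude_mm = 1.5,
                           sin_period_mm = 64)
  b <- generate_phantom_pair(phantom_config(deformation = spec, seed = 5))
  insp <- air_fraction(b$tlc_volume)
  expb <- air_fraction(b$exp_volume)
  tens <- deformation_gradient(b$true_field)
  J <- jacobian_determinant(tens, b$lobe_mask)
  dv <- fractional_air_volume_change(insp, expb, b$true_field, J, b$lobe_mask)
  expect_equal(sum(dv$delta_vair_frac), 1, tolerance = 1e-9)
  expect_equal(dv$delta_vair_frac, b$truth$delta_vair_frac, tolerance = 0.01)
  lj <- lobar_means(J, b$lobe_mask, exclude_boundary = TRUE, value_name = "J")
  expect_equal(lj$J[1:5], b$truth$mean_jacobian, tolerance = 1e-3)
})

test_that("voxel tissue mass is conserved through the prescribed deformation", {
  spec <- deformation_spec(affine = c(1.18, 1.15, 1.12), sin_amplitude_mm = 1.5,
                           sin_period_mm = 64)
  b <- generate_phantom_pair(phantom_config(margin = 0, deformation = spec,
                                            seed = 5))
  insp_t <- tissue_fraction(air_fraction(b$tlc_volume))
  exp_t <- tissue_fraction(air_fraction(b$exp_volume))
  J <- jacobian_determinant(deformation_gradient(b$true_field))
  wt <- warp_scalar(insp_t, b$true_field)
  keep <- b$lobe_mask$data > 0L & attr(wt, "valid")
  m_exp <- sum(exp_t$data[keep])
  m_insp <- sum((J$data * wt$data)[keep])
  expect_equal(m_exp, m_insp, tolerance = 1e-3)
})

test_that("the demons estimator recovers no motion, translations and smooth fields", {
  dm <- c(24, 24, 24)
  w <- lungqct:::grid_world(dm, c(1, 1, 1))
  blob <- function(cx, cy, cz, s) {
    exp(-((w$x - cx)^2 + (w$y - cy)^2 + (w$z - cz)^2) / (2 * s^2))
  }
  img <- 1000 * (blob(8, 12, 12, 4) + blob(16, 10, 14, 3) +
                   0.8 * blob(12, 16, 8, 5))
  fixed <- qct_volume(img)
  # identical images: essentially no displacement
  u_id <- estimate_displacement(fixed, fixed)
  expect_lt(max(abs(u_id$data)), 0.1)
  # known 2-voxel translation: mean endpoint error < 0.5 voxel where the
  # images carry structure
  img_t <- 1000 * (blob(10, 12, 12, 4) + blob(18, 10, 14, 3) +
                     0.8 * blob(14, 16, 8, 5))
  u_tr <- estimate_displacement(fixed, qct_volume(img_t))
  structured <- img > 100
  epe <- sqrt((u_tr$data[, , , 1] - 2)^2 + u_tr$data[, , , 2]^2 +
                u_tr$data[, , , 3]^2)
  expect_lt(mean(epe[structured]), 0.5)
})

test_that("the demons estimator recovers the mean Jacobian of a sinusoidal field", {
  dm <- c(28, 28, 28)
  w <- lungqct:::grid_world(dm, c(1, 1, 1))
  ctr <- (dm - 1) / 2
  spec <- deformation_spec(sin_amplitude_mm = 2, sin_period_mm = 56)
  set.seed(42)
  cs <- matrix(runif(3 * 14, 4, 24), ncol = 3)
  amp <- runif(14, 400, 1000); sg <- runif(14, 2.5, 5)
  fcont <- function(x, y, z) {
    v <- 0
    for (i in 1:14) {
      v <- v + amp[i] * exp(-((x - cs[i, 1])^2 + (y - cs[i, 2])^2 +
                                (z - cs[i, 3])^2) / (2 * sg[i]^2))
    }
    v
  }
  fixed <- qct_volume(fcont(w$x, w$y, w$z))
  inv <- lungqct:::spec_invert(spec, w$x, w$y, w$z, ctr)
  moving <- qct_volume(fcont(inv$x1, inv$x2, inv$x3))
  u <- estimate_displacement(fixed, moving, levels = 3, iterations = 40)
  Jest <- jacobian_determinant(deformation_gradient(u))$data
  Jan <- lungqct:::spec_jacobian(spec, w$x, w$y, w$z, ctr)
  core <- array(FALSE, dm); core[5:24, 5:24, 5:24] <- TRUE
  expect_equal(mean(Jest[core]), mean(Jan[core]), tolerance = 0.05)
})
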
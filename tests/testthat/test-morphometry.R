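test_that("circularity and hydraulic diameter match closed forms and the ellipse oracle", {
  # circle of radius 1
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(hydraulic_diameter(pi, 2 * pi), 2)
  # square of side 3
  expect_equal(circularity(9, 12), pi / 4)
  expect_equal(hydraulic_diameter(9, 12), 3)
  # ellipse a = 2, b = 1: perimeter from arc-length integration
  p_ell <- ellipse_perimeter(2, 1)
  a_ell <- pi * 2 * 1
  expect_equal(circularity(a_ell, p_ell), 4 * pi * a_ell / p_ell^2)
  expect_equal(circularity(a_ell, p_ell), 0.8412, tolerance = 1e-3)
  expect_equal(hydraulic_diameter(a_ell, p_ell), 2.594, tolerance = 1e-3)
  # isoperimetric violation: no shape has this little perimeter
  expect_error(circularity(pi, pi), "Isoperimetric")
  expect_error(circularity(-1, 2), "positive")
  expect_error(hydraulic_diameter(0, 1), "positive")
})

test_that("circularity is scale-invariant and hydraulic diameter scales linearly", {
  shapes <- list(c(pi * 2, ellipse_perimeter(2, 1)), c(9, 12), c(2, 7))
  for (s in c(0.25, 1, 3, 50)) {
    for (sh in shapes) {
      expect_equal(circularity(sh[1] * s^2, sh[2] * s),
                   circularity(sh[1], sh[2]))
      expect_equal(hydraulic_diameter(sh[1] * s^2, sh[2] * s),
                   s * hydraulic_diameter(sh[1], sh[2]))
    }
  }
})

test_that("circularity of inscribed polygons increases to 1 in the circle limit", {
  ns <- c(6, 12, 60, 180, 720)
  crs <- vapply(ns, function(n) {
    g <- polygon_circle(n)
    circularity(g$area, g$perimeter)
  }, numeric(1))
  expect_true(all(diff(crs) > 0))
  expect_true(all(crs <= 1))
  expect_equal(crs[length(crs)], 1, tolerance = 1e-3)
})

test_that("tracheal reference model recovers known coefficients and handles edge cases", {
  # constant response: predictions constant regardless of covariates
  const <- tibble::tibble(sex = rep(c("F", "M"), 5),
                          age = c(34, 61, 45, 52, 70, 38, 66, 41, 57, 48),
                          height = c(162, 180, 171, 155, 188, 176, 160, 184,
                                     168, 174), Dh = 20)
  # a saturated, exact fit: summary.lm warns about the perfect fit
  ref_const <- suppressWarnings(fit_trachea_reference(const))
  expect_equal(predict(ref_const, tibble::tibble(sex = "M", age = 99, height = 120)), 20)

  # parameter recovery on simulated data with known coefficients
  set.seed(71)
  n <- 200
  sim <- tibble::tibble(
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 25, 80),
    height = runif(n, 150, 195)
  )
  beta <- c(intercept = 4, sexM = 2.5, age = -0.02, height = 0.08)
  sim$Dh <- beta[1] + beta[2] * (sim$sex == "M") + beta[3] * sim$age +
    beta[4] * sim$height + rnorm(n, 0, 0.5)
  ref <- fit_trachea_reference(sim)
  td <- tidy(ref)
  expect_equal(td$term, c("(Intercept)", "sexM", "age", "height"))
  expect_true(all(abs(td$estimate - unname(beta)) < 3 * td$std.error))
  expect_equal(glance(ref)$nobs, n)

  # underdetermined: 3 subjects for 4 parameters
  expect_error(fit_trachea_reference(const[1:3, ]), "At least 4")
  # collinear covariates are named
  coll <- const
  coll$age <- coll$height
  expect_error(fit_trachea_reference(coll), "collinear")
})

test_that("normalisation is a plain ratio and rejects non-positive predictions", {
  expect_equal(normalize_airway(15, 20), 0.75)
  expect_equal(normalize_airway(20, 20), 1)
  expect_error(normalize_airway(15, 0), "positive")
  # a subject's own tracheal value over its prediction is its starred value
  expect_equal(normalize_airway(17.3, 19.1), 17.3 / 19.1)
})

test_that("regional summaries average branches and flag absent regions", {
  br <- tibble::tibble(
    subject_id = c("a", "a", "a", "b"),
    region = c("sLUL", "sLUL", "trachea", "RMB"),
    lumen_area = c(pi * 4 / (4 * 0.8), pi * 4 / (4 * 0.9), 60, 30),
    lumen_perimeter = c(pi * 2 / 0.8, pi * 2 / 0.9, 30, 22),
    wall_thickness = c(1.2, 1.4, 2.8, 2.2)
  )
  s <- summarize_regions(br)
  expect_equal(nrow(s), 20)  # 2 subjects x 10 regions
  # two sLUL branches with Cr 0.8 and 0.9 average to 0.85
  expect_equal(s$Cr[s$subject_id == "a" & s$region == "sLUL"], 0.85)
  expect_equal(s$n_branches[s$subject_id == "a" & s$region == "sLUL"], 2L)
  # single branch passes through
  expect_equal(s$WT[s$subject_id == "b" & s$region == "RMB"], 2.2)
  # absent region flagged, not zeroed
  tri <- s[s$subject_id == "a" & s$region == "TriLLB", ]
  expect_equal(tri$n_branches, 0L)
  expect_true(is.na(tri$Cr))
  expect_error(summarize_regions(dplyr::mutate(br, region = "bronchus9")),
               "Unknown airway region")
})

test_that("tracheal normalisation removes a consistent multiplicative size factor", {
  cc <- cohort_config(n_per_group = 20, seed = 9)
  br <- generate_airway_table(cc)
  demo <- generate_demographics(cc)
  out1 <- airway_morphometry(br, demo)
  s <- 1.3
  br2 <- dplyr::mutate(br, lumen_area = lumen_area * s^2,
                       lumen_perimeter = lumen_perimeter * s,
                       wall_thickness = wall_thickness * s)
  out2 <- airway_morphometry(br2, demo)
  expect_equal(out2$Dh_star, out1$Dh_star, tolerance = 1e-10)
  expect_equal(out2$WT_star, out1$WT_star, tolerance = 1e-10)
  expect_equal(out2$Cr, out1$Cr, tolerance = 1e-12)
  # unstarred values do scale
  expect_equal(out2$Dh, s * out1$Dh, tolerance = 1e-12)
})
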
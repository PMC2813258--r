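test_that("local anisotropy: conformal wedge is alpha-determined per area,
           sheared wedge is complex but meridionally flat", {
  f <- local_anisotropy_field(mod_logpolar, grid_small)
  expect_true(all(abs(f$local_anisotropy[f$area == "V1"] - 1) < 0.01))
  expect_true(all(abs(f$local_anisotropy[is_V3(f)] - 2.5) < 0.05))
  expect_true(all(abs(f$local_anisotropy[f$area %in% c("V2v", "V2d")] - 2)
                  < 0.04))
  # the sheared map trades meridional for local anisotropy near the
  # foveal V3 projection
  fs <- local_anisotropy_field(mod_dsech, grid_small)
  expect_gt(max(fs$local_anisotropy[is_V3(fs)], na.rm = TRUE), 2)
})

test_that("meridional anisotropy: flat per area for the sheared wedge,
           strongly eccentricity-dependent for the conformal wedge", {
  f <- meridional_anisotropy_field(mod_dsech, grid_small)
  expect_true(all(abs(f$meridional_anisotropy[is_V3(f)] - 0.4) < 0.02))
  expect_true(all(abs(f$meridional_anisotropy[f$area %in%
                                                c("V2v", "V2d")] - 0.5)
                  < 0.025))
  g <- meridional_anisotropy_field(mod_logpolar,
                                   grid_spec(c(0.1, 12), 48, 91))
  v3 <- g[is_V3(g) & g$ecc_deg >= 0.4 & g$ecc_deg <= 2.5, ]
  expect_gte(max(v3$meridional_anisotropy, na.rm = TRUE), 7)
})

test_that("the two anisotropy estimators are genuinely distinct", {
  # conformal wedge near E = a: locally isotropic yet meridionally very
  # anisotropic (the ballooning)
  g <- grid_spec(c(0.7, 1.6), 5, 41)
  f <- local_anisotropy_field(mod_logpolar, g)
  m <- meridional_anisotropy_field(mod_logpolar, g)
  v1 <- f$area == "V1"
  expect_true(all(abs(f$local_anisotropy[v1] - 1) < 1e-2))
  expect_gt(max(m$meridional_anisotropy[m$area == "V1"], na.rm = TRUE), 1.3)
})

test_that("anisotropy fields are mirror symmetric", {
  f <- meridional_anisotropy_field(mod_banded, grid_small)
  up <- f[f$theta_prime > 0, ]
  dn <- f[f$theta_prime < 0, ]
  dn <- dn[order(dn$ecc_deg, -dn$theta_prime), ]
  up <- up[order(up$ecc_deg, up$theta_prime), ]
  expect_equal(up$meridional_anisotropy, dn$meridional_anisotropy,
               tolerance = 1e-9)
})

test_that("finite-square areal estimate converges to the Jacobian
           determinant as the square shrinks", {
  for (m in list(mod_logpolar, mod_dsech)) {
    f_coarse <- meridional_anisotropy_field(m, grid_spec(c(0.5, 8), 4, 21,
                                                         delta_frac = 0.04))
    f_fine <- meridional_anisotropy_field(m, grid_spec(c(0.5, 8), 4, 21,
                                                       delta_frac = 0.01))
    pick <- seq(1, nrow(f_fine), by = 9)
    for (i in pick) {
      J <- local_jacobian(m, f_fine$ecc_deg[i], f_fine$polar_rad[i],
                          f_fine$area[i])
      det_sv <- prod(svd(J)$d)
      expect_equal(f_fine$Ma[i], det_sv, tolerance = 0.01)
      # halving-style refinement brings the square estimate closer
      expect_lte(abs(f_fine$Ma[i] - det_sv),
                 abs(f_coarse$Ma[i] - det_sv) + 1e-9)
    }
  }
})

test_that("magnification curve matches the closed-form dipole derivative on
           the horizontal meridian and scales linearly with k", {
  cur <- areal_magnification_curve(mod_logpolar, "V1", eccs = 10,
                                   theta_range = c(-0.02, 0.02))
  oracle <- 20 * abs(1 / (10 + 1.05) - 1 / (10 + 90))
  expect_equal(cur$M_mm_per_deg, oracle, tolerance = 0.02)
  m2 <- retinomap("dipole", k = 40)
  eccs <- c(0.3, 1, 4, 10)
  c1 <- areal_magnification_curve(mod_logpolar, "V3", eccs = eccs)
  c2 <- areal_magnification_curve(m2, "V3", eccs = eccs)
  expect_equal(c2$M_mm_per_deg, 2 * c1$M_mm_per_deg, tolerance = 1e-10)
  expect_error(areal_magnification_curve(mod_logpolar, "V1", eccs = 1,
                                         rel_width = 0), "positive")
})

test_that("banding enlarges foveal V2/V3 magnification and reduces foveal
           local anisotropy", {
  eccs <- c(0.1, 0.2, 0.35, 0.45)
  m1 <- areal_magnification_curve(mod_banded, "V1", eccs = eccs)
  m3 <- areal_magnification_curve(mod_banded, "V3", eccs = eccs)
  expect_true(all(m3$M_mm_per_deg > m1$M_mm_per_deg))
  g <- grid_spec(c(0.08, 0.5), 8, 41)
  la_b <- local_anisotropy_field(mod_banded, g)
  la_w <- local_anisotropy_field(mod_dsech, g)
  dev <- function(f) stats::median(abs(log(f$local_anisotropy[is_V3(f)])),
                                   na.rm = TRUE)
  expect_lt(dev(la_b), 0.5 * dev(la_w))
})

test_that("isolines: horizontal meridian of V1 lies on the x axis, contours
           are continuous border to border, and the banded foveal contour
           has positive length in V2/V3", {
  iso <- extract_isolines(mod_dsech, ecc_levels = c(1, 4))
  hm <- iso[iso$kind == "meridian_h" & iso$area == "V1", ]
  expect_true(all(abs(hm$y_mm) < 1e-9))
  for (lev in c(1, 4)) {
    lv <- iso[iso$kind == "isoecc" & iso$level == lev, ]
    ends <- function(ar) lv[lv$area == ar, c("x_mm", "y_mm")]
    v1 <- ends("V1"); v2v <- ends("V2v"); v3v <- ends("V3v")
    gap <- function(p, q) min(sqrt(outer(p$x_mm, q$x_mm, "-")[c(1, nrow(p)),
                                                             c(1, nrow(q))]^2 +
                                   outer(p$y_mm, q$y_mm, "-")[c(1, nrow(p)),
                                                             c(1, nrow(q))]^2))
    expect_lt(gap(v1, v2v), 1e-9)
    expect_lt(gap(v2v, v3v), 1e-9)
  }
  isb <- extract_isolines(mod_banded, ecc_levels = c(0.01))
  len <- function(d) sum(sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2))
  v3line <- isb[isb$area == "V3v" & isb$kind == "isoecc", ]
  expect_gt(len(v3line[order(v3line$seq), ]), 1)
})

test_that("numeric inversion round-trips sample points, prefers the
           lower-index area on borders, and signals off-map points", {
  for (m in list(mod_logpolar, mod_banded)) {
    s <- generate_synthetic_retinotopy(m, n_per_area = 20, noise_sd = 0,
                                       seed = 11)
    inv <- numeric_inverse(m, s$x_mm, s$y_mm)
    expect_true(all(inv$mapped))
    expect_true(all(abs(inv$ecc_deg - s$ecc_deg) < 1e-6))
    err_th <- abs(inv$polar_rad - s$polar_rad) * pmax(s$ecc_deg, 1e-3)
    expect_true(all(err_th < 1e-6))
  }
  border <- project_complex(3, pi / 2, "V2v", mod_dsech)
  inv <- numeric_inverse(mod_dsech, border$x_mm, border$y_mm)
  expect_equal(inv$area, "V1")
  off <- numeric_inverse(mod_dsech, -50, 0)
  expect_false(off$mapped)
  expect_true(is.na(off$area))
})
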
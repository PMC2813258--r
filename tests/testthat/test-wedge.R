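test_that("pacman mirroring follows the reflection sequence of the complex", {
  m <- mod_dsech
  q <- hemifield_to_pacman(5, 0, "V1", m)
  expect_equal(q$theta_prime, 0)
  expect_equal(q$r, 5)
  # shared vertical-meridian border of V1 and V2v is the mirror line
  q1 <- hemifield_to_pacman(5, pi / 2, "V1", m)
  q2 <- hemifield_to_pacman(5, pi / 2, "V2v", m)
  expect_equal(q1$theta_prime, q2$theta_prime)
  expect_equal(q1$theta_prime, pi / 2 * m$alpha[1])
  # horizontal meridian sits on the V2v/V3v border
  q3 <- hemifield_to_pacman(5, 0, "V2v", m)
  expect_equal(q3$theta_prime, pi / 2 * (m$alpha[1] + m$alpha[2]))
  expect_equal(hemifield_to_pacman(5, 0, "V3v", m)$theta_prime,
               q3$theta_prime)
  # enumeration with alpha2 = 0.5, alpha1 = 1: theta' = 3 pi / 4
  expect_equal(q3$theta_prime, 2.35619449019, tolerance = 1e-10)
  expect_error(hemifield_to_pacman(5, -0.3, "V2v", m), "incompatible")
  expect_error(hemifield_to_pacman(5, 0.3, "V3d", m), "incompatible")
})

test_that("area classification bins are half-open towards the fovea", {
  m <- mod_dsech
  expect_equal(classify_area(0, m), "V1")
  expect_equal(classify_area(pi / 2 * m$alpha[1], m), "V1")
  expect_equal(classify_area(-pi / 2 * (1 + 0.5 + 0.2), m), "V3d")
  expect_equal(classify_area(pi / 2 * 1.5, m), "V2v")
  expect_equal(classify_area(pi / 2 * 1.5 + 1e-9, m), "V3v")
  expect_error(classify_area(pi, m), "span")
  # the partition covers the whole span without overlap
  span <- pi / 2 * sum(m$alpha)
  th <- seq(-span, span, length.out = 401)
  lab <- classify_area(th, m)
  expect_true(all(lab %in% c("V1", "V2v", "V2d", "V3v", "V3d")))
  expect_true(!is.unsorted(match(lab[th >= 0], c("V1", "V2v", "V3v"))))
})

test_that("banding shift moves V1 rigidly and extends the apex into a line", {
  m <- mod_banded
  s0 <- banding_shift(c(0.3, 5), c(0, 0), retinomap(lambda = 0))
  expect_equal(s0$r, c(0.3, 5))
  expect_equal(s0$theta_prime, c(0, 0))
  s <- banding_shift(5, 0, m)
  expect_equal(s$r, 4.6)
  expect_equal(s$theta_prime, 0)
  # apex r = 0 beyond the V1 span: strictly positive, angle-dependent radius
  thp <- seq(pi / 2 + 0.05, pi / 2 * 1.9, length.out = 9)
  ap <- banding_shift(rep(0, 9), thp, m)
  expect_true(all(ap$r > m$lambda))
  expect_true(all(diff(ap$r) > 0))
})

test_that("cortical map is continuous across area borders and the foveal
           horizontal meridian", {
  for (m in list(mod_logpolar, mod_dsech, mod_banded)) {
    E <- c(0.15, 0.7, 3, 11)
    expect_equal(proj_c(m, E, rep(pi / 2, 4), rep("V1", 4)),
                 proj_c(m, E, rep(pi / 2, 4), rep("V2v", 4)))
    expect_equal(proj_c(m, E, rep(-pi / 2, 4), rep("V1", 4)),
                 proj_c(m, E, rep(-pi / 2, 4), rep("V2d", 4)))
    expect_equal(proj_c(m, E, rep(0, 4), rep("V2v", 4)),
                 proj_c(m, E, rep(0, 4), rep("V3v", 4)))
    # approaching the horizontal meridian from above and below
    eps <- 1e-9
    dHM <- Mod(proj_c(m, E, rep(eps, 4), rep("V1", 4)) -
               proj_c(m, E, rep(-eps, 4), rep("V1", 4)))
    expect_true(all(dHM < 1e-6))
  }
})

test_that("banded model reduces to the non-banded one at lambda = 0 and
           turns the V2/V3 foveal point into a line", {
  m0 <- retinomap("double_sech_dipole", lambda = 0, banded = TRUE)
  pts <- data.frame(ecc_deg = c(0.1, 1, 4, 9),
                    polar_rad = c(0, 0.8, -1.2, 0.3))
  expect_identical(predict(m0, pts), predict(mod_dsech, pts))
  th <- seq(0.01, pi / 2 - 0.01, length.out = 31)
  line_len <- function(m, area) {
    w <- proj_c(m, rep(1e-9, 31), th * (if (grepl("d$", area)) -1 else 1),
                rep(area, 31))
    sum(Mod(diff(w)))
  }
  for (area in c("V2v", "V2d", "V3v", "V3d")) {
    expect_lt(line_len(mod_dsech, area), 1e-6)   # wedge: a point
    expect_gt(line_len(mod_banded, area), 1)     # banded: a line (mm)
  }
  w_v1 <- proj_c(mod_banded, rep(1e-9, 31), seq(-1.5, 1.5, length.out = 31),
                 rep("V1", 31))
  expect_lt(max(Mod(w_v1 - w_v1[1])), 1e-6)      # V1 fovea stays a point
})

test_that("banding is a foveal modification: peripheral displacement is of
           order lambda * k / E", {
  m <- mod_banded
  for (E in c(2.5, 5, 10, 20)) {
    th <- seq(-1.5, 1.5, length.out = 9)
    d <- Mod(proj_c(m, rep(E, 9), th, rep("V1", 9)) -
             proj_c(m, rep(E, 9), th, rep("V1", 9), banded = FALSE))
    expect_lt(max(d), 3 * m$lambda * m$k / E)
  }
})

test_that("wedge surface ratios follow the alpha parameters for the sheared
           map over any eccentricity band", {
  for (band in list(c(0.5, 2), c(2, 8), c(0.5, 12))) {
    expect_equal(area_ratio(mod_dsech, "V3", "V1", band), 0.4,
                 tolerance = 0.02)
    expect_equal(area_ratio(mod_dsech, "V2", "V1", band), 0.5,
                 tolerance = 0.02)
  }
  expect_equal(area_ratio(mod_dsech, "V1", "V1", c(0.5, 12)), 1,
               tolerance = 1e-12)
  # conformal wedge balloons foveally: V3:V1 exceeds alpha3 near the fovea
  expect_gt(area_ratio(mod_logpolar, "V3", "V1", c(0.5, 2)), 0.4)
})

test_that("conformal wedge reproduces the foveal ballooning of the classical
           construction", {
  # projected size at matched visual location is far larger in V3 than in
  # V1 around E = a
  J1 <- local_jacobian(mod_logpolar, 1.05, 1.4, "V1")
  J3 <- local_jacobian(mod_logpolar, 1.05, 1.4, "V3v")
  Ma <- function(J) abs(det(J))
  expect_gt(Ma(J3) / Ma(J1), 5)
})
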
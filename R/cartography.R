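# Numerical analysis of projected grids: local anisotropy, meridional
# anisotropy, areal magnification, surface-area ratios, isoline
# extraction and numeric inversion.

#' Specification of the analysis grid
#'
#' Eccentricities are log-spaced and polar samples are uniform over the
#' full pacman arc, so a single grid covers all five areas of the
#' complex.  Each node carries a finite visual-field square of half-side
#' `delta_frac * ecc` whose sides are aligned with the iso-polar and
#' iso-eccentricity directions; the projected square drives all
#' finite-difference estimators.
#'
#' @param ecc_range numeric length 2, degrees.
#' @param n_ecc number of eccentricity samples.
#' @param n_polar number of polar samples across the pacman span.
#' @param delta_frac half-side of the estimator square as a fraction of
#'   the local eccentricity (kept small so squares never straddle the
#'   foveal ballooning region).
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(ecc_range = c(0.05, 24), n_ecc = 64, n_polar = 181,
                      delta_frac = 0.01) {
  stopifnot(length(ecc_range) == 2L, all(ecc_range > 0),
            ecc_range[2] > ecc_range[1], n_ecc >= 2, n_polar >= 3,
            delta_frac > 0, delta_frac < 0.5)
  structure(list(ecc_range = ecc_range, n_ecc = as.integer(n_ecc),
                 n_polar = as.integer(n_polar), delta_frac = delta_frac),
            class = "grid_spec")
}

# invert the pacman angle back to the visual polar angle for known areas
.fov_pacman_theta_inv <- function(theta_prime, area, alpha) {
  a1 <- alpha[1]; a2 <- alpha[2]; a3 <- alpha[3]
  hw <- .fov_halfpi
  out <- numeric(length(theta_prime))
  i <- area == "V1";  out[i] <- theta_prime[i] / a1
  i <- area == "V2v"; out[i] <- hw - (theta_prime[i] - hw * a1) / a2
  i <- area == "V2d"; out[i] <- -hw - (theta_prime[i] + hw * a1) / a2
  i <- area == "V3v"; out[i] <- (theta_prime[i] - hw * (a1 + a2)) / a3
  i <- area == "V3d"; out[i] <- (theta_prime[i] + hw * (a1 + a2)) / a3
  out
}

.fov_grid_nodes <- function(model, grid) {
  span <- .fov_halfpi * sum(model$alpha)
  thp <- seq(-span, span, length.out = grid$n_polar)
  ecc <- exp(seq(log(grid$ecc_range[1]), log(grid$ecc_range[2]),
                 length.out = grid$n_ecc))
  nodes <- expand.grid(ecc_deg = ecc, theta_prime = thp,
                       KEEP.OUT.ATTRS = FALSE)
  nodes$area <- classify_area(nodes$theta_prime, model)
  nodes$polar_rad <- .fov_pacman_theta_inv(nodes$theta_prime, nodes$area,
                                           model$alpha)
  nodes
}

# per-node projected-square measurements: side magnifications Mp/Me and
# the areal magnification from the shoelace area of the projected square.
# Everything vectorised over nodes.
.fov_square_measures <- function(model, nodes, delta_frac) {
  E <- nodes$ecc_deg; th <- nodes$polar_rad; area <- nodes$area
  d <- delta_frac * E
  dth <- d / E
  pr <- function(de, dt) .fov_project(model, E + de, th + dt, area)
  c1 <- pr(-d, -dth); c2 <- pr(d, -dth); c3 <- pr(d, dth); c4 <- pr(-d, dth)
  shoelace <- function(p1, p2, p3, p4) {
    x <- cbind(Re(p1), Re(p2), Re(p3), Re(p4))
    y <- cbind(Im(p1), Im(p2), Im(p3), Im(p4))
    xn <- x[, c(2, 3, 4, 1), drop = FALSE]
    yn <- y[, c(2, 3, 4, 1), drop = FALSE]
    0.5 * abs(rowSums(x * yn - xn * y))
  }
  Ma <- shoelace(c1, c2, c3, c4) / (2 * d)^2
  Mp <- Mod(pr(d, 0) - pr(-d, 0)) / (2 * d)
  Me <- Mod(pr(0, dth) - pr(0, -dth)) / (2 * d)
  flagged <- !(is.finite(Ma) & is.finite(Mp) & is.finite(Me))
  data.frame(Mp = Mp, Me = Me, Ma = Ma, flagged = flagged)
}

.fov_aniso_field <- function(model, grid) {
  nodes <- .fov_grid_nodes(model, grid)
  m <- .fov_square_measures(model, nodes, grid$delta_frac)
  out <- cbind(nodes, m)
  out$local_anisotropy <- ifelse(out$flagged, NA_real_, out$Mp / out$Me)
  ue <- unique(out$ecc_deg)
  refnodes <- data.frame(ecc_deg = ue, polar_rad = 0, area = "V1")
  ref <- .fov_square_measures(model, refnodes, grid$delta_frac)
  bad <- !is.finite(ref$Ma) | ref$Ma <= 0
  if (any(bad))
    warning("V1 horizontal-meridian reference not finite at ",
            sum(bad), " eccentricities; skipped")
  refMa <- ifelse(bad, NA_real_, ref$Ma)
  out$meridional_anisotropy <-
    ifelse(out$flagged, NA_real_, out$Ma / refMa[match(out$ecc_deg, ue)])
  rownames(out) <- NULL
  out
}

#' Anisotropy fields over the projected grid
#'
#' `local_anisotropy_field()` reports, per grid node, the ratio of the
#' projected side lengths of a visual-field square whose sides are
#' aligned with the iso-polar and iso-eccentricity directions: the linear
#' magnifications `Mp` and `Me` and their ratio `Mp/Me` (1 for a locally
#' isotropic map; the ratio convention is the one under which the
#' classical log-polar wedge gives `1/alpha3` in V3).
#'
#' `meridional_anisotropy_field()` reports the areal magnification `Ma`
#' of the projected square divided by the areal magnification on the V1
#' horizontal meridian at the same eccentricity, i.e. how magnification
#' varies with polar position and across areas at fixed eccentricity.
#'
#' Nodes whose square straddles a map singularity are flagged and their
#' measures set to `NA` rather than aggregated.
#'
#' @param model a [retinomap()] object.
#' @param grid a [grid_spec()].
#' @return A `data.frame` with one row per node: `ecc_deg`,
#'   `theta_prime`, `polar_rad`, `area`, `Mp`, `Me`, `Ma` (mm/deg and
#'   mm^2/deg^2), `local_anisotropy` or `meridional_anisotropy`, and
#'   `flagged`.
#' @examples
#' f <- local_anisotropy_field(retinomap("dipole"),
#'                             grid_spec(c(0.5, 8), 8, 31))
#' range(f$local_anisotropy)   # conformal: 1 everywhere
#' @export
local_anisotropy_field <- function(model, grid = grid_spec()) {
  model <- .fov_check_model(model)
  f <- .fov_aniso_field(model, grid)
  f[c("ecc_deg", "theta_prime", "polar_rad", "area", "Mp", "Me",
      "local_anisotropy", "flagged")]
}

#' @rdname local_anisotropy_field
#' @export
meridional_anisotropy_field <- function(model, grid = grid_spec()) {
  model <- .fov_check_model(model)
  f <- .fov_aniso_field(model, grid)
  f[c("ecc_deg", "theta_prime", "polar_rad", "area", "Ma",
      "meridional_anisotropy", "flagged")]
}

.fov_expand_group <- function(area) {
  switch(area,
         V1 = "V1", V2 = c("V2v", "V2d"), V3 = c("V3v", "V3d"),
         V2v = "V2v", V2d = "V2d", V3v = "V3v", V3d = "V3d",
         stop("unknown area '", area, "'", call. = FALSE))
}

.fov_quadrant_range <- function(area) {
  if (area == "V1") c(-.fov_halfpi, .fov_halfpi)
  else if (grepl("v$", area)) c(0, .fov_halfpi)
  else c(-.fov_halfpi, 0)
}

# cortical surface of the image of the visual band [E1,E2] x theta-range
# of one half-area, by triangulating projected quadrilaterals
.fov_band_surface <- function(model, area, E1, E2, n_ecc = 24,
                              n_polar = 48, theta_range = NULL) {
  rng <- .fov_quadrant_range(area)
  if (!is.null(theta_range)) {
    rng <- c(max(rng[1], theta_range[1]), min(rng[2], theta_range[2]))
    if (rng[2] <= rng[1]) return(c(cortical = 0, visual = 0))
  }
  Eg <- exp(seq(log(E1), log(E2), length.out = n_ecc + 1))
  thg <- seq(rng[1], rng[2], length.out = n_polar + 1)
  w <- .fov_project(model,
                    rep(Eg, times = n_polar + 1),
                    rep(thg, each = n_ecc + 1),
                    rep(area, (n_ecc + 1) * (n_polar + 1)))
  X <- matrix(Re(w), n_ecc + 1); Y <- matrix(Im(w), n_ecc + 1)
  i <- seq_len(n_ecc); j <- seq_len(n_polar)
  x1 <- X[i, j]; y1 <- Y[i, j]
  x2 <- X[i + 1, j]; y2 <- Y[i + 1, j]
  x3 <- X[i + 1, j + 1]; y3 <- Y[i + 1, j + 1]
  x4 <- X[i, j + 1]; y4 <- Y[i, j + 1]
  tri <- function(ax, ay, bx, by, cx, cy)
    0.5 * abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
  cortical <- sum(tri(x1, y1, x2, y2, x3, y3) + tri(x1, y1, x3, y3, x4, y4))
  visual <- diff(rng) * (E2^2 - E1^2) / 2
  c(cortical = cortical, visual = visual)
}

#' Areal magnification curve of an area
#'
#' Projects narrow iso-eccentricity bands through the model and reports
#' \eqn{M(E) = \sqrt{A_{cortex} / A_{visual}}} in mm/deg (the square root
#' of the projected surface over the surface in visual space).  For area
#' groups (`"V2"`, `"V3"`) the ventral and dorsal halves are pooled.
#'
#' @param model a [retinomap()] object.
#' @param area `"V1"`, `"V2"`, `"V3"` or a specific half such as
#'   `"V3v"`.
#' @param eccs eccentricities at which to evaluate, degrees.
#' @param rel_width relative half-width of each band (band =
#'   `[E/(1+rel_width), E*(1+rel_width)]`); must be positive.
#' @param n_polar polar resolution of the band integration.
#' @param theta_range optional visual polar-angle window (radians),
#'   e.g. a narrow window about 0 to evaluate the curve on the
#'   horizontal meridian only.
#' @return `data.frame` with `ecc_deg`, `M_mm_per_deg`, `area`.
#' @export
areal_magnification_curve <- function(model, area = "V1",
                                      eccs = exp(seq(log(0.1), log(12),
                                                     length.out = 24)),
                                      rel_width = 0.02, n_polar = 64,
                                      theta_range = NULL) {
  model <- .fov_check_model(model)
  if (rel_width <= 0)
    stop("band collapsed: 'rel_width' must be positive", call. = FALSE)
  halves <- .fov_expand_group(area)
  M <- vapply(eccs, function(E) {
    s <- rowSums(vapply(halves, function(h)
      .fov_band_surface(model, h, E / (1 + rel_width), E * (1 + rel_width),
                        n_ecc = 2, n_polar = n_polar,
                        theta_range = theta_range), c(0, 0)))
    if (s["visual"] <= 0)
      stop("band has zero visual surface", call. = FALSE)
    sqrt(s[["cortical"]] / s[["visual"]])
  }, 0)
  data.frame(ecc_deg = eccs, M_mm_per_deg = M, area = area)
}

#' Cortical surface-area ratio of two areas over an eccentricity band
#'
#' Numerically integrates the projected cortical surface of each area
#' over `ecc_range` (pooling ventral and dorsal halves of area groups)
#' and returns their ratio.  For the double-sech wedge the ratio of any
#' two areas equals the ratio of their `alpha` parameters at every
#' eccentricity band.
#'
#' @param model a [retinomap()] object.
#' @param area_i,area_j area labels or groups (see
#'   [areal_magnification_curve()]).
#' @param ecc_range numeric length 2, degrees.
#' @param n_ecc,n_polar integration resolution per half-area.
#' @return A single number, surface(area_i) / surface(area_j).
#' @examples
#' area_ratio(retinomap("double_sech_dipole"), "V3", "V1", c(0.5, 12))
#' @export
area_ratio <- function(model, area_i, area_j, ecc_range = c(0.5, 12),
                       n_ecc = 96, n_polar = 48) {
  model <- .fov_check_model(model)
  surf <- function(group) {
    sum(vapply(.fov_expand_group(group), function(h)
      .fov_band_surface(model, h, ecc_range[1], ecc_range[2],
                        n_ecc = n_ecc, n_polar = n_polar)[["cortical"]],
      0))
  }
  surf(area_i) / surf(area_j)
}

#' Iso-eccentricity and meridian contours of the cortical map
#'
#' Returns ordered polylines (cortical mm) for iso-eccentricity contours
#' in every area and for the images of the horizontal and vertical
#' meridians, tagged by kind and area.  Vertical-meridian lines run along
#' the V1/V2 borders and the outer V3 border; horizontal-meridian lines
#' along the V1 axis and the V2/V3 borders.
#'
#' @param model a [retinomap()] object.
#' @param ecc_levels iso-eccentricity levels, degrees.
#' @param n points per polyline.
#' @param meridians include meridian images?
#' @return `data.frame` with `line_id`, `kind` (`"isoecc"`,
#'   `"meridian_h"`, `"meridian_v"`), `level`, `area`, `seq`, `x_mm`,
#'   `y_mm`.
#' @export
extract_isolines <- function(model, ecc_levels = c(0.5, 1, 2, 4, 8, 12),
                             n = 121, meridians = TRUE) {
  model <- .fov_check_model(model)
  stopifnot(all(ecc_levels > 0))
  pieces <- list()
  add <- function(kind, level, area, ecc, polar) {
    w <- .fov_project(model, ecc, polar, rep(area, length(ecc)))
    id <- sprintf("%s_%s_%s", kind, format(level), area)
    pieces[[length(pieces) + 1L]] <<-
      data.frame(line_id = id, kind = kind, level = level, area = area,
                 seq = seq_along(ecc), x_mm = Re(w), y_mm = Im(w))
  }
  for (lev in ecc_levels)
    for (ar in .fov_area_levels) {
      rng <- .fov_quadrant_range(ar)
      add("isoecc", lev, ar, rep(lev, n), seq(rng[1], rng[2],
                                              length.out = n))
    }
  if (meridians) {
    Emax <- max(ecc_levels)
    Eg <- c(0, exp(seq(log(min(ecc_levels) / 20), log(Emax),
                       length.out = n - 1)))
    hw <- .fov_halfpi
    for (spec in list(list("meridian_h", 0, "V1", 0),
                      list("meridian_h", 0, "V2v", 0),
                      list("meridian_h", 0, "V2d", 0),
                      list("meridian_v", hw, "V1", hw),
                      list("meridian_v", -hw, "V1", -hw),
                      list("meridian_v", hw, "V3v", hw),
                      list("meridian_v", -hw, "V3d", -hw)))
      add(spec[[1]], spec[[2]], spec[[3]], Eg, rep(spec[[4]], n))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Numeric inversion of the cortical projection
#'
#' Recovers the visual-field coordinates and area label of cortical
#' points by damped Gauss--Newton root finding on the forward projection,
#' initialised from the best node of a coarse per-area grid.  Areas are
#' tried in foveal-to-peripheral label order, so a point on a shared
#' border reports the lower-index area.  Points that no area can explain
#' (residual above `tol_mm`) are returned as unmapped.
#'
#' @param model a [retinomap()] object.
#' @param x_mm,y_mm cortical coordinates (vectors, recycled).
#' @param ecc_max search bound on eccentricity, degrees.
#' @param tol_mm acceptance tolerance on the cortical residual, mm.
#' @return `data.frame` with `x_mm`, `y_mm`, `ecc_deg`, `polar_rad`,
#'   `area`, `residual_mm`, `mapped`.
#' @export
numeric_inverse <- function(model, x_mm, y_mm, ecc_max = 30,
                            tol_mm = 1e-6) {
  model <- .fov_check_model(model)
  n <- max(length(x_mm), length(y_mm))
  x_mm <- rep_len(x_mm, n); y_mm <- rep_len(y_mm, n)
  target <- complex(real = x_mm, imaginary = y_mm)
  Eg <- c(1e-4, exp(seq(log(0.02), log(ecc_max), length.out = 18)))
  out <- data.frame(x_mm = x_mm, y_mm = y_mm, ecc_deg = NA_real_,
                    polar_rad = NA_real_, area = NA_character_,
                    residual_mm = NA_real_, mapped = FALSE)
  for (i in seq_len(n)) {
    best <- list(res = Inf)
    for (ar in .fov_area_levels) {
      rng <- .fov_quadrant_range(ar)
      thg <- seq(rng[1], rng[2], length.out = 9)
      grd <- expand.grid(E = Eg, th = thg, KEEP.OUT.ATTRS = FALSE)
      wg <- .fov_project(model, grd$E, grd$th, rep(ar, nrow(grd)))
      j0 <- which.min(Mod(wg - target[i]))
      sol <- .fov_gauss_newton(model, ar, grd$E[j0], grd$th[j0],
                               target[i], rng, ecc_max)
      if (sol$res < tol_mm) { best <- c(sol, list(area = ar)); break }
      if (sol$res < best$res) best <- c(sol, list(area = ar))
    }
    if (best$res < tol_mm) {
      out$ecc_deg[i] <- best$E
      out$polar_rad[i] <- best$th
      out$area[i] <- best$area
      out$mapped[i] <- TRUE
    }
    out$residual_mm[i] <- best$res
  }
  out
}

.fov_gauss_newton <- function(model, area, E, th, target, th_rng, ecc_max,
                              iter_max = 40) {
  ar5 <- rep(area, 5)
  res_at <- function(E, th)
    Mod(.fov_project(model, E, th, area) - target)
  res <- res_at(E, th)
  for (it in seq_len(iter_max)) {
    hE <- 1e-6 * max(E, model$a / 10)
    hT <- 1e-6
    w <- .fov_project(model, c(E, E + hE, max(E - hE, 0), E, E),
                      c(th, th, th, th + hT, th - hT), ar5)
    r <- w[1] - target
    dE <- (w[2] - w[3]) / (hE + min(E, hE))
    dT <- (w[4] - w[5]) / (2 * hT)
    J <- matrix(c(Re(dE), Im(dE), Re(dT), Im(dT)), 2, 2)
    rhs <- -c(Re(r), Im(r))
    step <- tryCatch(solve(J, rhs), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    repeat {
      En <- min(max(E + lam * step[1], 0), ecc_max)
      tn <- min(max(th + lam * step[2], th_rng[1]), th_rng[2])
      rn <- res_at(En, tn)
      if (is.finite(rn) && rn < res) { E <- En; th <- tn; res <- rn; break }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6 || res < 1e-12) break
  }
  list(E = E, th = th, res = res)
}
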
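# Pointwise analytic maps from (intermediate) visual coordinates to
# planar cortical coordinates, plus local Jacobian evaluation.

# raw complex map of intermediate polar coordinates (r deg, theta rad);
# shear (double-sech variants) and banding shift applied as requested.
# Untranslated.  Within 1e-6 deg of a log-map pole the result is NaN
# (flagged non-finite) rather than an error: unreachable for hemifield
# inputs but reachable in intermediate space.
.fov_w_raw <- function(model, r, theta, shift = 0) {
  g <- if (.fov_sheared(model)) .fov_shear(theta, r, .fov_poles(model))
       else theta
  z <- r * exp(1i * g) - shift
  a <- model$a
  near <- Mod(z + a) < 1e-6
  if (model$variant %in% c("monopole", "double_sech_monopole")) {
    w <- model$k * log(z + a)
  } else {
    b <- model$b
    near <- near | Mod(z + b) < 1e-6
    w <- model$k * (log(z + a) - log(z + b))
  }
  w[near] <- NaN * (1 + 1i)
  w
}

.fov_check_visual <- function(ecc, polar) {
  if (!all(is.finite(ecc)) || !all(is.finite(polar)))
    stop("visual-field coordinates must be finite", call. = FALSE)
  if (any(ecc < 0))
    stop("eccentricity must be non-negative", call. = FALSE)
}

.fov_df_cortical <- function(w) {
  data.frame(x_mm = Re(w), y_mm = Im(w))
}

#' Complex-log map variants of the visual hemifield
#'
#' Pointwise evaluation of the analytic maps for a single area (no wedge
#' mirroring, no banding, no translation of the foveal point).  `ecc` and
#' `polar` are recycled against each other; with
#' \eqn{z = E e^{i\theta}} the maps are
#' \deqn{w_{mono} = k\,\log(z + a), \qquad
#'       w_{di}   = k\,\log\{(z + a)/(z + b)\},}
#' and the double-sech version applies the angular compression of
#' [shear_polar_angle()] to \eqn{\theta} before the log (the monopole or
#' dipole form follows the model's variant).  Real part in mm grows
#' logarithmically with eccentricity; positive polar angles (upper field)
#' map to positive `y_mm` (left-hemisphere convention for the right
#' hemifield).
#'
#' @param ecc eccentricity, degrees (non-negative, finite).
#' @param polar polar angle, radians; 0 on the horizontal meridian,
#'   positive towards the upper vertical meridian.
#' @param model a [retinomap()] object supplying `k`, `a` (and `b`).
#' @return `data.frame` with columns `x_mm`, `y_mm`.
#' @examples
#' m <- retinomap("monopole", k = 1, a = 1)
#' monopole_map(9, 0, m)            # (log 10, 0)
#' @export
monopole_map <- function(ecc, polar, model) {
  model <- .fov_check_model(model)
  .fov_check_visual(ecc, polar)
  m <- model; m$variant <- "monopole"
  .fov_df_cortical(.fov_w_raw(m, ecc, polar))
}

#' @rdname monopole_map
#' @export
dipole_map <- function(ecc, polar, model) {
  model <- .fov_check_model(model)
  .fov_check_visual(ecc, polar)
  if (model$b <= model$a)
    stop("degenerate dipole: 'a' and 'b' must differ", call. = FALSE)
  m <- model; m$variant <- "dipole"
  .fov_df_cortical(.fov_w_raw(m, ecc, polar))
}

#' @rdname monopole_map
#' @export
double_sech_map <- function(ecc, polar, model) {
  model <- .fov_check_model(model)
  .fov_check_visual(ecc, polar)
  m <- model
  m$variant <- if (model$variant %in% c("monopole", "double_sech_monopole"))
    "double_sech_monopole" else "double_sech_dipole"
  .fov_df_cortical(.fov_w_raw(m, ecc, polar))
}

#' Local Jacobian of the cortical projection
#'
#' Central finite-difference Jacobian of the full projection
#' ([project_complex()]) at a visual-field location, with both columns
#' expressed per degree of visual angle: the first along the iso-polar
#' (radial) direction, the second along the iso-eccentricity (tangential)
#' direction (arc length \eqn{E\,d\theta}).  The norms of the two columns
#' are the linear magnifications \eqn{M_p} and \eqn{M_e} (mm/deg),
#' attached as attributes; for the conformal variants the columns are
#' orthogonal and the two norms coincide with the singular values.
#'
#' @param model a [retinomap()] object.
#' @param ecc,polar visual-field location (scalar), degrees / radians.
#' @param area area label, one of `"V1"`, `"V2v"`, `"V2d"`, `"V3v"`,
#'   `"V3d"`.
#' @param rel_step relative finite-difference step; the absolute step is
#'   `rel_step * max(ecc, a / 10)` degrees, which stays stable as the
#'   fovea is approached.
#' @return A 2x2 matrix (rows: cortical x, y; columns: radial,
#'   tangential) with attributes `Mp` and `Me`.
#' @examples
#' J <- local_jacobian(retinomap("dipole"), ecc = 3, polar = 0.4)
#' attr(J, "Mp") / attr(J, "Me")    # 1: conformal
#' @export
local_jacobian <- function(model, ecc, polar, area = "V1",
                           rel_step = 1e-5) {
  model <- .fov_check_model(model)
  stopifnot(length(ecc) == 1L, length(polar) == 1L, rel_step > 0)
  .fov_check_visual(ecc, polar)
  h <- rel_step * max(ecc, model$a / 10)
  if (h == 0 || ecc - h < 0)
    stop("finite-difference step underflow at this location", call. = FALSE)
  wr <- .fov_project(model, c(ecc - h, ecc + h), c(polar, polar),
                     c(area, area))
  dth <- h / ecc
  wt <- .fov_project(model, c(ecc, ecc), c(polar - dth, polar + dth),
                     c(area, area))
  col_r <- (wr[2] - wr[1]) / (2 * h)
  col_t <- (wt[2] - wt[1]) / (2 * h)
  if (!all(is.finite(c(Re(col_r), Im(col_r), Re(col_t), Im(col_t)))))
    stop("non-finite derivative: location too close to a map singularity",
         call. = FALSE)
  J <- matrix(c(Re(col_r), Im(col_r), Re(col_t), Im(col_t)), 2, 2)
  dimnames(J) <- list(c("x_mm", "y_mm"), c("radial", "tangential"))
  structure(J, Mp = Mod(col_r), Me = Mod(col_t))
}
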
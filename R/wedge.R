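# The intermediate "pacman" space: mirroring of the hemifield quadrants
# into the V1-V2-V3 complex, the foveal banding shift, and the composed
# visual-field -> cortex projection.

.fov_halfpi <- pi / 2

# vectorised pacman angle for visual polar angle theta in [-pi/2, pi/2]
.fov_pacman_theta <- function(theta, area, alpha) {
  a1 <- alpha[1]; a2 <- alpha[2]; a3 <- alpha[3]
  hw <- .fov_halfpi
  out <- numeric(length(theta))
  i <- area == "V1";  out[i] <- a1 * theta[i]
  i <- area == "V2v"; out[i] <- hw * a1 + a2 * (hw - theta[i])
  i <- area == "V2d"; out[i] <- -hw * a1 - a2 * (hw + theta[i])
  i <- area == "V3v"; out[i] <- hw * (a1 + a2) + a3 * theta[i]
  i <- area == "V3d"; out[i] <- -hw * (a1 + a2) + a3 * theta[i]
  out
}

# graded banding shift magnitude as a function of the (pre-shear) pacman
# angle: constant lambda over V1, growing linearly beyond the V1 span so
# that the V2/V3 apex is drawn out into a line
.fov_shift_mag <- function(theta_prime, model) {
  model$lambda *
    (1 + (2 / pi) * pmax(0, abs(theta_prime) - .fov_halfpi * model$alpha[1]))
}

# full vectorised projection: visual (E, theta, area) -> complex mm.
# Stages: mirror -> shear -> shift -> log; the cortical frame is
# translated so the unbanded V1 foveal image sits at the origin.
.fov_project <- function(model, ecc, polar, area, banded = model$banded) {
  thp <- .fov_pacman_theta(polar, area, model$alpha)
  s <- if (banded) .fov_shift_mag(thp, model) else 0
  w <- .fov_w_raw(model, ecc, thp, shift = s)
  w - .fov_w_raw(model, 0, 0)
}

#' Classify a pacman angle into a visual area
#'
#' The mirrored intermediate space is partitioned by angle: V1 occupies
#' `|theta_prime| <= pi/2 * alpha1`, flanked by V2v/V2d and outermost
#' V3v/V3d (ventral = positive angles = upper visual field).  Boundary
#' angles belong to the lower-index (more foveal) area.
#'
#' @param theta_prime pacman angle(s), radians; must lie within the total
#'   span `pi/2 * sum(alpha)`.
#' @param model a [retinomap()] object.
#' @return Character vector of area labels.
#' @export
classify_area <- function(theta_prime, model) {
  model <- .fov_check_model(model)
  stopifnot(all(is.finite(theta_prime)))
  a <- model$alpha
  hw <- .fov_halfpi
  span <- hw * sum(a)
  if (any(abs(theta_prime) > span + 1e-9))
    stop("pacman angle outside the total angular span", call. = FALSE)
  at <- abs(theta_prime)
  out <- ifelse(at <= hw * a[1], "V1",
         ifelse(at <= hw * (a[1] + a[2]),
                ifelse(theta_prime > 0, "V2v", "V2d"),
                ifelse(theta_prime > 0, "V3v", "V3d")))
  out
}

#' Mirror a hemifield point into the intermediate pacman space
#'
#' Each visual-field point has one image per area: V1 keeps the (possibly
#' compressed) polar angle; V2 is formed by reflecting the quadrants
#' about the vertical-meridian border of V1 with compression `alpha2`,
#' and V3 by reflecting again about the V2/V3 border (which carries the
#' horizontal meridian) with compression `alpha3`.  Ventral areas
#' represent the upper field (`polar >= 0`), dorsal areas the lower
#' field.
#'
#' @param ecc,polar visual-field coordinates, degrees / radians
#'   (`|polar| <= pi/2`); recycled.
#' @param target area label(s): `"V1"`, `"V2v"`, `"V2d"`, `"V3v"`,
#'   `"V3d"`; recycled.
#' @param model a [retinomap()] object.
#' @return `data.frame` with columns `r` (degrees, equal to `ecc`),
#'   `theta_prime` (radians), `area`, and the source coordinates.
#' @export
hemifield_to_pacman <- function(ecc, polar, target, model) {
  model <- .fov_check_model(model)
  .fov_check_visual(ecc, polar)
  n <- max(length(ecc), length(polar), length(target))
  ecc <- rep_len(ecc, n); polar <- rep_len(polar, n)
  target <- rep_len(as.character(target), n)
  if (!all(target %in% .fov_area_levels))
    stop("unknown area label", call. = FALSE)
  if (any(abs(polar) > .fov_halfpi + 1e-12))
    stop("hemifield polar angle must satisfy |polar| <= pi/2",
         call. = FALSE)
  bad <- (target %in% c("V2v", "V3v") & polar < 0) |
         (target %in% c("V2d", "V3d") & polar > 0)
  if (any(bad))
    stop("target area incompatible with the sign of the polar angle ",
         "(ventral = upper field, dorsal = lower field)", call. = FALSE)
  data.frame(r = ecc,
             theta_prime = .fov_pacman_theta(polar, target, model$alpha),
             area = target, ecc_deg = ecc, polar_rad = polar)
}

#' Foveal banding shift of the pacman space
#'
#' Shifts the intermediate space towards negative x (through the origin)
#' by a graded amount: the whole of V1 moves by `lambda` degrees, and
#' beyond the V1 span the shift grows linearly with the pacman angle, so
#' that the foveal apex of V2 and V3 (at zero radius) is drawn out into a line
#' and their wedges become trapezoids.  The displacement is applied in
#' Cartesian coordinates and the result re-expressed in polar form.
#'
#' @param r intermediate radius, degrees; recycled against
#'   `theta_prime`.
#' @param theta_prime pacman angle, radians.
#' @param model a [retinomap()] object (supplies `lambda` and `alpha`).
#' @return `data.frame` with the shifted polar coordinates `r`,
#'   `theta_prime` and the applied `shift` (degrees).
#' @export
banding_shift <- function(r, theta_prime, model) {
  model <- .fov_check_model(model)
  stopifnot(all(is.finite(r)), all(is.finite(theta_prime)), all(r >= 0))
  n <- max(length(r), length(theta_prime))
  r <- rep_len(r, n); theta_prime <- rep_len(theta_prime, n)
  s <- .fov_shift_mag(theta_prime, model)
  x <- r * cos(theta_prime) - s
  y <- r * sin(theta_prime)
  data.frame(r = sqrt(x * x + y * y), theta_prime = atan2(y, x), shift = s)
}

#' Project visual-field points through the full V1-V2-V3 model
#'
#' Composes the pacman mirroring, the optional banding shift and the
#' model's map variant; the cortical frame is translated so that the
#' unbanded V1 foveal point sits at the origin (so banding remains a
#' purely foveal modification of the output coordinates).  Points within
#' 1e-6 deg of a log-map pole yield non-finite coordinates rather than an
#' error.
#'
#' @inheritParams hemifield_to_pacman
#' @param banded logical; overrides the model's `banded` flag.
#' @return `data.frame` with columns `x_mm`, `y_mm`, `area`.
#' @examples
#' m <- retinomap("double_sech_dipole", banded = TRUE)
#' project_complex(2, pi / 4, "V2v", m)
#' @export
project_complex <- function(ecc, polar, target, model,
                            banded = model$banded) {
  model <- .fov_check_model(model)
  q <- hemifield_to_pacman(ecc, polar, target, model)
  w <- .fov_project(model, q$ecc_deg, q$polar_rad, q$area, banded = banded)
  cbind(.fov_df_cortical(w), area = q$area)
}

#' Predict cortical positions for visual-field points
#'
#' @param object a [retinomap()] object.
#' @param newdata `data.frame` with columns `ecc_deg`, `polar_rad` and
#'   optionally `area`.  Without an `area` column each point is projected
#'   into every area of `areas` (ventral or dorsal half chosen by the
#'   sign of the polar angle; the horizontal meridian goes ventral).
#' @param areas areas used when `newdata` has no `area` column; default
#'   `c("V1", "V2", "V3")`.
#' @param banded logical; overrides the model's flag.
#' @param ... unused.
#' @return `data.frame` with `ecc_deg`, `polar_rad`, `area`, `x_mm`,
#'   `y_mm` (one row per point and area).
#' @export
predict.retinomap <- function(object, newdata, areas = c("V1", "V2", "V3"),
                              banded = object$banded, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("ecc_deg", "polar_rad") %in% names(newdata)))
  if (!"area" %in% names(newdata)) {
    pick <- function(grp, th)
      if (grp == "V1") "V1" else paste0(grp, ifelse(th >= 0, "v", "d"))
    newdata <- do.call(rbind, lapply(areas, function(grp) {
      d <- newdata[c("ecc_deg", "polar_rad")]
      d$area <- vapply(d$polar_rad, function(th) pick(grp, th), "")
      d
    }))
  }
  out <- project_complex(newdata$ecc_deg, newdata$polar_rad, newdata$area,
                         object, banded = banded)
  cbind(newdata[c("ecc_deg", "polar_rad")], out[c("area", "x_mm", "y_mm")])
}
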
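#' Construct a retino-cortical map model
#'
#' A `retinomap` object bundles the parameters of the analytic projection
#' from the visual hemifield onto the flattened cortical surface of the
#' V1--V2--V3 complex.  Four map variants are available:
#'
#' * `"monopole"`: the classical complex-log map \eqn{w = k \log(z + a)},
#'   conformal, with a single foveal pole `a`.
#' * `"dipole"`: \eqn{w = k \log\{(z + a)/(z + b)\}}, conformal, tapering
#'   towards both the fovea (`a`) and the periphery (`b`).
#' * `"double_sech_monopole"`, `"double_sech_dipole"`: the sheared
#'   versions, in which the polar angle is compressed by an eccentricity
#'   dependent factor before the log map so that areal magnification no
#'   longer varies with polar position (see [shear_polar_angle()]).
#'
#' The full V1--V2--V3 complex is obtained by mirroring the hemifield
#' quadrants into the intermediate "pacman" space
#' ([hemifield_to_pacman()]) and passing that space through the map.  With
#' `banded = TRUE` the pacman is additionally shifted by `lambda` degrees
#' ([banding_shift()]), which turns the foveal apex of V2 and V3 from a
#' point into a line so that on cortex they form bands around the foveal
#' tip of V1.
#'
#' @param variant character; one of `"double_sech_dipole"` (default),
#'   `"dipole"`, `"monopole"`, `"double_sech_monopole"`.
#' @param k scaling constant, mm of cortex per log-unit of visual field;
#'   `k > 0`.  Typical human values range from about 15 to 26.
#' @param a foveal pole, degrees of visual angle; limits the foveal
#'   singularity of the log map.  Default 1.05.
#' @param b peripheral pole, degrees; only used by the dipole variants.
#'   Default 90.  Must exceed `a`.
#' @param lambda banding shift, degrees of intermediate (pacman) space.
#'   Only used when `banded = TRUE`.  Default 0.4.
#' @param alpha numeric length 3; angular compression of V1, V2 and V3 in
#'   the pacman construction (dimensionless, `0 < alpha3 <= alpha2 <=
#'   alpha1 <= 1`).  The cortical surface ratio of the areas over any
#'   eccentricity band equals the ratio of these parameters for the
#'   double-sech variants.  Default `c(1, 0.5, 0.4)`.
#' @param banded logical; apply the foveal banding shift?  Default
#'   `FALSE`.
#'
#' @return An object of class `"retinomap"`.
#' @seealso [predict.retinomap()], [project_complex()],
#'   [fit_retinomap()], [simulate.retinomap()]
#' @examples
#' m <- retinomap("double_sech_dipole", k = 20)
#' m
#' predict(m, data.frame(ecc_deg = c(1, 4), polar_rad = c(0, pi / 4)))
#' @export
retinomap <- function(variant = c("double_sech_dipole", "dipole",
                                  "monopole", "double_sech_monopole"),
                      k = 20, a = 1.05, b = 90, lambda = 0.4,
                      alpha = c(1, 0.5, 0.4), banded = FALSE) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda >= 0)
  if (b <= a)
    stop("peripheral pole 'b' must exceed the foveal pole 'a'", call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 3L, all(is.finite(alpha)))
  if (!(alpha[3] > 0 && alpha[3] <= alpha[2] && alpha[2] <= alpha[1] &&
        alpha[1] <= 1))
    stop("'alpha' must satisfy 0 < alpha3 <= alpha2 <= alpha1 <= 1",
         call. = FALSE)
  stopifnot(is.logical(banded), length(banded) == 1L, !is.na(banded))
  structure(list(variant = variant, k = k, a = a, b = b, lambda = lambda,
                 alpha = alpha, banded = banded),
            class = "retinomap")
}

#' @export
print.retinomap <- function(x, ...) {
  cat("Retino-cortical map model (", x$variant,
      if (x$banded) ", banded" else "", ")\n", sep = "")
  cat(sprintf("  k = %g mm, a = %g deg, b = %g deg, lambda = %g deg\n",
              x$k, x$a, x$b, x$lambda))
  cat(sprintf("  alpha (V1, V2, V3) = %g, %g, %g;  pacman span = %.1f deg\n",
              x$alpha[1], x$alpha[2], x$alpha[3],
              180 * sum(x$alpha)))
  invisible(x)
}

#' @export
coef.retinomap <- function(object, ...) {
  c(k = object$k, a = object$a, b = object$b, lambda = object$lambda,
    alpha1 = object$alpha[1], alpha2 = object$alpha[2],
    alpha3 = object$alpha[3])
}

# poles of the log map / of the angular compression for a variant
.fov_poles <- function(model) {
  if (model$variant %in% c("monopole", "double_sech_monopole"))
    model$a
  else c(model$a, model$b)
}

.fov_sheared <- function(model) {
  model$variant %in% c("double_sech_monopole", "double_sech_dipole")
}

.fov_area_levels <- c("V1", "V2v", "V2d", "V3v", "V3d")

.fov_check_model <- function(model) {
  if (!inherits(model, "retinomap"))
    stop("'model' must be a retinomap object", call. = FALSE)
  model
}
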
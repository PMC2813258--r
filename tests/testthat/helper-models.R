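# shared fixtures: models at the default parameter set and a small grid
# that keeps estimator tests fast

mod_logpolar <- retinomap("dipole")
mod_dsech <- retinomap("double_sech_dipole")
mod_banded <- retinomap("double_sech_dipole", banded = TRUE)
mod_mono <- retinomap("monopole")

grid_small <- grid_spec(c(0.2, 12), n_ecc = 14, n_polar = 41)

is_V3 <- function(field) field$area %in% c("V3v", "V3d")

# complex convenience wrapper around the exported projection
proj_c <- function(model, ecc, polar, area, ...) {
  d <- project_complex(ecc, polar, area, model, ...)
  complex(real = d$x_mm, imaginary = d$y_mm)
}
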
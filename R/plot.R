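#' Plot the cortical flat map of a model
#'
#' Draws iso-eccentricity contours (dotted grey) and the images of the
#' horizontal (blue) and vertical (red) meridians for all five areas,
#' using base graphics.
#'
#' @param x a [retinomap()] object.
#' @param ecc_levels iso-eccentricity levels, degrees.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.retinomap <- function(x, ecc_levels = c(0.5, 1, 2, 4, 8, 12), ...) {
  iso <- extract_isolines(x, ecc_levels)
  graphics::plot(iso$x_mm, iso$y_mm, type = "n", asp = 1,
                 xlab = "cortical x (mm)", ylab = "cortical y (mm)",
                 main = sprintf("%s%s", x$variant,
                                if (x$banded) " (banded)" else ""), ...)
  for (d in split(iso, iso$line_id)) {
    d <- d[order(d$seq), ]
    sty <- switch(d$kind[1],
                  isoecc = list(col = "grey40", lty = 3, lwd = 1),
                  meridian_v = list(col = "red3", lty = 1, lwd = 1.6),
                  meridian_h = list(col = "blue3", lty = 1, lwd = 1.6))
    graphics::lines(d$x_mm, d$y_mm, col = sty$col, lty = sty$lty,
                    lwd = sty$lwd)
  }
  invisible(x)
}
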
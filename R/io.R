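# Readers and writers for the package's file formats.  Angles in files
# are always radians; CSV or JSON is selected by file extension.

.fov_ext <- function(path) tolower(tools::file_ext(path))

.fov_read_table <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  switch(.fov_ext(path),
         csv = utils::read.csv(path, stringsAsFactors = FALSE),
         json = as.data.frame(jsonlite::fromJSON(path)),
         stop("unsupported file extension: ", path, call. = FALSE))
}

.fov_write_table <- function(df, path) {
  switch(.fov_ext(path),
         csv = utils::write.csv(df, path, row.names = FALSE),
         json = jsonlite::write_json(df, path, digits = NA,
                                     dataframe = "columns"),
         stop("unsupported file extension: ", path, call. = FALSE))
  invisible(path)
}

#' Read and write visual-field / cortical point tables
#'
#' Visual point files carry `ecc_deg` and `polar_rad` (radians) and
#' optionally `area`; cortical outputs add `x_mm`, `y_mm` and always
#' carry `area`.  CSV and JSON are supported, chosen by extension.
#'
#' @param path file path (`.csv` or `.json`).
#' @return `read_visual_points()`: a `data.frame`.
#' @export
read_visual_points <- function(path) {
  df <- .fov_read_table(path)
  if (!all(c("ecc_deg", "polar_rad") %in% names(df)))
    stop("point file must contain ecc_deg and polar_rad columns",
         call. = FALSE)
  if (!all(is.finite(df$ecc_deg)) || !all(is.finite(df$polar_rad)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  df
}

#' @rdname read_visual_points
#' @param df a `data.frame` of projected points.
#' @export
write_cortical_points <- function(df, path) .fov_write_table(df, path)

#' Read and write model parameter files
#'
#' Flat key-value files (YAML or JSON) with keys `k`, `a_deg`, `b_deg`,
#' `lambda_deg`, `alpha1`..`alpha3`, `variant`, `banded`.  Missing keys
#' fall back to the [retinomap()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `read_map_params()`: a [retinomap()] object.
#' @export
read_map_params <- function(path) {
  cfg <- switch(.fov_ext(path),
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path),
                stop("unsupported parameter file: ", path, call. = FALSE))
  d <- formals(retinomap)
  retinomap(variant = cfg$variant %||% "double_sech_dipole",
            k = cfg$k %||% eval(d$k),
            a = cfg$a_deg %||% eval(d$a),
            b = cfg$b_deg %||% eval(d$b),
            lambda = cfg$lambda_deg %||% eval(d$lambda),
            alpha = c(cfg$alpha1 %||% 1, cfg$alpha2 %||% 0.5,
                      cfg$alpha3 %||% 0.4),
            banded = isTRUE(cfg$banded))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname read_map_params
#' @param model a [retinomap()] object.
#' @export
write_map_params <- function(model, path) {
  model <- .fov_check_model(model)
  cfg <- list(variant = model$variant, k = model$k, a_deg = model$a,
              b_deg = model$b, lambda_deg = model$lambda,
              alpha1 = model$alpha[1], alpha2 = model$alpha[2],
              alpha3 = model$alpha[3], banded = model$banded)
  switch(.fov_ext(path),
         yaml = , yml = yaml::write_yaml(cfg, path),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("unsupported parameter file: ", path, call. = FALSE))
  invisible(path)
}

#' @rdname read_visual_points
#' @param field an anisotropy field `data.frame` (one row per node).
#' @export
write_field <- function(field, path) .fov_write_table(field, path)

#' Write polylines as JSON
#'
#' One JSON object per line: `line_id`, `kind`, `level`, `area` and the
#' coordinate arrays `x_mm`, `y_mm`.
#'
#' @param isolines output of [extract_isolines()].
#' @param path output `.json` path.
#' @export
write_polylines_json <- function(isolines, path) {
  lines <- lapply(split(isolines, isolines$line_id), function(d) {
    d <- d[order(d$seq), ]
    list(line_id = d$line_id[1], kind = d$kind[1], level = d$level[1],
         area = d$area[1], x_mm = d$x_mm, y_mm = d$y_mm)
  })
  jsonlite::write_json(unname(lines), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- SVG rendering ---------------------------------------------------

.fov_svg_palette <- c(V1 = "#f4c7c3", V2v = "#c8e6c9", V2d = "#a5d6a7",
                      V3v = "#bbdefb", V3d = "#90caf9")

.fov_svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# diverging blue-white-red ramp on log2 of the value, clipped to +-3
.fov_svg_ramp <- function(v) {
  t <- pmin(pmax(log2(v), -3), 3) / 3
  up <- pmax(t, 0); dn <- pmax(-t, 0)
  grDevices::rgb(1 - dn * 0.8, 1 - (up + dn) * 0.8, 1 - up * 0.8)
}

#' Write a layered flat-map SVG
#'
#' Renders the cortical flat map as a standalone SVG: a background
#' layer, optional area fills, an optional colour-coded field layer
#' (quadrilaterals coloured by value on a diverging log ramp), then
#' iso-eccentricity contours (dotted), horizontal-meridian lines (blue)
#' and vertical-meridian lines (red).  An empty isoline set yields a
#' valid SVG with the background layer only.
#'
#' @param isolines output of [extract_isolines()] (possibly
#'   zero rows).
#' @param path output `.svg` path.
#' @param field optional `data.frame` of field quads with columns `x1`,
#'   `y1`, ..., `x4`, `y4`, `value` (see [run_cli()] figure commands).
#' @param fills optional named list of area-fill polygons
#'   (`data.frame`s with `x_mm`, `y_mm`), e.g. built from the model's
#'   outer contours.
#' @param mirror logical; render the mirrored (right-hemisphere) layout.
#' @param width_px canvas width in pixels.
#' @return The path, invisibly.
#' @export
write_flatmap_svg <- function(isolines, path, field = NULL, fills = NULL,
                              mirror = FALSE, width_px = 900) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  xs <- c(isolines$x_mm, field$x1, field$x3,
          unlist(lapply(fills, `[[`, "x_mm")))
  ys <- c(isolines$y_mm, field$y1, field$y3,
          unlist(lapply(fills, `[[`, "y_mm")))
  if (!length(xs)) { xs <- c(0, 1); ys <- c(0, 1) }
  pad <- 0.05 * max(diff(range(xs)), diff(range(ys)), 1)
  x0 <- min(xs) - pad; x1 <- max(xs) + pad
  y0 <- min(ys) - pad; y1 <- max(ys) + pad
  sc <- width_px / (x1 - x0)
  H <- (y1 - y0) * sc
  px <- function(x) if (mirror) (x1 - x) * sc else (x - x0) * sc
  py <- function(y) (y1 - y) * sc
  pts <- function(x, y) paste(sprintf("%.2f,%.2f", px(x), py(y)),
                              collapse = " ")
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
    width_px, H, width_px, H)
  w('<g id="background"><rect x="0" y="0" width="%.0f" height="%.0f" fill="white"/></g>',
    width_px, H)
  if (!is.null(fills) && length(fills)) {
    w('<g id="areas" stroke="none">')
    for (nm in names(fills))
      w('<polygon points="%s" fill="%s" fill-opacity="0.6"/>',
        pts(fills[[nm]]$x_mm, fills[[nm]]$y_mm),
        .fov_svg_esc(.fov_svg_palette[[nm]] %||% "#eeeeee"))
    w('</g>')
  }
  if (!is.null(field) && nrow(field)) {
    w('<g id="field" stroke="none">')
    cols <- .fov_svg_ramp(field$value)
    for (i in seq_len(nrow(field)))
      w('<polygon points="%s" fill="%s"/>',
        pts(c(field$x1[i], field$x2[i], field$x3[i], field$x4[i]),
            c(field$y1[i], field$y2[i], field$y3[i], field$y4[i])),
        cols[i])
    w('</g>')
  }
  if (!is.null(isolines) && nrow(isolines)) {
    style <- function(kind)
      switch(kind,
             isoecc = 'stroke="#555555" stroke-width="1" stroke-dasharray="3,4" fill="none"',
             meridian_v = 'stroke="#cc2222" stroke-width="1.8" fill="none"',
             meridian_h = 'stroke="#2244cc" stroke-width="1.8" fill="none"',
             'stroke="black" fill="none"')
    w('<g id="contours">')
    for (d in split(isolines, isolines$line_id)) {
      d <- d[order(d$seq), ]
      ok <- is.finite(d$x_mm) & is.finite(d$y_mm)
      if (sum(ok) < 2) next
      w('<polyline points="%s" %s/>', pts(d$x_mm[ok], d$y_mm[ok]),
        style(d$kind[1]))
    }
    w('</g>')
  }
  w('</svg>')
  invisible(path)
}
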
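#' Write a field as a legacy VTK structured-points file
#'
#' ASCII legacy VTK `STRUCTURED_POINTS` export of a scalar field on the voxel
#' grid (point data at voxel centers), readable by ParaView and friends.
#'
#' @param field A `temperature_field` or `flow_field`.
#' @param path Output file path.
#' @param name Scalar name recorded in the file.
#' @return Invisibly, `path`.
#' @export
write_vtk_structured_points <- function(field, path, name = "temperature_C") {
  d <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    paste(name, "on a", paste(d, collapse = " x "), "voxel grid"),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("ORIGIN", field$x[1], field$y[1], field$z[1]),
    paste("SPACING", field$spacing, field$spacing, field$spacing),
    paste("POINT_DATA", prod(d)),
    paste("SCALARS", name, "float 1"),
    "LOOKUP_TABLE default"
  ), con)
  writeLines(formatC(as.vector(field$values), format = "g", digits = 7), con)
  invisible(path)
}

#' Write anatomy labels as a legacy VTK structured-points file
#'
#' Integer tissue labels exported for inspection; the label-to-tissue mapping
#' is recorded in the header comment.
#'
#' @param vol An `anatomy_volume`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vtk_labels <- function(vol, path) {
  d <- vol$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    paste("tissue labels:",
          paste(seq_along(vol$tissues), vol$tissues, sep = "=",
                collapse = "; ")),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("ORIGIN", vol$x[1], vol$y[1], vol$z[1]),
    paste("SPACING", vol$spacing, vol$spacing, vol$spacing),
    paste("POINT_DATA", prod(d)),
    "SCALARS tissue_label int 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(as.character(as.vector(vol$labels)), con)
  invisible(path)
}

#' Write and read fitted flow-model parameters as JSON
#'
#' @param params A [flow_model_params()] object.
#' @param path JSON file path.
#' @return `write_flow_params_json` returns `path` invisibly;
#'   `read_flow_params_json` returns the reconstructed
#'   [flow_model_params()].
#' @export
write_flow_params_json <- function(params, path) {
  stopifnot(inherits(params, "flow_model_params"))
  fit <- attr(params, "fit")
  out <- list(F_o = params$F_o, F_max = params$F_max, a = params$a,
              b = params$b, form = params$form)
  if (!is.null(fit)) {
    out$fit <- list(sse = fit$sse, residuals = fit$residuals,
                    baseline_temperature = fit$baseline_temperature)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flow_params_json
#' @export
read_flow_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  flow_model_params(x$F_o, x$F_max, x$a, x$b, x$form)
}
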
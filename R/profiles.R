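#' Sample a field at arbitrary points by trilinear interpolation
#'
#' Interpolates the voxel-center values of a `temperature_field` (or
#' `flow_field`) at physical coordinates.  Points must lie within the convex
#' hull of voxel centers; sampling outside the grid is an error.  At an exact
#' voxel center the interpolant returns the stored value, and everywhere it
#' is a convex combination of the eight surrounding voxels, so probed values
#' are bounded by the field extremes.
#'
#' @param field A `temperature_field` or `flow_field`.
#' @param x,y,z Coordinates (mm), recycled to a common length.
#' @return Numeric vector of interpolated values.
#' @export
probe_field <- function(field, x, y, z) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  vals <- if (inherits(field, "flow_field")) field$values else field$values
  interp1 <- function(coords, p) {
    if (any(p < coords[1] - 1e-9) || any(p > coords[length(coords)] + 1e-9)) {
      stop("sample point outside the grid", call. = FALSE)
    }
    p <- pmin(pmax(p, coords[1]), coords[length(coords)])
    i <- findInterval(p, coords, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(coords) - 1L)
    list(i = i, w = (p - coords[i]) / (coords[i + 1] - coords[i]))
  }
  ix <- interp1(field$x, x); iy <- interp1(field$y, y); iz <- interp1(field$z, z)
  out <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) ix$w else 1 - ix$w) *
         (if (dy) iy$w else 1 - iy$w) *
         (if (dz) iz$w else 1 - iz$w)
    out <- out + w * vals[cbind(ix$i + dx, iy$i + dy, iz$i + dz)]
  }
  out
}

# Construct a profile_series; internal.
profile_series <- function(coordinate, value, quantity, anchor) {
  stopifnot(all(diff(coordinate) > 0), all(is.finite(value)))
  structure(data.frame(coordinate = coordinate, value = value),
            quantity = quantity, anchor = anchor,
            class = c("profile_series", "data.frame"))
}

#' Depth profile under a fixed surface point
#'
#' Samples a field along the depth axis at a fixed lateral/vertical anchor —
#' by default the centroid of one actuator — by trilinear interpolation.
#' Depth is measured from the posterior skin surface (z = 0).
#'
#' @param field A `temperature_field` or `flow_field`.
#' @param anchor_x,anchor_y Anchor coordinates (mm); default the (+60, +16)
#'   actuator centroid.
#' @param depths Depths (mm) to sample.
#' @return A `profile_series` data frame (`coordinate` in mm, `value`).
#' @examples
#' \donttest{
#' vol <- build_layered_anatomy(spacing = 4)
#' f <- pennes_steady(vol, actuator_layout(temperature = 45))
#' depth_profile(f, 60, 16, depths = c(10, 20, 30))
#' }
#' @export
depth_profile <- function(field, anchor_x = 60, anchor_y = 16,
                          depths = seq(2, 40, by = 2)) {
  v <- probe_field(field, anchor_x, anchor_y, depths)
  profile_series(depths, v,
                 quantity = if (inherits(field, "flow_field"))
                   "flow_L_min" else "temperature_C",
                 anchor = c(x = anchor_x, y = anchor_y))
}

#' Lateral profile at fixed depth
#'
#' Samples a field across the lateral (x) axis at a fixed depth and vertical
#' anchor, matching one horizontal pair of actuators by default.
#'
#' @param field A `temperature_field` or `flow_field`.
#' @param depth Fixed depth (mm); 20 by default.
#' @param anchor_y Vertical anchor (mm); default the actuator row y = 16.
#' @param x Lateral sample positions (mm).
#' @return A `profile_series` data frame.
#' @export
lateral_profile <- function(field, depth = 20, anchor_y = 16,
                            x = seq(-140, 140, by = 2)) {
  v <- probe_field(field, x, anchor_y, depth)
  profile_series(x, v,
                 quantity = if (inherits(field, "flow_field"))
                   "flow_L_min" else "temperature_C",
                 anchor = c(y = anchor_y, z = depth))
}

#' Extract a 2D slice from a field
#'
#' Nearest-plane extraction along one axis, with the physical coordinates of
#' the remaining axes attached — convenient for contour plots.
#'
#' @param field A `temperature_field` or `flow_field`.
#' @param axis `"x"` (sagittal), `"y"` (axial), or `"z"` (coronal/surface-
#'   parallel).
#' @param coordinate Position (mm) of the requested plane.
#' @return List with the 2D `values` matrix, the two remaining coordinate
#'   vectors, the extraction `axis`, and the `coordinate` actually used.
#' @export
slice_extract <- function(field, axis = c("x", "y", "z"), coordinate) {
  axis <- match.arg(axis)
  coords <- field[[axis]]
  if (coordinate < min(coords) - field$spacing / 2 ||
      coordinate > max(coords) + field$spacing / 2) {
    stop("slice coordinate out of range", call. = FALSE)
  }
  i <- which.min(abs(coords - coordinate))
  vals <- switch(axis,
                 x = field$values[i, , ],
                 y = field$values[, i, ],
                 z = field$values[, , i])
  rem <- setdiff(c("x", "y", "z"), axis)
  out <- list(values = vals, axis = axis, coordinate = coords[i])
  out[[rem[1]]] <- field[[rem[1]]]
  out[[rem[2]]] <- field[[rem[2]]]
  out
}

# Standard probes for a solved scene; internal helper shared by run_sweep
# and run_simulation.
standard_profiles <- function(field, flow, config) {
  pr <- config$profiles
  list(
    depth_actuator = depth_profile(field, pr$actuator_anchor[1],
                                   pr$actuator_anchor[2], pr$depths),
    depth_midline = depth_profile(field, 0, 0, pr$depths),
    lateral_20 = lateral_profile(field, pr$lateral_depths[1],
                                 pr$actuator_anchor[2], pr$lateral_x),
    lateral_30 = lateral_profile(field, pr$lateral_depths[2],
                                 pr$actuator_anchor[2], pr$lateral_x),
    flow_depth_actuator = depth_profile(flow, pr$actuator_anchor[1],
                                        pr$actuator_anchor[2], pr$depths),
    flow_depth_midline = depth_profile(flow, 0, 0, pr$depths)
  )
}

# Long summary table from the standard profiles; internal.
profiles_summary <- function(profiles, setting, F_o) {
  rows <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    q <- attr(p, "quantity")
    data.frame(setting_C = setting, probe = nm,
               coordinate_mm = p$coordinate,
               temperature_C = if (q == "temperature_C") p$value else NA_real_,
               flow_L_min = if (q == "flow_L_min") p$value else NA_real_,
               fold_change = if (q == "flow_L_min") p$value / F_o else NA_real_)
  })
  do.call(rbind, rows)
}

#' Sweep the actuator temperature setting
#'
#' Runs the full pipeline — steady bio-heat solve, flow coupling, standard
#' profile extraction — for each actuator temperature in the sweep list
#' (45 to 65 degrees C in steps of 5 by default).  A failed setting is
#' recorded and the remaining settings still run.
#'
#' @param config A simulation configuration (see [default_config()]).
#' @return A `sweep_result`: per-setting profiles, a combined long-format
#'   `summary` data frame (`setting_C`, `probe`, `coordinate_mm`,
#'   `temperature_C`, `flow_L_min`, `fold_change`), the fitted flow model,
#'   and any `failures`.
#' @export
run_sweep <- function(config = default_config()) {
  validate_config(config)
  settings <- sort(config$sweep$temperatures)
  vol <- anatomy_from_config(config)
  params <- flow_params_from_config(config)
  base <- baseline_field(vol, config$circulation$baseline_temperature)
  per_setting <- list()
  failures <- list()
  summaries <- list()
  for (s in settings) {
    key <- as.character(s)
    res <- tryCatch({
      field <- solve_scene(vol, config, actuator_temperature = s)
      flow <- flow_field(field, base, params)
      profs <- standard_profiles(field, flow, config)
      list(profiles = profs, diagnostics = field$diagnostics)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
    } else {
      per_setting[[key]] <- res
      summaries[[key]] <- profiles_summary(res$profiles, s, params$F_o)
    }
  }
  structure(list(settings = settings, results = per_setting,
                 summary = do.call(rbind, c(summaries,
                                            list(make.row.names = FALSE))),
                 params = params, failures = failures),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", length(x$results), "of", length(x$settings),
      "settings solved\n")
  if (length(x$failures)) {
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}
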
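#' Layer stack of the lumbar-back phantom
#'
#' The measured posterior-to-anterior tissue thicknesses of the lumbar back:
#' skin 1.1 mm, subcutaneous fat 13 mm, muscle 42 mm.  Depth beyond the listed
#' layers is filled with "soft tissue" (muscle-like properties), so the muscle
#' slab occupies roughly 1.5-5.5 cm from the surface.
#'
#' @param names Character vector of tissue labels, posterior first.
#' @param thicknesses Numeric vector of slab thicknesses (mm), same length.
#' @return A data frame with columns `name` and `thickness` (mm).
#' @examples
#' default_layers()
#' tissue_layers(c("skin", "muscle"), c(2, 40))
#' @export
tissue_layers <- function(names, thicknesses) {
  if (length(names) == 0) stop("empty layer list", call. = FALSE)
  if (length(names) != length(thicknesses)) {
    stop("names and thicknesses must have equal length", call. = FALSE)
  }
  if (any(thicknesses <= 0)) stop("layer thickness must be > 0", call. = FALSE)
  if (anyDuplicated(names)) stop("layer names must be unique", call. = FALSE)
  data.frame(name = as.character(names), thickness = as.numeric(thicknesses),
             stringsAsFactors = FALSE)
}

#' @rdname tissue_layers
#' @export
default_layers <- function() {
  tissue_layers(c("skin", "subcutaneous fat", "muscle"), c(1.1, 13, 42))
}

#' Build the voxelized layered phantom
#'
#' Constructs a rectangular voxel volume with planar tissue slabs stacked
#' along depth.  Coordinate convention: x is lateral with the midline at
#' x = 0, y is superior-inferior with y = 0 at the center of the actuator
#' rectangle, and z is depth from the posterior skin surface (z = 0 at the
#' surface, increasing anterior).  Voxels are classified by their center
#' against half-open layer boundaries `[lower, upper)`; depth beyond the last
#' listed layer is filled with `fill`.
#'
#' @param layers Layer stack from [tissue_layers()]; default [default_layers()].
#' @param lateral_extent,vertical_extent,depth_extent Domain size (mm).
#'   Extents are rounded up to a whole number of voxels.
#' @param spacing Isotropic voxel edge length (mm).
#' @param fill Tissue label used anterior to the listed stack.
#' @return An `anatomy_volume`: list with integer `labels` array
#'   (nx, ny, nz), the `tissues` label set, `spacing`, `dims`, and voxel
#'   center coordinate vectors `x`, `y`, `z` (mm).
#' @examples
#' vol <- build_layered_anatomy(spacing = 2)
#' table(vol$tissues[vol$labels])["muscle"]
#' @export
build_layered_anatomy <- function(layers = default_layers(),
                                  lateral_extent = 300,
                                  vertical_extent = 200,
                                  depth_extent = 100,
                                  spacing = 1,
                                  fill = "soft tissue") {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("spacing must be a positive number", call. = FALSE)
  }
  if (nrow(layers) == 0) stop("empty layer list", call. = FALSE)
  if (depth_extent < sum(layers$thickness)) {
    stop("depth_extent must cover the layer stack", call. = FALSE)
  }
  nx <- as.integer(ceiling(lateral_extent / spacing - 1e-9))
  ny <- as.integer(ceiling(vertical_extent / spacing - 1e-9))
  nz <- as.integer(ceiling(depth_extent / spacing - 1e-9))

  tissues <- unique(c(layers$name, fill))
  upper <- cumsum(layers$thickness)
  zc <- (seq_len(nz) - 0.5) * spacing
  # half-open intervals [lower, upper); beyond the stack -> fill
  zlab <- rep.int(match(fill, tissues), nz)
  for (i in rev(seq_len(nrow(layers)))) {
    zlab[zc < upper[i]] <- match(layers$name[i], tissues)
  }
  labels <- array(rep(zlab, each = nx * ny), dim = c(nx, ny, nz))
  storage.mode(labels) <- "integer"

  structure(list(
    labels = labels,
    tissues = tissues,
    spacing = spacing,
    dims = c(nx = nx, ny = ny, nz = nz),
    x = (seq_len(nx) - 0.5) * spacing - nx * spacing / 2,
    y = (seq_len(ny) - 0.5) * spacing - ny * spacing / 2,
    z = zc
  ), class = "anatomy_volume")
}

#' @export
print.anatomy_volume <- function(x, ...) {
  cat("anatomy_volume:", paste(x$dims, collapse = " x "),
      "voxels @", x$spacing, "mm\n")
  counts <- table(factor(x$tissues[x$labels], levels = x$tissues))
  for (t in names(counts)) cat(sprintf("  %-18s %d voxels\n", t, counts[[t]]))
  invisible(x)
}

#' Add a synthetic spinal column to a phantom
#'
#' Overwrites slab labels with a midline column of concentric shells running
#' along the superior-inferior (y) axis: vertebra outermost, then epidural
#' fat, CSF, and the spinal cord at the core.  Shell thicknesses follow the
#' measured values (epidural fat 2.2 mm, CSF 2.9 mm, cord 1.9 mm); the
#' concentric arrangement itself is a simplification, and the feature is off
#' by default because the standard probe lines (x = +-60 mm) lie lateral to
#' the column.
#'
#' @param vol An `anatomy_volume`.
#' @param vertebra,epidural_fat,csf Shell thicknesses (mm), outer to inner.
#' @param cord_radius Radius of the innermost cord cylinder (mm).
#' @param center_x Lateral position of the column axis (mm).
#' @param start_depth Depth (mm) of the posterior-most point of the column.
#' @return The modified `anatomy_volume`.
#' @export
add_spine_column <- function(vol, vertebra = 10, epidural_fat = 2.2,
                             csf = 2.9, cord_radius = 1.9,
                             center_x = 0, start_depth = 58.9) {
  stopifnot(inherits(vol, "anatomy_volume"))
  r_cord <- cord_radius
  r_csf <- r_cord + csf
  r_epi <- r_csf + epidural_fat
  r_out <- r_epi + vertebra
  if (start_depth <= 0) {
    stop("spine column would overlap the z = 0 skin surface", call. = FALSE)
  }
  z_axis <- start_depth + r_out
  if (z_axis + r_out > max(vol$z) + vol$spacing / 2 ||
      abs(center_x) + r_out > max(abs(vol$x)) + vol$spacing / 2) {
    stop("spine column does not fit inside the domain", call. = FALSE)
  }
  shells <- c("vertebrae", "epidural fat", "CSF", "spinal cord")
  tissues <- unique(c(vol$tissues, shells))
  labels <- vol$labels
  storage.mode(labels) <- "integer"
  # distance from the column axis in the (x, z) plane, constant in y
  d2 <- outer((vol$x - center_x)^2, (vol$z - z_axis)^2, "+")
  ring <- function(rin, rout) d2 >= rin^2 & d2 < rout^2
  sel <- list(ring(r_epi, r_out), ring(r_csf, r_epi),
              ring(r_cord, r_csf), d2 < r_cord^2)
  ny <- vol$dims[["ny"]]
  for (s in seq_along(shells)) {
    m <- which(sel[[s]], arr.ind = TRUE)      # (ix, iz) pairs
    if (nrow(m) == 0) next
    code <- match(shells[s], tissues)
    for (jy in seq_len(ny)) labels[cbind(m[, 1], jy, m[, 2])] <- code
  }
  vol$labels <- labels
  vol$tissues <- tissues
  vol
}

#' Actuator layout on the skin surface
#'
#' The massage bed's four heated rollers are modeled as fixed-temperature
#' contact discs of diameter 45 mm, arranged as the vertices of a rectangle:
#' lateral positions +-60 mm, vertical separation 32 mm.
#'
#' @param centers Numeric matrix (n x 2) of disc centers (x, y) in mm.
#' @param radius Contact disc radius (mm); default 22.5.
#' @param temperature Dirichlet contact temperature (degrees C).  The
#'   device's operating range is 45-65; values outside it warn but run.
#' @return An `actuator_layout` object.
#' @examples
#' actuator_layout(temperature = 55)
#' @export
actuator_layout <- function(centers = rbind(c(60, 16), c(60, -16),
                                            c(-60, 16), c(-60, -16)),
                            radius = 22.5, temperature = 45) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  stopifnot(radius > 0, is.finite(temperature))
  if (temperature < 45 || temperature > 65) {
    warning("actuator temperature ", temperature,
            " is outside the device's 45-65 degree C operating range")
  }
  structure(list(centers = centers, radius = radius,
                 temperature = temperature),
            class = "actuator_layout")
}

#' Assign boundary conditions to the posterior skin surface
#'
#' Every z = 0 surface voxel receives exactly one condition with precedence
#' actuator > mat > uncovered.  A voxel belongs to an actuator iff its center
#' lies within the contact disc.  Partially overlapping discs at the shared
#' actuator temperature merge into one contact patch (the default layout's
#' vertical pairs, 32 mm apart with 45 mm discs, overlap by construction,
#' echoing the device's two-lobed rollers); a disc whose center falls inside
#' another disc is rejected as a placement error, as is a disc clipped by the
#' domain edge.
#'
#' @param vol An `anatomy_volume`.
#' @param actuators An [actuator_layout()], or `NULL` for mat-only heating.
#' @param mat_temperature Mat Dirichlet temperature (degrees C).
#' @param mat_half_width Lateral half-extent of the mat (mm); surface voxels
#'   with `|x|` beyond it are "uncovered" and exchange heat convectively with
#'   the room.  `Inf` (default) covers the full surface.
#' @return A `surface_conditions` object with an integer `condition` matrix
#'   (nx x ny; 0 = mat, k > 0 = k-th actuator, -1 = uncovered) and a
#'   `temperature` matrix holding the Dirichlet value (NA where uncovered).
#' @export
surface_condition_masks <- function(vol, actuators = actuator_layout(),
                                    mat_temperature = 40,
                                    mat_half_width = Inf) {
  stopifnot(inherits(vol, "anatomy_volume"))
  nx <- vol$dims[["nx"]]; ny <- vol$dims[["ny"]]
  cond <- matrix(0L, nx, ny)
  temp <- matrix(mat_temperature, nx, ny)
  if (is.finite(mat_half_width)) {
    unc <- abs(vol$x) > mat_half_width
    cond[unc, ] <- -1L
    temp[unc, ] <- NA_real_
  }
  if (!is.null(actuators)) {
    stopifnot(inherits(actuators, "actuator_layout"))
    cen <- actuators$centers; r <- actuators$radius
    if (nrow(cen) > 1) {
      d <- as.matrix(stats::dist(cen))
      if (any(d[upper.tri(d)] < r)) {
        stop("overlapping actuator discs: a disc center lies inside another disc",
             call. = FALSE)
      }
    }
    half_x <- nx * vol$spacing / 2; half_y <- ny * vol$spacing / 2
    if (any(abs(cen[, 1]) + r > half_x | abs(cen[, 2]) + r > half_y)) {
      stop("actuator disc clipped by the domain edge", call. = FALSE)
    }
    for (a in seq_len(nrow(cen))) {
      inside <- outer((vol$x - cen[a, 1])^2, (vol$y - cen[a, 2])^2, "+") <= r^2
      cond[inside] <- a
      temp[inside] <- actuators$temperature
    }
  }
  structure(list(condition = cond, temperature = temp,
                 actuators = actuators, mat_temperature = mat_temperature,
                 mat_half_width = mat_half_width),
            class = "surface_conditions")
}
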
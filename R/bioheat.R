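#' Thermal boundary specification
#'
#' Collects every boundary condition for a steady solve: the per-voxel skin
#' surface assignment (actuator/mat Dirichlet values or uncovered convective
#' exchange), the convective pair (`h`, `T_amb`) applied to uncovered surface
#' voxels, the Dirichlet value applied at the cut boundaries where the
#' phantom is truncated (anterior face and, optionally, the four side faces),
#' and whether side faces are instead treated as adiabatic (used for
#' one-dimensional slab configurations).
#'
#' @param surface A `surface_conditions` object from
#'   [surface_condition_masks()].
#' @param h Convective heat-transfer coefficient (W m^-2 K^-1) for uncovered
#'   skin; default 5.
#' @param T_amb Ambient room temperature (degrees C); default 25.
#' @param cut_temperature Dirichlet value (degrees C) at cut boundaries;
#'   default core temperature 37.
#' @param sides `"dirichlet"` (default) clamps the four lateral faces to
#'   `cut_temperature`; `"adiabatic"` makes them no-flux.
#' @param anterior `"dirichlet"` (default) or `"adiabatic"` for the deep
#'   (z = max) face; its Dirichlet value is `anterior_temperature`.
#' @param anterior_temperature Dirichlet value for the anterior face;
#'   defaults to `cut_temperature`.
#' @return A `thermal_boundary_spec` object.
#' @export
thermal_boundary_spec <- function(surface, h = 5, T_amb = 25,
                                  cut_temperature = 37,
                                  sides = c("dirichlet", "adiabatic"),
                                  anterior = c("dirichlet", "adiabatic"),
                                  anterior_temperature = cut_temperature) {
  stopifnot(inherits(surface, "surface_conditions"), h >= 0)
  structure(list(surface = surface, h = h, T_amb = T_amb,
                 cut_temperature = cut_temperature,
                 sides = match.arg(sides), anterior = match.arg(anterior),
                 anterior_temperature = anterior_temperature),
            class = "thermal_boundary_spec")
}

#' Options for the steady-state solve
#'
#' @param tolerance Relative residual tolerance of the conjugate-gradient
#'   iteration; default 1e-8.
#' @param max_iterations Iteration cap; default 20000.
#' @return A `steady_solve_options` object.
#' @export
steady_solve_options <- function(tolerance = 1e-8, max_iterations = 20000) {
  stopifnot(tolerance > 0, tolerance < 1, max_iterations >= 1)
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "steady_solve_options")
}

#' Assemble the steady-state Pennes system
#'
#' Discretizes the steady Pennes bio-heat equation
#' \deqn{-\nabla\cdot(k\nabla T) + \rho_b c_b w_b (T - T_b) = Q_m}
#' on the voxel grid with a 7-point finite-volume stencil (all terms per unit
#' volume).  Face conductivity between neighboring voxels is the harmonic
#' mean of their conductivities.  Perfusion enters in the classical sink form
#' \eqn{\rho_b c_b w_b (T_b - T)}: a diagonal contribution plus a source
#' toward blood temperature, which keeps the operator symmetric positive
#' definite.  Dirichlet boundary faces are eliminated by ghost-value
#' substitution over the half-cell distance (coefficient `2k/h^2`);
#' convective (Robin) faces contribute `h/h_vox` on the diagonal and
#' `h T_amb / h_vox` on the right-hand side.
#'
#' @param vol An `anatomy_volume`.
#' @param props Property table; default [property_table()].
#' @param bcs A [thermal_boundary_spec()].
#' @param extra_source Optional array (same dims as the grid) of additional
#'   volumetric heat (W m^-3), used by the manufactured-solution check.
#' @return A `steady_system`: sparse SPD matrix `A` (dgCMatrix), right-hand
#'   side `b`, grid `dims`/`spacing`, and the originating `vol` and `bcs`.
#' @export
assemble_steady_system <- function(vol, props = property_table(), bcs,
                                   extra_source = NULL) {
  stopifnot(inherits(vol, "anatomy_volume"),
            inherits(bcs, "thermal_boundary_spec"))
  pv <- property_vectors(vol, props)
  nx <- vol$dims[["nx"]]; ny <- vol$dims[["ny"]]; nz <- vol$dims[["nz"]]
  n <- nx * ny * nz
  h <- vol$spacing / 1000                    # voxel edge in meters
  lab <- as.vector(vol$labels)
  kv <- pv$k[lab]
  perf <- pv$rho_b[lab] * pv$c_b[lab] * pv$w_b[lab]   # W m^-3 K^-1
  diag_acc <- perf
  rhs <- perf * pv$T_b[lab] + pv$Q_m[lab]
  if (!is.null(extra_source)) rhs <- rhs + as.vector(extra_source)

  idx <- array(seq_len(n), c(nx, ny, nz))
  neigh <- function(i1, i2) {
    g <- 2 * kv[i1] * kv[i2] / (kv[i1] + kv[i2]) / h^2
    diag_acc[i1] <<- diag_acc[i1] + g
    diag_acc[i2] <<- diag_acc[i2] + g
    list(i1 = i1, i2 = i2, g = g)
  }
  px <- neigh(as.vector(idx[-nx, , , drop = FALSE]),
              as.vector(idx[-1, , , drop = FALSE]))
  py <- neigh(as.vector(idx[, -ny, , drop = FALSE]),
              as.vector(idx[, -1, , drop = FALSE]))
  pz <- neigh(as.vector(idx[, , -nz, drop = FALSE]),
              as.vector(idx[, , -1, drop = FALSE]))

  dirichlet_face <- function(ii, value) {
    g <- 2 * kv[ii] / h^2
    diag_acc[ii] <<- diag_acc[ii] + g
    rhs[ii] <<- rhs[ii] + g * value
  }

  # posterior skin surface (z = 0 face)
  surf <- bcs$surface
  i0 <- as.vector(idx[, , 1])
  cond <- as.vector(surf$condition)
  tsurf <- as.vector(surf$temperature)
  covered <- cond >= 0L
  if (any(covered)) dirichlet_face(i0[covered], tsurf[covered])
  if (any(!covered)) {                        # Robin exchange with the room
    iu <- i0[!covered]
    diag_acc[iu] <- diag_acc[iu] + bcs$h / h
    rhs[iu] <- rhs[iu] + bcs$h * bcs$T_amb / h
  }
  # anterior (deep) face
  if (bcs$anterior == "dirichlet") {
    dirichlet_face(as.vector(idx[, , nz]), bcs$anterior_temperature)
  }
  # lateral cut faces
  if (bcs$sides == "dirichlet") {
    for (ii in list(as.vector(idx[1, , ]), as.vector(idx[nx, , ]),
                    as.vector(idx[, 1, ]), as.vector(idx[, ny, ]))) {
      dirichlet_face(ii, bcs$cut_temperature)
    }
  }

  A <- Matrix::sparseMatrix(
    i = c(px$i1, py$i1, pz$i1, px$i2, py$i2, pz$i2, seq_len(n)),
    j = c(px$i2, py$i2, pz$i2, px$i1, py$i1, pz$i1, seq_len(n)),
    x = c(-px$g, -py$g, -pz$g, -px$g, -py$g, -pz$g, diag_acc),
    dims = c(n, n))

  structure(list(A = A, b = rhs, dims = vol$dims, spacing = vol$spacing,
                 vol = vol, bcs = bcs),
            class = "steady_system")
}

# Jacobi-preconditioned conjugate gradients for the SPD steady system.
# Deterministic: fixed start, no randomized components.  Internal.
pcg_solve <- function(A, b, x0, tolerance, max_iterations) {
  minv <- 1 / Matrix::diag(A)
  x <- x0
  r <- b - as.numeric(A %*% x)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  rnorm <- sqrt(sum(r * r))
  it <- 0L
  while (rnorm > tolerance * bnorm && it < max_iterations) {
    it <- it + 1L
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rnorm <- sqrt(sum(r * r))
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = it, residual = rnorm / bnorm,
       converged = rnorm <= tolerance * bnorm)
}

#' Solve the assembled steady-state system
#'
#' Runs a deterministic Jacobi-preconditioned conjugate-gradient iteration
#' from a uniform 37 degree C start until the relative residual drops below
#' the tolerance.
#'
#' @param system A `steady_system` from [assemble_steady_system()].
#' @param options A [steady_solve_options()].
#' @return A `temperature_field`: scalar `values` array (degrees C) congruent
#'   with the anatomy grid, coordinate vectors, and solver `diagnostics`
#'   (iterations, final relative residual).
#' @export
solve_steady <- function(system, options = steady_solve_options()) {
  stopifnot(inherits(system, "steady_system"),
            inherits(options, "steady_solve_options"))
  n <- prod(system$dims)
  res <- pcg_solve(system$A, system$b, rep(37, n),
                   options$tolerance, options$max_iterations)
  if (!res$converged) {
    stop(sprintf(
      "steady solve did not converge in %d iterations (relative residual %.3e)",
      res$iterations, res$residual), call. = FALSE)
  }
  temperature_field(array(res$x, system$dims), system$vol,
                    diagnostics = list(iterations = res$iterations,
                                       residual = res$residual,
                                       tolerance = options$tolerance))
}

# Construct a temperature_field congruent with an anatomy grid.  Internal.
temperature_field <- function(values, vol, diagnostics = NULL) {
  stopifnot(all(dim(values) == vol$dims))
  structure(list(values = values, spacing = vol$spacing, dims = vol$dims,
                 x = vol$x, y = vol$y, z = vol$z,
                 diagnostics = diagnostics),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat("temperature_field:", paste(x$dims, collapse = " x "),
      "voxels @", x$spacing, "mm; range",
      sprintf("%.2f-%.2f C", min(x$values), max(x$values)), "\n")
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  solver: %d iterations, relative residual %.2e\n",
                x$diagnostics$iterations, x$diagnostics$residual))
  }
  invisible(x)
}

#' Solve a heating scene in one call
#'
#' Convenience wrapper: surface masks + boundary spec + assembly + solve.
#'
#' @param vol An `anatomy_volume`.
#' @param actuators An [actuator_layout()] or `NULL` for mat-only.
#' @param props Property table.
#' @param mat_temperature Mat Dirichlet value (degrees C).
#' @param mat_half_width Mat lateral half-extent (mm), `Inf` = full coverage.
#' @param options Solver options.
#' @param ... Further arguments passed to [thermal_boundary_spec()].
#' @return A `temperature_field`.
#' @examples
#' \donttest{
#' vol <- build_layered_anatomy(spacing = 4)
#' field <- pennes_steady(vol, actuator_layout(temperature = 45))
#' }
#' @export
pennes_steady <- function(vol, actuators = actuator_layout(),
                          props = property_table(), mat_temperature = 40,
                          mat_half_width = Inf,
                          options = steady_solve_options(), ...) {
  surf <- surface_condition_masks(vol, actuators, mat_temperature,
                                  mat_half_width)
  bcs <- thermal_boundary_spec(surf, ...)
  solve_steady(assemble_steady_system(vol, props, bcs), options)
}

#' Uniform unheated reference field
#'
#' The baseline against which temperature elevations (and hence flow
#' predictions) are measured: uniform core temperature, 37 degrees C by
#' default.
#'
#' @param vol An `anatomy_volume`.
#' @param core_temperature Reference temperature (degrees C).
#' @return A `temperature_field`.
#' @export
baseline_field <- function(vol, core_temperature = 37) {
  temperature_field(array(core_temperature, vol$dims), vol)
}

#' Closed-form one-dimensional Pennes slab solution
#'
#' Analytic steady solution of the 1D Pennes equation on a homogeneous slab
#' with Dirichlet temperatures at both faces, used as a verification oracle.
#' With perfusion the solution is
#' \deqn{T(x) = T_p + C_1 e^{x/\lambda} + C_2 e^{-x/\lambda}}
#' with penetration length \eqn{\lambda = \sqrt{k / (\rho_b c_b w_b)}} and
#' particular solution \eqn{T_p = T_b + Q_m / (\rho_b c_b w_b)}.  Without
#' perfusion it reduces to the linear-plus-quadratic conduction solution.
#'
#' @param k Thermal conductivity (W m^-1 K^-1).
#' @param rho_b,c_b Blood density (kg m^-3) and specific heat (J kg^-1 K^-1).
#' @param w_b Perfusion rate (1/s).
#' @param T_b Blood temperature (degrees C).
#' @param Q_m Metabolic heat (W m^-3).
#' @param L Slab thickness (mm).
#' @param T_left,T_right Dirichlet values at x = 0 and x = L (degrees C).
#' @param positions Positions (mm) at which to evaluate.
#' @return Numeric vector of temperatures (degrees C) at `positions`.
#' @examples
#' analytic_slab_1d(0.47, 1057, 3600, 4e-4, 36.55, 457,
#'                  L = 60, T_left = 45, T_right = 37,
#'                  positions = c(0, 10, 20, 30))
#' @export
analytic_slab_1d <- function(k, rho_b, c_b, w_b, T_b, Q_m,
                             L, T_left, T_right, positions) {
  if (L <= 0) stop("slab thickness must be positive", call. = FALSE)
  Lm <- L / 1000
  xm <- positions / 1000
  if (w_b > 0) {
    pc <- rho_b * c_b * w_b
    lambda <- sqrt(k / pc)
    Tp <- T_b + Q_m / pc
    # C1, C2 from T(0) = T_left, T(L) = T_right
    e <- exp(Lm / lambda)
    a1 <- T_left - Tp
    a2 <- T_right - Tp
    C1 <- (a2 - a1 / e) / (e - 1 / e)
    C2 <- a1 - C1
    Tp + C1 * exp(xm / lambda) + C2 * exp(-xm / lambda)
  } else {
    # -k T'' = Q_m
    T_left + (T_right - T_left) * xm / Lm + Q_m / (2 * k) * xm * (Lm - xm)
  }
}

#' Grid-convergence verification by manufactured solution
#'
#' Imposes the smooth field
#' \eqn{T(x,y,z) = 37 + A \sin(\pi x'/L)\sin(\pi y'/L)\sin(\pi z/L)}
#' (primes: coordinates shifted so the field vanishes on all faces of a
#' homogeneous cube), computes the volumetric source it implies under pure
#' conduction, solves the discrete system at each spacing, and reports the
#' observed L2-error convergence order of the second-order stencil.
#'
#' @param spacings Voxel spacings (mm), at least three, finest last.
#' @param side Cube edge length (mm).
#' @param amplitude Field amplitude A (degrees C).
#' @param k Conductivity of the homogeneous medium.
#' @return List with `spacings`, `l2_errors`, and the observed `order`
#'   (log-log regression slope of error on spacing).
#' @export
manufactured_solution_check <- function(spacings = c(4, 2, 1), side = 40,
                                        amplitude = 2, k = 0.47) {
  stopifnot(length(spacings) >= 3)
  props <- data.frame(tissue = "medium", k = k, rho = 1000, c = 3500,
                      rho_b = 0, c_b = 0, w_b = 0, T_b = 37, Q_m = 0)
  errs <- vapply(spacings, function(sp) {
    vol <- build_layered_anatomy(tissue_layers("medium", side),
                                 lateral_extent = side, vertical_extent = side,
                                 depth_extent = side, spacing = sp,
                                 fill = "medium")
    Lm <- side / 1000
    xs <- (vol$x - min(vol$x) + sp / 2) / 1000   # shifted to [h/2, L - h/2]
    ys <- (vol$y - min(vol$y) + sp / 2) / 1000
    zs <- vol$z / 1000
    sx <- sin(pi * xs / Lm); sy <- sin(pi * ys / Lm); sz <- sin(pi * zs / Lm)
    exact <- 37 + amplitude * outer(outer(sx, sy), sz)
    q <- 3 * k * (pi / Lm)^2 * (exact - 37)
    surf <- surface_condition_masks(vol, actuators = NULL,
                                    mat_temperature = 37)
    bcs <- thermal_boundary_spec(surf, cut_temperature = 37)
    sys <- assemble_steady_system(vol, props, bcs, extra_source = q)
    field <- solve_steady(sys, steady_solve_options(tolerance = 1e-10))
    sqrt(mean((field$values - exact)^2))
  }, numeric(1))
  fit <- stats::lm(log(errs) ~ log(spacings))
  list(spacings = spacings, l2_errors = errs,
       order = unname(stats::coef(fit)[2]))
}
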
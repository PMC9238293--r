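test_that("assembled matrix is symmetric with harmonic-mean face conductivity", {
  # two-voxel column: skin over subcutaneous-fat-like conductivities
  props <- data.frame(tissue = c("a", "b"), k = c(0.37, 0.47),
                      rho = 1000, c = 3500, rho_b = 0, c_b = 0, w_b = 0,
                      T_b = 37, Q_m = 0)
  vol <- build_layered_anatomy(tissue_layers(c("a", "b"), c(1, 1)),
                               lateral_extent = 1, vertical_extent = 1,
                               depth_extent = 2, spacing = 1, fill = "b")
  surf <- surface_condition_masks(vol, NULL, mat_temperature = 40)
  bcs <- thermal_boundary_spec(surf, sides = "adiabatic")
  sys <- assemble_steady_system(vol, props, bcs)
  kf <- 2 * 0.37 * 0.47 / (0.37 + 0.47)
  expect_equal(sys$A[1, 2], -kf / 1e-3^2)
  expect_equal(sys$A[2, 1], -kf / 1e-3^2)

  # symmetry on a small heterogeneous anatomy
  vol2 <- small_scene_volume(spacing = 8)
  surf2 <- surface_condition_masks(vol2, small_scene_actuators(55))
  sys2 <- assemble_steady_system(vol2, property_table(),
                                 thermal_boundary_spec(surf2))
  expect_equal(Matrix::norm(sys2$A - Matrix::t(sys2$A), "M"), 0)
})

test_that("all-Dirichlet-37 conduction scene returns uniform 37", {
  props <- data.frame(tissue = "muscle", k = 0.47, rho = 1142, c = 3432,
                      rho_b = 0, c_b = 0, w_b = 0, T_b = 37, Q_m = 0)
  vol <- build_layered_anatomy(tissue_layers("muscle", 6),
                               lateral_extent = 6, vertical_extent = 6,
                               depth_extent = 6, spacing = 2, fill = "muscle")
  surf <- surface_condition_masks(vol, NULL, mat_temperature = 37)
  sys <- assemble_steady_system(vol, props,
                                thermal_boundary_spec(surf,
                                                      cut_temperature = 37))
  field <- solve_steady(sys)
  expect_equal(max(abs(field$values - 37)), 0, tolerance = 1e-10)
})

test_that("unregistered labels are caught at assembly", {
  vol <- build_layered_anatomy(tissue_layers("mystery", 6),
                               lateral_extent = 6, vertical_extent = 6,
                               depth_extent = 6, spacing = 2,
                               fill = "mystery")
  surf <- surface_condition_masks(vol, NULL)
  expect_error(assemble_steady_system(vol, property_table(),
                                      thermal_boundary_spec(surf)),
               "unregistered")
})

test_that("analytic slab solution honors boundaries and muscle penetration length", {
  m <- tissue_properties("muscle")
  # penetration length for muscle is ~17.6 mm
  lambda <- sqrt(m$k / (m$rho_b * m$c_b * m$w_b)) * 1000
  expect_equal(lambda, 17.6, tolerance = 0.005)

  pos <- c(0, 7, 23, 60)
  v <- analytic_slab_1d(m$k, m$rho_b, m$c_b, m$w_b, m$T_b, m$Q_m,
                        L = 60, T_left = 45, T_right = 37, positions = pos)
  expect_equal(v[1], 45)
  expect_equal(v[4], 37)

  # T_left = T_right = T_p gives the constant particular solution
  Tp <- m$T_b + m$Q_m / (m$rho_b * m$c_b * m$w_b)
  vp <- analytic_slab_1d(m$k, m$rho_b, m$c_b, m$w_b, m$T_b, m$Q_m,
                         L = 60, T_left = Tp, T_right = Tp,
                         positions = c(5, 30, 55))
  expect_equal(vp, rep(Tp, 3), tolerance = 1e-12)

  # w_b = 0 reduces to the conduction solution (linear when Q_m = 0)
  v0 <- analytic_slab_1d(0.47, 1057, 3600, 0, 37, 0, L = 10,
                         T_left = 40, T_right = 30, positions = c(0, 5, 10))
  expect_equal(v0, c(40, 35, 30))
  expect_error(analytic_slab_1d(0.47, 1057, 3600, 0, 37, 0, L = -1,
                                T_left = 40, T_right = 30, positions = 0),
               "positive")
})

test_that("1D-configured 3D solve matches the analytic Pennes slab", {
  m <- tissue_properties("muscle")
  L <- 60
  vol <- build_layered_anatomy(tissue_layers("muscle", L),
                               lateral_extent = 0.5, vertical_extent = 0.5,
                               depth_extent = L, spacing = 0.5,
                               fill = "muscle")
  surf <- surface_condition_masks(vol, NULL, mat_temperature = 45)
  bcs <- thermal_boundary_spec(surf, sides = "adiabatic",
                               cut_temperature = 37)
  field <- solve_steady(assemble_steady_system(vol, property_table(), bcs),
                        steady_solve_options(tolerance = 1e-10))
  exact <- analytic_slab_1d(m$k, m$rho_b, m$c_b, m$w_b, m$T_b, m$Q_m,
                            L, 45, 37, positions = vol$z)
  expect_lt(max(abs(as.vector(field$values) - exact)), 0.05)
})

test_that("manufactured-solution convergence is second order", {
  mc <- manufactured_solution_check(c(4, 2, 1))
  expect_true(all(diff(mc$l2_errors) < 0))   # error decreases on refinement
  expect_gte(mc$order, 1.8)
})

test_that("discrete maximum principle holds on randomized scenes", {
  for (seed in c(3, 17, 42)) {
    sc <- random_scene(seed)
    expect_gte(min(sc$field$values), sc$bounds[1] - 1e-7)
    expect_lte(max(sc$field$values), sc$bounds[2] + 1e-7)
  }
})

test_that("temperature rises everywhere with actuator setting", {
  vol <- small_scene_volume()
  opts <- steady_solve_options(tolerance = 1e-10)
  f45 <- pennes_steady(vol, small_scene_actuators(45), options = opts)
  f65 <- pennes_steady(vol, small_scene_actuators(65), options = opts)
  expect_gte(min(f65$values - f45$values), -1e-6)
  # the field under the centroid decreases monotonically with depth
  prof <- probe_field(f45, 40, 12, seq(2, 56, by = 2))
  expect_true(all(diff(prof) < 0))
})

test_that("solved field is mirror symmetric for a symmetric scene", {
  vol <- small_scene_volume()
  f <- pennes_steady(vol, small_scene_actuators(55),
                     options = steady_solve_options(tolerance = 1e-10))
  flip <- f$values[rev(seq_len(dim(f$values)[1])), , ]
  expect_lt(max(abs(f$values - flip)), 1e-9)
})

test_that("solver reports diagnostics and enforces its iteration cap", {
  vol <- small_scene_volume(spacing = 8)
  surf <- surface_condition_masks(vol, small_scene_actuators(45))
  sys <- assemble_steady_system(vol, property_table(),
                                thermal_boundary_spec(surf))
  field <- solve_steady(sys)
  expect_lte(field$diagnostics$residual, 1e-8)
  expect_gt(field$diagnostics$iterations, 0)
  expect_error(solve_steady(sys, steady_solve_options(max_iterations = 2)),
               "did not converge")
})

test_that("baseline field is a congruent uniform reference", {
  vol <- small_scene_volume(spacing = 8)
  base <- baseline_field(vol)
  expect_true(all(base$values == 37))
  expect_equal(unname(dim(base$values)), unname(vol$dims))
  expect_equal(max(abs(base$values - baseline_field(vol)$values)), 0)
})

test_that("uncovered skin exchanges heat with the room convectively", {
  # mat restricted to |x| <= 20 mm: uncovered skin cools toward ambient
  vol <- small_scene_volume()
  f_cov <- pennes_steady(vol, NULL, mat_temperature = 40)
  f_unc <- pennes_steady(vol, NULL, mat_temperature = 40, mat_half_width = 20)
  edge <- length(vol$x)   # most lateral voxel column
  expect_lt(f_unc$values[edge, 1, 1], f_cov$values[edge, 1, 1])
  expect_gt(min(f_unc$values), 25)   # bounded below by ambient
})
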
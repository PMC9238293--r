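# Shared fixtures: small scenes built in code.

# Compact four-actuator scene that solves in ~1 s.
small_scene_volume <- function(spacing = 4) {
  build_layered_anatomy(spacing = spacing, lateral_extent = 160,
                        vertical_extent = 96, depth_extent = 60)
}

small_scene_actuators <- function(temperature = 45) {
  actuator_layout(rbind(c(40, 12), c(40, -12), c(-40, 12), c(-40, -12)),
                  radius = 14, temperature = temperature)
}

# Homogeneous random conduction scene for maximum-principle checks:
# random conductivity, random perfusion, Q_m = 0, random Dirichlet values.
random_scene <- function(seed) {
  set.seed(seed)
  k <- runif(1, 0.1, 1)
  w_b <- runif(1, 0, 1e-3)
  T_b <- runif(1, 35, 38)
  props <- data.frame(tissue = "medium", k = k, rho = 1000, c = 3500,
                      rho_b = 1057, c_b = 3600, w_b = w_b, T_b = T_b, Q_m = 0)
  n <- sample(5:9, 3, replace = TRUE)
  sp <- 2
  vol <- build_layered_anatomy(tissue_layers("medium", n[3] * sp),
                               lateral_extent = n[1] * sp,
                               vertical_extent = n[2] * sp,
                               depth_extent = n[3] * sp,
                               spacing = sp, fill = "medium")
  mat_T <- runif(1, 30, 45)
  cut_T <- runif(1, 30, 45)
  surf <- surface_condition_masks(vol, NULL, mat_temperature = mat_T)
  bcs <- thermal_boundary_spec(surf, cut_temperature = cut_T)
  field <- solve_steady(assemble_steady_system(vol, props, bcs),
                        steady_solve_options(tolerance = 1e-10))
  list(field = field, bounds = range(c(mat_T, cut_T, T_b)))
}

# Tiny sweep configuration sized for tests.
tiny_config <- function(spacing = 4, actuator_temperature = 45) {
  cfg <- default_config(spacing = spacing,
                        actuator_temperature = actuator_temperature)
  cfg$anatomy$lateral_extent <- 160
  cfg$anatomy$vertical_extent <- 96
  cfg$anatomy$depth_extent <- 60
  cfg$sources$actuators$centers <- list(c(40, 12), c(40, -12),
                                        c(-40, 12), c(-40, -12))
  cfg$sources$actuators$radius <- 14
  cfg$profiles$actuator_anchor <- c(40, 12)
  cfg$profiles$depths <- seq(4, 40, by = 4)
  cfg$profiles$lateral_x <- seq(-70, 70, by = 4)
  cfg$sweep$temperatures <- c(45, 55, 65)
  cfg$solver$tolerance <- 1e-10
  cfg
}
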
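test_that("an empty scene has a silent green channel", {
  sp <- small_scene_spec(n_mito = 0L)
  sc <- generate_scene(sp)
  expect_true(all(sc$green == 0))
  expect_identical(sc$true_foreground_voxels, 0L)
  expect_gt(sum(sc$red), 0)
})

test_that("every tubule is labelled and stays inside the cell ellipsoid", {
  sc <- generate_scene(scene_spec(rng_seed = 1))
  expect_identical(max(sc$labels), 15L)
  expect_setequal(unique(as.integer(sc$labels)), 0:15)
  idx <- which(sc$labels > 0, arr.ind = TRUE)
  vox <- sc$spec$voxel_size
  cell <- sc$cells[[1]]
  q <- ((idx[, 3] - 0.5) * vox[3] - cell$centre[1])^2 / cell$semi[1]^2 +
    ((idx[, 2] - 0.5) * vox[2] - cell$centre[2])^2 / cell$semi[2]^2 +
    ((idx[, 1] - 0.5) * vox[1] - cell$centre[3])^2 / cell$semi[3]^2
  expect_true(all(q <= 1 + 1e-9))
})

test_that("voxelised capsule volume matches the closed form", {
  sp <- small_scene_spec(seed = 11, n_mito = 1L)
  sp$mito_diameter_range <- c(0.30, 0.30)
  sp$mito_length_range <- c(1.0, 1.0)
  sc <- generate_scene(sp)
  r <- 0.15; L <- 1.0
  analytic <- pi * r^2 * L + 4 / 3 * pi * r^3
  voxelised <- sum(sc$labels > 0) * prod(sp$voxel_size)
  expect_lt(abs(voxelised - analytic) / analytic, 0.10)
})

test_that("scene generation is reproducible per seed", {
  a <- generate_scene(small_scene_spec(seed = 3))
  b <- generate_scene(small_scene_spec(seed = 3))
  c <- generate_scene(small_scene_spec(seed = 4))
  expect_identical(a$green, b$green)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$green, c$green))
})

test_that("bleach multipliers follow the linear trend exactly without fluctuation", {
  sched <- bleach_schedule(0.0175, 60, 13, fluctuation_sd = 0)
  m <- bleach_multipliers(sched)
  expect_equal(m[1], 1)
  expect_equal(m[13], 1 - 0.0175 * 12)
  expect_equal(m, 1 - 0.0175 * (0:12))
})

test_that("fluctuations respect the consecutive-step cap", {
  set.seed(9)
  sched <- bleach_schedule(0.0175, 60, 40, fluctuation_sd = 0.15,
                           step_cap = 0.30)
  m <- bleach_multipliers(sched)
  steps <- abs(m[-1] / m[-length(m)] - 1)
  expect_true(all(steps <= 0.30 + 1e-12))
  expect_true(all(m > 0))
})

test_that("a schedule that crosses zero names the offending timepoint", {
  sched <- bleach_schedule(0.2, 60, 10, fluctuation_sd = 0)
  expect_error(bleach_multipliers(sched), "timepoint 6")
})

test_that("an identity schedule reproduces timepoint 0 exactly", {
  sc <- generate_scene(small_scene_spec(seed = 5))
  sched <- bleach_schedule(0, 60, 3, fluctuation_sd = 0)
  sim <- simulate_timeseries(sc, sched, psf = NULL, bleedthrough_fraction = 0,
                             noise = NULL, red_schedule = sched, rng_seed = 1)
  expect_equal(sim$stack[3, 2, , , ], sim$stack[1, 2, , , ])
  expect_equal(sim$stack[3, 1, , , ], sim$stack[1, 1, , , ])
})

test_that("noise-free signal scales exactly with the bleach multiplier", {
  sc <- generate_scene(small_scene_spec(seed = 5))
  sched <- bleach_schedule(0.0175, 60, 13, fluctuation_sd = 0.05)
  sim <- simulate_timeseries(sc, sched, psf = NULL, bleedthrough_fraction = 0,
                             noise = NULL, rng_seed = 2,
                             materialise = c(1L, 7L, 13L))
  tot <- apply(sim$stack[, 2, , , ], 1, sum)
  m <- sim$truth$multipliers_green[c(1, 7, 13)]
  expect_equal(tot / tot[1], m / m[1], tolerance = 1e-12)
})

test_that("bleedthrough adds a linear red fraction to the green channel", {
  sp <- small_scene_spec(n_mito = 0L)
  sc <- generate_scene(sp)                 # red-only scene
  sched <- bleach_schedule(0, 60, 1, fluctuation_sd = 0)
  sim <- simulate_timeseries(sc, sched, psf = NULL,
                             bleedthrough_fraction = 0.08, noise = NULL,
                             red_schedule = sched, rng_seed = 1)
  expect_equal(sum(sim$stack[1, 2, , , ]), 0.08 * sum(sim$stack[1, 1, , , ]),
               tolerance = 1e-12)
})

test_that("the time series is bit-reproducible under a fixed seed", {
  sc <- generate_scene(small_scene_spec(seed = 6))
  sched <- bleach_schedule(0.0175, 60, 3)
  args <- list(sc, sched, psf = NULL, bleedthrough_fraction = 0.08,
               jitter = jitter_model(), noise = noise_model(), rng_seed = 42)
  a <- do.call(simulate_timeseries, args)
  b <- do.call(simulate_timeseries, args)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$transforms, b$truth$transforms)
})

test_that("division conserves the mitochondrial foreground exactly", {
  sc <- generate_scene(small_scene_spec(seed = 7))
  post <- simulate_division(sc)
  expect_identical(post$true_foreground_voxels, sc$true_foreground_voxels)
  expect_length(post$cells, 2)
  expect_setequal(unique(as.integer(post$labels)),
                  unique(as.integer(sc$labels)))
  # both daughter groups are populated
  expect_setequal(unique(post$division$groups), 1:2)
  expect_identical(sum(post$green), sum(sc$green))
})
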
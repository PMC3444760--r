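test_that("an equilibrium world without flow stays put", {
  cfg <- regime_config(u_max = 0, n_steps = 0)
  world <- build_world(cfg)
  p0 <- world$cell$points
  for (k in 1:20) world <- sim_step(world)
  expect_equal(world$cell$points$x, p0$x, tolerance = 1e-12)
  expect_equal(world$cell$points$y, p0$y, tolerance = 1e-12)
  expect_equal(max(abs(world$fluid$ux), abs(world$fluid$uy)), 0)
})

test_that("wall points barely move during a stepped run", {
  cfg <- regime_config(kC = 6, kN = 6, cell_position = "near_wall",
                       n_steps = 300, snapshot_every = 300)
  traj <- run_simulation(cfg)
  wp <- traj$world$wall$points
  disp <- sqrt((wp$x - wp$anchor_x)^2 + (wp$y - wp$anchor_y)^2)
  expect_lt(max(disp), 0.05 * traj$world$grid$h)
})

test_that("identical configurations give bit-identical trajectories", {
  cfg <- regime_config(adhesion = TRUE, cell_position = "near_wall",
                       clearance = um(0.3), n_steps = 60,
                       snapshot_every = 20)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$events, t2$events)
})

test_that("zero-step runs keep only the initial snapshot", {
  traj <- run_simulation(regime_config(n_steps = 0))
  expect_equal(length(traj$snapshots), 1L)
  expect_equal(traj$times, 0)
})

test_that("the stop rule halts once the centroid passes the threshold", {
  stop_x <- um(30)
  cfg <- regime_config(kC = 6, kN = 6, n_steps = 100000L,
                       snapshot_every = 200, stop_x = stop_x,
                       cell_position = "center")
  traj <- run_simulation(cfg)
  last <- traj$snapshots[[length(traj$snapshots)]]
  cx <- mean(last$x[last$structure_group == "cell" & last$outer])
  expect_gte(cx, stop_x)
  # and it stopped soon after crossing, not at the step budget
  expect_lt(traj$times[length(traj$times)], 0.05)
})

test_that("cell area is conserved within the leakage budget over a run", {
  cfg <- regime_config(kC = 3, kN = 3, cell_position = "near_wall",
                       n_steps = 3000, snapshot_every = 500)
  traj <- run_simulation(cfg)
  areas <- vapply(seq_along(traj$snapshots), function(k)
    shape_metrics(traj$snapshots[[k]])$area, numeric(1))
  expect_lt(max(abs(areas / areas[1] - 1)), 0.05)
})

test_that("a centered cell keeps mirror symmetry about the axis", {
  cfg <- regime_config(kC = 2, kN = 2, cell_position = "center",
                       n_steps = 2000, snapshot_every = 2000)
  traj <- run_simulation(cfg)
  last <- traj$snapshots[[length(traj$snapshots)]]
  cell <- last[last$structure_group == "cell" & last$outer, ]
  yc <- (traj$config$grid$Ly) / 2
  # mirror the contour and compare area above/below the centerline
  above <- cell$y - yc
  expect_lt(abs(mean(above)) / traj$config$cell$diameter, 0.02)
  expect_lt(abs(max(above) + min(above)) / traj$config$cell$diameter,
            0.05)
})

test_that("snapshot cadence and experiment bookkeeping are consistent", {
  cfg <- regime_config(n_steps = 55, snapshot_every = 20)
  traj <- run_simulation(cfg)
  # t = 0, 20, 40 by cadence plus the forced final snapshot at 55
  expect_equal(length(traj$snapshots), 4L)
  expect_true(all(diff(traj$times) > 0))
  sw <- experiment_sweep(kC_levels = c(1, 6), kN_levels = 3,
                         positions = "near_wall",
                         base_config = regime_config(),
                         n_steps = 40)
  expect_equal(nrow(sw$table), 2L)
  expect_equal(length(sw$runs), 2L)
  expect_true(all(c("circularity", "aspect") %in% names(sw$table)))
})

test_that("the default sweep grid enumerates all 72 combinations", {
  sw <- experiment_sweep(base_config = regime_config(), n_steps = 0)
  expect_equal(length(sw$runs), 6 * 6 * 2)
  expect_equal(nrow(sw$table), 72)
  expect_equal(nrow(unique(sw$table[c("position", "kC", "kN")])), 72)
})

test_that("halving dt leaves the trajectory essentially unchanged", {
  run_at <- function(dt, n) {
    cfg <- regime_config(kC = 3, kN = 3, cell_position = "near_wall",
                         dt = dt, n_steps = n, snapshot_every = n)
    traj <- run_simulation(cfg)
    last <- traj$snapshots[[length(traj$snapshots)]]
    mean(last$x[last$structure_group == "cell" & last$outer])
  }
  cx1 <- run_at(1e-5, 1500)
  cx2 <- run_at(5e-6, 3000)
  expect_lt(abs(cx1 - cx2) / cx2, 0.02)
})

test_that("dt violating the spring stability bound is halved automatically", {
  cfg <- regime_config(kC = 6, kN = 6, kW = 8, dt = 8e-5, n_steps = 40,
                       snapshot_every = 20, cell_position = "near_wall")
  traj <- run_simulation(cfg)
  expect_lt(traj$dt_used, 8e-5)
  expect_true(all(is.finite(traj$snapshots[[length(traj$snapshots)]]$x)))
})
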
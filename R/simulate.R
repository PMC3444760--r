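# The full immersed-boundary time loop and the three preset computational
# experiments: the stiffness sweep under flow, the rolling cases, and the
# anchoring/crawling run with adhesion-triggered cortex remodeling.
#
# One step of the loop:
#   update adhesions -> remodel cortex (if enabled) -> evaluate all spring
#   forces -> spread to the grid -> advance the fluid -> interpolate the
#   velocity -> move every material point with the local fluid velocity.
# There is no randomness anywhere on this path, so identical configurations
# produce bit-identical trajectories.

#' Simulation configuration with the study defaults
#'
#' Defaults encode the reference setup: a 30 x 75 micron vessel segment, a
#' parabolic plasma flow with 0.6 mm/s centerline maximum, a 10-micron cell
#' with a 4-micron nucleus and a 2-micron cortex band, and a baseline spring
#' stiffness of 50 dyn/cm for cortex and nuclear envelope. Cortex and
#' nucleus stiffness are scaled by the dimensionless multipliers `kC` and
#' `kN` (the sweep varies each over 1..6).
#'
#' @param nx,ny grid size (square cells). The y-extent of the domain is
#'   `Ly = Lx * ny / nx`; the vessel is centered in it, with quiescent dead
#'   bands behind the walls.
#' @param Lx domain length (cm), also the vessel length.
#' @param mu,rho plasma viscosity (g/(cm s)) and density (g/cm^3).
#' @param u_max target centerline speed of the undisturbed flow (cm/s).
#' @param vessel_width wall separation (cm).
#' @param cell_diameter,nucleus_diameter,cortex_band cell geometry (cm).
#' @param spacing Lagrangian point spacing (cm); NULL means `h/2`, the
#'   standard immersed-boundary rule that prevents leakage through
#'   boundaries.
#' @param S0 baseline spring stiffness (dyn/cm).
#' @param kC,kN,kW stiffness multipliers for cortex, nuclear envelope, and
#'   wall tethers/links.
#' @param cell_position `"center"` (mid-height) or `"near_wall"` (outer
#'   cortex `clearance` above the bottom wall).
#' @param clearance near-wall gap between outer cortex and wall (cm).
#' @param x0 initial cell-center x (cm); NULL means `Lx/6`.
#' @param with_cell logical; FALSE builds walls-only worlds.
#' @param adhesion logical, enable dynamic cell-wall adhesion.
#' @param adh_params an [adhesion_params()].
#' @param remodel logical, enable cortex softening at focal adhesions.
#' @param m_soft,r_soft remodeling multiplier and influence radius.
#' @param marker_span,marker_start stained-arc extent (radians).
#' @param dt time step (s).
#' @param n_steps number of steps for [run_simulation()].
#' @param snapshot_every snapshot cadence in steps.
#' @param stop_x unwrapped centroid-x stop rule (cm), or NULL.
#' @param adh_every adhesion update cadence in steps (creation/breakage and
#'   remodeling are slow compared to dt).
#' @param max_dt_retries automatic dt-halving retries on instability.
#' @return object of class `ctc_config` (a validated nested list).
#' @export
sim_config <- function(nx = 240, ny = 128, Lx = um(75),
                       mu = 0.012, rho = 1.0, u_max = 0.06,
                       vessel_width = um(30),
                       cell_diameter = um(10), nucleus_diameter = um(4),
                       cortex_band = um(2), spacing = NULL,
                       S0 = 50, kC = 1, kN = 1, kW = 8,
                       cell_position = c("center", "near_wall"),
                       clearance = um(1), x0 = NULL, with_cell = TRUE,
                       adhesion = FALSE, adh_params = adhesion_params(),
                       remodel = FALSE, m_soft = 1 / 3, r_soft = um(1.5),
                       marker_span = pi / 6, marker_start = -pi / 2,
                       dt = 1e-5, n_steps = 1000L, snapshot_every = 100L,
                       stop_x = NULL, adh_every = 10L, max_dt_retries = 3L) {
  cell_position <- match.arg(cell_position)
  cfg <- list(
    grid = list(nx = as.integer(nx), ny = as.integer(ny), Lx = Lx,
                Ly = Lx * ny / nx),
    fluid = list(mu = mu, rho = rho, u_max = u_max),
    vessel = list(width = vessel_width),
    cell = list(diameter = cell_diameter,
                nucleus_diameter = nucleus_diameter,
                cortex_band = cortex_band, position = cell_position,
                clearance = clearance, x0 = x0, with_cell = with_cell),
    spacing = spacing,
    stiffness = list(S0 = S0, kC = kC, kN = kN, kW = kW),
    adhesion = list(enabled = adhesion, params = adh_params,
                    remodel = remodel, m_soft = m_soft, r_soft = r_soft,
                    every = as.integer(adh_every)),
    marker = list(span = marker_span, start = marker_start),
    numerics = list(dt = dt, n_steps = as.integer(n_steps),
                    snapshot_every = as.integer(snapshot_every),
                    stop_x = stop_x,
                    max_dt_retries = as.integer(max_dt_retries)))
  class(cfg) <- "ctc_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks positivity and geometric consistency (vessel narrower than the
#' domain, cell fitting inside the vessel, multipliers positive). Returns
#' the config invisibly unchanged on success.
#'
#' @param cfg a `ctc_config`.
#' @return the config (invisibly validated).
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ctc_config"))
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$grid$nx >= 8 && cfg$grid$ny >= 8, "grid must be at least 8 x 8")
  chk(cfg$fluid$mu > 0, "mu must be positive")
  chk(cfg$fluid$rho > 0, "rho must be positive")
  chk(cfg$fluid$u_max >= 0, "u_max must be non-negative")
  chk(cfg$vessel$width < cfg$grid$Ly,
      "vessel width must be smaller than the domain height")
  chk(cfg$vessel$width > cfg$cell$diameter,
      "vessel width must exceed the cell diameter")
  with(cfg$stiffness, {
    chk(S0 > 0, "S0 must be positive")
    chk(kC > 0 && kN > 0 && kW > 0, "stiffness multipliers must be positive")
  })
  chk(cfg$numerics$dt > 0, "dt must be positive")
  chk(cfg$numerics$n_steps >= 0, "n_steps must be non-negative")
  chk(cfg$numerics$snapshot_every >= 1, "snapshot_every must be >= 1")
  if (!is.null(cfg$spacing))
    chk(cfg$spacing > 0, "spacing must be positive")
  cfg
}

point_spacing <- function(cfg, grid) {
  if (!is.null(cfg$spacing)) cfg$spacing else grid$h / 2
}

# walls centered in the domain, plus everything steady_channel_flow needs
build_world_walls <- function(cfg, grid) {
  y_bottom <- (cfg$grid$Ly - cfg$vessel$width) / 2
  geom <- vessel_geometry(length = cfg$grid$Lx, width = cfg$vessel$width,
                          spacing = point_spacing(cfg, grid),
                          y_bottom = y_bottom)
  Sw <- cfg$stiffness$S0 * cfg$stiffness$kW
  v <- build_vessel(geom, S_tether = Sw, S_link = Sw)
  v$y_bottom <- y_bottom
  v$geom <- geom
  v
}

#' Assemble the full simulation world from a configuration
#'
#' Builds the grid, fluid state, tethered walls, the cell (unless disabled)
#' with its marked cortex arc, the driving body force, and an empty
#' adhesion state.
#'
#' @param cfg a [sim_config()].
#' @return object of class `ctc_world`.
#' @export
build_world <- function(cfg) {
  cfg <- validate_config(cfg)
  grid <- make_grid(cfg$grid$nx, cfg$grid$ny, cfg$grid$Lx, cfg$grid$Ly)
  wall <- build_world_walls(cfg, grid)
  state <- fluid_state(grid, mu = cfg$fluid$mu, rho = cfg$fluid$rho)
  drive <- drive_force(cfg, grid, wall)

  cell <- NULL
  if (isTRUE(cfg$cell$with_cell)) {
    x0 <- if (is.null(cfg$cell$x0)) cfg$grid$Lx / 6 else cfg$cell$x0
    y0 <- if (cfg$cell$position == "center") {
      wall$y_bottom + cfg$vessel$width / 2
    } else {
      wall$y_bottom + cfg$cell$clearance + cfg$cell$diameter / 2
    }
    spec <- cell_geometry(center = c(x0, y0), diameter = cfg$cell$diameter,
                          nucleus_diameter = cfg$cell$nucleus_diameter,
                          cortex_band = cfg$cell$cortex_band,
                          spacing = point_spacing(cfg, grid))
    cell <- build_cell(spec, S = cfg$stiffness$S0)
    cell$cortex$S <- cell$cortex$S * cfg$stiffness$kC
    cell$nucleus$S <- cell$nucleus$S * cfg$stiffness$kN
    cell$points <- mark_cortex_arc(cell$points, span = cfg$marker$span,
                                   start = cfg$marker$start,
                                   center = c(x0, y0))
    cell$spec <- spec
  }

  structure(list(config = cfg, grid = grid, fluid = state, wall = wall,
                 cell = cell, drive = drive, adhesion = adhesion_state(),
                 time = 0, step = 0L),
            class = "ctc_world")
}

#' Advance the world one immersed-boundary step
#'
#' Composes one iteration of the coupled fluid-structure loop (adhesion
#' update, optional cortex remodeling, spring forces, force spreading,
#' fluid advance, velocity interpolation, point motion). Deterministic.
#'
#' @param world a [build_world()] world.
#' @return the advanced world.
#' @export
sim_step <- function(world) {
  cfg <- world$config
  grid <- world$grid
  dt <- cfg$numerics$dt

  # --- adhesion bookkeeping (cadenced: bond turnover is slow vs dt)
  if (!is.null(world$cell) && cfg$adhesion$enabled &&
      world$step %% cfg$adhesion$every == 0L) {
    world$adhesion <- update_adhesions(world$cell$points, world$wall$points,
                                       world$adhesion, cfg$adhesion$params,
                                       t = world$time, Lx = grid$Lx)
    if (cfg$adhesion$remodel)
      world$cell$cortex <- remodel_cortex(world$cell$cortex,
                                          world$cell$points, world$adhesion,
                                          m_soft = cfg$adhesion$m_soft,
                                          r_soft = cfg$adhesion$r_soft)
  }

  # --- Lagrangian forces (point forces, dyn)
  wf <- network_forces(world$wall$network, world$wall$points)
  if (!is.null(world$cell)) {
    cf <- network_forces(world$cell$cortex, world$cell$points) +
          network_forces(world$cell$nucleus, world$cell$points)
    if (cfg$adhesion$enabled && nrow(world$adhesion$links) > 0) {
      af <- adhesion_forces(world$adhesion, world$cell$points,
                            world$wall$points,
                            S_A = cfg$adhesion$params$S_A,
                            L_A = cfg$adhesion$params$L_A, Lx = grid$Lx)
      cf <- cf + af$cell
      wf <- wf + af$wall
    }
    pts <- rbind(world$cell$points[c("x", "y", "ds")],
                 world$wall$points[c("x", "y", "ds")])
    ff <- rbind(cf, wf)
  } else {
    pts <- world$wall$points
    ff <- wf
  }
  # spread() carries the ds quadrature weight, so hand it force densities
  pts$x <- pts$x %% grid$Lx   # coordinates are stored unwrapped
  f <- spread(pts, ff / pts$ds, grid)
  f$fx <- f$fx + world$drive$fx
  f$fy <- f$fy + world$drive$fy

  # --- fluid advance and point motion
  world$fluid <- step_fluid(world$fluid, f, dt)
  U <- interp_velocity(world$fluid, pts, grid)
  if (max(abs(U)) > 100 * max(cfg$fluid$u_max, 1e-6))
    stop("immersed-boundary instability: boundary speed blow-up",
         call. = FALSE)
  if (!is.null(world$cell)) {
    nc <- nrow(world$cell$points)
    world$cell$points$x <- world$cell$points$x + U[seq_len(nc), 1] * dt
    world$cell$points$y <- world$cell$points$y + U[seq_len(nc), 2] * dt
    iw <- nc + seq_len(nrow(world$wall$points))
  } else {
    iw <- seq_len(nrow(world$wall$points))
  }
  world$wall$points$x <- world$wall$points$x + U[iw, 1] * dt
  world$wall$points$y <- world$wall$points$y + U[iw, 2] * dt

  world$time <- world$time + dt
  world$step <- world$step + 1L
  world
}

world_snapshot <- function(world) {
  cfg <- world$config
  if (!is.null(world$cell)) {
    pts <- rbind(
      cbind(world$cell$points[c("id", "tag", "x", "y", "outer", "marker")],
            structure_group = "cell"),
      cbind(world$wall$points[c("id", "tag", "x", "y", "outer", "marker")],
            structure_group = "wall"))
    adh <- integer(nrow(world$cell$points))
    if (nrow(world$adhesion$links) > 0) {
      tab <- tabulate(world$adhesion$links$cell,
                      nbins = nrow(world$cell$points))
      adh <- tab
    }
    pts$adh <- c(adh, integer(nrow(world$wall$points)))
  } else {
    pts <- cbind(world$wall$points[c("id", "tag", "x", "y", "outer",
                                     "marker")],
                 structure_group = "wall")
    pts$adh <- 0L
  }
  pts <- cbind(time = world$time, pts)
  rownames(pts) <- NULL
  pts
}

#' Run a simulation to completion
#'
#' Iterates [sim_step()] for `n_steps` or until the unwrapped cell-centroid
#' x passes `stop_x`, recording snapshots at the configured cadence (the
#' initial and final states are always included). On an immersed-boundary
#' instability the run restarts from the initial state with the time step
#' halved, up to `max_dt_retries` times.
#'
#' @param cfg a [sim_config()].
#' @return object of class `ctc_trajectory`: `times`, `snapshots` (list of
#'   data frames), `multipliers` (per-snapshot cortex multiplier vectors),
#'   `links` (per-snapshot active-link counts), `events` (adhesion event
#'   log), `config`, `dt_used`, and the final `world`.
#' @export
run_simulation <- function(cfg) {
  cfg <- validate_config(cfg)
  dt <- cfg$numerics$dt
  for (try in 0:cfg$numerics$max_dt_retries) {
    cfg$numerics$dt <- dt / 2^try
    out <- tryCatch(run_once(cfg), ctcflow_instability = function(e) e)
    if (!inherits(out, "condition")) {
      out$dt_used <- cfg$numerics$dt
      return(out)
    }
  }
  stop("simulation unstable even after ", cfg$numerics$max_dt_retries,
       " dt halvings; last dt = ", cfg$numerics$dt, call. = FALSE)
}

run_once <- function(cfg) {
  world <- build_world(cfg)
  times <- world$time
  snaps <- list(world_snapshot(world))
  mults <- list(if (!is.null(world$cell)) world$cell$cortex$mult)
  nlinks <- nrow(world$adhesion$links)
  n <- cfg$numerics$n_steps
  every <- cfg$numerics$snapshot_every
  for (k in seq_len(n)) {
    world <- tryCatch(
      sim_step(world),
      error = function(e) {
        if (grepl("instability|diverged|CFL", conditionMessage(e))) {
          cond <- structure(class = c("ctcflow_instability", "condition"),
                            list(message = conditionMessage(e), call = NULL))
          stop(cond)
        }
        stop(e)
      })
    done <- k == n
    if (!is.null(cfg$numerics$stop_x) && !is.null(world$cell)) {
      out_ids <- world$cell$points$outer
      cx <- mean(world$cell$points$x[out_ids])
      if (cx >= cfg$numerics$stop_x) done <- TRUE
    }
    if (k %% every == 0L || done) {
      times <- c(times, world$time)
      snaps[[length(snaps) + 1L]] <- world_snapshot(world)
      mults[[length(mults) + 1L]] <-
        if (!is.null(world$cell)) world$cell$cortex$mult
      nlinks <- c(nlinks, nrow(world$adhesion$links))
      if (done) break
    }
  }
  structure(list(times = times, snapshots = snaps, multipliers = mults,
                 links = nlinks, events = world$adhesion$events,
                 config = cfg, world = world),
            class = "ctc_trajectory")
}

#' Snapshot interval used by the rolling and crawling experiments
#'
#' The figure-style snapshot unit "t" is taken as the time for the
#' undisturbed centerline flow to advect by one cell diameter
#' (10 um / 0.6 mm/s ~ 0.0167 s by default).
#'
#' @param cfg a [sim_config()].
#' @return interval in seconds.
#' @export
snapshot_unit <- function(cfg = sim_config()) {
  cfg$cell$diameter / cfg$fluid$u_max
}

#' Stiffness sweep under flow
#'
#' Runs every combination of cortex multiplier, nucleus multiplier, and
#' initial position with adhesion disabled, recording the final cell shape
#' once the cell has traversed `stop_frac` of the vessel length (or the
#' step budget is exhausted). Reproduces the stiffness-versus-deformation
#' table qualitatively: soft-cortex cells elongate (extreme cases resemble
#' clasmatosis), a sixfold-stiff cortex preserves the circular shape, and a
#' stiffer nuclear envelope damps whole-cell deformation.
#'
#' @param kC_levels,kN_levels multiplier levels (default 1..6).
#' @param positions initial positions to run.
#' @param base_config template configuration.
#' @param stop_frac stop rule as a fraction of vessel length (default 2/3).
#' @param n_steps step budget per run.
#' @return object of class `ctc_sweep`: list of runs plus a `table` of
#'   final-shape metrics (kC, kN, position, circularity, aspect, ...).
#' @export
experiment_sweep <- function(kC_levels = 1:6, kN_levels = 1:6,
                             positions = c("center", "near_wall"),
                             base_config = sim_config(),
                             stop_frac = 2 / 3, n_steps = NULL) {
  runs <- list()
  rows <- NULL
  for (pos in positions) for (kN in kN_levels) for (kC in kC_levels) {
    cfg <- base_config
    cfg$stiffness$kC <- kC
    cfg$stiffness$kN <- kN
    cfg$cell$position <- pos
    cfg$adhesion$enabled <- FALSE
    cfg$adhesion$remodel <- FALSE
    cfg$numerics$stop_x <- stop_frac * cfg$grid$Lx
    if (!is.null(n_steps)) cfg$numerics$n_steps <- as.integer(n_steps)
    traj <- run_simulation(cfg)
    m <- trajectory_shape(traj, which = length(traj$snapshots))
    key <- sprintf("%s_kC%d_kN%d", pos, kC, kN)
    runs[[key]] <- traj
    rows <- rbind(rows, data.frame(position = pos, kC = kC, kN = kN,
                                   circularity = m$circularity,
                                   aspect = m$aspect, area = m$area,
                                   centroid_x = m$centroid[1],
                                   centroid_y = m$centroid[2]))
  }
  structure(list(runs = runs, table = rows), class = "ctc_sweep")
}

rolling_case_multipliers <- function() {
  list(A = c(kC = 3, kN = 3), B = c(kC = 6, kN = 3),
       C = c(kC = 3, kN = 6), D = c(kC = 6, kN = 6))
}

#' Rolling experiment: four stiffness cases on the endothelium
#'
#' Near-wall start, adhesion enabled, remodeling disabled. The four cases
#' vary cortex/nucleus stiffness: A (3x, 3x), B (6x, 3x), C (3x, 6x),
#' D (6x, 6x). Snapshots are taken at t, 2t, 3t, 4t multiples of the
#' snapshot unit. Each trajectory is classified into a locomotion mode.
#'
#' @param cases subset of `c("A","B","C","D")`.
#' @param base_config template configuration.
#' @param t_unit snapshot interval (s); default [snapshot_unit()].
#' @param horizon_units run length in snapshot units (default 4).
#' @return object of class `ctc_rolling`: per-case list with `trajectory`,
#'   `mode`, and summary `table`.
#' @export
experiment_rolling <- function(cases = c("A", "B", "C", "D"),
                               base_config = sim_config(),
                               t_unit = snapshot_unit(base_config),
                               horizon_units = 4) {
  mult <- rolling_case_multipliers()
  out <- list()
  rows <- NULL
  for (cs in cases) {
    cfg <- base_config
    cfg$stiffness$kC <- mult[[cs]][["kC"]]
    cfg$stiffness$kN <- mult[[cs]][["kN"]]
    cfg$cell$position <- "near_wall"
    # start inside binding range so first contacts can form at once
    cfg$cell$clearance <- min(cfg$cell$clearance,
                              cfg$adhesion$params$r_on / 2)
    cfg$adhesion$enabled <- TRUE
    cfg$adhesion$remodel <- FALSE
    cfg$numerics$stop_x <- NULL
    steps_per_unit <- max(1L, round(t_unit / cfg$numerics$dt))
    cfg$numerics$n_steps <- as.integer(horizon_units * steps_per_unit)
    cfg$numerics$snapshot_every <- max(1L, steps_per_unit %/% 8L)
    traj <- run_simulation(cfg)
    md <- classify_mode(traj)
    out[[cs]] <- list(trajectory = traj, mode = md)
    rows <- rbind(rows, data.frame(
      case = cs, kC = cfg$stiffness$kC, kN = cfg$stiffness$kN,
      mode = md$label, rotation = md$evidence$rotation,
      advance = md$evidence$advance,
      links_final = traj$links[length(traj$links)]))
  }
  structure(list(cases = out, table = rows), class = "ctc_rolling")
}

#' Crawling experiment: cortex remodeling at focal adhesions
#'
#' Runs the anchoring-prone stiffness combination (cortex 3x, nucleus 6x)
#' near the wall with adhesion enabled, over a 10t horizon (2.5x the
#' rolling horizon). With remodeling enabled, cortex fibers near active
#' focal adhesions are softened and restored the moment those adhesions
#' break — the hypothesized switch from anchoring to crawling. How long
#' adhesion then persists is strongly calibration-dependent; see the
#' methods vignette for what the default calibration does and does not
#' reproduce.
#'
#' @param base_config template configuration.
#' @param remodel enable adhesion-triggered cortex softening.
#' @param t_unit snapshot interval (s).
#' @param horizon_units run length in snapshot units (default 10).
#' @return list with `trajectory` and `mode`, class `ctc_crawling`.
#' @export
experiment_crawling <- function(base_config = sim_config(), remodel = TRUE,
                                t_unit = snapshot_unit(base_config),
                                horizon_units = 10) {
  cfg <- base_config
  cfg$stiffness$kC <- 3
  cfg$stiffness$kN <- 6
  cfg$cell$position <- "near_wall"
  cfg$cell$clearance <- min(cfg$cell$clearance,
                            cfg$adhesion$params$r_on / 2)
  cfg$adhesion$enabled <- TRUE
  cfg$adhesion$remodel <- isTRUE(remodel)
  cfg$numerics$stop_x <- NULL
  steps_per_unit <- max(1L, round(t_unit / cfg$numerics$dt))
  cfg$numerics$n_steps <- as.integer(horizon_units * steps_per_unit)
  cfg$numerics$snapshot_every <- max(1L, steps_per_unit %/% 8L)
  traj <- run_simulation(cfg)
  structure(list(trajectory = traj, mode = classify_mode(traj)),
            class = "ctc_crawling")
}
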
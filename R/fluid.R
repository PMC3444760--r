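# Incompressible Navier-Stokes on a doubly periodic grid.
#
# Semi-implicit first-order scheme: explicit skew-symmetric centered
# advection and body force, implicit viscosity, and pressure projection,
# both solved in Fourier space using the symbols of the *finite-difference*
# operators (5-point Laplacian, centered first differences). Because the
# projection uses the centered-difference divergence symbol, the
# centered-difference divergence of the projected field vanishes to
# round-off. At the microvessel scale (Re ~ 0.015) the flow is strongly
# viscous and the implicit treatment keeps the diffusion stable at any dt.

#' Fluid state on a periodic grid
#'
#' @param grid a [make_grid()] grid.
#' @param mu dynamic viscosity, g/(cm s). Default 0.012 (blood plasma,
#'   about 1.2 cP).
#' @param rho density, g/cm^3. Default 1.
#' @return object of class `fluid_state`: velocity matrices `ux`, `uy`
#'   (cm/s), pressure `p` (dyn/cm^2), the grid, and precomputed Fourier
#'   symbols.
#' @export
fluid_state <- function(grid, mu = 0.012, rho = 1.0) {
  stopifnot(inherits(grid, "fluid_grid"), mu > 0, rho > 0)
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  tx <- 2 * pi * (seq_len(nx) - 1) / nx
  ty <- 2 * pi * (seq_len(ny) - 1) / ny
  lap <- outer((2 * cos(tx) - 2) / h^2, rep(1, ny)) +
         outer(rep(1, nx), (2 * cos(ty) - 2) / h^2)
  Dx <- outer(1i * sin(tx) / h, rep(1, ny))
  Dy <- outer(rep(1 + 0i, nx), 1i * sin(ty) / h)
  DD <- outer((sin(tx) / h)^2, rep(1, ny)) +
        outer(rep(1, nx), (sin(ty) / h)^2)
  structure(list(grid = grid, mu = mu, rho = rho,
                 ux = matrix(0, nx, ny), uy = matrix(0, nx, ny),
                 p = matrix(0, nx, ny),
                 sym = list(lap = lap, Dx = Dx, Dy = Dy, DD = DD)),
            class = "fluid_state")
}

# centered first differences on periodic matrices
shift_x <- function(m, k) m[((seq_len(nrow(m)) - 1 + k) %% nrow(m)) + 1L, ,
                            drop = FALSE]
shift_y <- function(m, k) m[, ((seq_len(ncol(m)) - 1 + k) %% ncol(m)) + 1L,
                            drop = FALSE]
ddx <- function(m, h) (shift_x(m, 1) - shift_x(m, -1)) / (2 * h)
ddy <- function(m, h) (shift_y(m, 1) - shift_y(m, -1)) / (2 * h)

#' Centered-difference divergence of the velocity field
#'
#' @param state a `fluid_state` (or a list with `ux`, `uy` plus a `grid`).
#' @param grid grid, defaulting to `state$grid`.
#' @return nx x ny matrix of the discrete divergence (1/s).
#' @export
divergence <- function(state, grid = state$grid) {
  ddx(state$ux, grid$h) + ddy(state$uy, grid$h)
}

#' Project a velocity field onto its divergence-free part
#'
#' Removes the discrete gradient component so the centered-difference
#' divergence vanishes; the mean flow is untouched. Projecting an already
#' divergence-free field is the identity to round-off.
#'
#' @param state a `fluid_state`.
#' @return the state with `ux`, `uy` replaced by the projected field and a
#'   pressure-like potential stored in `p` (up to the rho/dt scaling applied
#'   by [step_fluid()]).
#' @export
project_velocity <- function(state) {
  s <- state$sym
  n <- state$grid$nx * state$grid$ny
  ux_h <- stats::fft(state$ux)
  uy_h <- stats::fft(state$uy)
  div_h <- s$Dx * ux_h + s$Dy * uy_h
  phi_h <- matrix(0i, state$grid$nx, state$grid$ny)
  nz <- s$DD > 1e-14 * max(s$DD)
  phi_h[nz] <- -div_h[nz] / s$DD[nz]
  state$ux <- Re(stats::fft(ux_h - s$Dx * phi_h, inverse = TRUE)) / n
  state$uy <- Re(stats::fft(uy_h - s$Dy * phi_h, inverse = TRUE)) / n
  state$p <- Re(stats::fft(phi_h, inverse = TRUE)) / n
  state
}

#' Advance the fluid one time step
#'
#' One step of the semi-implicit scheme: explicit advection (skew-symmetric
#' centered form) and body force, then a combined implicit-viscosity solve
#' and pressure projection in Fourier space.
#'
#' @param state a [fluid_state()].
#' @param f body force density: list with `fx`, `fy` (dyn/cm^3 per unit
#'   depth), or NULL for unforced flow.
#' @param dt time step (s). Must satisfy the advective CFL
#'   `max|u| dt / h <= 0.5`.
#' @return the updated state (velocity, pressure).
#' @export
step_fluid <- function(state, f = NULL, dt) {
  g <- state$grid; h <- g$h
  umax <- max(abs(state$ux), abs(state$uy))
  if (umax * dt / h > 0.5)
    stop("advective CFL violated: max|u|*dt/h = ",
         signif(umax * dt / h, 3), " > 0.5", call. = FALSE)
  ux <- state$ux; uy <- state$uy
  # skew-symmetric advection: 1/2 (u . grad)u + 1/2 div(u u)
  advx <- 0.5 * (ux * ddx(ux, h) + uy * ddy(ux, h) +
                 ddx(ux * ux, h) + ddy(uy * ux, h))
  advy <- 0.5 * (ux * ddx(uy, h) + uy * ddy(uy, h) +
                 ddx(ux * uy, h) + ddy(uy * uy, h))
  wx <- ux + dt * (-advx + if (is.null(f)) 0 else f$fx / state$rho)
  wy <- uy + dt * (-advy + if (is.null(f)) 0 else f$fy / state$rho)

  s <- state$sym
  n <- g$nx * g$ny
  nu <- state$mu / state$rho
  den <- 1 - nu * dt * s$lap          # real, >= 1
  ux_h <- stats::fft(wx) / den
  uy_h <- stats::fft(wy) / den
  div_h <- s$Dx * ux_h + s$Dy * uy_h
  phi_h <- matrix(0i, g$nx, g$ny)
  nz <- s$DD > 0
  phi_h[nz] <- -div_h[nz] / s$DD[nz]
  state$ux <- Re(stats::fft(ux_h - s$Dx * phi_h, inverse = TRUE)) / n
  state$uy <- Re(stats::fft(uy_h - s$Dy * phi_h, inverse = TRUE)) / n
  state$p <- Re(stats::fft(phi_h * (state$rho / dt), inverse = TRUE)) / n
  if (!all(is.finite(state$ux)) || !all(is.finite(state$uy)))
    stop("fluid solver diverged: non-finite velocity field", call. = FALSE)
  state
}

#' Body force that drives a parabolic channel profile
#'
#' For plane Poiseuille flow between no-slip walls a distance `H` apart, a
#' uniform streamwise force density `g = 8 mu u_max / H^2` sustains a
#' parabolic profile with centerline maximum `u_max`.
#'
#' @param u_max target centerline speed (cm/s).
#' @param H wall separation (cm).
#' @param mu dynamic viscosity (g/(cm s)).
#' @return force density g (dyn/cm^3).
#' @export
calibrate_body_force <- function(u_max, H, mu) {
  stopifnot(u_max >= 0, H > 0, mu > 0)
  8 * mu * u_max / H^2
}

#' Steady cell-free channel flow between immersed walls
#'
#' Builds the tethered vessel walls, drives the fluid with the calibrated
#' uniform body force between them, and time-steps to a steady state. The
#' resulting profile matches the Poiseuille parabola with zero velocity at
#' the walls.
#'
#' @param config a [sim_config()]; the cell is ignored.
#' @param tol relative steady-state tolerance on the max-norm velocity
#'   change per step.
#' @param max_steps step budget before declaring non-convergence.
#' @param check_every convergence-check cadence in steps.
#' @return list: `state` (fluid), `wall` (points + network), `grid`,
#'   `profile` (data.frame y, ux at mid-x), `u_max` (max speed on the
#'   mid-channel line), `steps` taken.
#' @export
steady_channel_flow <- function(config = sim_config(), tol = 1e-8,
                                max_steps = 50000, check_every = 25) {
  cfg <- validate_config(config)
  for (try in seq_len(cfg$numerics$max_dt_retries + 1L)) {
    out <- tryCatch(steady_channel_once(cfg, tol, max_steps, check_every),
                    error = function(e) {
                      if (grepl("CFL|diverged", conditionMessage(e))) e
                      else stop(e)
                    })
    if (!inherits(out, "error")) return(out)
    cfg$numerics$dt <- cfg$numerics$dt / 2
  }
  stop("channel flow unstable after dt halvings", call. = FALSE)
}

steady_channel_once <- function(cfg, tol, max_steps, check_every) {
  grid <- make_grid(cfg$grid$nx, cfg$grid$ny, cfg$grid$Lx, cfg$grid$Ly)
  wall <- build_world_walls(cfg, grid)
  state <- fluid_state(grid, mu = cfg$fluid$mu, rho = cfg$fluid$rho)
  drive <- drive_force(cfg, grid, wall)
  dt <- cfg$numerics$dt

  prev <- state$ux
  steps <- 0L
  repeat {
    for (k in seq_len(check_every)) {
      wf <- network_forces(wall$network, wall$points)
      f <- spread(wall$points, wf / wall$points$ds, grid)
      f$fx <- f$fx + drive$fx
      f$fy <- f$fy + drive$fy
      state <- step_fluid(state, f, dt)
      U <- interp_velocity(state, wall$points, grid)
      wall$points$x <- wall$points$x + U[, 1] * dt
      wall$points$y <- wall$points$y + U[, 2] * dt
      steps <- steps + 1L
    }
    du <- max(abs(state$ux - prev))
    scale <- max(abs(state$ux), 1e-300)
    if (du / scale < tol) break
    if (steps >= max_steps)
      stop("channel flow did not reach steady state in ", max_steps,
           " steps", call. = FALSE)
    prev <- state$ux
  }
  ic <- max(1L, round(grid$nx / 2))
  ys <- (seq_len(grid$ny) - 1) * grid$h
  speed <- sqrt(state$ux^2 + state$uy^2)
  yc <- wall$y_bottom + cfg$vessel$width / 2
  mid_row <- which.min(abs(ys - yc))
  list(state = state, wall = wall, grid = grid,
       profile = data.frame(y = ys, ux = state$ux[ic, ]),
       u_max = max(speed[, mid_row]),
       steps = steps)
}

# uniform streamwise force density between the wall rows (the driving
# "pressure gradient"). Trapezoidal weighting: full strength on interior
# nodes, half strength on nodes within h of a wall line, so the discrete
# momentum input equals g * width exactly and stays symmetric about the
# channel axis (second-order accurate placement of the forced band).
drive_force <- function(cfg, grid, wall) {
  gmag <- calibrate_body_force(cfg$fluid$u_max, cfg$vessel$width,
                               cfg$fluid$mu)
  ys <- (seq_len(grid$ny) - 1) * grid$h
  yb <- wall$y_bottom
  yt <- wall$y_bottom + cfg$vessel$width
  w <- pmax(0, pmin(ys + grid$h / 2, yt) - pmax(ys - grid$h / 2, yb)) /
    grid$h
  fx <- matrix(gmag * rep(w, each = grid$nx), grid$nx, grid$ny)
  list(fx = fx, fy = matrix(0, grid$nx, grid$ny))
}
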
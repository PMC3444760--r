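# Small shared fixtures, built in code.

# coarse but geometrically faithful configuration for fast dynamic tests
coarse_config <- function(...) {
  sim_config(nx = 120, ny = 64, ...)
}

# even coarser grid for long dynamic regime runs (h = 1.25 um; wall rows
# still fall exactly on grid lines)
regime_config <- function(...) {
  sim_config(nx = 60, ny = 32, ...)
}

# a standalone default cell centered in a 30 x 30 um box
default_cell <- function(spacing = um(0.25)) {
  build_cell(cell_geometry(center = c(um(15), um(15)), spacing = spacing))
}

# random interior point sets for coupling identities
random_points <- function(n, grid, margin = 3) {
  lo <- margin * grid$h
  data.frame(x = runif(n, lo, grid$Lx - lo),
             y = runif(n, lo, grid$Ly - lo),
             ds = runif(n, grid$h / 4, grid$h / 2))
}
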
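# Eulerian-Lagrangian coupling via a regularized 2D Dirac delta.
#
# delta_h(x) = phi(x1/h) * phi(x2/h) / h^2 with Peskin's 4-point kernel phi.
# spread() pushes Lagrangian boundary forces onto the fluid grid;
# interp_velocity() pulls the fluid velocity back to the boundary points.
# Both are built from the same kernel, so they are adjoint in the natural
# discrete inner products.

#' Cartesian fluid grid
#'
#' Doubly periodic node-centered grid with square cells. Node coordinates
#' are `(i-1)*h, (j-1)*h` for `i in 1..nx`, `j in 1..ny`.
#'
#' @param nx,ny number of nodes in x and y.
#' @param Lx,Ly domain size (cm); must give square cells (`Lx/nx == Ly/ny`).
#' @return an object of class `fluid_grid` with fields nx, ny, Lx, Ly, h.
#' @export
make_grid <- function(nx, ny, Lx, Ly) {
  stopifnot(nx >= 4, ny >= 4, Lx > 0, Ly > 0)
  h <- Lx / nx
  if (abs(Ly / ny - h) > 1e-12 * h)
    stop("grid cells must be square: Lx/nx must equal Ly/ny", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 Lx = Lx, Ly = Ly, h = h),
            class = "fluid_grid")
}

#' One-dimensional 4-point immersed-boundary kernel
#'
#' Peskin's standard 4-point kernel: even, non-negative, supported on
#' `|r| < 2`, and satisfying the partition-of-unity and even-odd moment
#' conditions `sum_j phi(r - j) = 1`, `sum_j (r - j) phi(r - j) = 0`.
#'
#' @param r dimensionless offset in grid cells.
#' @return kernel weight(s).
#' @export
ib_delta <- function(r) {
  a <- abs(r)
  w <- numeric(length(a))
  near <- a < 1
  mid <- !near & a < 2
  w[near] <- (3 - 2 * a[near] + sqrt(1 + 4 * a[near] - 4 * a[near]^2)) / 8
  w[mid] <- (5 - 2 * a[mid] - sqrt(-7 + 12 * a[mid] - 4 * a[mid]^2)) / 8
  w
}

# 4x4 support stencil of each point: linear grid indices (16 x n) and
# weights wx*wy (16 x n). Shared by spread and interp.
ib_stencil <- function(pts_x, pts_y, grid) {
  gx <- pts_x / grid$h
  gy <- pts_y / grid$h
  jx0 <- floor(gx)
  jy0 <- floor(gy)
  n <- length(gx)
  offs <- -1:2
  # 4 x n weight and index blocks per axis, then 16 x n tensor products
  Wx <- matrix(ib_delta(rep(gx - jx0, each = 4) - offs), 4, n)
  Wy <- matrix(ib_delta(rep(gy - jy0, each = 4) - offs), 4, n)
  Ix <- matrix((rep(as.integer(jx0), each = 4) + offs) %% grid$nx, 4, n)
  Iy <- matrix((rep(as.integer(jy0), each = 4) + offs) %% grid$ny, 4, n)
  ox <- rep(1:4, times = 4)   # x varies fastest within the 16 block
  oy <- rep(1:4, each = 4)
  lin <- Ix[ox, , drop = FALSE] + 1L + Iy[oy, , drop = FALSE] * grid$nx
  wgt <- Wx[ox, , drop = FALSE] * Wy[oy, , drop = FALSE]
  list(lin = lin, wgt = wgt)
}

#' Spread Lagrangian forces onto the fluid grid
#'
#' Discrete version of the delta-function force transfer: the body-force
#' field is `f(x) = sum_l F(l) delta_h(x - X(l)) ds(l)`, where `ds` is each
#' point's frozen boundary quadrature weight. Total force is conserved
#' exactly: `sum_grid f * h^2 = sum_l F(l) * ds(l)` component-wise.
#'
#' @param pts point set with columns x, y, ds.
#' @param forces n x 2 matrix of Lagrangian force densities (force per unit
#'   boundary length; a point force divided by its `ds`).
#' @param grid a [make_grid()] grid.
#' @return list with `fx`, `fy`: nx x ny matrices of body-force density.
#' @export
spread <- function(pts, forces, grid) {
  forces <- rbind(forces)
  st <- ib_stencil(pts$x, pts$y, grid)
  scale <- pts$ds / grid$h^2
  vx <- st$wgt * rep(forces[, 1] * scale, each = 16)
  vy <- st$wgt * rep(forces[, 2] * scale, each = 16)
  idx <- as.vector(st$lin)
  fx <- matrix(0, grid$nx, grid$ny)
  fy <- matrix(0, grid$nx, grid$ny)
  sx <- rowsum(as.vector(vx), idx)
  sy <- rowsum(as.vector(vy), idx)
  at <- as.integer(rownames(sx))
  fx[at] <- sx
  fy[at] <- sy
  list(fx = fx, fy = fy)
}

#' Interpolate fluid velocity to boundary points
#'
#' Discrete version of `U(l) = sum_x u(x) delta_h(x - X(l)) h^2`. A
#' spatially uniform field interpolates exactly (partition of unity), and a
#' linear field is reproduced exactly by the 4-point kernel's first-moment
#' property.
#'
#' @param u list with `ux`, `uy` (nx x ny matrices), or an nx x ny x 2 array.
#' @param pts point set with columns x, y.
#' @param grid a [make_grid()] grid.
#' @return n x 2 matrix of point velocities (cm/s).
#' @export
interp_velocity <- function(u, pts, grid) {
  if (is.array(u) && length(dim(u)) == 3) u <- list(ux = u[, , 1], uy = u[, , 2])
  st <- ib_stencil(pts$x, pts$y, grid)
  ux <- matrix(u$ux[st$lin], nrow = 16)
  uy <- matrix(u$uy[st$lin], nrow = 16)
  cbind(colSums(st$wgt * ux), colSums(st$wgt * uy))
}
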
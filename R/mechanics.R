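# Hookean spring mechanics. Force law for a spring between X and X*:
#   F(X) = S * (||X* - X|| - L) * (X* - X)/||X* - X||
# i.e. magnitude proportional to extension beyond the rest length L,
# directed toward the partner when stretched, away when compressed. Forces
# come in action-reaction pairs, so any anchor-free network exerts zero net
# force on itself.

#' Hookean spring force
#'
#' Force exerted on `X` by a linear spring of stiffness `S` (dyn/cm) and
#' rest length `L` (cm) connecting it to `X_star`. The force on `X_star` is
#' the exact negation. Coincident endpoints with `L > 0` have no defined
#' direction; the force is set to zero for that evaluation (such an event
#' indicates a time step too large for the stiffness in play).
#'
#' @param X,X_star numeric length-2 points, or n x 2 matrices (cm).
#' @param S stiffness, dyn/cm (scalar or length n).
#' @param L rest length, cm (scalar or length n).
#' @return force(s) on `X` in dyn, same shape as `X`.
#' @export
spring_force <- function(X, X_star, S, L) {
  vec <- is.null(dim(X))
  X <- rbind(X); X_star <- rbind(X_star)
  d <- X_star - X
  len <- sqrt(d[, 1]^2 + d[, 2]^2)
  ok <- len > 0
  scale <- ifelse(ok, S * (len - L) / pmax(len, .Machine$double.xmin), 0)
  f <- d * scale
  if (vec && nrow(f) == 1) as.numeric(f) else f
}

#' Sum spring forces over a network
#'
#' Evaluates the Hookean force of every spring (scaled by its stiffness
#' multiplier) and accumulates the per-point vector sum. Tether springs pull
#' their point toward its fixed anchor; all other kinds act between two
#' points as action-reaction pairs.
#'
#' @param net a `spring_network` data frame (columns i, j, S, L, kind, mult).
#' @param pts the point set the network indexes into (needs columns x, y and,
#'   for tethers, anchor_x/anchor_y).
#' @return an n x 2 matrix of forces (dyn), one row per point in `pts`.
#' @export
network_forces <- function(net, pts) {
  n <- nrow(pts)
  out <- matrix(0, n, 2)
  if (nrow(net) == 0) return(out)
  si <- net$i; sj <- net$j
  Sm <- net$S * net$mult
  L <- net$L
  teth <- net$kind == "tether"
  px <- pts$x; py <- pts$y
  if (any(si < 1 | si > n) || any(!teth & (is.na(sj) | sj < 1 | sj > n)))
    stop("spring endpoint id outside the point set", call. = FALSE)
  # partner coordinates: the other point, or the fixed anchor for tethers
  qx <- ifelse(teth, pts$anchor_x[si], px[ifelse(teth, si, sj)])
  qy <- ifelse(teth, pts$anchor_y[si], py[ifelse(teth, si, sj)])
  if (anyNA(qx)) stop("tether springs need anchor coordinates",
                      call. = FALSE)
  dx <- qx - px[si]; dy <- qy - py[si]
  len <- sqrt(dx^2 + dy^2)
  sc <- ifelse(len > 0, Sm * (len - L) / pmax(len, .Machine$double.xmin), 0)
  fx <- sc * dx; fy <- sc * dy
  # accumulate: + on i, - on the partner point (tether anchors absorb
  # their reaction outside the system)
  el <- !teth
  idx <- c(si, sj[el])
  gx <- rowsum(c(fx, -fx[el]), idx)
  gy <- rowsum(c(fy, -fy[el]), idx)
  at <- as.integer(rownames(gx))
  out[at, 1] <- gx
  out[at, 2] <- gy
  out
}

#' Modify spring stiffness globally or locally
#'
#' Scales the stiffness multiplier of a selected subset of springs, leaving
#' the others untouched. Selection is by spring row index, by a spatial
#' predicate on spring midpoints, or (default) all springs. The operation
#' composes multiplicatively and is therefore exactly reversible: applying
#' `m` then `1/m` restores the original effective stiffnesses.
#'
#' @param net a `spring_network`.
#' @param multiplier new multiplier (> 0) for the selected springs.
#' @param springs integer row indices into `net`, or NULL.
#' @param where a function `(xm, ym) -> logical` applied to spring midpoints,
#'   or NULL. Requires `pts`.
#' @param pts point set, needed when `where` is given.
#' @return the updated network.
#' @export
set_stiffness <- function(net, multiplier, springs = NULL, where = NULL,
                          pts = NULL) {
  stopifnot(is.numeric(multiplier), multiplier > 0)
  if (!is.null(springs)) {
    sel <- springs
  } else if (!is.null(where)) {
    if (is.null(pts)) stop("spatial selection needs `pts`", call. = FALSE)
    j <- ifelse(is.na(net$j), net$i, net$j)
    xm <- (pts$x[net$i] + pts$x[j]) / 2
    ym <- (pts$y[net$i] + pts$y[j]) / 2
    sel <- which(where(xm, ym))
    if (length(sel) == 0) {
      warning("spatial predicate selects no springs; network unchanged",
              call. = FALSE)
      return(net)
    }
  } else {
    sel <- seq_len(nrow(net))
  }
  net$mult[sel] <- net$mult[sel] * multiplier
  net
}

#' Elastic energy of a spring network
#'
#' One half of stiffness times squared extension, summed over springs; zero
#' iff every spring sits at its rest length. [network_forces()] is the
#' negative gradient of this energy with respect to the point positions.
#'
#' @inheritParams network_forces
#' @return scalar energy in erg.
#' @export
elastic_energy <- function(net, pts) {
  if (nrow(net) == 0) return(0)
  j <- net$j
  x2 <- ifelse(is.na(j), pts$anchor_x[net$i], pts$x[j])
  y2 <- ifelse(is.na(j), pts$anchor_y[net$i], pts$y[j])
  len <- sqrt((x2 - pts$x[net$i])^2 + (y2 - pts$y[net$i])^2)
  sum(0.5 * net$S * net$mult * (len - net$L)^2)
}
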
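# Dynamic cell-wall adhesion: receptor-ligand bonds are modeled as short
# Hookean springs that assemble when an outer-cortex (membrane) point comes
# within a capture radius of a wall point and disassemble when stretched
# beyond a strain threshold. Binding kinetics are not modeled: binding is
# always effective at short range, which isolates the role of cell
# deformability. remodel_cortex() implements the crawling-mode rule that
# softens cortex fibers near active focal adhesions and restores them as
# soon as the adhesion is lost.

#' Adhesion parameters
#'
#' @param r_on capture radius (cm): an unlinked membrane point closer than
#'   this to a wall point binds its nearest wall point. Default 1.2
#'   microns. Must stay below the break length `lambda_break * L_A`:
#'   deterministic kinetics need that hysteresis, or a broken bond re-forms
#'   on the next update and the cell can never detach.
#' @param lambda_break break strain (> 1): a link longer than
#'   `lambda_break * max(L_A, eps)` is removed. Default 1.35.
#' @param S_A adhesive spring stiffness, dyn/cm. Default 4: per-bond break
#'   forces sit just below the drag load an attached cell shares across
#'   its bonds, so the trailing edge peels while the leading edge
#'   re-binds (the rolling limit cycle).
#' @param L_A adhesive spring rest length (cm). Default 1 micron, which
#'   holds the cell at a hydrodynamically resolved gap from the wall.
#' @param max_links maximum simultaneous links per membrane point.
#' @return object of class `adhesion_params`.
#' @export
adhesion_params <- function(r_on = um(1.2), lambda_break = 1.35, S_A = 4,
                            L_A = um(1.0), max_links = 1L) {
  stopifnot(r_on > L_A, L_A >= 0, lambda_break > 1, S_A >= 0, max_links >= 1)
  structure(list(r_on = r_on, lambda_break = lambda_break, S_A = S_A,
                 L_A = L_A, max_links = as.integer(max_links)),
            class = "adhesion_params")
}

#' Empty adhesion state
#'
#' Holds the active cell-wall links and the full creation/breakage event
#' log.
#'
#' @return object of class `adhesion_state` with `links` (cell id, wall id,
#'   birth time) and `events` (time, event, cell, wall, length).
#' @export
adhesion_state <- function() {
  structure(list(
    links = data.frame(cell = integer(), wall = integer(),
                       birth = numeric()),
    events = data.frame(time = numeric(), event = character(),
                        cell = integer(), wall = integer(),
                        length = numeric())),
    class = "adhesion_state")
}

# periodic minimal-image difference along x
wrap_dx <- function(dx, Lx) dx - Lx * round(dx / Lx)

link_lengths <- function(state, cell_pts, wall_pts, Lx = Inf) {
  dx <- wall_pts$x[state$links$wall] - cell_pts$x[state$links$cell]
  if (is.finite(Lx)) dx <- wrap_dx(dx, Lx)
  dy <- wall_pts$y[state$links$wall] - cell_pts$y[state$links$cell]
  sqrt(dx^2 + dy^2)
}

#' Create and break adhesive links from current positions
#'
#' Breakage first: every link whose current length exceeds
#' `lambda_break * max(L_A, eps)` is removed and logged. Creation second:
#' every outer-cortex point holding fewer than `max_links` links and lying
#' within `r_on` of some wall point gains a link to its nearest eligible
#' wall point (ties broken by lowest wall id). Fully deterministic.
#'
#' @param cell_pts cell point set (outer-cortex points are
#'   adhesion-competent).
#' @param wall_pts wall point set.
#' @param state an [adhesion_state()].
#' @param params an [adhesion_params()].
#' @param t current time (s), stamped on events.
#' @param Lx domain period in x for minimal-image distances (Inf for a
#'   non-periodic layout).
#' @return the updated state.
#' @export
update_adhesions <- function(cell_pts, wall_pts, state, params, t = 0,
                             Lx = Inf) {
  # --- break over-stretched links
  if (nrow(state$links) > 0) {
    len <- link_lengths(state, cell_pts, wall_pts, Lx)
    thresh <- params$lambda_break * max(params$L_A, .Machine$double.eps)
    gone <- len > thresh
    if (any(gone)) {
      state$events <- rbind(state$events, data.frame(
        time = t, event = "break", cell = state$links$cell[gone],
        wall = state$links$wall[gone], length = len[gone]))
      state$links <- state$links[!gone, , drop = FALSE]
    }
  }
  # --- create links for free membrane points near the wall
  cand <- which(cell_pts$outer & cell_pts$tag == "cortex")
  if (length(cand) > 0 && nrow(wall_pts) > 0) {
    nlink <- tabulate(state$links$cell, nbins = nrow(cell_pts))
    cand <- cand[nlink[cand] < params$max_links]
    # only points within r_on (in y) of some wall row can possibly bind
    if (length(cand) > 0) {
      wy <- unique(wall_pts$y)
      dy_min <- apply(abs(outer(cell_pts$y[cand], wy, "-")), 1, min)
      cand <- cand[dy_min < params$r_on]
    }
    new_rows <- NULL
    for (ci in cand) {
      dx <- wall_pts$x - cell_pts$x[ci]
      if (is.finite(Lx)) dx <- wrap_dx(dx, Lx)
      d2 <- dx^2 + (wall_pts$y - cell_pts$y[ci])^2
      ok <- d2 < params$r_on^2
      # a (cell, wall) pair may appear at most once
      if (nrow(state$links) > 0) {
        held <- state$links$wall[state$links$cell == ci]
        ok[held] <- FALSE
      }
      if (any(ok)) {
        j <- which(ok)[which.min(d2[ok])]   # nearest; which.min -> lowest id
        new_rows <- rbind(new_rows,
                          data.frame(cell = ci, wall = wall_pts$id[j],
                                     birth = t, length = sqrt(d2[j])))
      }
    }
    if (!is.null(new_rows)) {
      state$links <- rbind(state$links, new_rows[c("cell", "wall", "birth")])
      state$events <- rbind(state$events, data.frame(
        time = t, event = "create", cell = new_rows$cell,
        wall = new_rows$wall, length = new_rows$length))
    }
  }
  state
}

#' Forces exerted by the active adhesive springs
#'
#' Each link contributes equal and opposite Hookean forces to its cell and
#' wall endpoints, so adhesion imparts zero net force to the cell-wall
#' system.
#'
#' @inheritParams update_adhesions
#' @param S_A adhesive stiffness (dyn/cm).
#' @param L_A adhesive rest length (cm).
#' @return list with `cell` and `wall` force matrices (n x 2, dyn).
#' @export
adhesion_forces <- function(state, cell_pts, wall_pts, S_A, L_A, Lx = Inf) {
  fc <- matrix(0, nrow(cell_pts), 2)
  fw <- matrix(0, nrow(wall_pts), 2)
  if (nrow(state$links) == 0) return(list(cell = fc, wall = fw))
  ci <- state$links$cell; wi <- state$links$wall
  if (any(ci > nrow(cell_pts)) || any(wi > nrow(wall_pts)))
    stop("adhesion link references a missing point", call. = FALSE)
  dx <- wall_pts$x[wi] - cell_pts$x[ci]
  if (is.finite(Lx)) dx <- wrap_dx(dx, Lx)
  dy <- wall_pts$y[wi] - cell_pts$y[ci]
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 0
  s <- ifelse(ok, S_A * (len - L_A) / pmax(len, .Machine$double.xmin), 0)
  fx <- s * dx; fy <- s * dy
  sx <- rowsum(fx, ci); sy <- rowsum(fy, ci)
  at <- as.integer(rownames(sx))
  fc[at, 1] <- sx; fc[at, 2] <- sy
  sx <- rowsum(-fx, wi); sy <- rowsum(-fy, wi)
  at <- as.integer(rownames(sx))
  fw[at, 1] <- sx; fw[at, 2] <- sy
  list(cell = fc, wall = fw)
}

#' Soften the cortex near active focal adhesions
#'
#' Cortex springs with either endpoint within `r_soft` of any currently
#' adhered membrane point get stiffness multiplier `m_soft`; all other
#' cortex springs are restored to the base multiplier 1. Restoration is
#' immediate: a spring softened by a focal adhesion stiffens again on the
#' first update after that adhesion breaks. Idempotent for a fixed adhesion
#' state.
#'
#' @param cortex_net the cortex spring network.
#' @param cell_pts the cell point set.
#' @param state an [adhesion_state()].
#' @param m_soft soft multiplier in (0, 1). Default 1/3.
#' @param r_soft influence radius (cm). Default 1.5 micron.
#' @return the updated cortex network.
#' @export
remodel_cortex <- function(cortex_net, cell_pts, state, m_soft = 1 / 3,
                           r_soft = um(1.5)) {
  stopifnot(m_soft > 0, m_soft < 1, r_soft > 0)
  cortex_net$mult <- 1
  if (nrow(state$links) == 0) return(cortex_net)
  ax <- cell_pts$x[unique(state$links$cell)]
  ay <- cell_pts$y[unique(state$links$cell)]
  near <- function(ids) {
    px <- cell_pts$x[ids]; py <- cell_pts$y[ids]
    d2 <- outer(px, ax, "-")^2 + outer(py, ay, "-")^2
    apply(d2, 1, min) < r_soft^2
  }
  soft <- near(cortex_net$i) | near(cortex_net$j)
  cortex_net$mult[soft] <- m_soft
  cortex_net
}
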
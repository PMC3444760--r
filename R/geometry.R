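# Lagrangian geometry: cell (cortex band + nuclear envelope), vessel walls,
# and the stained cortex arc used to visualize rolling.
#
# All lengths are CGS (cm). `um()` converts microns to cm for convenience.

#' Convert microns to centimeters
#'
#' The package works in CGS units internally (lengths in cm, forces in dyn,
#' stiffness in dyn/cm). Geometry at the cell scale is naturally stated in
#' microns; this helper makes that explicit.
#'
#' @param x numeric, length(s) in microns.
#' @return lengths in cm.
#' @export
#' @examples
#' um(10)   # a 10-micron cell diameter, in cm
um <- function(x) x * 1e-4

#' Specify the geometry of a circular cell
#'
#' The cell is a circle with an annular actin-cortex band just inside the
#' membrane and a circular nuclear envelope at the center. Both are realized
#' as cross-linked Hookean spring networks by [build_cell()]; the cytoplasm
#' between them is the (viscous, incompressible) fluid itself.
#'
#' @param center numeric length-2, cell center (cm).
#' @param diameter cell diameter (cm). Default 10 microns.
#' @param nucleus_diameter diameter of the nuclear envelope ring (cm).
#'   Default 4 microns.
#' @param cortex_band radial width of the cortex band (cm). Default 2
#'   microns, i.e. the cortex occupies the annulus between radius 3 and 5
#'   microns for the default cell.
#' @param spacing target arc spacing between adjacent boundary points (cm).
#'   Should not exceed half the fluid grid spacing.
#' @return an object of class `cell_geometry`.
#' @export
cell_geometry <- function(center = c(0, 0),
                          diameter = um(10),
                          nucleus_diameter = um(4),
                          cortex_band = um(2),
                          spacing = um(0.25)) {
  stopifnot(length(center) == 2, diameter > 0, nucleus_diameter > 0,
            cortex_band > 0, spacing > 0)
  if (cortex_band >= diameter / 2)
    stop("cortex band width must be smaller than the cell radius",
         call. = FALSE)
  if (nucleus_diameter / 2 >= diameter / 2 - cortex_band)
    stop("nucleus must lie strictly inside the inner cortex ring",
         call. = FALSE)
  structure(list(center = as.numeric(center), diameter = diameter,
                 nucleus_diameter = nucleus_diameter,
                 cortex_band = cortex_band, spacing = spacing),
            class = "cell_geometry")
}

#' Specify the geometry of the straight microvessel segment
#'
#' The vessel is a straight channel: two parallel rows of wall points,
#' `width` apart, spanning the (periodic) domain length. Each wall point is
#' tethered to a fixed anchor so the wall stays rigid under load.
#'
#' @param length vessel length (cm). Default 75 microns.
#' @param width distance between the two wall rows (cm). Default 30 microns.
#' @param spacing wall point spacing along the wall (cm).
#' @param y_bottom y-coordinate of the bottom wall row (cm). The simulation
#'   centers the channel in the computational domain; the default 0 is only
#'   used when a vessel is built standalone.
#' @return an object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(length = um(75), width = um(30),
                            spacing = um(0.25), y_bottom = 0) {
  stopifnot(length > 0, width > 0, spacing > 0)
  structure(list(length = length, width = width, spacing = spacing,
                 y_bottom = y_bottom),
            class = "vessel_geometry")
}

# points evenly spaced on a circle; n chosen from circumference/spacing
ring_points <- function(center, radius, spacing, phase = 0) {
  n <- round(2 * pi * radius / spacing)
  if (n < 3)
    stop("point spacing too coarse: fewer than 3 points on a ring of radius ",
         signif(radius / 1e-4, 3), " um", call. = FALSE)
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

new_point_set <- function(x, y, tag, outer = FALSE, marker = FALSE,
                          ds = NA_real_, anchor_x = NA_real_,
                          anchor_y = NA_real_) {
  n <- length(x)
  data.frame(id = seq_len(n), x = x, y = y, tag = tag,
             outer = rep_len(outer, n), marker = rep_len(marker, n),
             ds = rep_len(ds, n), anchor_x = rep_len(anchor_x, n),
             anchor_y = rep_len(anchor_y, n))
}

# springs between consecutive points of a closed ring (ids given in order)
ring_springs <- function(ids) {
  cbind(i = ids, j = c(ids[-1], ids[1]))
}

make_network <- function(ij, pts, S, kind = "elastic", mult = 1) {
  i <- ij[, 1]; j <- ij[, 2]
  L <- sqrt((pts$x[j] - pts$x[i])^2 + (pts$y[j] - pts$y[i])^2)
  net <- data.frame(i = as.integer(i), j = as.integer(j), S = S, L = L,
                    kind = kind, mult = mult)
  class(net) <- c("spring_network", "data.frame")
  net
}

#' Build the Lagrangian cell: boundary points plus cortex and nucleus networks
#'
#' The cortex band is discretized as two concentric rings of points (at the
#' outer and inner radius of the band) joined by circumferential springs
#' along each ring, radial rungs to the nearest point on the other ring, and
#' diagonal cross-links, giving a shear-resistant meshwork. The nuclear
#' envelope is a single ring with circumferential springs plus chordal
#' braces every `brace_every`-th point. Every spring's rest length is its
#' initial length, so the constructed cell is stress-free.
#'
#' @param spec a [cell_geometry()] object.
#' @param S baseline spring stiffness in dyn/cm applied to every spring of
#'   both networks (default 50). Scale it (or use [set_stiffness()]) to
#'   model stiffer/softer cortex and nucleus.
#' @param brace_every chordal brace stride on the nuclear envelope.
#' @return a list with elements `points` (one data frame for cortex and
#'   nucleus points; cortex outer-ring points come first and carry
#'   `outer = TRUE`), `cortex` and `nucleus` (spring networks indexing into
#'   `points`).
#' @export
build_cell <- function(spec, S = 50, brace_every = 5) {
  stopifnot(inherits(spec, "cell_geometry"))
  r_out <- spec$diameter / 2
  r_in <- r_out - spec$cortex_band
  r_nuc <- spec$nucleus_diameter / 2

  p_out <- ring_points(spec$center, r_out, spec$spacing)
  p_in <- ring_points(spec$center, r_in, spec$spacing)
  p_nuc <- ring_points(spec$center, r_nuc, spec$spacing)
  n_out <- nrow(p_out); n_in <- nrow(p_in); n_nuc <- nrow(p_nuc)

  pts <- new_point_set(
    x = c(p_out[, 1], p_in[, 1], p_nuc[, 1]),
    y = c(p_out[, 2], p_in[, 2], p_nuc[, 2]),
    tag = rep(c("cortex", "cortex", "nucleus"), c(n_out, n_in, n_nuc)),
    outer = rep(c(TRUE, FALSE, FALSE), c(n_out, n_in, n_nuc)))
  # boundary quadrature weight: local arc spacing, frozen at construction
  pts$ds <- rep(c(2 * pi * r_out / n_out, 2 * pi * r_in / n_in,
                  2 * pi * r_nuc / n_nuc), c(n_out, n_in, n_nuc))

  ids_out <- seq_len(n_out)
  ids_in <- n_out + seq_len(n_in)
  ids_nuc <- n_out + n_in + seq_len(n_nuc)

  # nearest inner-ring partner of each outer point, by angle
  nearest <- function(n_from, n_to) {
    # both rings share phase 0 and uniform angles
    1L + (round((seq_len(n_from) - 1) / n_from * n_to) %% n_to)
  }
  rung_in <- nearest(n_out, n_in)
  cortex_ij <- rbind(
    ring_springs(ids_out),
    ring_springs(ids_in),
    cbind(ids_out, ids_in[rung_in]),                       # radial rungs
    cbind(ids_out, ids_in[1L + (rung_in %% n_in)]))        # diagonals
  cortex_ij <- unique(t(apply(cortex_ij, 1, sort)))

  nuc_ij <- ring_springs(ids_nuc)
  if (brace_every > 0 && n_nuc > 2 * brace_every) {
    k <- as.integer(brace_every)
    brace <- cbind(ids_nuc, ids_nuc[1L + ((seq_len(n_nuc) - 1 + k) %% n_nuc)])
    nuc_ij <- rbind(nuc_ij, brace)
  }
  nuc_ij <- unique(t(apply(nuc_ij, 1, sort)))

  list(points = pts,
       cortex = make_network(cortex_ij, pts, S = S),
       nucleus = make_network(nuc_ij, pts, S = S))
}

#' Build the tethered rigid vessel walls
#'
#' Two straight rows of points spanning the domain length, `width` apart.
#' Each point carries a zero-rest-length tether spring to a fixed anchor at
#' its initial position, plus stiff elastic links to its neighbors along the
#' wall (periodic in x). Under zero load the wall sits exactly at its
#' anchors.
#'
#' @param geom a [vessel_geometry()] object.
#' @param S_tether tether stiffness (dyn/cm); large values make the wall
#'   effectively rigid.
#' @param S_link neighbor-link stiffness (dyn/cm).
#' @return list with `points` (tags `wall_bottom`, `wall_top`) and `network`
#'   (tethers plus neighbor links).
#' @export
build_vessel <- function(geom, S_tether = 2000, S_link = 2000) {
  stopifnot(inherits(geom, "vessel_geometry"))
  n <- round(geom$length / geom$spacing)
  if (n < 3) stop("wall point spacing too coarse", call. = FALSE)
  xs <- (seq_len(n) - 1) * (geom$length / n)
  yb <- geom$y_bottom
  yt <- geom$y_bottom + geom$width
  pts <- new_point_set(
    x = c(xs, xs), y = c(rep(yb, n), rep(yt, n)),
    tag = rep(c("wall_bottom", "wall_top"), each = n))
  pts$ds <- geom$length / n
  pts$anchor_x <- pts$x
  pts$anchor_y <- pts$y

  ids_b <- seq_len(n); ids_t <- n + seq_len(n)
  link_ij <- rbind(ring_springs(ids_b), ring_springs(ids_t))
  links <- make_network(link_ij, pts, S = S_link)
  tethers <- data.frame(i = pts$id, j = NA_integer_, S = S_tether, L = 0,
                        kind = "tether", mult = 1)
  net <- rbind(links, tethers)
  class(net) <- c("spring_network", "data.frame")
  list(points = pts, network = net)
}

#' Mark a fixed arc of the outer cortex ring
#'
#' Sets the marker flag on outer-ring cortex points whose initial polar
#' angle about the cell center lies in `[start, start + span)`. The marked
#' ("stained") arc travels with the material points, so its angular drift
#' around the centroid reveals rolling.
#'
#' @param pts the cell point set from [build_cell()].
#' @param span angular width of the arc, radians, in (0, 2*pi].
#' @param start starting angle, radians.
#' @param center cell center; defaults to the centroid of the outer ring.
#' @return `pts` with the `marker` column set.
#' @export
mark_cortex_arc <- function(pts, span = pi / 6, start = -pi / 2,
                            center = NULL) {
  stopifnot(span > 0, span <= 2 * pi)
  out <- pts$outer & pts$tag == "cortex"
  if (!any(out)) stop("point set has no outer cortex ring", call. = FALSE)
  if (is.null(center))
    center <- c(mean(pts$x[out]), mean(pts$y[out]))
  th <- atan2(pts$y - center[2], pts$x - center[1])
  rel <- (th - start) %% (2 * pi)
  sel <- out & (rel < span | abs(span - 2 * pi) < 1e-12)
  if (!any(sel))
    stop("marked arc selects no points; widen the span or refine spacing",
         call. = FALSE)
  pts$marker <- sel
  pts
}
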
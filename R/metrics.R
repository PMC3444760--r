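# Shape and motion descriptors, rolling detection via the stained cortex
# arc, locomotion-mode classification, and the per-mode stiffness
# signature table.

#' Shape metrics of a closed boundary contour
#'
#' Area by the shoelace formula, perimeter by segment sum, circularity
#' `4 pi A / P^2` (1 for a circle, decreasing with elongation), and
#' major/minor axis lengths from the eigen-decomposition of the boundary
#' point covariance (scaled so that a circle of diameter d reports
#' major = minor = d). All quantities are invariant under rigid rotation
#' and translation.
#'
#' @param xy ordered n x 2 matrix of contour points (closed implicitly), or
#'   a point set data frame whose outer cortex ring is used.
#' @param check_simple if TRUE, error on a self-intersecting contour (a
#'   sign of numerical blow-up).
#' @return list: area, perimeter, circularity, major, minor, aspect,
#'   centroid, clasmatosis_flag.
#' @export
shape_metrics <- function(xy, check_simple = FALSE) {
  if (is.data.frame(xy)) {
    sel <- if ("outer" %in% names(xy)) xy$outer & xy$tag == "cortex"
           else rep(TRUE, nrow(xy))
    xy <- cbind(xy$x[sel], xy$y[sel])
  }
  n <- nrow(xy)
  if (n < 3) stop("contour needs at least 3 points", call. = FALSE)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- 0.5 * abs(sum(x * yn - xn * y))
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  circ <- 4 * pi * area / per^2
  ctr <- c(mean(x), mean(y))
  cv <- stats::cov(cbind(x - ctr[1], y - ctr[2]))
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  major <- 2 * sqrt(2 * ev[1])
  minor <- 2 * sqrt(2 * ev[2])
  aspect <- if (minor > 0) major / minor else Inf
  selfx <- contour_self_intersects(x, y)
  if (check_simple && selfx)
    stop("self-intersecting contour: shape metrics undefined",
         call. = FALSE)
  list(area = area, perimeter = per, circularity = circ,
       major = major, minor = minor, aspect = aspect, centroid = ctr,
       clasmatosis_flag = aspect > 4 || selfx)
}

# O(n^2) segment crossing test on a closed polyline, skipping neighbors
contour_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (length(js) == 0) next
    d1 <- cross(x2[i] - x[i], y2[i] - y[i], x[js] - x[i], y[js] - y[i])
    d2 <- cross(x2[i] - x[i], y2[i] - y[i], x2[js] - x[i], y2[js] - y[i])
    d3 <- cross(x2[js] - x[js], y2[js] - y[js], x[i] - x[js], y[i] - y[js])
    d4 <- cross(x2[js] - x[js], y2[js] - y[js], x2[i] - x[js], y2[i] - y[js])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# shape metrics of the outer cortex ring in snapshot `which` of a trajectory
trajectory_shape <- function(traj, which = length(traj$snapshots)) {
  shape_metrics(traj$snapshots[[which]])
}

#' Cumulative rotation of the stained cortex arc
#'
#' Tracks the circular-mean polar angle of the marked points about the
#' instantaneous cell centroid across snapshots, unwraps the increments,
#' and returns the accumulated angle. Rigid translation contributes
#' nothing; a rolling cell accumulates rotation monotonically.
#'
#' @param traj a `ctc_trajectory` whose cell has marked points.
#' @return cumulative rotation in radians (signed; negative = clockwise).
#' @export
marker_rotation <- function(traj) {
  angs <- vapply(traj$snapshots, function(s) {
    cell <- s[s$structure_group == "cell" & s$outer, , drop = FALSE]
    mk <- s$structure_group == "cell" & s$marker
    if (!any(mk)) stop("trajectory has no marked cortex points",
                       call. = FALSE)
    ctr <- c(mean(cell$x), mean(cell$y))
    th <- atan2(s$y[mk] - ctr[2], s$x[mk] - ctr[1])
    atan2(mean(sin(th)), mean(cos(th)))
  }, numeric(1))
  if (length(angs) < 2)
    stop("need at least two snapshots to measure rotation", call. = FALSE)
  d <- diff(angs)
  d <- (d + pi) %% (2 * pi) - pi
  sum(d)
}

#' Default thresholds for locomotion-mode classification
#'
#' Calibration constants for [classify_mode()]; the locomotion modes are
#' qualitative regimes, so the cutoffs are design choices, logged here with
#' their rationale:
#' * `rot_min`: minimum |marker rotation| per 4 snapshot units to call
#'   rolling. A sustained rolling cell at the reference calibration
#'   accumulates ~0.7 rad per 4 units; 0.5 sits below that with margin.
#' * `adv_min_frac`: minimum net centroid advance, as a fraction of the
#'   cell diameter, for rolling/crawling.
#' * `retention_min`: minimum ratio of final to peak bond count for
#'   rolling. A rolling cell maintains its contact (ratio ~0.6 at the
#'   reference calibration); a cell in the middle of detaching does not
#'   (~0.25).
#' * `float_speed_frac`: centroid speed at least this fraction of the
#'   local undisturbed flow speed counts as floating (a free near-wall
#'   cell drifts at ~0.4 of the local parabolic speed because of wall
#'   drag).
#' * `anchor_speed_frac`: centroid speed below this fraction of the local
#'   flow speed counts as anchored.
#' * `adh_frac_hi`: fraction of snapshots with at least one active link
#'   required for persistent adhesion (rolling/anchoring/crawling).
#' * `adh_free_frac`: fraction of link-free snapshots required for
#'   confident floating.
#' * `turnover_min`: minimum adhesion events per snapshot unit for
#'   rolling/crawling (distinguishes dynamic contact from static
#'   anchoring).
#'
#' @return named list of thresholds.
#' @export
ctc_mode_thresholds <- function() {
  list(rot_min = 0.5, adv_min_frac = 0.5, retention_min = 0.4,
       float_speed_frac = 0.35, anchor_speed_frac = 0.1,
       adh_frac_hi = 0.9, adh_free_frac = 0.9, turnover_min = 1)
}

mode_features <- function(traj) {
  cfg <- traj$config
  ns <- length(traj$snapshots)
  ctrs <- t(vapply(traj$snapshots, function(s) {
    cell <- s[s$structure_group == "cell" & s$outer, , drop = FALSE]
    c(mean(cell$x), mean(cell$y))
  }, numeric(2)))
  duration <- traj$times[ns] - traj$times[1]
  advance <- ctrs[ns, 1] - ctrs[1, 1]
  speed <- if (duration > 0) advance / duration else 0
  # undisturbed parabolic speed at the mean cell height
  yb <- (cfg$grid$Ly - cfg$vessel$width) / 2
  yc <- yb + cfg$vessel$width / 2
  yrel <- (mean(ctrs[, 2]) - yc) / (cfg$vessel$width / 2)
  u_local <- cfg$fluid$u_max * max(0, 1 - yrel^2)
  linked <- traj$links > 0
  ev <- traj$events
  horizon_units <- duration / snapshot_unit(cfg)
  lifetimes <- numeric(0)
  if (!is.null(ev) && nrow(ev) > 0) {
    br <- ev[ev$event == "break", , drop = FALSE]
    cr <- ev[ev$event == "create", , drop = FALSE]
    # lifetimes of broken links: match each break to the latest earlier
    # creation of the same pair
    if (nrow(br) > 0) {
      lifetimes <- vapply(seq_len(nrow(br)), function(k) {
        m <- cr$cell == br$cell[k] & cr$wall == br$wall[k] &
             cr$time <= br$time[k]
        if (any(m)) br$time[k] - max(cr$time[m]) else NA_real_
      }, numeric(1))
      lifetimes <- lifetimes[!is.na(lifetimes)]
    }
  }
  turnover <- if (!is.null(ev) && duration > 0)
    nrow(ev) / max(horizon_units, 1e-12) else 0
  rot <- tryCatch(marker_rotation(traj), error = function(e) 0)
  retention <- if (max(traj$links) > 0)
    traj$links[ns] / max(traj$links) else 0
  list(rotation = rot, advance = advance, speed = speed, u_local = u_local,
       adh_frac = mean(linked), adh_free_frac = mean(!linked),
       retention = retention,
       turnover = turnover, mean_lifetime = if (length(lifetimes))
         mean(lifetimes) else NA_real_,
       duration = duration, horizon_units = horizon_units,
       remodel = isTRUE(cfg$adhesion$remodel))
}

#' Classify the locomotion mode of a trajectory
#'
#' Assigns one of `floating`, `rolling`, `anchoring`, `crawling` from
#' marker rotation, adhesion persistence/turnover, and centroid speed
#' relative to the undisturbed local flow. Rules fire in the order
#' rolling, crawling, anchoring; floating is the fallback (flagged
#' low-confidence when the floating evidence itself is weak). A pure
#' function of its inputs; re-running yields identical labels.
#'
#' @param traj a `ctc_trajectory` (at least 4 snapshot intervals).
#' @param thresholds see [ctc_mode_thresholds()].
#' @return list: `label`, `confidence` (`"high"`/`"low"`), `evidence`
#'   (the feature list), `prefix` (an early-window label when the first
#'   half of the run behaved differently, e.g. anchoring before
#'   detachment).
#' @export
classify_mode <- function(traj, thresholds = ctc_mode_thresholds()) {
  if (length(traj$snapshots) < 5)
    stop("classification needs at least 4 snapshot intervals",
         call. = FALSE)
  th <- thresholds
  fe <- mode_features(traj)
  d_cell <- traj$config$cell$diameter
  adv_ok <- fe$advance >= th$adv_min_frac * d_cell
  rot_ok <- abs(fe$rotation) >=
    th$rot_min * max(fe$horizon_units, 1e-12) / 4
  persistent <- fe$adh_frac >= th$adh_frac_hi
  label <- NULL; conf <- "high"
  if (rot_ok && adv_ok && persistent &&
      fe$retention >= th$retention_min &&
      fe$turnover >= th$turnover_min) {
    label <- "rolling"
  } else if (fe$remodel && persistent && fe$turnover >= th$turnover_min &&
             adv_ok) {
    label <- "crawling"
  } else if (persistent && fe$speed < th$anchor_speed_frac * fe$u_local) {
    label <- "anchoring"
  } else {
    label <- "floating"
    if (!(fe$adh_free_frac >= th$adh_free_frac &&
          fe$speed >= th$float_speed_frac * fe$u_local))
      conf <- "low"
  }
  # early-window prefix: was the first half persistently adhered?
  prefix <- NULL
  ns <- length(traj$snapshots)
  first_half <- traj$links[seq_len(ceiling(ns / 2))]
  if (label == "floating" && mean(first_half > 0) >= 0.5)
    prefix <- "anchoring"
  list(label = label, confidence = conf, evidence = fe, prefix = prefix)
}

#' Per-mode stiffness signature table
#'
#' For each labeled run, reports the effective stiffness (dyn/cm, mean of
#' S x multiplier over springs and snapshots) of the bulk cortex, the
#' near-adhesion (softened) cortex, the nuclear envelope, and the adhesive
#' bonds. Modes without a run are omitted with a warning.
#'
#' @param runs named list: mode label -> `ctc_trajectory` (or a list with a
#'   `trajectory` element).
#' @return data frame with one row per mode.
#' @export
stiffness_signature <- function(runs) {
  modes <- c("floating", "rolling", "anchoring", "crawling")
  rows <- NULL
  for (m in modes) {
    if (is.null(runs[[m]])) {
      warning("no run supplied for mode '", m, "'; row omitted",
              call. = FALSE)
      next
    }
    traj <- runs[[m]]
    if (!inherits(traj, "ctc_trajectory")) traj <- traj$trajectory
    cfg <- traj$config
    S_cortex <- cfg$stiffness$S0 * cfg$stiffness$kC
    mults <- traj$multipliers
    soft_vals <- unlist(lapply(mults, function(mv) mv[mv < 1]))
    bulk_vals <- unlist(lapply(mults, function(mv) mv[mv >= 1]))
    near <- if (length(soft_vals)) S_cortex * mean(soft_vals) else S_cortex
    bulk <- if (length(bulk_vals)) S_cortex * mean(bulk_vals) else S_cortex
    any_links <- any(traj$links > 0)
    rows <- rbind(rows, data.frame(
      mode = m, cortex_S = bulk, cortex_near_adhesion_S = near,
      nucleus_S = cfg$stiffness$S0 * cfg$stiffness$kN,
      adhesion_S = if (any_links) cfg$adhesion$params$S_A else 0))
  }
  rows
}
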
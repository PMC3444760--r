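# Configuration files, trajectory serialization, VTK export, and the run
# manifest.
#
# Output layout (one directory per run):
#   snapshots/NNNNNN.csv   one file per recorded snapshot
#   adhesion_events.csv    the full creation/breakage log
#   config.echo            the effective configuration (defaults applied)
#   manifest.json          schema version, config hash, point/step counts
#
# CSVs are RFC-4180 with a '#'-prefixed schema/unit header comment and
# full round-trip ("%.17g") numeric precision, so a written trajectory
# reads back bit-exactly. All writes go through a temp-file-plus-rename so
# a killed run never leaves a truncated file that parses as valid.

snapshot_schema <- "ctcflow snapshot v1; units: s, cm; columns: time,id,tag,x,y,outer,marker,structure_group,adh"

#' Load a simulation configuration from a YAML file
#'
#' The file holds a flat mapping of [sim_config()] argument names to
#' values; omitted keys take the documented defaults, so an empty file
#' yields the full default setup (50 dyn/cm baseline stiffness, 30 x 75
#' micron vessel, 0.6 mm/s centerline flow, 10/4/2 micron cell). Unknown
#' keys are rejected by name. Length keys may be given in microns with an
#' explicit `_um` suffix (e.g. `cell_diameter_um: 12`).
#'
#' @param path YAML file path.
#' @return a validated `ctc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a YAML mapping", call. = FALSE)
  allowed <- names(formals(sim_config))
  adh_keys <- names(formals(adhesion_params))
  out <- list()
  adh <- list()
  for (key in names(vals)) {
    base <- sub("_um$", "", key)
    v <- if (grepl("_um$", key)) um(vals[[key]]) else vals[[key]]
    if (base %in% adh_keys) {
      adh[[base]] <- v
    } else if (base %in% allowed) {
      out[[base]] <- v
    } else {
      stop("unknown config key: '", key, "'", call. = FALSE)
    }
  }
  if (length(adh) > 0) out$adh_params <- do.call(adhesion_params, adh)
  do.call(sim_config, out)
}

# rebuild a config with selected overrides (e.g. grid size)
config_modify <- function(cfg, ...) {
  args <- config_args(cfg)
  adh_keys <- names(formals(adhesion_params))
  adh <- args[intersect(names(args), adh_keys)]
  args <- args[setdiff(names(args), adh_keys)]
  over <- list(...)
  args[names(over)] <- over
  args <- args[!vapply(args, is.null, logical(1))]
  adh <- adh[!vapply(adh, is.null, logical(1))]
  args$adh_params <- do.call(adhesion_params, adh)
  do.call(sim_config, args)
}

# flatten the nested config back to sim_config() argument form
config_args <- function(cfg) {
  list(nx = cfg$grid$nx, ny = cfg$grid$ny, Lx = cfg$grid$Lx,
       mu = cfg$fluid$mu, rho = cfg$fluid$rho, u_max = cfg$fluid$u_max,
       vessel_width = cfg$vessel$width,
       cell_diameter = cfg$cell$diameter,
       nucleus_diameter = cfg$cell$nucleus_diameter,
       cortex_band = cfg$cell$cortex_band, spacing = cfg$spacing,
       S0 = cfg$stiffness$S0, kC = cfg$stiffness$kC,
       kN = cfg$stiffness$kN, kW = cfg$stiffness$kW,
       cell_position = cfg$cell$position, clearance = cfg$cell$clearance,
       x0 = cfg$cell$x0, with_cell = cfg$cell$with_cell,
       adhesion = cfg$adhesion$enabled,
       remodel = cfg$adhesion$remodel, m_soft = cfg$adhesion$m_soft,
       r_soft = cfg$adhesion$r_soft,
       marker_span = cfg$marker$span, marker_start = cfg$marker$start,
       dt = cfg$numerics$dt, n_steps = cfg$numerics$n_steps,
       snapshot_every = cfg$numerics$snapshot_every,
       stop_x = cfg$numerics$stop_x, adh_every = cfg$adhesion$every,
       max_dt_retries = cfg$numerics$max_dt_retries,
       r_on = cfg$adhesion$params$r_on,
       lambda_break = cfg$adhesion$params$lambda_break,
       S_A = cfg$adhesion$params$S_A, L_A = cfg$adhesion$params$L_A,
       max_links = cfg$adhesion$params$max_links)
}

#' Save a configuration as YAML
#'
#' Writes the effective configuration (all defaults applied) in the flat
#' key form read by [load_config()]; `load_config(save_config(cfg))`
#' reproduces `cfg`.
#'
#' @param cfg a `ctc_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  args <- config_args(cfg)
  args <- args[!vapply(args, is.null, logical(1))]
  atomic_write(path, function(p) yaml::write_yaml(args, p, precision = 15))
  invisible(path)
}

#' Hash of a canonicalized configuration
#'
#' FNV-1a hash of the effective configuration's YAML text; changes iff the
#' configuration changes. Used to stamp run manifests.
#'
#' @param cfg a `ctc_config`.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(config_args(cfg))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply, split to stay within double precision
    hi16 <- floor(h / 65536)
    lo16 <- h %% 65536
    h <- (lo16 * p + ((hi16 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), pattern = ".tmp_ctcflow_")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_csv_commented <- function(df, path, comment) {
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste0("# ", comment), con)
    cols <- lapply(df, fmt_num)
    writeLines(paste(names(df), collapse = ","), con)
    if (nrow(df) > 0)
      writeLines(do.call(paste, c(cols, sep = ",")), con)
  })
}

read_csv_commented <- function(path, colClasses = NA) {
  utils::read.csv(path, comment.char = "#", colClasses = colClasses)
}

#' Write a trajectory to a run directory
#'
#' Emits one snapshot CSV per recorded time, the adhesion event log, the
#' effective-config echo, and a JSON manifest carrying the schema version
#' and config hash. Numeric fields use full round-trip precision, so
#' [read_trajectory()] reproduces coordinates bit-exactly.
#'
#' @param traj a `ctc_trajectory`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  snap_dir <- file.path(dir, "snapshots")
  dir.create(snap_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(snap_dir)) stop("cannot create ", snap_dir, call. = FALSE)
  for (k in seq_along(traj$snapshots)) {
    write_csv_commented(traj$snapshots[[k]],
                        file.path(snap_dir, sprintf("%06d.csv", k - 1L)),
                        snapshot_schema)
  }
  ev <- traj$events
  if (is.null(ev)) ev <- adhesion_state()$events
  write_csv_commented(ev, file.path(dir, "adhesion_events.csv"),
                      "ctcflow adhesion events v1; units: s, cm")
  save_config(traj$config, file.path(dir, "config.echo"))
  manifest <- list(schema = "ctcflow run v1",
                   package_version =
                     as.character(utils::packageVersion("ctcflow")),
                   config_hash = config_hash(traj$config),
                   n_snapshots = length(traj$snapshots),
                   dt_used = traj$dt_used,
                   times = range(traj$times))
  atomic_write(file.path(dir, "manifest.json"), function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}

#' Read a trajectory run directory back
#'
#' @param dir a directory written by [write_trajectory()].
#' @return list with `times`, `snapshots`, `events`, `config`, `manifest`
#'   (class `ctc_trajectory`; the live `world` is not serialized).
#' @export
read_trajectory <- function(dir) {
  files <- sort(list.files(file.path(dir, "snapshots"), pattern = "\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no snapshots under ", dir, call. = FALSE)
  snaps <- lapply(files, read_csv_commented)
  structure(list(
    times = vapply(snaps, function(s) s$time[1], numeric(1)),
    snapshots = snaps,
    events = read_csv_commented(file.path(dir, "adhesion_events.csv")),
    config = load_config(file.path(dir, "config.echo")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json")),
    links = vapply(snaps, function(s) sum(s$adh[s$structure_group == "cell"]),
                   numeric(1))),
    class = "ctc_trajectory")
}

#' Export boundaries as a legacy-VTK polyline file
#'
#' ASCII legacy VTK (POLYDATA with LINES), one polyline per closed contour
#' or wall row, for quick inspection in ParaView.
#'
#' @param snapshot one snapshot data frame from a trajectory.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_boundaries <- function(snapshot, path) {
  grp <- interaction(snapshot$structure_group, snapshot$tag,
                     if ("outer" %in% names(snapshot)) snapshot$outer else 0,
                     drop = TRUE)
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "ctcflow boundaries", "ASCII", "DATASET POLYDATA"), con)
    n <- nrow(snapshot)
    writeLines(sprintf("POINTS %d double", n), con)
    writeLines(sprintf("%.17g %.17g 0", snapshot$x, snapshot$y), con)
    pieces <- split(seq_len(n) - 1L, grp)
    sizes <- vapply(pieces, length, integer(1)) + 1L
    writeLines(sprintf("LINES %d %d", length(pieces),
                       sum(sizes) + length(pieces)), con)
    for (ids in pieces)
      writeLines(paste(c(length(ids) + 1L, ids, ids[1]), collapse = " "),
                 con)
  })
  invisible(path)
}

#' Export the velocity field as legacy-VTK structured points
#'
#' @param state a `fluid_state`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(state, path) {
  g <- state$grid
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "ctcflow velocity",
                 "ASCII", "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
                 "ORIGIN 0 0 0",
                 sprintf("SPACING %.17g %.17g 1", g$h, g$h),
                 sprintf("POINT_DATA %d", g$nx * g$ny),
                 "VECTORS velocity double"), con)
    # VTK iterates x fastest
    writeLines(sprintf("%.17g %.17g 0", as.vector(state$ux),
                       as.vector(state$uy)), con)
  })
  invisible(path)
}
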
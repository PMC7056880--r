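# ---------------------------------------------------------------------------
# Pipeline orchestration: config serialization, full runs with on-disk
# artifacts, mesh-sensitivity protocol and the command-line entry point.
# ---------------------------------------------------------------------------

#' Serialize a run configuration to JSON
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in names(obj)) {
    if (nm %in% c("geometry", "motion", "closure", "props", "fsi_opts")) {
      if (length(obj[[nm]]) > 0) cfg[[nm]] <- modifyList(cfg[[nm]], as.list(obj[[nm]]))
    } else if (!is.null(obj[[nm]])) cfg[[nm]] <- obj[[nm]]
  }
  cfg$n_cycles <- as.integer(cfg$n_cycles)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full pipeline and write artifacts
#'
#' Executes build -> motion -> BC -> mesh -> solve -> analyze and writes a
#' manifest, the geometry, contour and BC files, VTK snapshots, site
#' wall-shear records and the endpoint summary into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress output.
#' @return invisibly, list(run, summary).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("lvrun"),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- run_cycle(config, quiet = quiet)
  summary <- endpoint_summary(run)
  write_geometry_json(run$geometry, file.path(out_dir, "geometry.json"))
  write_geometry_csv(run$geometry, file.path(out_dir, "geometry.csv"))
  write_contours(run$contour, file.path(out_dir, "contours.csv"))
  write_bc_schedule(run$bc, file.path(out_dir, "bc_schedule.csv"))
  for (i in seq_along(run$snapshots)) {
    sn <- run$snapshots[[i]]
    write_vtk_snapshot(sn, sn$mesh,
                       file.path(out_dir, sprintf("snapshot_%03d.vtk", i)))
  }
  # per-site WSS records
  if (!is.null(run$geometry$sites) && is.null(run$geometry$lesion)) {
    for (s in run$geometry$sites) {
      rec <- extract_wall_shear(run, s)
      write.csv(data.frame(time_s = rec$times, tau12_pa = rec$tau),
                file.path(out_dir, sprintf("wss_site%d.csv", s$site_id)),
                row.names = FALSE)
    }
  }
  if (length(run$fsi_trace$times) > 0) {
    write.csv(data.frame(time_s = run$fsi_trace$times,
                         tip_deflection_m = run$fsi_trace$tip,
                         coupling_iters = run$fsi_trace$iters),
              file.path(out_dir, "lesion_trace.csv"), row.names = FALSE)
  }
  write_endpoint_summary(summary, file.path(out_dir, "endpoints.json"))
  cfg_file <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_file)
  manifest <- list(
    package = "lvotflow",
    model_id = config$model_id,
    config_file = "config.json",
    config_hash = sum(utf8ToInt(paste(readLines(cfg_file), collapse = ""))),
    dt = run$dt, steps_per_cycle = run$steps_per_cycle,
    n_cells = nrow(run$mesh$tris),
    remesh_count = run$remesh_count,
    max_continuity_residual = max(vapply(run$diag, function(d) max(d$resid), 0)),
    max_cfl = max(vapply(run$diag, function(d) max(d$cfl), 0)),
    periodicity = run$periodicity,
    snapshots = length(run$snapshots))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(run = run, summary = summary))
}

#' Mesh-sensitivity protocol
#'
#' Runs the filling phase at a sequence of cell sizes, extracts the
#' peak-filling velocity-magnitude profile along the LV short axis and
#' reports the correlation coefficient R^2 between profiles predicted by
#' consecutive cell sizes (the attainment criterion in the source protocol
#' is R^2 > 0.95).
#'
#' @param config base [run_config()].
#' @param sizes vector of cell sizes (m), coarse to fine (>= 2).
#' @param t_peak time of the filling peak sampled (s).
#' @param depth_frac chamber depth fraction of the sampling line.
#' @param n_sample sample stations across the short axis.
#' @param quiet suppress progress.
#' @return data.frame with consecutive-pair R^2 and the profiles as an
#'   attribute.
#' @export
run_mesh_sensitivity <- function(config = run_config(), sizes,
                                 t_peak = 0.16, depth_frac = 0.35,
                                 n_sample = 60L, quiet = TRUE) {
  if (length(sizes) < 2) stop("need at least two cell sizes")
  geometry <- build_geometry(config$model_id, config$geometry)
  cs <- generate_contours(geometry, config$motion, n_frames = config$n_frames,
                          n_nodes = config$n_nodes, seed = config$seed)
  sp <- contour_spline(cs)
  csf <- interpolate_contours(cs, 60L)
  wave <- compute_area_waveform(csf, geometry$inlet_extension$width,
                                geometry$outlet_extension$width)
  bcs <- derive_bc_schedule(wave, geometry$inlet_extension$width,
                            geometry$outlet_extension$width,
                            ramp_eps = config$ramp_eps)
  bci <- bc_interpolator(bcs)
  # sampling line: horizontal chord at the given depth, at t_peak
  profiles <- vector("list", length(sizes))
  for (iz in seq_along(sizes)) {
    mesh <- generate_mesh(geometry, cell_size = sizes[iz],
                          first_layer = config$first_layer, contour = cs)
    u_in_pk <- max(bcs$u_in_m_s)
    fl <- sqrt(rowSums((mesh$nodes[mesh$face_nodes[, 1], , drop = FALSE] -
                        mesh$nodes[mesh$face_nodes[, 2], , drop = FALSE])^2))
    per <- numeric(nrow(mesh$tris))
    for (f in seq_along(fl)) {
      per[mesh$face_owner[f]] <- per[mesh$face_owner[f]] + fl[f]
      if (mesh$face_neigh[f] > 0)
        per[mesh$face_neigh[f]] <- per[mesh$face_neigh[f]] + fl[f]
    }
    dt <- config$cfl_target * min(mesh$cell_area / (0.5 * per)) /
      (1.4 * max(u_in_pk, 0.05))
    steps <- as.integer(ceiling(t_peak / dt))
    dt <- t_peak / steps
    tgrid <- (0:steps) * dt
    bpos <- .build_bpos(mesh, sp, tgrid)
    bstep <- bci(tgrid[-1])
    st <- flow_state(mesh, config$closure)
    plan <- .base_plan(mesh, bpos, steps, dt, config$props, config$closure,
                       u_in = bstep$u_in, u_out = bstep$u_out,
                       phase = ifelse(bstep$phase == "diastole", 1L, 2L),
                       inlet_dir = c(0, -1), outlet_dir = geometry$lvot_axis,
                       conv_blend = config$conv_blend,
                       cont_tol = config$cont_tol,
                       q_ref = max(u_in_pk * geometry$inlet_extension$width /
                                     1000, 1e-9))
    res <- run_ale_cpp(plan, st)
    if (res$status != "ok")
      stop("profile extraction failure: solver status ", res$status)
    # sampling chord at the deformed configuration
    xs <- geometry$params
    y_line <- -depth_frac * xs$chamber_depth / 1000
    x0 <- (xs$junction_x - xs$inlet_width + 2) / 1000
    x1 <- (xs$crest_x - 2) / 1000
    pts <- cbind(seq(x0, x1, length.out = n_sample), y_line)
    loc <- locate_cells_cpp(pts, res$state$nodes, mesh$tris, nearest = TRUE) + 1L
    profiles[[iz]] <- sqrt(rowSums(res$state$u[loc, , drop = FALSE]^2))
    if (!quiet) message("size ", sizes[iz], ": done (", steps, " steps)")
  }
  r2 <- vapply(seq_len(length(sizes) - 1L), function(i) {
    stats::cor(profiles[[i]], profiles[[i + 1L]])^2
  }, 0)
  out <- data.frame(size_coarse = head(sizes, -1), size_fine = sizes[-1],
                    r_squared = r2, attained = r2 > 0.95)
  attr(out, "profiles") <- profiles
  out
}

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

.cli_usage <- "usage: lvotflow <command> [--key value ...]

commands:
  build-geometry   --model N-LV --out geom.json
  gen-motion       --model N-LV --seed 1 --out contours.csv
  derive-bc        --contours contours.csv --out bc.csv
  mesh             --model N-LV --cell-size 0.0012 --out mesh_info.json
  simulate         --config config.json --out-dir DIR
  run-all          --model N-LV --out-dir DIR [--cycles 2 --cell-size 0.0012]
  analyze          --run-dir DIR  (reserved; analysis runs inside simulate)
  compare          --a a/endpoints.json --b b/endpoints.json --out cmp.json
  mesh-sensitivity --model N-LV --sizes 0.0018,0.0014 --out sens.csv
"

.cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      out[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands; see `inst/cli/lvotflow.R` for the
#' executable wrapper.
#'
#' @param args character vector of CLI arguments (first element is the
#'   subcommand).
#' @return invisibly, the subcommand result.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { cat(.cli_usage); return(invisible(NULL)) }
  cmd <- args[1]
  kv <- .cli_args(args[-1])
  model <- kv[["model"]] %||% "N-LV"
  res <- switch(cmd,
    "build-geometry" = {
      g <- build_geometry(model)
      out <- kv[["out"]] %||% "geometry.json"
      write_geometry_json(g, out)
      write_geometry_csv(g, sub("\\.json$", ".csv", out))
      message("wrote ", out)
      g
    },
    "gen-motion" = {
      g <- build_geometry(model)
      cs <- generate_contours(g, seed = as.integer(kv[["seed"]] %||% "1"))
      out <- kv[["out"]] %||% "contours.csv"
      write_contours(cs, out)
      message("wrote ", out)
      cs
    },
    "derive-bc" = {
      cs <- read_contours(kv[["contours"]] %||% "contours.csv")
      wv <- compute_area_waveform(interpolate_contours(cs, 60L))
      bc <- derive_bc_schedule(wv)
      out <- kv[["out"]] %||% "bc_schedule.csv"
      write_bc_schedule(bc, out)
      message("wrote ", out)
      bc
    },
    "mesh" = {
      g <- build_geometry(model)
      m <- generate_mesh(g, cell_size = as.numeric(kv[["cell-size"]] %||% "0.0012"))
      info <- list(cells = nrow(m$tris), nodes = nrow(m$nodes),
                   boundary_nodes = m$n_boundary,
                   cell_size = m$cell_size, first_layer = m$first_layer)
      out <- kv[["out"]] %||% "mesh_info.json"
      jsonlite::write_json(info, out, auto_unbox = TRUE)
      message("wrote ", out)
      m
    },
    "simulate" = ,
    "run-all" = {
      cfg <- if (!is.null(kv[["config"]])) read_run_config(kv[["config"]])
             else run_config(model_id = model)
      if (!is.null(kv[["cycles"]])) cfg$n_cycles <- as.integer(kv[["cycles"]])
      if (!is.null(kv[["cell-size"]])) cfg$cell_size <- as.numeric(kv[["cell-size"]])
      if (!is.null(kv[["seed"]])) cfg$seed <- as.integer(kv[["seed"]])
      out_dir <- kv[["out-dir"]] %||% "lvotflow_run"
      run_pipeline(cfg, out_dir)
    },
    "compare" = {
      a <- jsonlite::read_json(kv[["a"]], simplifyVector = TRUE)
      b <- jsonlite::read_json(kv[["b"]], simplifyVector = TRUE)
      cls <- function(x) structure(x, class = "endpoint_summary")
      cmp <- compare_models(cls(a), cls(b))
      out <- kv[["out"]] %||% "comparison.json"
      jsonlite::write_json(cmp, out, auto_unbox = TRUE, digits = NA)
      message("wrote ", out)
      cmp
    },
    "mesh-sensitivity" = {
      sizes <- as.numeric(strsplit(kv[["sizes"]] %||% "0.0018,0.0014", ",")[[1]])
      cfg <- run_config(model_id = model)
      sens <- run_mesh_sensitivity(cfg, sizes)
      out <- kv[["out"]] %||% "mesh_sensitivity.csv"
      write.csv(sens, out, row.names = FALSE)
      message("wrote ", out)
      sens
    },
    { cat(.cli_usage); NULL })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
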
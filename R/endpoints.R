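# ---------------------------------------------------------------------------
# Hemodynamic endpoints: wall shear metrics (TSM, TSG, OSI), vorticity,
# turbulence kinetic energy, Reynolds shear stress, jet characteristics and
# cross-model comparison quantities.
# ---------------------------------------------------------------------------

#' Out-of-plane vorticity field
#'
#' Least-squares cell gradients of the velocity give
#' omega = du2/dx1 - du1/dx2 per cell.
#'
#' @param snapshot list with `u` (n x 2) and `nodes`; e.g. a solver snapshot.
#' @param mesh the `lvot_mesh` the snapshot lives on.
#' @return vorticity per cell (1/s).
#' @export
compute_vorticity <- function(snapshot, mesh) {
  g1 <- ls_gradient_cpp(.mesh_topo(mesh), snapshot$nodes, snapshot$u[, 1])
  g2 <- ls_gradient_cpp(.mesh_topo(mesh), snapshot$nodes, snapshot$u[, 2])
  g2[, 1] - g1[, 2]
}

#' Turbulence kinetic energy field
#'
#' The modeled k transported by the SST closure (identically zero for a
#' laminar run).
#'
#' @param snapshot solver snapshot (uses `k`).
#' @param closure the closure used for the run.
#' @return TKE per cell (m^2/s^2).
#' @export
compute_tke <- function(snapshot, closure = turbulence_closure()) {
  if (closure$model != "sst_k_omega") return(rep(0, length(snapshot$p)))
  snapshot$k
}

#' Modeled Reynolds shear stress field
#'
#' Boussinesq eddy-viscosity form:
#' RSS = -rho u1'u2' = rho nu_t (du1/dx2 + du2/dx1).
#'
#' @param snapshot solver snapshot (uses `u`, `nut`).
#' @param mesh the mesh.
#' @param closure run closure (laminar -> identically zero).
#' @param props fluid properties.
#' @return RSS per cell (Pa).
#' @export
compute_rss <- function(snapshot, mesh, closure = turbulence_closure(),
                        props = fluid_properties()) {
  if (closure$model != "sst_k_omega" || all(snapshot$nut == 0))
    return(rep(0, length(snapshot$p)))
  g1 <- ls_gradient_cpp(.mesh_topo(mesh), snapshot$nodes, snapshot$u[, 1])
  g2 <- ls_gradient_cpp(.mesh_topo(mesh), snapshot$nodes, snapshot$u[, 2])
  props$rho * snapshot$nut * (g1[, 2] + g2[, 1])
}

# trapezoidal integral of y over uniform grid spanning one period
.trapz_period <- function(y, T) {
  n <- length(y)
  h <- T / n
  # cyclic signal sampled on [0, T): close the loop
  sum((y + c(y[-1], y[1])) / 2) * h
}

#' Temporal shear magnitude
#'
#' TSM = (1/T) integral |tau12| dt over one cycle (trapezoidal rule on the
#' cyclic record).
#'
#' @param record wall-shear record: list with `times` (uniform grid spanning
#'   one period) and `tau` (Pa), or a numeric vector with attribute-free
#'   uniform sampling plus `period`.
#' @param period cycle duration (s); inferred from `record$times` if absent.
#' @return TSM in Pa.
#' @export
compute_tsm <- function(record, period = NULL) {
  tau <- if (is.list(record)) record$tau else record
  T <- .record_period(record, period)
  .check_uniform(record)
  .trapz_period(abs(tau), T) / T
}

#' Temporal shear gradient
#'
#' TSG = (1/T) integral |d tau12/dt| dt with centred differences and a
#' periodic wrap.
#'
#' @inheritParams compute_tsm
#' @return TSG in Pa/s.
#' @export
compute_tsg <- function(record, period = NULL) {
  tau <- if (is.list(record)) record$tau else record
  T <- .record_period(record, period)
  .check_uniform(record)
  n <- length(tau)
  h <- T / n
  dtau <- (tau[c(2:n, 1)] - tau[c(n, 1:(n - 1))]) / (2 * h)
  .trapz_period(abs(dtau), T) / T
}

#' Oscillatory shear index
#'
#' OSI = 1/2 (1 - |int tau dt| / int |tau| dt); 0 for unidirectional shear,
#' 0.5 for purely oscillatory shear.  An identically zero record returns 0
#' with a warning.
#'
#' @inheritParams compute_tsm
#' @return OSI in `[0, 0.5]`.
#' @export
compute_osi <- function(record, period = NULL) {
  tau <- if (is.list(record)) record$tau else record
  T <- .record_period(record, period)
  .check_uniform(record)
  denom <- .trapz_period(abs(tau), T)
  if (denom <= 0) {
    warning("identically zero shear record; OSI defined as 0")
    return(0)
  }
  num <- abs(.trapz_period(tau, T))
  osi <- 0.5 * (1 - num / denom)
  min(max(osi, 0), 0.5)
}

.record_period <- function(record, period) {
  if (!is.null(period)) return(period)
  if (is.list(record) && !is.null(record$period)) return(record$period)
  if (is.list(record) && !is.null(record$times)) {
    tt <- record$times
    return(diff(range(tt)) + (tt[2] - tt[1]))
  }
  stop("period not specified")
}

.check_uniform <- function(record) {
  if (is.list(record) && !is.null(record$times)) {
    dtv <- diff(record$times)
    if (length(dtv) > 1 && (max(dtv) - min(dtv)) > 1e-6 * max(dtv))
      stop("record error: non-uniform time grid")
  }
  invisible(TRUE)
}

#' Wall shear record extraction for a site window
#'
#' Area-averages the per-face tau12 records of a run over the faces whose
#' septal arc coordinate falls inside the site window, over the final cycle.
#'
#' @param run an `lvot_run`.
#' @param site a site window `list(site_id, arc_start, arc_end)` (mm).
#' @param cycle cycle to extract (default: final).
#' @return list with `times`, `tau` (Pa), `period`, `site_id`.
#' @export
extract_wall_shear <- function(run, site, cycle = NULL) {
  if (is.null(cycle)) cycle <- run$config$n_cycles
  chunks <- Filter(function(ch) ch$cycle == cycle, run$wss)
  if (length(chunks) == 0) stop("no wall-shear record for cycle ", cycle)
  times <- c(); tau <- c()
  for (ch in chunks) {
    inwin <- ch$s_face >= site$arc_start - 1e-9 &
             ch$s_face <= site$arc_end + 1e-9
    if (!any(inwin)) {
      if (all(!is.finite(ch$s_face)))
        stop("site error: no wall faces in the site window")
      # a remeshed epoch can stretch the moving-wall arc past the reference
      # window; fall back to the face nearest the window centre
      mid <- (site$arc_start + site$arc_end) / 2
      inwin <- seq_along(ch$s_face) == which.min(abs(ch$s_face - mid))
    }
    w <- ch$face_len[inwin]
    avg <- as.numeric(ch$tau[, inwin, drop = FALSE] %*% w) / sum(w)
    times <- c(times, ch$times)
    tau <- c(tau, avg)
  }
  list(times = times, tau = tau, period = run$contour$period,
       site_id = site$site_id)
}

#' Effective jet diameter across a cross-section
#'
#' Length of the contiguous segment, around the maximum, where the forward
#' axial velocity exceeds `frac` (default 10%) of the instantaneous
#' cross-sectional maximum.
#'
#' @param snapshot solver snapshot.
#' @param mesh its mesh.
#' @param p0,p1 cross-section segment endpoints (m).
#' @param axis unit vector of the forward (axial) direction.
#' @param n_sample sample points across the section.
#' @param frac threshold fraction of the maximum.
#' @return effective diameter (m); 0 with a warning when there is no forward
#'   flow.
#' @export
effective_jet_diameter <- function(snapshot, mesh, p0, p1, axis,
                                   n_sample = 80L, frac = 0.1) {
  tt <- seq(0, 1, length.out = n_sample)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
  loc <- locate_cells_cpp(pts, snapshot$nodes, mesh$tris, nearest = TRUE) + 1L
  ua <- snapshot$u[loc, 1] * axis[1] + snapshot$u[loc, 2] * axis[2]
  umax <- max(ua)
  if (umax <= 0) {
    warning("no forward flow across the section; jet diameter 0")
    return(0)
  }
  above <- ua > frac * umax
  imax <- which.max(ua)
  i0 <- imax; while (i0 > 1L && above[i0 - 1L]) i0 <- i0 - 1L
  i1 <- imax; while (i1 < n_sample && above[i1 + 1L]) i1 <- i1 + 1L
  L <- sqrt(sum((p1 - p0)^2))
  (tt[i1] - tt[i0]) * L
}

# LVOT cell classification: channel strip between the crest mouth and outlet
.lvot_cells <- function(mesh, geometry) {
  cen <- mesh$cell_centroid * 1000
  C <- geometry$crest_point; a <- geometry$lvot_axis; nh <- geometry$lvot_normal
  s <- (cen[, 1] - C[1]) * a[1] + (cen[, 2] - C[2]) * a[2]
  d <- (cen[, 1] - C[1]) * nh[1] + (cen[, 2] - C[2]) * nh[2]
  which(s > 0 & s < geometry$channel_length &
        d > 0 & d < geometry$outlet_extension$width)
}

#' Endpoint summary of a run
#'
#' Computes the per-site TSM/TSG/OSI (N-LV and S-LV), the field-level
#' maximum TKE, peak RSS and time-averaged LVOT |vorticity|, and the peak
#' systolic LVOT velocity and effective jet diameter used for cross-model
#' comparisons.  All quantities are taken on the final cycle.
#'
#' @param run an `lvot_run`.
#' @param jet_station axial position (fraction of channel length) of the
#'   LVOT-base cross-section used for jet metrics.
#' @return object of class `endpoint_summary`.
#' @export
endpoint_summary <- function(run, jet_station = 0.35) {
  geometry <- run$geometry
  closure <- run$config$closure
  sites_out <- NULL
  if (!is.null(geometry$sites) && is.null(geometry$lesion)) {
    sites_out <- lapply(geometry$sites, function(s) {
      rec <- extract_wall_shear(run, s)
      list(site_id = s$site_id,
           tsm = compute_tsm(rec), tsg = compute_tsg(rec),
           osi = compute_osi(rec))
    })
  }
  # field-level metrics over final-cycle snapshots
  max_tke <- 0; peak_rss <- 0
  vort_acc <- 0; vort_n <- 0
  peak_v <- 0; peak_v_time <- NA_real_
  jd <- NA_real_; jd_time <- NA_real_
  C <- geometry$crest_point / 1000; a <- geometry$lvot_axis
  nh <- geometry$lvot_normal
  w_out <- geometry$outlet_extension$width / 1000
  s_station <- jet_station * geometry$channel_length / 1000
  p0 <- C + s_station * a
  p1 <- p0 + w_out * nh
  best_flux <- -Inf
  for (sn in run$snapshots) {
    mesh <- sn$mesh
    lv <- .lvot_cells(mesh, geometry)
    if (length(lv) == 0) next
    vmag <- sqrt(rowSums(sn$u[lv, , drop = FALSE]^2))
    # systole: positive axial outflow
    ua <- sn$u[lv, 1] * a[1] + sn$u[lv, 2] * a[2]
    if (max(vmag) > peak_v && mean(ua) > 0) {
      peak_v <- max(vmag); peak_v_time <- sn$time
    }
    om <- compute_vorticity(sn, mesh)
    vort_acc <- vort_acc + sum(abs(om[lv]) * mesh$cell_area[lv]) /
      sum(mesh$cell_area[lv])
    vort_n <- vort_n + 1L
    tk <- compute_tke(sn, closure)
    if (max(tk) > max_tke) max_tke <- max(tk)
    rs <- compute_rss(sn, mesh, closure, run$config$props)
    if (max(abs(rs)) > peak_rss) peak_rss <- max(abs(rs))
    # jet diameter at the systolic peak-flux snapshot
    flx <- mean(ua)
    if (flx > best_flux) {
      best_flux <- flx
      jd <- effective_jet_diameter(sn, mesh, p0, p1, a)
      jd_time <- sn$time
    }
  }
  structure(list(model_id = run$config$model_id,
                 sites = sites_out,
                 max_tke = max_tke, peak_rss = peak_rss,
                 lvot_vorticity = if (vort_n > 0) vort_acc / vort_n else NA,
                 peak_lvot_velocity = peak_v, peak_velocity_time = peak_v_time,
                 jet_diameter = jd, jet_diameter_time = jd_time,
                 period = run$contour$period),
            class = "endpoint_summary")
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat("endpoint_summary:", x$model_id, "\n")
  if (!is.null(x$sites)) {
    for (s in x$sites)
      cat(sprintf("  site %d: TSM %.4g Pa, TSG %.4g Pa/s, OSI %.3f\n",
                  s$site_id, s$tsm, s$tsg, s$osi))
  }
  cat(sprintf("  peak LVOT velocity %.3f m/s; jet diameter %.2f mm\n",
              x$peak_lvot_velocity, x$jet_diameter * 1000))
  cat(sprintf("  LVOT <|vorticity|> %.3g 1/s; max TKE %.3g m2/s2; peak RSS %.3g Pa\n",
              x$lvot_vorticity, x$max_tke, x$peak_rss))
  invisible(x)
}

#' Compare two model endpoint summaries
#'
#' Ratios (B/A) for peak LVOT velocity and time-averaged |vorticity|,
#' percent reduction of the effective jet diameter, and site-wise percent
#' differences of TSM/TSG plus OSI differences.
#'
#' @param summary_a,summary_b `endpoint_summary` objects (reference A).
#' @return list of comparison quantities.
#' @export
compare_models <- function(summary_a, summary_b) {
  if (abs(summary_a$period - summary_b$period) > 1e-9)
    stop("phase mismatch: summaries from different cycle periods")
  out <- list(model_a = summary_a$model_id, model_b = summary_b$model_id,
              velocity_fold = summary_b$peak_lvot_velocity /
                summary_a$peak_lvot_velocity,
              vorticity_fold = summary_b$lvot_vorticity /
                summary_a$lvot_vorticity,
              jet_diameter_reduction =
                1 - summary_b$jet_diameter / summary_a$jet_diameter)
  if (!is.null(summary_a$sites) && !is.null(summary_b$sites)) {
    out$sites <- lapply(seq_along(summary_a$sites), function(i) {
      sa <- summary_a$sites[[i]]; sb <- summary_b$sites[[i]]
      list(site_id = sa$site_id,
           tsm_pct = 100 * (sb$tsm - sa$tsm) / sa$tsm,
           tsg_pct = 100 * (sb$tsg - sa$tsg) / sa$tsg,
           osi_diff = sb$osi - sa$osi)
    })
  }
  out
}

#' Write an endpoint summary as JSON
#' @param summary an `endpoint_summary` (or comparison list).
#' @param path output path.
#' @export
write_endpoint_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
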
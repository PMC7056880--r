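# ---------------------------------------------------------------------------
# Cardiac-cycle run driver: geometry -> motion -> BC -> mesh -> ALE solve,
# with optional lesion FSI, automatic remeshing on mesh-quality collapse and
# cycle-to-cycle periodicity reporting.
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' Desk-scale defaults: ~1.2 mm bulk cells, two cardiac cycles, laminar
#' closure.  The study-scale configuration (175 um cells, four cycles, SST
#' closure) is expressible through the same fields but is long-running.
#'
#' @param model_id `"N-LV"`, `"S-LV"` or `"DSS-LV"`.
#' @param geometry geometry parameters ([geometry_params()]).
#' @param motion wall-motion parameters ([motion_params()]).
#' @param seed integer seed for the motion generator.
#' @param n_frames,n_nodes contour frames per cycle and nodes per contour.
#' @param cell_size,first_layer mesh sizes (m).
#' @param dt time step (s), or `NULL` for a CFL-based automatic choice.
#' @param cfl_target target convective CFL for automatic dt.
#' @param n_cycles cycles to run (analysis uses the final one).
#' @param closure [turbulence_closure()].
#' @param props [fluid_properties()].
#' @param conv_blend second-order upwind reconstruction fraction.
#' @param cont_tol normalized continuity tolerance driven by the projection
#'   (the acceptance criterion is 1e-3; the solve targets tighter).
#' @param snapshots_per_cycle field snapshots stored over the final cycle.
#' @param fsi lesion coupling mode: `"auto"` (= `"oneway"` when a lesion is
#'   present), `"oneway"` (rigid-lesion flow driving the added-mass modal
#'   oscillator; desk-scale default), `"coupled"` (two-way partitioned with
#'   interface quasi-Newton; prone to added-mass instability at desk scale),
#'   `"rigid"` or `"off"`.
#' @param fsi_opts list: `n_length`, `n_thick`, `tol` (m), `max_iter`,
#'   `relax0`, `rayleigh_a`, `rayleigh_b`, `material`.
#' @param ramp_eps BC ramp half-width (s).
#' @param soft_start first-cycle wall-motion start-up envelope duration (s);
#'   avoids an impulsive start from the nonzero spline end-slope at t = 0.
#' @return a `run_config` list.
#' @export
run_config <- function(model_id = "N-LV",
                       geometry = geometry_params(),
                       motion = motion_params(),
                       seed = 1L,
                       n_frames = 29L, n_nodes = 80L,
                       cell_size = 1.2e-3, first_layer = NULL,
                       dt = NULL, cfl_target = 0.25,
                       n_cycles = 2L,
                       closure = turbulence_closure(),
                       props = fluid_properties(),
                       conv_blend = 1, cont_tol = 1e-5,
                       snapshots_per_cycle = 24L,
                       fsi = "auto",
                       fsi_opts = list(),
                       ramp_eps = 0.005,
                       soft_start = 0.05) {
  structure(list(model_id = model_id, geometry = geometry, motion = motion,
                 seed = as.integer(seed), n_frames = as.integer(n_frames),
                 n_nodes = as.integer(n_nodes),
                 cell_size = cell_size, first_layer = first_layer,
                 dt = dt, cfl_target = cfl_target,
                 n_cycles = as.integer(n_cycles),
                 closure = closure, props = props,
                 conv_blend = conv_blend, cont_tol = cont_tol,
                 snapshots_per_cycle = as.integer(snapshots_per_cycle),
                 fsi = fsi, fsi_opts = fsi_opts, ramp_eps = ramp_eps,
                 soft_start = soft_start),
            class = "run_config")
}

# boundary position array over one cycle for a mesh bound to a contour spline
.build_bpos <- function(mesh, spline, times) {
  nb <- mesh$n_boundary
  np <- length(times)
  Ct <- spline$at_times(times)            # np x 80 x 2, mm
  bpos <- array(0, dim = c(nb, 2, np))
  base <- mesh$nodes[seq_len(nb), , drop = FALSE]
  for (d in 1:2) bpos[, d, ] <- base[, d]
  mov <- which(mesh$btype == 2L)
  for (i in mov) {
    j <- mesh$mov_seg[i]; lam <- mesh$mov_lambda[i]
    for (d in 1:2) {
      bpos[i, d, ] <- ((1 - lam) * Ct[, j, d] + lam * Ct[, j + 1L, d]) / 1000
    }
  }
  bpos
}

# FSI plan entries for a lesion-bearing mesh
.fsi_plan <- function(mesh, geometry, dt, opts, mode, solid_disp = NULL) {
  les_idx <- which(mesh$btype == 3L)
  if (length(les_idx) == 0 || mode == "off") return(NULL)
  if (mode == "rigid") {
    # rigid flag: lesion boundary held fixed; no solid model needed
    return(NULL)
  }
  oneway <- identical(mode, "oneway")
  o <- modifyList(list(n_length = 24L, n_thick = 4L, tol = 1e-9,
                       max_iter = 25L, relax0 = 0.1, max_incr = 3e-4,
                       n_modes = 4L, zeta = 0.02,
                       added_mass_ratio = NULL,
                       material = lesion_material()), opts)
  lm <- geometry$lesion
  solid <- build_lesion_solid(length = lm$length / 1000,
                              thickness = lm$thickness / 1000,
                              material = o$material,
                              n_length = o$n_length, n_thick = o$n_thick,
                              origin = lm$root_centre / 1000,
                              axis = lm$axis, cross = lm$cross)
  # map fluid lesion boundary nodes to the two nearest solid boundary
  # nodes, matched in the *current* (possibly deflected) configuration
  sb <- which(solid$on_boundary)
  sbxy <- solid$nodes[sb, , drop = FALSE]
  if (!is.null(solid_disp))
    sbxy <- sbxy + cbind(solid_disp[2 * sb - 1L], solid_disp[2 * sb])
  fl <- mesh$nodes[les_idx, , drop = FALSE]
  les_map <- matrix(0L, length(les_idx), 2)
  les_wgt <- matrix(0, length(les_idx), 2)
  for (i in seq_along(les_idx)) {
    d2 <- (sbxy[, 1] - fl[i, 1])^2 + (sbxy[, 2] - fl[i, 2])^2
    ord <- order(d2)[1:2]
    w <- 1 / (sqrt(d2[ord]) + 1e-9)
    les_map[i, ] <- sb[ord]
    les_wgt[i, ] <- w / sum(w)
  }
  Wl <- .idw_weights(mesh, les_idx)$W
  # hydrodynamic added mass (transverse 2D-plate estimate rho_f pi L^2 / 4)
  # folded into the modal eigenproblem so the reduced dynamics carry the
  # in-fluid natural frequencies
  amr <- o$added_mass_ratio
  if (is.null(amr)) {
    rho_f <- 1050
    m_solid <- sum(solid$M_diag) / 2
    m_added <- rho_f * pi * (lm$length / 1000)^2 / 4
    amr <- m_added / m_solid
  }
  Mtot <- (1 + amr) * solid$M_diag
  Dm <- 1 / sqrt(Mtot)
  A <- sweep(sweep(solid$K, 1, Dm, "*"), 2, Dm, "*")
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  nm <- min(o$n_modes, length(ev$values))
  sel <- order(ev$values)[seq_len(nm)]
  Phi <- sweep(ev$vectors[, sel, drop = FALSE], 1, Dm, "*")
  lambda <- pmax(ev$values[sel], 0)
  tip <- solid$tip_node
  list(enabled = TRUE,
       W_l = Wl,
       les_nodes = as.integer(les_idx),
       les_map = les_map, les_wgt = les_wgt,
       Phi = Phi, lambda = lambda, zeta = o$zeta,
       if_dofmap = as.integer(solid$dofmap),
       max_iter = as.integer(o$max_iter), tol = o$tol, relax0 = o$relax0,
       max_incr = o$max_incr,
       tip_dof1 = solid$dofmap[2L * tip - 1L] + 1L,
       tip_dof2 = solid$dofmap[2L * tip] + 1L,
       cross = solid$cross,
       oneway = oneway,
       solid = solid, Phi = Phi)
}

#' Run one or more cardiac cycles
#'
#' Full pipeline for a single LV model: builds the geometry, generates the
#' synthetic wall motion, derives the valve-switched boundary conditions,
#' meshes the fluid domain and integrates the ALE flow (with two-way lesion
#' coupling for DSS-LV).  On mesh-quality collapse the domain is remeshed
#' from the current boundary and the fields are transferred.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `lvot_run`: final-cycle snapshots (with their
#'   meshes), septal wall-shear records, per-cycle diagnostics, periodicity
#'   metrics, the BC schedule and waveform, and the FSI trace.
#' @export
run_cycle <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  geometry <- build_geometry(config$model_id, config$geometry)
  cs <- generate_contours(geometry, config$motion, n_frames = config$n_frames,
                          n_nodes = config$n_nodes, seed = config$seed)
  sp <- contour_spline(cs)
  csf <- interpolate_contours(cs, 60L)
  wave <- compute_area_waveform(csf, inlet_width = geometry$inlet_extension$width,
                                outlet_width = geometry$outlet_extension$width)
  bcs <- derive_bc_schedule(wave,
                            inlet_width = geometry$inlet_extension$width,
                            outlet_width = geometry$outlet_extension$width,
                            ramp_eps = config$ramp_eps)
  bci <- bc_interpolator(bcs)
  mesh <- generate_mesh(geometry, cell_size = config$cell_size,
                        first_layer = config$first_layer, contour = cs)
  say(sprintf("[%s] mesh: %d cells, %d boundary nodes", config$model_id,
              nrow(mesh$tris), mesh$n_boundary))

  # time step
  T <- cs$period
  u_in_pk <- max(bcs$u_in_m_s); u_out_pk <- max(bcs$u_out_m_s)
  jet_fac <- if (!is.null(geometry$lesion))
    geometry$outlet_extension$width /
      (geometry$outlet_extension$width - geometry$lesion$protrusion) else 1
  u_est <- 1.4 * max(u_in_pk, u_out_pk * jet_fac, 0.05)
  if (is.null(config$dt)) {
    # per-cell outflow CFL estimate: u * (half perimeter) / V
    fl <- sqrt((mesh$nodes[mesh$face_nodes[, 1], 1] -
                mesh$nodes[mesh$face_nodes[, 2], 1])^2 +
               (mesh$nodes[mesh$face_nodes[, 1], 2] -
                mesh$nodes[mesh$face_nodes[, 2], 2])^2)
    per <- numeric(nrow(mesh$tris))
    for (f in seq_along(fl)) {
      per[mesh$face_owner[f]] <- per[mesh$face_owner[f]] + fl[f]
      if (mesh$face_neigh[f] > 0)
        per[mesh$face_neigh[f]] <- per[mesh$face_neigh[f]] + fl[f]
    }
    dt <- config$cfl_target * min(mesh$cell_area / (0.5 * per)) / u_est
  } else dt <- config$dt
  steps <- as.integer(ceiling(T / dt))
  dt <- T / steps
  say(sprintf("  dt = %.3g s (%d steps/cycle), est. peak velocity %.2f m/s",
              dt, steps, u_est))

  tgrid <- (0:steps) * dt
  bpos <- .build_bpos(mesh, sp, tgrid)
  # washout-cycle soft start: blend wall motion in over `soft_start` seconds
  bpos_c1 <- bpos
  if (config$soft_start > 0) {
    env <- (1 - cos(pi * pmin(1, tgrid / config$soft_start))) / 2
    for (i in seq_along(tgrid)) {
      bpos_c1[, , i] <- bpos[, , 1] + env[i] * (bpos[, , i] - bpos[, , 1])
    }
  }
  bstep <- bci(tgrid[-1])
  q_ref <- max(u_in_pk * geometry$inlet_extension$width,
               u_out_pk * geometry$outlet_extension$width) / 1000  # m^2/s
  q_ref <- max(q_ref, 1e-9)
  dAdt_fun <- approxfun(wave$times, wave$dA_dt, rule = 2)
  dAdt_step <- dAdt_fun(tgrid[-1] %% T) / 1e6   # m^2/s

  fsi_mode <- if (identical(config$fsi, "auto")) {
    if (!is.null(geometry$lesion)) "oneway" else "off"
  } else config$fsi
  fsi <- .fsi_plan(mesh, geometry, dt, config$fsi_opts, fsi_mode)
  solid <- if (!is.null(fsi)) fsi$solid else NULL
  if (!is.null(fsi)) fsi$solid <- NULL

  wssf <- which(!is.na(mesh$s_face))
  inlet_dir <- c(0, -1); outlet_dir <- geometry$lvot_axis

  state <- flow_state(mesh, config$closure)
  snap_stride_final <- max(1L, steps %/% config$snapshots_per_cycle)
  segments <- list()
  wss_chunks <- list()
  cyc_diag <- list()
  fsi_trace <- list(times = numeric(0), tip = numeric(0), iters = numeric(0))
  remesh_count <- 0L
  ke_cycles <- list()

  for (cyc in seq_len(config$n_cycles)) {
    final <- cyc == config$n_cycles
    step0 <- 0L
    ke_this <- numeric(0)
    while (step0 < steps) {
      nrun <- steps - step0
      bp_use <- if (cyc == 1L && config$soft_start > 0) bpos_c1 else bpos
      plan <- .base_plan(mesh, bp_use[, , (step0 + 1L):(step0 + nrun + 1L), drop = FALSE],
                         nrun, dt, config$props, config$closure,
                         u_in = bstep$u_in[(step0 + 1L):(step0 + nrun)],
                         u_out = bstep$u_out[(step0 + 1L):(step0 + nrun)],
                         phase = ifelse(bstep$phase[(step0 + 1L):(step0 + nrun)] ==
                                          "diastole", 1L, 2L),
                         inlet_dir = inlet_dir, outlet_dir = outlet_dir,
                         conv_blend = config$conv_blend,
                         cont_tol = config$cont_tol, q_ref = q_ref,
                         snap_stride = if (final) snap_stride_final else 0L,
                         wss_faces = wssf,
                         t0 = (cyc - 1L) * T + step0 * dt,
                         fsi = fsi)
      res <- run_ale_cpp(plan, state)
      if (res$status == "diverged")
        stop("solver diverged at cycle ", cyc, " step ",
             step0 + res$step_stop, "; reduce dt or cfl_target")
      nsteps_done <- if (res$status == "remesh") res$step_stop else nrun
      if (nsteps_done > 0) {
        rng <- seq_len(nsteps_done)
        wss_chunks[[length(wss_chunks) + 1L]] <- list(
          cycle = cyc,
          times = (cyc - 1L) * T + (step0 + rng) * dt,
          tau = res$wss[rng, , drop = FALSE],
          s_face = mesh$s_face[wssf],
          face_len = sqrt(rowSums((mesh$nodes[mesh$face_nodes[wssf, 1], , drop = FALSE] -
                                   mesh$nodes[mesh$face_nodes[wssf, 2], , drop = FALSE])^2)))
        cyc_diag[[length(cyc_diag) + 1L]] <- c(
          list(cycle = cyc, step0 = step0, n = nsteps_done,
               dAdt = dAdt_step[step0 + rng]),
          lapply(res$diag, function(v) v[rng]))
        ke_this <- c(ke_this, res$diag$ke[rng])
        if (!is.null(fsi)) {
          fsi_trace$times <- c(fsi_trace$times, (cyc - 1L) * T + (step0 + rng) * dt)
          fsi_trace$tip <- c(fsi_trace$tip, res$diag$tip_def[rng])
          fsi_trace$iters <- c(fsi_trace$iters, res$diag$fsi_iters[rng])
        }
        if (final && length(res$snapshots) > 0) {
          for (sn in res$snapshots) {
            sn$mesh <- mesh
            segments[[length(segments) + 1L]] <- sn
          }
        }
      }
      state <- res$state
      if (!is.null(fsi) && length(res$fsi) > 0) {
        fsi$d0 <- res$fsi$d; fsi$v0 <- res$fsi$v; fsi$a0 <- res$fsi$a
      }
      if (res$status == "remesh") {
        remesh_count <- remesh_count + 1L
        say(sprintf("  remesh #%d at cycle %d step %d", remesh_count, cyc,
                    step0 + nsteps_done))
        if (remesh_count > 40L) stop("excessive remeshing; aborting run")
        rem <- .remesh_lv(mesh, state, geometry, config, fsi, solid,
                          t_in_cycle = (step0 + nsteps_done) * dt, sp)
        mesh <- rem$mesh; state <- rem$state
        bpos <- .build_bpos(mesh, sp, tgrid)
        if (cyc == 1L && config$soft_start > 0) {
          # continue the soft envelope on the new mesh
          env <- (1 - cos(pi * pmin(1, tgrid / config$soft_start))) / 2
          bpos_c1 <- bpos
          ref1 <- bpos[, , step0 + nsteps_done + 1L] # current positions
          for (i in seq_along(tgrid)) {
            if (env[i] < 1)
              bpos_c1[, , i] <- ref1 + env[i] * (bpos[, , i] - ref1)
          }
        }
        if (!is.null(fsi)) {
          dfull <- numeric(2L * nrow(solid$nodes))
          if (!is.null(fsi$d0) && fsi_mode != "oneway")
            dfull[solid$free] <- as.numeric(fsi$Phi %*% fsi$d0)
          f2 <- .fsi_plan(mesh, geometry, dt, config$fsi_opts, fsi_mode,
                          solid_disp = if (fsi_mode == "oneway") NULL else dfull)
          f2$solid <- NULL
          f2$d0 <- fsi$d0; f2$v0 <- fsi$v0; f2$a0 <- fsi$a0
          # record the interface displacement already baked into the new
          # mesh so the solver applies only increments on top of it
          li <- f2$les_nodes
          if (length(li) > 0) {
            dref <- numeric(2L * length(li))
            for (i in seq_along(li)) {
              sn <- f2$les_map[i, ]; w <- f2$les_wgt[i, ]
              disp <- w[1] * c(dfull[2 * sn[1] - 1L], dfull[2 * sn[1]]) +
                      w[2] * c(dfull[2 * sn[2] - 1L], dfull[2 * sn[2]])
              dref[2 * i - 1L] <- disp[1]; dref[2 * i] <- disp[2]
            }
            f2$dles_ref <- dref
          }
          fsi <- f2
        }
        wssf <- which(!is.na(mesh$s_face))
        step0 <- step0 + nsteps_done
        next
      }
      step0 <- step0 + nrun
    }
    ke_cycles[[cyc]] <- ke_this
    say(sprintf("  cycle %d done; max resid %.2e, max CFL %.2f", cyc,
                max(cyc_diag[[length(cyc_diag)]]$resid),
                max(cyc_diag[[length(cyc_diag)]]$cfl)))
  }

  # periodicity: relative L2 difference of the kinetic-energy waveform
  periodicity <- rep(NA_real_, config$n_cycles)
  for (cyc in 2:max(2, config$n_cycles)) {
    if (cyc > config$n_cycles) break
    a <- ke_cycles[[cyc - 1L]]; b <- ke_cycles[[cyc]]
    n <- min(length(a), length(b))
    if (n > 0)
      periodicity[cyc] <- sqrt(sum((b[1:n] - a[1:n])^2)) /
        max(sqrt(sum(a[1:n]^2)), 1e-300)
  }

  structure(list(config = config, geometry = geometry, contour = cs,
                 waveform = wave, bc = bcs, mesh = mesh,
                 dt = dt, steps_per_cycle = steps,
                 snapshots = segments, wss = wss_chunks, diag = cyc_diag,
                 periodicity = periodicity, fsi_trace = fsi_trace,
                 remesh_count = remesh_count, state = state,
                 q_ref = q_ref, solid = solid),
            class = "lvot_run")
}

# remesh from the current deformed boundary, transferring fields.
# The boundary loop is rebuilt chain-by-chain: the moving chamber portion is
# resampled directly on the current contour polyline (and rebound to it),
# lesion chains are resampled on the deflected outline and rebound to the
# solid, rigid chains keep their original nodes.
.remesh_lv <- function(mesh, state, geometry, config, fsi, solid,
                       t_in_cycle, sp) {
  nb <- mesh$n_boundary
  pos_now <- state$nodes[seq_len(nb), , drop = FALSE] * 1000   # mm
  tags <- mesh$boundary_tag
  bt <- mesh$btype
  h_mm <- config$cell_size * 1000
  Cnow <- sp$at(t_in_cycle)                # 80 x 2, mm
  arcC <- c(0, cumsum(sqrt(rowSums(diff(Cnow)^2))))

  # walk the boundary loop in runs of constant btype
  runs <- split(seq_len(nb), cumsum(c(1, diff(bt) != 0)))
  poly <- NULL; ptag <- character(0)
  pbtype <- integer(0); pseg <- integer(0); plam <- numeric(0)
  les_new <- NULL                          # rows of lesion node positions
  for (r in runs) {
    kind <- bt[r[1]]
    if (kind == 2L) {
      # moving chamber: resample the current contour polyline between the
      # arc positions of the run endpoints
      s0 <- (1 - mesh$mov_lambda[r[1]]) * arcC[mesh$mov_seg[r[1]]] +
        mesh$mov_lambda[r[1]] * arcC[mesh$mov_seg[r[1]] + 1L]
      s1 <- (1 - mesh$mov_lambda[r[length(r)]]) * arcC[mesh$mov_seg[r[length(r)]]] +
        mesh$mov_lambda[r[length(r)]] * arcC[mesh$mov_seg[r[length(r)]] + 1L]
      npt <- max(2L, ceiling(abs(s1 - s0) / h_mm))
      svals <- seq(s0, s1, length.out = npt + 1L)   # keep both run endpoints
      for (s in svals) {
        j <- max(1L, min(length(arcC) - 1L, findInterval(s, arcC)))
        lam <- (s - arcC[j]) / max(arcC[j + 1L] - arcC[j], 1e-12)
        pt <- (1 - lam) * Cnow[j, ] + lam * Cnow[j + 1L, ]
        poly <- rbind(poly, pt)
        pbtype <- c(pbtype, 2L); pseg <- c(pseg, j); plam <- c(plam, lam)
        ptag <- c(ptag, tags[r[1]])
      }
      # preserve the tag split within the moving run (septal near crest)
      nadd <- length(svals)
      sep_tags <- tags[r][round(seq(1, length(r), length.out = nadd))]
      ptag[(length(ptag) - nadd + 1L):length(ptag)] <- sep_tags
    } else if (kind == 3L) {
      # lesion: resample the deflected outline
      chain <- pos_now[r, , drop = FALSE]
      rp <- .resample_chain(chain, min(h_mm, 0.45))  # keep both endpoints
      poly <- rbind(poly, rp)
      n2 <- nrow(rp)
      pbtype <- c(pbtype, rep(3L, n2)); pseg <- c(pseg, rep(NA_integer_, n2))
      plam <- c(plam, rep(NA_real_, n2))
      ptag <- c(ptag, rep("lesion", n2))
      les_new <- rbind(les_new, rp)
    } else {
      poly <- rbind(poly, pos_now[r, , drop = FALSE])
      n2 <- length(r)
      pbtype <- c(pbtype, rep(0L, n2)); pseg <- c(pseg, rep(NA_integer_, n2))
      plam <- c(plam, rep(NA_real_, n2))
      ptag <- c(ptag, tags[r])
    }
  }
  fl_mm <- if (is.null(config$first_layer)) NULL else config$first_layer * 1000
  newm <- NULL
  for (fac in c(1, 0.88, 1.12, 0.8)) {
    newm <- tryCatch(mesh_polygon(poly, ptag, h_mm * fac, fl_mm,
                                  resample = FALSE),
                     error = function(e) NULL)
    if (!is.null(newm)) break
  }
  if (is.null(newm)) {
    saveRDS(list(poly = poly, ptag = ptag, t = t_in_cycle),
            file.path(tempdir(), "remesh_fail.rds"))
    stop("remesh failed: boundary not recoverable at any cell size (dump: ",
         file.path(tempdir(), "remesh_fail.rds"), ")")
  }
  newm$btype <- pbtype
  newm$mov_seg <- pseg
  newm$mov_lambda <- plam
  newm$sigma <- ifelse(pbtype == 2L, plam, NA_real_)
  newm$geometry <- geometry
  newm$contour_nodes <- mesh$contour_nodes
  # septal face arc coordinates
  nf <- length(newm$face_tag)
  s_face <- rep(NA_real_, nf)
  sep <- geometry$septal
  C <- geometry$crest_point; a_ax <- geometry$lvot_axis
  for (i in which(newm$face_tag == "septal_wall")) {
    midp <- (newm$nodes[newm$face_nodes[i, 1], ] +
             newm$nodes[newm$face_nodes[i, 2], ]) / 2 * 1000
    pr <- sum((midp - C) * a_ax)
    s_face[i] <- if (pr > 0) sep$crest_s + pr
                 else sep$crest_s - sqrt(sum((midp - C)^2))
  }
  newm$s_face <- s_face
  # field transfer: containing/nearest old cell at the current configuration
  cen_new <- t(vapply(seq_len(nrow(newm$tris)), function(c2) {
    colMeans(newm$nodes[newm$tris[c2, ], , drop = FALSE])
  }, numeric(2)))
  loc <- locate_cells_cpp(cen_new, state$nodes, mesh$tris, nearest = TRUE) + 1L
  st <- flow_state(newm, config$closure)
  st$u <- state$u[loc, , drop = FALSE]
  st$p <- state$p[loc]
  st$k <- state$k[loc]
  st$omega <- state$omega[loc]
  st$time <- state$time
  list(mesh = newm, state = st)
}

#' @export
print.lvot_run <- function(x, ...) {
  cat("lvot_run:", x$config$model_id, "-", x$config$n_cycles, "cycles,",
      x$steps_per_cycle, "steps/cycle, dt =", signif(x$dt, 3), "s\n")
  cat("  cells:", nrow(x$mesh$tris), " remeshes:", x$remesh_count, "\n")
  if (any(!is.na(x$periodicity)))
    cat("  periodicity (KE rel L2):",
        paste(signif(stats::na.omit(x$periodicity), 3), collapse = ", "), "\n")
  invisible(x)
}
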
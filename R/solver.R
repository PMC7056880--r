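# ---------------------------------------------------------------------------
# R interface to the ALE finite-volume solver core.
# ---------------------------------------------------------------------------

#' Fluid properties
#' @param rho density (kg/m^3), blood default 1050.
#' @param mu dynamic viscosity (kg/(m s)), blood default 0.0035.
#' @export
fluid_properties <- function(rho = 1050, mu = 0.0035) {
  stopifnot(rho > 0, mu > 0)
  list(rho = rho, mu = mu)
}

#' Turbulence closure selection
#'
#' @param model `"laminar"` or `"sst_k_omega"` (Menter's standard constants,
#'   low-Reynolds wall treatment: the wall-adjacent specific dissipation rate
#'   is pinned to its viscous-sublayer value).
#' @param k_init,omega_init free-stream initial values.
#' @param omega_min floor on omega (1/s).
#' @param apply_wall_omega apply the viscous-sublayer wall override (disable
#'   only for homogeneous-decay verification).
#' @export
turbulence_closure <- function(model = c("laminar", "sst_k_omega"),
                               k_init = 1e-6, omega_init = 10,
                               omega_min = 1e-3, apply_wall_omega = TRUE) {
  model <- match.arg(model)
  list(model = model, k_init = k_init, omega_init = omega_init,
       omega_min = omega_min, apply_wall_omega = apply_wall_omega)
}

.face_kind <- function(face_tag) {
  kind <- integer(length(face_tag))
  kind[face_tag %in% .wall_tags] <- 1L
  kind[face_tag == "inlet"] <- 2L
  kind[face_tag == "outlet"] <- 3L
  kind
}

.mesh_topo <- function(mesh) {
  list(tris = mesh$tris,
       face_nodes = mesh$face_nodes,
       face_owner = as.integer(mesh$face_owner),
       face_neigh = as.integer(mesh$face_neigh),
       face_kind = .face_kind(mesh$face_tag))
}

# inverse-distance (power 4) interior-motion weights; rows sum to the
# fraction of total boundary weight carried by the listed columns
.idw_weights <- function(mesh, cols_idx) {
  nb <- mesh$n_boundary
  nall <- nrow(mesh$nodes)
  int_idx <- if (nall > nb) (nb + 1L):nall else integer(0)
  if (length(int_idx) == 0 || length(cols_idx) == 0)
    return(list(W = matrix(0, length(int_idx), length(cols_idx)),
                int_idx = int_idx))
  B <- mesh$nodes[seq_len(nb), , drop = FALSE]
  P <- mesh$nodes[int_idx, , drop = FALSE]
  eps4 <- (0.05 * mesh$cell_size)^4
  d2 <- outer(P[, 1], B[, 1], "-")^2 + outer(P[, 2], B[, 2], "-")^2
  w <- 1 / (d2^2 + eps4)
  denom <- rowSums(w)
  W <- w[, cols_idx, drop = FALSE] / denom
  list(W = W, int_idx = int_idx)
}

# probe cells for wall-shear sampling: points at d and 2d inside the wall,
# located in the reference configuration
.wss_probes <- function(mesh, wss_faces) {
  nws <- length(wss_faces)
  cells <- matrix(1L, nws, 2)
  dvec <- numeric(nws)
  pts <- matrix(0, 2L * nws, 2)
  for (i in seq_len(nws)) {
    f <- wss_faces[i]
    p <- mesh$nodes[mesh$face_nodes[f, 1], ]
    q <- mesh$nodes[mesh$face_nodes[f, 2], ]
    fm <- (p + q) / 2
    nh <- c(q[2] - p[2], -(q[1] - p[1]))
    nh <- nh / max(sqrt(sum(nh^2)), 1e-300)
    # uniform probe distance: face-to-face consistency matters more than
    # per-face optimality when the boundary layer is under-resolved
    d1 <- max(1.3 * mesh$cell_size, 1.5 * mesh$first_layer)
    dvec[i] <- d1
    pts[2 * i - 1L, ] <- fm - d1 * nh
    pts[2 * i, ] <- fm - 2 * d1 * nh
  }
  loc <- locate_cells_cpp(pts, mesh$nodes, mesh$tris, nearest = TRUE) + 1L
  cells[, 1] <- loc[seq(1, 2 * nws, by = 2)]
  cells[, 2] <- loc[seq(2, 2 * nws, by = 2)]
  list(cells = cells, d = dvec)
}

#' Create a resting flow state on a mesh
#' @param mesh an `lvot_mesh`.
#' @param closure turbulence closure (for k/omega initial values).
#' @export
flow_state <- function(mesh, closure = turbulence_closure()) {
  nc <- nrow(mesh$tris)
  st <- list(u = matrix(0, nc, 2), p = numeric(nc),
             k = rep(if (closure$model == "sst_k_omega") closure$k_init else 0, nc),
             omega = rep(closure$omega_init, nc),
             nut = numeric(nc), time = 0,
             nodes = mesh$nodes)
  class(st) <- "flow_state"
  st
}

# internal: assemble the C++ plan shared by advance_timestep and run_cycle
.base_plan <- function(mesh, bpos, n_steps, dt, props, closure,
                       u_in, u_out, inlet_dir, outlet_dir,
                       profile = NULL, conv_blend = 1, cont_tol = 1e-4,
                       q_ref = NULL, cg_maxit = 3000, snap_stride = 0L,
                       wss_faces = integer(0), wall_extra_vel = NULL,
                       mov_idx = NULL, t0 = 0, fsi = NULL,
                       nonorth_corr = 1, p_incremental = FALSE,
                       remesh_vratio = 2.2, phase = NULL) {
  nb <- mesh$n_boundary
  nf <- length(mesh$face_tag)
  if (is.null(profile)) profile <- rep(1, nf)
  if (is.null(wall_extra_vel)) wall_extra_vel <- matrix(0, nf, 2)
  if (is.null(mov_idx)) {
    mov_idx <- if (!is.null(mesh$btype)) which(mesh$btype == 2L)
               else seq_len(nb)
    if (length(mov_idx) == 0) mov_idx <- seq_len(nb)
  }
  idw <- .idw_weights(mesh, mov_idx)
  phase <- if (is.null(phase)) integer(n_steps)
           else rep_len(as.integer(phase), n_steps)
  if (is.null(q_ref)) {
    q_ref <- max(abs(u_in), abs(u_out)) * 0.02   # ~ velocity * opening scale
    q_ref <- max(q_ref, 1e-9)
  }
  list(mesh_topo = .mesh_topo(mesh),
       nodes0 = mesh$nodes,
       bpos = bpos,
       idw_W = idw$W,
       idw_int_idx = as.integer(idw$int_idx),
       idw_mov_idx = as.integer(mov_idx),
       n_steps = as.integer(n_steps), dt = dt,
       rho = props$rho, mu = props$mu,
       conv_blend = conv_blend,
       closure = if (closure$model == "sst_k_omega") 1L else 0L,
       sst = list(omega_min = closure$omega_min,
                  apply_wall_omega = closure$apply_wall_omega),
       q_ref = q_ref, cont_tol = cont_tol, cg_maxit = as.integer(cg_maxit),
       snap_stride = as.integer(snap_stride), t0 = t0,
       u_in = rep_len(u_in, n_steps), u_out = rep_len(u_out, n_steps),
       phase = phase,
       inlet_dir = inlet_dir, outlet_dir = outlet_dir,
       profile = profile,
       wall_extra_vel = wall_extra_vel,
       wss_faces = as.integer(wss_faces),
       wall_dist = mesh$wall_dist,
       nonorth_corr = nonorth_corr, p_incremental = p_incremental,
       remesh_vratio = remesh_vratio) -> plan
  if (length(wss_faces) > 0) {
    pr <- .wss_probes(mesh, wss_faces)
    plan$wss_probe_cells <- pr$cells
    plan$wss_probe_d <- pr$d
  }
  if (!is.null(fsi)) plan$fsi <- fsi
  plan
}

#' Advance the flow one time step on a moving mesh
#'
#' Single-step entry to the ALE solver: moves the mesh boundary to
#' `next_boundary`, deforms the interior by inverse-distance weighting,
#' advances momentum with ALE convective fluxes (exact face swept volumes)
#' and projects onto the divergence constraint until the normalized
#' continuity residual is below `cont_tol`.
#'
#' @param state a `flow_state` (from [flow_state()] or a previous call).
#' @param mesh an `lvot_mesh`.
#' @param next_boundary nb x 2 matrix of boundary node positions at t + dt
#'   (metres); `NULL` keeps the boundary fixed.
#' @param bc list with `u_in`, `u_out` (plug magnitudes, m/s), `inlet_dir`,
#'   `outlet_dir` (unit vectors), optional `profile` (per-face factors) and
#'   optional `wall_extra_vel` (nf x 2 tangential lid velocity).
#' @param props from [fluid_properties()].
#' @param closure from [turbulence_closure()].
#' @param dt time step (s).
#' @param ... advanced solver options (`conv_blend`, `cont_tol`, `q_ref`).
#' @return updated `flow_state`; diagnostics in `attr(, "diag")`.
#' @export
advance_timestep <- function(state, mesh, next_boundary = NULL,
                             bc = list(u_in = 0, u_out = 0,
                                       inlet_dir = c(0, -1),
                                       outlet_dir = c(0, 1)),
                             props = fluid_properties(),
                             closure = turbulence_closure(),
                             dt = 1e-4, ...) {
  stopifnot(dt > 0)
  nb <- mesh$n_boundary
  cur <- state$nodes[seq_len(nb), , drop = FALSE]
  nxt <- if (is.null(next_boundary)) cur else next_boundary
  stopifnot(nrow(nxt) == nb)
  bpos <- array(0, dim = c(nb, 2, 2))
  bpos[, , 1] <- cur; bpos[, , 2] <- nxt
  plan <- .base_plan(mesh, bpos, 1L, dt, props, closure,
                     u_in = bc$u_in, u_out = bc$u_out,
                     inlet_dir = bc$inlet_dir, outlet_dir = bc$outlet_dir,
                     profile = bc$profile,
                     wall_extra_vel = bc$wall_extra_vel,
                     mov_idx = seq_len(nb), t0 = state$time, ...)
  # single-step entry moves every boundary node explicitly
  plan$nodes0 <- state$nodes
  res <- run_ale_cpp(plan, state)
  if (res$status == "remesh")
    stop("remesh-needed error: mesh inverted during motion")
  new_state <- res$state
  new_state$time <- state$time + dt
  class(new_state) <- "flow_state"
  attr(new_state, "diag") <- res$diag
  new_state
}

#' Advance several uniform time steps (static or moving boundary)
#'
#' Convenience multi-step driver used by the verification cases: boundary
#' positions given per step (or fixed), constant BC magnitudes.
#'
#' @inheritParams advance_timestep
#' @param n_steps number of steps.
#' @param bpos optional nb x 2 x (n_steps + 1) array of boundary positions.
#' @param snap_stride snapshot interval in steps (0: none).
#' @export
advance_steps <- function(state, mesh, n_steps, dt, bc, bpos = NULL,
                          props = fluid_properties(),
                          closure = turbulence_closure(), snap_stride = 0L,
                          ...) {
  nb <- mesh$n_boundary
  if (is.null(bpos)) {
    cur <- state$nodes[seq_len(nb), , drop = FALSE]
    bpos <- array(rep(cur, n_steps + 1L), dim = c(nb, 2, n_steps + 1L))
  }
  plan <- .base_plan(mesh, bpos, n_steps, dt, props, closure,
                     u_in = bc$u_in, u_out = bc$u_out,
                     inlet_dir = bc$inlet_dir, outlet_dir = bc$outlet_dir,
                     profile = bc$profile,
                     wall_extra_vel = bc$wall_extra_vel,
                     mov_idx = seq_len(nb), t0 = state$time,
                     snap_stride = snap_stride, ...)
  plan$nodes0 <- state$nodes
  res <- run_ale_cpp(plan, state)
  if (res$status == "remesh")
    stop("remesh-needed error: mesh inverted during motion")
  new_state <- res$state
  new_state$time <- state$time + n_steps * dt
  class(new_state) <- "flow_state"
  attr(new_state, "diag") <- res$diag
  attr(new_state, "snapshots") <- res$snapshots
  attr(new_state, "wss") <- res$wss
  new_state
}

#' Single SST k-omega transport step
#'
#' Advances the turbulence fields one step on a frozen velocity field:
#' upwind advection by the face fluxes, blended diffusion, strain-based
#' production, implicit destruction, cross-diffusion and the SST
#' eddy-viscosity limiter.
#'
#' @param state `flow_state` (uses `u`, `k`, `omega`).
#' @param closure from [turbulence_closure()] (`model` must be
#'   `"sst_k_omega"`).
#' @param dt time step (s).
#' @param mesh the `lvot_mesh`.
#' @param phi optional face volume fluxes (m^2/s); default zero (no
#'   advection).
#' @param props fluid properties.
#' @return state with updated `k`, `omega`, `nut`.
#' @export
step_turbulence <- function(state, closure, dt, mesh, phi = NULL,
                            props = fluid_properties()) {
  if (closure$model != "sst_k_omega")
    stop("step_turbulence requires the sst_k_omega closure")
  if (any(state$omega <= 0)) stop("omega must be initialized positive")
  nf <- length(mesh$face_tag)
  if (is.null(phi)) phi <- numeric(nf)
  res <- sst_step_cpp(.mesh_topo(mesh), state$nodes, state$u,
                      state$k, state$omega, phi, mesh$wall_dist,
                      props$mu / props$rho, dt,
                      closure$apply_wall_omega, closure$omega_min)
  if (any(!is.finite(res$k)) || any(!is.finite(res$omega)))
    stop("turbulence breakdown: non-finite k or omega")
  state$k <- res$k; state$omega <- res$omega; state$nut <- res$nut
  state
}
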
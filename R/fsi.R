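# ---------------------------------------------------------------------------
# Compliant DSS lesion: plane-strain linear elastic solid.
#
# The lesion tab is discretized with bilinear quadrilaterals; the volumetric
# strain part is evaluated at the element centre (B-bar selective
# integration), which removes the locking that plain Q4 elements exhibit at
# Poisson ratio 0.49.  Dynamics use Newmark average acceleration; the fluid
# coupling (partitioned, Aitken-relaxed) runs inside the solver core.
# ---------------------------------------------------------------------------

#' Lesion material properties
#' @param density kg/m^3 (default 1100).
#' @param E Young's modulus, Pa (default 0.37e6).
#' @param nu Poisson ratio (default 0.49; must be < 0.5).
#' @export
lesion_material <- function(density = 1100, E = 0.37e6, nu = 0.49) {
  stopifnot(E > 0, nu > 0, nu < 0.5, density > 0)
  list(density = density, E = E, nu = nu)
}

#' Build the lesion solid model
#'
#' Assembles mass and stiffness matrices for the rectangular lesion tab in
#' its local frame (xi along the tab axis from the clamped root, eta across
#' the thickness), mapped to global coordinates via the lesion axis stored in
#' the geometry.
#'
#' @param length,thickness tab dimensions (m).
#' @param material from [lesion_material()].
#' @param n_length,n_thick element counts along/across.
#' @param origin,axis,cross global-frame root centre (m) and unit vectors;
#'   defaults build in the local frame.
#' @return object of class `lesion_solid`: nodes (m), element table, dense
#'   `K`, `M` (free dofs), dof maps, interface (boundary) node info.
#' @export
build_lesion_solid <- function(length = 10e-3, thickness = 1e-3,
                               material = lesion_material(),
                               n_length = 24L, n_thick = 4L,
                               origin = c(0, 0), axis = c(1, 0),
                               cross = c(0, 1)) {
  nl <- n_length; nt <- n_thick
  xi <- seq(0, length, length.out = nl + 1L)
  eta <- seq(-thickness / 2, thickness / 2, length.out = nt + 1L)
  nodes_loc <- as.matrix(expand.grid(xi = xi, eta = eta))
  nid <- function(i, j) (j - 1L) * (nl + 1L) + i       # i along xi, j along eta
  elems <- matrix(0L, nl * nt, 4L)
  e <- 0L
  for (j in seq_len(nt)) for (i in seq_len(nl)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  }
  nn <- nrow(nodes_loc)
  # plane-strain constitutive split into deviatoric + volumetric parts
  E <- material$E; nu <- material$nu
  G <- E / (2 * (1 + nu))
  Kb <- E / (3 * (1 - 2 * nu))                        # bulk modulus
  Ddev <- G * rbind(c(4 / 3, -2 / 3, 0), c(-2 / 3, 4 / 3, 0), c(0, 0, 1))
  mvol <- c(1, 1, 0)
  Dvol <- Kb * (mvol %o% mvol)
  gp <- 1 / sqrt(3)
  gauss <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  shapeB <- function(xi_, eta_, xe, ye) {
    dN <- rbind(c(-(1 - eta_), (1 - eta_), (1 + eta_), -(1 + eta_)) / 4,
                c(-(1 - xi_), -(1 + xi_), (1 + xi_), (1 - xi_)) / 4)
    J <- dN %*% cbind(xe, ye)
    detJ <- det(J)
    dNxy <- solve(J, dN)
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNxy[1, ]
    B[2, seq(2, 8, 2)] <- dNxy[2, ]
    B[3, seq(1, 8, 2)] <- dNxy[2, ]
    B[3, seq(2, 8, 2)] <- dNxy[1, ]
    list(B = B, detJ = detJ)
  }
  ndof <- 2L * nn
  K <- matrix(0, ndof, ndof)
  Mlump <- numeric(ndof)
  Bvol_store <- vector("list", nrow(elems))
  for (e in seq_len(nrow(elems))) {
    en <- elems[e, ]
    xe <- nodes_loc[en, 1]; ye <- nodes_loc[en, 2]
    # volumetric B at element centre (B-bar)
    c0 <- shapeB(0, 0, xe, ye)
    Bv <- matrix(rep(mvol %*% c0$B, each = 1), nrow = 1)   # 1 x 8 (div u)
    ke <- matrix(0, 8, 8)
    area <- 0
    for (g in seq_len(4)) {
      s <- shapeB(gauss[g, 1], gauss[g, 2], xe, ye)
      Bdev_part <- s$B
      ke <- ke + t(Bdev_part) %*% Ddev %*% Bdev_part * s$detJ
      area <- area + s$detJ
    }
    ke <- ke + t(Bv) %*% (Kb * Bv) * area                  # B-bar volumetric
    idx <- as.vector(rbind(2 * en - 1L, 2 * en))
    K[idx, idx] <- K[idx, idx] + ke
    Mlump[idx] <- Mlump[idx] + material$density * area / 4
    Bvol_store[[e]] <- c0
  }
  clamped <- which(nodes_loc[, 1] < 1e-12)                 # root nodes
  fixed_dofs <- as.vector(rbind(2 * clamped - 1L, 2 * clamped))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  # boundary (interface) nodes: everything except strictly interior
  i_idx <- ((seq_len(nn) - 1L) %% (nl + 1L)) + 1L
  j_idx <- ((seq_len(nn) - 1L) %/% (nl + 1L)) + 1L
  on_boundary <- i_idx == nl + 1L | j_idx == 1L | j_idx == nt + 1L
  tip_node <- nid(nl + 1L, (nt %/% 2L) + 1L)
  # global node positions
  nodes_glob <- cbind(origin[1] + nodes_loc[, 1] * axis[1] + nodes_loc[, 2] * cross[1],
                      origin[2] + nodes_loc[, 1] * axis[2] + nodes_loc[, 2] * cross[2])
  # dof map: for each node, global free-dof index of (x, y) or -1
  dofmap <- rep(-1L, ndof)
  dofmap[free] <- seq_along(free) - 1L                     # 0-based for C++
  structure(list(
    nodes_loc = nodes_loc, nodes = nodes_glob, elems = elems,
    K = K[free, free, drop = FALSE],
    M = diag(Mlump[free]),
    M_diag = Mlump[free],
    free = free, dofmap = dofmap, clamped = clamped,
    on_boundary = on_boundary, tip_node = tip_node,
    axis = axis, cross = cross, origin = origin,
    length = length, thickness = thickness,
    material = material, n_length = nl, n_thick = nt,
    Ddev = Ddev, Kb = Kb
  ), class = "lesion_solid")
}

#' Create a resting lesion state
#' @param solid a `lesion_solid`.
#' @export
lesion_state <- function(solid) {
  nfree <- nrow(solid$K)
  structure(list(d = numeric(nfree), v = numeric(nfree), a = numeric(nfree),
                 time = 0),
            class = "lesion_state")
}

# full displacement vector (all dofs) from free-dof vector
.full_disp <- function(solid, d) {
  out <- numeric(2L * nrow(solid$nodes_loc))
  out[solid$free] <- d
  out
}

#' Advance the lesion solid one implicit time step
#'
#' Newmark average-acceleration update of the clamped plane-strain tab under
#' a given interface load.
#'
#' @param state a `lesion_state`.
#' @param traction external force vector on free dofs (N per unit depth), or
#'   a function(nodes) returning nodal forces; zero default.
#' @param material unused placeholder for signature compatibility (material
#'   enters through the prebuilt matrices).
#' @param dt time step (s).
#' @param solid the `lesion_solid` model.
#' @param rayleigh_a,rayleigh_b Rayleigh damping coefficients (C = aM + bK).
#' @return updated `lesion_state` with `tip_deflection` (m) and
#'   `max_von_mises` (Pa).
#' @export
solve_solid_step <- function(state, traction = NULL, material = NULL,
                             dt = 1e-4, solid,
                             rayleigh_a = 0, rayleigh_b = 1e-5) {
  nfree <- nrow(solid$K)
  F <- if (is.null(traction)) numeric(nfree) else traction
  if (length(F) != nfree) stop("traction vector has wrong length")
  C <- rayleigh_a * solid$M + rayleigh_b * solid$K
  Keff <- solid$K + (4 / dt^2) * solid$M + (2 / dt) * C
  rhs <- F + solid$M %*% ((4 / dt^2) * state$d + (4 / dt) * state$v + state$a) +
    C %*% ((2 / dt) * state$d + state$v)
  dn <- tryCatch(solve(Keff, rhs), error = function(e)
    stop("singular system: insufficient constraints (", conditionMessage(e), ")"))
  dn <- as.numeric(dn)
  an <- (4 / dt^2) * (dn - state$d) - (4 / dt) * state$v - state$a
  vn <- state$v + dt / 2 * (state$a + an)
  st <- structure(list(d = dn, v = vn, a = an, time = state$time + dt),
                  class = "lesion_state")
  st$tip_deflection <- lesion_tip_deflection(solid, dn)
  st$max_von_mises <- max(lesion_von_mises(solid, dn))
  st
}

#' Static solve under a load vector
#' @param solid a `lesion_solid`.
#' @param F force vector on free dofs.
#' @return free-dof displacement vector.
#' @export
solve_solid_static <- function(solid, F) {
  as.numeric(solve(solid$K, F))
}

#' Nodal force vector for a uniform pressure on one lateral face
#' @param solid a `lesion_solid`.
#' @param q pressure (Pa), acting in +cross direction on the eta = -t/2 face.
#' @return force vector on free dofs.
#' @export
lesion_face_load <- function(solid, q) {
  nl <- solid$n_length
  # nodes on the eta = -t/2 face: j = 1 -> node ids 1..nl+1
  ids <- seq_len(nl + 1L)
  w <- rep(solid$length / nl, nl + 1L)
  w[c(1, nl + 1L)] <- w[c(1, nl + 1L)] / 2
  Ffull <- numeric(2L * nrow(solid$nodes_loc))
  Ffull[2 * ids - 1L] <- q * w * solid$cross[1]
  Ffull[2 * ids] <- q * w * solid$cross[2]
  Ffull[solid$free]
}

#' Tip deflection magnitude from a free-dof displacement vector
#' @param solid a `lesion_solid`.
#' @param d free-dof displacements.
#' @export
lesion_tip_deflection <- function(solid, d) {
  full <- .full_disp(solid, d)
  tn <- solid$tip_node
  sqrt(full[2 * tn - 1L]^2 + full[2 * tn]^2)
}

#' Element von Mises stress (plane strain)
#' @param solid a `lesion_solid`.
#' @param d free-dof displacements.
#' @return vector of element-centre von Mises stresses (Pa).
#' @export
lesion_von_mises <- function(solid, d) {
  full <- .full_disp(solid, d)
  nu <- solid$material$nu
  out <- numeric(nrow(solid$elems))
  # sample at the top/bottom fibre midpoints (parent (0, +-1)) so the
  # reported bending stress tracks the surface fibre at any refinement
  samp <- rbind(c(0, -1), c(0, 1))
  for (e in seq_len(nrow(solid$elems))) {
    en <- solid$elems[e, ]
    xe <- solid$nodes_loc[en, 1]; ye <- solid$nodes_loc[en, 2]
    idx <- as.vector(rbind(2 * en - 1L, 2 * en))
    vmax <- 0
    for (sidx in 1:2) {
      xi_ <- samp[sidx, 1]; eta_ <- samp[sidx, 2]
      dN <- rbind(c(-(1 - eta_), (1 - eta_), (1 + eta_), -(1 + eta_)) / 4,
                  c(-(1 - xi_), -(1 + xi_), (1 + xi_), (1 - xi_)) / 4)
      J <- dN %*% cbind(xe, ye)
      dNxy <- solve(J, dN)
      B <- matrix(0, 3, 8)
      B[1, seq(1, 8, 2)] <- dNxy[1, ]
      B[2, seq(2, 8, 2)] <- dNxy[2, ]
      B[3, seq(1, 8, 2)] <- dNxy[2, ]
      B[3, seq(2, 8, 2)] <- dNxy[1, ]
      eps <- as.numeric(B %*% full[idx])
      sig <- (solid$Ddev + solid$Kb * (c(1, 1, 0) %o% c(1, 1, 0))) %*% eps
      s11 <- sig[1]; s22 <- sig[2]; s12 <- sig[3]
      s33 <- nu * (s11 + s22)
      vm <- sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
                 3 * s12^2)
      if (vm > vmax) vmax <- vm
    }
    out[e] <- vmax
  }
  out
}

#' Lesion solid mesh-independence report
#'
#' Repeats the static bending solve on increasingly refined meshes and
#' reports the relative change in tip deflection and peak von Mises stress
#' between consecutive refinements (the acceptance protocol targets < 1% and
#' < 5% respectively).
#'
#' @param q load pressure (Pa).
#' @param n_levels number of refinement levels.
#' @param base_n starting element count along the tab.
#' @param material from [lesion_material()].
#' @return data.frame with element counts and relative deltas.
#' @export
lesion_mesh_study <- function(q = 200,
                              levels = list(c(87L, 4L), c(111L, 5L),
                                            c(117L, 6L)),
                              material = lesion_material()) {
  nlev <- length(levels)
  defl <- numeric(nlev); vm <- numeric(nlev); nel <- integer(nlev)
  for (i in seq_len(nlev)) {
    nl <- levels[[i]][1]; nt <- levels[[i]][2]
    s <- build_lesion_solid(n_length = nl, n_thick = nt,
                            material = material)
    d <- solve_solid_static(s, lesion_face_load(s, q))
    defl[i] <- lesion_tip_deflection(s, d)
    vm[i] <- max(lesion_von_mises(s, d))
    nel[i] <- nl * nt
  }
  data.frame(elements = nel, tip_deflection = defl, max_von_mises = vm,
             d_deflection = c(NA, abs(diff(defl)) / head(defl, -1)),
             d_von_mises = c(NA, abs(diff(vm)) / head(vm, -1)))
}

#' Flutter frequency from a tip-deflection time series
#'
#' Counts zero crossings of the mean-removed (detrended) deflection signal;
#' frequency = crossings / (2 * duration).
#'
#' @param times sample times (s).
#' @param deflection tip deflection (m).
#' @param detrend subtract a moving-average trend before counting (window as
#'   a fraction of the series length).
#' @return frequency in Hz.
#' @export
flutter_frequency <- function(times, deflection, detrend = 0.2) {
  n <- length(deflection)
  stopifnot(n == length(times), n > 4)
  w <- max(3L, round(n * detrend))
  trend <- stats::filter(deflection, rep(1 / w, w), sides = 2)
  trend[is.na(trend)] <- mean(deflection)
  x <- deflection - as.numeric(trend)
  s <- sign(x)
  s[s == 0] <- 1
  crossings <- sum(abs(diff(s)) > 0)
  crossings / (2 * (times[n] - times[1]))
}
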
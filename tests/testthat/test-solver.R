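# ale_flow_solver verification: free-stream preservation, Poiseuille wall
# shear, impulsive Couette, SST reduced-ODE decay, energy sanity

# square with all-open boundary, n points per side
.square_mesh <- function(n = 10, tags = NULL, cell = 1) {
  sq <- NULL
  for (i in 0:(n - 1)) sq <- rbind(sq, c(i / n * 10, 0))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(10, i / n * 10))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(10 - i / n * 10, 10))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(0, 10 - i / n * 10))
  if (is.null(tags))
    tags <- c(rep("inlet", n), rep("outlet", n), rep("outlet", n),
              rep("inlet", n))
  mesh_polygon(sq, tags, cell_size = cell, first_layer = 0)
}

.channel_mesh <- function(Lc = 10, Hc = 2, hc = 0.25, first_layer = hc / 3) {
  poly <- NULL; tags <- NULL
  add <- function(pts, tg) {
    poly <<- rbind(poly, pts); tags <<- c(tags, rep(tg, nrow(pts)))
  }
  add(cbind(seq(0, Lc - hc, by = hc), 0), "wall")
  add(cbind(Lc, seq(0, Hc - hc, by = hc)), "outlet")
  add(cbind(seq(Lc, hc, by = -hc), Hc), "wall")
  add(cbind(0, seq(Hc, hc, by = -hc)), "inlet")
  mesh_polygon(poly, tags, cell_size = hc, first_layer = first_layer)
}

test_that("free stream is preserved under uniform mesh translation", {
  m <- .square_mesh()
  U0 <- c(0.3, 0.1); sp <- sqrt(sum(U0^2))
  st <- flow_state(m)
  st$u[, 1] <- U0[1]; st$u[, 2] <- U0[2]
  nb <- m$n_boundary; ns <- 100L
  bpos <- array(0, dim = c(nb, 2, ns + 1))
  shift <- c(0.02, 0.013) * 1e-3
  for (s in 0:ns)
    bpos[, , s + 1] <- m$nodes[1:nb, ] + s * matrix(shift, nb, 2, byrow = TRUE)
  bc <- list(u_in = sp, u_out = sp, inlet_dir = U0 / sp, outlet_dir = U0 / sp)
  st2 <- advance_steps(st, m, ns, dt = 2.5e-4, bc = bc, bpos = bpos,
                       q_ref = sp * 0.01)
  expect_lt(max(abs(sweep(st2$u, 2, U0))), 1e-10)
  d <- attr(st2, "diag")
  expect_lt(max(d$cfl), 0.5)
})

test_that("plane Poiseuille wall shear matches 3 mu U / h within 2%", {
  m <- .channel_mesh()
  U <- 0.05; h <- 1e-3; upk <- 1.5 * U
  nf <- length(m$face_tag)
  prof <- rep(1, nf)
  for (f in which(m$face_tag %in% c("inlet", "outlet"))) {
    ym <- (m$nodes[m$face_nodes[f, 1], 2] + m$nodes[m$face_nodes[f, 2], 2]) / 2
    prof[f] <- 1 - ((ym - h) / h)^2
  }
  st <- flow_state(m)
  yc <- m$cell_centroid[, 2]
  st$u[, 1] <- upk * (1 - ((yc - h) / h)^2)
  bc <- list(u_in = upk, u_out = upk, inlet_dir = c(1, 0),
             outlet_dir = c(1, 0), profile = prof)
  wallf <- which(m$face_tag == "wall")
  fx <- (m$nodes[m$face_nodes[wallf, 1], 1] +
         m$nodes[m$face_nodes[wallf, 2], 1]) / 2 * 1000
  wallf <- wallf[fx > 3 & fx < 7]
  st2 <- advance_steps(st, m, 3000L, dt = 1.2e-4, bc = bc,
                       q_ref = U * 2e-3, wss_faces = wallf)
  w <- attr(st2, "wss")
  tau <- mean(abs(w[nrow(w), ]))
  expect_equal(tau, 3 * 0.0035 * U / h, tolerance = 0.02)
  # flow reversal flips the sign, preserves the magnitude
  st3 <- st; st3$u[, 1] <- -st3$u[, 1]
  bc3 <- bc; bc3$inlet_dir <- c(-1, 0); bc3$outlet_dir <- c(-1, 0)
  st4 <- advance_steps(st3, m, 200L, dt = 1.2e-4, bc = bc3,
                       q_ref = U * 2e-3, wss_faces = wallf)
  w4 <- attr(st4, "wss")
  expect_lt(max(w4[nrow(w4), ] * w[nrow(w), ]), 0)  # opposite signs
})

test_that("impulsively started Couette matches the analytic series within 2%", {
  Lc <- 4; Hc <- 2; hc <- 0.15
  poly <- NULL; tags <- NULL
  add <- function(pts, tg) {
    poly <<- rbind(poly, pts); tags <<- c(tags, rep(tg, nrow(pts)))
  }
  add(cbind(seq(0, Lc - hc, by = hc), 0), "wall")
  add(cbind(Lc, seq(0, Hc - hc, by = hc)), "outlet")
  add(cbind(seq(Lc, hc, by = -hc), Hc), "wall")
  add(cbind(0, seq(Hc, hc, by = -hc)), "inlet")
  m <- mesh_polygon(poly, tags, cell_size = hc, first_layer = 0)
  Uw <- 0.05; H <- 2e-3; nu <- 0.0035 / 1050
  uan <- function(y, t) {
    s <- y / H
    val <- s
    for (n in 1:80)
      val <- val + 2 / (n * pi) * (-1)^n * exp(-nu * (n * pi / H)^2 * t) *
        sin(n * pi * s)
    Uw * val
  }
  nf <- length(m$face_tag)
  wev <- matrix(0, nf, 2)
  fy <- (m$nodes[m$face_nodes[, 1], 2] + m$nodes[m$face_nodes[, 2], 2]) / 2
  topf <- which(m$face_tag == "wall" & fy > Hc * 1e-3 - 1e-6)
  wev[topf, 1] <- Uw
  open_f <- which(m$face_tag %in% c("inlet", "outlet"))
  st <- flow_state(m)
  dt <- 1.5e-4; tend <- 0.12; ns <- round(tend / dt)
  prof <- rep(1, nf)
  for (s in 1:ns) {
    prof[open_f] <- uan(fy[open_f], s * dt) / Uw
    bc <- list(u_in = Uw, u_out = Uw, inlet_dir = c(1, 0),
               outlet_dir = c(1, 0), profile = prof, wall_extra_vel = wev)
    st <- advance_steps(st, m, 1L, dt = dt, bc = bc, q_ref = Uw * H)
  }
  sel <- abs(m$cell_centroid[, 1] - Lc / 2 * 1e-3) < 1e-3
  err <- max(abs(st$u[sel, 1] - uan(m$cell_centroid[sel, 2], tend)))
  expect_lt(err / Uw, 0.02)
})

test_that("SST free decay matches the reduced ODE within 1%", {
  m <- .square_mesh(n = 8, tags = rep("wall", 32), cell = 1.2)
  cl <- turbulence_closure("sst_k_omega", apply_wall_omega = FALSE)
  st <- flow_state(m, cl)
  k0 <- 1; w0 <- 100
  st$k[] <- k0; st$omega[] <- w0; st$u[] <- 0
  dt <- 1e-4; ns <- 2000L
  for (s in seq_len(ns)) st <- step_turbulence(st, cl, dt, m)
  t <- ns * dt
  beta <- 0.075; bstar <- 0.09              # F1 = 1 in free decay
  kan <- k0 * (1 + beta * w0 * t)^(-bstar / beta)
  wan <- w0 / (1 + beta * w0 * t)
  expect_equal(mean(st$k), kan, tolerance = 0.01)
  expect_equal(mean(st$omega), wan, tolerance = 0.01)
})

test_that("SST production vanishes under solid-body rotation", {
  m <- .square_mesh(n = 8, tags = rep("wall", 32), cell = 1.2)
  cl <- turbulence_closure("sst_k_omega", apply_wall_omega = FALSE)
  st <- flow_state(m, cl)
  Om <- 50
  cc <- sweep(m$cell_centroid, 2, c(5e-3, 5e-3))
  st$u[, 1] <- -Om * cc[, 2]; st$u[, 2] <- Om * cc[, 1]
  st$k[] <- 1e-4; st$omega[] <- 1
  st2 <- step_turbulence(st, cl, 1e-4, m)
  dk <- mean(st2$k) - 1e-4
  dk_dest <- -0.09 * 1e-4 * 1 * 1e-4       # destruction-only change
  expect_lt(abs(dk - dk_dest), 0.2 * abs(dk_dest))
})

test_that("k = 0 remains 0 and the closure reduces to laminar", {
  m <- .square_mesh(n = 8, tags = rep("wall", 32), cell = 1.2)
  cl <- turbulence_closure("sst_k_omega")
  st <- flow_state(m, cl)
  st$k[] <- 0; st$omega[] <- 10
  st$u[, 1] <- 0.1 * m$cell_centroid[, 2] * 1000   # shear, but no k
  st2 <- step_turbulence(st, cl, 1e-3, m)
  expect_identical(max(st2$k), 0)
  expect_identical(max(st2$nut), 0)
  expect_error(step_turbulence(st, turbulence_closure("laminar"), 1e-3, m),
               "sst_k_omega")
})

test_that("kinetic energy decays in a closed box at rest boundaries", {
  m <- .square_mesh(n = 10, tags = rep("wall", 40), cell = 1)
  st <- flow_state(m)
  cc <- sweep(m$cell_centroid, 2, c(5e-3, 5e-3)) / 5e-3
  # smooth vortex blob
  st$u[, 1] <- -0.1 * cc[, 2] * exp(-2 * rowSums(cc^2))
  st$u[, 2] <- 0.1 * cc[, 1] * exp(-2 * rowSums(cc^2))
  bc <- list(u_in = 0, u_out = 0, inlet_dir = c(1, 0), outlet_dir = c(1, 0))
  st2 <- advance_steps(st, m, 300L, dt = 2e-4, bc = bc, q_ref = 1e-5)
  d <- attr(st2, "diag")
  ke <- d$ke
  expect_lt(ke[300], ke[1])
  # non-increasing within small tolerance for roundoff
  expect_true(all(diff(ke) < 1e-9 + 0.001 * ke[-length(ke)]))
})

test_that("zero motion, zero BC, zero flow stays identically zero", {
  m <- .square_mesh(n = 8, tags = rep("wall", 32), cell = 1.2)
  st <- flow_state(m)
  bc <- list(u_in = 0, u_out = 0, inlet_dir = c(1, 0), outlet_dir = c(1, 0))
  st2 <- advance_steps(st, m, 50L, dt = 2e-4, bc = bc, q_ref = 1e-9)
  expect_identical(max(abs(st2$u)), 0)
  expect_identical(max(abs(st2$p)), 0)
})

test_that("piston compression drives the expected outflow", {
  sq <- NULL; n <- 10
  for (i in 0:(n - 1)) sq <- rbind(sq, c(i / n * 10, 0))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(10, i / n * 10))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(10 - i / n * 10, 10))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(0, 10 - i / n * 10))
  tags <- c(rep("wall", n), rep("wall", n), rep("outlet", n), rep("wall", n))
  m <- mesh_polygon(sq, tags, cell_size = 1)
  nb <- m$n_boundary
  vy <- 0.01; dt <- 5e-5; ns <- 400L
  bpos <- array(0, dim = c(nb, 2, ns + 1))
  bxy <- m$nodes[1:nb, ]
  bottom <- which(bxy[, 2] < 1e-9)
  for (s in 0:ns) {
    b <- bxy; b[bottom, 2] <- b[bottom, 2] + s * dt * vy
    bpos[, , s + 1] <- b
  }
  st <- flow_state(m)
  bc <- list(u_in = 0, u_out = vy, inlet_dir = c(0, 1), outlet_dir = c(0, 1))
  st2 <- advance_steps(st, m, ns, dt = dt, bc = bc, bpos = bpos,
                       q_ref = vy * 0.01)
  d <- attr(st2, "diag")
  # global mass closure: open flux balances the wall swept-volume rate
  expect_lt(max(abs(d$q_open - d$q_wall)), 1e-12)
  expect_equal(d$q_open[ns], vy * 0.01, tolerance = 0.01)  # 10 mm opening
  expect_lt(max(d$resid), 1e-3)
})
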
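# hemodynamic_endpoints: WSS metrics, vorticity, TKE/RSS, jet diameter,
# model comparison arithmetic

.square_endpoint_mesh <- function(n = 10, cell = 1) {
  sq <- NULL
  for (i in 0:(n - 1)) sq <- rbind(sq, c(i / n * 10, 0))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(10, i / n * 10))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(10 - i / n * 10, 10))
  for (i in 0:(n - 1)) sq <- rbind(sq, c(0, 10 - i / n * 10))
  mesh_polygon(sq, rep("wall", 4 * n), cell_size = cell, first_layer = 0)
}

.snapshot <- function(mesh, ufun) {
  u <- t(apply(mesh$cell_centroid, 1, ufun))
  list(u = u, p = numeric(nrow(u)), k = numeric(nrow(u)),
       omega = rep(1, nrow(u)), nut = numeric(nrow(u)),
       nodes = mesh$nodes, time = 0)
}

test_that("vorticity of canonical fields", {
  m <- .square_endpoint_mesh()
  cc <- sweep(m$cell_centroid, 2, c(5e-3, 5e-3))
  Om <- 30
  # rigid rotation -> 2 Omega
  sn <- .snapshot(m, function(p) Om * c(-(p[2] - 5e-3), p[1] - 5e-3))
  vort <- compute_vorticity(sn, m)
  interior <- m$wall_dist > 1.5e-3
  expect_equal(mean(vort[interior]), 2 * Om, tolerance = 0.01)
  # uniform flow -> 0
  sn0 <- .snapshot(m, function(p) c(0.3, 0.1))
  expect_lt(max(abs(compute_vorticity(sn0, m))), 1e-9)
  # shear u1 = gamma x2 -> -gamma
  gam <- 100
  sn2 <- .snapshot(m, function(p) c(gam * p[2], 0))
  expect_equal(mean(compute_vorticity(sn2, m)[interior]), -gam,
               tolerance = 0.01)
})

test_that("TKE and RSS follow the closure contracts", {
  m <- .square_endpoint_mesh()
  sn <- .snapshot(m, function(p) c(0, 0))
  # laminar -> identically zero
  expect_identical(compute_tke(sn, turbulence_closure("laminar")),
                   rep(0, nrow(m$tris)))
  # uniform k = 2 -> max TKE = 2
  cl <- turbulence_closure("sst_k_omega")
  sn$k <- rep(2, nrow(m$tris))
  expect_identical(max(compute_tke(sn, cl)), 2)
  # nut = 0 -> RSS = 0
  expect_identical(max(abs(compute_rss(sn, m, cl))), 0)
  # uniform shear gamma with uniform nut -> rho nut gamma
  gam <- 50; nut0 <- 1e-4
  sn2 <- .snapshot(m, function(p) c(gam * p[2], 0))
  sn2$nut <- rep(nut0, nrow(m$tris))
  rss <- compute_rss(sn2, m, cl, fluid_properties())
  interior <- m$wall_dist > 1.5e-3
  expect_equal(mean(rss[interior]), 1050 * nut0 * gam, tolerance = 0.01)
})

test_that("TSM/TSG/OSI match independent quadrature oracles to 1e-6", {
  T <- 0.772
  n <- 20000L
  tgrid <- (seq_len(n) - 1) / n * T
  # composite analytic signal
  f <- function(t) 0.4 + sin(2 * pi * t / T) + 0.3 * cos(4 * pi * t / T)
  fd <- function(t) 2 * pi / T * cos(2 * pi * t / T) -
    1.2 * pi / T * sin(4 * pi * t / T)
  rec <- list(times = tgrid, tau = f(tgrid), period = T)
  # oracle: adaptive high-order quadrature on the closed forms
  tsm_o <- stats::integrate(function(t) abs(f(t)), 0, T,
                            subdivisions = 2000L, rel.tol = 1e-12)$value / T
  tsg_o <- stats::integrate(function(t) abs(fd(t)), 0, T,
                            subdivisions = 2000L, rel.tol = 1e-12)$value / T
  int_o <- stats::integrate(f, 0, T, rel.tol = 1e-12)$value
  absint_o <- tsm_o * T
  osi_o <- 0.5 * (1 - abs(int_o) / absint_o)
  expect_equal(compute_tsm(rec), tsm_o, tolerance = 1e-6)
  expect_equal(compute_tsg(rec), tsg_o, tolerance = 1e-6)
  expect_equal(compute_osi(rec), osi_o, tolerance = 1e-6)
})

test_that("TSM/TSG/OSI limiting cases", {
  T <- 1; n <- 4000L
  tgrid <- (seq_len(n) - 1) / n * T
  # constant signal
  cst <- list(times = tgrid, tau = rep(-2.5, n), period = T)
  expect_equal(compute_tsm(cst), 2.5)
  expect_equal(compute_tsg(cst), 0)
  expect_equal(compute_osi(cst), 0)
  # zero-mean sinusoid: TSM = 2/pi, TSG = 4/T, OSI = 0.5
  sig <- list(times = tgrid, tau = sin(2 * pi * tgrid / T), period = T)
  expect_equal(compute_tsm(sig), 2 / pi, tolerance = 1e-5)
  expect_equal(compute_tsg(sig), 4 / T, tolerance = 1e-5)
  expect_equal(compute_osi(sig), 0.5, tolerance = 1e-12)
  # strictly positive signal: OSI = 0
  pos <- list(times = tgrid, tau = 1.2 + sin(2 * pi * tgrid / T), period = T)
  expect_equal(compute_osi(pos), 0, tolerance = 1e-12)
  # 3/4 cycle at +1, 1/4 at -1: OSI = 1/4
  step_sig <- list(times = tgrid,
                   tau = ifelse(tgrid < 0.75 * T, 1, -1), period = T)
  expect_equal(compute_osi(step_sig), 0.25, tolerance = 1e-3)
  # sawtooth amplitude a: TSG = 4a/T
  a <- 2
  saw <- list(times = tgrid,
              tau = a * (2 * abs(2 * (tgrid / T - floor(tgrid / T + 0.5))) - 1),
              period = T)
  expect_equal(compute_tsg(saw), 4 * a / T, tolerance = 1e-2)
  # zero signal: OSI defined 0 with warning
  expect_warning(z <- compute_osi(list(times = tgrid, tau = rep(0, n),
                                       period = T)), "zero")
  expect_identical(z, 0)
  # non-uniform grid rejected
  bad <- list(times = tgrid^1.2, tau = rep(1, n), period = T)
  expect_error(compute_tsm(bad), "non-uniform")
})

test_that("OSI properties: range and scale invariance; TSM >= |mean|", {
  T <- 1; n <- 3000L
  tgrid <- (seq_len(n) - 1) / n * T
  set.seed(7)
  for (rep in 1:12) {
    a <- stats::rnorm(4)
    tau <- a[1] + a[2] * sin(2 * pi * tgrid / T + a[3]) +
      a[4] * sin(6 * pi * tgrid / T)
    rec <- list(times = tgrid, tau = tau, period = T)
    osi <- compute_osi(rec)
    expect_gte(osi, 0); expect_lte(osi, 0.5)
    rec2 <- rec; rec2$tau <- 3.7 * tau
    expect_equal(compute_osi(rec2), osi, tolerance = 1e-12)
    expect_gte(compute_tsm(rec) + 1e-12, abs(mean(tau)))
  }
})

test_that("effective jet diameter on analytic profiles", {
  m <- .square_endpoint_mesh(n = 20, cell = 0.5)
  w <- 10e-3
  p0 <- c(0, 5e-3); p1 <- c(10e-3, 5e-3); ax <- c(0, 1)
  # uniform plug -> full width
  sn <- .snapshot(m, function(p) c(0, 0.5))
  expect_equal(effective_jet_diameter(sn, m, p0, p1, ax), w,
               tolerance = 0.06)
  # top-hat of width w/2 -> w/2
  sn2 <- .snapshot(m, function(p) c(0, ifelse(abs(p[1] - 5e-3) < w / 4, 1, 0)))
  expect_equal(effective_jet_diameter(sn2, m, p0, p1, ax), w / 2,
               tolerance = 0.1)
  # triangular profile peaking at centre: u > 0.1 umax over 90% of width
  sn3 <- .snapshot(m, function(p) c(0, max(0, 1 - abs(p[1] - 5e-3) / (w / 2))))
  expect_equal(effective_jet_diameter(sn3, m, p0, p1, ax), 0.9 * w,
               tolerance = 0.1)
  # no forward flow -> 0 with warning
  sn4 <- .snapshot(m, function(p) c(0, -0.2))
  expect_warning(jd <- effective_jet_diameter(sn4, m, p0, p1, ax),
                 "no forward flow")
  expect_identical(jd, 0)
})

test_that("model comparison arithmetic", {
  mk <- function(v, om, jd, tsm, tsg, osi) {
    structure(list(model_id = "X", period = 0.772,
                   sites = lapply(1:3, function(i)
                     list(site_id = i, tsm = tsm[i], tsg = tsg[i],
                          osi = osi[i])),
                   peak_lvot_velocity = v, lvot_vorticity = om,
                   jet_diameter = jd, max_tke = 0, peak_rss = 0),
              class = "endpoint_summary")
  }
  a <- mk(1.0, 100, 0.018, c(1, 0.8, 0.6), c(10, 8, 6), c(0.3, 0.35, 0.36))
  expect_equal(compare_models(a, a)$velocity_fold, 1)
  expect_equal(compare_models(a, a)$jet_diameter_reduction, 0)
  expect_equal(compare_models(a, a)$sites[[1]]$tsm_pct, 0)
  b <- mk(2.4, 280, 0.0099, c(1.23, 0.88, 0.63), c(16.9, 9.76, 6),
          c(0.29, 0.34, 0.37))
  cmp <- compare_models(a, b)
  expect_equal(cmp$velocity_fold, 2.4)
  expect_equal(cmp$vorticity_fold, 2.8)
  expect_equal(cmp$jet_diameter_reduction, 0.45)
  expect_equal(cmp$sites[[1]]$tsm_pct, 23)
  expect_equal(cmp$sites[[1]]$tsg_pct, 69)
  expect_equal(cmp$sites[[3]]$osi_diff, 0.01)
  # phase mismatch rejected
  b2 <- b; b2$period <- 0.8
  expect_error(compare_models(a, b2), "phase mismatch")
})
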
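# geometry_builder: parametric N-LV / S-LV / DSS-LV construction

test_that("built geometries reproduce the requested aortoseptal angle", {
  for (m in c("N-LV", "S-LV", "DSS-LV")) {
    g <- build_geometry(m)
    expected <- if (m == "N-LV") 130 else 110
    expect_equal(measure_aosa(g), expected, tolerance = 0.5 / expected)
    expect_true(polygon_is_simple(g$poly$xy))
    expect_gt(polygon_area(g$poly$xy), 0)
  }
  # non-default angle round-trips too
  g <- build_geometry("N-LV", geometry_params(aosa = 121))
  expect_lt(abs(measure_aosa(g) - 121), 0.5)
})

test_that("inlet/outlet extension widths are exact", {
  g <- build_geometry("S-LV")
  expect_identical(g$outlet_extension$width, 18.6)
  expect_identical(g$inlet_extension$width, 24.4)
  # measured on the polyline: opening chord lengths
  xy <- g$poly$xy; tg <- g$poly$tag
  for (tag in c("inlet", "outlet")) {
    idx <- which(tg == tag)
    v0 <- xy[idx[1], ]
    v1 <- xy[(idx[length(idx)] %% nrow(xy)) + 1L, ]
    w <- sqrt(sum((v1 - v0)^2))
    expect_equal(w, if (tag == "inlet") 24.4 else 18.6, tolerance = 1e-9)
  }
})

test_that("default DSS-LV lesion reduces the 18.6 mm lumen by 25%", {
  g <- build_geometry("DSS-LV")
  expect_equal(min_lumen_width(g), 18.6 * 0.75, tolerance = 0.01)
  expect_equal(g$lesion$protrusion, 0.25 * 18.6, tolerance = 1e-9)
  expect_equal(g$lesion$spec$length, 10)
  expect_equal(g$lesion$spec$thickness, 1)
})

test_that("zero stenosis fraction degenerates DSS-LV to S-LV", {
  p <- geometry_params(stenosis_fraction = 0)
  g0 <- build_geometry("DSS-LV", p)
  s0 <- build_geometry("S-LV", p)
  expect_equal(g0$poly$xy, s0$poly$xy)
  expect_identical(g0$poly$tag, s0$poly$tag)
  expect_null(g0$lesion)
})

test_that("N-LV and S-LV coincide exactly outside the LVOT region", {
  n <- build_geometry("N-LV")
  s <- build_geometry("S-LV")
  # vertices not belonging to channel walls / openings: chamber + inlet
  in_chamber <- function(g) {
    # chamber/inlet vertices away from the angle-dependent region (channel
    # walls and the crest blending fillet, whose tangency length depends on
    # the angle)
    xy <- g$poly$xy
    (xy[, 2] <= 1e-9 | xy[, 1] <= g$params$junction_x + 1e-9) &
      !(xy[, 1] > g$params$crest_x - 1e-6 & xy[, 2] > -4.5)
  }
  a <- n$poly$xy[in_chamber(n), ]
  b <- s$poly$xy[in_chamber(s), ]
  expect_equal(a, b)
})

test_that("DSS-LV minus lesion equals S-LV node-for-node", {
  dss <- build_geometry("DSS-LV")
  slv <- build_geometry("S-LV")
  tg <- dss$poly$tag
  n <- length(tg)
  prev_tag <- tg[c(n, 1:(n - 1L))]
  keep <- tg != "lesion" & prev_tag != "lesion"
  kept <- dss$poly$xy[keep, ]
  # every kept DSS vertex appears in the S-LV polyline (same coordinates)
  sxy <- slv$poly$xy
  match_row <- function(p) any(abs(sxy[, 1] - p[1]) < 1e-9 &
                               abs(sxy[, 2] - p[2]) < 1e-9)
  ok <- apply(kept, 1, match_row)
  expect_true(all(ok))
})

test_that("septal crest location and tie-breaks", {
  # default S-LV: brute-force curvature-scan oracle over the septal path
  g <- build_geometry("S-LV")
  cr <- locate_septal_crest(g)
  pts <- g$septal$pts; s <- g$septal$s
  kap <- rep(NA_real_, nrow(pts))
  for (i in 2:(nrow(pts) - 1L)) {
    u <- pts[i, ] - pts[i - 1L, ]; v <- pts[i + 1L, ] - pts[i, ]
    ang <- atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
    kap[i] <- ang / ((sqrt(sum(u^2)) + sqrt(sum(v^2))) / 2)
  }
  km <- max(-kap, na.rm = TRUE)                # lumen-ward turning
  run <- which(!is.na(kap) & -kap >= km - 1e-6 * km)
  oracle <- (s[min(run)] + s[max(run)]) / 2
  expect_equal(cr, oracle, tolerance = 1e-6)
  # the crest sits near the configured corner point
  expect_lt(abs(cr - g$septal$crest_s), 1.5)

  # circular-arc septum tangent to two straight segments: crest at midpoint
  R <- 5; th <- seq(-pi / 4, pi / 4, length.out = 21)
  arcp <- cbind(R * cos(th), R * sin(th))
  t1 <- c(-sin(th[1]), cos(th[1])); t2 <- c(-sin(th[21]), cos(th[21]))
  pre <- t(sapply(rev(seq(0.4, 3, by = 0.4)), function(d) arcp[1, ] - d * t1))
  post <- t(sapply(seq(0.4, 3, by = 0.4), function(d) arcp[21, ] + d * t2))
  pts <- rbind(pre, arcp, post)
  sarc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  mid <- (sarc[nrow(pre) + 1L] + sarc[nrow(pre) + 21L]) / 2
  expect_equal(locate_septal_crest(list(pts = pts)), mid, tolerance = 1e-6)

  # two equal separated maxima: deterministic LVOT-ward tie-break
  mk_corner <- function(x0) {
    # unit right-angle corner at (x0, 1)
    rbind(c(x0 - 1, 0), c(x0 - 0.5, 0.5), c(x0, 1), c(x0 + 0.5, 0.5),
          c(x0 + 1, 0))
  }
  two <- rbind(mk_corner(0), mk_corner(10))
  sarc2 <- c(0, cumsum(sqrt(rowSums(diff(two)^2))))
  cr2 <- locate_septal_crest(list(pts = two))
  expect_equal(cr2, sarc2[8], tolerance = 1e-9)  # second (LVOT-ward) corner

  # flat wall: error
  flat <- cbind(seq(0, 10, by = 0.5), 0)
  expect_error(locate_septal_crest(list(pts = flat)), "crest-not-found")
})

test_that("site windows are 2 mm, contiguous and correctly ordered", {
  g <- build_geometry("N-LV")
  sites <- define_sites(g, crest = 20)
  # crest at s=20 -> [21,23], [19,21], [17,19]
  expect_equal(sapply(sites, `[[`, "arc_start"), c(21, 19, 17))
  expect_equal(sapply(sites, `[[`, "arc_end"), c(23, 21, 19))
  expect_equal(sapply(sites, `[[`, "site_id"), 1:3)
  for (s in sites) expect_equal(s$arc_end - s$arc_start, 2.0)
  # partition 6 mm contiguously: union covers [17, 23] without gaps
  ord <- order(sapply(sites, `[[`, "arc_start"))
  starts <- sapply(sites, `[[`, "arc_start")[ord]
  ends <- sapply(sites, `[[`, "arc_end")[ord]
  expect_equal(starts[-1], ends[-3])
  # default geometry sites exist and bracket the crest
  expect_length(g$sites, 3)
  cr <- locate_septal_crest(g)
  expect_equal(g$sites[[2]]$arc_start, cr - 1)
  expect_equal(g$sites[[2]]$arc_end, cr + 1)
})

test_that("site definition near septal wall end raises an error", {
  g <- build_geometry("N-LV")
  expect_error(define_sites(g, crest = 1.5), "site error")
  expect_error(define_sites(g, crest = max(g$septal$s) - 1), "site error")
})

test_that("parameter validation errors", {
  expect_error(build_geometry("N-LV", geometry_params(aosa = 80)),
               "aosa")
  expect_error(build_geometry("DSS-LV", geometry_params(stenosis_fraction = 0.7)),
               "stenosis")
})

test_that("geometry JSON and CSV round-trips", {
  g <- build_geometry("DSS-LV")
  jf <- tempfile(fileext = ".json")
  write_geometry_json(g, jf)
  g2 <- read_geometry_json(jf)
  expect_equal(g2$poly$xy, g$poly$xy)
  expect_identical(g2$model_id, "DSS-LV")

  cf <- tempfile(fileext = ".csv")
  write_geometry_csv(g, cf)
  df <- read.csv(cf)
  expect_identical(names(df), c("s", "x1", "x2", "tag"))
  expect_equal(nrow(df), nrow(g$poly$xy))
  expect_equal(cbind(df$x1, df$x2), unname(g$poly$xy))
  unlink(c(jf, cf))
})
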
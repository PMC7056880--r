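#' @useDynLib lvotflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats splinefun uniroot approx approxfun
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

# ---------------------------------------------------------------------------
# Parametric 2D LV / LVOT geometries.
#
# Units: millimetres.  Coordinates: x1 horizontal, x2 vertical, with the
# ventricular base plane at x2 = 0 and the chamber below it.  The septal wall
# is the right-hand wall; the LVOT channel leaves the chamber at the septal
# crest (x_crest, 0) and leans rightward.  The aortoseptal angle (AoSA) is
# the angle at the crest between the apex-ward septal wall direction and the
# outflow-ward LVOT axis: 130 deg = normal, 110 deg = steep.
# ---------------------------------------------------------------------------

#' Default geometry configuration
#'
#' Returns the parameter list consumed by [build_geometry()].  All lengths in
#' millimetres, angles in degrees.  The chamber outline (a straight-walled
#' basal section joined to a half-ellipse) is shared by all three models so
#' that angle and lesion effects are isolated.
#'
#' @param aosa aortoseptal angle (deg); defaults per model inside
#'   [build_geometry()] (130 for N-LV, 110 for S-LV / DSS-LV).
#' @param outlet_width,outlet_length LVOT outlet extension (mm).
#' @param inlet_width,inlet_length mitral inlet extension (mm).
#' @param crest_x x1 of the septal crest (mm).
#' @param junction_x x1 of the sharp mitral-inlet/aortic-outlet junction (mm).
#' @param chamber_depth chamber depth below the base plane (mm, end systole).
#' @param basal_straight length of the straight basal side walls (mm).
#' @param lvot_length length of the parallel LVOT channel between the funnel
#'   mouth and the outlet extension (mm).
#' @param septal_tag_length extent of the `septal_wall` tag below the crest (mm).
#' @param ds polyline resampling target spacing (mm).
#' @param crest_fillet blending fillet radius at the septal crest (mm); the
#'   anatomical crest is smooth, and a sharp corner would force systolic
#'   separation right at the wall-shear characterization sites.
#' @param stenosis_fraction fractional luminal reduction caused by the lesion.
#' @param lesion_length,lesion_thickness lesion tab dimensions (mm).
#' @param lesion_attach_s arc distance of the lesion root centre downstream of
#'   the crest along the septal channel wall (mm).
#' @param lesion_fillet root fillet radius (mm).
#' @return named list of geometry parameters.
#' @export
geometry_params <- function(aosa = NULL,
                            outlet_width = 18.6, outlet_length = 10,
                            inlet_width = 24.4, inlet_length = 2,
                            crest_x = 20, junction_x = -5,
                            chamber_depth = 55, basal_straight = 12,
                            lvot_length = 12, septal_tag_length = 10,
                            ds = 0.8, crest_fillet = 4,
                            stenosis_fraction = 0.25,
                            lesion_length = 10, lesion_thickness = 1,
                            lesion_attach_s = 5, lesion_fillet = 0.5) {
  list(aosa = aosa,
       outlet_width = outlet_width, outlet_length = outlet_length,
       inlet_width = inlet_width, inlet_length = inlet_length,
       crest_x = crest_x, junction_x = junction_x,
       chamber_depth = chamber_depth, basal_straight = basal_straight,
       lvot_length = lvot_length, septal_tag_length = septal_tag_length,
       ds = ds, crest_fillet = crest_fillet,
       stenosis_fraction = stenosis_fraction,
       lesion_length = lesion_length, lesion_thickness = lesion_thickness,
       lesion_attach_s = lesion_attach_s, lesion_fillet = lesion_fillet)
}

# stations along segment p1 -> p2 at spacing <= ds, excluding p1, including p2
.seg_stations <- function(p1, p2, ds) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(1L, ceiling(len / ds))
  t <- seq_len(n) / n
  cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
}

# shoelace signed area of an open-listed closed polygon (n x 2)
#' Signed polygon area (shoelace formula)
#' @param xy n x 2 matrix of vertices (closed implicitly).
#' @return signed area; positive for counterclockwise ordering.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Test a closed polygon for self-intersection
#'
#' Brute-force segment-pair test; adjacent segments are skipped.
#' @param xy n x 2 vertex matrix.
#' @param tol touch tolerance.
#' @return TRUE if the polygon is simple.
#' @export
polygon_is_simple <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- (i + 2L):jmax
    # cross products for segment i vs all segments js
    p <- a[i, ]; r <- b[i, ] - p
    q <- a[js, , drop = FALSE]; s <- b[js, , drop = FALSE] - q
    denom <- r[1] * s[, 2] - r[2] * s[, 1]
    qp <- cbind(q[, 1] - p[1], q[, 2] - p[2])
    tnum <- qp[, 1] * s[, 2] - qp[, 2] * s[, 1]
    unum <- qp[, 1] * r[2] - qp[, 2] * r[1]
    ok <- abs(denom) > tol
    tt <- tnum[ok] / denom[ok]
    uu <- unum[ok] / denom[ok]
    if (any(tt > tol & tt < 1 - tol & uu > tol & uu < 1 - tol)) return(FALSE)
  }
  TRUE
}

# fillet a corner: replace vertex `corner` with an arc of radius r tangent to
# both adjacent edges.  Returns a matrix of replacement points.
.fillet_corner <- function(p_prev, corner, p_next, r, n_pts = 4L) {
  u <- p_prev - corner; v <- p_next - corner
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  u <- u / lu; v <- v / lv
  cosang <- sum(u * v)
  ang <- acos(pmin(1, pmax(-1, cosang)))
  if (ang < 1e-6 || abs(ang - pi) < 1e-3) return(rbind(corner))
  d <- r / tan(ang / 2)
  dmax <- 0.45 * min(lu, lv)
  if (d > dmax) { d <- dmax; r <- d * tan(ang / 2) }
  t1 <- corner + d * u           # tangency on incoming edge
  t2 <- corner + d * v
  bis <- (u + v); bis <- bis / sqrt(sum(bis^2))
  centre <- corner + bis * sqrt(d^2 + r^2)
  a1 <- atan2(t1[2] - centre[2], t1[1] - centre[1])
  a2 <- atan2(t2[2] - centre[2], t2[1] - centre[1])
  da <- a2 - a1
  if (da > pi) da <- da - 2 * pi
  if (da < -pi) da <- da + 2 * pi
  th <- a1 + seq(0, 1, length.out = n_pts + 2L) * da
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# lesion tab outline along the septal channel wall.
# Wall line: W(s) = C + s*a; inward lumen normal nh.  The tab is a rounded
# rectangle of total length L (root to tip extremity) and thickness t,
# leaning toward the outlet so that its maximum normal protrusion equals
# `protrusion`.  Returns list(points, meta).
.lesion_tab <- function(C, a, nh, params) {
  w_out <- params$outlet_width
  p_depth <- params$stenosis_fraction * w_out
  L <- params$lesion_length
  t <- params$lesion_thickness
  if (p_depth <= 0) return(NULL)
  if (p_depth >= w_out)
    stop("stenosis error: lesion protrusion ", p_depth,
         " mm >= lumen width ", w_out, " mm")
  if (p_depth < t)
    stop("stenosis error: nonzero protrusion smaller than lesion thickness")
  sin_lam <- (p_depth - t / 2) / (L - t / 2)
  if (sin_lam >= 1)
    stop("stenosis error: requested protrusion exceeds lesion length")
  lam <- asin(sin_lam)
  e <- cos(lam) * a + sin(lam) * nh        # tab axis (leaning downstream)
  m <- -sin(lam) * a + cos(lam) * nh       # tab cross direction
  s_c <- params$lesion_attach_s
  A0 <- C + s_c * a                        # root centre on the wall
  A1 <- A0 + (L - t / 2) * e               # tip cap centre
  # intersections of the two long edges with the wall line (param s along a)
  # edge through A1 -/+ (t/2) m, direction e;  wall point: C + s a
  root_s <- function(sign) {
    P <- A1 + sign * (t / 2) * m
    # solve P + mu * (-e) = C + s * a  => cross with nh to eliminate s
    # (P - C) . nh - mu * (e . nh) = 0
    mu <- sum((P - C) * nh) / sum(e * nh)
    Q <- P - mu * e
    sum((Q - C) * a)
  }
  # +m side has smaller wall projection (m . a = -sin lam): upstream face
  s_up <- root_s(+1)                        # upstream (crest-side) root corner
  s_dn <- root_s(-1)
  corner_up <- C + s_up * a
  corner_dn <- C + s_dn * a
  # tip cap: semicircle of radius t/2 about A1 swinging from the +m side
  # through the tip (+e) to the -m side
  th0 <- atan2(m[2], m[1])
  th <- th0 - seq(0, pi, length.out = 7L)
  # outline traversed in wall direction crest -> outlet: upstream corner,
  # out along the upstream face, around the cap, back along the downstream
  # face to the downstream corner.
  up_face <- rbind(corner_up, .seg_stations(corner_up, A1 + (t / 2) * m,
                                            params$ds / 2))
  up_face <- up_face[-nrow(up_face), , drop = FALSE]
  cap <- cbind(A1[1] + (t / 2) * cos(th), A1[2] + (t / 2) * sin(th))
  dn_face <- .seg_stations(A1 - (t / 2) * m, corner_dn, params$ds / 2)
  pts <- rbind(up_face, cap, dn_face)
  # root fillets
  r_f <- params$lesion_fillet
  if (r_f > 1e-9) {
    wall_prev <- corner_up - a   # a point on the wall upstream of the root
    first_dir <- pts[2, ]
    head_f <- .fillet_corner(wall_prev, pts[1, ], first_dir, r_f)
    wall_next <- corner_dn + a
    nlast <- nrow(pts)
    tail_f <- .fillet_corner(pts[nlast - 1L, ], pts[nlast, ], wall_next, r_f)
    pts <- rbind(head_f, pts[2:(nlast - 1L), , drop = FALSE], tail_f)
  }
  list(points = pts,
       meta = list(root_centre = A0, tip_centre = A1, axis = e, cross = m,
                   length = L, thickness = t, protrusion = p_depth,
                   lean_angle = lam, s_root_up = s_up, s_root_dn = s_dn,
                   attachment_arc_position = s_c,
                   root_fillet_radius = r_f))
}

#' Build a parametric 2D LV/LVOT geometry
#'
#' Constructs one of the three study geometries: `N-LV` (normal 130 deg
#' aortoseptal angle), `S-LV` (steep 110 deg) or `DSS-LV` (steep angle plus a
#' compliant lesion tab on the septal wall causing, by default, a 25%
#' reduction of the 18.6 mm luminal width).  The three models share the same
#' chamber outline; the angle is imposed by rotating the LVOT channel about
#' the septal crest.
#'
#' @param model_id one of `"N-LV"`, `"S-LV"`, `"DSS-LV"`.
#' @param params geometry configuration from [geometry_params()].
#' @return an object of class `lvot_geometry`: the tagged boundary polyline
#'   (counterclockwise, mm), septal arc parameterization, site windows,
#'   extension specs and (for DSS-LV) the lesion description.
#' @export
build_geometry <- function(model_id = c("N-LV", "S-LV", "DSS-LV"),
                           params = geometry_params()) {
  model_id <- match.arg(model_id)
  if (is.null(params$aosa))
    params$aosa <- if (model_id == "N-LV") 130 else 110
  if (params$aosa < 90 || params$aosa > 160)
    stop("geometry error: aosa must lie in [90, 160] degrees")
  if (params$stenosis_fraction < 0 || params$stenosis_fraction >= 0.6)
    stop("geometry error: stenosis fraction must lie in [0, 0.6)")
  ds <- params$ds
  x_C <- params$crest_x; x_J <- params$junction_x
  x_L <- x_J - params$inlet_width
  dstr <- params$basal_straight
  depth <- params$chamber_depth
  psi <- (180 - params$aosa) * pi / 180
  a <- c(sin(psi), cos(psi))               # LVOT axis, outflow-ward
  nh <- c(-a[2], a[1])                      # inward lumen normal (anterior side)
  C <- c(x_C, 0)
  J <- c(x_J, 0)
  chan_len <- params$lvot_length + params$outlet_length
  P_ant <- C + params$outlet_width * nh
  P_out_ant <- P_ant + chan_len * a
  P_out_sep <- C + chan_len * a

  # crest fillet tangency distance along each wall
  Rf <- params$crest_fillet
  theta <- params$aosa * pi / 180
  d_tan <- if (Rf > 0) Rf / tan(theta / 2) else 0
  if (d_tan > dstr - params$ds)
    stop("geometry error: crest fillet too large for the basal wall")
  T_wall <- c(x_C, -d_tan)                # tangency on the straight wall
  pts <- rbind(T_wall); tags <- character(0)
  add <- function(newpts, tag) {
    tags <<- c(tags, rep(tag, nrow(newpts)))
    pts <<- rbind(pts, newpts)
  }
  # 1. septal straight wall down on an angle-independent station grid
  # (stations below the fillet tangency coincide exactly across models)
  ys <- seq(ds, dstr, by = ds)
  if (abs(ys[length(ys)] - dstr) > 1e-9) ys <- c(ys, dstr)
  ys <- ys[ys > d_tan + 1e-9]
  st1 <- cbind(x_C, -ys)
  seg_tags <- ifelse(ys <= params$septal_tag_length + 1e-9,
                     "septal_wall", "lv_wall")
  tags <- c(tags, seg_tags)
  pts <- rbind(pts, st1)
  # 2. half ellipse around the apex
  a_e <- (x_C - x_L) / 2; b_e <- depth - dstr
  cx <- (x_C + x_L) / 2
  arc_len_est <- pi * sqrt((a_e^2 + b_e^2) / 2)
  n_arc <- max(24L, ceiling(arc_len_est / ds))
  tau <- seq(0, pi, length.out = n_arc + 1L)[-1]
  ell <- cbind(cx + a_e * cos(tau), -dstr - b_e * sin(tau))
  add(ell, "lv_wall")
  # 3. left wall up, 4. inlet left wall
  add(.seg_stations(c(x_L, -dstr), c(x_L, 0), ds), "lv_wall")
  add(.seg_stations(c(x_L, 0), c(x_L, params$inlet_length), ds), "lv_wall")
  # 5. inlet opening
  add(.seg_stations(c(x_L, params$inlet_length),
                    c(x_J, params$inlet_length), ds), "inlet")
  # 6. inlet right wall down to the Mi-Ao junction
  add(.seg_stations(c(x_J, params$inlet_length), J, ds), "lv_wall")
  # 7. funnel anterior wall, 8. channel anterior wall
  add(.seg_stations(J, P_ant, ds), "lv_wall")
  add(.seg_stations(P_ant, P_out_ant, ds), "lv_wall")
  # 9. outlet opening
  add(.seg_stations(P_out_ant, P_out_sep, ds), "outlet")
  # 10. channel septal wall back to the crest (with lesion for DSS-LV)
  lesion <- NULL
  if (model_id == "DSS-LV") {
    lesion <- .lesion_tab(C, a, nh, params)
  }
  T_chan <- C + d_tan * a                  # tangency on the channel wall
  close_with_fillet <- function() {
    if (d_tan > 0) {
      arc <- .fillet_corner(C + 2 * d_tan * a, C, c(x_C, -2 * d_tan),
                            Rf, n_pts = max(6L, ceiling(2 * d_tan / ds)))
      arc <- arc[-nrow(arc), , drop = FALSE]    # last point = trace start
      if (nrow(arc) > 0) add(arc, "septal_wall")
    }
    tags <<- c(tags, "septal_wall")             # closing segment
  }
  if (is.null(lesion)) {
    wall <- .seg_stations(P_out_sep, T_chan, ds)
    if (d_tan == 0) wall <- wall[-nrow(wall), , drop = FALSE]
    if (nrow(wall) > 0) add(wall, "septal_wall")
    close_with_fillet()
  } else {
    # wall splice limits: projections of the first/last tab outline points
    # (fillet tangencies lie on the wall line).  Wall stations outside the
    # footprint reuse the S-LV stations exactly, so DSS-LV minus the lesion
    # equals S-LV node-for-node.
    tab <- lesion$points
    s_lo <- sum((tab[1, ] - C) * a)             # crest-side tangency
    s_hi <- sum((tab[nrow(tab), ] - C) * a)     # outlet-side tangency
    wall <- .seg_stations(P_out_sep, T_chan, ds)  # same stations as S-LV
    s_wall <- (wall[, 1] - C[1]) * a[1] + (wall[, 2] - C[2]) * a[2]
    if (s_lo < d_tan + 0.5)
      stop("geometry error: lesion attachment overlaps the crest fillet")
    w1 <- wall[s_wall > s_hi + 0.25 * ds, , drop = FALSE]
    if (nrow(w1) > 0) add(w1, "septal_wall")
    tab_rev <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
    add(tab_rev, "lesion")
    w2 <- wall[s_wall < s_lo - 0.25 * ds & s_wall > d_tan - 1e-9, ,
               drop = FALSE]
    if (nrow(w2) > 0) add(w2, "septal_wall")
    close_with_fillet()
  }
  stopifnot(length(tags) == nrow(pts))

  # orient counterclockwise (positive area), remapping segment tags
  if (polygon_area(pts) < 0) {
    n <- nrow(pts)
    pts <- pts[n:1, , drop = FALSE]
    tags <- tags[c((n - 1L):1L, n)]
  }
  # rotate so vertex 1 is the inlet-opening left corner (keeps the septal run
  # contiguous, away from the wrap)
  i0 <- which.min((pts[, 1] - x_L)^2 + (pts[, 2] - params$inlet_length)^2)
  if (i0 > 1L) {
    n <- nrow(pts)
    ord <- c(i0:n, 1:(i0 - 1L))
    pts <- pts[ord, , drop = FALSE]
    tags <- tags[ord]
  }
  if (!polygon_is_simple(pts))
    stop("geometry error: constructed boundary polyline self-intersects")

  geom <- structure(list(
    model_id = model_id, params = params,
    poly = list(xy = pts, tag = tags),
    aosa = params$aosa,
    outlet_extension = list(length = params$outlet_length,
                            width = params$outlet_width),
    inlet_extension = list(length = params$inlet_length,
                           width = params$inlet_width),
    lesion = if (!is.null(lesion)) c(lesion$meta,
                                     list(spec = list(
                                       length = params$lesion_length,
                                       thickness = params$lesion_thickness,
                                       protrusion_depth = lesion$meta$protrusion,
                                       attachment_arc_position = params$lesion_attach_s,
                                       root_fillet_radius = params$lesion_fillet))) else NULL,
    crest_point = C, junction_point = J,
    lvot_axis = a, lvot_normal = nh, channel_length = chan_len,
    sites = NULL, septal = NULL
  ), class = "lvot_geometry")
  geom$septal <- .septal_arc(geom)
  crest <- locate_septal_crest(geom)
  geom$sites <- tryCatch(define_sites(geom, crest), error = function(e) NULL)
  geom
}

# Extract the contiguous septal-wall path (vertices + arc coordinates).
# Lesion-tagged vertices interrupt the straight channel wall in DSS-LV; for
# arc-coordinate purposes the septal path is taken along the *wall line*
# (lesion footprint included as wall arc length).
.septal_arc <- function(geom) {
  tg <- geom$poly$tag; xy <- geom$poly$xy
  n <- nrow(xy)
  seg_is <- tg %in% c("septal_wall", "lesion")
  idx <- which(seg_is)
  if (length(idx) == 0) stop("geometry error: no septal wall tagged")
  # vertices on the path: start vertex of each tagged segment + final end
  # (tagged run is contiguous by construction)
  run <- idx
  if (any(diff(run) != 1L))
    stop("geometry error: septal wall tag is not contiguous")
  vidx <- c(run, run[length(run)] %% n + 1L)
  pts <- xy[vidx, , drop = FALSE]
  # Arc coordinate: cumulative along the chamber portion up to the crest;
  # beyond the crest the wall-line projection is used so that the lesion
  # outline (DSS-LV) does not inflate the septal arc coordinate.
  C <- geom$crest_point; a <- geom$lvot_axis
  s_pr <- (pts[, 1] - C[1]) * a[1] + (pts[, 2] - C[2]) * a[2]
  dl <- sqrt(rowSums(diff(pts)^2))
  s_cum <- c(0, cumsum(dl))
  icrest <- which.min((pts[, 1] - C[1])^2 + (pts[, 2] - C[2])^2)
  crest_s <- s_cum[icrest]
  s <- ifelse(s_pr > 1e-9, crest_s + s_pr, s_cum)
  list(vidx = vidx, pts = pts, s = s, crest_vertex = icrest,
       crest_s = crest_s, tag = c(tg[run], tg[run[length(run)]]))
}

#' Locate the septal crest
#'
#' Scans the septal wall polyline for the maximum of the discrete signed
#' curvature (exterior turning angle at each vertex divided by the mean
#' adjacent segment length; positive where the wall turns into the LVOT).
#' For a contiguous run of equal maxima (e.g. a circular arc) the run's arc
#' midpoint is returned; for several separated equal maxima the most
#' LVOT-ward run wins (documented tie-break).
#'
#' @param geometry an `lvot_geometry`, or a list with `pts` (n x 2) and
#'   optionally `s` for standalone polyline use.
#' @param curvature_threshold minimum curvature (1/mm) for crest detection.
#' @return arc-length coordinate (mm) of the crest on the septal path.
#' @export
locate_septal_crest <- function(geometry, curvature_threshold = 0.02) {
  if (inherits(geometry, "lvot_geometry")) {
    # exclude lesion vertices: crest detection works on the wall proper
    sep <- geometry$septal
    keep <- sep$tag != "lesion"
    pts <- sep$pts[keep, , drop = FALSE]
    s <- sep$s[keep]
  } else {
    pts <- geometry$pts
    s <- if (!is.null(geometry$s)) geometry$s
         else c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  }
  n <- nrow(pts)
  if (n < 3) stop("crest-not-found error: septal wall too short")
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1L)) {
    u <- pts[i, ] - pts[i - 1L, ]; v <- pts[i + 1L, ] - pts[i, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    cross <- u[1] * v[2] - u[2] * v[1]
    dot <- sum(u * v)
    ang <- atan2(cross, dot)              # signed exterior turning angle
    kappa[i] <- ang / ((lu + lv) / 2)
  }
  # sign convention: with counterclockwise boundary ordering and arc running
  # apex->LVOT, the crest corner turns toward the lumen; use the magnitude of
  # the dominant sign
  kmax <- max(kappa, na.rm = TRUE); kmin <- min(kappa, na.rm = TRUE)
  ksig <- if (abs(kmin) > kmax) -kappa else kappa
  km <- max(ksig, na.rm = TRUE)
  if (!is.finite(km) || km < curvature_threshold)
    stop("crest-not-found error: no curvature maximum above threshold")
  tol <- 1e-6 * max(1, abs(km))
  at_max <- which(!is.na(ksig) & ksig >= km - tol)
  runs <- split(at_max, cumsum(c(1, diff(at_max) != 1L)))
  run <- runs[[length(runs)]]             # most LVOT-ward run
  (s[run[1]] + s[run[length(run)]]) / 2
}

#' Define the three 2-mm septal wall shear characterization sites
#'
#' Site 2 is centred on the septal crest; site 1 sits immediately LVOT-ward,
#' site 3 immediately apex-ward.  Arc coordinates increase toward the LVOT.
#'
#' @param geometry an `lvot_geometry`.
#' @param crest crest arc coordinate (mm), e.g. from [locate_septal_crest()].
#' @param width site window arc length (mm, default 2).
#' @return list of three site windows `list(site_id, arc_start, arc_end)`,
#'   ordered site 1, 2, 3.
#' @export
define_sites <- function(geometry, crest, width = 2) {
  smax <- max(geometry$septal$s)
  h <- width / 2
  if (crest - 3 * h < -1e-9 || crest + 3 * h > smax + 1e-9)
    stop("site error: crest within ", 3 * h, " mm of septal-wall end")
  mk <- function(id, s0, s1) list(site_id = id, arc_start = s0, arc_end = s1)
  list(mk(1L, crest + h, crest + 3 * h),
       mk(2L, crest - h, crest + h),
       mk(3L, crest - 3 * h, crest - h))
}

#' Measure the aortoseptal angle of a built geometry
#'
#' Angle at the septal crest between the apex-ward septal wall direction and
#' the outflow-ward LVOT channel direction, measured from the polyline
#' segments adjacent to the crest vertex.
#'
#' @param geometry an `lvot_geometry`.
#' @return angle in degrees.
#' @export
measure_aosa <- function(geometry) {
  sep <- geometry$septal
  keep <- sep$tag != "lesion"
  pts <- sep$pts[keep, , drop = FALSE]
  s <- sep$s[keep]
  cr <- sep$crest_s
  Rf <- geometry$params$crest_fillet
  d_tan <- if (Rf > 0) Rf / tan(geometry$aosa * pi / 360) else 0
  # wall directions from chords beyond the blending fillet
  pick <- function(starget) which.min(abs(s - starget))
  iA1 <- pick(cr - d_tan - 0.5); iA2 <- pick(cr - d_tan - 3)
  iB1 <- pick(cr + d_tan + 0.5); iB2 <- pick(cr + d_tan + 3)
  if (iA1 == iA2 || iB1 == iB2) stop("crest vertex at septal path end")
  u <- pts[iA2, ] - pts[iA1, ]            # apex-ward
  v <- pts[iB2, ] - pts[iB1, ]            # outflow-ward
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Minimum luminal width of the LVOT channel
#'
#' Perpendicular distance between the anterior channel wall and the most
#' protruding boundary point on the septal side (lesion tip for DSS-LV).
#'
#' @param geometry an `lvot_geometry`.
#' @return minimum lumen width (mm).
#' @export
min_lumen_width <- function(geometry) {
  C <- geometry$crest_point; a <- geometry$lvot_axis; nh <- geometry$lvot_normal
  xy <- geometry$poly$xy
  tg <- geometry$poly$tag
  s <- (xy[, 1] - C[1]) * a[1] + (xy[, 2] - C[2]) * a[2]
  d <- (xy[, 1] - C[1]) * nh[1] + (xy[, 2] - C[2]) * nh[2]
  w <- geometry$outlet_extension$width
  # septal-side boundary vertices within the channel span
  n <- length(tg)
  prev_tag <- tg[c(n, 1:(n - 1L))]     # tag of segment ending at vertex i
  on_sep <- (tg %in% c("septal_wall", "lesion")) |
            (prev_tag %in% c("septal_wall", "lesion"))
  insp <- on_sep & s > 1e-9 & s < geometry$channel_length - 1e-9 & d < w / 2
  if (!any(insp)) return(w)
  w - max(d[insp])
}

#' @export
print.lvot_geometry <- function(x, ...) {
  cat("lvot_geometry:", x$model_id, "\n")
  cat("  AoSA (requested/measured):", x$aosa, "/",
      round(measure_aosa(x), 2), "deg\n")
  cat("  boundary vertices:", nrow(x$poly$xy),
      " area:", round(polygon_area(x$poly$xy), 1), "mm^2\n")
  if (!is.null(x$lesion))
    cat("  lesion: L =", x$lesion$length, "mm, t =", x$lesion$thickness,
        "mm, protrusion =", round(x$lesion$protrusion, 2), "mm\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Geometry I/O
# ---------------------------------------------------------------------------

#' Write geometry to JSON (parameter form)
#' @param geometry an `lvot_geometry`.
#' @param path output file.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(list(model_id = geometry$model_id,
                            params = geometry$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read geometry from JSON (parameter form); rebuilds the polyline.
#' @param path JSON file written by [write_geometry_json()].
#' @return an `lvot_geometry`.
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_geometry(obj$model_id, params = obj$params)
}

#' Write the boundary polyline as CSV (s, x1, x2, tag)
#' @param geometry an `lvot_geometry`.
#' @param path output file.
#' @export
write_geometry_csv <- function(geometry, path) {
  xy <- geometry$poly$xy
  sarc <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  df <- data.frame(s = sarc, x1 = xy[, 1], x2 = xy[, 2],
                   tag = geometry$poly$tag)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
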
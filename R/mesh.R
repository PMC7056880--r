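# ---------------------------------------------------------------------------
# Unstructured triangular mesh generation on a tagged polygon.
#
# Strategy: resample the tagged boundary chains at the target spacing, add an
# optional single offset row at `first_layer` inside no-slip walls (wall
# refinement for shear prediction), fill the interior with a hexagonal point
# lattice at the bulk cell size, triangulate everything with a deterministic
# Bowyer-Watson Delaunay, and keep triangles whose centroid falls inside the
# polygon.  Boundary edge recovery is verified, not assumed.
# ---------------------------------------------------------------------------

.wall_tags <- c("lv_wall", "septal_wall", "lesion", "wall")
.open_tags <- c("inlet", "outlet")

# resample a polyline chain (k x 2) at spacing <= h, keeping endpoints
.resample_chain <- function(pts, h) {
  dl <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, dl > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) return(pts)
  dl <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(dl))
  stot <- s[length(s)]
  n <- max(1L, ceiling(stot / h))
  so <- seq(0, stot, length.out = n + 1L)
  cbind(approx(s, pts[, 1], xout = so)$y, approx(s, pts[, 2], xout = so)$y)
}

#' Mesh a tagged polygon with triangles
#'
#' Low-level mesher used by [generate_mesh()] and directly by solver
#' verification cases.
#'
#' @param poly n x 2 boundary polygon (counterclockwise, mm).
#' @param tags length-n character vector: tag of the segment starting at each
#'   vertex (`wall`-like tags get the offset row; `inlet`/`outlet` are open).
#' @param cell_size bulk target cell size (mm).
#' @param first_layer wall offset-row distance (mm); `NULL` for
#'   `cell_size / 3`, `0` to disable.
#' @param lesion_spacing boundary spacing used on `lesion`-tagged chains (mm).
#' @return an `lvot_mesh` (coordinates in metres): nodes, triangles, face
#'   connectivity with tags, boundary loop bookkeeping and quality metrics.
#' @export
mesh_polygon <- function(poly, tags, cell_size, first_layer = NULL,
                         lesion_spacing = NULL, resample = TRUE) {
  stopifnot(nrow(poly) == length(tags))
  if (is.null(first_layer)) first_layer <- cell_size / 3
  if (is.null(lesion_spacing)) lesion_spacing <- min(cell_size, 0.45)
  n <- nrow(poly)
  if (resample) {
    # split boundary into maximal constant-tag chains (cyclic)
    brk <- which(tags != tags[c(n, 1:(n - 1L))])   # chain starts
    if (length(brk) == 0) brk <- 1L
    brk <- sort(brk)
    chains <- list()
    for (i in seq_along(brk)) {
      i0 <- brk[i]
      i1 <- if (i < length(brk)) brk[i + 1L] else brk[1L] + n
      idx <- ((i0:(i1)) - 1L) %% n + 1L           # includes both endpoints
      chains[[i]] <- list(pts = poly[idx, , drop = FALSE], tag = tags[i0])
    }
    # resample chains; concatenate boundary loop (drop duplicated joints)
    bpts <- NULL; btag <- character(0); bchain <- integer(0)
    for (ci in seq_along(chains)) {
      h <- if (chains[[ci]]$tag == "lesion") lesion_spacing else cell_size
      rp <- .resample_chain(chains[[ci]]$pts, h)
      rp <- rp[-nrow(rp), , drop = FALSE]         # endpoint = next chain start
      bpts <- rbind(bpts, rp)
      btag <- c(btag, rep(chains[[ci]]$tag, nrow(rp)))
      bchain <- c(bchain, rep(ci, nrow(rp)))
    }
  } else {
    # keep the supplied vertices as boundary nodes (remeshing path:
    # node-for-node binding carry-over)
    bpts <- poly; btag <- tags; bchain <- rep(1L, n)
  }
  nb <- nrow(bpts)
  if (nb < 8) stop("meshing failure: degenerate boundary (", nb, " nodes)")
  # offset row inside no-slip walls
  off <- NULL
  if (first_layer > 0) {
    nxt <- c(2:nb, 1L); prv <- c(nb, 1:(nb - 1L))
    e1 <- bpts - bpts[prv, , drop = FALSE]
    e2 <- bpts[nxt, , drop = FALSE] - bpts
    nrm <- function(e) {
      l <- sqrt(rowSums(e^2)); l[l == 0] <- 1
      cbind(-e[, 2], e[, 1]) / l                  # inward for CCW boundary
    }
    nn <- nrm(e1) + nrm(e2)
    l <- sqrt(rowSums(nn^2)); l[l == 0] <- 1
    nn <- nn / l
    iswall <- btag %in% .wall_tags
    cand <- bpts[iswall, , drop = FALSE] + first_layer * nn[iswall, , drop = FALSE]
    ok <- points_in_polygon_cpp(cand, bpts) &
      dist_to_polyline_cpp(cand, bpts) > 0.7 * first_layer
    off <- cand[ok, , drop = FALSE]
    # greedy dedupe: offsets from concave stretches (e.g. the rounded lesion
    # tip) can converge onto nearly the same point
    if (nrow(off) > 1) {
      keep <- rep(TRUE, nrow(off))
      for (i in 2:nrow(off)) {
        prev <- which(keep[seq_len(i - 1L)])
        if (length(prev) > 0) {
          d2 <- (off[prev, 1] - off[i, 1])^2 + (off[prev, 2] - off[i, 2])^2
          if (min(d2) < (0.55 * first_layer)^2) keep[i] <- FALSE
        }
      }
      off <- off[keep, , drop = FALSE]
    }
  }
  # hexagonal interior lattice
  h <- cell_size
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  ys <- seq(yr[1] + 0.4 * h, yr[2] - 0.2 * h, by = h * sqrt(3) / 2)
  lat <- NULL
  for (i in seq_along(ys)) {
    xs <- seq(xr[1] + 0.3 * h + (i %% 2) * h / 2, xr[2] - 0.2 * h, by = h)
    lat <- rbind(lat, cbind(xs, ys[i]))
  }
  clearance <- if (first_layer > 0) max(0.7 * h, first_layer + 0.5 * h)
               else 0.7 * h
  ok <- points_in_polygon_cpp(lat, bpts) &
    dist_to_polyline_cpp(lat, bpts) > clearance
  lat <- lat[ok, , drop = FALSE]
  if (!is.null(off) && nrow(off) > 0 && nrow(lat) > 0) {
    # avoid lattice points crowding the offset row
    keep <- rep(TRUE, nrow(lat))
    d <- dist_to_polyline_cpp(lat, bpts)
    keep <- d > first_layer + 0.45 * h
    lat <- lat[keep, , drop = FALSE]
  }
  allpts <- rbind(bpts, off, lat)
  pkind <- c(rep(0L, nb), rep(1L, if (is.null(off)) 0 else nrow(off)),
             rep(2L, if (is.null(lat)) 0 else nrow(lat)))
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  bseq <- ekey(seq_len(nb), c(2:nb, 1L))
  tris <- NULL
  for (attempt in 1:8) {
    tris <- delaunay_cpp(allpts) + 1L             # 1-based
    cen <- (allpts[tris[, 1], ] + allpts[tris[, 2], ] + allpts[tris[, 3], ]) / 3
    inside <- points_in_polygon_cpp(cen, bpts)
    tris <- tris[inside, , drop = FALSE]
    if (nrow(tris) < 1) stop("meshing failure: no interior triangles")
    eset <- unique(c(ekey(tris[, 1], tris[, 2]), ekey(tris[, 2], tris[, 3]),
                     ekey(tris[, 3], tris[, 1])))
    missing <- which(!(bseq %in% eset))
    if (length(missing) == 0) break
    # drop interior points encroaching the diametral circles of missing edges
    drop <- integer(0)
    for (i in missing) {
      j <- (i %% nb) + 1L
      cmid <- (bpts[i, ] + bpts[j, ]) / 2
      r2 <- sum((bpts[j, ] - bpts[i, ])^2) / 4
      ii <- (nb + 1L):nrow(allpts)
      d2 <- (allpts[ii, 1] - cmid[1])^2 + (allpts[ii, 2] - cmid[2])^2
      drop <- c(drop, ii[d2 < r2 * (1.2 + 0.35 * attempt)])
    }
    drop <- unique(drop)
    if (length(drop) == 0)
      stop("meshing failure: ", length(missing),
           " boundary edges not recovered; adjust cell sizes")
    allpts <- allpts[-drop, , drop = FALSE]
    pkind <- pkind[-drop]
  }
  if (length(missing) > 0)
    stop("meshing failure: ", length(missing),
         " boundary edges not recovered; adjust cell sizes")

  # face connectivity: owner keeps its CCW directed edge
  m <- nrow(tris)
  ed <- rbind(cbind(tris[, 1], tris[, 2], seq_len(m)),
              cbind(tris[, 2], tris[, 3], seq_len(m)),
              cbind(tris[, 3], tris[, 1], seq_len(m)))
  key <- ekey(ed[, 1], ed[, 2])
  first <- !duplicated(key)
  fidx <- match(key, key[first])
  nf <- sum(first)
  face_n1 <- ed[first, 1]; face_n2 <- ed[first, 2]
  face_owner <- ed[first, 3]
  face_neigh <- integer(nf)
  dupe <- which(!first)
  face_neigh[fidx[dupe]] <- ed[dupe, 3]
  # boundary faces: tag from the boundary segment (n1 -> n2 consecutive)
  face_tag <- rep("interior", nf)
  bnd <- face_neigh == 0L
  for (i in which(bnd)) {
    a <- face_n1[i]; b <- face_n2[i]
    if (a > nb || b > nb)
      stop("meshing failure: boundary face with interior node")
    # segment index: the one starting at min position in cyclic order
    if ((a %% nb) + 1L == b) face_tag[i] <- btag[a]
    else if ((b %% nb) + 1L == a) face_tag[i] <- btag[b]
    else stop("meshing failure: boundary face skips boundary nodes")
  }
  area <- 0.5 * ((allpts[tris[, 2], 1] - allpts[tris[, 1], 1]) *
                 (allpts[tris[, 3], 2] - allpts[tris[, 1], 2]) -
                 (allpts[tris[, 2], 2] - allpts[tris[, 1], 2]) *
                 (allpts[tris[, 3], 1] - allpts[tris[, 1], 1]))
  if (any(area <= 0)) stop("meshing failure: non-positive triangle area")

  # wall distance per cell (for turbulence closure and diagnostics)
  wallpts <- bpts[btag %in% .wall_tags, , drop = FALSE]
  wd <- if (nrow(wallpts) > 1)
    dist_to_polyline_cpp(cen[inside, , drop = FALSE], wallpts, closed = FALSE)
  else rep(1e9, nrow(tris))

  structure(list(
    nodes = allpts / 1000,                        # metres
    tris = tris,
    n_boundary = nb,
    boundary_tag = btag,
    boundary_chain = bchain,
    face_nodes = cbind(face_n1, face_n2),
    face_owner = face_owner, face_neigh = face_neigh,
    face_tag = face_tag,
    cell_area = area / 1e6,                       # m^2
    cell_centroid = cen[inside, , drop = FALSE] / 1000,
    wall_dist = wd / 1000,
    cell_size = cell_size / 1000,
    first_layer = first_layer / 1000,
    n_offset = sum(pkind == 1L)
  ), class = "lvot_mesh")
}

#' Generate the fluid mesh for an LV geometry
#'
#' @param geometry an `lvot_geometry`.
#' @param cell_size bulk cell size in metres (default 1 mm, desk scale; the
#'   study-scale configuration uses 175 um).
#' @param first_layer wall offset-row distance in metres (`NULL`:
#'   `cell_size / 3`).
#' @param contour optional `contour_sequence`; when supplied, the moving
#'   chamber boundary is meshed on the frame-1 contour polyline and each node
#'   is bound to its normalized contour arc position so the solver can follow
#'   the motion.
#' @return an `lvot_mesh` with motion binding metadata.
#' @export
generate_mesh <- function(geometry, cell_size = 1e-3, first_layer = NULL,
                          contour = NULL) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (!is.null(first_layer)) {
    if (first_layer <= 0) stop("first_layer must be positive")
    if (first_layer > cell_size) stop("first_layer must be <= cell_size")
  }
  h_mm <- cell_size * 1000
  fl_mm <- if (is.null(first_layer)) NULL else first_layer * 1000
  if (is.null(contour)) contour <- generate_contours(geometry)
  # boundary polygon: moving contour (L -> apex -> C) + rigid closure,
  # with tags walked from the geometry polyline
  mov <- contour$nodes[1, , ]
  closure <- contour$closure
  # tags for the moving portion: septal near the crest end, lv_wall elsewhere
  sep_len <- geometry$params$septal_tag_length
  arc <- c(0, cumsum(sqrt(rowSums(diff(mov)^2))))
  mov_tag <- ifelse(max(arc) - arc < sep_len - 1e-9, "septal_wall", "lv_wall")
  # closure tags: match each closure vertex to the geometry polyline tag
  gxy <- geometry$poly$xy; gtg <- geometry$poly$tag
  cl_tag <- character(nrow(closure))
  for (i in seq_len(nrow(closure))) {
    j <- which.min((gxy[, 1] - closure[i, 1])^2 + (gxy[, 2] - closure[i, 2])^2)
    cl_tag[i] <- gtg[j]
  }
  # the contour runs L -> apex -> crest; closure continues from the crest's
  # outgoing channel segment (septal wall) back to just before L
  poly <- rbind(mov, closure)
  tags <- c(mov_tag[-length(mov_tag)], "septal_wall", cl_tag)
  stopifnot(length(tags) == nrow(poly))
  mesh <- mesh_polygon(poly, tags, h_mm, fl_mm)

  # motion binding: boundary nodes on the moving portion get the normalized
  # contour arc parameter sigma; all other boundary nodes are rigid (lesion
  # nodes are identified for the FSI coupling)
  nb <- mesh$n_boundary
  bxy <- mesh$nodes[seq_len(nb), , drop = FALSE] * 1000
  stot <- max(arc)
  btype <- integer(nb)                    # 0 rigid
  sigma <- rep(NA_real_, nb)
  mov_seg <- rep(NA_integer_, nb)         # contour segment of each node
  mov_lambda <- rep(NA_real_, nb)         # fraction along that segment
  d_mov <- dist_to_polyline_cpp(bxy, mov, closed = FALSE)
  on_mov <- d_mov < 1e-6
  for (i in which(on_mov)) {
    p <- bxy[i, ]
    best <- Inf; sbest <- 0; jbest <- 1L; tbest <- 0
    for (j in seq_len(nrow(mov) - 1L)) {
      a <- mov[j, ]; b <- mov[j + 1L, ]
      ab <- b - a; L2 <- sum(ab^2)
      t <- if (L2 > 0) min(1, max(0, sum((p - a) * ab) / L2)) else 0
      q <- a + t * ab
      d2 <- sum((p - q)^2)
      if (d2 < best) { best <- d2; sbest <- arc[j] + t * sqrt(L2)
                       jbest <- j; tbest <- t }
    }
    btype[i] <- 2L
    sigma[i] <- sbest / stot
    mov_seg[i] <- jbest
    mov_lambda[i] <- tbest
  }
  btype[mesh$boundary_tag == "lesion"] <- 3L
  # boundary faces on the septal wall: arc coordinate (mm) for site windows
  nf <- length(mesh$face_tag)
  s_face <- rep(NA_real_, nf)
  sep <- geometry$septal
  C <- geometry$crest_point; a_ax <- geometry$lvot_axis
  for (i in which(mesh$face_tag == "septal_wall")) {
    midp <- (mesh$nodes[mesh$face_nodes[i, 1], ] +
             mesh$nodes[mesh$face_nodes[i, 2], ]) / 2 * 1000
    pr <- sum((midp - C) * a_ax)
    if (pr > 0) s_face[i] <- sep$crest_s + pr
    else {
      # distance along the septal path below the crest (straight wall)
      s_face[i] <- sep$crest_s - sqrt(sum((midp - C)^2))
    }
  }
  mesh$btype <- btype
  mesh$sigma <- sigma
  mesh$mov_seg <- mov_seg
  mesh$mov_lambda <- mov_lambda
  mesh$s_face <- s_face
  mesh$geometry <- geometry
  mesh$contour_nodes <- contour$n_nodes
  mesh
}

#' @export
print.lvot_mesh <- function(x, ...) {
  cat("lvot_mesh:", nrow(x$nodes), "nodes,", nrow(x$tris), "cells,",
      length(x$face_tag), "faces\n")
  cat("  cell size:", x$cell_size * 1000, "mm; first layer:",
      signif(x$first_layer * 1000, 3), "mm; boundary nodes:", x$n_boundary, "\n")
  invisible(x)
}
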
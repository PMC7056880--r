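# ---------------------------------------------------------------------------
# Synthetic cyclic LV wall motion.
#
# The study's MRI-segmented wall motion is not deposited; this module stands
# in for it with a parametric, seeded generator.  The moving portion of the
# boundary is the chamber wall between the two basal corners (below the
# LVOT); inlet/outlet channels are rigid.  Nodes move along rays through a
# contraction centre with a smooth basal taper, driven by a piecewise
# raised-cosine waveform with an E-wave, diastasis, A-wave (0 - 0.480 s) and
# systolic ejection (0.480 - 0.772 s).
# ---------------------------------------------------------------------------

#' Default wall-motion parameters
#'
#' @param efa ejection-fraction analog: fractional reduction of the 2D
#'   chamber area from end diastole to end systole (default 0.5).
#' @param ea_ratio ratio of the E-wave to A-wave peak area-rate (default 1.7,
#'   a normal adult transmitral pattern).
#' @param t_e end of the E-wave (s).
#' @param t_a0 start of the A-wave (s); diastasis spans `[t_e, t_a0]`.
#' @param phase_split diastole to systole transition time (s).
#' @param period cardiac period (s).
#' @param noise_amp amplitude (mm) of optional smooth cyclic perturbation
#'   noise; 0 (default) keeps the generator fully deterministic.
#' @return named list of motion parameters.
#' @export
motion_params <- function(efa = 0.5, ea_ratio = 1.7, t_e = 0.25, t_a0 = 0.37,
                          phase_split = 0.480, period = 0.772,
                          noise_amp = 0) {
  list(efa = efa, ea_ratio = ea_ratio, t_e = t_e, t_a0 = t_a0,
       phase_split = phase_split, period = period, noise_amp = noise_amp)
}

# raised-cosine smoothstep on [0, 1]
.rc <- function(x) (1 - cos(pi * pmin(1, pmax(0, x)))) / 2

# scale waveform m(t): 0 at end systole (t = 0 and t = period), rising
# through E and A waves, falling through ejection; C1 everywhere
.m_wave <- function(t, m_e, m_max, p) {
  t <- t %% p$period
  out <- numeric(length(t))
  iE <- t < p$t_e
  iD <- t >= p$t_e & t < p$t_a0
  iA <- t >= p$t_a0 & t < p$phase_split
  iS <- t >= p$phase_split
  out[iE] <- m_e * .rc(t[iE] / p$t_e)
  out[iD] <- m_e
  out[iA] <- m_e + (m_max - m_e) * .rc((t[iA] - p$t_a0) / (p$phase_split - p$t_a0))
  out[iS] <- m_max * (1 - .rc((t[iS] - p$phase_split) / (p$period - p$phase_split)))
  out
}

# moving-portion vertex indices of a geometry polyline: the run from the
# left basal corner (x_L, 0) to the crest through the apex
.moving_run <- function(geometry) {
  xy <- geometry$poly$xy
  x_L <- geometry$params$junction_x - geometry$params$inlet_width
  iL <- which.min((xy[, 1] - x_L)^2 + xy[, 2]^2)
  C <- geometry$crest_point
  iC <- which.min((xy[, 1] - C[1])^2 + (xy[, 2] - C[2])^2)
  i0 <- min(iL, iC); i1 <- max(iL, iC)
  run_in <- i0:i1
  if (min(xy[run_in, 2]) < -1e-6) run_in
  else c(i1:nrow(xy), 1:i0)   # complement run holds the apex
}

#' Generate a synthetic contour sequence
#'
#' Produces `n_frames` cyclic frames of `n_nodes` wall-node positions over
#' one cardiac cycle.  Frame 1 (t = 0) is the end-systolic outline of the
#' geometry; the area waveform has an E and an A filling peak in
#' `(0, phase_split)` and monotone ejection afterwards.  Only chamber nodes
#' below the LVOT move.
#'
#' @param geometry an `lvot_geometry`.
#' @param motion_params list from [motion_params()].
#' @param n_frames number of frames over one cycle (>= 8; default 29).
#' @param n_nodes nodes per contour (default 80).
#' @param seed integer seed for the optional perturbation noise.
#' @return an object of class `contour_sequence` with fields `times`,
#'   `nodes` (F x N x 2 array, mm), `period`, `phase_split`, `closure`
#'   (rigid remainder of the boundary, mm) and generator metadata.
#' @export
generate_contours <- function(geometry, motion_params = NULL,
                              n_frames = 29L, n_nodes = 80L, seed = 1L) {
  p <- if (is.null(motion_params)) lvotflow::motion_params() else motion_params
  if (n_frames < 8) stop("motion error: n_frames must be >= 8")
  if (p$efa < 0 || p$efa >= 0.8)
    stop("motion error: ejection-fraction analog must lie in [0, 0.8)")
  run <- .moving_run(geometry)
  xy <- geometry$poly$xy
  mov <- xy[run, , drop = FALSE]
  # moving run ordered from left basal corner to crest (through the apex)
  if (mov[1, 1] > mov[nrow(mov), 1]) mov <- mov[nrow(mov):1, , drop = FALSE]
  # closure: rigid boundary from crest around the channels back to the left
  # basal corner (complement of the moving run, in boundary order)
  nall <- nrow(xy)
  comp <- setdiff(seq_len(nall), run[-c(1, length(run))])
  # order complement starting at crest vertex going forward (boundary is CCW)
  iC <- which.min((xy[comp, 1] - geometry$crest_point[1])^2 +
                  (xy[comp, 2] - geometry$crest_point[2])^2)
  closure <- xy[c(comp[iC:length(comp)], comp[seq_len(iC - 1L)]), , drop = FALSE]
  # drop the crest and left-corner endpoints (they belong to the contour)
  closure <- closure[-c(1L, nrow(closure)), , drop = FALSE]

  # resample the moving run at n_nodes uniform arc stations
  dl <- sqrt(rowSums(diff(mov)^2))
  sarc <- c(0, cumsum(dl))
  stot <- sarc[length(sarc)]
  sigma <- seq(0, 1, length.out = n_nodes)
  ref <- cbind(approx(sarc, mov[, 1], xout = sigma * stot)$y,
               approx(sarc, mov[, 2], xout = sigma * stot)$y)

  centre <- c((geometry$params$crest_x + geometry$params$junction_x -
               geometry$params$inlet_width) / 2,
              -0.45 * geometry$params$chamber_depth)
  w <- sin(pi * sigma)^2                  # basal taper, 0 at both corners
  rays <- sweep(ref, 2, centre)           # node-specific radial directions

  area_of <- function(m) {
    nodes <- sweep(rays * (1 + m * w), 2, centre, "+")
    polygon_area(rbind(nodes, closure))
  }
  A_es <- area_of(0)
  if (p$efa == 0) {
    m_max <- 0
  } else {
    target <- A_es / (1 - p$efa)
    m_max <- uniroot(function(m) area_of(m) - target, c(0, 2),
                     tol = 1e-10)$root
  }
  # E/A amplitude split from the peak area-rate ratio; one fixed-point
  # refinement accounts for dA/dm growing with chamber size
  r <- p$ea_ratio
  dur_A <- p$phase_split - p$t_a0
  m_e <- m_max * r * p$t_e / (dur_A + r * p$t_e)
  if (m_max > 0) {
    dAdm <- function(m) (area_of(m + 1e-6) - area_of(m)) / 1e-6
    for (it in 1:2) {
      g_E <- dAdm(m_e / 2); g_A <- dAdm((m_e + m_max) / 2)
      r_eff <- r * g_A / g_E
      m_e <- m_max * r_eff * p$t_e / (dur_A + r_eff * p$t_e)
    }
  }

  times <- (seq_len(n_frames) - 1L) / n_frames * p$period
  mvals <- .m_wave(times, m_e, m_max, p)

  # optional smooth seeded perturbation: low-order space-time Fourier modes
  noise <- NULL
  if (p$noise_amp > 0) {
    set.seed(seed)
    nk <- 3L; nhar <- 2L
    cf <- array(stats::rnorm(nk * nhar * 2), dim = c(nk, nhar, 2))
    noise <- function(tt) {
      d <- numeric(n_nodes)
      for (k in seq_len(nk)) for (h in seq_len(nhar)) {
        d <- d + sin(k * pi * sigma) *
          (cf[k, h, 1] * cos(2 * pi * h * tt / p$period) +
           cf[k, h, 2] * sin(2 * pi * h * tt / p$period))
      }
      p$noise_amp * w * d / sqrt(nk * nhar)
    }
  }

  nodes <- array(0, dim = c(n_frames, n_nodes, 2))
  rhat <- rays / pmax(sqrt(rowSums(rays^2)), 1e-12)
  for (f in seq_len(n_frames)) {
    pos <- sweep(rays * (1 + mvals[f] * w), 2, centre, "+")
    if (!is.null(noise)) pos <- pos + rhat * noise(times[f])
    nodes[f, , ] <- pos
    if (polygon_area(rbind(pos, closure)) <= 0)
      stop("motion error: non-positive enclosed area at frame ", f)
  }

  structure(list(times = times, nodes = nodes, period = p$period,
                 phase_split = p$phase_split, n_frames = n_frames,
                 n_nodes = n_nodes, closure = closure, sigma = sigma,
                 motion_params = p, seed = seed,
                 model_id = geometry$model_id),
            class = "contour_sequence")
}

#' Temporal spline interpolation of a contour sequence
#'
#' Fits a periodic cubic spline in time through every node coordinate and
#' inserts `n_intermediate` uniformly spaced samples between consecutive
#' frames.  Original frame positions are reproduced exactly.
#'
#' @param cs a `contour_sequence`.
#' @param n_intermediate intermediate positions per inter-frame interval
#'   (>= 0; the study design corresponds to 60).
#' @return a `contour_sequence` on the refined time grid; the achieved
#'   temporal resolution is recorded in `$dt`.
#' @export
interpolate_contours <- function(cs, n_intermediate = 60L) {
  stopifnot(inherits(cs, "contour_sequence"), n_intermediate >= 0)
  if (n_intermediate == 0L) {
    cs$dt <- cs$period / cs$n_frames
    return(cs)
  }
  F0 <- cs$n_frames; N <- cs$n_nodes
  k <- n_intermediate + 1L
  Fn <- F0 * k
  tnew <- (seq_len(Fn) - 1L) / Fn * cs$period
  tknot <- c(cs$times, cs$period)
  out <- array(0, dim = c(Fn, N, 2))
  for (j in seq_len(N)) for (d in 1:2) {
    y <- cs$nodes[, j, d]
    sf <- splinefun(tknot, c(y, y[1]), method = "periodic")
    out[, j, d] <- sf(tnew)
  }
  cs$nodes <- out
  cs$times <- tnew
  cs$n_frames <- Fn
  cs$dt <- cs$period / Fn
  cs$interpolated <- TRUE
  cs
}

#' Continuous-time evaluator for a contour sequence
#'
#' Returns a function `f(t)` giving the N x 2 node positions at arbitrary
#' times (periodic cubic spline through the frames), plus a vectorized
#' `f_all(tvec)` evaluator used by the solver.
#'
#' @param cs a `contour_sequence`.
#' @return list with elements `at` (function of scalar t) and `at_times`
#'   (function of a time vector, returning a length(t) x N x 2 array).
#' @export
contour_spline <- function(cs) {
  tknot <- c(cs$times, cs$period)
  N <- cs$n_nodes
  sfs <- vector("list", 2L * N)
  for (j in seq_len(N)) for (d in 1:2) {
    y <- cs$nodes[, j, d]
    sfs[[(d - 1L) * N + j]] <- splinefun(tknot, c(y, y[1]),
                                         method = "periodic")
  }
  at_times <- function(tv) {
    tv <- tv %% cs$period
    out <- array(0, dim = c(length(tv), N, 2))
    for (j in seq_len(N)) for (d in 1:2)
      out[, j, d] <- sfs[[(d - 1L) * N + j]](tv)
    out
  }
  list(at = function(t) at_times(t)[1, , ], at_times = at_times)
}

#' Chamber area waveform and its time rate
#'
#' Computes the enclosed area (2D analog of LV volume) of the closed fluid
#' domain at every frame by the shoelace formula, and dA/dt by centred
#' finite differences with a periodic wrap.
#'
#' @param cs a `contour_sequence` (ideally after [interpolate_contours()]).
#' @param inlet_width,outlet_width recorded for downstream boundary-condition
#'   derivation (mm); not used in the area computation.
#' @param check_simple `"coarse"` (default, up to 64 frames), `"all"` or
#'   `"none"`: self-intersection screening of the domain polygon.
#' @return an object of class `volume_waveform`: `times` (s), `area` (mm^2),
#'   `dA_dt` (mm^2/s), `period`, `phase_split`.
#' @export
compute_area_waveform <- function(cs, inlet_width = NULL, outlet_width = NULL,
                                  check_simple = c("coarse", "all", "none")) {
  check_simple <- match.arg(check_simple)
  F <- cs$n_frames
  poly_at <- function(f) {
    if (is.null(cs$closure)) cs$nodes[f, , ] else rbind(cs$nodes[f, , ],
                                                        cs$closure)
  }
  chk <- switch(check_simple,
                none = integer(0),
                all = seq_len(F),
                coarse = unique(round(seq(1, F, length.out = min(F, 64L)))))
  for (f in chk) {
    if (!polygon_is_simple(poly_at(f)))
      stop("motion error: non-simple domain polygon at frame ", f)
  }
  area <- vapply(seq_len(F), function(f) polygon_area(poly_at(f)), 0)
  if (any(area <= 0)) stop("motion error: non-positive area")
  if (F >= 3) {
    ip <- c(F, seq_len(F - 1L)); inx <- c(seq_len(F)[-1], 1L)
    dt <- cs$period / F
    dA <- (area[inx] - area[ip]) / (2 * dt)
  } else {
    dA <- rep(0, F)
  }
  structure(list(times = cs$times, area = area, dA_dt = dA,
                 period = cs$period, phase_split = cs$phase_split,
                 inlet_width = inlet_width, outlet_width = outlet_width),
            class = "volume_waveform")
}

#' @export
print.contour_sequence <- function(x, ...) {
  cat("contour_sequence:", x$n_frames, "frames x", x$n_nodes,
      "nodes, period", x$period, "s\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Contour sequence I/O: CSV of (frame, time_s, node_id, x1_mm, x2_mm) plus a
# JSON sidecar with period, phase_split, N, F and the rigid closure.
# ---------------------------------------------------------------------------

#' Write a contour sequence (CSV + JSON sidecar)
#' @param cs a `contour_sequence`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_contours <- function(cs, path) {
  F <- cs$n_frames; N <- cs$n_nodes
  df <- data.frame(frame = rep(seq_len(F), each = N),
                   time_s = rep(cs$times, each = N),
                   node_id = rep(seq_len(N), F),
                   x1_mm = as.vector(t(cs$nodes[, , 1])),
                   x2_mm = as.vector(t(cs$nodes[, , 2])))
  write.csv(df, path, row.names = FALSE)
  side <- list(period = cs$period, phase_split = cs$phase_split,
               N = N, F = F,
               closure = if (!is.null(cs$closure)) cs$closure else NULL,
               sigma = cs$sigma, model_id = cs$model_id)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a contour sequence written by [write_contours()]
#' @param path CSV path.
#' @return a `contour_sequence`.
#' @export
read_contours <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  F <- side$F; N <- side$N
  nodes <- array(0, dim = c(F, N, 2))
  nodes[, , 1] <- matrix(df$x1_mm, nrow = F, ncol = N, byrow = TRUE)
  nodes[, , 2] <- matrix(df$x2_mm, nrow = F, ncol = N, byrow = TRUE)
  times <- df$time_s[seq(1, nrow(df), by = N)]
  structure(list(times = times, nodes = nodes, period = side$period,
                 phase_split = side$phase_split, n_frames = F, n_nodes = N,
                 closure = if (!is.null(side$closure))
                   matrix(unlist(side$closure), ncol = 2) else NULL,
                 sigma = side$sigma, model_id = side$model_id),
            class = "contour_sequence")
}
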
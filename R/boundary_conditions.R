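# ---------------------------------------------------------------------------
# Phase-switched inlet/outlet velocity schedules.
#
# Valve action is modeled exactly as a velocity switch: during diastolic
# filling (t < phase_split) the aortic outlet is a zero-velocity wall and the
# mitral inlet carries a spatially uniform (plug) velocity whose magnitude is
# the chamber area rate divided by the inlet width; during systolic ejection
# the roles swap.  A short raised-cosine ramp (default 5 ms) regularizes the
# instantaneous switch; the underlying waveform has a near-zero area rate at
# the transition, so the ramp removes only a negligible flux.
# ---------------------------------------------------------------------------

#' Derive the inlet/outlet velocity schedule from an area waveform
#'
#' @param wave a `volume_waveform` (area in mm^2, rate in mm^2/s).
#' @param inlet_width,outlet_width opening widths (mm).
#' @param phase_split diastole/systole transition time (s); defaults to the
#'   waveform's.
#' @param ramp_eps half-width (s) of the smooth ramp at phase transitions;
#'   0 disables ramping.
#' @param clip_tol fraction of the peak |dA/dt| beyond which a sign
#'   inconsistency between the area rate and the phase triggers a warning
#'   before clipping (smaller excursions are clipped silently).
#' @return an object of class `bc_schedule`: `times` (s), `phase`
#'   (`"diastole"`/`"systole"`), `u_in_m_s`, `u_out_m_s` (plug magnitudes,
#'   m/s; inlet positive into the domain, outlet positive out).
#' @export
derive_bc_schedule <- function(wave, inlet_width = 24.4, outlet_width = 18.6,
                               phase_split = NULL, ramp_eps = 0.005,
                               clip_tol = 0.05) {
  stopifnot(inherits(wave, "volume_waveform"))
  if (inlet_width <= 0 || outlet_width <= 0) stop("widths must be positive")
  if (is.null(phase_split)) phase_split <- wave$phase_split
  period <- wave$period
  if (phase_split <= 0 || phase_split >= period)
    stop("phase_split must lie inside (0, period)")
  t <- wave$times %% period
  dA <- wave$dA_dt
  dia <- t < phase_split
  peak <- max(abs(dA), 1e-300)
  # sign consistency: small counter-phase excursions (spline overshoot of the
  # frame sequence) are carried through signed so that the time-integrated
  # flux matches the area change; excursions beyond tolerance are clipped
  bad_d <- dia & dA < -clip_tol * peak
  bad_s <- !dia & dA > clip_tol * peak
  if (any(bad_d) || any(bad_s)) {
    warning("area rate sign inconsistent with phase at ",
            sum(bad_d) + sum(bad_s), " samples; clipping to zero")
    dA[bad_d | bad_s] <- 0
  }
  u_in <- ifelse(dia, dA / inlet_width, 0) / 1000   # mm/s -> m/s
  u_out <- ifelse(!dia, -dA / outlet_width, 0) / 1000
  if (ramp_eps > 0) {
    ramp <- function(dt_edge) (1 - cos(pi * pmin(1, dt_edge / ramp_eps))) / 2
    # distance to the nearest phase transition (0 and phase_split, cyclic)
    d0 <- pmin(t, period - t)
    d1 <- abs(t - phase_split)
    env <- ramp(pmin(d0, d1))
    u_in <- u_in * env
    u_out <- u_out * env
  }
  structure(list(times = wave$times,
                 phase = ifelse(dia, "diastole", "systole"),
                 u_in_m_s = u_in, u_out_m_s = u_out,
                 inlet_width = inlet_width, outlet_width = outlet_width,
                 period = period, phase_split = phase_split,
                 ramp_eps = ramp_eps, profile = "plug"),
            class = "bc_schedule")
}

#' Continuous-time evaluator of a BC schedule
#'
#' Periodic linear interpolation of the schedule, for solver time stepping.
#' @param bc a `bc_schedule`.
#' @return function of a time vector returning a data.frame with columns
#'   `u_in`, `u_out`, `phase`.
#' @export
bc_interpolator <- function(bc) {
  tt <- c(bc$times, bc$period)
  ui <- c(bc$u_in_m_s, bc$u_in_m_s[1])
  uo <- c(bc$u_out_m_s, bc$u_out_m_s[1])
  function(tv) {
    tv <- tv %% bc$period
    data.frame(u_in = approx(tt, ui, xout = tv)$y,
               u_out = approx(tt, uo, xout = tv)$y,
               phase = ifelse(tv < bc$phase_split, "diastole", "systole"))
  }
}

#' @export
print.bc_schedule <- function(x, ...) {
  cat("bc_schedule:", length(x$times), "samples, peak inlet",
      round(max(x$u_in_m_s), 3), "m/s, peak outlet",
      round(max(x$u_out_m_s), 3), "m/s\n")
  invisible(x)
}

#' Write a BC schedule as CSV
#' @param bc a `bc_schedule`.
#' @param path output CSV.
#' @export
write_bc_schedule <- function(bc, path) {
  df <- data.frame(time_s = bc$times, phase = bc$phase,
                   u_in_m_s = bc$u_in_m_s, u_out_m_s = bc$u_out_m_s)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a BC schedule written by [write_bc_schedule()]
#' @param path CSV path.
#' @param inlet_width,outlet_width,period,phase_split metadata not stored in
#'   the CSV; supply to reconstruct a full schedule object.
#' @export
read_bc_schedule <- function(path, inlet_width = 24.4, outlet_width = 18.6,
                             period = 0.772, phase_split = 0.480) {
  df <- read.csv(path)
  structure(list(times = df$time_s, phase = df$phase,
                 u_in_m_s = df$u_in_m_s, u_out_m_s = df$u_out_m_s,
                 inlet_width = inlet_width, outlet_width = outlet_width,
                 period = period, phase_split = phase_split,
                 ramp_eps = NA_real_, profile = "plug"),
            class = "bc_schedule")
}
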
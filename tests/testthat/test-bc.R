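# boundary_conditions: phase-switched velocity schedules from the area rate

test_that("inlet velocity arithmetic and phase exclusivity", {
  # constant filling rate 186 mm^2/s over diastole -> 10 mm/s inlet plug
  T <- 0.772; n <- 772L
  times <- (seq_len(n) - 1L) / n * T
  dA <- ifelse(times < 0.480, 186, -186 * 0.480 / (T - 0.480))
  wv <- structure(list(times = times, area = 3000 + cumsum(dA) * T / n,
                       dA_dt = dA, period = T, phase_split = 0.480),
                  class = "volume_waveform")
  bc <- derive_bc_schedule(wv, inlet_width = 18.6, outlet_width = 18.6,
                           ramp_eps = 0)
  dia <- bc$phase == "diastole"
  expect_equal(unique(bc$u_in_m_s[dia]), 0.010)      # 186/18.6 mm/s = 10 mm/s
  expect_true(all(bc$u_in_m_s[!dia] == 0))
  expect_true(all(bc$u_out_m_s[dia] == 0))
  expect_true(all(bc$u_out_m_s[!dia] > 0))
  # exactly one open boundary at any time (no ramp)
  expect_true(all((bc$u_in_m_s == 0) | (bc$u_out_m_s == 0)))
})

test_that("zero area rate gives identically zero schedules", {
  wv <- structure(list(times = seq(0, 0.75, by = 0.01), area = rep(100, 76),
                       dA_dt = rep(0, 76), period = 0.772,
                       phase_split = 0.480),
                  class = "volume_waveform")
  bc <- derive_bc_schedule(wv)
  expect_true(all(bc$u_in_m_s == 0))
  expect_true(all(bc$u_out_m_s == 0))
})

test_that("diastolic inlet flux integrates to the diastolic area gain", {
  geom <- build_geometry("N-LV")
  cs <- interpolate_contours(generate_contours(geom), 60L)
  wv <- compute_area_waveform(cs)
  bc <- derive_bc_schedule(wv)
  dia <- which(wv$times < wv$phase_split)
  dt <- wv$period / length(wv$times)
  f <- bc$u_in_m_s * 1000 * bc$inlet_width          # mm^2/s
  flux <- sum((f[dia[-length(dia)]] + f[dia[-1]]) / 2) * dt
  iA <- which.min(abs(wv$times - wv$phase_split))
  dA <- wv$area[iA] - wv$area[1]
  expect_lt(abs(flux - dA) / dA, 0.001)
  # cyclic balance: diastolic inflow equals systolic outflow within tolerance
  g <- bc$u_out_m_s * 1000 * bc$outlet_width
  sys <- which(wv$times >= wv$phase_split)
  out <- sum((g[sys[-length(sys)]] + g[sys[-1]]) / 2) * dt
  expect_lt(abs(out - dA) / dA, 0.005)
})

test_that("beyond-tolerance sign inconsistency warns and clips", {
  T <- 1; n <- 100L
  times <- (seq_len(n) - 1L) / n * T
  dA <- ifelse(times < 0.5, 100, -100)
  dA[10] <- -50                                     # gross violation in diastole
  wv <- structure(list(times = times, area = rep(100, n), dA_dt = dA,
                       period = T, phase_split = 0.5),
                  class = "volume_waveform")
  expect_warning(bc <- derive_bc_schedule(wv, ramp_eps = 0), "inconsistent")
  expect_equal(bc$u_in_m_s[10], 0)
  # small excursions pass through signed (mass closure)
  dA[10] <- -2
  wv$dA_dt <- dA
  bc2 <- derive_bc_schedule(wv, ramp_eps = 0)
  expect_lt(bc2$u_in_m_s[10], 0)
})

test_that("ramp suppresses the open boundary near phase transitions", {
  T <- 1; n <- 1000L
  times <- (seq_len(n) - 1L) / n * T
  dA <- ifelse(times < 0.5, 100, -100)
  wv <- structure(list(times = times, area = rep(100, n), dA_dt = dA,
                       period = T, phase_split = 0.5),
                  class = "volume_waveform")
  bc <- derive_bc_schedule(wv, ramp_eps = 0.02)
  i0 <- which.min(abs(times - 0.5))                 # just past the switch
  expect_lt(bc$u_out_m_s[i0 + 1L], 0.2 * max(bc$u_out_m_s))
  mid <- which.min(abs(times - 0.25))
  expect_equal(bc$u_in_m_s[mid], 100 / 24.4 / 1000)
})

test_that("BC schedule CSV round-trip", {
  geom <- build_geometry("N-LV")
  cs <- interpolate_contours(generate_contours(geom), 10L)
  wv <- compute_area_waveform(cs)
  bc <- derive_bc_schedule(wv)
  f <- tempfile(fileext = ".csv")
  write_bc_schedule(bc, f)
  bc2 <- read_bc_schedule(f)
  expect_equal(bc2$u_in_m_s, bc$u_in_m_s)
  expect_equal(bc2$u_out_m_s, bc$u_out_m_s)
  expect_equal(bc2$times, bc$times)
  unlink(f)
})
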
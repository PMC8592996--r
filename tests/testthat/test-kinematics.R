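test_that("zero-lag low-pass has unit DC gain, half-power at cutoff, zero lag", {
  const <- timeseries(data.frame(x = rep(3.7, 801)), 200)
  out <- zero_lag_lowpass(const, 6)
  mid <- 200:600  # away from the filter's edge transients
  expect_equal(out$x[mid], const$x[mid], tolerance = 1e-9)

  # two cascaded passes of a 2nd-order Butterworth: |H|^2 = 1/2 at the cutoff
  s <- sine_ts(6, 200, duration = 10)
  filt <- zero_lag_lowpass(s, 6)
  expect_equal(mid_amplitude(filt$x), 0.5, tolerance = 0.02)

  # zero group delay: cross-correlation of a band-limited signal peaks at lag 0
  set.seed(42)
  noise <- timeseries(data.frame(x = rnorm(2000)), 200)
  band <- zero_lag_lowpass(noise, 10)
  smooth <- zero_lag_lowpass(band, 5)
  cc <- ccf(band$x, smooth$x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(zero_lag_lowpass(const, 200), "Nyquist")
  expect_error(zero_lag_lowpass(const, 100), "Nyquist")
})

test_that("band-pass removes DC, keeps mid-band, rejects out-of-band", {
  const <- timeseries(data.frame(x = rep(2, 4001)), 2000)
  out <- bandpass(const, 30, 450)
  expect_lt(max(abs(out$x[1000:3000])), 0.01 * 2)

  mid <- bandpass(sine_ts(100, 2000, 4), 30, 450)
  expect_equal(mid_amplitude(mid$x), 1, tolerance = 0.05)

  low <- bandpass(sine_ts(1, 2000, 4), 30, 450)
  expect_lt(mid_amplitude(low$x), 0.1)

  expect_error(bandpass(const, 450, 30), "band edges")
  expect_error(bandpass(const, 0, 450), "band edges")
})

test_that("filtering an already band-limited signal is nearly idempotent", {
  set.seed(7)
  noise <- timeseries(data.frame(x = rnorm(4000)), 200)
  once <- zero_lag_lowpass(noise, 6)
  twice <- zero_lag_lowpass(once, 20)  # passband well above the signal band
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(twice$x) - rms(once$x)) / rms(once$x), 0.01)
})

test_that("static phase averaging is the exact window mean", {
  rate <- 100
  tt <- seq(0, 5, by = 1 / rate)
  ts <- timeseries(data.frame(const = rep(2.5, length(tt)), ramp = tt), rate)
  avg <- static_phase_average(ts, start = 1, duration = 3)
  expect_equal(avg$const, 2.5)
  expect_equal(avg$ramp, 2.5)  # midpoint of the 1..4 s window
  expect_error(static_phase_average(ts, start = 4, duration = 3), "window")
})

test_that("trunk-pelvis rotation decomposes the relative rotation", {
  I <- diag(3)
  ang <- trunk_pelvis_rotation(I, I)
  expect_equal(unlist(ang), c(flexion = 0, lateral = 0, axial = 0))

  R30 <- euler_to_matrix(c(30, 0, 0))
  ang <- trunk_pelvis_rotation(R30, I)
  expect_equal(ang$flexion, 30, tolerance = 1e-9)
  expect_equal(ang$lateral, 0, tolerance = 1e-9)

  # composed rotations recover their generating angles and the matrix
  for (angles in list(c(25, 10, 0), c(40, -12, 18), c(-15, 5, -30))) {
    R <- euler_to_matrix(angles)
    dec <- trunk_pelvis_rotation(R, I)
    expect_equal(unlist(dec), c(flexion = angles[1], lateral = angles[2], axial = angles[3]),
                 tolerance = 1e-6)
    expect_equal(euler_to_matrix(unlist(dec)), R, tolerance = 1e-9)
  }

  # relative rotation with a rotated pelvis
  Rp <- euler_to_matrix(c(20, 0, 5))
  Rt <- Rp %*% euler_to_matrix(c(15, 8, -4))
  dec <- trunk_pelvis_rotation(Rt, Rp)
  expect_equal(unlist(dec), c(flexion = 15, lateral = 8, axial = -4), tolerance = 1e-6)

  expect_error(trunk_pelvis_rotation(matrix(1:9, 3), I), "rotation matrix")
})

test_that("lumbar rhythm distributes and conserves each plane's rotation", {
  coeffs <- lumbar_rhythm_coefficients()
  expect_equal(colSums(coeffs[, c("flexion", "lateral", "axial")]),
               c(flexion = 1, lateral = 1, axial = 1), tolerance = 1e-9)

  zero <- distribute_lumbar_rotation(c(0, 0, 0), coeffs)
  expect_true(all(unlist(zero[, -1]) == 0))

  unif <- lumbar_rhythm_coefficients(list(flexion = rep(1 / 6, 6),
                                          lateral = rep(1 / 6, 6),
                                          axial = rep(1 / 6, 6)))
  d <- distribute_lumbar_rotation(c(40, 0, 0), unif)
  expect_equal(d$flexion, rep(40 / 6, 6), tolerance = 1e-9)

  d2 <- distribute_lumbar_rotation(c(40, 10, 5), coeffs)
  expect_equal(d2$flexion, coeffs$flexion * 40)
  expect_equal(d2$lateral, coeffs$lateral * 10)
  expect_equal(d2$axial, coeffs$axial * 5)
  expect_equal(colSums(d2[, -1]), c(flexion = 40, lateral = 10, axial = 5), tolerance = 1e-9)

  bad <- coeffs
  bad$flexion <- bad$flexion * 1.1
  expect_error(distribute_lumbar_rotation(c(10, 0, 0), bad), "sum to 1")
  expect_error(lumbar_rhythm_coefficients(list(flexion = rep(0.2, 6),
                                               lateral = rep(1 / 6, 6),
                                               axial = rep(1 / 6, 6))), "sum to 1")
})

test_that("series CSV and TRC readers round-trip generated fixtures", {
  rate <- 100
  ts <- timeseries(data.frame(a = sin(1:50), b = cos(1:50)), rate)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ts, f)
  back <- read_series_csv(f)
  expect_equal(ts_rate(back), rate)
  expect_equal(back$a, ts$a, tolerance = 1e-9)
  expect_equal(back$b, ts$b, tolerance = 1e-9)

  # minimal TRC fixture written in code (mm -> m conversion, header block)
  trc <- withr::local_tempfile(fileext = ".trc")
  lines <- c(
    "PathFileType\t4\t(X/Y/Z)\ttest.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits",
    "200\t200\t2\t2\tmm",
    "Frame#\tTime\tSACR\t\t\tC7\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2",
    "1\t0.000\t100\t200\t300\t110\t210\t310",
    "2\t0.005\t101\t201\t301\t111\t211\t311"
  )
  writeLines(lines, trc)
  m <- read_trc(trc)
  expect_equal(ts_rate(m), 200)
  expect_equal(m$SACR_x, c(0.100, 0.101))
  expect_equal(m$C7_z, c(0.310, 0.311))
})
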
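test_that("three-phase demodulation recovers DC and AC exactly", {
  # flat field
  st <- phase_stack(matrix(7, 4, 4), matrix(7, 4, 4), matrix(7, 4, 4),
                    f = 3, pitch_um = 10)
  d <- demodulate(st)
  expect_equal(d$DC, matrix(7, 4, 4))
  expect_equal(d$AC, matrix(0, 4, 4))

  # sinusoid with arbitrary phase and position
  st <- ideal_stack(n = 48, a0 = 123.4, a1 = 17.8, f = 7, phi = 1.234)
  d <- demodulate(st)
  expect_equal(max(abs(d$DC - 123.4)), 0, tolerance = 1e-10)
  expect_equal(max(abs(d$AC - 17.8)), 0, tolerance = 1e-10)
})

test_that("AC equals an independent complex-demodulation expression", {
  set.seed(4)
  P <- lapply(1:3, function(i) matrix(runif(64, 0, 255), 8, 8))
  st <- phase_stack(P[[1]], P[[2]], P[[3]], f = 5, pitch_um = 10)
  d <- demodulate(st)
  # amplitude of the fundamental of the 3-point DFT over the phase index
  z <- P[[1]] + P[[2]] * exp(-2i * pi / 3) + P[[3]] * exp(-4i * pi / 3)
  expect_equal(d$AC, 2 / 3 * Mod(z), tolerance = 1e-12)
  expect_equal(d$DC, (P[[1]] + P[[2]] + P[[3]]) / 3)
})

test_that("demodulation is linear and phase-offset invariant", {
  st <- ideal_stack(a0 = 90, a1 = 9, phi = 0.1)
  st2 <- ideal_stack(a0 = 90, a1 = 9, phi = 2.7)     # different offset
  s <- 3.7
  st3 <- st
  for (p in c("P1", "P2", "P3")) st3[[p]] <- st[[p]] * s
  expect_equal(demodulate(st3)$AC, demodulate(st)$AC * s)
  expect_equal(demodulate(st2)$AC, demodulate(st)$AC, tolerance = 1e-10)
})

test_that("dark subtraction removes additive offsets and validates shapes", {
  st <- ideal_stack(a0 = 100, a1 = 10)
  zero <- phase_stack(matrix(0, 64, 64), matrix(0, 64, 64),
                      matrix(0, 64, 64), f = st$f, pitch_um = st$pitch_um)
  expect_equal(subtract_dark(st, st)$P2, matrix(0, 64, 64))
  expect_equal(subtract_dark(st, zero)$P1, st$P1)

  off <- 13
  sto <- st
  dark <- zero
  for (p in c("P1", "P2", "P3")) {
    sto[[p]] <- st[[p]] + off
    dark[[p]] <- matrix(off, 64, 64)
  }
  out <- subtract_dark(sto, dark)
  expect_equal(out$P3, st$P3)

  small <- phase_stack(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                       f = st$f, pitch_um = st$pitch_um)
  expect_error(subtract_dark(st, small), "shape")
  wrongf <- zero; wrongf$f <- 99
  expect_error(subtract_dark(st, wrongf), "frequency")
})

test_that("block binning averages exactly and keeps slow sinusoids", {
  expect_equal(bin_image(matrix(3.2, 16, 16), 8), matrix(3.2, 2, 2))

  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(bin_image(cb, 8), matrix(0.5, 1, 1))

  # mean over 2x2 blocks, done by hand
  m <- matrix(1:16, 4, 4)
  by_hand <- matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                      mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2, 2)
  expect_equal(bin_image(m, 2), by_hand)

  # slow sinusoid survives 8x8 binning with < 1% amplitude loss
  st <- ideal_stack(n = 512, a0 = 100, a1 = 20, f = 1, pitch_um = 4)
  d <- demodulate(bin_stack(st, 8))
  expect_equal(mean(d$AC), 20, tolerance = 0.01)
  expect_equal(d$pitch_um, 32)

  expect_error(bin_image(matrix(1, 4, 4), 8), "smaller")
})

test_that("Butterworth high-pass has the designed radial gain", {
  n <- 256; pitch <- 10   # 2.56 mm field, Nyquist 50/mm
  x_mm <- (seq_len(n) - (n + 1) / 2) * pitch / 1000
  sin_img <- function(f) matrix(cos(2 * pi * f * x_mm), n, n)
  amp <- function(img) sqrt(2) * sd(img[65:192, 65:192])

  # constant image is annihilated
  out <- butterworth_highpass(matrix(5, n, n), f_proj = 10, pitch_um = pitch)
  expect_lt(max(abs(out)), 5 * 1e-10)

  # at the cutoff the gain is 1/sqrt(2); at the projection frequency with
  # f_c = f/4 the gain is 1/sqrt(1 + (1/4)^4)
  f_proj <- 12.5
  g_cut <- amp(butterworth_highpass(sin_img(f_proj / 4), f_proj,
                                    pitch_um = pitch)) /
    amp(sin_img(f_proj / 4))
  expect_equal(g_cut, 1 / sqrt(2), tolerance = 0.02)

  g_pass <- amp(butterworth_highpass(sin_img(f_proj), f_proj,
                                     pitch_um = pitch)) /
    amp(sin_img(f_proj))
  expect_equal(g_pass, 1 / sqrt(1 + (1 / 4)^4), tolerance = 0.02)

  expect_error(butterworth_highpass(sin_img(10), f_proj = 300,
                                    pitch_um = pitch), "Nyquist")
})

test_that("ROI mean averages the central disc", {
  n <- 101; pitch <- 10
  img <- matrix(4.2, n, n)
  mask <- matrix(TRUE, n, n)
  expect_equal(roi_mean(img, mask, 600, pitch), 4.2)

  # radial gradient image r (um): disc mean is 2R/3
  ctr <- (n + 1) / 2
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)) * pitch
  expect_equal(roi_mean(r, mask, 600, pitch), 2 * 300 / 3, tolerance = 0.02)

  # ROI as large as the field reduces to the mask mean
  expect_equal(roi_mean(r, mask, 2 * n * pitch, pitch), mean(r))
  expect_error(roi_mean(img, mask & FALSE, 600, pitch), "mask")
})

test_that("reference normalisation is a guarded ratio", {
  expect_equal(normalize_to_reference(2, 2), 1)
  expect_equal(normalize_to_reference(4, 2), 2)
  m <- matrix(1:4, 2, 2)
  expect_equal(normalize_to_reference(2 * m, m), matrix(2, 2, 2))
  expect_error(normalize_to_reference(1, 0), "positive")
})

test_that("the full pipeline recovers synthetic ground truth", {
  cfg <- synth_scan_config(field_diameter_um = 900, pitch_um = 3,
                           dc_level = 150, dark_offset = 10)
  labs <- names(cfg$frequencies)
  ref_cfg <- cfg
  mk <- function(conf) {
    list(stacks = setNames(lapply(labs, function(l)
           make_phase_stack(conf, l, noise = FALSE)), labs),
         darks = setNames(lapply(labs, function(l)
           make_dark_stack(conf, l, noise = FALSE)), labs))
  }
  tis <- mk(cfg)
  # reference with half the AC amplitude: known ratio 2
  ref_cfg$ac_amplitude <- cfg$ac_amplitude / 2
  ref <- mk(ref_cfg)
  out <- process_scan(tis$stacks, tis$darks, ref$stacks,
                      reference_darks = ref$darks, highpass = FALSE)
  expect_equal(nrow(out), 4)
  # 8x8 block averaging attenuates a sinusoid by the known Dirichlet
  # factor; correct for it when comparing against the generator amplitude
  att <- function(f, pitch_mm, k) {
    abs(sin(pi * f * k * pitch_mm) / (k * sin(pi * f * pitch_mm)))
  }
  truth_ac <- unname(cfg$ac_amplitude)
  expect_equal(out$ac_roi / att(out$f, 0.003, 8), truth_ac,
               tolerance = 0.01)
  expect_equal(out$R_norm, rep(2, 4), tolerance = 0.01)

  # all-dark scan demodulates to zero AC
  drk <- mk(cfg)$darks
  out0 <- process_scan(drk, drk, ref$stacks, reference_darks = ref$darks,
                       highpass = FALSE)
  expect_equal(out0$ac_roi, rep(0, 4), tolerance = 1e-9)

  # linearity: scaling the scan scales the normalised output
  tis2 <- tis
  for (l in labs) for (p in c("P1", "P2", "P3")) {
    tis2$stacks[[l]][[p]] <- tis$darks[[l]][[p]] +
      (tis$stacks[[l]][[p]] - tis$darks[[l]][[p]]) * 1.5
  }
  out2 <- process_scan(tis2$stacks, tis$darks, ref$stacks,
                       reference_darks = ref$darks, highpass = FALSE)
  expect_equal(out2$R_norm, out$R_norm * 1.5, tolerance = 1e-8)

  expect_error(process_scan(tis$stacks, tis$darks[-1], ref$stacks),
               "missing dark")
})

test_that("pipeline order is pinned: bin before high-pass filtering", {
  cfg <- synth_scan_config(field_diameter_um = 600, pitch_um = 3)
  st <- make_phase_stack(cfg, "15", noise = FALSE)
  a <- highpass_stack(bin_stack(st, 8))
  b_raw <- highpass_stack(st)
  b <- bin_stack(b_raw, 8)
  ac_a <- demodulate(a)$AC
  ac_b <- demodulate(b)$AC
  # the two orders are genuinely different operations
  expect_gt(max(abs(ac_a - ac_b)), 1e-6)
  # process_scan follows bin-then-filter
  drk <- make_dark_stack(cfg, "15", noise = FALSE)
  out <- process_scan(list(`15` = st), list(`15` = drk), list(`15` = st),
                      bin_k = 8)
  d <- demodulate(a)
  expect_equal(out$ac_roi,
               roi_mean(ac_a, d$mask, 600, d$pitch_um), tolerance = 1e-9)
})
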
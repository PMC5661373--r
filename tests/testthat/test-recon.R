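# Reconstruction: spatial transform against a direct-DFT oracle,
# frequency/phase estimation against injected truth, coil combination,
# difference spectra, linewidths.

test_that("1x1x1 encoding passes through reconstruction unchanged", {
  basis <- test_basis()
  raw <- generateAcquisition(basis, phantomConfig(),
                             makeSensitivities(1, c(1, 1, 1), uniform = TRUE),
                             encoding = list(matrix = c(1, 1, 1),
                                             averages = 1))
  img <- csiReconstruct(raw)
  expect_identical(csiData(img), csiData(raw))
  expect_identical(csiEncoding(img)$domain, "image")
})

test_that("reconstruction matches a direct discrete-Fourier oracle to 1e-10", {
  set.seed(5)
  n <- 8L; nt <- 4L
  ksp <- array(complex(real = rnorm(n * n * nt),
                       imaginary = rnorm(n * n * nt)),
               dim = c(1, 1, n, n, 1, nt))
  raw <- new("MultiCoilCSI",
             data = list(edited = ksp, non_edited = ksp),
             encoding = list(matrix = c(n, n, 1L), averages = 1L,
                             dwell_s = 2.5e-4, domain = "kspace"),
             params = test_params(n_points = as.integer(nt)),
             truth = list())
  for (shift in list(c(0, 0), c(0.5, 0.5))) {
    img <- csiReconstruct(raw, half_voxel_shift = shift)
    # independent oracle: explicit inverse DFT with the shift in the
    # exponent, s(r) = (1/N^2) sum_k S(k) exp(+2pi i k (r + s) / N)
    oracle <- array(0i, dim = c(n, n, nt))
    for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
      acc <- complex(nt)
      for (kx in 0:(n - 1)) for (ky in 0:(n - 1)) {
        phase <- exp(2i * pi * (kx * (x - shift[1]) / n +
                                  ky * (y - shift[2]) / n))
        acc <- acc + ksp[1, 1, kx + 1, ky + 1, 1, ] * phase
      }
      oracle[x + 1, y + 1, ] <- acc / n^2
    }
    got <- array(csiData(img)$edited[1, 1, , , 1, ], dim = c(n, n, nt))
    expect_lt(max(Mod(got - oracle)) / max(Mod(oracle)), 1e-10)
  }
})

test_that("opposite half-voxel shifts compose to the identity", {
  mat <- c(8L, 8L, 1L)
  kx <- 0:7
  ramp <- function(s) exp(-2i * pi * outer(kx * s / 8, kx * s / 8, "+"))
  expect_lt(max(Mod(ramp(0.5) * ramp(-0.5) - 1)), 1e-12)
})

test_that("the spatial transform conserves energy (Parseval)", {
  set.seed(11)
  img <- array(complex(real = rnorm(8 * 8 * 3),
                       imaginary = rnorm(8 * 8 * 3)), dim = c(8, 8, 3))
  ksp <- gabedit:::.dft2(img)
  back <- gabedit:::.dft2(ksp, inverse = TRUE)
  expect_lt(max(Mod(back - img)), 1e-12)
  expect_equal(sum(Mod(ksp)^2) / 64, sum(Mod(img)^2), tolerance = 1e-10)
})

test_that("frequency/phase estimation recovers injected truth", {
  basis <- test_basis()
  p <- seqParams(basis)
  ph <- phantomConfig(residual_water_amp = 2)
  co <- makeSensitivities(2, c(1, 1, 1), seed = 6)

  # noiseless, no drift: estimates are numerically zero
  raw0 <- generateAcquisition(basis, ph, co,
                              encoding = list(matrix = c(1, 1, 1),
                                              averages = 4))
  v0 <- array(csiData(raw0)$non_edited[, , 1, 1, 1, ], dim = c(4, 2, 1024))
  e0 <- estimateFreqPhase(v0, p)
  expect_lt(max(abs(e0@freq_hz)), 1e-4)
  expect_lt(max(abs(e0@phase_deg)), 1e-3)

  # constant +30 degree phase on one average recovered within 1 degree
  v1 <- v0
  v1[2, , ] <- v1[2, , ] * exp(1i * 30 * pi / 180)
  e1 <- estimateFreqPhase(v1, p)
  expect_lt(max(abs(e1@phase_deg[2, ] - 30)), 1)

  # linear drift at SNR >= 20: per-average shifts within 0.1 Hz RMS
  spec1 <- fidToSpectrum(mk_fid(v0[1, 1, ], p))
  w <- ppmWindow(spec1, c(2.9, 3.1))
  peak <- max(Mod(specValues(spec1)[w]))
  nsd <- peak / 20 / sqrt(p@n_points)
  raw <- generateAcquisition(basis, ph, co,
                             encoding = list(matrix = c(1, 1, 1),
                                             averages = 64),
                             noise_sd = nsd, drift_hz_per_avg = 0.2,
                             phase_sd_deg = 5, seed = 13)
  v <- array(csiData(raw)$non_edited[, , 1, 1, 1, ], dim = c(64, 2, 1024))
  # full-spectrum registration plus drift smoothing: the 0.2-ppm Cr
  # window alone is information-limited near 0.4 Hz at this SNR
  est <- estimateFreqPhase(v, p, ref_window_ppm = c(1.8, 5.0),
                           smooth_averages = 9)
  tru <- csiTruth(raw)$freq_hz["non_edited", ]
  tru <- tru - tru[1]
  expect_lt(sqrt(mean((est@freq_hz - tru)^2)), 0.1)
})

test_that("estimation below the SNR floor warns and returns zeros", {
  p <- test_params(n_points = 512L)
  set.seed(2)
  noise <- matrix(complex(real = rnorm(2 * 512, sd = 1),
                          imaginary = rnorm(2 * 512, sd = 1)), 2, 512)
  expect_warning(est <- estimateFreqPhase(noise, p), "SNR below floor")
  expect_true(all(est@freq_hz == 0))
})

test_that("coil combination is amplitude-preserving and rejects zero maps", {
  p <- test_params(n_points = 512L)
  s <- exp(2i * pi * 40 * (0:511) / 4000)
  expect_equal(combineCoils(matrix(s, 1), 1 + 0i), as.complex(s))
  many <- matrix(rep(s, 4), 4, byrow = TRUE)
  expect_equal(combineCoils(many, rep(1 + 0i, 4)), as.complex(s))
  expect_error(combineCoils(many, rep(0i, 4)), "all-zero")
})

test_that("matched-weight combination beats the best single coil in SNR", {
  p <- test_params(n_points = 256L)
  sens <- complex(real = c(1, 0.8, -0.5, 0.3),
                  imaginary = c(0, 0.4, 0.6, -0.7))
  tt <- (0:255) / 4000
  sig <- exp(2i * pi * 100 * tt - pi * 10 * tt)
  peak_bin <- which.max(Mod(stats::fft(sig)))
  set.seed(77)
  wins <- 0L
  for (i in 1:100) {
    fids <- t(vapply(sens, function(cs) cs * sig +
        complex(real = rnorm(256, sd = 0.3),
                imaginary = rnorm(256, sd = 0.3)), complex(256)))
    snr_of <- function(x) {
      sp <- stats::fft(x)
      Mod(sp[peak_bin]) / stats::sd(Re(sp[150:250]))
    }
    single <- max(apply(fids, 1, snr_of))
    comb <- snr_of(combineCoils(fids, sens))
    if (comb >= single) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("difference spectra subtract pointwise and flag axis mismatch", {
  b <- test_basis()
  e <- fidToSpectrum(applyDamping(basisEntry(b, "GABA", "edited"), 5))
  n <- fidToSpectrum(applyDamping(basisEntry(b, "GABA", "non_edited"), 5))
  z <- differenceSpectrum(e, e)
  expect_true(all(specValues(z) == 0i))
  d1 <- differenceSpectrum(e, n)
  d2 <- differenceSpectrum(n, e)
  expect_equal(specValues(d1), -specValues(d2))
  expect_gt(peakAmplitude(d1, 3.01), 0)  # GABA multiplet, positive
  other <- fidToSpectrum(applyDamping(
    basisEntry(test_basis(n_points = 512L), "GABA", "edited"), 5))
  expect_error(differenceSpectrum(e, other), "axes")
})

test_that("linewidth measurement matches the Lorentzian closed form", {
  p <- test_params(n_points = 4096L, sweep_hz = 2000)
  tt <- (0:4095) / 2000
  nu <- ppmToHz(3.0, p)
  for (lw in c(8, 16)) {
    fid <- mk_fid(exp(2i * pi * nu * tt - pi * lw * tt), p)
    expect_equal(linewidthFwhm(fidToSpectrum(fid), 3.0, window_ppm = 0.3),
                 lw, tolerance = 0.02)
  }
  # resolution-limited, undamped singlet
  p2 <- test_params(n_points = 1024L)
  tt2 <- (0:1023) / 4000
  fid2 <- mk_fid(exp(2i * pi * ppmToHz(3.0, p2) * tt2), p2)
  expect_lt(linewidthFwhm(fidToSpectrum(fid2), 3.0), 2 * 4000 / 1024)
  flat <- mk_fid(rep(0i, 1024), p2)
  expect_error(linewidthFwhm(fidToSpectrum(flat), 3.0), "maximum")
})
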
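# Synthetic acquisition generator: sensitivities, determinism, linearity,
# noise calibration, contamination localisation.

test_that("coil sensitivities are smooth, nonzero and deterministic", {
  s1 <- makeSensitivities(32, c(8, 8, 1), seed = 4)
  s2 <- makeSensitivities(32, c(8, 8, 1), seed = 4)
  expect_identical(s1@maps, s2@maps)
  expect_true(all(apply(Mod(s1@maps)^2, c(2, 3, 4), sum) > 0))
  u <- makeSensitivities(3, c(2, 2, 1), uniform = TRUE)
  expect_true(all(u@maps == 1 + 0i))
  expect_error(makeSensitivities(0, c(1, 1, 1)), ">= 1")
})

test_that("zero concentrations and zero noise give all-zero data", {
  basis <- test_basis()
  ph <- phantomConfig(regions = list(list(concentrations = c(NAA = 0),
                                          linewidth_hz = 5)))
  co <- makeSensitivities(2, c(1, 1, 1), seed = 1)
  raw <- generateAcquisition(basis, ph, co,
                             encoding = list(matrix = c(1, 1, 1),
                                             averages = 2))
  expect_true(all(csiData(raw)$edited == 0i))
  expect_true(all(csiData(raw)$non_edited == 0i))
})

test_that("identical seeds give bit-identical datasets", {
  basis <- test_basis()
  ph <- phantomConfig()
  co <- makeSensitivities(3, c(1, 1, 1), seed = 2)
  args <- list(basis, ph, co, encoding = list(matrix = c(1, 1, 1),
                                              averages = 4),
               noise_sd = 0.1, drift_hz_per_avg = 0.1, phase_sd_deg = 3,
               seed = 42L)
  r1 <- do.call(generateAcquisition, args)
  r2 <- do.call(generateAcquisition, args)
  expect_identical(csiData(r1), csiData(r2))
  expect_identical(csiTruth(r1)$freq_hz, csiTruth(r2)$freq_hz)
})

test_that("noiseless data are exactly linear in concentrations", {
  basis <- test_basis()
  co <- makeSensitivities(2, c(1, 1, 1), seed = 3)
  ph1 <- phantomConfig(regions = list(list(
    concentrations = brainConcentrations(), linewidth_hz = 8)))
  ph2 <- phantomConfig(regions = list(list(
    concentrations = 2 * brainConcentrations(), linewidth_hz = 8)))
  enc <- list(matrix = c(1, 1, 1), averages = 1)
  r1 <- generateAcquisition(basis, ph1, co, enc)
  r2 <- generateAcquisition(basis, ph2, co, enc)
  expect_equal(csiData(r2)$edited, 2 * csiData(r1)$edited)
  expect_equal(csiData(r2)$non_edited, 2 * csiData(r1)$non_edited)
})

test_that("single-voxel identity: reconstruction equals the basis mixture", {
  basis <- test_basis()
  ph <- phantomConfig()
  co <- makeSensitivities(1, c(1, 1, 1), uniform = TRUE)
  raw <- generateAcquisition(basis, ph, co,
                             encoding = list(matrix = c(1, 1, 1),
                                             averages = 2))
  rec <- reconstructVoxel(raw, correct = FALSE)
  conc <- brainConcentrations()
  p <- seqParams(basis)
  expected <- complex(p@n_points)
  for (m in names(conc))
    expected <- expected + conc[[m]] *
      applyDamping(basisEntry(basis, m, "edited"), 8)@samples
  expect_lt(max(Mod(fidSamples(rec$fids$edited) - expected)) /
              max(Mod(expected)), 1e-9)
})

test_that("spectral noise level matches the injected noise within 5%", {
  basis <- test_basis(n_points = 512L)
  ph <- phantomConfig(regions = list(list(concentrations = c(NAA = 0),
                                          linewidth_hz = 5)))
  co <- makeSensitivities(1, c(1, 1, 1), uniform = TRUE)
  noise_sd <- 0.2
  raw <- generateAcquisition(basis, ph, co,
                             encoding = list(matrix = c(1, 1, 1),
                                             averages = 100),
                             noise_sd = noise_sd, seed = 8)
  # FID noise sd s maps to real-part spectral sd s * sqrt(N)
  vals <- apply(csiData(raw)$non_edited[, 1, 1, 1, 1, ], 1, stats::fft)
  observed <- stats::sd(Re(vals))
  expect_equal(observed, noise_sd * sqrt(512), tolerance = 0.05)
})

test_that("phase encoding localises contamination away from the voxel, VSS only attenuates it", {
  basis <- test_basis(n_points = 512L)
  g <- c(8L, 8L, 1L)
  contam <- list(list(location = c(1, 1, 1), metabolite = "water",
                      amplitude = 5, linewidth_hz = 10))
  # empty phantom: any reconstructed signal is contamination
  ph8 <- phantomConfig(grid_shape = g,
                       regions = list(list(concentrations = c(NAA = 0),
                                           linewidth_hz = 5)),
                       region_map = array(0L, dim = g),
                       contamination = contam)
  co8 <- makeSensitivities(1, g, uniform = TRUE)
  raw8 <- generateAcquisition(basis, ph8, co8,
                              encoding = list(matrix = g, averages = 1))
  img <- csiReconstruct(raw8, half_voxel_shift = FALSE)
  e <- csiData(img)$edited
  src <- max(Mod(e[1, 1, 1, 1, 1, ]))
  far <- max(Mod(e[1, 1, 5, 5, 1, ]))
  expect_gt(src, 0)
  # on-grid source: inter-voxel leakage is at numerical precision
  expect_lt(far, 1e-9 * src)

  # single-voxel mode: the same contamination leaks in, attenuated by VSS
  ph1 <- phantomConfig(grid_shape = c(1L, 1L, 1L),
                       regions = list(list(concentrations = c(NAA = 0),
                                           linewidth_hz = 5)),
                       region_map = array(0L, dim = c(1, 1, 1)),
                       contamination = list(list(
                         location = c(1, 1, 1), metabolite = "water",
                         amplitude = 5, linewidth_hz = 10)),
                       vss_suppression = 0.95)
  co1 <- makeSensitivities(1, c(1, 1, 1), uniform = TRUE)
  raw1 <- generateAcquisition(basis, ph1, co1,
                              encoding = list(matrix = c(1, 1, 1),
                                              averages = 1))
  resid <- max(Mod(csiData(raw1)$edited[1, 1, 1, 1, 1, ]))
  expect_gt(resid, 0)
  expect_equal(resid, 0.05 * src, tolerance = 1e-9)
})

test_that("mismatched phantom grid and encoding matrix error", {
  basis <- test_basis()
  ph <- phantomConfig(grid_shape = c(4L, 4L, 1L))
  co <- makeSensitivities(1, c(4, 4, 1), seed = 1)
  expect_error(
    generateAcquisition(basis, ph, co,
                        encoding = list(matrix = c(8, 8, 1))),
    "does not match")
})
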
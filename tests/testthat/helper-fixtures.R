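# Shared fixtures: basis sets are deterministic but cost ~0.5 s each, so
# they are built once per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

test_params <- function(n_points = 1024L, ...) {
  sequenceParams(n_points = n_points, ...)
}

test_basis <- function(scheme = "symmetric_1p7", n_points = 1024L) {
  cached(paste0("basis_", scheme, "_", n_points),
         function() makeBasis(test_params(n_points), scheme))
}

# two-spin system mirroring the GABA 4-CH2 / 3-CH2 pair
ax_system <- function(shifts = c(3.01, 1.89), j = 7.3) {
  new("SpinSystem", name = "AX", shifts_ppm = shifts,
      j_hz = matrix(c(0, j, j, 0), 2), proton_scale = c(1, 1))
}

mk_fid <- function(samples, params) {
  new("Fid", samples = as.complex(samples),
      dwell_s = 1 / params@sweep_hz, t0_s = 0, params = params)
}

# hand-derived weak-coupling product-operator closed forms for the AX
# echo (see test-spin-sim.R for the derivation sketch): the FID at the
# echo top continues the J evolution accumulated over TE; in the edited
# cycle the inverted spin is dephased by the editing crushers and the
# refocused partner alone survives
ax_closed_form <- function(params, j = 7.3, shifts = c(3.01, 1.89),
                           edited = FALSE) {
  tt <- (seq_len(params@n_points) - 1) / params@sweep_hz
  te <- params@te_ms * 1e-3
  w <- 2 * pi * ppmToHz(shifts, params)
  if (edited) cos(pi * j * tt) * exp(1i * w[1] * tt)
  else cos(pi * j * (te + tt)) * (exp(1i * w[1] * tt) + exp(1i * w[2] * tt))
}

rel_rms <- function(a, b) sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))

# concentration-weighted damped basis mixture (difference cycle), the
# noiseless truth for quantification tests
mixture_difference <- function(basis, conc, lw_hz = 8) {
  p <- basis@params
  acc <- complex(p@n_points)
  for (m in names(conc)) {
    e <- basisEntry(basis, m)
    acc <- acc + conc[[m]] *
      (applyDamping(e$edited, lw_hz)@samples -
         applyDamping(e$non_edited, lw_hz)@samples)
  }
  fidToSpectrum(mk_fid(acc, p))
}

# spectral real-part noise level that yields a given GABA peak SNR in
# the difference spectrum; a DFT of iid complex noise with per-component
# sd s has real-part sd s * sqrt(N)
noise_for_snr <- function(spec, snr, at_ppm = 3.01) {
  peak <- abs(peakAmplitude(spec, at_ppm))
  (peak / snr) / sqrt(length(specValues(spec)))
}

add_spec_noise <- function(spec, fid_noise_sd) {
  n <- length(spec@values)
  nz <- stats::fft(complex(real = stats::rnorm(n, sd = fid_noise_sd),
                           imaginary = stats::rnorm(n, sd = fid_noise_sd)))
  spec@values <- spec@values + nz
  spec
}
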
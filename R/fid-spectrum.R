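# FID <-> spectrum plumbing: Fourier transform onto a ppm axis,
# damping/frequency/phase manipulations, difference spectra, linewidth.

#' Fourier transform an FID onto a ppm axis
#'
#' Plain DFT (no 1/N scaling) of the complex FID, reordered so the axis
#' runs from `carrier - sweep/2` to `carrier + sweep/2` and then reversed
#' to the conventional strictly descending ppm display. A resonance at
#' chemical shift d ppm appears at d on the axis.
#'
#' @param fid a [Fid-class]
#' @return a [Spectrum-class]
#' @export
fidToSpectrum <- function(fid) {
  p <- fid@params
  n <- p@n_points
  x <- stats::fft(fid@samples)
  shift_idx <- c((n / 2 + 1):n, 1:(n / 2))
  freq <- (seq_len(n) - 1 - n / 2) * (p@sweep_hz / n)
  ppm <- p@carrier_ppm + freq / p@larmor_mhz
  new("Spectrum", values = rev(x[shift_idx]), ppm_axis = rev(ppm),
      params = p)
}

#' Apply Lorentzian damping to an FID
#'
#' Multiplies by `exp(-pi * lw_hz * t)`, producing a Lorentzian line of
#' full width at half maximum `lw_hz` in the spectrum.
#'
#' @param fid a [Fid-class]
#' @param lw_hz target Lorentzian FWHM, Hz
#' @return a damped [Fid-class]
#' @export
applyDamping <- function(fid, lw_hz) {
  if (lw_hz < 0) stop("lw_hz must be >= 0", call. = FALSE)
  tt <- fid@t0_s + (seq_along(fid@samples) - 1) * fid@dwell_s
  fid@samples <- fid@samples * exp(-pi * lw_hz * tt)
  fid
}

#' Frequency-shift and phase-rotate an FID
#'
#' @param fid a [Fid-class]
#' @param freq_hz frequency shift, Hz (positive moves peaks downfield)
#' @param phase_deg zero-order phase, degrees
#' @return the modified [Fid-class]
#' @export
applyFreqPhase <- function(fid, freq_hz = 0, phase_deg = 0) {
  tt <- fid@t0_s + (seq_along(fid@samples) - 1) * fid@dwell_s
  fid@samples <- fid@samples *
    exp(1i * (2 * pi * freq_hz * tt + phase_deg * pi / 180))
  fid
}

#' Pointwise difference of two spectra
#'
#' Returns `spec_a - spec_b` after checking that the ppm axes match. The
#' J-difference spectrum that displays the edited metabolite multiplets
#' (GABA at 3.01 ppm) with positive absorption is
#' `differenceSpectrum(edited, non_edited)`, the convention used
#' throughout the pipeline.
#'
#' @param spec_a,spec_b [Spectrum-class] objects on identical axes
#' @return a [Spectrum-class]
#' @export
differenceSpectrum <- function(spec_a, spec_b) {
  if (length(spec_a@values) != length(spec_b@values) ||
      max(abs(spec_a@ppm_axis - spec_b@ppm_axis)) > 1e-9)
    stop("spectra are on different ppm axes", call. = FALSE)
  spec_a@values <- spec_a@values - spec_b@values
  spec_a
}

#' Indices of a ppm window
#'
#' @param spec a [Spectrum-class]
#' @param ppm_range length-2 numeric, any order
#' @return integer indices into the spectrum
#' @export
ppmWindow <- function(spec, ppm_range) {
  r <- range(ppm_range)
  which(spec@ppm_axis >= r[1] & spec@ppm_axis <= r[2])
}

#' Peak amplitude within a ppm window
#'
#' @param spec a [Spectrum-class]
#' @param ppm window centre, ppm
#' @param window_ppm half-width of the search window, ppm
#' @param mode `"real"` (signed maximum-magnitude real value) or `"mod"`
#' @return scalar amplitude
#' @export
peakAmplitude <- function(spec, ppm, window_ppm = 0.06,
                          mode = c("real", "mod")) {
  mode <- match.arg(mode)
  idx <- ppmWindow(spec, c(ppm - window_ppm, ppm + window_ppm))
  if (!length(idx)) stop("window outside ppm axis", call. = FALSE)
  v <- spec@values[idx]
  if (mode == "mod") return(max(Mod(v)))
  re <- Re(v)
  re[which.max(abs(re))]
}

#' Full width at half maximum of a spectral peak
#'
#' Locates the magnitude-mode local maximum nearest `peak_ppm`, rotates
#' the local region into absorption by the phase at the apex (the
#' magnitude of a Lorentzian is sqrt(3) times wider than its absorption,
#' so widths are measured on the phased real part), refines the apex by
#' quadratic interpolation over the three surrounding bins, and finds
#' the half-maximum crossings by linear interpolation between bins. The
#' width is returned in Hz.
#'
#' @param spec a [Spectrum-class]
#' @param peak_ppm expected peak position, ppm
#' @param window_ppm half-width of the search window, ppm
#' @return FWHM in Hz
#' @export
linewidthFwhm <- function(spec, peak_ppm, window_ppm = 0.1) {
  p <- spec@params
  idx <- ppmWindow(spec, c(peak_ppm - window_ppm, peak_ppm + window_ppm))
  if (length(idx) < 3) stop("search window too narrow", call. = FALSE)
  mag0 <- Mod(spec@values)
  loc <- idx[which.max(mag0[idx])]
  if (loc <= min(idx) || loc >= max(idx))
    stop("no local maximum near ", peak_ppm, " ppm", call. = FALSE)
  # absorption-mode profile: phase the region by the apex phase
  mag <- Re(spec@values * exp(-1i * Arg(spec@values[loc])))
  # quadratic apex refinement
  y0 <- mag[loc - 1]; y1 <- mag[loc]; y2 <- mag[loc + 1]
  denom <- (y0 - 2 * y1 + y2)
  delta <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
  apex <- y1 - 0.25 * (y0 - y2) * delta
  half <- apex / 2
  hz_per_bin <- p@sweep_hz / p@n_points

  cross <- function(step) {
    i <- loc
    while (i + step >= 1 && i + step <= length(mag) && mag[i + step] > half)
      i <- i + step
    if (i + step < 1 || i + step > length(mag))
      stop("half-maximum crossing outside spectrum", call. = FALSE)
    frac <- (mag[i] - half) / (mag[i] - mag[i + step])
    (i - loc) + step * frac
  }
  (cross(1L) - cross(-1L)) * hz_per_bin
}
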
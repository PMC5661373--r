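#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Acquisition and editing sequence parameters
#'
#' Holds the timing, frequency-axis and editing-pulse parameters shared by
#' every simulated FID and spectrum: echo/repetition time, proton Larmor
#' frequency, carrier (receiver reference, water at 4.7 ppm), spectral
#' width and number of points, and the centres/width of the two
#' frequency-selective editing inversions.
#'
#' @slot te_ms echo time, ms
#' @slot tr_ms repetition time, ms
#' @slot larmor_mhz proton Larmor frequency, MHz (297.2 at 7 T)
#' @slot carrier_ppm transmitter/receiver reference, ppm
#' @slot sweep_hz spectral width, Hz
#' @slot n_points samples per FID (a power of two)
#' @slot edit_on_ppm editing-pulse centre of the edited cycle, ppm
#' @slot edit_off_ppm editing-pulse centre of the non-edited cycle, ppm
#' @slot edit_fwhm_hz full width at half maximum of the editing inversion
#'   profile, Hz
#' @export
setClass("SequenceParams",
  representation(
    te_ms = "numeric", tr_ms = "numeric", larmor_mhz = "numeric",
    carrier_ppm = "numeric", sweep_hz = "numeric", n_points = "integer",
    edit_on_ppm = "numeric", edit_off_ppm = "numeric",
    edit_fwhm_hz = "numeric"
  )
)

setValidity("SequenceParams", function(object) {
  msg <- character()
  if (object@te_ms <= 0) msg <- c(msg, "te_ms must be > 0")
  if (object@tr_ms <= 0) msg <- c(msg, "tr_ms must be > 0")
  if (object@larmor_mhz <= 0) msg <- c(msg, "larmor_mhz must be > 0")
  if (object@sweep_hz <= 0) msg <- c(msg, "sweep_hz must be > 0")
  n <- object@n_points
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    msg <- c(msg, "n_points must be a power of two")
  if (object@edit_fwhm_hz <= 0) msg <- c(msg, "edit_fwhm_hz must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct sequence parameters
#'
#' Defaults reproduce a 7 T BASING-PRESS GABA editing protocol: TE/TR
#' 68/2000 ms, editing pulses at 2.0 and 1.4 ppm (symmetric about 1.7 ppm)
#' with a 60 Hz inversion-profile width.
#'
#' @param te_ms,tr_ms echo and repetition time, ms
#' @param larmor_mhz proton frequency, MHz
#' @param carrier_ppm receiver reference, ppm (water)
#' @param sweep_hz spectral width, Hz
#' @param n_points FID length (power of two)
#' @param edit_on_ppm,edit_off_ppm editing-pulse centres of the two cycles
#' @param edit_fwhm_hz editing inversion profile FWHM, Hz
#' @return a [SequenceParams-class] object
#' @export
sequenceParams <- function(te_ms = 68, tr_ms = 2000, larmor_mhz = 297.2,
                           carrier_ppm = 4.7, sweep_hz = 4000,
                           n_points = 2048L, edit_on_ppm = 2.0,
                           edit_off_ppm = 1.4, edit_fwhm_hz = 60) {
  new("SequenceParams",
    te_ms = te_ms, tr_ms = tr_ms, larmor_mhz = larmor_mhz,
    carrier_ppm = carrier_ppm, sweep_hz = sweep_hz,
    n_points = as.integer(n_points), edit_on_ppm = edit_on_ppm,
    edit_off_ppm = edit_off_ppm, edit_fwhm_hz = edit_fwhm_hz
  )
}

#' Coupled spin system of one metabolite
#'
#' Chemical shifts (ppm) and scalar-coupling matrix (Hz) of the protons of
#' one metabolite. Equivalent CH_n groups are represented by a single
#' pseudo-spin whose `proton_scale` carries the multiplicity, so signal
#' amplitude is proportional to the proton count.
#'
#' @slot name metabolite identifier
#' @slot shifts_ppm chemical shift per spin, ppm
#' @slot j_hz symmetric scalar-coupling matrix, Hz, zero diagonal
#' @slot proton_scale multiplicity weight per spin
#' @export
setClass("SpinSystem",
  representation(
    name = "character", shifts_ppm = "numeric",
    j_hz = "matrix", proton_scale = "numeric"
  )
)

setValidity("SpinSystem", function(object) {
  msg <- character()
  n <- length(object@shifts_ppm)
  if (n < 1L) msg <- c(msg, "at least one spin required")
  if (n > 8L) msg <- c(msg, "at most 8 spins per system (Hilbert dim <= 256)")
  if (any(object@shifts_ppm < 0 | object@shifts_ppm > 10))
    msg <- c(msg, "shifts must lie within [0, 10] ppm")
  j <- object@j_hz
  if (!is.numeric(j) || nrow(j) != n || ncol(j) != n)
    msg <- c(msg, "j_hz must be an n x n numeric matrix")
  else {
    if (max(abs(j - t(j))) > 1e-9) msg <- c(msg, "j_hz must be symmetric")
    if (any(abs(diag(j)) > 1e-12)) msg <- c(msg, "j_hz diagonal must be zero")
  }
  if (length(object@proton_scale) != n || any(object@proton_scale <= 0))
    msg <- c(msg, "proton_scale must be positive, one value per spin")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpinSystem", function(object) {
  cat(sprintf(
    "SpinSystem '%s': %d spin(s) at %s ppm (proton weights %s)\n",
    object@name, length(object@shifts_ppm),
    paste(format(object@shifts_ppm, digits = 4), collapse = ", "),
    paste(object@proton_scale, collapse = ", ")
  ))
  nz <- which(upper.tri(object@j_hz) & abs(object@j_hz) > 0, arr.ind = TRUE)
  if (nrow(nz))
    cat(sprintf("  %d scalar coupling(s), |J| up to %.2f Hz\n",
                nrow(nz), max(abs(object@j_hz))))
})

#' Time-domain signal (free induction decay)
#'
#' @slot samples complex signal samples
#' @slot dwell_s sampling interval, s (1 / sweep width)
#' @slot t0_s first-sample time offset, s
#' @slot params the [SequenceParams-class] the FID was simulated with
#' @export
setClass("Fid",
  representation(
    samples = "complex", dwell_s = "numeric",
    t0_s = "numeric", params = "SequenceParams"
  )
)

setValidity("Fid", function(object) {
  msg <- character()
  if (length(object@samples) != object@params@n_points)
    msg <- c(msg, "length(samples) must equal params@n_points")
  if (abs(object@dwell_s - 1 / object@params@sweep_hz) > 1e-12)
    msg <- c(msg, "dwell_s must equal 1/params@sweep_hz")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Fid", function(object) {
  cat(sprintf("Fid: %d complex points, dwell %.3g ms, |s(0)| = %.4g\n",
              length(object@samples), 1e3 * object@dwell_s,
              Mod(object@samples[1])))
})

#' Frequency-domain spectrum on a ppm axis
#'
#' Values are stored against a strictly descending ppm axis (conventional
#' left-to-right display), referenced to the carrier.
#'
#' @slot values complex spectral values
#' @slot ppm_axis ppm per bin, strictly descending
#' @slot params originating [SequenceParams-class]
#' @export
setClass("Spectrum",
  representation(
    values = "complex", ppm_axis = "numeric", params = "SequenceParams"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@values) != length(object@ppm_axis))
    msg <- c(msg, "values and ppm_axis lengths differ")
  if (any(diff(object@ppm_axis) >= 0))
    msg <- c(msg, "ppm_axis must be strictly descending")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.2f to %.2f ppm\n",
              length(object@values), max(object@ppm_axis),
              min(object@ppm_axis)))
})

#' Simulated basis set of edited / non-edited metabolite FIDs
#'
#' @slot entries named list; each element is `list(edited =, non_edited =)`
#'   of [Fid-class] objects simulated with identical parameters
#' @slot params shared [SequenceParams-class]
#' @slot scheme editing scheme label (`"symmetric_1p7"` or
#'   `"water_symmetric"`)
#' @export
setClass("BasisSet",
  representation(entries = "list", params = "SequenceParams",
                 scheme = "character")
)

.basis_required <- c("NAA", "Glu", "Gln", "GABA", "GSH", "NAAG")

setValidity("BasisSet", function(object) {
  msg <- character()
  if (!all(.basis_required %in% names(object@entries)))
    msg <- c(msg, paste("basis must contain at least",
                        paste(.basis_required, collapse = ", ")))
  ok <- vapply(object@entries, function(e) {
    is.list(e) && all(c("edited", "non_edited") %in% names(e)) &&
      is(e$edited, "Fid") && is(e$non_edited, "Fid") &&
      identical(e$edited@params@n_points, object@params@n_points)
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "each entry needs edited/non_edited Fids sharing params")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet (%s): %s\n", object@scheme,
              paste(names(object@entries), collapse = ", ")))
  cat(sprintf("  TE %.0f ms, %d points, sweep %.0f Hz, edit at %.2f/%.2f ppm\n",
              object@params@te_ms, object@params@n_points,
              object@params@sweep_hz, object@params@edit_on_ppm,
              object@params@edit_off_ppm))
})

#' Complex coil sensitivity maps
#'
#' @slot maps complex array `(coil, nx, ny, nz)`
#' @export
setClass("CoilSensitivities", representation(maps = "array"))

setValidity("CoilSensitivities", function(object) {
  d <- dim(object@maps)
  if (length(d) != 4L) return("maps must be a 4-d (coil, nx, ny, nz) array")
  if (d[1] < 1L) return("at least one coil required")
  pow <- apply(Mod(object@maps)^2, 1, sum)
  if (any(pow == 0)) return("no coil map may be identically zero")
  TRUE
})

#' Multi-coil, multi-average edited/non-edited k-space dataset
#'
#' `data` is a named list with elements `edited` and `non_edited`, each a
#' complex array `(average, coil, kx, ky, kz, time)`. `encoding` records the
#' matrix size, averages per cycle and dwell; `truth` (synthetic data only)
#' stores the generating phantom, sensitivities and injected per-average
#' frequency/phase error tables.
#'
#' @slot data named list of complex arrays, one per editing cycle
#' @slot encoding list: `matrix`, `averages`, `dwell_s`
#' @slot params [SequenceParams-class]
#' @slot truth list of ground-truth generation records (may be empty)
#' @export
setClass("MultiCoilCSI",
  representation(data = "list", encoding = "list",
                 params = "SequenceParams", truth = "list")
)

setValidity("MultiCoilCSI", function(object) {
  msg <- character()
  if (!all(c("edited", "non_edited") %in% names(object@data)))
    msg <- c(msg, "data must have 'edited' and 'non_edited' elements")
  else if (!identical(dim(object@data$edited), dim(object@data$non_edited)))
    msg <- c(msg, "edited and non-edited arrays must have identical shape")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MultiCoilCSI", function(object) {
  d <- dim(object@data$edited)
  cat(sprintf(
    "MultiCoilCSI: %dx%dx%d encoding, %d average(s) x %d coil(s), %d points%s\n",
    d[3], d[4], d[5], d[1], d[2], d[6],
    if (length(object@truth)) " [synthetic truth attached]" else ""))
})

#' Linear-combination fit result
#'
#' @slot amplitudes named non-negative metabolite amplitudes
#' @slot crlb_pct named Cramer-Rao lower bounds, % of amplitude (999 when
#'   the amplitude is zero)
#' @slot ratios named ratios to the reference metabolite
#' @slot noise_sd residual noise estimate (real-part spectral units)
#' @slot baseline_coeffs polynomial baseline coefficients
#' @slot included named logical CRLB-filter outcome
#' @slot phase0_deg zero-order phase applied before fitting, degrees
#' @export
setClass("QuantResult",
  representation(
    amplitudes = "numeric", crlb_pct = "numeric", ratios = "numeric",
    noise_sd = "numeric", baseline_coeffs = "numeric",
    included = "logical", phase0_deg = "numeric"
  )
)

setValidity("QuantResult", function(object) {
  msg <- character()
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@crlb_pct < 0)) msg <- c(msg, "crlb_pct must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult:\n")
  df <- data.frame(
    amplitude = round(object@amplitudes, 4),
    crlb_pct = round(object@crlb_pct, 1),
    included = object@included
  )
  if (length(object@ratios))
    df$ratio <- round(object@ratios[rownames(df)], 4)
  print(df)
  cat(sprintf("  noise sd %.4g, zero-order phase %.1f deg\n",
              object@noise_sd, object@phase0_deg))
})

#' Oriented rectangular prescription volume
#'
#' A spectroscopy voxel prescription in scanner RAS millimetre
#' coordinates: centre, half-lengths along the box axes, and a
#' row-orthonormal rotation whose rows are the box axis directions.
#'
#' @slot center_mm centre, mm (length 3)
#' @slot half_mm half-lengths per axis, mm (length 3)
#' @slot orientation 3x3 row-orthonormal rotation
#' @export
setClass("VoxelBox",
  representation(center_mm = "numeric", half_mm = "numeric",
                 orientation = "matrix")
)

setValidity("VoxelBox", function(object) {
  msg <- character()
  if (length(object@center_mm) != 3L) msg <- c(msg, "center_mm must be length 3")
  if (length(object@half_mm) != 3L || any(object@half_mm <= 0))
    msg <- c(msg, "half_mm must be 3 positive values")
  R <- object@orientation
  if (!is.numeric(R) || !all(dim(R) == c(3L, 3L)) ||
      max(abs(R %*% t(R) - diag(3))) > 1e-8)
    msg <- c(msg, "orientation must be 3x3 orthonormal (to 1e-8)")
  if (length(msg)) msg else TRUE
})

#' Construct a voxel box
#'
#' @param center_mm centre in scanner RAS mm
#' @param size_mm full edge lengths, mm
#' @param orientation 3x3 row-orthonormal rotation (rows = box axes);
#'   identity by default (axis-aligned)
#' @return a [VoxelBox-class]
#' @export
voxelBox <- function(center_mm, size_mm, orientation = diag(3)) {
  new("VoxelBox", center_mm = as.numeric(center_mm),
      half_mm = as.numeric(size_mm) / 2, orientation = orientation)
}

setMethod("show", "VoxelBox", function(object) {
  cat(sprintf("VoxelBox: centre (%s) mm, size (%s) mm\n",
              paste(format(object@center_mm, digits = 4), collapse = ", "),
              paste(format(2 * object@half_mm, digits = 4), collapse = ", ")))
})
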
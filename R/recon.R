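# Reconstruction: k-space FFT with half-voxel in-plane shift, per-coil /
# per-average frequency and phase correction by time-domain spectral
# registration, sensitivity-weighted coil combination, averaging and
# difference spectra.

#' Per-average, per-coil frequency/phase correction estimates
#'
#' @slot freq_hz matrix (average, coil) of frequency shifts relative to
#'   the reference, Hz
#' @slot phase_deg matrix (average, coil) of zero-order phases, degrees
#' @export
setClass("CorrectionEstimate",
  representation(freq_hz = "matrix", phase_deg = "matrix")
)

setValidity("CorrectionEstimate", function(object) {
  if (!all(is.finite(object@freq_hz)) || !all(is.finite(object@phase_deg)))
    return("estimates must be finite")
  if (!identical(dim(object@freq_hz), dim(object@phase_deg)))
    return("freq_hz and phase_deg must have identical shape")
  TRUE
})

setMethod("show", "CorrectionEstimate", function(object) {
  cat(sprintf(
    "CorrectionEstimate: %d average(s) x %d coil(s); |freq| up to %.3f Hz, |phase| up to %.2f deg\n",
    nrow(object@freq_hz), ncol(object@freq_hz),
    max(abs(object@freq_hz)), max(abs(object@phase_deg))))
})

#' Spatial reconstruction of a phase-encoded acquisition
#'
#' Inverse 2-d discrete Fourier transform over (kx, ky) for every cycle,
#' average and coil. When `half_voxel_shift` is on, a linear k-space phase
#' ramp equivalent to a half-voxel in-plane translation is applied before
#' the transform (the convention used to centre the reconstruction grid
#' on the prescribed volume). A 1x1x1 encoding passes through unchanged.
#'
#' @param raw a [MultiCoilCSI-class] in the k-space domain
#' @param half_voxel_shift logical, or a numeric length-2 shift in voxel
#'   units (e.g. `c(0.5, 0.5)`); `TRUE` means half a voxel in x and y
#' @return a [MultiCoilCSI-class] whose `data` arrays are in the image
#'   domain (`encoding$domain == "image"`)
#' @export
csiReconstruct <- function(raw, half_voxel_shift = TRUE) {
  stopifnot(is(raw, "MultiCoilCSI"))
  mat <- raw@encoding$matrix
  if (all(mat == 1L)) {
    raw@encoding$domain <- "image"
    return(raw)
  }
  shift <- if (isTRUE(half_voxel_shift)) c(0.5, 0.5)
           else if (isFALSE(half_voxel_shift)) c(0, 0)
           else as.numeric(half_voxel_shift)
  kx <- 0:(mat[1] - 1); ky <- 0:(mat[2] - 1)
  ramp <- exp(-2i * pi * (outer(kx * shift[1] / mat[1],
                                ky * shift[2] / mat[2], "+")))
  out <- raw
  for (cyc in names(raw@data)) {
    arr <- raw@data[[cyc]]
    d <- dim(arr)  # (avg, coil, kx, ky, kz, t)
    for (a in seq_len(d[1])) for (ci in seq_len(d[2])) {
      ksp <- array(arr[a, ci, , , 1, ], dim = c(d[3], d[4], d[6]))
      ksp <- sweep(ksp, c(1, 2), ramp, `*`)
      arr[a, ci, , , 1, ] <- .dft2(ksp, inverse = TRUE)
    }
    out@data[[cyc]] <- arr
  }
  out@encoding$domain <- "image"
  out
}

# restrict an FID to one or more ppm windows (frequency-domain mask,
# back-transform); window_ppm is a length-2 vector or a list of them
.bandpass_fid <- function(x, params, window_ppm) {
  n <- params@n_points
  sp <- stats::fft(x)
  shift_idx <- c((n / 2 + 1):n, 1:(n / 2))
  freq <- (seq_len(n) - 1 - n / 2) * (params@sweep_hz / n)
  ppm <- params@carrier_ppm + freq / params@larmor_mhz
  if (!is.list(window_ppm)) window_ppm <- list(window_ppm)
  mask_shifted <- Reduce(`|`, lapply(window_ppm, function(w)
    ppm >= min(w) & ppm <= max(w)))
  mask <- logical(n)
  mask[shift_idx] <- mask_shifted
  sp[!mask] <- 0i
  stats::fft(sp, inverse = TRUE) / n
}

# frequency and phase of s relative to ref.
# Coarse stage: zero-padded FFT peak of the full-band cross signal
# g(t) = s conj(ref) with quadratic interpolation. Fine stage: windowed
# nonlinear least squares in which the REFERENCE is frequency-shifted in
# the time domain before the spectral window is applied (windowing a
# shifted signal with a fixed mask destroys the phase-ramp model), with
# the zero-order phase solved analytically at each candidate shift.
.freq_phase_of <- function(s, ref, params, window_ppm, pad = 8L,
                           fine_bracket_hz = 1.5) {
  dwell <- 1 / params@sweep_hz
  g <- s * Conj(ref)
  n <- length(g)
  m <- n * pad
  G <- stats::fft(c(g, complex(m - n)))
  mag <- Mod(G)
  k <- which.max(mag) - 1L
  km <- (k - 1L) %% m + 1L; kp <- (k + 1L) %% m + 1L
  y0 <- mag[km]; y1 <- mag[k + 1L]; y2 <- mag[kp]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
  kk <- k + delta
  if (kk > m / 2) kk <- kk - m
  df0 <- kk / (m * dwell)

  tt <- (seq_len(n) - 1) * dwell
  bs <- .bandpass_fid(s, params, window_ppm)
  es <- sum(Mod(bs)^2)
  cross_at <- function(df) {
    br <- .bandpass_fid(ref * exp(2i * pi * df * tt), params, window_ppm)
    list(c = sum(bs * Conj(br)), e = sum(Mod(br)^2))
  }
  obj <- function(df) {
    cr <- cross_at(df)
    es + cr$e - 2 * Mod(cr$c)
  }
  opt <- stats::optimize(obj, df0 + c(-1, 1) * fine_bracket_hz, tol = 1e-5)
  df <- opt$minimum
  ph <- Arg(cross_at(df)$c)
  c(freq_hz = df, phase_deg = ph * 180 / pi)
}

#' Estimate per-average frequency and phase errors
#'
#' Time-domain spectral registration against a reference average,
#' restricted to a spectral window containing a stable peak (default
#' 2.9-3.1 ppm, the creatine region). For each average (and coil) the
#' dominant frequency of `s_a(t) * conj(ref(t))` gives the frequency
#' shift, and its residual argument the zero-order phase, both relative
#' to the reference; applying the negated estimates aligns the averages.
#' If the reference-window signal is below the SNR floor a warning is
#' issued and zero corrections are returned.
#'
#' @param fids complex matrix (average, time) or 3-d array
#'   (average, coil, time)
#' @param params a [SequenceParams-class]
#' @param ref_window_ppm spectral registration window, ppm (a length-2
#'   vector or a list of them)
#' @param reference reference FID (defaults to the first average; pass
#'   the first non-edited average to align both cycles to one target)
#' @param snr_floor minimum window peak / noise ratio
#' @param smooth_averages odd window length for local-linear smoothing
#'   of the frequency series across averages (1 = none). Scanner drift
#'   is smooth in time, so pooling neighbouring averages sharpens the
#'   per-average frequency estimates well below the single-average
#'   information limit; phases are left per-average (phase jitter is
#'   not smooth). Estimates are re-anchored to the (smoothed) value at
#'   the first average so they stay relative to it.
#' @param refine_reference after a first alignment pass, register once
#'   more against the aligned mean of all averages; this removes the
#'   error floor contributed by the noise of the single reference
#'   average, which is common to every estimate
#' @return a [CorrectionEstimate-class]
#' @export
estimateFreqPhase <- function(fids, params, ref_window_ppm = c(2.9, 3.1),
                              reference = NULL, snr_floor = 5,
                              smooth_averages = 1L,
                              refine_reference = TRUE) {
  if (length(dim(fids)) == 2L)
    dim(fids) <- c(nrow(fids), 1L, ncol(fids))
  d <- dim(fids)
  if (d[3] != params@n_points)
    stop("time dimension does not match params@n_points", call. = FALSE)
  freq <- matrix(0, d[1], d[2])
  phase <- matrix(0, d[1], d[2])
  dwell <- 1 / params@sweep_hz
  for (ci in seq_len(d[2])) {
    ref_raw <- if (is.null(reference)) fids[1, ci, ] else {
      if (length(dim(reference)) == 2L) reference[ci, ] else reference
    }
    ref <- .bandpass_fid(ref_raw, params, ref_window_ppm)
    # SNR floor: window peak against a robust full-spectrum noise level
    # (metabolite peaks are sparse, so the median absolute deviation of
    # the real part tracks the noise)
    peak <- max(Mod(stats::fft(ref)))
    noise <- stats::mad(Re(stats::fft(ref_raw)))
    if (!is.finite(noise) || noise == 0) noise <- .Machine$double.eps
    if (peak / noise < snr_floor) {
      warning("reference window SNR below floor; returning zero corrections")
      next
    }
    tt <- (seq_len(d[3]) - 1) * dwell
    run_pass <- function(target) {
      out <- matrix(0, d[1], 2)
      for (a in seq_len(d[1]))
        out[a, ] <- .freq_phase_of(fids[a, ci, ], target, params,
                                   ref_window_ppm)
      out
    }
    est <- run_pass(ref_raw)
    if (refine_reference && d[1] > 1L) {
      aligned <- vapply(seq_len(d[1]), function(a)
        fids[a, ci, ] * exp(-1i * (2 * pi * est[a, 1] * tt +
                                     est[a, 2] * pi / 180)),
        complex(d[3]))
      est <- run_pass(as.complex(rowMeans(aligned)))
    }
    freq[, ci] <- est[, 1]
    phase[, ci] <- est[, 2]
  }
  if (smooth_averages > 1L && d[1] > 2L)
    freq <- apply(freq, 2, .local_linear,
                  half_width = (smooth_averages - 1L) %/% 2L)
  freq <- sweep(freq, 2, freq[1, ])
  phase <- sweep(phase, 2, phase[1, ])
  phase <- ((phase + 180) %% 360) - 180
  new("CorrectionEstimate", freq_hz = as.matrix(freq),
      phase_deg = as.matrix(phase))
}

# local linear (Savitzky-Golay degree 1) smoother; unbiased for a
# linear trend including at the series ends
.local_linear <- function(x, half_width) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half_width):min(n, i + half_width)
    if (length(j) < 3) { out[i] <- x[i]; next }
    fit <- stats::lm.fit(cbind(1, j - i), x[j])
    out[i] <- fit$coefficients[1]
  }
  out
}

#' Apply (negated) correction estimates to per-average FIDs
#'
#' @param fids matrix (average, time) or array (average, coil, time)
#' @param est a [CorrectionEstimate-class] from [estimateFreqPhase()]
#' @param params a [SequenceParams-class]
#' @return corrected array of the input shape
#' @export
applyCorrections <- function(fids, est, params) {
  two_d <- length(dim(fids)) == 2L
  if (two_d) dim(fids) <- c(nrow(fids), 1L, ncol(fids))
  d <- dim(fids)
  tt <- (seq_len(d[3]) - 1) / params@sweep_hz
  for (a in seq_len(d[1])) for (ci in seq_len(d[2])) {
    fids[a, ci, ] <- fids[a, ci, ] *
      exp(-1i * (2 * pi * est@freq_hz[a, ci] * tt +
                   est@phase_deg[a, ci] * pi / 180))
  }
  if (two_d) dim(fids) <- d[c(1, 3)]
  fids
}

#' Sensitivity-weighted coil combination
#'
#' Weighted sum with conjugate-sensitivity weights normalised by the sum
#' of squared sensitivity magnitudes at the voxel, so a signal identical
#' in all coils under unit sensitivities is returned unchanged.
#'
#' @param fids complex matrix (coil, time)
#' @param sens complex sensitivity per coil at the voxel
#' @return complex vector (time)
#' @export
combineCoils <- function(fids, sens) {
  if (is.null(dim(fids))) fids <- matrix(fids, nrow = 1)
  if (length(sens) != nrow(fids))
    stop("coil count does not match sensitivities", call. = FALSE)
  norm <- sum(Mod(sens)^2)
  if (norm == 0) stop("all-zero sensitivities at voxel", call. = FALSE)
  as.complex(crossprod(fids, Conj(sens))[, 1] / norm)
}

#' Full voxel reconstruction pipeline
#'
#' Spatial reconstruction, per-coil/per-average frequency-phase
#' correction (both cycles registered to the first non-edited average),
#' sensitivity-weighted coil combination, averaging, Fourier transform
#' and cycle difference.
#'
#' @param raw a [MultiCoilCSI-class]
#' @param voxel spatial voxel index `c(i, j, k)` (1-based)
#' @param correct apply frequency/phase correction
#' @param half_voxel_shift see [csiReconstruct()]
#' @param ref_window_ppm spectral registration window
#' @param smooth_averages drift-smoothing window passed to
#'   [estimateFreqPhase()]
#' @return list with elements `edited`, `non_edited`, `difference`
#'   ([Spectrum-class]; difference = edited - non_edited), the combined
#'   per-cycle FIDs, and the [CorrectionEstimate-class]s used
#' @export
reconstructVoxel <- function(raw, voxel = c(1L, 1L, 1L), correct = TRUE,
                             half_voxel_shift = TRUE,
                             ref_window_ppm = c(2.9, 3.1),
                             smooth_averages = 9L) {
  img <- if (identical(raw@encoding$domain, "image")) raw
         else csiReconstruct(raw, half_voxel_shift)
  p <- raw@params
  truth <- raw@truth
  sens <- if (!is.null(truth$coils))
    truth$coils@maps[, voxel[1], voxel[2], voxel[3]]
  else rep(1 + 0i, dim(img@data$edited)[2])
  sens <- as.complex(sens)

  vox_fids <- lapply(img@data, function(arr) {
    d <- dim(arr)
    array(arr[, , voxel[1], voxel[2], voxel[3], ], dim = d[c(1, 2, 6)])
  })

  ests <- NULL
  if (correct) {
    # each cycle registered to its own first average (identical spectral
    # content within a cycle); the residual between-cycle offset is one
    # drift step and is small next to the uncorrected spread
    ests <- lapply(vox_fids, estimateFreqPhase, params = p,
                   ref_window_ppm = ref_window_ppm,
                   smooth_averages = smooth_averages)
    vox_fids <- mapply(function(f, e) applyCorrections(f, e, p),
                       vox_fids, ests, SIMPLIFY = FALSE)
  }

  combined <- lapply(vox_fids, function(arr) {
    d <- dim(arr)
    acc <- complex(d[3])
    for (a in seq_len(d[1]))
      acc <- acc + combineCoils(array(arr[a, , ], dim = d[2:3]), sens)
    acc / d[1]
  })

  if (correct) {
    # the within-cycle step aligns each cycle to its own first average,
    # leaving an inter-cycle frequency/phase offset that would dominate
    # the subtraction artifact. Direct spectral registration between the
    # cycles is contaminated by the genuine editing differences (their
    # dispersive tails reach every window), so instead:
    # (1) frequency offset from the interleaving structure: a non-edited
    #     average sits midway in time between two edited ones, so for a
    #     smooth drift the offset is the mean midpoint discrepancy of
    #     the two within-cycle shift series;
    # (2) zero-order phase by closed-form minimisation of the
    #     subtraction residual over the creatine windows.
    n_avg <- nrow(ests$edited@freq_hz)
    df_ic <- 0
    if (n_avg >= 2) {
      a <- seq_len(n_avg - 1)
      per_coil <- colMeans(
        ests$non_edited@freq_hz[a, , drop = FALSE] -
          (ests$edited@freq_hz[a, , drop = FALSE] +
             ests$edited@freq_hz[a + 1, , drop = FALSE]) / 2)
      df_ic <- mean(per_coil)
    }
    tt <- (seq_len(p@n_points) - 1) / p@sweep_hz
    ed_shift <- combined$edited * exp(-2i * pi * df_ic * tt)
    # phase windows hold only resonances common to both cycles: the
    # residual water (which dominates the estimate whenever present, the
    # most reliable phase reference), the Cr methylene and the NAA
    # aspartyl region; the edited multiplets around 2.0-2.35 and
    # 3.01 ppm would bias the estimate
    wins <- list(c(4.55, 4.85), c(3.85, 3.97), c(2.55, 2.75))
    be <- .bandpass_fid(ed_shift, p, wins)
    bn <- .bandpass_fid(combined$non_edited, p, wins)
    ph_ic <- Arg(sum(be * Conj(bn)))
    combined$edited <- ed_shift * exp(-1i * ph_ic)
  }

  mk <- function(x) new("Fid", samples = as.complex(x), dwell_s = 1 / p@sweep_hz,
                        t0_s = 0, params = p)
  spec <- lapply(combined, function(x) fidToSpectrum(mk(x)))
  list(
    edited = spec$edited,
    non_edited = spec$non_edited,
    difference = differenceSpectrum(spec$edited, spec$non_edited),
    fids = lapply(combined, mk),
    corrections = ests
  )
}
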
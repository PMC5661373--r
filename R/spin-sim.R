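# Density-matrix simulation of PRESS with BASING/MEGA-style
# frequency-selective editing.
#
# Localization is idealised (hard-pulse double spin echo); the editing
# pulse is an instantaneous per-spin rotation whose longitudinal scaling
# follows a Gaussian inversion profile. The full scalar-coupling
# Hamiltonian is used (strong coupling); weak-coupling product-operator
# formulas appear only as oracles in the tests.

.Ix <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
.Iy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
.Iz <- diag(c(0.5, -0.5))

# full-space single-spin operator: op on spin i of n
.spin_op <- function(op, i, n) {
  m <- if (i == 1L) op else diag(2)
  if (n == 1L) return(m + 0i)
  for (k in 2:n) m <- kronecker(m, if (k == i) op else diag(2))
  m + 0i
}

# product rotation exp(-i * sum theta_i Ix_i) as a matrix product of
# single-spin rotations (they commute across spins)
.rotation_x <- function(theta, n) {
  U <- diag(2^n) + 0i
  for (i in seq_len(n)) {
    if (abs(theta[i]) < 1e-15) next
    r2 <- cos(theta[i] / 2) * diag(2) - 2i * sin(theta[i] / 2) * .Ix
    U <- U %*% .spin_op(r2, i, n)
  }
  U
}

# coherence-order decomposition: element (r, c) of the density matrix in
# the Zeeman product basis carries order m_r - m_c, with m the total Iz
# eigenvalue. Crusher gradients in PRESS/BASING dephase every pathway but
# the echo pathway (-1 -> +1 -> -1 across the two refocusing pulses);
# zeroing the other orders emulates that selection and removes the
# anti-echo strong-coupling artifacts an ideal-unitary simulation would
# otherwise retain.
.coherence_orders <- function(iz_list) {
  m <- Re(diag(Reduce(`+`, iz_list)))
  outer(m, m, "-")
}

.hamiltonian <- function(system, params, coupling = "strong") {
  n <- length(system@shifts_ppm)
  nu <- ppmToHz(system@shifts_ppm, params)
  d <- 2L^n
  H <- matrix(0i, d, d)
  iz <- lapply(seq_len(n), function(i) .spin_op(.Iz, i, n))
  ix <- lapply(seq_len(n), function(i) .spin_op(.Ix, i, n))
  iy <- lapply(seq_len(n), function(i) .spin_op(.Iy, i, n))
  for (i in seq_len(n)) H <- H + 2 * pi * nu[i] * iz[[i]]
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (k <= i || system@j_hz[i, k] == 0) next
    jterm <- iz[[i]] %*% iz[[k]]
    if (coupling == "strong")
      jterm <- jterm + ix[[i]] %*% ix[[k]] + iy[[i]] %*% iy[[k]]
    H <- H + 2 * pi * system@j_hz[i, k] * jterm
  }
  list(H = H, iz = iz, ix = ix, iy = iy, n = n)
}

#' Longitudinal scaling of a frequency-selective inversion pulse
#'
#' Gaussian inversion profile `1 - 2 exp(-4 ln 2 * offset^2 / fwhm^2)`:
#' -1 (full inversion) on resonance, rising monotonically to +1
#' (unperturbed) far off resonance; even in the offset.
#'
#' @param offset_hz frequency offset from the pulse centre, Hz
#' @param fwhm_hz profile full width at half maximum, Hz
#' @return longitudinal scaling in `[-1, 1]`
#' @examples
#' inversionProfile(0, 60)    # -1
#' inversionProfile(300, 60)  # ~ +1
#' @export
inversionProfile <- function(offset_hz, fwhm_hz) {
  if (!is.numeric(fwhm_hz) || length(fwhm_hz) != 1L || fwhm_hz <= 0)
    stop("fwhm_hz must be a positive scalar", call. = FALSE)
  1 - 2 * exp(-4 * log(2) * offset_hz^2 / fwhm_hz^2)
}

#' Simulate one BASING-PRESS cycle of a spin system
#'
#' Ideal 90-degree excitation followed by a hard-pulse double spin echo of
#' total duration TE (refocusing pulses at TE/4 and 3TE/4), with a
#' frequency-selective editing inversion applied immediately after each
#' refocusing pulse. This placement separates the two editing inversions
#' by TE/2 symmetrically about the echo centre, which refocuses the
#' J-evolution of partners of the inverted spins. Each spin is rotated by
#' `acos(lambda)` where `lambda` is [inversionProfile()] evaluated at the
#' spin's offset from `edit_center_ppm`; with `edit_center_ppm = NULL` the
#' editing pulse is absent (non-edited cycle). The returned FID starts at
#' the echo top and is normalised so its `t = 0` value for an uncoupled
#' system equals the sum of `proton_scale`.
#'
#' @param system a [SpinSystem-class]
#' @param params a [SequenceParams-class]
#' @param edit_center_ppm editing-pulse centre (ppm), or `NULL` for the
#'   non-edited cycle
#' @param diagnostics when `TRUE`, attach attributes `trace_dev` and
#'   `herm_dev` (maximum deviation of the density-matrix trace and of
#'   hermiticity across all evolution steps)
#' @param coupling `"strong"` (default: full isotropic scalar coupling) or
#'   `"weak"` (secular IzSz term only). The weak mode exists so the engine
#'   can be validated against analytic product-operator closed forms,
#'   which are exact only in the secular approximation; all production
#'   simulation uses the full Hamiltonian.
#' @return a [Fid-class]
#' @export
simulatePressBasing <- function(system, params, edit_center_ppm = NULL,
                                diagnostics = FALSE,
                                coupling = c("strong", "weak")) {
  stopifnot(is(system, "SpinSystem"), is(params, "SequenceParams"))
  coupling <- match.arg(coupling)
  n <- length(system@shifts_ppm)
  if (2^n > 256) stop("Hilbert dimension ", 2^n, " exceeds 256", call. = FALSE)

  ops <- .hamiltonian(system, params, coupling)
  eg <- eigen(ops$H, symmetric = TRUE)
  V <- eg$vectors
  lam <- eg$values
  Vh <- Conj(t(V))
  prop <- function(tau) V %*% (exp(-1i * lam * tau) * Vh)

  # equilibrium deviation density operator, weighted by multiplicity
  rho <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) rho <- rho + system@proton_scale[i] * ops$iz[[i]]

  tr0 <- sum(diag(rho))
  dev_trace <- 0
  dev_herm <- 0
  apply_u <- function(rho, U) {
    Uh <- Conj(t(U))
    out <- U %*% rho %*% Uh
    if (diagnostics) {
      dev_trace <<- max(dev_trace, Mod(sum(diag(out)) - tr0))
      # a unitary step maps the anti-Hermitian part exactly; any growth
      # beyond U (rho - rho^H) U^H is numerical error
      dev_herm <<- max(dev_herm, max(Mod(
        (out - Conj(t(out))) - U %*% (rho - Conj(t(rho))) %*% Uh)))
    }
    out
  }

  u90 <- .rotation_x(rep(pi / 2, n), n)
  u180 <- .rotation_x(rep(pi, n), n)
  uedit <- NULL
  if (!is.null(edit_center_ppm)) {
    off <- ppmToHz(system@shifts_ppm, params) -
      ppmToHz(edit_center_ppm, params)
    lambda <- pmin(1, pmax(-1, inversionProfile(off, params@edit_fwhm_hz)))
    uedit <- .rotation_x(acos(lambda), n)
  }

  te <- params@te_ms * 1e-3
  u_quarter <- prop(te / 4)
  u_half <- prop(te / 2)
  ord <- .coherence_orders(ops$iz)
  select_order <- function(rho, p) { rho[ord != p] <- 0i; rho }

  rho <- apply_u(rho, u90)
  rho <- select_order(rho, -1)
  rho <- apply_u(rho, u_quarter)
  rho <- apply_u(rho, u180)
  if (!is.null(uedit)) rho <- apply_u(rho, uedit)
  rho <- select_order(rho, +1)
  rho <- apply_u(rho, u_half)
  rho <- apply_u(rho, u180)
  if (!is.null(uedit)) rho <- apply_u(rho, uedit)
  rho <- select_order(rho, -1)
  rho <- apply_u(rho, u_quarter)

  # acquisition: express the observable trace in the Hamiltonian
  # eigenbasis and read the FID off the coherence frequencies
  fplus <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) fplus <- fplus + ops$ix[[i]] + 1i * ops$iy[[i]]
  obs <- Vh %*% fplus %*% V
  rho_t <- Vh %*% rho %*% V
  amp <- t(obs) * rho_t              # amp[l,k] = obs_kl * rho~_lk
  omega <- outer(lam, lam, "-")      # omega[l,k] = lam_l - lam_k
  keep <- Mod(amp) > max(Mod(amp)) * 1e-12
  a <- amp[keep]
  w <- omega[keep]                   # s(t) = sum a * exp(-i w t)

  dwell <- 1 / params@sweep_hz
  tt <- (seq_len(params@n_points) - 1) * dwell
  sig <- exp(-1i * outer(tt, w)) %*% a
  sig <- as.complex(sig * (2i / 2^(n - 1)))

  fid <- new("Fid", samples = sig, dwell_s = dwell, t0_s = 0,
             params = params)
  if (diagnostics) {
    attr(fid, "trace_dev") <- dev_trace
    attr(fid, "herm_dev") <- dev_herm
  }
  fid
}

#' Editing-pulse centres of a named editing scheme
#'
#' `symmetric_1p7` places the two cycles at 2.0 and 1.4 ppm, symmetric
#' about the 1.7 ppm resonance that macromolecules couple to (so MM
#' co-editing cancels in the difference); `water_symmetric` places them at
#' 2.0 ppm and its mirror about the carrier (7.4 ppm for water at 4.7).
#'
#' @param scheme `"symmetric_1p7"` or `"water_symmetric"`
#' @param params a [SequenceParams-class] (supplies the carrier)
#' @return named numeric `c(on = , off = )`, ppm
#' @export
editingCenters <- function(scheme = c("symmetric_1p7", "water_symmetric"),
                           params = sequenceParams()) {
  scheme <- match.arg(scheme)
  on <- 2.0
  off <- if (scheme == "symmetric_1p7") 1.4 else 2 * params@carrier_ppm - on
  c(on = on, off = off)
}

#' Simulate a full edited/non-edited basis set
#'
#' Runs [simulatePressBasing()] for every metabolite in the spin-system
#' library (or a chosen subset), once per editing cycle, with identical
#' sequence parameters. Deterministic.
#'
#' @param params a [SequenceParams-class]
#' @param scheme editing scheme, see [editingCenters()]
#' @param metabolites metabolite names to simulate (default: the whole
#'   library)
#' @return a [BasisSet-class]
#' @export
makeBasis <- function(params = sequenceParams(),
                      scheme = c("symmetric_1p7", "water_symmetric"),
                      metabolites = spinLibraryNames()) {
  scheme <- match.arg(scheme)
  centers <- editingCenters(scheme, params)
  params@edit_on_ppm <- centers[["on"]]
  params@edit_off_ppm <- centers[["off"]]
  entries <- lapply(metabolites, function(m) {
    sys <- buildSpinSystem(m)
    list(
      edited = simulatePressBasing(sys, params, centers[["on"]]),
      non_edited = simulatePressBasing(sys, params, centers[["off"]])
    )
  })
  names(entries) <- metabolites
  new("BasisSet", entries = entries, params = params, scheme = scheme)
}
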
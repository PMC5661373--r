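# Test-retest reproducibility and prescription-geometry statistics:
# two-point CVs, dice overlap of oriented voxel boxes, centre shifts,
# affine transport of prescriptions, tissue fractions, paired t-tests,
# chemical-shift displacement.

#' Two-measurement coefficient of variation
#'
#' Sample standard deviation of the two measurements (n-1 denominator,
#' i.e. `|a-b|/sqrt(2)`) divided by their mean, in percent.
#'
#' @param a,b the two measurements (scalars or equal-length vectors,
#'   paired elementwise)
#' @return CV in percent
#' @examples
#' cvTwo(0.106, 0.100) # 4.1
#' @export
cvTwo <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must pair up", call. = FALSE)
  m <- (a + b) / 2
  if (any(m == 0)) stop("mean of the two measurements is zero", call. = FALSE)
  100 * (abs(a - b) / sqrt(2)) / m
}

#' Mean of a set of coefficients of variation
#'
#' @param cvs numeric vector of CVs, percent
#' @return arithmetic mean, percent
#' @export
averagedCv <- function(cvs) {
  if (!length(cvs)) stop("empty CV list", call. = FALSE)
  mean(cvs)
}

# world coordinates of a rasterisation grid covering box(es)
.box_corners <- function(box) {
  s <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  t(apply(s, 1, function(sg)
    box@center_mm + as.numeric(t(box@orientation) %*% (sg * box@half_mm))))
}

.points_in_box <- function(pts, box) {
  loc <- box@orientation %*% (t(pts) - box@center_mm)
  colSums(abs(loc) <= box@half_mm + 1e-12) == 3L
}

#' Dice overlap of two oriented voxel boxes
#'
#' `2 |A and B| / (|A| + |B|)` computed by rasterising both boxes on a
#' common grid (cell centres at `resolution_mm` spacing) covering their
#' joint bounding box.
#'
#' @param a,b [VoxelBox-class] objects
#' @param resolution_mm rasterisation step, mm (default 0.5)
#' @return dice ratio in `[0, 1]`
#' @export
diceOverlap <- function(a, b, resolution_mm = 0.5) {
  if (resolution_mm <= 0) stop("resolution_mm must be > 0", call. = FALSE)
  corners <- rbind(.box_corners(a), .box_corners(b))
  lo <- apply(corners, 2, min) - resolution_mm
  hi <- apply(corners, 2, max) + resolution_mm
  ax <- lapply(1:3, function(i)
    seq(lo[i] + resolution_mm / 2, hi[i], by = resolution_mm))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  in_a <- .points_in_box(pts, a)
  in_b <- .points_in_box(pts, b)
  na <- sum(in_a); nb <- sum(in_b)
  if (na + nb == 0) return(0)
  2 * sum(in_a & in_b) / (na + nb)
}

#' Total shift between two prescription centres
#'
#' Euclidean norm of the centre displacement (square root of the sum of
#' squared shifts along the three orthogonal dimensions).
#'
#' @param c1,c2 length-3 centres, mm (or [VoxelBox-class] objects)
#' @return distance, mm
#' @export
totalShift <- function(c1, c2) {
  if (is(c1, "VoxelBox")) c1 <- c1@center_mm
  if (is(c2, "VoxelBox")) c2 <- c2@center_mm
  if (length(c1) != 3L || length(c2) != 3L)
    stop("centres must have 3 components", call. = FALSE)
  sqrt(sum((c2 - c1)^2))
}

#' Transport a voxel box through an affine transform
#'
#' Maps the centre through the 4x4 transform and composes the
#' orientation with the rotational factor of its polar decomposition;
#' half-lengths are scaled by the isotropic scale factor. A box is only
#' preserved exactly under rigid plus isotropic-scale transforms: shear
#' or anisotropic stretch beyond `tol` triggers a warning, and the
#' returned box is the rotation-scale approximation.
#'
#' @param box a [VoxelBox-class] (e.g. an MNI-space prescription)
#' @param t 4x4 affine matrix, bottom row (0, 0, 0, 1), voxel-to-mm /
#'   space-to-space convention
#' @param tol relative anisotropy/shear tolerance (default 1e-3)
#' @return the transformed [VoxelBox-class]
#' @export
applyAffineToBox <- function(box, t, tol = 1e-3) {
  if (!is.matrix(t) || !all(dim(t) == c(4, 4)))
    stop("t must be a 4x4 matrix", call. = FALSE)
  if (max(abs(t[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("bottom row of the affine must be (0, 0, 0, 1)", call. = FALSE)
  A <- t[1:3, 1:3]
  if (abs(det(A)) < 1e-12) stop("affine is not invertible", call. = FALSE)
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {  # keep a proper rotation
    u <- sv$u; u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  scale_iso <- exp(mean(log(sv$d)))
  if (max(abs(sv$d / scale_iso - 1)) > tol)
    warning("anisotropic scale/shear: transformed box is approximate")
  new("VoxelBox",
      center_mm = as.numeric(A %*% box@center_mm + t[1:3, 4]),
      half_mm = box@half_mm * scale_iso,
      orientation = box@orientation %*% t(R))
}

#' Tissue fractions within a prescription box
#'
#' Probability-weighted mean of gray matter, white matter and CSF over
#' the rasterised box interior, normalised so the three classes sum to
#' 100 percent.
#'
#' @param box a [VoxelBox-class] in scanner mm
#' @param masks list with probability arrays `gm`, `wm`, `csf` in
#'   `[0, 1]` and a 4x4 `affine` (voxel index to mm, 0-based indices)
#' @param resolution_mm rasterisation step, mm
#' @return named numeric `(gm, wm, csf)` percentages
#' @export
tissueFractions <- function(box, masks, resolution_mm = 1) {
  stopifnot(all(c("gm", "wm", "csf", "affine") %in% names(masks)))
  dg <- dim(masks$gm)
  if (any(masks$gm + masks$wm + masks$csf > 1 + 1e-6))
    stop("tissue probabilities exceed 1", call. = FALSE)
  corners <- .box_corners(box)
  lo <- apply(corners, 2, min); hi <- apply(corners, 2, max)
  ax <- lapply(1:3, function(i)
    seq(lo[i] + resolution_mm / 2, hi[i], by = resolution_mm))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  pts <- pts[.points_in_box(pts, box), , drop = FALSE]
  inv <- solve(masks$affine)
  vox <- t(inv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
  # nearest-neighbour sampling, 0-based voxel convention
  iv <- round(vox) + 1
  ok <- iv[, 1] >= 1 & iv[, 1] <= dg[1] & iv[, 2] >= 1 & iv[, 2] <= dg[2] &
    iv[, 3] >= 1 & iv[, 3] <= dg[3]
  if (!any(ok)) stop("box does not intersect the mask volume", call. = FALSE)
  iv <- iv[ok, , drop = FALSE]
  lin <- iv[, 1] + dg[1] * (iv[, 2] - 1) + dg[1] * dg[2] * (iv[, 3] - 1)
  raw <- c(gm = mean(masks$gm[lin]), wm = mean(masks$wm[lin]),
           csf = mean(masks$csf[lin]))
  100 * raw / sum(raw)
}

#' Read tissue probability masks from NIfTI files
#'
#' Thin convenience reader producing the list [tissueFractions()]
#' expects. Requires the RNifti package.
#'
#' @param gm_file,wm_file,csf_file NIfTI file paths
#' @return list with `gm`, `wm`, `csf` arrays and the `affine`
#' @export
readTissueMasks <- function(gm_file, wm_file, csf_file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI masks", call. = FALSE)
  gm <- RNifti::readNifti(gm_file)
  list(gm = as.array(gm), wm = as.array(RNifti::readNifti(wm_file)),
       csf = as.array(RNifti::readNifti(csf_file)),
       affine = structure(RNifti::xform(gm), class = "matrix"))
}

#' GABA+ overestimation factor
#'
#' Fractional excess of the macromolecule-contaminated estimate over the
#' clean one: `(gaba_plus_ratio - gaba_ratio) / gaba_ratio`.
#'
#' @param gaba_plus_ratio GABA+/NAA from water-symmetric editing
#' @param gaba_ratio GABA/NAA from symmetric-1.7 editing
#' @return fractional excess (1.76 means 1.76 times higher)
#' @examples
#' overestimationFactor(0.58, 0.21) # ~1.76
#' @export
overestimationFactor <- function(gaba_plus_ratio, gaba_ratio) {
  if (any(gaba_ratio <= 0)) stop("gaba_ratio must be > 0", call. = FALSE)
  (gaba_plus_ratio - gaba_ratio) / gaba_ratio
}

#' Paired t-test on two measurement sessions
#'
#' Standard paired t statistic with a two-sided p value on n-1 degrees
#' of freedom. Identical sessions return `t = 0, p = 1`; constant
#' non-zero differences (zero variance) are degenerate and error.
#'
#' @param a,b equal-length numeric vectors (length >= 2)
#' @return list with `t`, `p`, `df`
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need equal-length vectors of length >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1L))
    stop("degenerate input: constant non-zero differences", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Chemical-shift displacement between two resonances
#'
#' Fraction of the selected dimension by which the excited volume shifts
#' between resonances `offset_ppm` apart, for a localisation pulse of
#' the given bandwidth: `offset_ppm * larmor_mhz / pulse_bw_hz`.
#'
#' @param offset_ppm chemical-shift separation, ppm
#' @param pulse_bw_hz localisation pulse bandwidth, Hz
#' @param larmor_mhz proton frequency, MHz
#' @return fractional voxel displacement
#' @export
chemicalShiftDisplacement <- function(offset_ppm, pulse_bw_hz,
                                      larmor_mhz = 297.2) {
  if (pulse_bw_hz <= 0) stop("pulse_bw_hz must be > 0", call. = FALSE)
  offset_ppm * larmor_mhz / pulse_bw_hz
}

#' Minimum over-excitation factor covering a ppm range
#'
#' The excited volume must be enlarged so that every resonance in
#' `range_ppm` still covers the prescribed voxel despite its
#' chemical-shift displacement; the factor is `1 + 2 * d` with `d` the
#' one-sided displacement of the range edges from the carrier of the
#' localisation pulses. The protocol default used at 7 T is 1.9.
#'
#' @param range_ppm length-2 ppm interval to keep fully excited
#' @param pulse_bw_hz localisation pulse bandwidth, Hz
#' @param larmor_mhz proton frequency, MHz
#' @param center_ppm frequency the localisation pulses are centred on
#' @return over-excitation factor (>= 1)
#' @export
overExcitationFactor <- function(range_ppm, pulse_bw_hz,
                                 larmor_mhz = 297.2,
                                 center_ppm = mean(range_ppm)) {
  d <- max(abs(range_ppm - center_ppm)) * larmor_mhz / pulse_bw_hz
  1 + 2 * d
}

#' Protocol over-excitation factor
#'
#' @return the configured over-excitation factor (1.9)
#' @export
defaultOverExcitation <- function() 1.9
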
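# Synthetic multi-coil, multi-average edited/non-edited acquisitions:
# spatial phantom -> concentration-weighted basis FIDs -> coil-weighted
# phase encoding -> per-average frequency drift / phase jitter -> noise.

#' Spatial phantom configuration
#'
#' Describes what is inside the excited volume on a spatial grid matching
#' the phase-encoding matrix: per-region metabolite concentrations and
#' Lorentzian linewidth, residual water amplitude, and out-of-volume
#' contamination components (unspoiled-coherence / saturation-band
#' residues) with the attenuation the outer-volume suppression bands
#' apply to them in single-voxel mode.
#'
#' @slot grid_shape integer spatial grid (nx, ny, nz)
#' @slot voxel_mm spatial resolution per axis, mm
#' @slot region_map integer array (nx, ny, nz); 0 = empty, otherwise an
#'   index into `regions`
#' @slot regions list of `list(concentrations = named numeric,
#'   linewidth_hz = scalar)`
#' @slot residual_water_amp relative residual-water amplitude added to
#'   every non-empty cell
#' @slot contamination list of `list(location = c(x, y, z), metabolite =,
#'   amplitude =, linewidth_hz =)` entries outside the selected voxel
#' @slot vss_suppression fraction of contamination suppressed in
#'   single-voxel mode (0.95 emulates six very-selective-saturation bands;
#'   the 8x8x1 acquisition instead localises contamination away spatially)
#' @export
setClass("PhantomConfig",
  representation(
    grid_shape = "integer", voxel_mm = "numeric", region_map = "array",
    regions = "list", residual_water_amp = "numeric",
    contamination = "list", vss_suppression = "numeric"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@grid_shape) != 3L || any(object@grid_shape < 1L))
    msg <- c(msg, "grid_shape must be 3 positive integers")
  if (!identical(dim(object@region_map), as.integer(object@grid_shape)))
    msg <- c(msg, "region_map dimensions must equal grid_shape")
  if (any(object@region_map < 0) ||
      any(object@region_map > length(object@regions)))
    msg <- c(msg, "region_map indices out of range")
  for (r in object@regions)
    if (any(r$concentrations < 0))
      msg <- c(msg, "concentrations must be non-negative")
  if (object@vss_suppression < 0 || object@vss_suppression > 1)
    msg <- c(msg, "vss_suppression must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom configuration
#'
#' @param grid_shape spatial grid (nx, ny, nz)
#' @param regions list of `list(concentrations, linewidth_hz)` per region
#' @param region_map integer array assigning grid cells to regions (0 =
#'   empty); defaults to region 1 everywhere
#' @param voxel_mm grid resolution, mm
#' @param residual_water_amp residual water amplitude per cell
#' @param contamination list of out-of-volume components, see
#'   [PhantomConfig-class]
#' @param vss_suppression suppression fraction applied to contamination in
#'   single-voxel mode
#' @return a [PhantomConfig-class]
#' @export
phantomConfig <- function(grid_shape = c(1L, 1L, 1L),
                          regions = list(list(
                            concentrations = brainConcentrations(),
                            linewidth_hz = 8)),
                          region_map = NULL,
                          voxel_mm = c(2.5, 2.5, 20),
                          residual_water_amp = 0,
                          contamination = list(),
                          vss_suppression = 0.95) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(region_map))
    region_map <- array(1L, dim = grid_shape)
  new("PhantomConfig", grid_shape = grid_shape, voxel_mm = voxel_mm,
      region_map = array(as.integer(region_map), dim = grid_shape),
      regions = regions, residual_water_amp = residual_water_amp,
      contamination = contamination, vss_suppression = vss_suppression)
}

#' Nominal brain-like relative metabolite concentrations
#'
#' Relative concentrations (NAA = 1) in the range typical of healthy gray
#' matter; used as the phantom default.
#'
#' @param gaba GABA level relative to NAA
#' @param mm macromolecule pseudo-system level
#' @return named numeric vector
#' @export
brainConcentrations <- function(gaba = 0.2, mm = 0.3) {
  c(NAA = 1.0, Cr = 0.8, Glu = 0.9, Gln = 0.3, GSH = 0.25,
    NAAG = 0.15, GABA = gaba, MM_pseudo = mm)
}

# run expr with a private RNG stream; restores the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate smooth synthetic coil sensitivity maps
#'
#' Low-order complex spatial polynomials (constant + linear + quadratic
#' terms with random coefficients and a random global phase per coil),
#' deterministic per seed. With `uniform = TRUE` every coil is a constant
#' unit map.
#'
#' @param n_coils number of receive coils (>= 1)
#' @param grid spatial grid shape (nx, ny, nz)
#' @param seed RNG seed
#' @param uniform return constant unit maps
#' @return a [CoilSensitivities-class]
#' @export
makeSensitivities <- function(n_coils, grid = c(1L, 1L, 1L), seed = 1L,
                              uniform = FALSE) {
  if (n_coils < 1) stop("n_coils must be >= 1", call. = FALSE)
  grid <- as.integer(grid)
  maps <- array(0i, dim = c(n_coils, grid))
  if (uniform) {
    maps[] <- 1 + 0i
    return(new("CoilSensitivities", maps = maps))
  }
  cx <- if (grid[1] > 1) seq(-1, 1, length.out = grid[1]) else 0
  cy <- if (grid[2] > 1) seq(-1, 1, length.out = grid[2]) else 0
  cz <- if (grid[3] > 1) seq(-1, 1, length.out = grid[3]) else 0
  .with_seed(seed, {
    for (c_i in seq_len(n_coils)) {
      co <- stats::rnorm(6, sd = c(1, 0.5, 0.5, 0.25, 0.25, 0.25))
      ph <- stats::runif(1, -pi, pi)
      for (ix in seq_len(grid[1])) for (iy in seq_len(grid[2]))
        for (iz in seq_len(grid[3])) {
          x <- cx[ix]; y <- cy[iy]
          mag <- 1 + co[1] * 0.3 + co[2] * x + co[3] * y +
            co[4] * x^2 + co[5] * y^2 + co[6] * x * y
          maps[c_i, ix, iy, iz] <- (0.3 + abs(mag)) * exp(1i * ph)
        }
    }
  })
  new("CoilSensitivities", maps = maps)
}

# forward 2-d DFT along dims 1,2 of a (nx, ny, nt) complex array
.dft2 <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  sgn <- if (inverse) 1 else -1
  fx <- exp(sgn * 2i * pi * outer(0:(d[1] - 1), 0:(d[1] - 1)) / d[1])
  fy <- exp(sgn * 2i * pi * outer(0:(d[2] - 1), 0:(d[2] - 1)) / d[2])
  tmp <- fx %*% matrix(arr, d[1], d[2] * d[3])
  dim(tmp) <- d
  tmp <- aperm(tmp, c(2, 1, 3))
  tmp <- fy %*% matrix(tmp, d[2], d[1] * d[3])
  dim(tmp) <- d[c(2, 1, 3)]
  out <- aperm(tmp, c(2, 1, 3))
  if (inverse) out / (d[1] * d[2]) else out
}

# per-cell complex FID stack (cells x time) for one editing cycle
.phantom_cell_fids <- function(basis, phantom, cycle) {
  p <- basis@params
  nt <- p@n_points
  region_fid <- lapply(phantom@regions, function(r) {
    acc <- complex(nt)
    for (m in names(r$concentrations)) {
      if (r$concentrations[[m]] == 0) next
      if (!m %in% names(basis@entries))
        stop("phantom metabolite '", m, "' missing from basis", call. = FALSE)
      acc <- acc + r$concentrations[[m]] *
        basis@entries[[m]][[cycle]]@samples
    }
    if (phantom@residual_water_amp != 0 && "water" %in% names(basis@entries))
      acc <- acc + phantom@residual_water_amp *
        basis@entries[["water"]][[cycle]]@samples
    dampv <- exp(-pi * r$linewidth_hz * (seq_len(nt) - 1) / p@sweep_hz)
    acc * dampv
  })
  g <- phantom@grid_shape
  cells <- matrix(0i, prod(g), nt)
  rm_idx <- as.vector(phantom@region_map)
  for (i in seq_along(rm_idx))
    if (rm_idx[i] > 0) cells[i, ] <- region_fid[[rm_idx[i]]]
  cells
}

.contamination_fid <- function(entry, basis, params) {
  if (!entry$metabolite %in% names(basis@entries))
    stop("contamination metabolite '", entry$metabolite,
         "' missing from basis", call. = FALSE)
  lw <- if (is.null(entry$linewidth_hz)) 8 else entry$linewidth_hz
  f <- basis@entries[[entry$metabolite]]
  function(cycle) {
    dampv <- exp(-pi * lw * (seq_len(params@n_points) - 1) / params@sweep_hz)
    entry$amplitude * f[[cycle]]@samples * dampv
  }
}

#' Generate a synthetic multi-coil edited/non-edited acquisition
#'
#' Builds each average as the spatial-phase-encoded sum over the phantom
#' grid of concentration-weighted, linewidth-damped basis FIDs multiplied
#' by the coil sensitivities, then applies the injected per-average
#' frequency drift (linear in the interleaved global acquisition index)
#' and Gaussian zero-order phase jitter, and adds i.i.d. circular complex
#' Gaussian noise. With a 1x1x1 encoding the acquisition is single-voxel:
#' the grid signal is summed directly and out-of-volume contamination
#' enters attenuated by `1 - vss_suppression`; with a larger matrix the
#' contamination is phase-encoded at its spatial location instead. Ground
#' truth (phantom, sensitivities, injected error tables) is stored in the
#' result for validation.
#'
#' @param basis a [BasisSet-class]
#' @param phantom a [PhantomConfig-class] whose grid matches the encoding
#' @param coils a [CoilSensitivities-class] on the same grid
#' @param encoding list with `matrix` (e.g. `c(8, 8, 1)`) and `averages`
#'   per cycle (defaults: 2 for phase-encoded, 64 for single-voxel)
#' @param noise_sd standard deviation of the complex noise per sample
#'   (each of the real/imaginary parts)
#' @param drift_hz_per_avg linear frequency drift per acquisition, Hz
#' @param phase_sd_deg per-average zero-order phase jitter, degrees
#' @param seed RNG seed (noise and phase draws)
#' @return a [MultiCoilCSI-class]
#' @export
generateAcquisition <- function(basis, phantom, coils,
                                encoding = list(matrix = c(8L, 8L, 1L)),
                                noise_sd = 0, drift_hz_per_avg = 0,
                                phase_sd_deg = 0, seed = 1L) {
  stopifnot(is(basis, "BasisSet"), is(phantom, "PhantomConfig"),
            is(coils, "CoilSensitivities"))
  p <- basis@params
  mat <- as.integer(encoding$matrix)
  svs <- all(mat == 1L)
  if (mat[3] != 1L)
    stop("only single-slice (kz = 1) encoding is supported", call. = FALSE)
  n_avg <- encoding$averages
  if (is.null(n_avg)) n_avg <- if (svs) 64L else 2L
  n_avg <- as.integer(n_avg)
  g <- phantom@grid_shape
  if (!svs && !identical(g, mat))
    stop("phantom grid (", paste(g, collapse = "x"),
         ") does not match encoding matrix (",
         paste(mat, collapse = "x"), ")", call. = FALSE)
  if (!identical(as.integer(dim(coils@maps)[-1]), g))
    stop("coil maps do not match the phantom grid", call. = FALSE)
  n_coil <- dim(coils@maps)[1]
  nt <- p@n_points
  cycles <- c("edited", "non_edited")

  # noiseless per-coil k-space (or single-voxel) signal for one cycle
  base_signal <- function(cycle) {
    cells <- .phantom_cell_fids(basis, phantom, cycle)
    out <- array(0i, dim = c(n_coil, mat, nt))
    if (svs) {
      for (ci in seq_len(n_coil)) {
        w <- as.vector(coils@maps[ci, , , ])
        sig <- colSums(cells * w)
        for (ent in phantom@contamination) {
          cf <- .contamination_fid(ent, basis, p)
          loc <- pmin(pmax(as.integer(ent$location), 1L), g)
          sig <- sig + (1 - phantom@vss_suppression) *
            coils@maps[ci, loc[1], loc[2], loc[3]] * cf(cycle)
        }
        out[ci, 1, 1, 1, ] <- sig
      }
    } else {
      cells_c <- cells
      for (ent in phantom@contamination) {
        cf <- .contamination_fid(ent, basis, p)
        loc <- as.integer(ent$location)
        idx <- loc[1] + g[1] * (loc[2] - 1) + g[1] * g[2] * (loc[3] - 1)
        cells_c[idx, ] <- cells_c[idx, ] + cf(cycle)
      }
      for (ci in seq_len(n_coil)) {
        w <- as.vector(coils@maps[ci, , , ])
        img <- array(cells_c * w, dim = c(g[1], g[2], nt)) # nz = 1 assumed
        out[ci, , , 1, ] <- .dft2(img)
      }
    }
    out
  }

  noiseless <- lapply(cycles, base_signal)
  names(noiseless) <- cycles

  tvec <- (seq_len(nt) - 1) / p@sweep_hz
  freq_tab <- matrix(0, 2, n_avg, dimnames = list(cycles, NULL))
  phase_tab <- matrix(0, 2, n_avg, dimnames = list(cycles, NULL))
  data <- list()
  .with_seed(seed, {
    for (cyc in seq_along(cycles)) {
      phase_tab[cyc, ] <- stats::rnorm(n_avg, sd = phase_sd_deg)
    }
    for (cyc in seq_along(cycles)) {
      # interleaved acquisition: edited_1, non_edited_1, edited_2, ...
      global_idx <- 2 * (seq_len(n_avg) - 1) + (cyc - 1)
      freq_tab[cyc, ] <- drift_hz_per_avg * global_idx
      arr <- array(0i, dim = c(n_avg, n_coil, mat, nt))
      base <- noiseless[[cyc]]
      for (a in seq_len(n_avg)) {
        mod <- exp(1i * (2 * pi * freq_tab[cyc, a] * tvec +
                           phase_tab[cyc, a] * pi / 180))
        shifted <- sweep(base, length(dim(base)), mod, `*`)
        if (noise_sd > 0) {
          nz <- array(complex(
            real = stats::rnorm(length(shifted), sd = noise_sd),
            imaginary = stats::rnorm(length(shifted), sd = noise_sd)),
            dim = dim(shifted))
          shifted <- shifted + nz
        }
        arr[a, , , , , ] <- shifted
      }
      data[[cycles[cyc]]] <- arr
    }
  })

  new("MultiCoilCSI", data = data,
      encoding = list(matrix = mat, averages = n_avg,
                      dwell_s = 1 / p@sweep_hz, domain = "kspace"),
      params = p,
      truth = list(phantom = phantom, coils = coils,
                   freq_hz = freq_tab, phase_deg = phase_tab,
                   noise_sd = noise_sd,
                   drift_hz_per_avg = drift_hz_per_avg,
                   phase_sd_deg = phase_sd_deg, seed = seed))
}
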
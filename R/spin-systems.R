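# Table of record for metabolite spin systems.
#
# One pseudo-spin per group of equivalent protons; proton_scale carries the
# multiplicity. Shifts and couplings follow the standard literature values
# for human-brain proton metabolites (Govindaraju-style compilations),
# trimmed to the groups that matter over the 1.4-4.7 ppm editing/fit range.
# The macromolecule pseudo-system is a deliberately minimal stand-in: a
# 3.0 ppm group J-coupled to a 1.7 ppm group, which is the coupling
# topology that makes MM co-edit when the editing pulses are not symmetric
# about 1.7 ppm.

.spin_library <- list(
  water = list(
    shifts = 4.70, scale = 2, j = NULL
  ),
  Cr = list(
    # methyl singlet + methylene singlet, uncoupled
    shifts = c(3.027, 3.913), scale = c(3, 2), j = NULL
  ),
  NAA = list(
    # acetyl CH3 + aspartyl CH2/CH
    shifts = c(2.008, 2.486, 2.673, 4.382), scale = c(3, 1, 1, 1),
    j = rbind(
      c(2, 3, -15.59),
      c(2, 4, 3.86),
      c(3, 4, 9.82)
    )
  ),
  NAAG = list(
    shifts = c(2.042, 2.519, 2.721, 4.607), scale = c(3, 1, 1, 1),
    j = rbind(
      c(2, 3, -15.91),
      c(2, 4, 4.41),
      c(3, 4, 9.52)
    )
  ),
  Glu = list(
    # alpha CH, beta CH2, gamma CH2
    shifts = c(3.746, 2.042, 2.120, 2.336, 2.352),
    scale = c(1, 1, 1, 1, 1),
    j = rbind(
      c(1, 2, 7.33), c(1, 3, 4.65),
      c(2, 3, -14.85),
      c(2, 4, 6.43), c(2, 5, 8.48),
      c(3, 4, 8.39), c(3, 5, 6.88),
      c(4, 5, -15.92)
    )
  ),
  Gln = list(
    shifts = c(3.757, 2.129, 2.109, 2.432, 2.454),
    scale = c(1, 1, 1, 1, 1),
    j = rbind(
      c(1, 2, 5.85), c(1, 3, 6.50),
      c(2, 3, -14.45),
      c(2, 4, 9.17), c(2, 5, 6.35),
      c(3, 4, 6.35), c(3, 5, 9.25),
      c(4, 5, -15.92)
    )
  ),
  GSH = list(
    # cysteinyl CH/CH2 (the coupled part), glycinyl CH2, glutamyl
    # beta-CH2 collapsed to an uncoupled pseudo-group
    shifts = c(4.561, 2.926, 2.975, 3.769, 2.146),
    scale = c(1, 1, 1, 2, 2),
    j = rbind(
      c(1, 2, 7.09), c(1, 3, 4.71),
      c(2, 3, -14.06)
    )
  ),
  GABA = list(
    # 4-CH2 (3.01) - 3-CH2 (1.89) - 2-CH2 (2.28) vicinal chain
    shifts = c(3.013, 1.889, 2.284), scale = c(2, 2, 2),
    j = rbind(
      c(1, 2, 7.30),
      c(2, 3, 7.30)
    )
  ),
  MM_pseudo = list(
    shifts = c(3.00, 1.70), scale = c(2, 2),
    j = rbind(c(1, 2, 7.00))
  )
)

#' Canonical spin system of a supported metabolite
#'
#' Returns the package's table-of-record spin system for one metabolite:
#' chemical shifts (ppm), scalar-coupling matrix (Hz) and per-spin proton
#' multiplicity weights. Repeated calls return identical values.
#'
#' @param name one of `r paste0('"', paste(names(gabedit:::.spin_library),
#'   collapse = '", "'), '"')`
#' @return a [SpinSystem-class]
#' @examples
#' buildSpinSystem("GABA")
#' buildSpinSystem("Cr")
#' @export
buildSpinSystem <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.spin_library))
    stop("unsupported metabolite '", paste(name, collapse = ","),
         "'; supported: ", paste(names(.spin_library), collapse = ", "),
         call. = FALSE)
  entry <- .spin_library[[name]]
  n <- length(entry$shifts)
  j <- matrix(0, n, n)
  if (!is.null(entry$j)) {
    for (r in seq_len(nrow(entry$j))) {
      i <- entry$j[r, 1]; k <- entry$j[r, 2]
      j[i, k] <- j[k, i] <- entry$j[r, 3]
    }
  }
  new("SpinSystem", name = name, shifts_ppm = entry$shifts,
      j_hz = j, proton_scale = entry$scale)
}

#' Names of the supported metabolite spin systems
#' @return character vector
#' @export
spinLibraryNames <- function() names(.spin_library)
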
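# Accessor generics and methods for the core classes. Slot access outside
# the package should go through these.

#' @rdname accessors
#' @param object an object of one of the package classes
#' @export
setGeneric("seqParams", function(object) standardGeneric("seqParams"))

#' @rdname accessors
#' @export
setMethod("seqParams", "Fid", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("seqParams", "Spectrum", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("seqParams", "BasisSet", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("seqParams", "MultiCoilCSI", function(object) object@params)

#' Accessors
#'
#' Small accessor family: `seqParams()` returns the [SequenceParams-class]
#' carried by FIDs, spectra, basis sets and raw datasets; `fidSamples()`,
#' `specValues()` and `ppmAxis()` return the underlying vectors;
#' `basisNames()`/`basisEntry()` index a [BasisSet-class];
#' `amplitudes()`, `crlbPct()`, `ratios()` and `included()` read a
#' [QuantResult-class].
#'
#' @param fid a [Fid-class]
#' @name accessors
#' @export
fidSamples <- function(fid) fid@samples

#' @rdname accessors
#' @param spec a [Spectrum-class]
#' @export
specValues <- function(spec) spec@values

#' @rdname accessors
#' @export
ppmAxis <- function(spec) spec@ppm_axis

#' @rdname accessors
#' @param basis a [BasisSet-class]
#' @export
basisNames <- function(basis) names(basis@entries)

#' @rdname accessors
#' @param name metabolite name
#' @param cycle `"edited"`, `"non_edited"` or `"both"`
#' @export
basisEntry <- function(basis, name, cycle = c("both", "edited", "non_edited")) {
  cycle <- match.arg(cycle)
  if (!name %in% names(basis@entries))
    stop("metabolite '", name, "' not in basis", call. = FALSE)
  e <- basis@entries[[name]]
  if (cycle == "both") e else e[[cycle]]
}

#' @rdname accessors
#' @param result a [QuantResult-class]
#' @export
amplitudes <- function(result) result@amplitudes

#' @rdname accessors
#' @export
crlb <- function(result) result@crlb_pct

#' @rdname accessors
#' @export
ratios <- function(result) result@ratios

#' @rdname accessors
#' @export
included <- function(result) result@included

#' @rdname accessors
#' @param csi a [MultiCoilCSI-class]
#' @export
csiData <- function(csi) csi@data

#' @rdname accessors
#' @export
csiEncoding <- function(csi) csi@encoding

#' @rdname accessors
#' @export
csiTruth <- function(csi) csi@truth

#' @rdname accessors
#' @param box a [VoxelBox-class]
#' @export
boxCenter <- function(box) box@center_mm

#' @rdname accessors
#' @export
boxHalf <- function(box) box@half_mm

#' @rdname accessors
#' @export
boxOrientation <- function(box) box@orientation

#' Frequency offset of a ppm position from the carrier
#'
#' @param ppm chemical shift, ppm
#' @param params a [SequenceParams-class]
#' @return offset in Hz (positive downfield of the carrier)
#' @export
ppmToHz <- function(ppm, params) (ppm - params@carrier_ppm) * params@larmor_mhz
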
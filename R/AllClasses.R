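#' @include AllGenerics.R
NULL

## Central S4 classes. Pixel matrices are indexed [row, col] with 1-based
## coordinates and pixel centers at integer positions; intensities live in
## [0, 1] whatever the source bit depth.

#' TiledWellImage: one stitched per-well scan
#'
#' A single mosaic image of one well of a multi-well plate, together with
#' its plate/well/timepoint identity and the tile layout of the mosaic.
#' Intensities are stored as doubles in \[0, 1\]; the original bit depth is
#' kept only as metadata.
#'
#' @slot pixels numeric matrix \[row, col\] with values in \[0, 1\].
#' @slot bitDepth integer, bits per channel of the source file (8 or 16).
#' @slot plateId character scalar.
#' @slot wellId character scalar, row letter + column number (\code{"A1"}
#'   \ldots \code{"H12"} for a 96-well plate).
#' @slot timepoint numeric scalar, days (non-negative).
#' @slot tileRows,tileCols integer, mosaic layout (e.g. 3 x 4).
#' @slot sourcePath character, originating file (\code{NA} for in-memory
#'   images).
#' @export
setClass("TiledWellImage",
    slots = c(
        pixels = "matrix",
        bitDepth = "integer",
        plateId = "character",
        wellId = "character",
        timepoint = "numeric",
        tileRows = "integer",
        tileCols = "integer",
        sourcePath = "character"
    )
)

setValidity("TiledWellImage", function(object) {
    px <- object@pixels
    if (!is.numeric(px) || nrow(px) < 2L || ncol(px) < 2L)
        return("'pixels' must be a numeric matrix with >= 2 rows and columns")
    rng <- range(px)
    if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 1)
        return("'pixels' values must lie in [0, 1] and contain no NA")
    if (!object@bitDepth %in% c(8L, 16L))
        return("'bitDepth' must be 8 or 16")
    if (!grepl("^[A-H](1[0-2]|[1-9])$", object@wellId))
        return("'wellId' must be A1..H12 (row A-H, column 1-12)")
    if (length(object@timepoint) != 1L || is.na(object@timepoint) ||
        object@timepoint < 0)
        return("'timepoint' must be a single non-negative number")
    if (object@tileRows < 1L || object@tileCols < 1L)
        return("'tileRows' and 'tileCols' must be >= 1")
    TRUE
})

#' Construct a TiledWellImage
#'
#' @param pixels numeric matrix in \[0, 1\], indexed \[row, col\].
#' @param bitDepth source bits per channel (8 or 16).
#' @param plateId,wellId,timepoint identity metadata.
#' @param tileRows,tileCols mosaic layout of the stitched scan.
#' @param sourcePath originating file path, if any.
#' @return A \linkS4class{TiledWellImage}.
#' @examples
#' img <- TiledWellImage(matrix(runif(100), 10, 10))
#' dim(pixels(img))
#' @export
TiledWellImage <- function(pixels, bitDepth = 8L, plateId = "plate1",
                           wellId = "A1", timepoint = 0,
                           tileRows = 3L, tileCols = 4L,
                           sourcePath = NA_character_) {
    new("TiledWellImage", pixels = pixels, bitDepth = as.integer(bitDepth),
        plateId = as.character(plateId), wellId = as.character(wellId),
        timepoint = as.numeric(timepoint), tileRows = as.integer(tileRows),
        tileCols = as.integer(tileCols), sourcePath = as.character(sourcePath))
}

#' @rdname pixels
#' @export
setMethod("pixels", "TiledWellImage", function(object) object@pixels)

#' @rdname pixels
#' @export
setReplaceMethod("pixels", "TiledWellImage", function(object, value) {
    object@pixels <- value
    validObject(object)
    object
})

#' @rdname wellId
#' @export
setMethod("wellId", "TiledWellImage", function(object) object@wellId)

#' @rdname plateId
#' @export
setMethod("plateId", "TiledWellImage", function(object) object@plateId)

#' @rdname timepoint
#' @export
setMethod("timepoint", "TiledWellImage", function(object) object@timepoint)

setMethod("show", "TiledWellImage", function(object) {
    cat(sprintf(
        "TiledWellImage %s / %s (day %g)\n  %d x %d px, %d-bit source, %dx%d mosaic\n",
        object@plateId, object@wellId, object@timepoint,
        nrow(object@pixels), ncol(object@pixels), object@bitDepth,
        object@tileRows, object@tileCols))
    cat(sprintf("  intensity range [%.4f, %.4f]\n",
        min(object@pixels), max(object@pixels)))
})

#' WellMask: the detected growth area of one well
#'
#' Boolean region of the well's circular growth area, with the
#' least-squares disc fitted to its boundary and the moment-based
#' eccentricity of the detected region (used for ovoid-compression QC).
#'
#' @slot mask logical matrix, same shape as the source pixels.
#' @slot center numeric (row, col) of the fitted disc center, pixels.
#' @slot radius numeric, fitted disc radius, pixels.
#' @slot eccentricity numeric in \[0, 1) from second moments of the region.
#' @slot erosionAppliedPx integer, total erosion applied so far.
#' @export
setClass("WellMask",
    slots = c(
        mask = "matrix",
        center = "numeric",
        radius = "numeric",
        eccentricity = "numeric",
        erosionAppliedPx = "integer"
    )
)

setValidity("WellMask", function(object) {
    if (!is.logical(object@mask))
        return("'mask' must be a logical matrix")
    if (!any(object@mask))
        return("'mask' must contain at least one TRUE pixel")
    if (length(object@center) != 2L || object@radius <= 0)
        return("'center' must be (row, col) and 'radius' positive")
    if (object@eccentricity < 0 || object@eccentricity >= 1)
        return("'eccentricity' must be in [0, 1)")
    if (object@erosionAppliedPx < 0L)
        return("'erosionAppliedPx' must be non-negative")
    TRUE
})

#' @rdname wellCenter
#' @export
setMethod("wellCenter", "WellMask", function(object) object@center)

#' @rdname wellRadius
#' @export
setMethod("wellRadius", "WellMask", function(object) object@radius)

#' @rdname eccentricity
#' @export
setMethod("eccentricity", "WellMask", function(object) object@eccentricity)

#' Logical mask matrix of a WellMask
#' @param object a \linkS4class{WellMask}.
#' @return Logical matrix, TRUE inside the growth area.
#' @export
maskMatrix <- function(object) object@mask

#' Area of a WellMask in pixels
#' @param object a \linkS4class{WellMask}.
#' @return Integer pixel count.
#' @export
maskArea <- function(object) sum(object@mask)

setMethod("show", "WellMask", function(object) {
    cat(sprintf(
        "WellMask %d x %d px\n  area %d px, center (%.1f, %.1f), radius %.1f px\n  eccentricity %.3f, erosion applied %d px\n",
        nrow(object@mask), ncol(object@mask), sum(object@mask),
        object@center[1L], object@center[2L], object@radius,
        object@eccentricity, object@erosionAppliedPx))
})

#' IlluminationField: a set-wide multiplicative gain surface
#'
#' Smooth, strictly positive gain estimated from an image set; dividing
#' each image by the gain flattens the vignetting/tile-seam artifact of
#' stitched mosaics. Normalized so the brightest point has gain 1.
#'
#' @slot gain numeric matrix in (0, 1\], same shape as the images.
#' @slot nImagesUsed integer, how many images entered the estimate.
#' @slot smoothingSigmaPx numeric, Gaussian smoothing applied (pixels).
#' @export
setClass("IlluminationField",
    slots = c(
        gain = "matrix",
        nImagesUsed = "integer",
        smoothingSigmaPx = "numeric"
    )
)

setValidity("IlluminationField", function(object) {
    g <- object@gain
    if (!is.numeric(g) || any(is.na(g)))
        return("'gain' must be numeric without NA")
    if (min(g) <= 0 || max(g) > 1 + 1e-12)
        return("'gain' values must lie in (0, 1]")
    rough <- max(max(abs(diff(g))), max(abs(t(diff(t(g))))))
    if (rough >= 0.02)
        return("'gain' must be smooth (4-neighbor differences < 0.02)")
    if (object@nImagesUsed < 1L)
        return("'nImagesUsed' must be >= 1")
    TRUE
})

#' @rdname gain
#' @export
setMethod("gain", "IlluminationField", function(object) object@gain)

setMethod("show", "IlluminationField", function(object) {
    cat(sprintf(
        "IlluminationField %d x %d px\n  gain range [%.4f, %.4f], smoothing sigma %.1f px, from %d image(s)\n",
        nrow(object@gain), ncol(object@gain), min(object@gain),
        max(object@gain), object@smoothingSigmaPx, object@nImagesUsed))
})

#' LabelImage: labeled segmentation of one well
#'
#' Connected-component labeling of detected nuclei; 0 is background and
#' objects are labeled contiguously 1..n.
#'
#' @slot labels integer matrix.
#' @slot nObjects integer, number of distinct objects.
#' @export
setClass("LabelImage",
    slots = c(labels = "matrix", nObjects = "integer")
)

setValidity("LabelImage", function(object) {
    lab <- object@labels
    u <- sort(unique(as.integer(lab[lab > 0])))
    if (length(u) != object@nObjects)
        return("'nObjects' must equal the number of distinct nonzero labels")
    if (object@nObjects > 0L && !identical(u, seq_len(object@nObjects)))
        return("labels must be contiguous 1..n")
    TRUE
})

setMethod("show", "LabelImage", function(object) {
    cat(sprintf("LabelImage %d x %d px, %d object(s)\n",
        nrow(object@labels), ncol(object@labels), object@nObjects))
})

#' GroundTruth: the known content of one synthetic well
#'
#' Truth channel emitted by the synthetic generator: where the nuclei
#' were placed, how many there are, and where the well disc sits.
#' Coordinates refer to the emitted image (after any ovoid compression).
#'
#' @slot nucleusCenters numeric n x 2 matrix of (row, col) centers.
#' @slot nucleusCount integer, equal to \code{nrow(nucleusCenters)}.
#' @slot wellCenter numeric (row, col), pixels.
#' @slot wellRadius numeric, horizontal well radius, pixels (the vertical
#'   semi-axis is \code{wellRadius * ovoidYScale} when compression is on).
#' @slot wellId character.
#' @slot imagePath character, emitted image file (\code{NA} if in-memory).
#' @export
setClass("GroundTruth",
    slots = c(
        nucleusCenters = "matrix",
        nucleusCount = "integer",
        wellCenter = "numeric",
        wellRadius = "numeric",
        wellId = "character",
        imagePath = "character"
    )
)

setValidity("GroundTruth", function(object) {
    if (object@nucleusCount != nrow(object@nucleusCenters))
        return("'nucleusCount' must equal nrow(nucleusCenters)")
    if (length(object@wellCenter) != 2L || object@wellRadius <= 0)
        return("'wellCenter' must be (row, col) and 'wellRadius' positive")
    TRUE
})

#' @rdname wellCenter
#' @export
setMethod("wellCenter", "GroundTruth", function(object) object@wellCenter)

#' @rdname wellRadius
#' @export
setMethod("wellRadius", "GroundTruth", function(object) object@wellRadius)

#' @rdname wellId
#' @export
setMethod("wellId", "GroundTruth", function(object) object@wellId)

#' Nucleus centers of a GroundTruth
#' @param object a \linkS4class{GroundTruth}.
#' @return Numeric n x 2 matrix of (row, col) centers.
#' @export
nucleusCenters <- function(object) object@nucleusCenters

#' Nucleus count of a GroundTruth
#' @param object a \linkS4class{GroundTruth}.
#' @return Integer.
#' @export
nucleusCount <- function(object) object@nucleusCount

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(
        "GroundTruth well %s: %d nuclei, well center (%.1f, %.1f), radius %.1f px\n",
        object@wellId, object@nucleusCount, object@wellCenter[1L],
        object@wellCenter[2L], object@wellRadius))
})
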
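#' @include AllClasses.R
NULL

#' PipelineConfig: all tunable parameters of the counting pipeline
#'
#' Houses every free parameter of the processing chain. Defaults are
#' sized for 4x-magnification mosaics of 96-well plates (roughly 3.3 um
#' per pixel), where nuclei appear as bright spots a handful of pixels
#' across.
#'
#' @slot logGainK positive number; gain constant k of the normalized log
#'   contrast transform \code{log(1 + k x) / log(1 + k)}. Default 255
#'   reduces to the classic 8-bit log mapping.
#' @slot wellSmoothSigma Gaussian sigma (px) of the heavy smoothing used
#'   while locating the well as one large object. Default 25.
#' @slot wellThreshold thresholding for well detection: \code{"otsu"} or a
#'   number in (0, 1).
#' @slot wellMinDiameterFrac minimum equivalent diameter of the well
#'   object as a fraction of the short image side, in (0, 1\]. Default 0.5.
#' @slot erosionPx mask contraction in px; \code{NA} means automatic
#'   (1\% of the fitted radius, at least 3 px).
#' @slot illumSmoothSigma Gaussian sigma (px) smoothing the illumination
#'   function. Default 15: small enough to preserve the tile-scale seam
#'   pattern that the correction must cancel (a sigma comparable to the
#'   tile size would blur the pattern out of the field and leave it in
#'   the corrected images).
#' @slot illumFloorEps lower floor of the gain surface, in (0, 1).
#'   Default 0.05, so correction never amplifies more than 20x.
#' @slot denoiseSigma mild Gaussian blur (px) before segmentation.
#'   Default 1.
#' @slot nucleusDiameterPx numeric (min, max) accepted equivalent
#'   diameter of a nucleus, px. Default c(3, 20).
#' @slot nucleusThreshold nuclei thresholding: \code{"otsu"} (Otsu over
#'   in-mask pixels) or a fixed manual threshold in (0, 1). A manual
#'   value overrides the automatic method.
#' @slot declump \code{"watershed"} (split over-size components by
#'   distance-transform watershed) or \code{"none"}.
#' @slot ovoidEccentricityMax eccentricity above which a well is flagged
#'   OVOID. Default 0.25.
#' @slot minMaskAreaFrac mask area below this fraction of the frame is
#'   flagged LOW_MASK_AREA. Default 0.2.
#' @slot rngSeed integer seed recorded in run manifests.
#' @export
setClass("PipelineConfig",
    slots = c(
        logGainK = "numeric",
        wellSmoothSigma = "numeric",
        wellThreshold = "ANY",
        wellMinDiameterFrac = "numeric",
        erosionPx = "integer",
        illumSmoothSigma = "numeric",
        illumFloorEps = "numeric",
        denoiseSigma = "numeric",
        nucleusDiameterPx = "numeric",
        nucleusThreshold = "ANY",
        declump = "character",
        ovoidEccentricityMax = "numeric",
        minMaskAreaFrac = "numeric",
        rngSeed = "integer"
    )
)

setValidity("PipelineConfig", function(object) {
    if (object@logGainK <= 0)
        return("'logGainK' must be > 0")
    if (object@wellSmoothSigma <= 0 || object@illumSmoothSigma <= 0)
        return("smoothing sigmas must be > 0")
    if (object@denoiseSigma < 0)
        return("'denoiseSigma' must be >= 0")
    if (object@wellMinDiameterFrac <= 0 || object@wellMinDiameterFrac > 1)
        return("'wellMinDiameterFrac' must be in (0, 1]")
    if (object@illumFloorEps <= 0 || object@illumFloorEps >= 1)
        return("'illumFloorEps' must be in (0, 1)")
    d <- object@nucleusDiameterPx
    if (length(d) != 2L || d[1L] <= 0 || d[1L] >= d[2L])
        return("'nucleusDiameterPx' must be (min, max) with 0 < min < max")
    if (!object@declump %in% c("none", "watershed"))
        return("'declump' must be 'none' or 'watershed'")
    for (nm in c("wellThreshold", "nucleusThreshold")) {
        v <- slot(object, nm)
        ok <- (is.character(v) && length(v) == 1L && v == "otsu") ||
            (is.numeric(v) && length(v) == 1L && v > 0 && v < 1)
        if (!ok)
            return(sprintf("'%s' must be \"otsu\" or a number in (0, 1)", nm))
    }
    if (object@ovoidEccentricityMax <= 0 || object@ovoidEccentricityMax >= 1)
        return("'ovoidEccentricityMax' must be in (0, 1)")
    if (object@minMaskAreaFrac <= 0 || object@minMaskAreaFrac >= 1)
        return("'minMaskAreaFrac' must be in (0, 1)")
    TRUE
})

#' Construct a PipelineConfig
#'
#' @param logGainK,wellSmoothSigma,wellThreshold,wellMinDiameterFrac
#'   see \linkS4class{PipelineConfig}.
#' @param erosionPx,illumSmoothSigma,illumFloorEps,denoiseSigma
#'   see \linkS4class{PipelineConfig}.
#' @param nucleusDiameterPx,nucleusThreshold,declump
#'   see \linkS4class{PipelineConfig}.
#' @param ovoidEccentricityMax,minMaskAreaFrac,rngSeed
#'   see \linkS4class{PipelineConfig}.
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(nucleusThreshold = 0.6)
#' @export
pipelineConfig <- function(logGainK = 255,
                           wellSmoothSigma = 25,
                           wellThreshold = "otsu",
                           wellMinDiameterFrac = 0.5,
                           erosionPx = NA,
                           illumSmoothSigma = 15,
                           illumFloorEps = 0.05,
                           denoiseSigma = 1,
                           nucleusDiameterPx = c(3, 20),
                           nucleusThreshold = "otsu",
                           declump = "watershed",
                           ovoidEccentricityMax = 0.25,
                           minMaskAreaFrac = 0.2,
                           rngSeed = 1L) {
    new("PipelineConfig",
        logGainK = logGainK,
        wellSmoothSigma = wellSmoothSigma,
        wellThreshold = wellThreshold,
        wellMinDiameterFrac = wellMinDiameterFrac,
        erosionPx = as.integer(erosionPx),
        illumSmoothSigma = illumSmoothSigma,
        illumFloorEps = illumFloorEps,
        denoiseSigma = denoiseSigma,
        nucleusDiameterPx = as.numeric(nucleusDiameterPx),
        nucleusThreshold = nucleusThreshold,
        declump = declump,
        ovoidEccentricityMax = ovoidEccentricityMax,
        minMaskAreaFrac = minMaskAreaFrac,
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "PipelineConfig", function(object) {
    fmtThr <- function(v) if (is.character(v)) v else sprintf("%.4f", v)
    cat("PipelineConfig\n")
    cat(sprintf("  log gain k: %g\n", object@logGainK))
    cat(sprintf("  well detection: smooth sigma %g px, threshold %s, min diameter frac %g\n",
        object@wellSmoothSigma, fmtThr(object@wellThreshold),
        object@wellMinDiameterFrac))
    cat(sprintf("  erosion: %s px\n",
        if (is.na(object@erosionPx)) "auto (1% of radius, >= 3)"
        else as.character(object@erosionPx)))
    cat(sprintf("  illumination: smooth sigma %g px, floor %g\n",
        object@illumSmoothSigma, object@illumFloorEps))
    cat(sprintf("  nuclei: denoise sigma %g px, diameter gate [%g, %g] px, threshold %s, declump %s\n",
        object@denoiseSigma, object@nucleusDiameterPx[1L],
        object@nucleusDiameterPx[2L], fmtThr(object@nucleusThreshold),
        object@declump))
    cat(sprintf("  QC: ovoid eccentricity > %g, mask area < %g of frame\n",
        object@ovoidEccentricityMax, object@minMaskAreaFrac))
})

#' Read a PipelineConfig from a YAML file
#'
#' The YAML keys mirror the \code{\link{pipelineConfig}} argument names
#' exactly; absent keys keep their defaults. Unknown keys are an error so
#' that typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "),
             "; known fields: ", paste(known, collapse = ", "))
    do.call(pipelineConfig, vals)
}

## Resolve the automatic erosion rule: 1% of the fitted radius, >= 3 px.
resolveErosionPx <- function(cfg, radius) {
    if (is.na(cfg@erosionPx)) max(3L, as.integer(round(0.01 * radius)))
    else cfg@erosionPx
}

#' Convert a PipelineConfig to a plain list
#'
#' Used when echoing the resolved configuration into run manifests.
#'
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return Named list of all parameter values.
#' @export
configAsList <- function(cfg) {
    nms <- slotNames("PipelineConfig")
    stats::setNames(lapply(nms, function(n) slot(cfg, n)), nms)
}
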
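#' @include config.R utils.R
NULL

## Synthetic plate-scan generator: renders tiled well images containing
## every artifact the counting pipeline must survive -- bright well halo,
## per-tile radial vignetting (the stitched-mosaic grid), medium
## autofluorescence, debris specks, exposure variation, well-position
## jitter and ovoid frame compression -- with exact ground truth.

#' SyntheticWellSpec: parameters of one synthetic tiled well
#'
#' Defaults emulate a 4x objective scan of one 96-well: a 3 x 4 mosaic of
#' roughly 300 px tiles, a bright halo ring where the plastic wall
#' fluoresces, a faint uniform medium background, a quadratic radial
#' vignette per tile (brightest tile centers, dimmest corners, hence a
#' soft grid at the seams), Gaussian-spot nuclei and small bright debris.
#'
#' @slot imageHeight,imageWidth frame size, px (default 1000 x 1200).
#' @slot tileRows,tileCols mosaic layout (default 3 x 4).
#' @slot wellCenter numeric (row, col) of the well center, px.
#' @slot wellRadius radius of the growth area, px.
#' @slot haloWidth radial thickness of the halo ring, px.
#' @slot haloIntensity added intensity of the halo, \[0, 1\].
#' @slot backgroundLevel medium autofluorescence, \[0, 1\].
#' @slot vignetteStrength per-tile falloff at the tile corner, \[0, 1).
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusDiameterPx numeric (min, max) spot diameter, px; the
#'   Gaussian profile uses sigma = diameter / 4.
#' @slot nucleusPeakIntensity added peak intensity of a nucleus, \[0, 1\].
#' @slot nDebris number of debris specks (1-3 px clusters), placed both
#'   inside and outside the well.
#' @slot debrisIntensity added intensity of debris, \[0, 1\].
#' @slot exposureGain multiplicative exposure factor (> 0), emulating
#'   autoexposure variance between wells.
#' @slot ovoidYScale vertical compression factor in (0, 1\]; 1 means no
#'   ovoid artifact.
#' @slot noiseSigma zero-mean Gaussian read-noise sd.
#' @slot nonOverlapping logical; reject-and-resample nucleus centers so
#'   no two are closer than (max diameter + 2) px.
#' @slot rngSeed integer seed; rendering is bit-reproducible for a fixed
#'   seed.
#' @export
setClass("SyntheticWellSpec",
    slots = c(
        imageHeight = "integer", imageWidth = "integer",
        tileRows = "integer", tileCols = "integer",
        wellCenter = "numeric", wellRadius = "numeric",
        haloWidth = "numeric", haloIntensity = "numeric",
        backgroundLevel = "numeric", vignetteStrength = "numeric",
        nNuclei = "integer", nucleusDiameterPx = "numeric",
        nucleusPeakIntensity = "numeric",
        nDebris = "integer", debrisIntensity = "numeric",
        exposureGain = "numeric", ovoidYScale = "numeric",
        noiseSigma = "numeric", nonOverlapping = "logical",
        rngSeed = "integer"
    )
)

setValidity("SyntheticWellSpec", function(object) {
    if (object@imageHeight < 16L || object@imageWidth < 16L)
        return("frame must be at least 16 x 16 px")
    if (object@tileRows < 1L || object@tileCols < 1L)
        return("'tileRows' and 'tileCols' must be >= 1")
    if (object@wellRadius + object@haloWidth >=
        min(object@imageHeight, object@imageWidth) / 2)
        return("wellRadius + haloWidth must be < half the short frame side")
    if (object@vignetteStrength < 0 || object@vignetteStrength >= 1)
        return("'vignetteStrength' must be in [0, 1)")
    if (object@exposureGain <= 0)
        return("'exposureGain' must be > 0")
    if (object@ovoidYScale <= 0 || object@ovoidYScale > 1)
        return("'ovoidYScale' must be in (0, 1]")
    if (object@nNuclei < 0L)
        return("'nNuclei' must be >= 0")
    if (object@nDebris < 0L)
        return("'nDebris' must be >= 0")
    d <- object@nucleusDiameterPx
    if (length(d) != 2L || d[1L] <= 0 || d[1L] > d[2L])
        return("'nucleusDiameterPx' must be (min, max) with 0 < min <= max")
    if (object@noiseSigma < 0)
        return("'noiseSigma' must be >= 0")
    for (nm in c("haloIntensity", "backgroundLevel", "nucleusPeakIntensity",
                 "debrisIntensity")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1)
            return(sprintf("'%s' must be in [0, 1]", nm))
    }
    TRUE
})

#' Construct a SyntheticWellSpec
#'
#' @param imageHeight,imageWidth,tileRows,tileCols frame and mosaic
#'   geometry; see \linkS4class{SyntheticWellSpec}.
#' @param wellCenter,wellRadius,haloWidth,haloIntensity well geometry and
#'   halo; \code{wellCenter = NULL} centers the well in the frame.
#' @param backgroundLevel,vignetteStrength background and tile vignette.
#' @param nNuclei,nucleusDiameterPx,nucleusPeakIntensity nuclei.
#' @param nDebris,debrisIntensity debris specks.
#' @param exposureGain,ovoidYScale,noiseSigma acquisition artifacts.
#' @param nonOverlapping,rngSeed placement mode and seed.
#' @return A \linkS4class{SyntheticWellSpec}.
#' @examples
#' spec <- syntheticWellSpec(nNuclei = 50, rngSeed = 7)
#' @export
syntheticWellSpec <- function(imageHeight = 1000L, imageWidth = 1200L,
                              tileRows = 3L, tileCols = 4L,
                              wellCenter = NULL, wellRadius = 430,
                              haloWidth = 40, haloIntensity = 0.7,
                              backgroundLevel = 0.05,
                              vignetteStrength = 0.25,
                              nNuclei = 100L,
                              nucleusDiameterPx = c(6, 12),
                              nucleusPeakIntensity = 0.5,
                              nDebris = 0L, debrisIntensity = 0.9,
                              exposureGain = 1, ovoidYScale = 1,
                              noiseSigma = 0.01,
                              nonOverlapping = TRUE, rngSeed = 1L) {
    if (is.null(wellCenter))
        wellCenter <- c(imageHeight / 2, imageWidth / 2)
    new("SyntheticWellSpec",
        imageHeight = as.integer(imageHeight),
        imageWidth = as.integer(imageWidth),
        tileRows = as.integer(tileRows), tileCols = as.integer(tileCols),
        wellCenter = as.numeric(wellCenter),
        wellRadius = as.numeric(wellRadius),
        haloWidth = as.numeric(haloWidth),
        haloIntensity = as.numeric(haloIntensity),
        backgroundLevel = as.numeric(backgroundLevel),
        vignetteStrength = as.numeric(vignetteStrength),
        nNuclei = as.integer(nNuclei),
        nucleusDiameterPx = as.numeric(nucleusDiameterPx),
        nucleusPeakIntensity = as.numeric(nucleusPeakIntensity),
        nDebris = as.integer(nDebris),
        debrisIntensity = as.numeric(debrisIntensity),
        exposureGain = as.numeric(exposureGain),
        ovoidYScale = as.numeric(ovoidYScale),
        noiseSigma = as.numeric(noiseSigma),
        nonOverlapping = isTRUE(nonOverlapping),
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "SyntheticWellSpec", function(object) {
    cat(sprintf(
        "SyntheticWellSpec %d x %d px (%dx%d mosaic), well r=%g at (%g, %g)\n",
        object@imageHeight, object@imageWidth, object@tileRows,
        object@tileCols, object@wellRadius, object@wellCenter[1L],
        object@wellCenter[2L]))
    cat(sprintf(
        "  %d nuclei (d %g-%g px, peak %g), %d debris, bg %g, halo %g, vignette %g\n",
        object@nNuclei, object@nucleusDiameterPx[1L],
        object@nucleusDiameterPx[2L], object@nucleusPeakIntensity,
        object@nDebris, object@backgroundLevel, object@haloIntensity,
        object@vignetteStrength))
    cat(sprintf("  gain %g, ovoid %g, noise %g, seed %d\n",
        object@exposureGain, object@ovoidYScale, object@noiseSigma,
        object@rngSeed))
})

## Modify selected fields of a spec, revalidating.
updateSpec <- function(spec, ...) {
    args <- list(...)
    for (nm in names(args)) {
        cur <- slot(spec, nm)
        slot(spec, nm) <- if (is.integer(cur)) as.integer(args[[nm]])
            else if (is.logical(cur)) isTRUE(args[[nm]])
            else as.numeric(args[[nm]])
    }
    validObject(spec)
    spec
}

## Sample nucleus centers uniformly in the placement disc; in
## non-overlapping mode, reject-and-resample until all pairwise center
## distances exceed (max diameter + 2) px, with a bounded attempt budget.
## Nuclei are kept ~3% inside the wall (plus half a spot) because cells
## flush against the wall are optically swallowed by the halo.
sampleNucleusCenters <- function(spec) {
    n <- spec@nNuclei
    if (n == 0L) return(matrix(numeric(0), 0L, 2L))
    rmax <- 0.97 * spec@wellRadius - spec@nucleusDiameterPx[2L] / 2
    if (rmax <= 0)
        psError("well too small to place nuclei", "platescan_generation_error")
    minDist <- spec@nucleusDiameterPx[2L] + 2
    centers <- matrix(NA_real_, n, 2L)
    attempts <- 0L
    budget <- 200L * n
    placed <- 0L
    while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > budget)
            psError(sprintf(
                "could not place %d non-overlapping nuclei in the well (placed %d after %d attempts)",
                n, placed, attempts), "platescan_generation_error")
        r <- rmax * sqrt(stats::runif(1L))
        th <- stats::runif(1L, 0, 2 * pi)
        p <- spec@wellCenter + r * c(cos(th), sin(th))
        if (spec@nonOverlapping && placed > 0L) {
            d2 <- (centers[seq_len(placed), 1L] - p[1L])^2 +
                  (centers[seq_len(placed), 2L] - p[2L])^2
            if (min(d2) <= minDist^2) next
        }
        placed <- placed + 1L
        centers[placed, ] <- p
    }
    centers
}

## Add Gaussian spots at the given centers; sigma = diameter / 4,
## truncated at 3.5 sigma. Operates on a local window per spot.
addGaussianSpots <- function(px, centers, diameters, amplitude) {
    h <- nrow(px); w <- ncol(px)
    for (i in seq_len(nrow(centers))) {
        s <- diameters[i] / 4
        rad <- ceiling(3.5 * s)
        r0 <- max(1L, floor(centers[i, 1L] - rad))
        r1 <- min(h, ceiling(centers[i, 1L] + rad))
        c0 <- max(1L, floor(centers[i, 2L] - rad))
        c1 <- min(w, ceiling(centers[i, 2L] + rad))
        dr <- (r0:r1) - centers[i, 1L]
        dc <- (c0:c1) - centers[i, 2L]
        spot <- amplitude * exp(-outer(dr^2, dc^2, "+") / (2 * s^2))
        px[r0:r1, c0:c1] <- px[r0:r1, c0:c1] + spot
    }
    px
}

## Compress the frame vertically by factor s about the top edge,
## filling vacated rows with the fill level (linear row interpolation).
compressRows <- function(px, s, fill) {
    h <- nrow(px)
    out <- matrix(fill, h, ncol(px))
    newH <- floor(h * s)
    src <- (seq_len(newH) - 0.5) / s + 0.5  # fractional source rows
    lo <- pmax(1L, pmin(h - 1L, floor(src)))
    fr <- pmin(pmax(src - lo, 0), 1)
    out[seq_len(newH), ] <- px[lo, ] * (1 - fr) + px[lo + 1L, ] * fr
    out
}

#' Render one synthetic tiled well image with ground truth
#'
#' Composes the scene additively -- uniform background, halo ring,
#' per-tile radial vignette applied to the background and halo, Gaussian
#' nuclei, debris specks, Gaussian read noise -- then multiplies by the
#' exposure gain, applies the ovoid row compression if requested, and
#' clips to \[0, 1\]. Bit-identical output for a fixed
#' \code{spec@rngSeed}.
#'
#' @param spec a \linkS4class{SyntheticWellSpec}.
#' @param plateId,wellId,timepoint identity stamped on the image.
#' @return List with \code{image} (a \linkS4class{TiledWellImage}) and
#'   \code{truth} (a \linkS4class{GroundTruth}; coordinates refer to the
#'   emitted, possibly compressed, frame).
#' @examples
#' r <- renderWell(syntheticWellSpec(imageHeight = 300L, imageWidth = 360L,
#'     wellRadius = 120, nNuclei = 20L, rngSeed = 3))
#' nucleusCount(r$truth)
#' @export
renderWell <- function(spec, plateId = "plate1", wellId = "A1",
                       timepoint = 0) {
    validObject(spec)
    h <- spec@imageHeight; w <- spec@imageWidth
    withSeed(spec@rngSeed, {
        D <- distanceField(h, w, spec@wellCenter)
        scene <- matrix(spec@backgroundLevel, h, w)
        if (spec@haloIntensity > 0 && spec@haloWidth > 0) {
            ring <- D >= spec@wellRadius &
                    D <= spec@wellRadius + spec@haloWidth
            scene[ring] <- scene[ring] + spec@haloIntensity
        }
        if (spec@vignetteStrength > 0) {
            rt <- tileRadiusField(h, w, spec@tileRows, spec@tileCols)
            scene <- scene * (1 - spec@vignetteStrength * rt^2)
        }
        centers <- sampleNucleusCenters(spec)
        if (nrow(centers)) {
            diams <- stats::runif(nrow(centers), spec@nucleusDiameterPx[1L],
                                  spec@nucleusDiameterPx[2L])
            scene <- addGaussianSpots(scene, centers, diams,
                                      spec@nucleusPeakIntensity)
        }
        if (spec@nDebris > 0L) {
            for (i in seq_len(spec@nDebris)) {
                r <- sample.int(h - 1L, 1L)
                c <- sample.int(w - 1L, 1L)
                k <- sample.int(3L, 1L)  # speck of 1-3 pixels
                offs <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L))[seq_len(k), ,
                                                               drop = FALSE]
                scene[cbind(r + offs[, 1L], c + offs[, 2L])] <-
                    scene[cbind(r + offs[, 1L], c + offs[, 2L])] +
                    spec@debrisIntensity
            }
        }
        if (spec@noiseSigma > 0)
            scene <- scene + matrix(stats::rnorm(h * w, 0, spec@noiseSigma),
                                    h, w)
        scene <- scene * spec@exposureGain
        truthCenter <- spec@wellCenter
        if (spec@ovoidYScale < 1) {
            fill <- spec@backgroundLevel * spec@exposureGain
            scene <- compressRows(scene, spec@ovoidYScale, fill)
            if (nrow(centers))
                centers[, 1L] <- centers[, 1L] * spec@ovoidYScale
            truthCenter[1L] <- truthCenter[1L] * spec@ovoidYScale
        }
        scene <- pmin(pmax(scene, 0), 1)
        img <- TiledWellImage(scene, bitDepth = 8L, plateId = plateId,
                              wellId = wellId, timepoint = timepoint,
                              tileRows = spec@tileRows,
                              tileCols = spec@tileCols)
        truth <- new("GroundTruth", nucleusCenters = centers,
                     nucleusCount = nrow(centers),
                     wellCenter = truthCenter,
                     wellRadius = spec@wellRadius,
                     wellId = wellId, imagePath = NA_character_)
        list(image = img, truth = truth)
    })
}

#' All 96 well identifiers of a standard plate
#'
#' @return Character vector \code{"A1"} \ldots \code{"H12"} in row-major
#'   order.
#' @export
wellIds96 <- function() {
    as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Render a full synthetic 96-well plate
#'
#' Renders one image per well from a shared base spec, jittering the well
#' center uniformly in \[-jitter, +jitter\] px per axis independently per
#' well (the well-position variability of real scans). Each well gets
#' a deterministic sub-seed hashed from the master seed and the well's
#' index in the standard 96-well order, so any single well can be
#' re-rendered without rendering the plate and different master seeds
#' yield unrelated plates.
#'
#' @param baseSpec a \linkS4class{SyntheticWellSpec} shared by all wells.
#' @param jitter non-negative center jitter magnitude, px.
#' @param perWellCounts optional named vector/list mapping well ids to
#'   nucleus counts, overriding \code{baseSpec@nNuclei}.
#' @param seed integer master seed.
#' @param wells well ids to render (default all 96).
#' @param plateId,timepoint identity stamped on the images.
#' @return Named list (by well id) of \code{list(image, truth)} pairs.
#' @export
renderPlate <- function(baseSpec, jitter = 0, perWellCounts = NULL,
                        seed = baseSpec@rngSeed, wells = wellIds96(),
                        plateId = "plate1", timepoint = 0) {
    stopifnot(jitter >= 0)
    if (!is.null(perWellCounts)) {
        bad <- setdiff(names(perWellCounts), wellIds96())
        if (length(bad))
            psError(paste0("perWellCounts references unknown well id(s): ",
                           paste(bad, collapse = ", ")),
                    "platescan_config_error")
    }
    maxR <- baseSpec@wellRadius + baseSpec@haloWidth
    hw <- c(baseSpec@imageHeight, baseSpec@imageWidth)
    out <- vector("list", length(wells))
    names(out) <- wells
    for (i in seq_along(wells)) {
        wid <- wells[i]
        ## sub-seed keyed to the well's position in the standard 96-well
        ## order via a multiplicative hash, so one well can be
        ## re-rendered without the plate and different master seeds do
        ## not share per-well streams (a plain seed+index rule would
        ## collide across nearby seeds)
        idx <- match(wid, wellIds96(), nomatch = 96L + i)
        subSeed <- (as.double(seed) * 2654435761 + idx * 97) %% 2^31
        offset <- withSeed(subSeed, stats::runif(2L, -jitter, jitter))
        ctr <- baseSpec@wellCenter + offset
        ctr <- pmin(pmax(ctr, maxR + 1), hw - maxR - 1)
        n <- if (!is.null(perWellCounts) && wid %in% names(perWellCounts))
            as.integer(perWellCounts[[wid]]) else baseSpec@nNuclei
        spec <- updateSpec(baseSpec, wellCenter = ctr, nNuclei = n,
                           rngSeed = subSeed)
        out[[i]] <- renderWell(spec, plateId = plateId, wellId = wid,
                               timepoint = timepoint)
    }
    out
}

#' Write a rendered plate to disk as PNG images plus ground truth
#'
#' Emits one PNG per well named
#' \code{<plateId>_day<NN>_<well>.png}, a \code{truth.csv} with the known
#' content of each well (well id, nucleus count, well center and radius,
#' image path) and the spec as \code{spec.yaml}.
#'
#' @param rendered output of \code{\link{renderPlate}} (or a list of
#'   \code{list(image, truth)} pairs).
#' @param dir output directory (created if needed).
#' @param bitDepth 8 (native PNG writer) or 16 (packaged 16-bit encoder).
#' @param spec optional \linkS4class{SyntheticWellSpec} to serialize
#'   alongside the images.
#' @return Invisibly, the truth data.frame (with an \code{image} column
#'   of emitted paths).
#' @export
writeSyntheticPlate <- function(rendered, dir, bitDepth = 8L, spec = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- vector("list", length(rendered))
    for (i in seq_along(rendered)) {
        img <- rendered[[i]]$image
        truth <- rendered[[i]]$truth
        fname <- sprintf("%s_day%02d_%s.png", img@plateId,
                         as.integer(round(img@timepoint)), img@wellId)
        path <- file.path(dir, fname)
        if (bitDepth == 16L) writePNG16(pixels(img), path)
        else png::writePNG(pixels(img), path)
        rows[[i]] <- data.frame(
            well_id = truth@wellId, n_nuclei = truth@nucleusCount,
            center_row = truth@wellCenter[1L],
            center_col = truth@wellCenter[2L],
            radius = truth@wellRadius, image = fname,
            stringsAsFactors = FALSE)
    }
    truthDf <- do.call(rbind, rows)
    utils::write.csv(truthDf, file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(spec)) {
        vals <- lapply(slotNames("SyntheticWellSpec"),
                       function(n) slot(spec, n))
        names(vals) <- slotNames("SyntheticWellSpec")
        yaml::write_yaml(vals, file.path(dir, "spec.yaml"))
    }
    invisible(truthDf)
}

#' Read a SyntheticWellSpec from a YAML file
#'
#' Field names mirror the \code{\link{syntheticWellSpec}} arguments.
#' Unknown or invalid fields raise a validation error naming the field.
#'
#' @param path YAML file.
#' @return A \linkS4class{SyntheticWellSpec}.
#' @export
readSyntheticSpec <- function(path) {
    if (!file.exists(path))
        stop("spec file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(syntheticWellSpec))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        psError(paste0("unknown synthetic spec field(s): ",
                       paste(bad, collapse = ", ")),
                "platescan_validation_error")
    tryCatch(do.call(syntheticWellSpec, vals),
             error = function(e)
                 psError(paste0("invalid synthetic spec: ",
                                conditionMessage(e)),
                         "platescan_validation_error"))
}
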
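## Contrast rescue and flat-field correction: the normalized log
## transform applied after masking (so dim nuclei survive the
## illumination correction), a set-wide illumination function, and a
## mild denoising blur.

#' Normalized log contrast transform
#'
#' Applies \code{out = log(1 + k * in) / log(1 + k)} pixel-wise. The
#' mapping fixes 0 and 1, is strictly increasing, and expands the dim
#' end of the range where nuclear signal lives; \code{k = 255} reduces
#' to the classic 8-bit log mapping. In the processing chain it runs
#' after masking and before illumination correction, so that the
#' correction does not attenuate dim nuclei below the detection
#' threshold.
#'
#' @param image a \linkS4class{TiledWellImage} or a numeric matrix in
#'   \[0, 1\].
#' @param k positive gain constant.
#' @return Same type as the input.
#' @examples
#' logTransform(matrix(c(0, 0.5, 1), 1, 3), k = 255)
#' @export
logTransform <- function(image, k = 255) {
    if (!is.numeric(k) || length(k) != 1L || k <= 0)
        psError("'k' must be a single positive number",
                "platescan_config_error")
    f <- function(m) log1p(k * m) / log1p(k)
    if (is(image, "TiledWellImage")) {
        pixels(image) <- f(pixels(image))
        image
    } else {
        f(image)
    }
}

#' Estimate a set-wide illumination function
#'
#' Computes the per-pixel median across the image set restricted to
#' in-mask pixels (robust to wells dense with cells, whose nuclei sit at
#' different positions in every well), imputes pixels never covered by
#' any mask from the tile-local radial profile of the observed values,
#' smooths with a Gaussian, floors the result, and normalizes to max 1.
#' Inputs should be the masked, log-transformed images of one plate and
#' timepoint.
#'
#' @param images list of \linkS4class{TiledWellImage}s, all of one shape.
#' @param cfg a \linkS4class{PipelineConfig} (smoothing sigma and floor).
#' @param masks optional list of \linkS4class{WellMask}s matching
#'   \code{images}; if omitted, pixels with intensity > 0 are treated as
#'   in-mask (i.e. images masked with zero fill).
#' @return An \linkS4class{IlluminationField}.
#' @export
estimateIllumination <- function(images, cfg = pipelineConfig(),
                                 masks = NULL) {
    if (!length(images))
        psError("need at least one image to estimate illumination",
                "platescan_contract_error")
    dims <- lapply(images, function(im) dim(pixels(im)))
    if (length(unique(vapply(dims, paste, character(1L),
                             collapse = "x"))) != 1L)
        psError("images must all have the same shape",
                "platescan_contract_error")
    if (!is.null(masks) && length(masks) != length(images))
        psError("'masks' must match 'images' in length",
                "platescan_contract_error")
    mats <- lapply(seq_along(images), function(i) {
        m <- pixels(images[[i]])
        keep <- if (is.null(masks)) m > 0 else masks[[i]]@mask
        m[!keep] <- NA_real_
        m
    })
    med <- stackMedian(mats)
    if (all(is.na(med)))
        psError("no in-mask pixels in the image set",
                "platescan_contract_error")
    ## impute never-covered pixels from the tile-local radial profile
    if (anyNA(med)) {
        im1 <- images[[1L]]
        rt <- tileRadiusField(nrow(med), ncol(med),
                              im1@tileRows, im1@tileCols)
        bins <- pmin(findInterval(rt, seq(0, 1, length.out = 51L),
                                  all.inside = TRUE), 50L)
        obs <- !is.na(med)
        prof <- tapply(med[obs], bins[obs], stats::median)
        lookup <- rep(stats::median(med[obs]), 50L)
        lookup[as.integer(names(prof))] <- prof
        ## fill empty bins from the nearest populated one
        for (b in seq_len(50L)[-as.integer(names(prof))]) {
            near <- as.integer(names(prof))
            lookup[b] <- prof[[which.min(abs(near - b))]]
        }
        med[!obs] <- lookup[bins[!obs]]
    }
    g <- gaussianBlur(med, cfg@illumSmoothSigma)
    g <- pmax(g, cfg@illumFloorEps)
    g <- g / max(g)
    new("IlluminationField", gain = g, nImagesUsed = length(images),
        smoothingSigmaPx = cfg@illumSmoothSigma)
}

#' Correct an image with an illumination field
#'
#' Divides the image by the gain surface (multiplicative shading model;
#' vignetting is a gain phenomenon) and clips to \[0, 1\]. Division is
#' safe because the gain is floored away from zero.
#'
#' @param image a \linkS4class{TiledWellImage}.
#' @param field an \linkS4class{IlluminationField} of the same shape.
#' @return The corrected \linkS4class{TiledWellImage}.
#' @export
correctIllumination <- function(image, field) {
    px <- pixels(image)
    if (!identical(dim(px), dim(field@gain)))
        psError("image and illumination field shapes differ",
                "platescan_contract_error")
    pixels(image) <- pmin(pmax(px / field@gain, 0), 1)
    image
}

#' Mild Gaussian denoising blur
#'
#' Gaussian convolution with reflective boundary handling;
#' \code{sigma = 0} is the identity. Removes read noise and shrinks
#' sub-nuclear debris specks below the detection threshold while leaving
#' nucleus-sized spots nearly untouched.
#'
#' @param image a \linkS4class{TiledWellImage} or numeric matrix.
#' @param sigma non-negative blur sigma, px.
#' @return Same type as the input.
#' @export
denoise <- function(image, sigma = 1) {
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
        psError("'sigma' must be a single non-negative number",
                "platescan_config_error")
    if (is(image, "TiledWellImage")) {
        pixels(image) <- pmin(pmax(gaussianBlur(pixels(image), sigma), 0), 1)
        image
    } else {
        gaussianBlur(image, sigma)
    }
}

#' Persist an illumination field for reuse across timepoints
#'
#' Writes the gain surface as a 16-bit grayscale PNG plus a JSON sidecar
#' (shape, smoothing sigma, image count, gain range) so a field
#' estimated on one plate scan can be reapplied to later scans.
#'
#' @param field an \linkS4class{IlluminationField}.
#' @param path output PNG path; the sidecar is \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
saveIlluminationField <- function(field, path) {
    g <- field@gain
    writePNG16(g, path)
    meta <- list(shape = dim(g), n_images_used = field@nImagesUsed,
                 smoothing_sigma_px = field@smoothingSigmaPx,
                 gain_min = min(g), gain_max = max(g))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname saveIlluminationField
#' @export
loadIlluminationField <- function(path) {
    g <- png::readPNG(path)
    meta <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    ## 16-bit quantization can nudge stored values; restore the exact
    ## range recorded in the sidecar and re-normalize
    g <- meta$gain_min +
        (g - min(g)) / max(max(g) - min(g), 1e-12) *
        (meta$gain_max - meta$gain_min)
    g <- pmin(g / max(g), 1)
    g[g <= 0] <- min(g[g > 0])
    new("IlluminationField", gain = g,
        nImagesUsed = as.integer(meta$n_images_used),
        smoothingSigmaPx = as.numeric(meta$smoothing_sigma_px))
}
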
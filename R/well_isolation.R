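## Locating the circular growth area inside a tiled image, masking,
## erosion, and geometric QC.

## Per-angle refinement of the growth-area boundary: from the coarse
## center, march each ray outwards over the (lightly smoothed) original
## image and take the inner edge of the outermost long bright run -- the
## halo ring. Short bright runs (debris, nuclei) are ignored by the
## minimum run length. Returns radii per angle (NA where no halo is
## crossed, e.g. rays exiting the frame first).
traceHaloInnerEdge <- function(px, center, rCoarse, nAngles = 720L,
                               minRunPx = 4L) {
    h <- nrow(px); w <- ncol(px)
    theta <- seq(0, 2 * pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
    rGrid <- seq(0.5 * rCoarse, 1.6 * rCoarse, by = 1)
    rows <- outer(cos(theta), rGrid) + center[1L]   # nAngles x nR
    cols <- outer(sin(theta), rGrid) + center[2L]
    inside <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
    ri <- pmin(pmax(round(rows), 1L), h)
    ci <- pmin(pmax(round(cols), 1L), w)
    vals <- matrix(px[cbind(as.vector(ri), as.vector(ci))],
                   nrow = nAngles)
    vals[!inside] <- NA
    ## threshold between interior background and halo brightness
    bg <- stats::median(vals[, seq_len(ceiling(0.3 * length(rGrid)))],
                        na.rm = TRUE)
    hi <- stats::quantile(vals, 0.98, na.rm = TRUE, names = FALSE)
    if (!is.finite(hi) || hi - bg < 0.05) return(rep(NA_real_, nAngles))
    tau <- bg + 0.5 * (hi - bg)
    radii <- rep(NA_real_, nAngles)
    for (a in seq_len(nAngles)) {
        v <- vals[a, ]
        ok <- which(!is.na(v) & v >= tau)
        if (!length(ok)) next
        ## split into runs, keep the longest
        breaks <- c(0L, which(diff(ok) > 1L), length(ok))
        lens <- diff(breaks)
        j <- which.max(lens)
        if (lens[j] < minRunPx) next
        radii[a] <- rGrid[ok[breaks[j] + 1L]]
    }
    ## 5-point circular median filter: one debris-crossing ray cannot
    ## drag the boundary
    if (sum(!is.na(radii)) >= 5L) {
        ext <- c(radii[(nAngles - 1L):nAngles], radii,
                 radii[1:2])
        radii <- vapply(seq_len(nAngles), function(a)
            stats::median(ext[a:(a + 4L)], na.rm = TRUE), numeric(1L))
        radii[is.nan(radii)] <- NA_real_
    }
    radii
}

## Rasterize the region enclosed by a per-angle radius profile around
## `center` into a logical mask (star-shaped, hence connected).
polarMask <- function(h, w, center, theta, radii) {
    ok <- !is.na(radii)
    th <- theta[ok]; rr <- radii[ok]
    ## close the circle for interpolation
    th <- c(th - 2 * pi, th, th + 2 * pi)
    rr <- c(rr, rr, rr)
    dr <- seq_len(h) - center[1L]
    dc <- seq_len(w) - center[2L]
    D <- sqrt(outer(dr^2, dc^2, "+"))
    ## pixel angles: atan2(dcol, drow) to match theta = (cos->row, sin->col)
    angM <- atan2(matrix(dc, h, w, byrow = TRUE), matrix(dr, h, w))
    angM[angM < 0] <- angM[angM < 0] + 2 * pi
    lim <- matrix(stats::approx(th, rr, xout = as.vector(angM),
                                rule = 2)$y, h, w)
    D <= lim
}

#' Detect the circular growth area of a well
#'
#' Treats the well as one very large object: inverts the image, smooths
#' it heavily so only the largest structure survives, thresholds
#' (default Otsu), keeps the largest connected component whose
#' equivalent diameter passes the size gate, and fills holes. A
#' least-squares circle is fitted to the component boundary, and the
#' boundary is then refined at full resolution by tracing the inner edge
#' of the halo ring along rays from the fitted center, which recovers
#' the growth-area outline to pixel accuracy regardless of where the
#' well sits in the frame. Eccentricity comes from the second moments of
#' the final region (ovoid frames give visibly eccentric regions).
#'
#' @param image a \linkS4class{TiledWellImage}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{WellMask}.
#' @seealso \code{\link{erodeMask}}, \code{\link{applyMask}},
#'   \code{\link{qcGeometry}}
#' @export
detectWell <- function(image, cfg = pipelineConfig()) {
    px <- pixels(image)
    h <- nrow(px); w <- ncol(px)
    sm <- gaussianBlur(1 - px, cfg@wellSmoothSigma)
    if (max(sm) - min(sm) < 0.02)
        psError("no well found: image has no large-scale structure",
                "platescan_no_well_found")
    thr <- if (is.numeric(cfg@wellThreshold)) cfg@wellThreshold
           else otsuThreshold(as.vector(sm))
    bw <- sm > thr
    lab <- EBImage::bwlabel(bw)
    tab <- tabulate(lab[lab > 0])
    if (!length(tab))
        psError("no well found: nothing above threshold",
                "platescan_no_well_found")
    ## drop candidates holding >= 3 frame corners: that is the region
    ## outside the well (or a degenerate full-frame component)
    corners <- c(lab[1L, 1L], lab[1L, w], lab[h, 1L], lab[h, w])
    for (id in unique(corners[corners > 0]))
        if (sum(corners == id) >= 3L) tab[id] <- 0L
    eqd <- 2 * sqrt(tab / pi)
    gate <- cfg@wellMinDiameterFrac * min(h, w)
    pass <- which(eqd >= gate & tab > 0L)
    if (!length(pass))
        psError(sprintf(
            "no well found: largest candidate has equivalent diameter %.0f px (gate %.0f px)",
            if (length(eqd)) max(eqd) else 0, gate),
            "platescan_no_well_found",
            largest_diameter = if (length(eqd)) max(eqd) else 0)
    id <- pass[which.max(tab[pass])]
    comp <- EBImage::fillHull(lab == id)
    mom <- regionMoments(comp)
    ## boundary of the coarse component for the initial circle fit
    bnd <- comp & !EBImage::erode(comp, EBImage::makeBrush(3L, "box"))
    bidx <- which(bnd, arr.ind = TRUE)
    fit <- fitCircle(bidx[, 1L], bidx[, 2L])
    if (is.null(fit)) fit <- list(center = mom$center, radius = mom$radius)
    ## full-resolution refinement against the halo ring
    nAngles <- 720L
    theta <- seq(0, 2 * pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
    radii <- traceHaloInnerEdge(px, fit$center, fit$radius,
                                nAngles = nAngles)
    if (mean(!is.na(radii)) >= 0.5) {
        mask <- polarMask(h, w, fit$center, theta, radii - 1)
        ok <- !is.na(radii)
        rows <- fit$center[1L] + radii[ok] * cos(theta[ok])
        cols <- fit$center[2L] + radii[ok] * sin(theta[ok])
        fit2 <- fitCircle(rows, cols)
        if (!is.null(fit2)) fit <- fit2
        mom <- regionMoments(mask)
    } else {
        mask <- comp
    }
    new("WellMask", mask = mask, center = fit$center, radius = fit$radius,
        eccentricity = mom$eccentricity, erosionAppliedPx = 0L)
}

#' Contract a well mask by morphological erosion
#'
#' Erodes with a disc structuring element, pulling the growth-area mask
#' away from the well edge so residual halo pixels are not mistaken for
#' cells. Center, radius and eccentricity are re-derived from the eroded
#' region's moments.
#'
#' @param wm a \linkS4class{WellMask}.
#' @param pixels non-negative erosion radius in px; \code{NULL} applies
#'   the automatic rule of \code{cfg} (1\% of the fitted radius, >= 3 px).
#' @param cfg a \linkS4class{PipelineConfig} (used only when
#'   \code{pixels} is \code{NULL}).
#' @return The eroded \linkS4class{WellMask}.
#' @export
erodeMask <- function(wm, pixels = NULL, cfg = pipelineConfig()) {
    if (is.null(pixels)) pixels <- resolveErosionPx(cfg, wm@radius)
    pixels <- as.integer(pixels)
    stopifnot(pixels >= 0L)
    if (pixels == 0L) return(wm)
    er <- EBImage::erode(wm@mask,
                         EBImage::makeBrush(2L * pixels + 1L, "disc"))
    er <- er > 0
    if (!any(er))
        psError(sprintf("erosion by %d px removed the entire mask", pixels),
                "platescan_low_mask_area")
    mom <- regionMoments(er)
    new("WellMask", mask = er, center = mom$center,
        radius = max(wm@radius - pixels, mom$radius),
        eccentricity = mom$eccentricity,
        erosionAppliedPx = wm@erosionAppliedPx + pixels)
}

#' Mask a well image
#'
#' Sets pixels outside the growth-area mask to the fill value and leaves
#' interior pixels untouched.
#'
#' @param image a \linkS4class{TiledWellImage}.
#' @param wm a \linkS4class{WellMask} of the same shape.
#' @param fill \code{"zero"} or \code{"background-median"} (the median
#'   of in-mask intensities, which avoids a hard edge at the boundary).
#' @return The masked \linkS4class{TiledWellImage}.
#' @export
applyMask <- function(image, wm, fill = c("zero", "background-median")) {
    fill <- match.arg(fill)
    px <- pixels(image)
    if (!identical(dim(px), dim(wm@mask)))
        psError("image and mask shapes differ", "platescan_contract_error")
    val <- if (fill == "zero") 0 else stats::median(px[wm@mask])
    px[!wm@mask] <- val
    pixels(image) <- px
    image
}

#' Geometric quality-control flags for a detected well
#'
#' Advisory flags that propagate into the per-well count records:
#' \code{OVOID} when the detected region's eccentricity exceeds the
#' configured bound (the vertical-compression acquisition fault) and
#' \code{LOW_MASK_AREA} when the mask covers too little of the frame.
#' Processing continues either way.
#'
#' @param wm a \linkS4class{WellMask}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return Character vector of flags (possibly empty).
#' @export
qcGeometry <- function(wm, cfg = pipelineConfig()) {
    flags <- character()
    if (wm@eccentricity > cfg@ovoidEccentricityMax)
        flags <- c(flags, "OVOID")
    if (sum(wm@mask) < cfg@minMaskAreaFrac * length(wm@mask))
        flags <- c(flags, "LOW_MASK_AREA")
    flags
}
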
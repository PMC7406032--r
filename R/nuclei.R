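## Nuclei segmentation and counting: in-mask thresholding, connected
## components, diameter gating, optional watershed declumping, and the
## truth-matching harness used to validate counts against the synthetic
## generator.

## Resolve the nuclei threshold for a vector of in-mask intensities.
## A numeric method is a fixed manual threshold (the workflow of record
## for optimized batch runs). "otsu" computes Otsu over the in-mask
## pixels, with a unimodality guard: Otsu famously misplaces the
## threshold inside the background mode when the foreground fraction is
## tiny (a handful of cells at clonal density in a whole well), so a
## threshold that would call an implausibly large fraction of the
## growth area "nuclei" is replaced by a robust background model
## (median + 5 * MAD-based sigma), which clears the background tail and
## still sits well below nuclear peaks.
nucleusThresholdValue <- function(v, method, maxForegroundFrac = 0.15,
                                  robustK = 5) {
    if (is.numeric(method)) return(method)
    thr <- otsuThreshold(v)
    if (mean(v > thr) > maxForegroundFrac) {
        thr <- stats::median(v) + robustK * stats::mad(v)
    }
    thr
}

## Per-label areas of an integer label matrix.
labelAreas <- function(lab, n) tabulate(lab[lab > 0L], nbins = n)

## Relabel a label matrix to contiguous 1..n keeping a subset.
keepLabels <- function(lab, keep) {
    map <- integer(max(lab) + 1L)
    map[keep + 1L] <- seq_along(keep)
    out <- matrix(map[lab + 1L], nrow(lab), ncol(lab))
    out
}

#' Segment and count nuclei in an enhanced well image
#'
#' Thresholds the in-mask pixels (Otsu over in-mask intensities by
#' default, or a fixed manual threshold), labels connected components
#' (8-connectivity), splits components larger than the maximum accepted
#' diameter by distance-transform watershed when declumping is on, and
#' then discards components whose equivalent diameter falls outside the
#' configured gate -- sub-gate residual debris below, halo remnants and
#' condensation patches above. Records are sorted by centroid (row,
#' col).
#'
#' @param image the enhanced (masked, log-transformed,
#'   illumination-corrected, denoised) \linkS4class{TiledWellImage}.
#' @param wm the \linkS4class{WellMask} of the well.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return List with \code{labels} (a \linkS4class{LabelImage}) and
#'   \code{records}, a data.frame with one row per nucleus: label,
#'   centroid_row, centroid_col, area_px, equivalent_diameter_px,
#'   mean_intensity.
#' @export
segmentNuclei <- function(image, wm, cfg = pipelineConfig()) {
    px <- pixels(image)
    if (!identical(dim(px), dim(wm@mask)))
        psError("image and mask shapes differ", "platescan_contract_error")
    if (!any(wm@mask))
        psError("empty well mask", "platescan_contract_error")
    thr <- nucleusThresholdValue(px[wm@mask], cfg@nucleusThreshold)
    bw <- (px > thr) & wm@mask
    dmin <- cfg@nucleusDiameterPx[1L]
    dmax <- cfg@nucleusDiameterPx[2L]
    if (cfg@declump == "watershed" && any(bw)) {
        ## distance-transform watershed over the whole foreground:
        ## touching nuclei separate at the waist of their combined
        ## blob, while a convex single spot keeps one basin (the
        ## tolerance merges shallow ridge-line maxima, so isolated
        ## objects are never split)
        lab <- EBImage::watershed(EBImage::distmap(bw), tolerance = 1)
        lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
    } else {
        lab <- EBImage::bwlabel(bw)
        lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
    }
    n <- max(lab)
    if (n == 0L) {
        return(list(labels = new("LabelImage",
                                 labels = matrix(0L, nrow(px), ncol(px)),
                                 nObjects = 0L),
                    records = emptyNucleusRecords()))
    }
    areas <- labelAreas(lab, n)
    eqd <- 2 * sqrt(areas / pi)
    keep <- which(eqd >= dmin & eqd <= dmax)
    lab <- keepLabels(lab, keep)
    n <- length(keep)
    if (n == 0L) {
        return(list(labels = new("LabelImage", labels = lab,
                                 nObjects = 0L),
                    records = emptyNucleusRecords()))
    }
    idx <- which(lab > 0L, arr.ind = TRUE)
    lv <- lab[lab > 0L]
    cr <- as.numeric(tapply(idx[, 1L], lv, mean))
    cc <- as.numeric(tapply(idx[, 2L], lv, mean))
    ar <- as.integer(tabulate(lv, nbins = n))
    mi <- as.numeric(tapply(px[lab > 0L], lv, mean))
    ord <- order(cr, cc)
    rec <- data.frame(label = seq_len(n),
                      centroid_row = cr[ord], centroid_col = cc[ord],
                      area_px = ar[ord],
                      equivalent_diameter_px = 2 * sqrt(ar[ord] / pi),
                      mean_intensity = mi[ord])
    ## relabel the image to match the sorted records
    lab <- keepLabels(lab, ord)
    list(labels = new("LabelImage", labels = lab, nObjects = n),
         records = rec)
}

emptyNucleusRecords <- function() {
    data.frame(label = integer(), centroid_row = numeric(),
               centroid_col = numeric(), area_px = integer(),
               equivalent_diameter_px = numeric(),
               mean_intensity = numeric())
}

#' Match detected nuclei to generator ground truth
#'
#' Greedy nearest-neighbor bipartite matching of detected centroids to
#' true centers within a distance cap. Deterministic and adequate for
#' sparse, non-overlapping truth.
#'
#' @param records nucleus records from \code{\link{segmentNuclei}}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param maxDist maximum centroid-to-center distance for a match, px.
#' @return Named integer vector \code{c(n_matched, n_missed,
#'   n_spurious)}; matched + missed equals the truth count, matched +
#'   spurious equals the detected count.
#' @export
matchToTruth <- function(records, truth, maxDist = 5) {
    stopifnot(maxDist > 0)
    nd <- nrow(records)
    nt <- truth@nucleusCount
    if (nd == 0L || nt == 0L)
        return(c(n_matched = 0L, n_missed = nt, n_spurious = nd))
    det <- cbind(records$centroid_row, records$centroid_col)
    tru <- truth@nucleusCenters
    d2 <- outer(det[, 1L], tru[, 1L], "-")^2 +
          outer(det[, 2L], tru[, 2L], "-")^2
    cand <- which(d2 <= maxDist^2, arr.ind = TRUE)
    if (!nrow(cand))
        return(c(n_matched = 0L, n_missed = nt, n_spurious = nd))
    cand <- cand[order(d2[cand]), , drop = FALSE]
    usedD <- logical(nd); usedT <- logical(nt)
    m <- 0L
    for (i in seq_len(nrow(cand))) {
        a <- cand[i, 1L]; b <- cand[i, 2L]
        if (!usedD[a] && !usedT[b]) {
            usedD[a] <- usedT[b] <- TRUE
            m <- m + 1L
        }
    }
    c(n_matched = m, n_missed = nt - m, n_spurious = nd - m)
}

#' Render detection outlines over the source image
#'
#' Writes an RGB PNG with the source intensities in the green channel
#' and object boundaries (object pixels with a 4-neighbor outside the
#' object) drawn in purple, mirroring the merged outline images used to
#' eyeball segmentation quality.
#'
#' @param image the original \linkS4class{TiledWellImage}.
#' @param labels a \linkS4class{LabelImage} of the same shape.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
renderOutlines <- function(image, labels, path) {
    px <- pixels(image)
    lab <- labels@labels
    if (!identical(dim(px), dim(lab)))
        psError("image and labels shapes differ", "platescan_contract_error")
    h <- nrow(lab); w <- ncol(lab)
    pad <- matrix(0L, h + 2L, w + 2L)
    pad[2:(h + 1L), 2:(w + 1L)] <- lab
    ctr <- pad[2:(h + 1L), 2:(w + 1L)]
    bnd <- ctr > 0L & (pad[1:h, 2:(w + 1L)] != ctr |
                       pad[3:(h + 2L), 2:(w + 1L)] != ctr |
                       pad[2:(h + 1L), 1:w] != ctr |
                       pad[2:(h + 1L), 3:(w + 2L)] != ctr)
    rgb <- array(0, c(h, w, 3L))
    rgb[, , 2L] <- px
    r <- rgb[, , 1L]; g <- rgb[, , 2L]; b <- rgb[, , 3L]
    r[bnd] <- 0.8; g[bnd] <- 0.1; b[bnd] <- 0.8
    rgb[, , 1L] <- r; rgb[, , 2L] <- g; rgb[, , 3L] <- b
    ok <- tryCatch({png::writePNG(rgb, path); TRUE},
                   error = function(e)
                       psError(sprintf("cannot write '%s': %s", path,
                                       conditionMessage(e)),
                               "platescan_io_error"))
    invisible(path)
}
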
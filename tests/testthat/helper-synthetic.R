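# Shared fixtures: a small, fast well geometry for unit tests and an
# in-memory processing chain mirroring the plate pipeline's stage order.

smallSpec <- function(...) {
    args <- list(...)
    defaults <- list(imageHeight = 400L, imageWidth = 480L,
                     wellRadius = 150, haloWidth = 18, nNuclei = 30L,
                     rngSeed = 1L)
    do.call(syntheticWellSpec, utils::modifyList(defaults, args))
}

# Run the per-well chain (detect, erode, mask, log, illumination,
# denoise, segment) on a renderWell() result. `field` reuses an
# existing illumination field; `thr` forces a manual threshold.
processWell <- function(r, cfg = pipelineConfig(), applyLog = TRUE,
                        applyIllum = TRUE, field = NULL, thr = NULL) {
    wm <- erodeMask(detectWell(r$image, cfg), NULL, cfg)
    img <- applyMask(r$image, wm, "zero")
    if (applyLog) img <- logTransform(img, cfg@logGainK)
    if (applyIllum) {
        if (is.null(field))
            field <- estimateIllumination(list(img), cfg, masks = list(wm))
        img <- correctIllumination(img, field)
    }
    img <- denoise(img, cfg@denoiseSigma)
    segCfg <- if (is.null(thr)) cfg else {
        cl <- configAsList(cfg)
        cl$nucleusThreshold <- thr
        cl$erosionPx <- if (is.na(cl$erosionPx)) NA else cl$erosionPx
        do.call(pipelineConfig, cl)
    }
    seg <- segmentNuclei(img, wm, segCfg)
    list(count = nrow(seg$records), seg = seg, wm = wm, img = img,
         field = field)
}

# Full-frame mask for constructed fixtures.
fullMask <- function(h, w) {
    new("WellMask", mask = matrix(TRUE, h, w), center = c(h / 2, w / 2),
        radius = min(h, w) / 2, eccentricity = 0, erosionAppliedPx = 0L)
}

# Plant a Gaussian spot with chosen sigma into a matrix (independent of
# the generator's diameter/4 convention, for constructed cases).
plantSpot <- function(px, ctr, sigma, amp) {
    h <- nrow(px); w <- ncol(px)
    dr <- seq_len(h) - ctr[1L]
    dc <- seq_len(w) - ctr[2L]
    pmin(px + amp * exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2)), 1)
}
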
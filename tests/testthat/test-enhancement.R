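test_that("log transform matches its closed form and fixes 0 and 1", {
    # arbitrary-precision reference values
    expect_equal(logTransform(matrix(0.5, 1, 1), k = 255)[1, 1],
                 0.87570306864923476, tolerance = 1e-9)
    expect_equal(logTransform(matrix(0.15, 1, 1), k = 255)[1, 1],
                 0.66182759361145338, tolerance = 1e-9)
    expect_equal(logTransform(matrix(0.3, 1, 1), k = 100)[1, 1],
                 0.74407313784201680, tolerance = 1e-9)
    for (k in c(0.5, 10, 255, 4000)) {
        ends <- logTransform(matrix(c(0, 1), 1, 2), k = k)
        expect_equal(as.vector(ends), c(0, 1), tolerance = 1e-12)
    }
})

test_that("log transform is strictly monotone on random pairs", {
    set.seed(11)
    a <- runif(1e4); b <- runif(1e4)
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- lo < hi
    out <- logTransform(rbind(lo[keep], hi[keep]), k = 255)
    expect_true(all(out[1, ] < out[2, ]))
    expect_error(logTransform(matrix(0.5), k = 0),
                 class = "platescan_config_error")
})

test_that("flat fields give unit gain; single image degenerates to itself", {
    imgs <- lapply(1:3, function(i) TiledWellImage(matrix(0.4, 60, 80)))
    fld <- estimateIllumination(imgs, masks = lapply(1:3, function(i)
        fullMask(60L, 80L)))
    expect_equal(range(gain(fld)), c(1, 1), tolerance = 1e-9)
    expect_identical(fld@nImagesUsed, 3L)
    # single-image input: smoothed, normalized version of that image
    grad <- matrix(rep(seq(0.3, 0.5, length.out = 80), each = 60), 60, 80)
    f1 <- estimateIllumination(list(TiledWellImage(grad)),
                               masks = list(fullMask(60L, 80L)))
    expect_equal(max(gain(f1)), 1)
    expect_identical(f1@nImagesUsed, 1L)
    expect_gt(cor(as.vector(gain(f1)), as.vector(grad)), 0.99)
})

test_that("estimation rejects empty or mismatched inputs", {
    expect_error(estimateIllumination(list()),
                 class = "platescan_contract_error")
    imgs <- list(TiledWellImage(matrix(0.4, 60, 80)),
                 TiledWellImage(matrix(0.4, 50, 80)))
    expect_error(estimateIllumination(imgs),
                 class = "platescan_contract_error")
})

test_that("estimation is permutation-invariant in the image list", {
    set.seed(21)
    imgs <- lapply(1:5, function(i) {
        m <- matrix(0.3 + 0.1 * runif(60 * 80), 60, 80)
        TiledWellImage(m)
    })
    masks <- lapply(1:5, function(i) fullMask(60L, 80L))
    f1 <- estimateIllumination(imgs, masks = masks)
    f2 <- estimateIllumination(rev(imgs), masks = rev(masks))
    expect_equal(gain(f1), gain(f2), tolerance = 1e-12)
})

test_that("estimated gain tracks the true vignette on synthetic sets", {
    cfg <- pipelineConfig()
    specs <- lapply(1:6, function(s)
        smallSpec(nNuclei = 30L, vignetteStrength = 0.4,
                  rngSeed = 100L + s))
    prep <- lapply(specs, function(sp) {
        r <- renderWell(sp)
        wm <- erodeMask(detectWell(r$image, cfg), NULL, cfg)
        list(img = logTransform(applyMask(r$image, wm, "zero"), 255),
             wm = wm)
    })
    fld <- estimateIllumination(lapply(prep, `[[`, "img"), cfg,
                                masks = lapply(prep, `[[`, "wm"))
    rt <- platescan:::tileRadiusField(400L, 480L, 3L, 4L)
    vtrue <- 1 - 0.4 * rt^2
    m <- maskMatrix(prep[[1]]$wm)
    expect_gt(cor(gain(fld)[m], vtrue[m]), 0.95)
})

test_that("correction flattens a vignetted background and removes the grid", {
    cfg <- pipelineConfig()
    # noise-free blank well at the full mosaic geometry isolates the
    # illumination artifact (the smoothing sigma is small relative to
    # the ~300 px tile period only at full scale)
    spec <- syntheticWellSpec(nNuclei = 0L, noiseSigma = 0,
                              vignetteStrength = 0.4, rngSeed = 31L)
    r <- renderWell(spec)
    wm <- erodeMask(detectWell(r$image, cfg), NULL, cfg)
    blog <- logTransform(applyMask(r$image, wm, "zero"), 255)
    fld <- estimateIllumination(list(blog), cfg, masks = list(wm))
    bcorr <- correctIllumination(blog, fld)
    m <- maskMatrix(wm)
    cv <- function(v) sd(v) / mean(v)
    expect_gt(cv(pixels(blog)[m]) / cv(pixels(bcorr)[m]), 5)
    # tile-seam contrast drops below 10% of its uncorrected value
    rt <- platescan:::tileRadiusField(1000L, 1200L, 3L, 4L)
    seam <- rt > 0.55 & m; ctr <- rt < 0.3 & m
    gridC <- function(px) abs(mean(px[seam]) - mean(px[ctr]))
    expect_lt(gridC(pixels(bcorr)) / gridC(pixels(blog)), 0.1)
    # identity field leaves the image unchanged
    unit <- new("IlluminationField", gain = matrix(1, 1000, 1200),
                nImagesUsed = 1L, smoothingSigmaPx = 15)
    expect_identical(pixels(correctIllumination(blog, unit)), pixels(blog))
    expect_error(
        correctIllumination(TiledWellImage(matrix(0.5, 10, 10)), fld),
        class = "platescan_contract_error")
})

test_that("denoise preserves constants and total intensity, sigma 0 is identity", {
    m <- matrix(0.42, 50, 60)
    expect_equal(denoise(m, 3), m, tolerance = 1e-6)
    expect_identical(denoise(m, 0), m)
    spot <- matrix(0, 41, 41); spot[21, 21] <- 1
    sm <- denoise(spot, 1)
    expect_lt(max(sm), 0.5)           # peak reduced
    expect_equal(sum(sm), 1, tolerance = 1e-3)  # mass preserved
    expect_error(denoise(m, -1), class = "platescan_config_error")
})

test_that("illumination fields persist through the 16-bit PNG round trip", {
    d <- withr::local_tempdir()
    rt <- platescan:::tileRadiusField(80L, 100L, 2L, 2L)
    g <- platescan:::gaussianBlur(1 - 0.3 * rt^2, 5)
    g <- g / max(g)
    fld <- new("IlluminationField", gain = g, nImagesUsed = 4L,
               smoothingSigmaPx = 5)
    p <- file.path(d, "field.png")
    saveIlluminationField(fld, p)
    expect_true(file.exists(p) && file.exists(paste0(p, ".json")))
    back <- loadIlluminationField(p)
    expect_lt(max(abs(gain(back) - gain(fld))), 1e-4)
    expect_identical(back@nImagesUsed, 4L)
})
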
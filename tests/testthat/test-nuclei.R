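test_that("blank masked images yield zero objects", {
    img <- TiledWellImage(matrix(0.1, 100, 100))
    seg <- segmentNuclei(img, fullMask(100L, 100L),
                         pipelineConfig(nucleusThreshold = 0.5))
    expect_identical(seg$labels@nObjects, 0L)
    expect_identical(nrow(seg$records), 0L)
    expect_error(segmentNuclei(img, fullMask(50L, 50L)),
                 class = "platescan_contract_error")
})

test_that("the full chain counts non-overlapping nuclei exactly", {
    r <- renderWell(smallSpec(nNuclei = 60L, rngSeed = 13L))
    p <- processWell(r)
    expect_identical(p$count, 60L)
    m <- matchToTruth(p$seg$records, r$truth)
    expect_identical(unname(m), c(60L, 0L, 0L))
    # records are sorted by centroid and satisfy the diameter identity
    rec <- p$seg$records
    expect_true(!is.unsorted(rec$centroid_row))
    expect_equal(rec$equivalent_diameter_px, 2 * sqrt(rec$area_px / pi),
                 tolerance = 1e-12)
})

test_that("touching spots split under watershed declumping but not without", {
    px <- matrix(0.02, 120, 140)
    px <- plantSpot(px, c(60, 60), sigma = 5, amp = 0.8)
    px <- plantSpot(px, c(60, 78), sigma = 5, amp = 0.8)
    img <- TiledWellImage(px)
    wm <- fullMask(120L, 140L)
    gate <- c(4, 20)
    sW <- segmentNuclei(img, wm, pipelineConfig(nucleusThreshold = 0.2,
        nucleusDiameterPx = gate, declump = "watershed"))
    sN <- segmentNuclei(img, wm, pipelineConfig(nucleusThreshold = 0.2,
        nucleusDiameterPx = gate, declump = "none"))
    expect_identical(sW$labels@nObjects, 2L)
    # without declumping the merged blob exceeds the gate and is dropped
    expect_identical(sN$labels@nObjects, 0L)
    sN2 <- segmentNuclei(img, wm, pipelineConfig(nucleusThreshold = 0.2,
        nucleusDiameterPx = c(4, 40), declump = "none"))
    expect_identical(sN2$labels@nObjects, 1L)
})

test_that("raising a manual threshold never increases the object count", {
    r <- renderWell(smallSpec(nNuclei = 40L, rngSeed = 17L))
    p <- processWell(r)
    counts <- vapply(seq(0.5, 0.95, by = 0.05), function(thr)
        segmentNuclei(p$img, p$wm,
                      pipelineConfig(nucleusThreshold = thr))$labels@nObjects,
        integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("counts are invariant under whole-scene translation", {
    cA <- processWell(renderWell(smallSpec(nNuclei = 25L,
        wellCenter = c(200, 240), rngSeed = 19L)))$count
    cB <- processWell(renderWell(smallSpec(nNuclei = 25L,
        wellCenter = c(185, 258), rngSeed = 19L)))$count
    expect_identical(cA, 25L)
    expect_identical(cB, 25L)
})

test_that("sub-gate debris specks are not counted as nuclei", {
    for (s in 23:25) {
        r <- renderWell(smallSpec(nNuclei = 40L, nDebris = 30L,
                                  rngSeed = s))
        expect_identical(processWell(r)$count, 40L)
    }
})

test_that("truth matching partitions detections and truths", {
    truth <- new("GroundTruth",
                 nucleusCenters = cbind(seq(10, 100, by = 10), 50),
                 nucleusCount = 10L, wellCenter = c(50, 50),
                 wellRadius = 45, wellId = "A1",
                 imagePath = NA_character_)
    rec <- function(rows, cols)
        data.frame(label = seq_along(rows), centroid_row = rows,
                   centroid_col = cols,
                   area_px = rep(10L, length(rows)),
                   equivalent_diameter_px = rep(3.57, length(rows)),
                   mean_intensity = rep(0.5, length(rows)))
    # perfect detection
    m <- matchToTruth(rec(seq(10, 100, by = 10), rep(50, 10)), truth)
    expect_identical(unname(m), c(10L, 0L, 0L))
    # empty detections
    m2 <- matchToTruth(rec(numeric(0), numeric(0)), truth)
    expect_identical(unname(m2), c(0L, 10L, 0L))
    # 9 near-matches within 2 px plus 1 far spurious
    m3 <- matchToTruth(rec(c(seq(10, 90, by = 10) + 1.5, 200),
                           c(rep(50, 9), 200)), truth, maxDist = 5)
    expect_identical(unname(m3), c(9L, 1L, 1L))
    # greedy matching is one-to-one: two detections near one truth
    m4 <- matchToTruth(rec(c(10, 11), c(50, 50)), truth, maxDist = 5)
    expect_identical(unname(m4), c(1L, 9L, 1L))
})

test_that("outline rendering marks boundaries and round-trips dimensions", {
    d <- withr::local_tempdir()
    px <- matrix(0.1, 60, 70)
    disc <- platescan:::distanceField(60L, 70L, c(30, 35)) <= 5
    px[disc] <- 0.9
    img <- TiledWellImage(px)
    seg <- segmentNuclei(img, fullMask(60L, 70L),
                         pipelineConfig(nucleusThreshold = 0.5,
                                        nucleusDiameterPx = c(3, 20)))
    f <- file.path(d, "outlines.png")
    renderOutlines(img, seg$labels, f)
    out <- png::readPNG(f)
    expect_identical(dim(out), c(60L, 70L, 3L))
    # boundary pixel count is close to the disc circumference
    nb <- sum(out[, , 1] > 0.5)
    expect_lt(abs(nb - 2 * pi * 5) / (2 * pi * 5), 0.2)
    # with no objects the output is the green-channel rendering
    seg0 <- segmentNuclei(TiledWellImage(matrix(0.1, 60, 70)),
                          fullMask(60L, 70L),
                          pipelineConfig(nucleusThreshold = 0.5))
    renderOutlines(img, seg0$labels, f)
    out0 <- png::readPNG(f)
    expect_equal(out0[, , 2], round(px * 255) / 255, tolerance = 1e-9)
    expect_true(all(out0[, , 1] == 0) && all(out0[, , 3] == 0))
})
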
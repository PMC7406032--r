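test_that("all-layers-off spec renders a constant background times gain", {
    spec <- smallSpec(nNuclei = 0L, nDebris = 0L, noiseSigma = 0,
                      vignetteStrength = 0, haloIntensity = 0,
                      exposureGain = 1.5)
    r <- renderWell(spec)
    expect_equal(unique(as.vector(pixels(r$image))), 0.05 * 1.5,
                 tolerance = 1e-12)
    expect_identical(nucleusCount(r$truth), 0L)
})

test_that("rendering is bit-identical for a fixed seed", {
    spec <- smallSpec(nNuclei = 100L, nDebris = 10L, rngSeed = 42L)
    r1 <- renderWell(spec)
    r2 <- renderWell(spec)
    expect_identical(pixels(r1$image), pixels(r2$image))
    expect_identical(r1$truth@nucleusCenters, r2$truth@nucleusCenters)
    # a different seed changes the scene
    r3 <- renderWell(smallSpec(nNuclei = 100L, nDebris = 10L, rngSeed = 43L))
    expect_false(identical(pixels(r1$image), pixels(r3$image)))
})

test_that("non-overlap placement respects the pairwise distance bound", {
    spec <- smallSpec(nNuclei = 100L, rngSeed = 7L)
    r <- renderWell(spec)
    ctr <- r$truth@nucleusCenters
    expect_identical(nrow(ctr), 100L)
    d <- as.matrix(dist(ctr))
    diag(d) <- Inf
    expect_gt(min(d), spec@nucleusDiameterPx[2L])  # > max diameter
    # all centers strictly inside the well disc
    cd <- sqrt((ctr[, 1] - spec@wellCenter[1])^2 +
               (ctr[, 2] - spec@wellCenter[2])^2)
    expect_true(all(cd < spec@wellRadius))
})

test_that("infeasible non-overlap placement raises a generation error", {
    spec <- smallSpec(wellRadius = 40, haloWidth = 5, nNuclei = 200L)
    expect_error(renderWell(spec), class = "platescan_generation_error")
})

test_that("halo ring is brighter than the well interior background", {
    spec <- smallSpec(nNuclei = 0L, noiseSigma = 0)
    r <- renderWell(spec)
    px <- pixels(r$image)
    D <- platescan:::distanceField(400L, 480L, spec@wellCenter)
    ring <- D >= spec@wellRadius + 2 & D <= spec@wellRadius + 10
    interior <- D < spec@wellRadius - 10
    expect_gt(mean(px[ring]), mean(px[interior]))
})

test_that("vignette depresses tile corners by about the configured factor", {
    spec <- smallSpec(nNuclei = 0L, noiseSigma = 0, haloIntensity = 0,
                      vignetteStrength = 0.4)
    r <- renderWell(spec)
    px <- pixels(r$image)
    rt <- platescan:::tileRadiusField(400L, 480L, 3L, 4L)
    corner <- px[rt > 0.97]
    center <- px[rt < 0.1]
    want <- (1 - 0.4 * mean(rt[rt > 0.97]^2)) /
            (1 - 0.4 * mean(rt[rt < 0.1]^2))
    expect_equal(mean(corner) / mean(center), want, tolerance = 0.005)
})

test_that("plate rendering jitters centers within bounds, deterministically", {
    base <- smallSpec(nNuclei = 5L)
    plate0 <- renderPlate(base, jitter = 0, seed = 3L,
                          wells = c("A1", "B2", "C3"))
    ctrs0 <- t(vapply(plate0, function(x) wellCenter(x$truth), numeric(2)))
    expect_true(all(ctrs0[, 1] == ctrs0[1, 1] & ctrs0[, 2] == ctrs0[1, 2]))

    plate <- renderPlate(base, jitter = 30, seed = 3L,
                         wells = wellIds96()[1:8])
    ctrs <- t(vapply(plate, function(x) wellCenter(x$truth), numeric(2)))
    offs <- sweep(ctrs, 2, base@wellCenter)
    expect_true(all(abs(offs) <= 30))
    expect_gt(max(abs(offs)), 0)
    plateB <- renderPlate(base, jitter = 30, seed = 3L,
                          wells = wellIds96()[1:8])
    expect_identical(pixels(plate[[4]]$image), pixels(plateB[[4]]$image))
})

test_that("per-well count overrides apply and unknown wells error", {
    base <- smallSpec(nNuclei = 5L)
    plate <- renderPlate(base, perWellCounts = c(A1 = 10L, H12 = 50L),
                         seed = 1L, wells = c("A1", "B1", "H12"))
    expect_identical(nucleusCount(plate[["A1"]]$truth), 10L)
    expect_identical(nucleusCount(plate[["B1"]]$truth), 5L)
    expect_identical(nucleusCount(plate[["H12"]]$truth), 50L)
    expect_error(renderPlate(base, perWellCounts = c(Z9 = 1L)),
                 class = "platescan_config_error")
})

test_that("spec validation rejects out-of-range fields by name", {
    expect_error(smallSpec(nNuclei = -1L), "nNuclei")
    expect_error(smallSpec(vignetteStrength = 1), "vignetteStrength")
    expect_error(smallSpec(ovoidYScale = 0), "ovoidYScale")
    expect_error(smallSpec(wellRadius = 400), "haloWidth")
})

test_that("written plates round-trip through PNG with matching truth", {
    d <- withr::local_tempdir()
    spec <- smallSpec(nNuclei = 12L, rngSeed = 9L)
    truth <- simulatePlate(spec, d, wells = c("A1", "B2", "C3", "D4"),
                           jitter = 5)
    expect_identical(nrow(truth), 4L)
    pngs <- list.files(d, pattern = "\\.png$")
    expect_length(pngs, 4L)
    img <- readWellImage(file.path(d, truth$image[2]))
    expect_identical(wellId(img), "B2")
    # 8-bit emission quantizes to 1/255
    rendered <- renderPlate(spec, jitter = 5, seed = spec@rngSeed,
                            wells = c("A1", "B2", "C3", "D4"))
    expect_lt(max(abs(pixels(img) - pixels(rendered[["B2"]]$image))),
              1 / 255)
    # determinism of the emitted truth
    d2 <- withr::local_tempdir()
    simulatePlate(spec, d2, wells = c("A1", "B2", "C3", "D4"), jitter = 5)
    expect_identical(readLines(file.path(d, "truth.csv")),
                     readLines(file.path(d2, "truth.csv")))
})
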
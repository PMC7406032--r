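test_that("population doublings match the log2 closed form", {
    expect_identical(populationDoublings(100, 100), 0)
    expect_identical(populationDoublings(800, 100), 3)
    expect_equal(populationDoublings(300, 100), 1.5849625007211562,
                 tolerance = 1e-12)
    # exact on powers of two
    expect_identical(populationDoublings(2^c(1, 5, 10) * 37, 37),
                     c(1, 5, 10))
    expect_error(populationDoublings(0, 100),
                 class = "platescan_undefined_pd")
    expect_error(populationDoublings(100, 0),
                 class = "platescan_undefined_pd")
})

test_that("doublings are scale-invariant and additive over intervals", {
    set.seed(33)
    for (i in 1:20) {
        a <- runif(1, 0.1, 10); b <- sample(1:500, 1); cc <- sample(1:500, 1)
        expect_equal(populationDoublings(a * cc, a * b),
                     populationDoublings(cc, b), tolerance = 1e-12)
    }
    n <- c(100, 170, 260, 410, 800)
    steps <- sum(populationDoublings(n[-1], n[-length(n)]))
    expect_equal(steps, populationDoublings(n[5], n[1]), tolerance = 1e-12)
})

test_that("growth curves aggregate replicates with mean and sample SD", {
    # 12 wells doubling exactly each 2-day step: mean 0,1,2..., sd 0
    wells <- wellIds96()[1:12]
    recs <- do.call(rbind, lapply(0:3, function(t)
        do.call(rbind, lapply(wells, function(w)
            wellCountRecord("P1", w, t * 2, 100L * 2L^t, 1000L)))))
    gc <- buildGrowthCurves(recs, list(MCF7 = wells))
    expect_equal(gc$mean_pd, 0:3)
    expect_equal(gc$sd_pd, rep(0, 4))
    expect_identical(gc$n, rep(12L, 4))
    # baseline row is exactly zero by construction
    expect_identical(gc$mean_pd[gc$timepoint == 0], 0)
    # replicate ordering does not change the curve
    gc2 <- buildGrowthCurves(recs[rev(seq_len(nrow(recs))), ],
                             list(MCF7 = wells))
    expect_equal(gc2, gc)
})

test_that("flagged wells are excluded under strict QC with n reduced", {
    wells <- wellIds96()[1:12]
    recs <- do.call(rbind, lapply(c(0, 2), function(t)
        do.call(rbind, lapply(wells, function(w)
            wellCountRecord("P1", w, t, 100L + 10L * t, 1000L,
                            if (w == "A3") "OVOID" else character())))))
    expect_warning(
        gc <- buildGrowthCurves(recs, list(g = wells), strictQc = TRUE),
        "A3")
    expect_identical(unique(gc$n), 11L)
    gcAll <- buildGrowthCurves(recs, list(g = wells))
    expect_identical(unique(gcAll$n), 12L)
})

test_that("zero-baseline wells are dropped with a warning, not infinite", {
    wells <- c("A1", "A2", "A3")
    recs <- rbind(wellCountRecord("P1", "A1", 0, 0L, 10L),
                  wellCountRecord("P1", "A2", 0, 50L, 10L),
                  wellCountRecord("P1", "A3", 0, 60L, 10L),
                  wellCountRecord("P1", "A1", 2, 80L, 10L),
                  wellCountRecord("P1", "A2", 2, 100L, 10L),
                  wellCountRecord("P1", "A3", 2, 120L, 10L))
    expect_warning(gc <- buildGrowthCurves(recs, list(g = wells)), "A1")
    expect_identical(unique(gc$n), 2L)
    expect_true(all(is.finite(gc$mean_pd)))
    # an empty group is an aggregation error naming the condition
    recs0 <- rbind(wellCountRecord("P1", "B1", 0, 0L, 10L),
                   wellCountRecord("P1", "B1", 2, 5L, 10L))
    expect_error(suppressWarnings(
        buildGrowthCurves(recs0, list(empty = "B1"))),
        "empty", class = "platescan_aggregation_error")
})

test_that("noisy exponential growth recovers the doubling rate by regression", {
    # counts N_t = 100 * 2^(t/2) with +/-5% noise, 12 wells, 8 timepoints
    set.seed(7)
    wells <- wellIds96()[1:12]
    tps <- seq(0, 14, by = 2)
    recs <- do.call(rbind, lapply(tps, function(t)
        do.call(rbind, lapply(wells, function(w) {
            n <- round(100 * 2^(t / 2) * runif(1, 0.95, 1.05))
            wellCountRecord("P1", w, t, as.integer(n), 1000L)
        }))))
    gc <- buildGrowthCurves(recs, list(line = wells))
    slope <- coef(lm(mean_pd ~ timepoint, data = gc))[["timepoint"]]
    expect_lt(abs(slope - 0.5) / 0.5, 0.1)
    expect_true(all(gc$sd_pd[gc$timepoint > 0] > 0))
    expect_identical(unique(gc$n), 12L)
})

test_that("circular ROI statistics match constructed fields", {
    img <- TiledWellImage(matrix(0.3, 50, 60))
    expect_equal(measureRoiBackground(img, c(25, 30), 10),
                 c(mean = 0.3, sd = 0), tolerance = 1e-12)
    # degenerate radius-0 ROI
    px <- matrix(0.3, 50, 60); px[25, 30] <- 0.77
    img2 <- TiledWellImage(px)
    expect_equal(measureRoiBackground(img2, c(25, 30), 0),
                 c(mean = 0.77, sd = 0))
    expect_error(measureRoiBackground(img, c(5, 5), 10),
                 class = "platescan_contract_error")
    # media comparison: bright vs imaging medium separated by > 5 SD
    mkWell <- function(bg, seed) {
        renderWell(smallSpec(nNuclei = 0L, backgroundLevel = bg,
                             rngSeed = seed))$image
    }
    dim_ <- measureRoiBackground(mkWell(0.05, 41L), c(200, 240), 60)
    bright <- measureRoiBackground(mkWell(0.5, 42L), c(200, 240), 60)
    expect_gt(bright[["mean"]] - dim_[["mean"]],
              5 * max(dim_[["sd"]], bright[["sd"]]))
})
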
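## Internal numeric helpers shared across modules.

## Evaluate an expression with a temporary RNG state seeded from `seed`,
## restoring the caller's state afterwards. All stochastic code in the
## package funnels through this so that a single seed fixes every output.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}

## Error constructors: condition classes let callers distinguish
## pipeline-level failures (e.g. a well that cannot be found) from
## programming errors.
psError <- function(msg, class, ...) {
    stop(errorCondition(msg, ..., class = c(class, "platescan_error")))
}

## Gaussian blur with reflective boundary handling. EBImage's gblur uses
## a circular boundary, which bleeds opposite edges into each other; we
## pad by reflection, blur, and crop so borders see mirrored content.
gaussianBlur <- function(m, sigma) {
    if (sigma == 0) return(m)
    pad <- min(ceiling(4 * sigma), nrow(m) - 1L, ncol(m) - 1L)
    ri <- c(rev(seq_len(pad) + 1L), seq_len(nrow(m)),
            nrow(m) - seq_len(pad))
    ci <- c(rev(seq_len(pad) + 1L), seq_len(ncol(m)),
            ncol(m) - seq_len(pad))
    big <- m[ri, ci]
    sm <- EBImage::gblur(big, sigma = sigma)
    sm[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}

## Otsu threshold of a numeric vector on [0, 1]; wraps EBImage's
## implementation so in-mask pixel sets (not whole frames) can be used.
otsuThreshold <- function(v, levels = 256L) {
    v <- v[!is.na(v)]
    if (!length(v)) psError("no pixels available for thresholding",
                            "platescan_contract_error")
    EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)),
                  range = c(0, 1), levels = levels)
}

## Least-squares (Kasa) circle fit to boundary points.
## Returns list(center = c(row, col), radius).
fitCircle <- function(rows, cols) {
    A <- cbind(2 * rows, 2 * cols, 1)
    b <- rows^2 + cols^2
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    ctr <- sol[1:2]
    r2 <- sol[3] + sum(ctr^2)
    if (r2 <= 0) return(NULL)
    list(center = as.numeric(ctr), radius = sqrt(r2))
}

## Moment statistics of a logical region: centroid, equivalent radius
## and eccentricity from the second-moment (covariance) eigenvalues.
regionMoments <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    n <- nrow(idx)
    ctr <- colMeans(idx)
    cv <- stats::cov(idx)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ecc <- if (ev[1L] <= 0) 0 else sqrt(max(0, 1 - ev[2L] / ev[1L]))
    list(center = as.numeric(ctr), area = n,
         radius = sqrt(n / pi), eccentricity = min(ecc, 1 - 1e-9))
}

## Normalized tile-local radius field for a mosaic: for every pixel, the
## distance to the center of its tile divided by the tile's corner
## distance (0 at tile centers, 1 at tile corners). Shared between the
## synthetic vignette model and illumination-profile imputation.
tileRadiusField <- function(h, w, tileRows, tileCols) {
    tileH <- h / tileRows
    tileW <- w / tileCols
    du <- ((seq_len(h) - 0.5) %% tileH) - tileH / 2
    dv <- ((seq_len(w) - 0.5) %% tileW) - tileW / 2
    rc <- sqrt((tileH / 2)^2 + (tileW / 2)^2)
    sqrt(outer(du^2, dv^2, "+")) / rc
}

## Distance of each pixel center from a point, as a matrix.
distanceField <- function(h, w, center) {
    dr <- seq_len(h) - center[1L]
    dc <- seq_len(w) - center[2L]
    sqrt(outer(dr^2, dc^2, "+"))
}

## Row-wise medians of a pixel stack (npix x nimages), NA-aware,
## processed in blocks to bound memory.
stackMedian <- function(mats) {
    n <- length(mats)
    if (n == 1L) return(mats[[1L]])
    npix <- length(mats[[1L]])
    out <- numeric(npix)
    block <- max(1L, floor(4e6 / n))
    start <- 1L
    while (start <= npix) {
        idx <- start:min(start + block - 1L, npix)
        sub <- vapply(mats, function(m) m[idx], numeric(length(idx)))
        out[idx] <- Biobase::rowMedians(sub, na.rm = TRUE)
        start <- start + block
    }
    dim(out) <- dim(mats[[1L]])
    out
}

## --- Minimal 16-bit grayscale PNG writer -------------------------------
## The png package reads 16-bit files but writes only 8-bit; illumination
## fields need the extra precision, so we emit the format directly:
## deflate via memCompress plus a table-driven CRC-32.

crc32Table <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) {
            t <- integer(256L)
            for (i in 0:255) {
                c <- i
                for (k in 1:8) {
                    c <- if (bitwAnd(c, 1L))
                        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))
                    else bitwShiftR(bitwAnd(c, -2L), 1L)
                }
                t[i + 1L] <- c
            }
            tab <<- t
        }
        tab
    }
})

crc32 <- function(bytes) {
    tab <- crc32Table()
    crc <- -1L
    for (b in as.integer(bytes)) {
        crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                       bitwShiftR(bitwAnd(crc, -256L), 8L))
    }
    bitwXor(crc, -1L)
}

uint32Raw <- function(x) {
    x <- as.double(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

pngChunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    crc <- crc32(body) %% 2^32
    c(uint32Raw(length(data)), body, uint32Raw(crc))
}

## Write a [0,1] matrix as a 16-bit grayscale PNG.
writePNG16 <- function(m, path) {
    h <- nrow(m); w <- ncol(m)
    v <- round(pmin(pmax(t(m), 0), 1) * 65535)  # row-major scanlines
    hi <- as.raw(v %/% 256L)
    lo <- as.raw(v %% 256L)
    scan <- raw(w * 2L)
    lines <- vector("list", h)
    for (r in seq_len(h)) {
        i <- (r - 1L) * w + seq_len(w)
        scan[seq(2L, 2L * w, 2L)] <- lo[i]
        scan[seq(1L, 2L * w, 2L)] <- hi[i]
        lines[[r]] <- c(as.raw(0L), scan)
    }
    payload <- memCompress(unlist(lines), type = "gzip")
    ihdr <- c(uint32Raw(w), uint32Raw(h),
              as.raw(c(16L, 0L, 0L, 0L, 0L)))
    out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             pngChunk("IHDR", ihdr),
             pngChunk("IDAT", payload),
             pngChunk("IEND", raw(0)))
    writeBin(out, path)
    invisible(path)
}
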
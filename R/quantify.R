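## Growth statistics from per-well counts, and the circular-ROI
## background measurement used when comparing imaging media.

#' Population doublings between two counts
#'
#' \code{log2(countT / count0)}: the number of times the population
#' doubled between the baseline scan and time t. Scale-invariant and
#' additive over consecutive intervals.
#'
#' @param countT,count0 positive cell counts (count at time t, count at
#'   baseline).
#' @return Numeric, may be negative if the population shrank.
#' @examples
#' populationDoublings(800, 100)  # 3 doublings
#' @export
populationDoublings <- function(countT, count0) {
    if (any(countT <= 0) || any(count0 <= 0))
        psError("population doublings undefined for zero counts",
                "platescan_undefined_pd")
    log2(countT / count0)
}

#' Build replicate growth curves from per-well count records
#'
#' For each condition and timepoint, computes population doublings per
#' well against that well's own baseline scan, then the mean and sample
#' standard deviation (n - 1) across replicate wells. Wells with a zero
#' baseline count are excluded with a warning (their doublings are
#' undefined); with \code{strictQc} wells carrying any QC flag are also
#' excluded.
#'
#' @param records counts data.frame (see \code{\link{wellCountRecord}}).
#' @param groups named list mapping condition names to well-id vectors.
#' @param baseline baseline timepoint (default: earliest in the records).
#' @param strictQc drop wells with QC flags.
#' @return data.frame with columns condition, timepoint, mean_pd, sd_pd,
#'   n.
#' @export
buildGrowthCurves <- function(records, groups, baseline = NULL,
                              strictQc = FALSE) {
    stopifnot(is.list(groups), length(groups) > 0)
    if (is.null(baseline)) baseline <- min(records$timepoint)
    out <- list()
    for (cond in names(groups)) {
        wells <- groups[[cond]]
        sub <- records[records$well_id %in% wells, , drop = FALSE]
        if (strictQc) {
            flagged <- unique(sub$well_id[nzchar(sub$qc_flags)])
            if (length(flagged))
                warning(sprintf("condition '%s': excluding flagged well(s) %s",
                                cond, paste(flagged, collapse = ", ")),
                        call. = FALSE)
            sub <- sub[!sub$well_id %in% flagged, , drop = FALSE]
        }
        base <- sub[sub$timepoint == baseline, , drop = FALSE]
        zero <- base$well_id[base$count <= 0]
        missing <- setdiff(intersect(wells, sub$well_id),
                           base$well_id)
        drop <- union(zero, missing)
        if (length(drop))
            warning(sprintf(
                "condition '%s': excluding well(s) %s (zero or missing baseline count)",
                cond, paste(drop, collapse = ", ")), call. = FALSE)
        sub <- sub[!sub$well_id %in% drop, , drop = FALSE]
        base <- base[!base$well_id %in% drop, , drop = FALSE]
        if (!nrow(sub))
            psError(sprintf("condition '%s': no usable wells", cond),
                    "platescan_aggregation_error")
        base0 <- stats::setNames(base$count, base$well_id)
        pd <- populationDoublings(pmax(sub$count, 1e-9),
                                  base0[sub$well_id])
        ## wells with zero counts at later timepoints are undefined too;
        ## exclude those observations only
        ok <- sub$count > 0
        pd <- pd[ok]; tp <- sub$timepoint[ok]
        agg <- tapply(pd, tp, function(v)
            c(mean(v), stats::sd(v), length(v)))
        tps <- as.numeric(names(agg))
        m <- do.call(rbind, agg)
        out[[cond]] <- data.frame(condition = cond, timepoint = tps,
                                  mean_pd = m[, 1L], sd_pd = m[, 2L],
                                  n = as.integer(m[, 3L]))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write growth curves to CSV
#'
#' @param curves output of \code{\link{buildGrowthCurves}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGrowthCsv <- function(curves, path) {
    utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Mean and SD of intensities in a circular ROI
#'
#' Measures the pixels whose centers lie within \code{radius} of
#' \code{center} -- the background-fluorescence measurement used to
#' compare imaging media. A radius of 0 measures the single nearest
#' pixel (SD 0).
#'
#' @param image a \linkS4class{TiledWellImage}.
#' @param center numeric (row, col), px.
#' @param radius ROI radius, px; the circle must lie inside the frame.
#' @return Named numeric \code{c(mean, sd)} (sample SD, n - 1).
#' @export
measureRoiBackground <- function(image, center, radius) {
    px <- pixels(image)
    h <- nrow(px); w <- ncol(px)
    if (radius < 0 || center[1L] - radius < 1 || center[1L] + radius > h ||
        center[2L] - radius < 1 || center[2L] + radius > w)
        psError("ROI circle must lie fully inside the image",
                "platescan_contract_error")
    if (radius == 0) {
        v <- px[round(center[1L]), round(center[2L])]
        return(c(mean = v, sd = 0))
    }
    D <- distanceField(h, w, center)
    v <- px[D <= radius]
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
}
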
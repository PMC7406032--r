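## Reading scans, parsing filenames, writing tabular outputs.

#' Default filename pattern for per-well scan images
#'
#' Imagers write one PNG per well but the naming dialect varies between
#' installations, so the pattern is a single Perl regular expression with
#' the named groups \code{plate}, \code{day} and \code{well} (only
#' \code{well} is mandatory). The default accepts names like
#' \code{"P1_day04_B07.png"} or \code{"scan_A1.png"}: an optional plate
#' prefix (\code{P<n>} or \code{plate<n>}), arbitrary noise, an optional
#' \code{day<n>} tag, and the well.
#'
#' @return Character scalar, a Perl-compatible regular expression.
#' @export
wellFilenamePattern <- function() {
    paste0("^(?:(?<plate>[Pp](?:late)?[0-9A-Za-z-]*[0-9])_)?",
           "(?:[Dd]ay(?<day>[0-9]+)_)?",
           "(?:.*?_)?",
           "(?<well>[A-Ha-h](?:0?[1-9]|1[0-2]))",
           "\\.[Pp][Nn][Gg]$")
}

#' Parse plate, well and timepoint from a scan filename
#'
#' @param name file name (directories are stripped).
#' @param pattern Perl regular expression with named groups \code{well}
#'   (mandatory) and optionally \code{plate} and \code{day}; see
#'   \code{\link{wellFilenamePattern}}.
#' @return List with \code{plateId} (default \code{"plate1"}),
#'   \code{wellId} (uppercased, leading zero stripped: \code{"b07"} ->
#'   \code{"B7"}) and \code{timepoint} (days, default 0).
#' @examples
#' parseWellFilename("P1_day04_B07.png")
#' @export
parseWellFilename <- function(name, pattern = wellFilenamePattern()) {
    name <- basename(name)
    m <- regexpr(pattern, name, perl = TRUE)
    if (m == -1L)
        psError(sprintf(
            "filename '%s' does not match the well-image pattern '%s'",
            name, pattern), "platescan_metadata_error")
    cs <- attr(m, "capture.start")[1L, ]
    cl <- attr(m, "capture.length")[1L, ]
    grab <- function(g) {
        if (!g %in% names(cs) || cs[[g]] <= 0L) return(NA_character_)
        substr(name, cs[[g]], cs[[g]] + cl[[g]] - 1L)
    }
    well <- grab("well")
    if (is.na(well))
        psError("pattern must contain a named group 'well'",
                "platescan_metadata_error")
    wellRow <- toupper(substr(well, 1L, 1L))
    wellCol <- as.integer(sub("^0+", "", substring(well, 2L)))
    plate <- grab("plate")
    day <- grab("day")
    list(plateId = if (is.na(plate)) "plate1" else plate,
         wellId = paste0(wellRow, wellCol),
         timepoint = if (is.na(day)) 0 else as.numeric(day))
}

#' Read one tiled well image from a PNG file
#'
#' Decodes an 8- or 16-bit grayscale or RGB PNG, normalizes intensities
#' to \[0, 1\] by dividing by \code{2^bitDepth - 1}, collapses RGB to one
#' channel, and parses identity metadata from the filename.
#'
#' @param path PNG file.
#' @param channelPolicy how to collapse RGB sources: the default
#'   \code{"green"} keeps the green channel (GFP-labeled nuclei emit
#'   there); \code{"luminance"} is the Rec. 601 weighted average;
#'   \code{"max"} is the per-pixel channel maximum. Grayscale sources
#'   ignore the policy.
#' @param pattern filename pattern, see \code{\link{parseWellFilename}}.
#' @param tileRows,tileCols mosaic layout the scan was acquired with.
#' @return A \linkS4class{TiledWellImage}.
#' @export
readWellImage <- function(path,
                          channelPolicy = c("green", "luminance", "red",
                                            "blue", "max"),
                          pattern = wellFilenamePattern(),
                          tileRows = 3L, tileCols = 4L) {
    channelPolicy <- match.arg(channelPolicy)
    if (!file.exists(path))
        psError(sprintf("cannot read image '%s': no such file", path),
                "platescan_io_error")
    a <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e)
                      psError(sprintf("cannot decode PNG '%s': %s",
                                      path, conditionMessage(e)),
                              "platescan_io_error"))
    depth <- attr(a, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    px <- if (length(dim(a)) == 2L) {
        a
    } else if (dim(a)[3L] %in% c(1L, 2L)) {
        a[, , 1L]  # grayscale (+ alpha)
    } else {
        switch(channelPolicy,
               red = a[, , 1L],
               green = a[, , 2L],
               blue = a[, , 3L],
               max = pmax(a[, , 1L], a[, , 2L], a[, , 3L]),
               luminance = 0.299 * a[, , 1L] + 0.587 * a[, , 2L] +
                   0.114 * a[, , 3L])
    }
    meta <- parseWellFilename(path, pattern)
    TiledWellImage(pixels = unclass(px), bitDepth = as.integer(depth),
                   plateId = meta$plateId, wellId = meta$wellId,
                   timepoint = meta$timepoint,
                   tileRows = tileRows, tileCols = tileCols,
                   sourcePath = path)
}

qcFlagLevels <- c("OVOID", "NO_WELL_FOUND", "LOW_MASK_AREA")

#' Assemble one per-well count record
#'
#' @param plateId,wellId,timepoint well identity.
#' @param count non-negative nucleus count (0 is a valid count).
#' @param maskAreaPx pixels of the growth-area mask used.
#' @param qcFlags character vector, subset of \code{OVOID},
#'   \code{NO_WELL_FOUND}, \code{LOW_MASK_AREA}.
#' @return One-row data.frame in the counts-table layout.
#' @export
wellCountRecord <- function(plateId, wellId, timepoint, count,
                            maskAreaPx = 0L, qcFlags = character()) {
    stopifnot(count >= 0, maskAreaPx >= 0, all(qcFlags %in% qcFlagLevels))
    data.frame(plate_id = plateId, well_id = wellId,
               timepoint = as.numeric(timepoint),
               count = as.integer(count),
               mask_area_px = as.integer(maskAreaPx),
               qc_flags = paste(qcFlags, collapse = ";"),
               stringsAsFactors = FALSE)
}

## Stable ordering: plate, timepoint, well row letter, well column.
orderCountRecords <- function(df) {
    rowL <- substr(df$well_id, 1L, 1L)
    colN <- as.integer(substring(df$well_id, 2L))
    df[order(df$plate_id, df$timepoint, rowL, colN), , drop = FALSE]
}

#' Write per-well count records to CSV
#'
#' Emits an RFC-4180 CSV (UTF-8, LF) with the columns
#' \code{plate_id,well_id,timepoint,count,mask_area_px,qc_flags}, rows
#' ordered deterministically by plate, timepoint and well position
#' regardless of input order. \code{\link{readCountsCsv}} re-reads the
#' file into the identical data.frame.
#'
#' @param records data.frame of \code{\link{wellCountRecord}} rows (an
#'   empty data.frame writes the header only).
#' @param path output file.
#' @return The output path, invisibly.
#' @export
writeCountsCsv <- function(records, path) {
    cols <- c("plate_id", "well_id", "timepoint", "count",
              "mask_area_px", "qc_flags")
    if (nrow(records)) {
        stopifnot(all(cols %in% names(records)))
        records <- orderCountRecords(records)[, cols, drop = FALSE]
    } else {
        records <- stats::setNames(
            data.frame(character(), character(), numeric(), integer(),
                       integer(), character()), cols)
    }
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e)
                        psError(sprintf("cannot write '%s': %s", path,
                                        conditionMessage(e)),
                                "platescan_io_error"))
    on.exit(close(con))
    utils::write.csv(records, con, row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a per-well counts CSV written by \code{\link{writeCountsCsv}}
#'
#' @param path CSV file.
#' @return data.frame with the counts-table columns.
#' @export
readCountsCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(plate_id = "character",
                                         well_id = "character",
                                         timepoint = "numeric",
                                         count = "integer",
                                         mask_area_px = "integer",
                                         qc_flags = "character"))
    df$qc_flags[is.na(df$qc_flags)] <- ""
    df
}
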
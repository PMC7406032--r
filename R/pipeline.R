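## Plate-level orchestration: read every well image of a scan, isolate
## and mask the wells, log-transform, estimate and apply the set-wide
## illumination function, denoise, segment, and write the counts table
## plus a run manifest.

pkgVersion <- function() {
    as.character(utils::packageVersion("platescan"))
}

#' Run the full counting pipeline over one plate scan
#'
#' Stage order is fixed: read, detect well, apply mask, erode,
#' log-transform, estimate the illumination function over all wells of
#' the plate, correct, denoise, segment. Per-well failures (no well
#' found) produce a flagged zero-count row and never abort the plate.
#'
#' The \code{applyLog} and \code{applyIllum} switches disable single
#' stages for diagnostic comparisons (e.g. quantifying how many grid
#' artifacts are counted as cells without illumination correction);
#' production runs leave both on.
#'
#' @param inputDir directory of per-well PNG images (one per well).
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param outDir output directory for \code{counts.csv} and
#'   \code{manifest.json}; \code{NULL} skips writing.
#' @param pattern filename pattern, see \code{\link{parseWellFilename}}.
#' @param channelPolicy RGB collapse policy, see
#'   \code{\link{readWellImage}}.
#' @param tileRows,tileCols mosaic layout of the scan.
#' @param strictQc if TRUE, QC-flagged wells keep their rows but are
#'   marked for exclusion downstream (the flags always propagate).
#' @param illumField optional pre-computed
#'   \linkS4class{IlluminationField} reused instead of estimating one
#'   from this plate (e.g. loaded with
#'   \code{\link{loadIlluminationField}}).
#' @param saveIllumPath optional path: persist the estimated field.
#' @param applyLog,applyIllum stage switches (see Details).
#' @param perObject if TRUE, per-nucleus records are kept in the result
#'   (and written per well when \code{outDir} is set).
#' @param debugImages if TRUE and \code{outDir} is set, writes an
#'   outline overlay PNG per well.
#' @param verbose emit per-stage progress to stderr.
#' @return List with \code{records} (counts data.frame), \code{objects}
#'   (named list of per-nucleus data.frames if \code{perObject}),
#'   \code{illumination} (the field used) and \code{manifest}.
#' @export
runPlate <- function(inputDir, cfg = pipelineConfig(), outDir = NULL,
                     pattern = wellFilenamePattern(),
                     channelPolicy = "green",
                     tileRows = 3L, tileCols = 4L,
                     strictQc = FALSE, illumField = NULL,
                     saveIllumPath = NULL,
                     applyLog = TRUE, applyIllum = TRUE,
                     perObject = FALSE, debugImages = FALSE,
                     verbose = FALSE) {
    t0 <- proc.time()[["elapsed"]]
    files <- list.files(inputDir, pattern = "\\.[Pp][Nn][Gg]$",
                        full.names = TRUE)
    parsed <- lapply(files, function(f)
        tryCatch(parseWellFilename(f, pattern), error = function(e) NULL))
    keep <- !vapply(parsed, is.null, logical(1L))
    rejected <- basename(files[!keep])
    files <- files[keep]; parsed <- parsed[keep]
    if (!length(files))
        psError(paste0("no parseable well images in ", inputDir,
                       if (length(rejected))
                           paste0("; rejected: ",
                                  paste(rejected, collapse = ", "))
                       else ""),
                "platescan_run_error")
    note <- function(...) if (verbose) message(sprintf(...))
    timings <- c()
    stage <- function(name, expr) {
        s <- proc.time()[["elapsed"]]
        r <- force(expr)
        timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
        r
    }
    warnings <- character()
    n <- length(files)
    imgs <- vector("list", n)
    masks <- vector("list", n)
    flags <- vector("list", n)
    note("reading and masking %d well image(s)", n)
    prep <- stage("crop_and_mask", {
        for (i in seq_len(n)) {
            img <- tryCatch(
                readWellImage(files[i], channelPolicy = channelPolicy,
                              pattern = pattern, tileRows = tileRows,
                              tileCols = tileCols),
                error = function(e) {
                    if (inherits(e, "platescan_io_error")) NULL else stop(e)
                })
            if (is.null(img)) {
                flags[[i]] <- "NO_WELL_FOUND"
                warnings <- c(warnings, sprintf("%s: unreadable image",
                                                basename(files[i])))
                next
            }
            wm <- tryCatch(detectWell(img, cfg), error = function(e) {
                if (inherits(e, "platescan_no_well_found")) NULL
                else stop(e)
            })
            if (is.null(wm)) {
                flags[[i]] <- "NO_WELL_FOUND"
                warnings <- c(warnings, sprintf("%s: no well found",
                                                basename(files[i])))
                next
            }
            wm <- tryCatch(erodeMask(wm, NULL, cfg), error = function(e) {
                if (inherits(e, "platescan_low_mask_area")) NULL
                else stop(e)
            })
            if (is.null(wm)) {
                flags[[i]] <- "LOW_MASK_AREA"
                next
            }
            flags[[i]] <- qcGeometry(wm, cfg)
            img <- applyMask(img, wm, fill = "zero")
            if (applyLog) img <- logTransform(img, cfg@logGainK)
            imgs[[i]] <- img
            masks[[i]] <- wm
        }
        NULL
    })
    usable <- !vapply(imgs, is.null, logical(1L))
    field <- NULL
    if (applyIllum && any(usable)) {
        field <- stage("illumination", {
            if (!is.null(illumField)) illumField
            else estimateIllumination(imgs[usable], cfg,
                                      masks = masks[usable])
        })
        if (!is.null(saveIllumPath)) saveIlluminationField(field, saveIllumPath)
    }
    records <- list()
    objects <- list()
    note("counting nuclei")
    stage("count", {
        for (i in seq_len(n)) {
            p <- parsed[[i]]
            if (is.null(imgs[[i]])) {
                records[[i]] <- wellCountRecord(p$plateId, p$wellId,
                                                p$timepoint, 0L, 0L,
                                                flags[[i]])
                next
            }
            img <- imgs[[i]]
            if (!is.null(field)) img <- correctIllumination(img, field)
            img <- denoise(img, cfg@denoiseSigma)
            seg <- segmentNuclei(img, masks[[i]], cfg)
            records[[i]] <- wellCountRecord(p$plateId, p$wellId,
                                            p$timepoint,
                                            nrow(seg$records),
                                            maskArea(masks[[i]]),
                                            flags[[i]])
            if (perObject) objects[[p$wellId]] <- seg$records
            if (debugImages && !is.null(outDir)) {
                dir.create(file.path(outDir, "debug"),
                           showWarnings = FALSE, recursive = TRUE)
                renderOutlines(
                    readWellImage(files[i], channelPolicy = channelPolicy,
                                  pattern = pattern),
                    seg$labels,
                    file.path(outDir, "debug",
                              sprintf("%s_outlines.png", p$wellId)))
            }
        }
        NULL
    })
    records <- orderCountRecords(do.call(rbind, records))
    manifest <- list(
        software = paste0("platescan ", pkgVersion()),
        config = configAsList(cfg),
        rng_seed = cfg@rngSeed,
        input_dir = normalizePath(inputDir),
        inputs = data.frame(file = basename(files),
                            md5 = unname(tools::md5sum(files)),
                            stringsAsFactors = FALSE),
        stage_seconds = as.list(timings),
        applied_stages = list(log_transform = applyLog,
                              illumination_correction = applyIllum),
        n_wells = n,
        rejected_files = rejected,
        warnings = warnings,
        elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeCountsCsv(records, file.path(outDir, "counts.csv"))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        if (perObject)
            for (wid in names(objects))
                utils::write.csv(objects[[wid]],
                                 file.path(outDir,
                                           sprintf("objects_%s.csv", wid)),
                                 row.names = FALSE)
    }
    list(records = records,
         objects = if (perObject) objects else NULL,
         illumination = field, manifest = manifest)
}

#' Render a synthetic plate from a spec file and write it to disk
#'
#' The simulate entry point: reads a \code{\link{syntheticWellSpec}}
#' YAML (or takes the spec object directly), renders the requested
#' wells, and writes the PNG images, ground-truth CSV and a manifest.
#'
#' @param spec a \linkS4class{SyntheticWellSpec} or path to a YAML spec.
#' @param outDir output directory.
#' @param wells well ids to render (default all 96).
#' @param jitter well-center jitter in px.
#' @param seed master seed (default: the spec's).
#' @param perWellCounts optional named nucleus-count overrides.
#' @param bitDepth 8 or 16.
#' @param plateId,timepoint identity stamped on the images.
#' @return Invisibly, the truth data.frame.
#' @export
simulatePlate <- function(spec, outDir, wells = wellIds96(), jitter = 0,
                          seed = NULL, perWellCounts = NULL,
                          bitDepth = 8L, plateId = "plate1",
                          timepoint = 0) {
    if (is.character(spec)) spec <- readSyntheticSpec(spec)
    validObject(spec)
    if (is.null(seed)) seed <- spec@rngSeed
    rendered <- renderPlate(spec, jitter = jitter,
                            perWellCounts = perWellCounts, seed = seed,
                            wells = wells, plateId = plateId,
                            timepoint = timepoint)
    truth <- writeSyntheticPlate(rendered, outDir, bitDepth = bitDepth,
                                 spec = spec)
    manifest <- list(software = paste0("platescan ", pkgVersion()),
                     rng_seed = seed, jitter_px = jitter,
                     n_wells = length(wells), bit_depth = bitDepth)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(truth)
}
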
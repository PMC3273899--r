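#' Run the full lamina analysis pipeline from a configuration
#'
#' Chains simulation (or stack loading), segmentation, feature extraction
#' and classification, writing a feature CSV, a classification JSON report,
#' a population-trend plot and a per-cell log to the output directory.
#' Cells whose lamina cannot be completely segmented are excluded and
#' listed in the log with their failure reasons.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' blocks \code{simulate} (templates, n_per_label, jitter, spacing_nm,
#' microscope) or \code{input} (dir with TIFF stacks + labels_csv),
#' \code{segmentation}, \code{features} and \code{classification}; the
#' top-level fields \code{seed} and \code{output_dir} are mandatory and
#' every random choice flows from \code{seed}.
#'
#' @param config path to a YAML config file, or a named list.
#' @return invisibly, a list with \code{features} (data.frame),
#'   \code{classification} (\linkS4class{ClassificationResult}),
#'   \code{pValue}, \code{excluded} (data.frame of excluded cells) and the
#'   output paths.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    for (field in c("seed", "output_dir"))
        if (is.null(config[[field]]))
            stop(sprintf("config schema violation: missing '%s'", field),
                 call. = FALSE)
    if (is.null(config$simulate) && is.null(config$input))
        stop("config schema violation: need a 'simulate' or 'input' block",
             call. = FALSE)
    outDir <- config$output_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outDir, "pipeline.log")
    logCon <- file(logPath, "w")
    on.exit(close(logCon))
    logLine <- function(...) writeLines(sprintf(...), logCon)
    seed <- as.integer(config$seed)
    logLine("pipeline start; seed=%d", seed)

    segCfg <- config$segmentation
    segArgs <- list(
        smoothingSigma = segCfg$smoothing_sigma %||% 100,
        threshold = segCfg$threshold %||% "otsu",
        minVolume = segCfg$min_volume %||% 1e10,
        closingIter = as.integer(segCfg$closing_iter %||% 2L),
        subdiv = as.integer(segCfg$subdiv %||% 4L))
    featCfg <- config$features
    nbr <- featCfg$neighborhood_radius

    cells <- if (!is.null(config$simulate)) {
        sc <- config$simulate
        tmplNames <- unlist(sc$templates %||% c("fresh", "senescent"))
        all <- phenotypeTemplates()
        .stopIfNot(all(tmplNames %in% names(all)),
                   "unknown template name in config")
        mic <- sc$microscope
        micList <- if (is.null(mic)) NULL else list(
            psfSigma = unlist(mic$psf_sigma %||% c(250, 120, 120)),
            photonScale = mic$photon_scale %||% 1,
            readNoiseSd = mic$read_noise_sd %||% 2,
            background = mic$background %||% 5)
        simulatePopulation(all[tmplNames],
                           nPerLabel = as.integer(sc$n_per_label %||% 10L),
                           jitter = sc$jitter %||% 0.05, seed = seed,
                           spacing = sc$spacing_nm %||% 50,
                           microscope = micList)
    } else {
        labels <- utils::read.csv(config$input$labels_csv,
                                  stringsAsFactors = FALSE)
        lapply(seq_len(nrow(labels)), function(i) {
            p <- file.path(config$input$dir, labels$file[i])
            list(stack = readStack(p), truth = NULL,
                 label = labels$label[i],
                 cellId = tools::file_path_sans_ext(labels$file[i]))
        })
    }
    logLine("cells to process: %d", length(cells))

    feats <- list()
    excluded <- data.frame(cell_id = character(), label = character(),
                           reason = character(), stringsAsFactors = FALSE)
    for (cell in cells) {
        res <- tryCatch(
            do.call(computeFeatures,
                    c(list(stack = cell$stack, cellId = cell$cellId,
                           label = cell$label, neighborhoodRadius = nbr),
                      segArgs)),
            laminaSegmentationError = function(e) e)
        if (is(res, "laminaSegmentationError")) {
            logLine("cell %s [%s]: EXCLUDED: %s", cell$cellId, cell$label,
                    conditionMessage(res))
            excluded <- rbind(excluded, data.frame(
                cell_id = cell$cellId, label = cell$label,
                reason = conditionMessage(res), stringsAsFactors = FALSE))
        } else {
            logLine("cell %s [%s]: ok (intensity=%.4g skewness=%.4g curvature=%.4g)",
                    cell$cellId, cell$label, res@intensity, res@skewness,
                    res@curvature)
            feats[[length(feats) + 1L]] <- res
        }
    }
    .stopIfNot(length(feats) >= 6, "too few segmentable cells to classify")
    ftab <- featureTable(feats)
    csvPath <- file.path(outDir, "features.csv")
    utils::write.csv(ftab, csvPath, row.names = FALSE)

    clsCfg <- config$classification
    subset <- unlist(clsCfg$feature_subset %||%
                     c("intensity", "skewness", "curvature"))
    ds <- populationDataset(ftab, subset)
    standardize <- clsCfg$standardize %||% TRUE
    result <- loocvError(ds, standardize = standardize)
    p <- permutationP(ds, nPerm = as.integer(clsCfg$n_perm %||% 199L),
                      seed = seed, standardize = standardize)
    result@pValue <- as.numeric(p)
    logLine("classification: LOO error %.4g +/- %.4g, p = %.4g",
            result@errorRate, result@errorSD, result@pValue)

    jsonPath <- file.path(outDir, "classification.json")
    jsonlite::write_json(list(
        error_rate = result@errorRate, error_sd = result@errorSD,
        p_value = result@pValue, n_cells = result@nCells,
        feature_subset = subset,
        confusion = as.data.frame(result@confusion),
        n_excluded = nrow(excluded)),
        jsonPath, auto_unbox = TRUE, digits = NA)

    trend <- populationTrendReport(ds)
    plotPath <- file.path(outDir, "population_trend.pdf")
    if (!is.null(trend$plot)) {
        grDevices::pdf(plotPath, width = 6, height = 5)
        print(trend$plot)
        grDevices::dev.off()
    }
    logLine("pipeline done")
    invisible(list(features = ftab, classification = result,
                   pValue = result@pValue, excluded = excluded,
                   paths = list(features = csvPath, json = jsonPath,
                                plot = plotPath, log = logPath)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
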
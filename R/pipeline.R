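.logStage <- function(fmt, ...) message(sprintf(paste0("[crisprarNoise] ", fmt), ...))

.PIPELINE_DEFAULTS <- list(
    output_dir = "crisprar_out",
    seed = 1L,
    paths = list(events = NULL, library = "default"),
    model = list(k_on_wt = 1, k_off_wt = 1, tau = 1, C = 10,
                 K_ro = 0.01, K_ao = 0.02, K_i = 10, K_int1 = 0.5,
                 K_int2 = 2),
    generate = list(n_replicates = 6L, n_events = 20000L,
                    measurement_cv = 0.05, replicate_cv = 0.05,
                    blank_fraction = 0.01, mode = "gamma_approx"),
    analysis = list(gating_quantile = 0.99, match_tolerance = 0.03,
                    region_threshold = 1, mean_tolerance = 0.05,
                    noise_tolerance = 0.10, noise_region_quantile = 0.5),
    contour = list(k_on = list(min = 0.01, max = 1, n = 50),
                   k_off = list(min = 0.01, max = 1, n = 50)))

.mergeConfig <- function(defaults, user, where = "config") {
    .assertKnownKeys(user, names(defaults), where)
    for (k in names(user)) {
        if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
            defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                          paste(where, k, sep = "$"))
        } else {
            defaults[[k]] <- user[[k]]
        }
    }
    defaults
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration covering paths, model parameters, generation settings
#' and analysis knobs. Any key absent from the file keeps its default;
#' unknown keys are rejected before any stage runs. With \code{path = NULL}
#' the full default configuration is returned.
#'
#' @param path YAML file, or NULL for defaults.
#' @return Validated configuration list.
#' @seealso [runGenerate()], [runAnalyze()], [runContour()]
#' @export
readPipelineConfig <- function(path = NULL) {
    user <- if (is.null(path)) list() else yaml::read_yaml(path)
    cfg <- .mergeConfig(.PIPELINE_DEFAULTS, user)
    stopifnot(cfg$analysis$gating_quantile > 0, cfg$analysis$gating_quantile <= 1)
    cfg
}

.configWt <- function(cfg) {
    promoterKinetics(kOn = cfg$model$k_on_wt, kOff = cfg$model$k_off_wt,
                     tau = cfg$model$tau, C = cfg$model$C)
}

.configParams <- function(cfg) {
    crisprParams(KRo = cfg$model$K_ro, KAo = cfg$model$K_ao,
                 Ki = cfg$model$K_i, Kint1 = cfg$model$K_int1,
                 Kint2 = cfg$model$K_int2)
}

.configLibrary <- function(cfg) {
    libPath <- cfg$paths$library
    if (is.null(libPath) || identical(libPath, "default"))
        list(singleModules = defaultSingleModules(),
             library = enumerateLibrary())
    else readLibraryConfig(libPath)
}

#' Generate a synthetic study bundle from a configuration
#'
#' Wraps [generateStudy()]: builds the design from the configuration's
#' model, generation and library settings and writes the bundle
#' (\code{events.csv}, \code{ground_truth.tsv}, \code{library.yaml},
#' \code{manifest.yaml}) into \code{output_dir}.
#'
#' @param config configuration list from [readPipelineConfig()].
#' @return The [generateStudy()] result, invisibly.
#' @export
runGenerate <- function(config = readPipelineConfig()) {
    lib <- .configLibrary(config)
    design <- syntheticDesign(
        library = lib$library, singleModules = lib$singleModules,
        params = .configParams(config), wt = .configWt(config),
        nReplicates = config$generate$n_replicates,
        nEvents = config$generate$n_events,
        measurementCv = config$generate$measurement_cv,
        replicateCv = config$generate$replicate_cv,
        blankFraction = config$generate$blank_fraction,
        seed = config$seed)
    .logStage("generate: %d constructs + %d single variants, %d x %d events",
              length(design@library), length(design@singleModules),
              design@nReplicates, design@nEvents)
    res <- generateStudy(design, dir = config$output_dir,
                         mode = config$generate$mode)
    .logStage("generate: wrote bundle to %s", config$output_dir)
    invisible(res)
}

#' Run the full measurement analysis from a configuration
#'
#' Reads the event table and library, gates against the blank, computes
#' per-replicate summaries and control-normalized means, fits the
#' single-sgRNA noise line, scores the CRISPRar constructs' region-wise
#' average deviation from it, attaches empirical-rule labels, and runs both
#' decision-tree selections. Writes \code{summaries.tsv},
#' \code{noise_fit.tsv}, \code{rules.tsv}, \code{selections_sm.tsv} and
#' \code{selections_sn.tsv} into \code{output_dir} (selections and rules
#' only when CRISPRar constructs are present).
#'
#' @param config configuration list; \code{paths$events} and
#'   \code{paths$library} must point at a generated (or measured) bundle.
#' @return List with \code{summaries}, \code{points}, \code{fit},
#'   \code{d_ave}, \code{rules}, \code{selection_sm}, \code{selection_sn},
#'   invisibly.
#' @export
runAnalyze <- function(config = readPipelineConfig()) {
    if (is.null(config$paths$events))
        stop("configuration error: paths$events is required for analysis")
    events <- readEventTable(config$paths$events)
    lib <- .configLibrary(config)
    .logStage("analyze: %d events in %d groups", nrow(events),
              length(unique(events$construct_id)))

    blank <- events[events$construct_id == "blank", , drop = FALSE]
    rest <- events[events$construct_id != "blank", , drop = FALSE]
    gated <- gateEvents(rest, blank, config$analysis$gating_quantile)
    .logStage("analyze: gating kept %d of %d events (threshold %.4g)",
              nrow(gated), nrow(rest), attr(gated, "threshold"))

    if (!"control" %in% gated$construct_id)
        stop("missing control group: cannot normalize expression means")
    summaries <- normalizeToControl(summarizeEvents(gated))

    ## replicate-averaged per-construct points
    agg <- function(v) tapply(v, summaries$construct_id, mean)
    points <- data.frame(construct_id = names(agg(summaries$mu)),
                         mu = as.numeric(agg(summaries$mu)),
                         noise = as.numeric(agg(summaries$eta2)),
                         norm_mean = as.numeric(agg(summaries$norm_mean)))
    points$inv_norm_mean <- 1 / points$norm_mean
    points$region <- ifelse(points$inv_norm_mean > config$analysis$region_threshold,
                            "low_expression", "high_expression")

    singleIds <- paste0("single_", vapply(lib$singleModules,
                                          function(m) m@name, character(1)))
    singles <- points[points$construct_id %in% singleIds, , drop = FALSE]
    fit <- NULL
    if (nrow(singles) >= 3) {
        fit <- fitNoiseLine(singles)
        .logStage("analyze: single-sgRNA line slope %.4g intercept %.4g R^2 %.4f",
                  fit@slope, fit@intercept, fit@rSquared)
    }

    libIds <- vapply(lib$library, constructId, character(1))
    crisprar <- points[points$construct_id %in% libIds, , drop = FALSE]
    dAve <- NULL
    rules <- NULL
    selSm <- selSn <- NULL
    if (nrow(crisprar) > 0) {
        labels <- t(vapply(lib$library[crisprar$construct_id],
                           classifyConstruct, character(3)))
        crisprar$rule1 <- labels[, "rule1"]
        crisprar$rule2 <- labels[, "rule2"]
        crisprar$rule3 <- labels[, "rule3"]
        rules <- crisprar[, c("construct_id", "rule1", "rule2", "rule3")]
        if (!is.null(fit)) {
            dAve <- averageDeviation(crisprar, fit)
            .logStage("analyze: d_ave by region: %s",
                      paste(names(dAve), sprintf("%.4g", dAve),
                            collapse = ", "))
        }
        selIn <- crisprar
        selIn$mean <- selIn$norm_mean
        selSm <- decisionTreeSelect(selIn, "same_mean_diff_noise",
                                    meanTolerance = config$analysis$mean_tolerance,
                                    noiseTolerance = config$analysis$noise_tolerance,
                                    noiseRegionQuantile = config$analysis$noise_region_quantile)
        selSn <- decisionTreeSelect(selIn, "same_noise_diff_mean",
                                    meanTolerance = config$analysis$mean_tolerance,
                                    noiseTolerance = config$analysis$noise_tolerance,
                                    noiseRegionQuantile = config$analysis$noise_region_quantile)
        .logStage("analyze: selections: %d same-mean, %d same-noise",
                  nrow(selSm), nrow(selSn))
    }

    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)
    wt(summaries, "summaries.tsv")
    if (!is.null(fit)) {
        fitRow <- data.frame(slope = fit@slope, intercept = fit@intercept,
                             r_squared = fit@rSquared, n = fit@n)
        if (!is.null(dAve))
            for (rg in names(dAve)) fitRow[[paste0("d_ave_", rg)]] <- dAve[[rg]]
        wt(fitRow, "noise_fit.tsv")
    }
    if (!is.null(rules)) wt(rules, "rules.tsv")
    if (!is.null(selSm)) wt(selSm, "selections_sm.tsv")
    if (!is.null(selSn)) wt(selSn, "selections_sn.tsv")

    invisible(list(summaries = summaries, points = points, fit = fit,
                   d_ave = dAve, rules = rules, selection_sm = selSm,
                   selection_sn = selSn))
}

#' Compute the contour grid and construct projections
#'
#' Evaluates the analytic mean/noise surfaces over the configured
#' (kOn, kOff) grid and projects the library's model-predicted construct
#' rates onto it. Writes \code{contour.tsv} (long format) and
#' \code{projection.tsv} into \code{output_dir}.
#'
#' @param config configuration list.
#' @return List with \code{grid} ([ContourGrid-class]) and
#'   \code{projection} (data.frame), invisibly.
#' @export
runContour <- function(config = readPipelineConfig()) {
    gc <- config$contour
    kOnValues <- seq(gc$k_on$min, gc$k_on$max, length.out = gc$k_on$n)
    kOffValues <- seq(gc$k_off$min, gc$k_off$max, length.out = gc$k_off$n)
    grid <- contourGrid(kOnValues, kOffValues, tau = config$model$tau,
                        C = config$model$C)
    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeContourGrid(grid, file.path(dir, "contour.tsv"))

    lib <- .configLibrary(config)
    projection <- NULL
    if (length(lib$library) == 0) {
        warning("empty library: contour grid written without projections")
    } else {
        projection <- predictLibrarySummaries(lib$library,
                                              .configParams(config),
                                              .configWt(config))
        projection$in_grid <- projection$k_on >= min(kOnValues) &
            projection$k_on <= max(kOnValues) &
            projection$k_off >= min(kOffValues) &
            projection$k_off <= max(kOffValues)
        utils::write.table(
            projection[, c("construct_id", "k_on", "k_off", "mean", "noise",
                           "in_grid")],
            file.path(dir, "projection.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        .logStage("contour: %d projections (%d inside grid bounds)",
                  nrow(projection), sum(projection$in_grid))
    }
    invisible(list(grid = grid, projection = projection))
}
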
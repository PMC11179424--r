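#' Simulate a full instability study
#'
#' Generates a multi-arm time-course experiment: for each condition, a set
#' of replicate cultures evolves under the Poisson gain/loss walk with the
#' condition's rate multiplier, each culture additionally drawing a
#' lognormal replicate-level rate factor (mean 1, coefficient of variation
#' \code{replicateRateCv}) to emulate biological variability between
#' parallel cultures. At every timepoint the population is PCR-stuttered
#' and rendered into a sized peak table under \code{map}.
#'
#' @param config a [SimConfig-class]; its \code{rateMultiplier} is replaced
#'   per condition, and its seed is ignored in favour of \code{seed}.
#' @param conditions named numeric vector of rate multipliers, e.g.
#'   \code{c(NTC = 1, MLH1 = 0.31)}.
#' @param nReplicates replicate cultures per condition.
#' @param nPools independent pools the replicates are drawn from (recorded
#'   in the replicate label).
#' @param times timepoints in \code{timeUnit}, starting at 0.
#' @param timeUnit \code{"days"} or \code{"weeks"} (rates in
#'   [SimConfig()] are per day).
#' @param controlCondition name of the non-targeting control arm.
#' @param replicateRateCv CV of the per-culture lognormal rate factor.
#' @param map [SizeToRepeatMap-class] used to place peaks on the bp axis.
#' @param heightScale fluorescence units of a unit-mass peak.
#' @param minHeight peaks below this synthesized height are not exported
#'   (detection floor of the instrument).
#' @param seed integer seed; all randomness in the run flows from it.
#' @param outDir optional directory; when given, writes \code{peaks.csv},
#'   \code{sheet.csv}, \code{truth.csv} and \code{config.yaml}.
#' @return Invisibly, a list with \code{peakTables} (named list of
#'   [PeakTable-class]), \code{sheet}, \code{truth} (per-timepoint true
#'   modal and mean repeat per replicate), and \code{map}.
#' @examples
#' run <- simulateStudy(SimConfig(nAlleles = 500),
#'                      conditions = c(NTC = 1, KD = 0.35),
#'                      times = c(0, 20, 40, 60, 80), seed = 1)
#' head(run$truth)
#' @export
simulateStudy <- function(config = simPreset("iPSC-control"),
                          conditions = c(NTC = 1),
                          nReplicates = 4L, nPools = 2L,
                          times = seq(0, 80, by = 20),
                          timeUnit = c("days", "weeks"),
                          controlCondition = names(conditions)[1L],
                          replicateRateCv = 0.15,
                          map = SizeToRepeatMap(interceptBp = 87.5),
                          heightScale = 10000, minHeight = 1,
                          seed = 1L, outDir = NULL) {
    timeUnit <- match.arg(timeUnit)
    if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
        stop("conditions must be a named vector of rate multipliers")
    if (!controlCondition %in% names(conditions))
        stop("controlCondition '", controlCondition,
             "' is not among the conditions")
    set.seed(as.integer(seed))
    dayFactor <- if (timeUnit == "weeks") 7 else 1
    sdlog <- sqrt(log(1 + replicateRateCv^2))

    peakTables <- list()
    sheetRows <- list()
    truthRows <- list()
    for (cond in names(conditions)) {
        for (r in seq_len(nReplicates)) {
            pool <- ((r - 1L) %% nPools) + 1L
            repLabel <- sprintf("p%d_c%d", pool, r)
            mult <- conditions[[cond]] *
                exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog))
            cfg <- initialize(config, rateMultiplier = mult,
                              seed = NA_integer_)
            pops <- simulatePopulation(cfg, times * dayFactor)
            for (k in seq_along(times)) {
                pop <- pops[[k]]
                dist <- applyStutter(pop, config@stutterRatio,
                                     config@stutterOrders)
                h <- dist@masses * heightScale
                keep <- h >= minHeight
                id <- sprintf("%s_%s_t%03d", cond, repLabel, times[k])
                peakTables[[id]] <- PeakTable(
                    id, repeatToBp(dist@repeats[keep], map), h[keep])
                sheetRows[[id]] <- data.frame(
                    sample_id = id, condition = cond, replicate = repLabel,
                    time = times[k], time_unit = timeUnit,
                    is_control = cond == controlCondition,
                    is_baseline = k == 1L, stringsAsFactors = FALSE)
                truthRows[[id]] <- data.frame(
                    sample_id = id, condition = cond, replicate = repLabel,
                    time = times[k], rate_multiplier = mult,
                    true_modal = modalRepeat(pop),
                    true_mean = mean(pop@repeatLengths),
                    stringsAsFactors = FALSE)
            }
        }
    }
    sheet <- do.call(rbind, unname(sheetRows))
    truth <- do.call(rbind, unname(truthRows))
    out <- list(peakTables = peakTables, sheet = sheet, truth = truth,
                map = map, seed = as.integer(seed))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!dir.exists(outDir)) stop("cannot create output dir: ", outDir)
        writePeakTable(peakTables, file.path(outDir, "peaks.csv"))
        utils::write.csv(sheet, file.path(outDir, "sheet.csv"),
                         row.names = FALSE)
        utils::write.csv(truth, file.path(outDir, "truth.csv"),
                         row.names = FALSE)
        writeRunConfig(list(
            mode = "simulate", seed = as.integer(seed),
            time_unit = timeUnit, times = as.numeric(times),
            conditions = as.list(conditions),
            control_condition = controlCondition,
            n_replicates = as.integer(nReplicates),
            n_pools = as.integer(nPools),
            replicate_rate_cv = replicateRateCv,
            initial_repeat = config@initialRepeat,
            n_alleles = config@nAlleles,
            gain_rate = config@gainRate, loss_rate = config@lossRate,
            length_dependence = config@lengthDependence,
            stutter_ratio = config@stutterRatio,
            stutter_orders = config@stutterOrders,
            bp_per_repeat = map@bpPerRepeat,
            intercept_bp = map@interceptBp),
            file.path(outDir, "config.yaml"))
    }
    invisible(out)
}

#' Analyze a fragment-analysis study end to end
#'
#' Reads peak tables and a sample sheet, calibrates the size-to-repeat map
#' against a sample of known modal repeat, summarizes every sample (modal
#' repeat and modified instability index, referenced to the replicate's own
#' baseline modal repeat), and fits per-condition expansion rates, percent
#' slowing versus the control, and Tukey-adjusted pairwise contrasts for
#' each requested metric. Progress and exclusions are logged to stderr;
#' results go to files (when \code{outDir} is given) and the returned list
#' only.
#'
#' @param peaks path to a peak-table CSV or a named list of
#'   [PeakTable-class] objects.
#' @param sheet path to a sample-sheet CSV or a data.frame.
#' @param config an [AnalysisConfig-class].
#' @param map a calibrated [SizeToRepeatMap-class], or NULL to calibrate
#'   from \code{calibrationSample}.
#' @param calibrationSample sample id used for intercept calibration;
#'   defaults to the first baseline sample of the control condition.
#' @param knownModalRepeat the calibration sample's true modal CAG count.
#' @param bpPerRepeat slope of the size-to-repeat map.
#' @param metrics metrics to fit rates for.
#' @param method rate estimator passed to [fitConditionRates()].
#' @param outDir optional output directory for \code{results.csv},
#'   \code{rates_<metric>.csv} and \code{contrasts_<metric>.csv}.
#' @return A list with \code{results} (per-sample data.frame),
#'   \code{rates} and \code{contrasts} (named by metric), and \code{map}.
#' @examples
#' run <- simulateStudy(SimConfig(nAlleles = 500),
#'                      conditions = c(NTC = 1, KD = 0.35), seed = 1)
#' ans <- analyzeStudy(run$peakTables, run$sheet)
#' ans$rates$instability_index
#' @export
analyzeStudy <- function(peaks, sheet, config = AnalysisConfig(),
                         map = NULL, calibrationSample = NULL,
                         knownModalRepeat = 125L, bpPerRepeat = 2.724117,
                         metrics = c("instability_index", "modal_repeat"),
                         method = c("two-stage", "mixed"),
                         outDir = NULL) {
    method <- match.arg(method)
    if (is.character(peaks)) peaks <- readPeakTable(peaks)
    if (!length(peaks)) stop("trace_io: no peak tables supplied")
    if (is.character(sheet)) sheet <- readSampleSheet(sheet)
    sheet <- validateSampleSheet(sheet)
    miss <- setdiff(sheet$sample_id, names(peaks))
    if (length(miss))
        stop("trace_io: no peak table for sample(s): ",
             paste(miss, collapse = ", "))

    if (is.null(map)) {
        if (is.null(calibrationSample)) {
            cand <- sheet$sample_id[sheet$is_control & sheet$is_baseline]
            if (!length(cand))
                stop("repeat_metrics: no control baseline sample available ",
                     "for calibration; pass calibrationSample or map")
            calibrationSample <- cand[1L]
        }
        map <- calibrateIntercept(peaks[[calibrationSample]],
                                  knownModalRepeat, bpPerRepeat)
        message("calibrated intercept ", format(map@interceptBp),
                " bp from sample '", calibrationSample, "'")
    }

    # reference for the modified index: the replicate's baseline modal CAG
    baseRows <- sheet[sheet$is_baseline, , drop = FALSE]
    baseModal <- vapply(baseRows$sample_id, function(id)
        as.integer(modalRepeat(filterPeaks(
            peaksToRepeatDistribution(peaks[[id]], map),
            config@thresholdFrac))), integer(1))
    repKey <- paste(sheet$condition, sheet$replicate)
    baseKey <- paste(baseRows$condition, baseRows$replicate)
    refs <- baseModal[match(repKey, baseKey)]
    names(refs) <- sheet$sample_id

    results <- summarizeSamples(peaks[sheet$sample_id], map, config,
                                referenceRepeats = refs)
    nIn <- sum(vapply(peaks[sheet$sample_id], function(p)
        length(p@height), integer(1)))
    message("summarized ", nrow(results), " samples; ",
            nIn - sum(results$n_peaks_retained),
            " of ", nIn, " peaks removed by the ",
            format(config@thresholdFrac), " modal-height threshold")
    message("run config hash ", runConfigHash(list(
        threshold = config@thresholdFrac, bp = bpPerRepeat,
        intercept = map@interceptBp, method = method)))

    rates <- list()
    contrasts <- list()
    for (m in metrics) {
        rates[[m]] <- fitConditionRates(results, sheet, metric = m,
                                        method = method)
        slopes <- attr(rates[[m]], "replicate_slopes")
        if (length(unique(slopes$condition)) >= 2L)
            contrasts[[m]] <- compareConditions(slopes)
    }
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(results, file.path(outDir, "results.csv"),
                         row.names = FALSE)
        for (m in metrics) {
            utils::write.csv(rates[[m]],
                             file.path(outDir, paste0("rates_", m, ".csv")),
                             row.names = FALSE)
            utils::write.csv(contrasts[[m]],
                             file.path(outDir,
                                       paste0("contrasts_", m, ".csv")),
                             row.names = FALSE)
        }
    }
    list(results = results, rates = rates, contrasts = contrasts,
         map = map)
}

#' Serialize / restore a run configuration
#'
#' Plain-YAML round trip for run configurations, so a run can be repeated
#' from its recorded file.
#'
#' @param config a named list of scalar/vector fields.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: the path, invisibly;
#'   \code{readRunConfig}: the restored list.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

# content hash of a run configuration, for the analysis log
runConfigHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(config, f, version = 2)
    unname(tools::md5sum(f))
}
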
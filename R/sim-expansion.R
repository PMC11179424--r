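#' Construct a simulation configuration
#'
#' The generative model is a length-dependent birth-death walk: over an
#' interval of length \eqn{\Delta t} each allele of length \eqn{L} gains
#' \eqn{\mathrm{Poisson}(g\,m\,\Delta t\,(1 + c\,(L - L_0)))} repeats and
#' loses \eqn{\mathrm{Poisson}(\ell\,\Delta t\,(1 + c\,(L - L_0)))}, where
#' \eqn{g} is \code{gainRate}, \eqn{m} the condition's
#' \code{rateMultiplier}, \eqn{\ell} \code{lossRate}, \eqn{c}
#' \code{lengthDependence} and \eqn{L_0} \code{initialRepeat}. Lengths are
#' floored at 1. With \eqn{c = \ell = 0} the expected gain after time
#' \eqn{t} is exactly \eqn{g\,m\,t} with Poisson variance.
#'
#' @param initialRepeat integer CAG count at baseline (default 125, a
#'   juvenile-onset-range HD allele).
#' @param nAlleles population size.
#' @param gainRate expected gains per allele per day.
#' @param lossRate expected losses per allele per day.
#' @param lengthDependence linear rate scaling per repeat above baseline.
#' @param rateMultiplier per-condition factor on \code{gainRate}.
#' @param stutterRatio geometric stutter decay in [0, 1).
#' @param stutterOrders maximum stutter offset in repeats.
#' @param traceSigmaBp Gaussian peak width (bp) for trace synthesis.
#' @param noiseSd baseline noise SD for trace synthesis.
#' @param seed integer RNG seed, or NA to leave the RNG state alone.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(gainRate = 0.05, nAlleles = 1000, seed = 1)
#' pops <- simulatePopulation(cfg, times = c(0, 40, 80))
#' @export
SimConfig <- function(initialRepeat = 125L, nAlleles = 1000L,
                      gainRate = 0.0625, lossRate = 0,
                      lengthDependence = 0, rateMultiplier = 1,
                      stutterRatio = 0.15, stutterOrders = 5L,
                      traceSigmaBp = 0.7, noiseSd = 0,
                      seed = NA_integer_) {
    new("SimConfig",
        initialRepeat = as.integer(initialRepeat),
        nAlleles = as.integer(nAlleles),
        gainRate = as.numeric(gainRate),
        lossRate = as.numeric(lossRate),
        lengthDependence = as.numeric(lengthDependence),
        rateMultiplier = as.numeric(rateMultiplier),
        stutterRatio = as.numeric(stutterRatio),
        stutterOrders = as.integer(stutterOrders),
        traceSigmaBp = as.numeric(traceSigmaBp),
        noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed))
}

#' Calibrated simulation presets
#'
#' Two presets whose expansion rates were calibrated so the simulated control
#' arms land on the ranges reported for 125-CAG HD model cultures:
#' \describe{
#'   \item{\code{"iPSC-control"}}{dividing iPSC cultures; gain rate 0.0625
#'     repeats/day, i.e. an expected modal gain of about 5 CAG over an
#'     80-day passage series (observed range 4-6).}
#'   \item{\code{"MSN-control"}}{post-mitotic striatal neuron cultures;
#'     gain rate 0.0336 repeats/day (0.2352/week), calibrated so the fitted
#'     instability-index slope through the full stutter + 20%-threshold
#'     pipeline is about 0.20 units/week.}
#' }
#' The presets are calibrated targets, not reproductions of any instrument
#' data.
#'
#' @param name preset name.
#' @param ... overrides passed to [SimConfig()].
#' @return A [SimConfig-class] object.
#' @examples
#' simPreset("iPSC-control", nAlleles = 5000, seed = 7)
#' @export
simPreset <- function(name = c("iPSC-control", "MSN-control"), ...) {
    name <- match.arg(name)
    defaults <- switch(name,
        "iPSC-control" = list(gainRate = 0.0625, nAlleles = 10000L),
        "MSN-control"  = list(gainRate = 0.2352 / 7, nAlleles = 10000L))
    args <- utils::modifyList(defaults, list(...))
    do.call(SimConfig, args)
}

#' Simulate a repeat-length population over a time course
#'
#' Evolves \code{config@nAlleles} alleles from \code{config@initialRepeat}
#' through the requested timepoints under the Poisson gain/loss walk
#' described in [SimConfig()]. The population at time 0 is
#' \code{nAlleles} identical copies of \code{initialRepeat}.
#'
#' @param config a [SimConfig-class] object.
#' @param times numeric vector of days, sorted, non-negative, starting at 0.
#' @return A list of [AllelePopulation-class] objects, one per timepoint.
#' @examples
#' pops <- simulatePopulation(SimConfig(seed = 1), c(0, 20, 40))
#' vapply(pops, function(p) mean(repeatLengths(p)), numeric(1))
#' @export
simulatePopulation <- function(config, times) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (length(times) < 1L || any(!is.finite(times)))
        stop("times must be a non-empty finite numeric vector")
    if (any(times < 0))
        stop("times must be non-negative")
    if (is.unsorted(times, strictly = TRUE))
        stop("times must be strictly increasing")
    if (times[1L] != 0)
        stop("times must start at 0 (baseline)")
    if (!is.na(config@seed)) set.seed(config@seed)

    lengths <- rep.int(config@initialRepeat, config@nAlleles)
    out <- vector("list", length(times))
    out[[1L]] <- new("AllelePopulation", repeatLengths = lengths,
                     timeDays = 0)
    g <- config@gainRate * config@rateMultiplier
    l <- config@lossRate
    for (i in seq_along(times)[-1L]) {
        dt <- times[i] - times[i - 1L]
        scale <- pmax(0, 1 + config@lengthDependence *
                             (lengths - config@initialRepeat))
        gains <- stats::rpois(length(lengths), g * dt * scale)
        losses <- stats::rpois(length(lengths), l * dt * scale)
        lengths <- pmax(1L, lengths + gains - losses)
        out[[i]] <- new("AllelePopulation",
                        repeatLengths = as.integer(lengths),
                        timeDays = times[i])
    }
    out
}

#' Apply a downward PCR-stutter model to an allele population
#'
#' Each allele of length L contributes relative mass
#' \code{stutterRatio^k} at repeat L - k for k = 0..\code{stutterOrders}
#' (geometric decay, downward only, the standard behaviour of polymerase
#' slippage across long CAG tracts); masses are summed per repeat length and
#' normalized to 1.
#'
#' @param population an [AllelePopulation-class] object.
#' @param stutterRatio per-repeat decay in [0, 1); 0 returns the empirical
#'   allele-length frequencies unchanged.
#' @param stutterOrders maximum stutter offset in repeat units.
#' @return A [RepeatDistribution-class] object.
#' @examples
#' pop <- new("AllelePopulation", repeatLengths = rep(100L, 5), timeDays = 0)
#' applyStutter(pop, 0.5, 2L)   # masses 4/7, 2/7, 1/7 at 100, 99, 98
#' @rdname applyStutter
#' @export
setMethod("applyStutter", "AllelePopulation",
    function(population, stutterRatio = 0.15, stutterOrders = 5L) {
        if (stutterRatio < 0 || stutterRatio >= 1)
            stop("stutterRatio must lie in [0, 1)")
        stutterOrders <- as.integer(stutterOrders)
        if (stutterOrders < 0L) stop("stutterOrders must be >= 0")
        lens <- population@repeatLengths
        counts <- table(lens)
        alleleReps <- as.integer(names(counts))
        alleleMass <- as.numeric(counts)
        offs <- 0:stutterOrders
        w <- stutterRatio^offs
        reps <- rep(alleleReps, each = length(offs)) - offs
        mass <- rep(alleleMass, each = length(offs)) * w
        keep <- reps >= 1L
        agg <- tapply(mass[keep], reps[keep], sum)
        r <- as.integer(names(agg))
        m <- as.numeric(agg)
        pos <- m > 0
        r <- r[pos]
        m <- m[pos]
        o <- order(r)
        new("RepeatDistribution", repeats = r[o], masses = m[o] / sum(m))
    })

# default Mapmarker-ROX-1000-like size standard: 50..1000 bp every 50 bp
defaultLadderSizes <- function() seq(50, 1000, by = 50)

#' Render a repeat distribution into a synthetic electropherogram
#'
#' The inverse of peak calling: each retained repeat peak is placed at its
#' bp position under \code{sizeMap}, rendered as a Gaussian kernel of width
#' \code{config@traceSigmaBp} with height proportional to its mass, and
#' summed on a scan axis with \code{scansPerBp} scans per bp. Gaussian
#' baseline noise of SD \code{config@noiseSd} is added (seeded through
#' \code{config@seed}). A ladder channel carries narrow spikes at the
#' configured ladder sizes.
#'
#' @param dist a normalized [RepeatDistribution-class].
#' @param sizeMap a [SizeToRepeatMap-class] giving repeat -> bp positions.
#' @param config a [SimConfig-class] (uses \code{traceSigmaBp},
#'   \code{noiseSd}, \code{seed}).
#' @param ladderSizes bp sizes of the co-run size standard.
#' @param scansPerBp scan-axis resolution (default 10).
#' @param peakScale height of a unit-mass peak in fluorescence units.
#' @return An [Electropherogram-class] with ladder scans and sizes filled in.
#' @examples
#' map <- SizeToRepeatMap()
#' dist <- new("RepeatDistribution", repeats = c(99L, 100L),
#'             masses = c(0.3, 0.7))
#' tr <- synthesizeTrace(dist, map, SimConfig(noiseSd = 0))
#' @export
synthesizeTrace <- function(dist, sizeMap, config = SimConfig(),
                            ladderSizes = defaultLadderSizes(),
                            scansPerBp = 10, peakScale = 10000) {
    stopifnot(is(dist, "RepeatDistribution"), is(sizeMap, "SizeToRepeatMap"),
              is(config, "SimConfig"))
    if (config@traceSigmaBp <= 0) stop("traceSigmaBp must be > 0")
    if (!is.na(config@seed)) set.seed(config@seed)
    bp <- repeatToBp(dist@repeats, sizeMap)
    if (any(bp <= 0)) stop("size map places peaks at non-positive bp")
    lo <- min(ladderSizes)
    hi <- max(ladderSizes)
    scans <- seq.int(1L, as.integer(ceiling((hi + 2) * scansPerBp)) + 1L)
    scanBp <- (scans - 1) / scansPerBp
    sigma <- config@traceSigmaBp
    signal <- numeric(length(scans))
    for (i in seq_along(bp)) {
        # evaluate the kernel only within +-6 sigma of the peak centre
        win <- which(abs(scanBp - bp[i]) <= 6 * sigma)
        signal[win] <- signal[win] + peakScale * dist@masses[i] *
            exp(-0.5 * ((scanBp[win] - bp[i]) / sigma)^2)
    }
    if (config@noiseSd > 0)
        signal <- signal + stats::rnorm(length(signal), 0, config@noiseSd)
    signal <- pmax(0, signal)
    ladderScans <- 1 + ladderSizes * scansPerBp
    ladderSignal <- numeric(length(scans))
    idx <- as.integer(round(ladderScans))
    ladderSignal[idx] <- peakScale
    shoulder <- c(idx - 1L, idx + 1L)
    shoulder <- shoulder[shoulder >= 1L & shoulder <= length(scans)]
    ladderSignal[shoulder] <- peakScale / 2
    new("Electropherogram", scans = scans, signal = signal,
        ladderScans = as.numeric(ladderScans),
        ladderSizes = as.numeric(ladderSizes),
        ladderSignal = ladderSignal)
}

#' Write population and distribution snapshots as tidy CSV
#'
#' @param populations list of [AllelePopulation-class] objects.
#' @param path output CSV path.
#' @param sampleId sample identifier written in the first column.
#' @return The path, invisibly.
#' @export
writePopulations <- function(populations, path, sampleId = "sim") {
    rows <- do.call(rbind, lapply(populations, function(p) {
        counts <- table(p@repeatLengths)
        data.frame(sample_id = sampleId, time_days = p@timeDays,
                   repeat_length = as.integer(names(counts)),
                   count = as.integer(counts))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}

#' @param dist a [RepeatDistribution-class].
#' @param timeDays elapsed time recorded with the snapshot.
#' @rdname writePopulations
#' @export
writeDistribution <- function(dist, path, sampleId = "sim", timeDays = NA) {
    rows <- data.frame(sample_id = sampleId, time_days = timeDays,
                       repeat_length = dist@repeats, mass = dist@masses)
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}
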
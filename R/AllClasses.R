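#' @import methods
NULL

#' Simulation configuration for somatic repeat expansion
#'
#' Parameters of the generative model: a population of alleles starting at a
#' common CAG length performs a length-dependent Poisson gain/loss walk over
#' time, is broadened by downward PCR stutter, and can be rendered into a
#' noisy capillary trace.
#'
#' @slot initialRepeat integer; CAG count of every allele at time zero.
#' @slot nAlleles integer; number of alleles (template molecules) tracked.
#' @slot gainRate numeric; expected repeat gains per allele per unit time.
#' @slot lossRate numeric; expected repeat losses per allele per unit time.
#' @slot lengthDependence numeric; dimensionless coefficient scaling both
#'   rates by \code{1 + lengthDependence * (L - initialRepeat)}.
#' @slot rateMultiplier numeric; per-condition factor applied to
#'   \code{gainRate} (knockdown arms use values < 1).
#' @slot stutterRatio numeric in [0, 1); per-repeat geometric decay of
#'   downward PCR stutter.
#' @slot stutterOrders integer; maximum stutter offset in repeat units.
#' @slot traceSigmaBp numeric; Gaussian peak width (bp) when synthesizing
#'   traces.
#' @slot noiseSd numeric; baseline Gaussian noise SD on synthesized traces.
#' @slot seed integer or NA; RNG seed (NA leaves the RNG state untouched).
#'
#' @seealso [SimConfig()], [simPreset()], [simulatePopulation()]
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        initialRepeat = "integer",
        nAlleles = "integer",
        gainRate = "numeric",
        lossRate = "numeric",
        lengthDependence = "numeric",
        rateMultiplier = "numeric",
        stutterRatio = "numeric",
        stutterOrders = "integer",
        traceSigmaBp = "numeric",
        noiseSd = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@initialRepeat < 1L)
        msg <- c(msg, "initialRepeat must be >= 1")
    if (object@nAlleles < 1L)
        msg <- c(msg, "nAlleles must be >= 1")
    if (object@gainRate < 0 || object@lossRate < 0)
        msg <- c(msg, "gainRate and lossRate must be >= 0")
    if (object@rateMultiplier < 0)
        msg <- c(msg, "rateMultiplier must be >= 0")
    if (object@stutterRatio < 0 || object@stutterRatio >= 1)
        msg <- c(msg, "stutterRatio must lie in [0, 1)")
    if (object@stutterOrders < 0L)
        msg <- c(msg, "stutterOrders must be >= 0")
    if (object@traceSigmaBp <= 0)
        msg <- c(msg, "traceSigmaBp must be > 0")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' A population of alleles at one timepoint
#'
#' A multiset of integer CAG lengths together with the elapsed time, the
#' ground-truth object produced by [simulatePopulation()].
#'
#' @slot repeatLengths integer vector of CAG counts, all >= 1.
#' @slot timeDays numeric; elapsed time in days since baseline.
#'
#' @exportClass AllelePopulation
setClass("AllelePopulation",
    representation(repeatLengths = "integer", timeDays = "numeric")
)

setValidity("AllelePopulation", function(object) {
    msg <- character()
    if (length(object@repeatLengths) < 1L)
        msg <- c(msg, "population must contain at least one allele")
    if (any(object@repeatLengths < 1L))
        msg <- c(msg, "all repeat lengths must be >= 1")
    if (length(object@timeDays) != 1L || object@timeDays < 0)
        msg <- c(msg, "timeDays must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' A raw capillary electropherogram
#'
#' Scan-indexed fluorescence signal for the sample channel, plus the size
#' standard: scan positions of ladder peaks and their known bp sizes. An
#' optional raw ladder-channel signal may be carried alongside.
#'
#' @slot scans integer vector, strictly increasing scan indices.
#' @slot signal numeric vector of non-negative fluorescence values, one per
#'   scan.
#' @slot ladderScans numeric vector, strictly increasing scan positions of
#'   the size-standard peaks.
#' @slot ladderSizes numeric vector of known bp sizes, parallel to
#'   \code{ladderScans}.
#' @slot ladderSignal numeric; raw ladder-channel signal (may be empty).
#'
#' @exportClass Electropherogram
setClass("Electropherogram",
    representation(
        scans = "integer",
        signal = "numeric",
        ladderScans = "numeric",
        ladderSizes = "numeric",
        ladderSignal = "numeric"
    )
)

setValidity("Electropherogram", function(object) {
    msg <- character()
    if (length(object@scans) != length(object@signal))
        msg <- c(msg, "scans and signal must have equal length")
    if (length(object@scans) > 1L && any(diff(object@scans) <= 0L))
        msg <- c(msg, "scans must be strictly increasing")
    if (any(object@signal < 0))
        msg <- c(msg, "signal must be non-negative")
    if (length(object@ladderScans) != length(object@ladderSizes))
        msg <- c(msg, "ladderScans and ladderSizes must have equal length")
    if (length(object@ladderScans) > 1L && any(diff(object@ladderScans) <= 0))
        msg <- c(msg, "ladderScans must be strictly increasing")
    if (length(object@ladderSignal) &&
        length(object@ladderSignal) != length(object@scans))
        msg <- c(msg, "ladderSignal, when present, must match scans in length")
    if (length(msg)) msg else TRUE
})

#' A table of sized peaks for one sample
#'
#' The GeneMapper-export-level object: fragment sizes in bp and peak heights
#' in arbitrary fluorescence units, sorted by size.
#'
#' @slot sampleId character scalar.
#' @slot sizeBp numeric; fragment sizes in bp, strictly positive, sorted,
#'   with no duplicates within 0.1 bp.
#' @slot height numeric; strictly positive peak heights, parallel to
#'   \code{sizeBp}.
#'
#' @exportClass PeakTable
setClass("PeakTable",
    representation(sampleId = "character", sizeBp = "numeric",
                   height = "numeric")
)

setValidity("PeakTable", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-missing string")
    if (length(object@sizeBp) != length(object@height))
        msg <- c(msg, "sizeBp and height must have equal length")
    if (any(object@sizeBp <= 0))
        msg <- c(msg, "sizeBp must be > 0")
    if (any(object@height <= 0))
        msg <- c(msg, "height must be > 0")
    if (length(object@sizeBp) > 1L) {
        d <- diff(object@sizeBp)
        if (any(d < 0))
            msg <- c(msg, "peaks must be sorted by sizeBp")
        else if (any(d < 0.1))
            msg <- c(msg, "duplicate sizeBp within 0.1 bp tolerance")
    }
    if (length(msg)) msg else TRUE
})

#' A repeat-length distribution with proportional peak heights
#'
#' Filtered peaks on the repeat-count axis; masses are proportional heights
#' normalized to sum to one over the retained peaks.
#'
#' @slot repeats integer; strictly increasing CAG counts.
#' @slot masses numeric; non-negative, summing to 1 within 1e-9.
#'
#' @exportClass RepeatDistribution
setClass("RepeatDistribution",
    representation(repeats = "integer", masses = "numeric")
)

setValidity("RepeatDistribution", function(object) {
    msg <- character()
    if (length(object@repeats) != length(object@masses))
        msg <- c(msg, "repeats and masses must have equal length")
    if (length(object@repeats) < 1L)
        msg <- c(msg, "distribution must be non-empty")
    if (length(object@repeats) > 1L && any(diff(object@repeats) <= 0L))
        msg <- c(msg, "repeats must be strictly increasing")
    if (any(object@masses < 0))
        msg <- c(msg, "masses must be >= 0")
    if (abs(sum(object@masses) - 1) > 1e-9)
        msg <- c(msg, "masses must sum to 1 within 1e-9")
    if (length(msg)) msg else TRUE
})

#' Linear map between fragment size and repeat count
#'
#' Apparent fragment size in bp is modelled as
#' \code{interceptBp + bpPerRepeat * repeats}. The slope defaults to
#' 2.724117 bp of apparent mobility per CAG unit; the intercept is
#' calibrated against a sample of known modal repeat (see
#' [calibrateIntercept()]).
#'
#' @slot bpPerRepeat numeric > 0; bp of apparent mobility per CAG unit.
#' @slot interceptBp numeric; apparent size at zero repeats.
#'
#' @exportClass SizeToRepeatMap
setClass("SizeToRepeatMap",
    representation(bpPerRepeat = "numeric", interceptBp = "numeric")
)

setValidity("SizeToRepeatMap", function(object) {
    if (length(object@bpPerRepeat) != 1L || object@bpPerRepeat <= 0)
        return("bpPerRepeat must be a single positive number")
    if (length(object@interceptBp) != 1L || !is.finite(object@interceptBp))
        return("interceptBp must be a single finite number")
    TRUE
})

#' Analysis configuration for repeat metrics
#'
#' @slot thresholdFrac numeric in [0, 1); peaks below this fraction of the
#'   modal peak height are discarded (inclusive comparison, default 0.20).
#' @slot roundingRule character; repeat assignment rule, currently
#'   \code{"nearest"}.
#' @slot referenceRepeat integer or NA; control modal repeat used as the
#'   instability-index reference. NA means each sample is referenced to its
#'   own modal repeat.
#'
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
    representation(thresholdFrac = "numeric", roundingRule = "character",
                   referenceRepeat = "integer")
)

setValidity("AnalysisConfig", function(object) {
    msg <- character()
    if (object@thresholdFrac < 0 || object@thresholdFrac >= 1)
        msg <- c(msg, "thresholdFrac must lie in [0, 1)")
    if (!object@roundingRule %in% "nearest")
        msg <- c(msg, "roundingRule must be 'nearest'")
    if (length(msg)) msg else TRUE
})

#' Per-sample instability summary
#'
#' @slot sampleId character scalar.
#' @slot modalRepeat integer; repeat with maximum proportional height.
#' @slot instabilityIndex numeric; height-weighted mean deviation from the
#'   reference repeat, in repeat units.
#' @slot nPeaksRetained integer >= 1; peaks surviving the modal-height
#'   threshold.
#' @slot referenceRepeat integer; reference CAG count used for the index.
#'
#' @exportClass InstabilityResult
setClass("InstabilityResult",
    representation(
        sampleId = "character",
        modalRepeat = "integer",
        instabilityIndex = "numeric",
        nPeaksRetained = "integer",
        referenceRepeat = "integer"
    )
)

setValidity("InstabilityResult", function(object) {
    msg <- character()
    if (!is.finite(object@instabilityIndex))
        msg <- c(msg, "instabilityIndex must be finite")
    if (object@nPeaksRetained < 1L)
        msg <- c(msg, "nPeaksRetained must be >= 1")
    if (length(msg)) msg else TRUE
})
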
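#' Construct a size-to-repeat map
#'
#' @param bpPerRepeat bp of apparent mobility per CAG unit. The default,
#'   2.724117, is the empirical correction factor for CAG tracts run on
#'   capillary sequencers: long repeat fragments migrate anomalously, so the
#'   apparent bp per repeat unit is less than 3.
#' @param interceptBp apparent fragment size at zero repeats; calibrate
#'   with [calibrateIntercept()] against a sample of known modal repeat.
#' @return A [SizeToRepeatMap-class].
#' @export
SizeToRepeatMap <- function(bpPerRepeat = 2.724117, interceptBp = 0) {
    new("SizeToRepeatMap", bpPerRepeat = as.numeric(bpPerRepeat),
        interceptBp = as.numeric(interceptBp))
}

#' Construct an analysis configuration
#'
#' @param thresholdFrac fraction of the modal peak height below which peaks
#'   are discarded; default 0.20, the standard modal-height threshold for
#'   CAG fragment analysis. The comparison is inclusive (a peak at exactly
#'   the threshold is retained).
#' @param roundingRule repeat-assignment rule; \code{"nearest"} rounds the
#'   continuous repeat estimate to the nearest integer.
#' @param referenceRepeat control modal CAG used as the instability-index
#'   reference, or NA to reference each sample to its own modal repeat.
#' @return An [AnalysisConfig-class].
#' @export
AnalysisConfig <- function(thresholdFrac = 0.20, roundingRule = "nearest",
                           referenceRepeat = NA_integer_) {
    new("AnalysisConfig", thresholdFrac = as.numeric(thresholdFrac),
        roundingRule = roundingRule,
        referenceRepeat = as.integer(referenceRepeat))
}

#' Convert fragment sizes to integer repeat counts
#'
#' \code{round((sizeBp - interceptBp) / bpPerRepeat)} under the
#' nearest-integer rule.
#'
#' @param sizeBp numeric vector of fragment sizes in bp.
#' @param map a [SizeToRepeatMap-class].
#' @return Integer repeat counts.
#' @examples
#' map <- SizeToRepeatMap(interceptBp = 0)
#' sizeToRepeat(125 * 2.724117, map)   # 125
#' @export
sizeToRepeat <- function(sizeBp, map) {
    stopifnot(is(map, "SizeToRepeatMap"))
    r <- as.integer(round((sizeBp - map@interceptBp) / map@bpPerRepeat))
    if (any(r < 0))
        stop("calibration error: fragment size maps to a negative repeat ",
             "count; check interceptBp")
    r
}

#' @rdname sizeToRepeat
#' @param repeats integer repeat counts.
#' @return \code{repeatToBp}: fragment sizes in bp (exact inverse on
#'   integers).
#' @export
repeatToBp <- function(repeats, map) {
    stopifnot(is(map, "SizeToRepeatMap"))
    map@interceptBp + repeats * map@bpPerRepeat
}

#' Calibrate the sizing intercept against a known-genotype sample
#'
#' Anchors the linear size-to-repeat map so the modal peak of
#' \code{peakTable} maps exactly to \code{knownModalRepeat}:
#' \code{interceptBp = modal size - knownModalRepeat * bpPerRepeat}.
#'
#' @param peakTable a [PeakTable-class] with an unambiguous modal peak.
#' @param knownModalRepeat the sample's known modal CAG count (e.g. 125 for
#'   the 125Q HD line).
#' @param bpPerRepeat slope of the map (default 2.724117).
#' @return A calibrated [SizeToRepeatMap-class].
#' @examples
#' pt <- PeakTable("cal", c(337.8, 340.51, 343.2), c(400, 1000, 300))
#' calibrateIntercept(pt, 125)
#' @export
calibrateIntercept <- function(peakTable, knownModalRepeat,
                               bpPerRepeat = 2.724117) {
    stopifnot(is(peakTable, "PeakTable"))
    if (!length(peakTable@height))
        stop("calibration error: peak table is empty")
    top <- which(peakTable@height == max(peakTable@height))
    if (length(top) > 1L &&
        diff(range(peakTable@sizeBp[top])) > bpPerRepeat)
        stop("calibration error: modal tie spans more than 1 repeat unit")
    modalSize <- peakTable@sizeBp[top[1L]]
    SizeToRepeatMap(bpPerRepeat = bpPerRepeat,
                    interceptBp = modalSize - knownModalRepeat * bpPerRepeat)
}

#' Filter peaks by the modal-height threshold
#'
#' Retains peaks whose height is at least \code{thresholdFrac} times the
#' modal (maximum) peak height; the comparison is inclusive, so the modal
#' peak itself is always retained and \code{thresholdFrac = 0} keeps
#' everything. For a [RepeatDistribution-class] the retained masses are
#' renormalized to sum to 1.
#'
#' @param x a [PeakTable-class] or [RepeatDistribution-class].
#' @param thresholdFrac fraction of modal height in [0, 1).
#' @return An object of the same class containing only retained peaks.
#' @examples
#' pt <- PeakTable("s", c(100, 103, 106), c(1000, 210, 199))
#' peakHeights(filterPeaks(pt, 0.20))   # 199 < 200 is dropped
#' @rdname filterPeaks
#' @export
setMethod("filterPeaks", "PeakTable", function(x, thresholdFrac = 0.20) {
    if (thresholdFrac < 0 || thresholdFrac >= 1)
        stop("thresholdFrac must lie in [0, 1)")
    keep <- x@height >= thresholdFrac * max(x@height)
    initialize(x, sizeBp = x@sizeBp[keep], height = x@height[keep])
})

#' @rdname filterPeaks
#' @export
setMethod("filterPeaks", "RepeatDistribution",
    function(x, thresholdFrac = 0.20) {
        if (thresholdFrac < 0 || thresholdFrac >= 1)
            stop("thresholdFrac must lie in [0, 1)")
        keep <- x@masses >= thresholdFrac * max(x@masses)
        m <- x@masses[keep]
        initialize(x, repeats = x@repeats[keep], masses = m / sum(m))
    })

#' Modal repeat length
#'
#' The repeat with maximum proportional height; an exact tie is broken
#' toward the smaller repeat (conservative against spurious expansion
#' calls).
#'
#' @param x a [RepeatDistribution-class] or [AllelePopulation-class].
#' @param ... unused.
#' @return Integer CAG count.
#' @rdname modalRepeat
#' @export
setMethod("modalRepeat", "RepeatDistribution", function(x, ...) {
    x@repeats[which.max(x@masses)]
})

#' @rdname modalRepeat
#' @export
setMethod("modalRepeat", "AllelePopulation", function(x, ...) {
    counts <- table(x@repeatLengths)
    as.integer(names(counts)[which.max(counts)])
})

#' Modified instability index
#'
#' The height-weighted mean deviation of repeat lengths from a reference
#' repeat: \eqn{\sum_i m_i (r_i - r_{ref})}, where \eqn{m_i} are the
#' proportional peak heights of the retained peaks. "Modified" refers to
#' the reference being the control sample's modal repeat rather than the
#' sample's own mode, so directional drift between conditions is preserved.
#'
#' @param x a filtered, normalized [RepeatDistribution-class].
#' @param referenceRepeat the reference CAG count.
#' @param ... unused.
#' @return Numeric index in repeat units.
#' @examples
#' d <- new("RepeatDistribution", repeats = c(98L, 100L, 101L),
#'          masses = c(0.25, 0.50, 0.25))
#' instabilityIndex(d, 100)   # -0.25
#' instabilityIndex(d, 98)    # 1.75
#' @rdname instabilityIndex
#' @export
setMethod("instabilityIndex", "RepeatDistribution",
    function(x, referenceRepeat, ...) {
        sum(x@masses * (x@repeats - referenceRepeat))
    })

#' Collapse a sized peak table onto the repeat axis
#'
#' Converts each peak's size to an integer repeat under \code{map}, sums
#' the heights of peaks rounding to the same repeat, and normalizes to a
#' [RepeatDistribution-class] (no threshold applied here).
#'
#' @param peakTable a [PeakTable-class].
#' @param map a calibrated [SizeToRepeatMap-class].
#' @return A [RepeatDistribution-class].
#' @export
peaksToRepeatDistribution <- function(peakTable, map) {
    stopifnot(is(peakTable, "PeakTable"))
    reps <- sizeToRepeat(peakTable@sizeBp, map)
    agg <- tapply(peakTable@height, reps, sum)
    r <- as.integer(names(agg))
    o <- order(r)
    m <- as.numeric(agg)[o]
    new("RepeatDistribution", repeats = r[o], masses = m / sum(m))
}

#' Summarize one sample: modal repeat and instability index
#'
#' The full per-sample chain: size-to-repeat conversion (merging peaks that
#' round to the same repeat), modal-height threshold filtering,
#' renormalization over the retained peaks, modal call, and the modified
#' instability index against the configured reference.
#'
#' @param peakTable a [PeakTable-class].
#' @param map a calibrated [SizeToRepeatMap-class].
#' @param config an [AnalysisConfig-class].
#' @param referenceRepeat optional override of
#'   \code{config@referenceRepeat}; if both are NA the sample's own modal
#'   repeat is used.
#' @return An [InstabilityResult-class].
#' @examples
#' map <- SizeToRepeatMap()
#' pt <- PeakTable("s", repeatToBp(c(98, 100, 101), map),
#'                 c(250, 500, 250))
#' summarizeSample(pt, map, AnalysisConfig(referenceRepeat = 100))
#' @export
summarizeSample <- function(peakTable, map, config = AnalysisConfig(),
                            referenceRepeat = NA) {
    stopifnot(is(config, "AnalysisConfig"))
    dist <- peaksToRepeatDistribution(peakTable, map)
    dist <- filterPeaks(dist, config@thresholdFrac)
    modal <- modalRepeat(dist)
    ref <- if (!is.na(referenceRepeat)) as.integer(referenceRepeat)
           else if (!is.na(config@referenceRepeat)) config@referenceRepeat
           else modal
    new("InstabilityResult",
        sampleId = peakTable@sampleId,
        modalRepeat = modal,
        instabilityIndex = instabilityIndex(dist, ref),
        nPeaksRetained = length(dist@repeats),
        referenceRepeat = ref)
}

#' Summarize many samples into a tidy data.frame
#'
#' @param peakTables list of [PeakTable-class] objects.
#' @param referenceRepeats optional named vector (by sample id) of
#'   reference repeats overriding the config.
#' @inheritParams summarizeSample
#' @return A data.frame with one row per sample (columns as in
#'   [as.data.frame.InstabilityResult()]).
#' @export
summarizeSamples <- function(peakTables, map, config = AnalysisConfig(),
                             referenceRepeats = NULL) {
    rows <- lapply(peakTables, function(pt) {
        ref <- NA
        if (!is.null(referenceRepeats) &&
            pt@sampleId %in% names(referenceRepeats))
            ref <- referenceRepeats[[pt@sampleId]]
        as.data.frame(summarizeSample(pt, map, config, ref))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
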
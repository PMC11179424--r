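#' @include AllClasses.R
NULL

#' @rdname applyStutter
#' @export
setGeneric("applyStutter", function(population, stutterRatio, stutterOrders)
    standardGeneric("applyStutter"))

#' @rdname modalRepeat
#' @export
setGeneric("modalRepeat", function(x, ...) standardGeneric("modalRepeat"))

#' @rdname instabilityIndex
#' @export
setGeneric("instabilityIndex", function(x, referenceRepeat, ...)
    standardGeneric("instabilityIndex"))

#' @rdname filterPeaks
#' @export
setGeneric("filterPeaks", function(x, thresholdFrac = 0.20)
    standardGeneric("filterPeaks"))

#' Accessors for RepeatInstability classes
#'
#' Small accessor generics exposing slots of the package's S4 classes:
#' sample identifier, peak sizes and heights, repeat counts and proportional
#' masses, allele lengths and elapsed time.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases sampleId peakSizes peakHeights repeats masses repeatLengths
#'   timeDays
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("peakSizes", function(x) standardGeneric("peakSizes"))

#' @rdname accessors
#' @export
setGeneric("peakHeights", function(x) standardGeneric("peakHeights"))

#' @rdname accessors
#' @export
setGeneric("repeats", function(x) standardGeneric("repeats"))

#' @rdname accessors
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @rdname accessors
#' @export
setGeneric("repeatLengths", function(x) standardGeneric("repeatLengths"))

#' @rdname accessors
#' @export
setGeneric("timeDays", function(x) standardGeneric("timeDays"))

setMethod("sampleId", "PeakTable", function(x) x@sampleId)
setMethod("sampleId", "InstabilityResult", function(x) x@sampleId)
setMethod("peakSizes", "PeakTable", function(x) x@sizeBp)
setMethod("peakHeights", "PeakTable", function(x) x@height)
setMethod("repeats", "RepeatDistribution", function(x) x@repeats)
setMethod("masses", "RepeatDistribution", function(x) x@masses)
setMethod("repeatLengths", "AllelePopulation", function(x) x@repeatLengths)
setMethod("timeDays", "AllelePopulation", function(x) x@timeDays)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:",
        sprintf("%d alleles starting at %d CAG", object@nAlleles,
                object@initialRepeat), "\n")
    cat(sprintf("  gain %.4g/day x %.3g, loss %.4g/day, length dep %.3g\n",
                object@gainRate, object@rateMultiplier, object@lossRate,
                object@lengthDependence))
    cat(sprintf("  stutter %.3g (orders %d), trace sigma %.3g bp, noise %.3g\n",
                object@stutterRatio, object@stutterOrders,
                object@traceSigmaBp, object@noiseSd))
    if (!is.na(object@seed)) cat("  seed", object@seed, "\n")
    invisible(NULL)
})

setMethod("show", "AllelePopulation", function(object) {
    cat(sprintf("AllelePopulation: %d alleles at day %.3g, lengths %d-%d (modal %d)\n",
                length(object@repeatLengths), object@timeDays,
                min(object@repeatLengths), max(object@repeatLengths),
                modalRepeat(object)))
    invisible(NULL)
})

setMethod("show", "Electropherogram", function(object) {
    cat(sprintf("Electropherogram: %d scans, %d ladder peaks (%g-%g bp)\n",
                length(object@scans), length(object@ladderScans),
                if (length(object@ladderSizes)) min(object@ladderSizes) else NA,
                if (length(object@ladderSizes)) max(object@ladderSizes) else NA))
    invisible(NULL)
})

setMethod("show", "PeakTable", function(object) {
    cat(sprintf("PeakTable '%s': %d peaks, %.2f-%.2f bp\n", object@sampleId,
                length(object@sizeBp), min(object@sizeBp), max(object@sizeBp)))
    invisible(NULL)
})

setMethod("show", "RepeatDistribution", function(object) {
    cat(sprintf("RepeatDistribution: %d peaks, repeats %d-%d, modal %d\n",
                length(object@repeats), min(object@repeats),
                max(object@repeats), modalRepeat(object)))
    invisible(NULL)
})

setMethod("show", "SizeToRepeatMap", function(object) {
    cat(sprintf("SizeToRepeatMap: size_bp = %.6f + repeat * %.6f\n",
                object@interceptBp, object@bpPerRepeat))
    invisible(NULL)
})

setMethod("show", "InstabilityResult", function(object) {
    cat(sprintf(
        "InstabilityResult '%s': modal %d, index %.4f (ref %d), %d peaks retained\n",
        object@sampleId, object@modalRepeat, object@instabilityIndex,
        object@referenceRepeat, object@nPeaksRetained))
    invisible(NULL)
})

#' Coerce an InstabilityResult to a one-row data.frame
#'
#' @param x an [InstabilityResult-class] object.
#' @param row.names,optional,... passed for interface compatibility; unused.
#' @return A one-row data.frame with columns \code{sample_id},
#'   \code{modal_repeat}, \code{instability_index}, \code{n_peaks_retained},
#'   \code{reference_repeat}.
#' @export
as.data.frame.InstabilityResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
    data.frame(
        sample_id = x@sampleId,
        modal_repeat = x@modalRepeat,
        instability_index = x@instabilityIndex,
        n_peaks_retained = x@nPeaksRetained,
        reference_repeat = x@referenceRepeat,
        stringsAsFactors = FALSE
    )
}
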
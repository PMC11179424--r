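#' Construct a PeakTable
#'
#' @param sampleId sample identifier.
#' @param sizeBp fragment sizes in bp.
#' @param height peak heights (arbitrary fluorescence units).
#' @return A [PeakTable-class] with peaks sorted by size.
#' @export
PeakTable <- function(sampleId, sizeBp, height) {
    o <- order(sizeBp)
    new("PeakTable", sampleId = as.character(sampleId),
        sizeBp = as.numeric(sizeBp)[o], height = as.numeric(height)[o])
}

#' Read GeneMapper-style peak tables from CSV
#'
#' Reads a comma-separated export with one row per peak and columns for the
#' sample identifier, fragment size (bp) and peak height. The
#' \code{dialect} maps those roles onto the file's actual column names, so
#' exports using e.g. \code{"Sample File"}, \code{"Size"} and
#' \code{"Height"} headers can be read directly. Rows with non-positive
#' height are dropped with a warning reporting the count.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param dialect named character vector with entries \code{sample},
#'   \code{size} and \code{height} giving the column names.
#' @return A named list of [PeakTable-class] objects, one per sample.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sample_id = "s1", size_bp = c(340.5, 337.8),
#'                      height = c(900, 350)), tmp, row.names = FALSE)
#' readPeakTable(tmp)
#' @export
readPeakTable <- function(path,
                          dialect = c(sample = "sample_id",
                                      size = "size_bp",
                                      height = "height")) {
    if (!file.exists(path)) stop("peak table file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("peak table file is empty: ", path)
    for (role in c("sample", "size", "height")) {
        col <- dialect[[role]]
        if (is.null(col) || !col %in% names(df))
            stop("peak table is missing required column '",
                 if (is.null(col)) role else col, "' (", role, ")")
    }
    sample <- as.character(df[[dialect[["sample"]]]])
    size <- as.numeric(df[[dialect[["size"]]]])
    height <- as.numeric(df[[dialect[["height"]]]])
    bad <- !is.na(height) & height <= 0
    if (any(bad)) {
        warning(sum(bad), " peak(s) with non-positive height dropped")
        sample <- sample[!bad]; size <- size[!bad]; height <- height[!bad]
    }
    if (!length(sample)) stop("no usable peaks in ", path)
    ids <- unique(sample)
    out <- lapply(ids, function(id) {
        i <- sample == id
        PeakTable(id, size[i], height[i])
    })
    names(out) <- ids
    out
}

#' Write peak tables to CSV in the package dialect
#'
#' @param tables a [PeakTable-class] or list of them.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @rdname readPeakTable
#' @export
writePeakTable <- function(tables, path) {
    if (is(tables, "PeakTable")) tables <- list(tables)
    rows <- do.call(rbind, lapply(tables, function(pt) {
        data.frame(sample_id = pt@sampleId,
                   size_bp = round(pt@sizeBp, 6),
                   height = round(pt@height, 6),
                   stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}

#' Read a raw trace plus ladder from CSV
#'
#' @param tracePath CSV with columns \code{scan}, \code{signal}.
#' @param ladderPath CSV with columns \code{scan}, \code{size_bp} giving the
#'   called ladder peaks.
#' @return An [Electropherogram-class].
#' @export
readTrace <- function(tracePath, ladderPath) {
    tr <- utils::read.csv(tracePath)
    if (!all(c("scan", "signal") %in% names(tr)))
        stop("trace CSV must have columns 'scan' and 'signal'")
    ld <- utils::read.csv(ladderPath)
    if (!all(c("scan", "size_bp") %in% names(ld)))
        stop("ladder CSV must have columns 'scan' and 'size_bp'")
    o <- order(ld$scan)
    new("Electropherogram", scans = as.integer(tr$scan),
        signal = as.numeric(tr$signal),
        ladderScans = as.numeric(ld$scan[o]),
        ladderSizes = as.numeric(ld$size_bp[o]),
        ladderSignal = numeric())
}

#' @rdname readTrace
#' @param trace an [Electropherogram-class].
#' @export
writeTrace <- function(trace, tracePath, ladderPath) {
    utils::write.csv(data.frame(scan = trace@scans, signal = trace@signal),
                     tracePath, row.names = FALSE)
    utils::write.csv(data.frame(scan = trace@ladderScans,
                                size_bp = trace@ladderSizes),
                     ladderPath, row.names = FALSE)
    invisible(tracePath)
}

#' Detect peaks in a raw trace
#'
#' Finds local maxima with signal at or above \code{minHeight}, enforcing a
#' minimum spacing: when two candidate maxima fall within
#' \code{minSpacingScans} of each other only the taller survives (the
#' earlier one on an exact height tie). On a flat-topped plateau the
#' leftmost scan of the plateau is reported.
#'
#' @param trace an [Electropherogram-class] (or numeric signal vector).
#' @param minHeight minimum apex signal (>= 0).
#' @param minSpacingScans minimum separation between reported peaks, in
#'   scans.
#' @return A data.frame with columns \code{scan} and \code{height}, ordered
#'   by scan.
#' @examples
#' sig <- dnorm(1:100, 50, 5)
#' tr <- new("Electropherogram", scans = 1:100, signal = sig,
#'           ladderScans = numeric(), ladderSizes = numeric(),
#'           ladderSignal = numeric())
#' detectPeaks(tr, minHeight = 0.01)
#' @export
detectPeaks <- function(trace, minHeight = 0, minSpacingScans = 1L) {
    if (is(trace, "Electropherogram")) {
        scans <- trace@scans
        signal <- trace@signal
    } else {
        signal <- as.numeric(trace)
        scans <- seq_along(signal)
    }
    if (minHeight < 0) stop("minHeight must be >= 0")
    n <- length(signal)
    if (n < 3L) stop("trace must contain at least 3 samples")

    # local maximum: rises above the previous distinct value and is not
    # exceeded before the next distinct value (plateaus collapse to their
    # leftmost scan)
    cand <- integer()
    i <- 2L
    while (i <= n - 1L) {
        if (signal[i] > signal[i - 1L]) {
            j <- i
            while (j < n && signal[j + 1L] == signal[j]) j <- j + 1L
            if (j == n || signal[j + 1L] < signal[j]) cand <- c(cand, i)
            i <- j + 1L
        } else {
            i <- i + 1L
        }
    }
    cand <- cand[signal[cand] >= minHeight]
    if (!length(cand))
        return(data.frame(scan = integer(), height = numeric()))
    # spacing: a candidate is suppressed by any taller candidate closer than
    # minSpacingScans (earlier scan wins an exact height tie)
    keep <- vapply(seq_along(cand), function(k) {
        p <- cand[k]
        rival <- cand[abs(scans[cand] - scans[p]) < minSpacingScans]
        !any(signal[rival] > signal[p] |
                 (signal[rival] == signal[p] & rival < p))
    }, logical(1))
    kept <- cand[keep]
    data.frame(scan = scans[kept], height = signal[kept])
}

#' Convert detected peak scans to fragment sizes against a ladder
#'
#' Piecewise-linear interpolation of bp size from scan position through the
#' (ladder scan, ladder size) points. Peaks outside the ladder span cannot
#' be sized and are excluded with a warning reporting the count.
#'
#' @param peaks data.frame with columns \code{scan}, \code{height} (as
#'   returned by [detectPeaks()]).
#' @param ladderScans scan positions of >= 2 ladder peaks, increasing.
#' @param ladderSizes known bp sizes, parallel to \code{ladderScans}.
#' @return A data.frame with columns \code{scan}, \code{height},
#'   \code{size_bp}, containing only in-span peaks.
#' @examples
#' sizeCall(data.frame(scan = 150, height = 10), c(100, 200), c(100, 200))
#' @export
sizeCall <- function(peaks, ladderScans, ladderSizes) {
    if (length(ladderScans) < 2L)
        stop("at least 2 ladder points are required for sizing")
    if (length(ladderScans) != length(ladderSizes))
        stop("ladderScans and ladderSizes must have equal length")
    o <- order(ladderScans)
    ladderScans <- ladderScans[o]
    ladderSizes <- ladderSizes[o]
    inSpan <- peaks$scan >= ladderScans[1L] &
        peaks$scan <= ladderScans[length(ladderScans)]
    if (any(!inSpan))
        warning(sum(!inSpan), " peak(s) outside the ladder span excluded")
    kept <- peaks[inSpan, , drop = FALSE]
    kept$size_bp <- stats::approx(ladderScans, ladderSizes,
                                  xout = kept$scan, ties = "ordered")$y
    rownames(kept) <- NULL
    kept
}

#' Call ladder peaks from a raw ladder channel
#'
#' Detects the tallest \code{length(ladderSizes)} peaks in the ladder-channel
#' signal and pairs them, in scan order, with the known ladder sizes.
#'
#' @param trace an [Electropherogram-class] carrying \code{ladderSignal}.
#' @param ladderSizes known bp sizes of the standard (defaults to the sizes
#'   stored in the trace).
#' @param minSpacingScans minimum spacing between ladder peaks.
#' @return The trace with \code{ladderScans}/\code{ladderSizes} replaced by
#'   the called values.
#' @export
callLadder <- function(trace, ladderSizes = trace@ladderSizes,
                       minSpacingScans = 5L) {
    stopifnot(is(trace, "Electropherogram"))
    if (!length(trace@ladderSignal))
        stop("trace has no ladder channel to call")
    pk <- detectPeaks(new("Electropherogram", scans = trace@scans,
                          signal = trace@ladderSignal,
                          ladderScans = numeric(), ladderSizes = numeric(),
                          ladderSignal = numeric()),
                      minHeight = 0, minSpacingScans = minSpacingScans)
    if (nrow(pk) < length(ladderSizes))
        stop("found ", nrow(pk), " ladder peaks but expected ",
             length(ladderSizes))
    top <- pk[order(-pk$height)[seq_along(ladderSizes)], ]
    top <- top[order(top$scan), ]
    initialize(trace, ladderScans = as.numeric(top$scan),
               ladderSizes = as.numeric(sort(ladderSizes)))
}
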
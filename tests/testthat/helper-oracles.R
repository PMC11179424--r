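# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops, recomputed from first principles.

# straight-line recomputation of the per-sample summary chain
oracleSummarize <- function(sizes, heights, interceptBp, bpPerRepeat,
                            thresholdFrac, reference = NA) {
    reps <- as.integer(round((sizes - interceptBp) / bpPerRepeat))
    ur <- sort(unique(reps))
    h <- numeric(length(ur))
    for (i in seq_along(ur)) {
        acc <- 0
        for (j in seq_along(reps))
            if (reps[j] == ur[i]) acc <- acc + heights[j]
        h[i] <- acc
    }
    keep <- h >= thresholdFrac * max(h)
    ur <- ur[keep]
    h <- h[keep]
    m <- h / sum(h)
    modal <- ur[which(m == max(m))][1L]
    ref <- if (is.na(reference)) modal else as.integer(reference)
    idx <- 0
    for (i in seq_along(ur)) idx <- idx + m[i] * (ur[i] - ref)
    list(modal = modal, index = idx, n = length(ur), ref = ref)
}

# all-windows maxima scan: candidate local maxima (plateau-left), then a
# full pairwise suppression pass
oraclePeaks <- function(signal, minHeight = 0, minSpacing = 1L) {
    n <- length(signal)
    cand <- integer()
    for (i in 2:(n - 1L)) {
        if (!(signal[i] > signal[i - 1L])) next
        k <- i
        while (k < n && signal[k + 1L] == signal[k]) k <- k + 1L
        if (k == n || signal[k + 1L] < signal[k]) cand <- c(cand, i)
    }
    cand <- cand[signal[cand] >= minHeight]
    keep <- integer()
    for (p in cand) {
        beaten <- FALSE
        for (q in cand) {
            if (q == p) next
            if (abs(q - p) < minSpacing &&
                (signal[q] > signal[p] ||
                     (signal[q] == signal[p] && q < p)))
                beaten <- TRUE
        }
        if (!beaten) keep <- c(keep, p)
    }
    keep
}

# random peak table on a known linear size map; repeats stay well positive
randomPeakCase <- function() {
    n <- sample(1:12, 1)
    baseRep <- sample(50:150, 1)
    reps <- sort(sample(baseRep + (-8:8), n))
    slope <- 2.724117
    intercept <- runif(1, 50, 120)
    sizes <- intercept + reps * slope + runif(n, -0.3, 0.3)
    list(sizes = sizes,
         heights = runif(n, 0.5, 1000),
         intercept = intercept, slope = slope,
         threshold = sample(c(0, 0.05, 0.2, 0.5, 0.9), 1),
         reference = if (runif(1) < 0.5) NA else sample(reps, 1))
}

# build an Electropherogram from a bare signal vector
traceFromSignal <- function(signal) {
    new("Electropherogram", scans = seq_along(signal),
        signal = as.numeric(signal), ladderScans = numeric(),
        ladderSizes = numeric(), ladderSignal = numeric())
}
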
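test_that("the linear size-to-repeat map round-trips and rounds correctly", {
    map <- SizeToRepeatMap(interceptBp = 10)
    expect_identical(sizeToRepeat(10, map), 0L)
    expect_identical(sizeToRepeat(10 + 125 * 2.724117, map), 125L)
    expect_identical(sizeToRepeat(10 + 125.4 * 2.724117, map), 125L)
    expect_identical(sizeToRepeat(repeatToBp(0:200, map), map), 0:200)
    expect_error(sizeToRepeat(1, SizeToRepeatMap(interceptBp = 100)),
                 "calibration error")
})

test_that("intercept calibration anchors the modal peak to the known repeat", {
    pt <- PeakTable("cal", c(337.8, 340.51, 343.2), c(400, 1000, 300))
    map <- calibrateIntercept(pt, 125)
    expect_equal(map@interceptBp, 340.51 - 125 * 2.724117,
                 tolerance = 1e-12)
    expect_lt(abs(map@interceptBp - (-0.0046)), 1e-3)
    expect_identical(sizeToRepeat(340.51, map), 125L)

    single <- PeakTable("s", 500, 10)
    m2 <- calibrateIntercept(single, 80)
    expect_identical(sizeToRepeat(500, m2), 80L)

    expect_error(calibrateIntercept(PeakTable("e", numeric(), numeric()),
                                    125),
                 "empty")
    tie <- PeakTable("t", c(300, 310), c(5, 5))
    expect_error(calibrateIntercept(tie, 100), "modal tie")
})

test_that("modal-height threshold is inclusive and keeps the modal peak", {
    pt <- PeakTable("s", c(100, 103, 106), c(1000, 210, 199))
    expect_equal(peakHeights(filterPeaks(pt, 0.20)), c(1000, 210))
    expect_identical(length(peakSizes(filterPeaks(pt, 0))), 3L)

    boundary <- PeakTable("b", c(100, 103), c(500, 100))
    expect_identical(length(peakSizes(filterPeaks(boundary, 0.20))), 2L)
    expect_error(filterPeaks(pt, 1), "thresholdFrac")
})

test_that("the retained set shrinks weakly as the threshold rises", {
    set.seed(17)
    for (i in 1:40) {
        case <- randomPeakCase()
        pt <- PeakTable("p", case$sizes, case$heights)
        thresholds <- sort(runif(4, 0, 0.99))
        ns <- vapply(thresholds,
                     function(f) length(peakSizes(filterPeaks(pt, f))),
                     integer(1))
        expect_true(all(diff(ns) <= 0))
        expect_gte(min(ns), 1L)
    }
})

test_that("modal repeat breaks exact ties toward the smaller repeat", {
    d <- new("RepeatDistribution", repeats = c(100L, 101L),
             masses = c(0.7, 0.3))
    expect_identical(modalRepeat(d), 100L)
    tie <- new("RepeatDistribution", repeats = c(100L, 101L),
               masses = c(0.5, 0.5))
    expect_identical(modalRepeat(tie), 100L)
    one <- new("RepeatDistribution", repeats = 77L, masses = 1)
    expect_identical(modalRepeat(one), 77L)
})

test_that("instability index reproduces the hand-computed worked examples", {
    d <- new("RepeatDistribution", repeats = c(98L, 100L, 101L),
             masses = c(0.25, 0.50, 0.25))
    expect_equal(instabilityIndex(d, 100), -0.25, tolerance = 1e-12)
    expect_equal(instabilityIndex(d, 98), 1.75, tolerance = 1e-12)
    single <- new("RepeatDistribution", repeats = 100L, masses = 1)
    expect_identical(instabilityIndex(single, 100), 0)
})

test_that("index is scale-invariant in heights and shifts with the reference", {
    set.seed(23)
    for (i in 1:20) {
        case <- randomPeakCase()
        map <- SizeToRepeatMap(interceptBp = case$intercept)
        pt1 <- PeakTable("a", case$sizes, case$heights)
        pt2 <- PeakTable("a", case$sizes, case$heights * runif(1, 0.01, 50))
        cfg <- AnalysisConfig(thresholdFrac = case$threshold)
        r1 <- summarizeSample(pt1, map, cfg, referenceRepeat = 100)
        r2 <- summarizeSample(pt2, map, cfg, referenceRepeat = 100)
        expect_equal(r1@instabilityIndex, r2@instabilityIndex,
                     tolerance = 1e-9)
        # shift property: II(ref - k) = II(ref) + k
        k <- sample(1:10, 1)
        r3 <- summarizeSample(pt1, map, cfg, referenceRepeat = 100 - k)
        expect_equal(r3@instabilityIndex, r1@instabilityIndex + k,
                     tolerance = 1e-9)
    }
})

test_that("summarizeSample merges peaks that round to the same repeat", {
    map <- SizeToRepeatMap(interceptBp = 0)
    # two peaks 0.3 bp apart both round to repeat 100
    sizes <- c(100 * 2.724117 - 0.15, 100 * 2.724117 + 0.15,
               103 * 2.724117)
    pt <- PeakTable("m", sizes, c(300, 300, 900))
    r <- summarizeSample(pt, map, AnalysisConfig(thresholdFrac = 0),
                         referenceRepeat = 103)
    expect_identical(r@nPeaksRetained, 2L)
    expect_equal(r@instabilityIndex, (600 / 1500) * (100 - 103),
                 tolerance = 1e-12)
})

test_that("a stuttered single allele summarizes to the -4/7 worked index", {
    map <- SizeToRepeatMap(interceptBp = 50)
    pop <- new("AllelePopulation", repeatLengths = rep(100L, 10),
               timeDays = 0)
    d <- applyStutter(pop, 0.5, 2L)
    pt <- PeakTable("s", repeatToBp(repeats(d), map), masses(d) * 10000)
    r <- summarizeSample(pt, map, AnalysisConfig(thresholdFrac = 0),
                         referenceRepeat = 100)
    expect_equal(r@instabilityIndex, -4 / 7, tolerance = 1e-12)
    expect_identical(r@modalRepeat, 100L)
})

test_that("summarizeSample equals the brute-force oracle on random tables", {
    set.seed(1234)
    for (i in 1:200) {
        case <- randomPeakCase()
        map <- SizeToRepeatMap(interceptBp = case$intercept)
        pt <- PeakTable("r", case$sizes, case$heights)
        got <- summarizeSample(pt, map,
                               AnalysisConfig(thresholdFrac = case$threshold),
                               referenceRepeat = case$reference)
        want <- oracleSummarize(case$sizes, case$heights, case$intercept,
                                case$slope, case$threshold, case$reference)
        expect_identical(got@modalRepeat, want$modal)
        expect_identical(got@nPeaksRetained, want$n)
        expect_lt(abs(got@instabilityIndex - want$index), 1e-9)
    }
})

test_that("simulated day-80 control cultures expand relative to baseline", {
    cfg <- SimConfig(nAlleles = 4000, gainRate = 0.0625, seed = 3)
    pops <- simulatePopulation(cfg, c(0, 80))
    map <- SizeToRepeatMap(interceptBp = 87.5)
    mk <- function(pop, id) {
        d <- applyStutter(pop, 0.15, 5L)
        PeakTable(id, repeatToBp(repeats(d), map), masses(d) * 1e4)
    }
    cfgA <- AnalysisConfig(referenceRepeat = 125L)
    r0 <- summarizeSample(mk(pops[[1]], "d0"), map, cfgA)
    r80 <- summarizeSample(mk(pops[[2]], "d80"), map, cfgA)
    expect_gt(r80@modalRepeat - r0@modalRepeat, 0)
    expect_gt(r80@instabilityIndex, r0@instabilityIndex)
})
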
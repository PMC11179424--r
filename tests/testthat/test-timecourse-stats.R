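# small builders for design data -------------------------------------------

makeSheet <- function(conditions, nRep, times, control = conditions[1],
                      timeUnit = "days") {
    rows <- expand.grid(condition = conditions,
                        replicate = paste0("r", seq_len(nRep)),
                        time = times, stringsAsFactors = FALSE)
    rows$sample_id <- sprintf("%s_%s_t%g", rows$condition, rows$replicate,
                              rows$time)
    rows$time_unit <- timeUnit
    rows$is_control <- rows$condition == control
    rows$is_baseline <- rows$time == times[1]
    rows
}

linearResults <- function(sheet, slopes, noiseSd = 0, baseIndex = 0) {
    s <- slopes[sheet$condition]
    data.frame(sample_id = sheet$sample_id,
               modal_repeat = 125L,
               instability_index = baseIndex + s * sheet$time +
                   stats::rnorm(nrow(sheet), 0, noiseSd),
               stringsAsFactors = FALSE)
}

test_that("baseline-relative deltas zero the baseline and subtract it elsewhere", {
    sheet <- makeSheet("NTC", 1, c(0, 20))
    res <- data.frame(sample_id = sheet$sample_id, modal_repeat = c(125L, 127L),
                      instability_index = c(2.0, 2.5))
    df <- baselineRelative(res, sheet)
    expect_equal(df$delta_instability_index[df$time == 0], 0)
    expect_equal(df$delta_instability_index[df$time == 20], 0.5)
    expect_equal(df$delta_modal_repeat[df$time == 20], 2)

    const <- data.frame(sample_id = sheet$sample_id, modal_repeat = 125L,
                        instability_index = 3.3)
    expect_true(all(baselineRelative(const, sheet)$delta_instability_index == 0))
})

test_that("a replicate without a baseline row is reported by name", {
    sheet <- makeSheet("NTC", 2, c(0, 20, 40))
    sheet$is_baseline[sheet$replicate == "r2"] <- FALSE
    res <- linearResults(sheet, c(NTC = 0.1))
    expect_error(baselineRelative(res, sheet), "NTC/r2")
})

test_that("noiseless linear data recovers the slope exactly with zero SE", {
    sheet <- makeSheet(c("NTC", "KD"), 3, seq(0, 80, 20))
    res <- linearResults(sheet, c(NTC = 0.025, KD = 0.010))
    rates <- fitConditionRates(res, sheet, metric = "instability_index")
    ntc <- rates[rates$condition == "NTC", ]
    kd <- rates[rates$condition == "KD", ]
    expect_equal(ntc$slope, 0.025, tolerance = 1e-12)
    expect_equal(ntc$se, 0)
    expect_equal(ntc$percent_slowing, 0)
    expect_equal(kd$slope, 0.010, tolerance = 1e-12)
    expect_equal(kd$percent_slowing, 60, tolerance = 1e-9)
    expect_identical(unique(rates$time_unit), "days")
})

test_that("percent slowing is undefined when the control slope is not positive", {
    sheet <- makeSheet(c("NTC", "KD"), 2, c(0, 10, 20))
    res <- linearResults(sheet, c(NTC = 0, KD = 0.01))
    rates <- fitConditionRates(res, sheet, metric = "instability_index")
    expect_true(is.na(rates$percent_slowing[rates$condition == "KD"]))
})

test_that("replicates with fewer than 3 timepoints are excluded with warning", {
    sheet <- makeSheet("NTC", 2, c(0, 20, 40))
    sheet <- sheet[!(sheet$replicate == "r2" & sheet$time == 40), ]
    res <- linearResults(sheet, c(NTC = 0.02))
    expect_warning(slopes <- replicateSlopes(res, sheet,
                                             "instability_index"),
                   "fewer than 3 timepoints")
    expect_identical(nrow(slopes), 1L)

    # every replicate too short -> condition-level error
    short <- makeSheet("NTC", 2, c(0, 20))
    resS <- linearResults(short, c(NTC = 0.02))
    expect_error(suppressWarnings(
        replicateSlopes(resS, short, "instability_index")),
        "no replicate")
})

test_that("the two-stage slope estimator is unbiased on noisy linear data", {
    set.seed(61)
    trueSlope <- 0.025
    times <- seq(0, 80, 20)
    noise <- 0.2 * trueSlope * max(times)   # 20% of total change
    bias <- replicate(200, {
        sheet <- makeSheet("NTC", 4, times)
        res <- linearResults(sheet, c(NTC = trueSlope), noiseSd = noise)
        rates <- fitConditionRates(res, sheet, "instability_index")
        rates$slope[1] - trueSlope
    })
    expect_lt(abs(mean(bias)), 0.05 * trueSlope)
})

test_that("rate estimates are invariant to input row order", {
    set.seed(71)
    sheet <- makeSheet(c("NTC", "KD"), 3, seq(0, 60, 15))
    res <- linearResults(sheet, c(NTC = 0.03, KD = 0.02), noiseSd = 0.1)
    r1 <- fitConditionRates(res, sheet, "instability_index")
    perm <- sample(nrow(sheet))
    r2 <- fitConditionRates(res[sample(nrow(res)), ], sheet[perm, ],
                            "instability_index")
    r2 <- r2[match(r1$condition, r2$condition), ]
    expect_equal(r1$slope, r2$slope, tolerance = 1e-12)
    expect_equal(r1$percent_slowing, r2$percent_slowing, tolerance = 1e-12)
})

test_that("identical replicate slopes give zero difference and p = 1", {
    slopes <- data.frame(condition = rep(c("A", "B"), each = 3),
                         replicate = rep(1:3, 2),
                         is_control = rep(c(TRUE, FALSE), each = 3),
                         slope = rep(0.02, 6))
    out <- compareConditions(slopes)
    expect_equal(out$difference, 0)
    expect_equal(out$p_adj, 1)
    expect_false(out$significant)
})

test_that("with two conditions Tukey equals the pooled-variance t-test", {
    set.seed(81)
    for (i in 1:10) {
        a <- rnorm(4, 0.02, 0.004)
        b <- rnorm(4, 0.012, 0.004)
        slopes <- data.frame(condition = rep(c("A", "B"), each = 4),
                             replicate = rep(1:4, 2),
                             is_control = rep(c(TRUE, FALSE), each = 4),
                             slope = c(a, b))
        out <- compareConditions(slopes)
        want <- t.test(a, b, var.equal = TRUE)$p.value
        expect_equal(out$p_adj, want, tolerance = 1e-4)
    }
})

test_that("Tukey-adjusted p is never below the unadjusted (LSD) p", {
    set.seed(91)
    for (i in 1:10) {
        k <- sample(3:5, 1)
        slopes <- data.frame(
            condition = rep(LETTERS[1:k], each = 4),
            replicate = rep(1:4, k),
            is_control = rep(c(TRUE, rep(FALSE, k - 1)), each = 4),
            slope = rnorm(4 * k, 0.02, 0.005))
        out <- compareConditions(slopes)
        fit <- aov(slope ~ condition, data = slopes)
        mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
        dfres <- summary(fit)[[1]]["Residuals", "Df"]
        means <- tapply(slopes$slope, slopes$condition, mean)
        for (j in seq_len(nrow(out))) {
            pair <- strsplit(out$pair[j], "-")[[1]]
            tstat <- abs(means[pair[1]] - means[pair[2]]) /
                sqrt(mse * (1 / 4 + 1 / 4))
            lsd <- 2 * pt(tstat, dfres, lower.tail = FALSE)
            expect_gte(out$p_adj[j] + 1e-12, lsd)
        }
    }
})

test_that("a strong simulated effect is flagged significant", {
    set.seed(101)
    sheet <- makeSheet(c("NTC", "KD"), 4, seq(0, 80, 20))
    res <- linearResults(sheet, c(NTC = 0.025, KD = 0.025 * 0.35),
                         noiseSd = 0.05)
    rates <- fitConditionRates(res, sheet, "instability_index")
    out <- compareConditions(attr(rates, "replicate_slopes"))
    expect_true(out$significant)
    expect_error(compareConditions(
        data.frame(condition = "A", replicate = 1:3, is_control = TRUE,
                   slope = rnorm(3))),
        "2 conditions")
})

test_that("the mixed-model backend agrees with two-stage on balanced data", {
    set.seed(111)
    sheet <- makeSheet(c("NTC", "KD"), 4, seq(0, 80, 20))
    res <- linearResults(sheet, c(NTC = 0.025, KD = 0.010), noiseSd = 0.08)
    two <- fitConditionRates(res, sheet, "instability_index",
                             method = "two-stage")
    mix <- fitConditionRates(res, sheet, "instability_index",
                             method = "mixed")
    mix <- mix[match(two$condition, mix$condition), ]
    expect_equal(mix$slope, two$slope, tolerance = 0.02)
})

test_that("sample sheets are validated", {
    sheet <- makeSheet(c("NTC", "KD"), 2, c(0, 10, 20))
    expect_silent(validateSampleSheet(sheet))
    noCtrl <- sheet
    noCtrl$is_control <- FALSE
    expect_error(validateSampleSheet(noCtrl), "control")
    expect_error(validateSampleSheet(sheet[0, ]), "empty")
    expect_error(validateSampleSheet(sheet[, -1]), "missing column")
    dup <- sheet
    dup$sample_id[2] <- dup$sample_id[1]
    expect_error(validateSampleSheet(dup), "duplicate")
})
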
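#' Read and validate a sample sheet
#'
#' The sample sheet maps each fragment-analysis sample to its experimental
#' design cell: condition (guide/target label), replicate culture,
#' timepoint, time unit, and whether the condition is the non-targeting
#' control and the row the replicate's baseline.
#'
#' @param path CSV with columns \code{sample_id}, \code{condition},
#'   \code{replicate}, \code{time}, \code{time_unit}, \code{is_control},
#'   \code{is_baseline}.
#' @return A validated data.frame.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path)) stop("sample sheet not found: ", path)
    sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateSampleSheet(sheet)
}

#' @rdname readSampleSheet
#' @param sheet a sample-sheet data.frame.
#' @export
validateSampleSheet <- function(sheet) {
    req <- c("sample_id", "condition", "replicate", "time", "is_control",
             "is_baseline")
    miss <- setdiff(req, names(sheet))
    if (length(miss))
        stop("sample sheet is missing column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(sheet) == 0L) stop("sample sheet is empty")
    if (!"time_unit" %in% names(sheet)) sheet$time_unit <- "days"
    sheet$is_control <- as.logical(sheet$is_control)
    sheet$is_baseline <- as.logical(sheet$is_baseline)
    ctrl <- unique(sheet$condition[sheet$is_control])
    if (length(ctrl) != 1L)
        stop("exactly one condition must be flagged as control (found ",
             length(ctrl), ")")
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id in sample sheet")
    sheet
}

#' Express metrics relative to each replicate's baseline
#'
#' Joins per-sample instability results to the sample sheet and, within
#' each (condition, replicate) culture, subtracts the metric values of the
#' designated baseline timepoint. Baseline rows therefore become exactly 0,
#' and \code{time_delta} counts time since baseline.
#'
#' @param results data.frame of per-sample results (from
#'   [summarizeSamples()]), keyed by \code{sample_id}.
#' @param sheet a validated sample sheet.
#' @param metrics metric columns to difference.
#' @return The joined data.frame with added \code{time_delta} and
#'   \code{delta_<metric>} columns.
#' @export
baselineRelative <- function(results, sheet,
                             metrics = c("modal_repeat",
                                         "instability_index")) {
    sheet <- validateSampleSheet(sheet)
    miss <- setdiff(sheet$sample_id, results$sample_id)
    if (length(miss))
        stop("no result for sample(s): ", paste(miss, collapse = ", "))
    df <- merge(sheet, results, by = "sample_id", sort = FALSE)
    metrics <- intersect(metrics, names(df))
    df$time_delta <- NA_real_
    for (m in metrics) df[[paste0("delta_", m)]] <- NA_real_
    df$.rep <- paste(df$condition, df$replicate, sep = "\r")
    for (rep in unique(df$.rep)) {
        i <- df$.rep == rep
        b <- i & df$is_baseline
        if (!any(b))
            stop("replicate '", sub("\r", "/", rep),
                 "' has no baseline timepoint")
        if (sum(b) > 1L)
            stop("replicate '", sub("\r", "/", rep),
                 "' has multiple baseline rows")
        df$time_delta[i] <- df$time[i] - df$time[b]
        for (m in metrics)
            df[[paste0("delta_", m)]][i] <- df[[m]][i] - df[[m]][b]
    }
    df$.rep <- NULL
    df[order(df$condition, df$replicate, df$time), , drop = FALSE]
}

#' Per-replicate expansion slopes
#'
#' For each replicate culture, the ordinary-least-squares slope of the
#' baseline-relative metric against time since baseline, with the intercept
#' fixed at 0 (the regression is through the replicate's own baseline, which
#' is 0 by construction). Replicates with fewer than 3 timepoints are
#' excluded with a warning.
#'
#' @param results per-sample results data.frame.
#' @param sheet sample sheet.
#' @param metric \code{"instability_index"} or \code{"modal_repeat"}.
#' @return data.frame with columns \code{condition}, \code{replicate},
#'   \code{is_control}, \code{slope}, \code{n_timepoints}.
#' @export
replicateSlopes <- function(results, sheet,
                            metric = c("instability_index",
                                       "modal_repeat")) {
    metric <- match.arg(metric)
    df <- baselineRelative(results, sheet, metrics = metric)
    y <- df[[paste0("delta_", metric)]]
    key <- interaction(df$condition, df$replicate, drop = TRUE)
    rows <- lapply(levels(key), function(k) {
        i <- key == k
        t <- df$time_delta[i]
        if (length(unique(t)) < 3L) {
            warning("replicate '", df$condition[i][1L], "/",
                    df$replicate[i][1L],
                    "' has fewer than 3 timepoints; excluded from rate fit")
            return(NULL)
        }
        data.frame(condition = df$condition[i][1L],
                   replicate = df$replicate[i][1L],
                   is_control = df$is_control[i][1L],
                   slope = sum(t * y[i]) / sum(t^2),
                   n_timepoints = length(unique(t)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) == 0L)
        stop("no replicate has enough timepoints for rate fitting")
    rownames(out) <- NULL
    out
}

#' Per-condition expansion rates and percent slowing
#'
#' Two-stage estimator: the condition slope is the mean of its replicate
#' slopes (see [replicateSlopes()]), its standard error SD/sqrt(n), and the
#' 95% CI uses the t distribution on n - 1 df. Percent slowing of each
#' condition relative to the control is \code{100 * (1 - slope /
#' control_slope)}, with a delta-method CI; it is undefined (NA) when the
#' control slope is not positive. For balanced designs the two-stage
#' condition means coincide with the fixed-effect slopes of a
#' random-slope linear mixed model, available as \code{method = "mixed"}
#' (fit per condition with \pkg{lme4}).
#'
#' @param results per-sample results data.frame (from
#'   [summarizeSamples()]).
#' @param sheet sample sheet data.frame or CSV path.
#' @param metric response metric.
#' @param method \code{"two-stage"} (primary) or \code{"mixed"}.
#' @return data.frame with one row per condition: \code{condition},
#'   \code{metric}, \code{n_replicates}, \code{slope}, \code{se},
#'   \code{ci_lo}, \code{ci_hi}, \code{percent_slowing},
#'   \code{slowing_ci_lo}, \code{slowing_ci_hi}, \code{time_unit}. The
#'   replicate-slope table is attached as
#'   \code{attr(, "replicate_slopes")}.
#' @export
fitConditionRates <- function(results, sheet,
                              metric = c("instability_index",
                                         "modal_repeat"),
                              method = c("two-stage", "mixed")) {
    metric <- match.arg(metric)
    method <- match.arg(method)
    if (is.character(sheet)) sheet <- readSampleSheet(sheet)
    sheet <- validateSampleSheet(sheet)
    slopes <- replicateSlopes(results, sheet, metric)
    timeUnit <- unique(as.character(sheet$time_unit))
    if (length(timeUnit) != 1L)
        stop("mixed time units in one sample sheet are not supported")

    conds <- unique(slopes$condition)
    est <- lapply(conds, function(cond) {
        s <- slopes$slope[slopes$condition == cond]
        n <- length(s)
        if (method == "mixed") {
            fit <- mixedConditionSlope(results, sheet, metric, cond)
            slope <- fit$slope
            se <- fit$se
        } else {
            slope <- mean(s)
            se <- if (n > 1L) stats::sd(s) / sqrt(n) else NA_real_
        }
        half <- if (n > 1L) stats::qt(0.975, n - 1L) * se else NA_real_
        data.frame(condition = cond, metric = metric, n_replicates = n,
                   slope = slope, se = se,
                   ci_lo = slope - half, ci_hi = slope + half,
                   stringsAsFactors = FALSE)
    })
    est <- do.call(rbind, est)

    ctrlCond <- unique(slopes$condition[slopes$is_control])
    ctrl <- est[est$condition == ctrlCond, ]
    est$percent_slowing <- NA_real_
    est$slowing_ci_lo <- NA_real_
    est$slowing_ci_hi <- NA_real_
    if (nrow(ctrl) == 1L && is.finite(ctrl$slope) && ctrl$slope > 0) {
        for (i in seq_len(nrow(est))) {
            if (est$condition[i] == ctrlCond) {
                est$percent_slowing[i] <- 0
                next
            }
            r <- est$slope[i] / ctrl$slope
            est$percent_slowing[i] <- 100 * (1 - r)
            if (is.finite(est$se[i]) && is.finite(ctrl$se)) {
                dfR <- est$n_replicates[i] + ctrl$n_replicates - 2L
                ci <- fiellerRatioCI(est$slope[i], ctrl$slope,
                                     est$se[i], ctrl$se, dfR)
                est$slowing_ci_lo[i] <- 100 * (1 - ci[2L])
                est$slowing_ci_hi[i] <- 100 * (1 - ci[1L])
            }
        }
    }
    est$time_unit <- timeUnit
    rownames(est) <- NULL
    attr(est, "replicate_slopes") <- slopes
    attr(est, "control_condition") <- ctrlCond
    est
}

# Fieller 95% CI for the ratio a/b of two independent estimates; exact under
# normality and well-behaved at small n, unlike the delta method. Returns
# c(NA, NA) when the denominator is not significantly nonzero (g >= 1).
fiellerRatioCI <- function(a, b, seA, seB, df) {
    tt <- stats::qt(0.975, df)
    g <- tt^2 * seB^2 / b^2
    if (!is.finite(g) || g >= 1) return(c(NA_real_, NA_real_))
    r <- a / b
    disc <- seA^2 + r^2 * seB^2 - g * seA^2
    half <- (tt / abs(b)) * sqrt(disc)
    c((r - half) / (1 - g), (r + half) / (1 - g))
}

# random-slope mixed model for one condition: delta ~ 0 + time with a
# per-replicate random slope
mixedConditionSlope <- function(results, sheet, metric, condition) {
    df <- baselineRelative(results, sheet, metrics = metric)
    df <- df[df$condition == condition, , drop = FALSE]
    df$y <- df[[paste0("delta_", metric)]]
    fit <- suppressMessages(lme4::lmer(
        y ~ 0 + time_delta + (0 + time_delta | replicate), data = df,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
    list(slope = unname(lme4::fixef(fit)[["time_delta"]]),
         se = sqrt(diag(as.matrix(stats::vcov(fit))))[1L])
}

#' Pairwise condition contrasts by Tukey's method
#'
#' Tukey honest-significant-difference comparison of per-replicate slopes
#' across conditions (one-way layout on the replicate slopes, studentized
#' range adjustment via [stats::TukeyHSD()]). If the replicate slopes are
#' numerically identical within and across a pair (zero residual variance),
#' the adjusted p for that pair is 1 by convention.
#'
#' @param slopes replicate-slope data.frame (from [replicateSlopes()] or
#'   \code{attr(rates, "replicate_slopes")}).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns \code{pair}, \code{difference},
#'   \code{ci_lo}, \code{ci_hi}, \code{p_adj}, \code{significant}.
#' @export
compareConditions <- function(slopes, alpha = 0.05) {
    if (length(unique(slopes$condition)) < 2L)
        stop("at least 2 conditions are required for contrasts")
    reps <- table(slopes$condition)
    if (any(reps < 2L))
        stop("every condition needs >= 2 replicate slopes (violated by: ",
             paste(names(reps)[reps < 2L], collapse = ", "), ")")
    d <- data.frame(slope = slopes$slope,
                    condition = factor(slopes$condition))
    fit <- stats::aov(slope ~ condition, data = d)
    sigma2 <- sum(stats::residuals(fit)^2)
    tuk <- stats::TukeyHSD(fit)$condition
    out <- data.frame(pair = rownames(tuk),
                      difference = tuk[, "diff"],
                      ci_lo = tuk[, "lwr"], ci_hi = tuk[, "upr"],
                      p_adj = tuk[, "p adj"],
                      stringsAsFactors = FALSE)
    # degenerate case: no residual variance at all
    scale <- max(abs(d$slope), 1)
    if (sigma2 <= (1e-12 * scale)^2)
        out$p_adj <- ifelse(abs(out$difference) <= 1e-12 * scale, 1, 0)
    out$significant <- out$p_adj < alpha
    rownames(out) <- NULL
    out
}
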
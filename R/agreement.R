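#' @include correspondence.R
NULL

#' Paired per-case biomarker series
#'
#' A validated container for reader-vs-model (or reader-vs-reader)
#' comparisons: one reference and one comparison value of the same biomarker
#' per case, in the same units.
#'
#' @param reference,comparison numeric vectors of equal length.
#' @param caseIds optional case identifiers (default `1:n`).
#' @return data.frame of class `PairedSeries` with columns `case`,
#'   `reference`, `comparison`.
#' @export
pairedSeries <- function(reference, comparison, caseIds = seq_along(reference)) {
    if (!is.numeric(reference) || !is.numeric(comparison))
        stop("reference and comparison must be numeric", call. = FALSE)
    if (length(reference) != length(comparison))
        stop("reference and comparison must have equal length", call. = FALSE)
    if (length(reference) < 1L)
        stop("at least one paired case is required", call. = FALSE)
    structure(data.frame(case = caseIds, reference = as.numeric(reference),
                         comparison = as.numeric(comparison)),
              class = c("PairedSeries", "data.frame"))
}

.asPairedSeries <- function(x, ...) {
    if (inherits(x, "PairedSeries")) x else pairedSeries(x, ...)
}

#' Per-case percentage differences (Bland-Altman style)
#'
#' For each case, 100 * (reference - comparison) / mean(reference,
#' comparison). The sign convention follows reader-vs-model reporting: a
#' comparison (model) value larger than the reference yields a negative
#' percentage, i.e. negative bias indicates overestimation by the
#' comparison. Cases where both values are 0 have an undefined denominator
#' and are excluded with a warning.
#'
#' @param series a [pairedSeries()] (or the `reference` vector, with
#'   `comparison` passed through `...`).
#' @param ... passed to [pairedSeries()] when `series` is a bare vector.
#' @return Numeric vector of percentages, named by case id, excluding
#'   both-zero cases.
#' @export
#' @examples
#' percentDifferences(pairedSeries(100, 110))  # -9.52: model overestimates
percentDifferences <- function(series, ...) {
    s <- .asPairedSeries(series, ...)
    denom <- (s$reference + s$comparison) / 2
    bothZero <- s$reference == 0 & s$comparison == 0
    if (any(bothZero)) {
        warning(sprintf("excluding %d case(s) with both values zero: %s",
                        sum(bothZero),
                        paste(s$case[bothZero], collapse = ", ")),
                call. = FALSE)
        s <- s[!bothZero, , drop = FALSE]
        denom <- denom[!bothZero]
    }
    stats::setNames(100 * (s$reference - s$comparison) / denom, s$case)
}

#' Bland-Altman bias and limits of agreement
#'
#' Mean and standard deviation (n - 1 denominator) of the per-case
#' differences — percentage differences ([percentDifferences()]) or
#' absolute differences (reference - comparison) — with 95% limits of
#' agreement at bias +/- 1.96 * SD.
#'
#' @param series a [pairedSeries()].
#' @param mode `"percent"` or `"absolute"`.
#' @return A list with `bias`, `sd`, `loa_lower`, `loa_upper`, `n`, `mode`.
#' @export
#' @examples
#' s <- pairedSeries(c(100, 100), c(110, 90))
#' blandAltman(s, mode = "absolute")  # differences -10, +10
blandAltman <- function(series, mode = c("percent", "absolute")) {
    mode <- match.arg(mode)
    s <- .asPairedSeries(series)
    diffs <- if (mode == "percent") unname(percentDifferences(s))
             else s$reference - s$comparison
    if (length(diffs) < 2L)
        stop("at least two paired cases are required for limits of agreement",
             call. = FALSE)
    bias <- mean(diffs)
    sdv <- stats::sd(diffs)
    list(bias = bias, sd = sdv,
         loa_lower = bias - 1.96 * sdv, loa_upper = bias + 1.96 * sdv,
         n = length(diffs), mode = mode)
}

#' Pearson correlation and ordinary least-squares fit
#'
#' Pearson r with its two-sided p-value (via [stats::cor.test()]) and the
#' OLS regression of the comparison on the reference.
#'
#' @param series a [pairedSeries()] of length >= 3 with non-degenerate
#'   variance in both columns.
#' @return A list with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
correlationAndFit <- function(series) {
    s <- .asPairedSeries(series)
    if (nrow(s) < 3L)
        stop("at least three paired cases are required", call. = FALSE)
    if (stats::sd(s$reference) == 0 || stats::sd(s$comparison) == 0)
        stop("zero variance in reference or comparison series", call. = FALSE)
    ct <- stats::cor.test(s$reference, s$comparison, method = "pearson")
    fit <- stats::lm(comparison ~ reference, data = s)
    list(r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = nrow(s))
}

#' Agreement of predicted eGFR slopes between two biomarker series
#'
#' Maps both sides of a paired biomarker series (TCN counts or CPSA in
#' cm^2) through the affine eGFR-slope predictor, then reports regression/
#' correlation and Bland-Altman agreement of the predicted slopes. Because
#' the predictor is affine, Pearson r equals the r of the raw biomarkers.
#'
#' @param series a [pairedSeries()] of raw biomarker values.
#' @param model an [egfrSlopeModel()] matching the biomarker kind.
#' @param mode Bland-Altman mode, `"absolute"` (default; slope units) or
#'   `"percent"`.
#' @return A list with `slopes` (the mapped `PairedSeries`), `fit`
#'   (see [correlationAndFit()]) and `bland_altman` (see [blandAltman()]).
#' @export
egfrSlopeAgreement <- function(series, model = egfrSlopeModel("TCN"),
                               mode = c("absolute", "percent")) {
    mode <- match.arg(mode)
    s <- .asPairedSeries(series)
    mapped <- pairedSeries(egfrSlope(model, s$reference),
                           egfrSlope(model, s$comparison), caseIds = s$case)
    list(slopes = mapped,
         fit = correlationAndFit(mapped),
         bland_altman = blandAltman(mapped, mode = mode))
}

#' Bland-Altman plot
#'
#' Standard agreement plot: per-case mean of the pair on the x axis,
#' difference (percent or absolute) on the y axis, with the bias and the
#' 95% limits of agreement drawn as horizontal lines.
#'
#' @param series a [pairedSeries()].
#' @param mode `"percent"` or `"absolute"`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return The [blandAltman()] summary, invisibly.
#' @export
plotBlandAltman <- function(series, mode = c("percent", "absolute"), ...) {
    mode <- match.arg(mode)
    s <- .asPairedSeries(series)
    ba <- blandAltman(s, mode = mode)
    means <- (s$reference + s$comparison) / 2
    diffs <- if (mode == "percent") {
        keep <- !(s$reference == 0 & s$comparison == 0)
        means <- means[keep]
        suppressWarnings(unname(percentDifferences(s)))
    } else s$reference - s$comparison
    graphics::plot(means, diffs,
                   xlab = "Mean of pair",
                   ylab = if (mode == "percent") "Difference (%)" else "Difference",
                   ...)
    graphics::abline(h = ba$bias, lty = 1)
    graphics::abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2)
    invisible(ba)
}
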
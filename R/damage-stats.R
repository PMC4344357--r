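#' Welch two-sample t-test
#'
#' Unequal-variance t-test of the hypothesis that two samples share a
#' mean: t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny) with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student-t distribution.
#'
#' @param x,y numeric samples, each of length >= 2; at least one must have
#'   nonzero variance.
#' @return data.frame: \code{statistic}, \code{df}, \code{pValue},
#'   \code{nX}, \code{nY}, \code{meanX}, \code{meanY}.
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 4, 6))
#' @export
welchTTest <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) < 2L || length(y) < 2L)
        stop("each sample needs at least 2 observations")
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0)
        stop("both samples have zero variance; t is undefined")
    nx <- length(x); ny <- length(y)
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(statistic = t, df = df, pValue = p, nX = nx, nY = ny,
               meanX = mean(x), meanY = mean(y))
}

#' Brown-Forsythe (median-centred Levene) test for equal variances
#'
#' One-way F statistic on the absolute deviations of each observation from
#' its group median; robust to non-normality, which suits the right-skewed
#' B_Damage distributions.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return data.frame: \code{statistic} (F), \code{df1}, \code{df2},
#'   \code{pValue}, \code{nTotal}.
#' @examples
#' brownForsytheLevene(list(c(1, 2, 3, 4), c(1, 3, 5, 7)))
#' @export
brownForsytheLevene <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need a list of at least two groups")
    ns <- lengths(groups)
    if (any(ns < 2L)) stop("every group needs at least 2 observations")
    k <- length(groups)
    z <- lapply(groups, function(g) abs(g - stats::median(g)))
    N <- sum(ns)
    zbars <- vapply(z, mean, 0)
    zbar <- sum(unlist(z)) / N
    ssBetween <- sum(ns * (zbars - zbar)^2)
    ssWithin <- sum(vapply(seq_len(k),
                           function(i) sum((z[[i]] - zbars[i])^2), 0))
    df1 <- k - 1L
    df2 <- N - k
    if (ssWithin == 0) {
        stat <- if (ssBetween == 0) 0 else Inf
    } else {
        stat <- (ssBetween / df1) / (ssWithin / df2)
    }
    p <- if (is.infinite(stat)) 0 else stats::pf(stat, df1, df2,
                                                 lower.tail = FALSE)
    data.frame(statistic = stat, df1 = df1, df2 = df2, pValue = p,
               nTotal = N)
}

#' Simple linear regression with slope significance
#'
#' Ordinary least squares of y on x; the slope's two-sided p-value comes
#' from the t distribution with n - 2 degrees of freedom.  When the fit is
#' exact (zero residual variance) the p-value is reported as 0 with
#' \code{degenerate = TRUE}.
#'
#' @param x predictor (nonzero variance), \code{length(x) >= 3}.
#' @param y response, same length.
#' @return data.frame: \code{slope}, \code{intercept}, \code{slopeP},
#'   \code{n}, \code{degenerate}.
#' @examples
#' linearFit(c(0, 1, 2), c(0, 1, 3))  # slope 1.5, intercept -1/6
#' @export
linearFit <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y)) stop("x and y must have equal length")
    n <- length(x)
    if (n < 3L) stop("need at least 3 points for a slope p-value")
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) stop("constant predictor: slope undefined")
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    resid <- y - intercept - slope * x
    rss <- sum(resid^2)
    degenerate <- rss < .Machine$double.eps * max(1, sum(y^2))
    if (degenerate) {
        p <- 0
    } else {
        se <- sqrt(rss / (n - 2) / sxx)
        p <- 2 * stats::pt(-abs(slope / se), n - 2)
    }
    data.frame(slope = slope, intercept = intercept, slopeP = p, n = n,
               degenerate = degenerate)
}

#' Compare an atom group between two structures
#'
#' The low-dose/high-dose comparison protocol: Welch t-tests on the raw
#' B-factors and on B_Damage for the selected atoms, a median-centred
#' Levene test on the two B_Damage samples, and the group sizes, means and
#' medians of both sides.
#'
#' @param low,high [BDamageResult-class] objects computed with identical
#'   radius and bin width.
#' @param selector selector string (see [parseAtomSelector()]) or
#'   predicate function; must match atoms in both results.
#' @return list of class \code{"comparisonReport"} with components
#'   \code{selector}, \code{welchB}, \code{welchBDamage},
#'   \code{leveneBDamage}, \code{summaryLow}, \code{summaryHigh},
#'   \code{deltaMedianBDamage}.
#' @seealso [writeComparisonJSON()], [deltaGroupMedian()]
#' @export
compareModels <- function(low, high, selector = "*") {
    stopifnot(is(low, "BDamageResult"), is(high, "BDamageResult"))
    if (low@radius != high@radius || low@binWidth != high@binWidth)
        stop("results were computed with different parameters")
    pred <- parseAtomSelector(selector)
    mLow <- pred(low@atoms); mHigh <- pred(high@atoms)
    if (!any(mLow) || !any(mHigh))
        stop("selector '", .selectorLabel(selector),
             "' matches no atoms in one of the results")
    bdL <- low@atoms$bdamage[mLow]; bdH <- high@atoms$bdamage[mHigh]
    biL <- low@atoms$bIso[mLow]; biH <- high@atoms$bIso[mHigh]
    rep <- list(selector = .selectorLabel(selector),
                welchB = welchTTest(biL, biH),
                welchBDamage = welchTTest(bdL, bdH),
                leveneBDamage = brownForsytheLevene(list(bdL, bdH)),
                summaryLow = summarizeGroup(low, selector),
                summaryHigh = summarizeGroup(high, selector),
                deltaMedianBDamage = stats::median(bdH) - stats::median(bdL))
    class(rep) <- c("comparisonReport", "list")
    rep
}

#' @export
print.comparisonReport <- function(x, ...) {
    cat("Comparison for selector:", x$selector, "\n")
    cat(sprintf("  n low/high: %d / %d\n", x$summaryLow$n, x$summaryHigh$n))
    cat(sprintf("  B-factor Welch:  t = %8.4f  df = %7.2f  p = %.4g\n",
                x$welchB$statistic, x$welchB$df, x$welchB$pValue))
    cat(sprintf("  B_Damage Welch:  t = %8.4f  df = %7.2f  p = %.4g\n",
                x$welchBDamage$statistic, x$welchBDamage$df,
                x$welchBDamage$pValue))
    cat(sprintf("  B_Damage Levene: F = %8.4f  p = %.4g\n",
                x$leveneBDamage$statistic, x$leveneBDamage$pValue))
    cat(sprintf("  Delta median B_Damage (high - low): %.4f\n",
                x$deltaMedianBDamage))
    invisible(x)
}

#' Serialize a comparison report to JSON
#' @param report a \code{comparisonReport} from [compareModels()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeComparisonJSON <- function(report, path) {
    stopifnot(inherits(report, "comparisonReport"))
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    invisible(path)
}
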
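#' Smoothed density overlay of a damage metric for two structures
#'
#' Presentation-only helper mirroring the usual low-dose/high-dose overlay
#' figures: Gaussian kernel density estimates (reference-rule bandwidth,
#' \code{stats::bw.nrd0}) of B_Damage or raw B for a selected atom group in
#' two results.  Non-normative: no statistic is derived from the smoothing.
#'
#' @param low,high [BDamageResult-class] objects.
#' @param selector selector string or predicate (default all atoms).
#' @param what \code{"bdamage"} (default) or \code{"bIso"}.
#' @param main plot title.
#' @return invisibly, a list with the two \code{stats::density} objects.
#' @export
plotDamageDensity <- function(low, high, selector = "*",
                              what = c("bdamage", "bIso"), main = NULL) {
    what <- match.arg(what)
    pred <- parseAtomSelector(selector)
    vLow <- low@atoms[[what]][pred(low@atoms)]
    vHigh <- high@atoms[[what]][pred(high@atoms)]
    if (!length(vLow) || !length(vHigh))
        stop("selector matches no atoms in one of the results")
    dLow <- stats::density(vLow, kernel = "gaussian")
    dHigh <- stats::density(vHigh, kernel = "gaussian")
    xl <- range(dLow$x, dHigh$x)
    yl <- range(0, dLow$y, dHigh$y)
    graphics::plot(dLow, xlim = xl, ylim = yl, col = "black", lwd = 2,
                   main = if (is.null(main))
                       paste0(what, " (", .selectorLabel(selector), ")")
                   else main,
                   xlab = what)
    graphics::lines(dHigh, col = "firebrick", lwd = 2)
    graphics::legend("topright", legend = c("low dose", "high dose"),
                     col = c("black", "firebrick"), lwd = 2, bty = "n")
    invisible(list(low = dLow, high = dHigh))
}
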
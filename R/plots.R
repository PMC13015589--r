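#' Scatter plot of mice in two-PC space
#'
#' Plots PC1 vs PC2 with genotype glyphs (WT open circles, AS filled
#' triangles), the genotype centroids (crosses) and the segment joining
#' them, annotated with the centroid distance.
#'
#' @param x A \linkS4class{PhenotypeResult}.
#' @param main Plot title.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plotPhenotype <- function(x, main = "Phenotype clustering", ...) {
    sc <- pcScores(x)
    geno <- as.character(x@genotype)
    pch <- ifelse(geno == "AS", 17, 1)
    col <- ifelse(geno == "AS", "firebrick", "black")
    plot(sc[, 1], sc[, 2], pch = pch, col = col,
         xlab = sprintf("PC1 (%.1f%%)", 100 * varianceExplained(x)[1]),
         ylab = sprintf("PC2 (%.1f%%)", 100 * varianceExplained(x)[2]),
         main = main, ...)
    cen <- centroids(x)
    points(cen[, 1], cen[, 2], pch = 4, cex = 2, lwd = 2,
           col = c("black", "firebrick"))
    segments(cen[1, 1], cen[1, 2], cen[2, 1], cen[2, 2], lty = 2)
    legend("topright", bty = "n",
           legend = c("WT", "AS",
                      sprintf("centroid dist %.2f", centroidDistance(x))),
           pch = c(1, 17, NA), col = c("black", "firebrick", NA))
    invisible(x)
}

#' Plot Monte-Carlo power curves
#'
#' One curve per measure (smoothed power vs per-group n) with horizontal
#' reference lines at the target power levels.
#'
#' @param x A \linkS4class{SampleSizeTable}.
#' @param measures Measures to draw (default all).
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, \code{x}.
#' @export
plotPowerCurves <- function(x, measures = NULL, ...) {
    curves <- powerCurves(x)
    if (!is.null(measures)) curves <- curves[measures]
    if (length(curves) == 0) stop("no power curves to plot")
    n <- curves[[1]]$n
    pw <- vapply(curves, function(cv) cv$power_smoothed,
                 numeric(length(n)))
    cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 3")
    graphics::matplot(n, pw, type = "l", lty = 1, lwd = 2,
                      col = cols[seq_along(curves)],
                      xlab = "n per group", ylab = "power",
                      ylim = c(0, 1), ...)
    graphics::abline(h = x@powers, lty = 3, col = "grey50")
    legend("bottomright", legend = names(curves), bty = "n",
           col = cols[seq_along(curves)], lty = 1, lwd = 2, cex = 0.8)
    invisible(x)
}
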
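## Bootstrap power analysis: Cohen's d, Monte-Carlo power curves over a
## per-group sample-size grid, minimum n per target power, and the
## sample-size planning table.

#' Pooled Cohen's d
#'
#' Standardized mean difference \code{(mean(x) - mean(y)) / s_pooled} with
#' \code{s_pooled^2 = ((n1 - 1) s1^2 + (n2 - 1) s2^2) / (n1 + n2 - 2)}.
#' Sign preserved.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return Cohen's d.
#' @examples
#' cohensD(c(0, 2), c(2, 4))  # -sqrt(2)
#' @export
cohensD <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) stop("pooled SD is zero; d is undefined")
    (mean(x) - mean(y)) / sqrt(sp2)
}

#' Closed-form two-sample t-test power
#'
#' Analytic power of the two-sided pooled-variance two-sample t-test for
#' standardized effect d and n per group, via the noncentral t distribution
#' with 2n - 2 degrees of freedom and noncentrality \code{d * sqrt(n / 2)}.
#' Serves as the independent oracle for the Monte-Carlo estimator.
#'
#' @param d Standardized mean difference (vectorized).
#' @param n Per-group sample size (>= 2, vectorized).
#' @param alpha Two-sided significance level.
#' @return Power in [0, 1].
#' @examples
#' analyticPower(0, 10)          # = alpha
#' analyticPower(1.64, 7)        # ~0.83
#' @export
analyticPower <- function(d, n, alpha = 0.05) {
    if (any(n < 2)) stop("n must be >= 2")
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp = ncp) + pt(-tc, df, ncp = ncp)
}

## Vectorized two-sided two-sample t-test p-values over resample columns.
.columnTTestP <- function(x, y, var.equal = TRUE) {
    n1 <- nrow(x); n2 <- nrow(y)
    m1 <- colMeans(x); m2 <- colMeans(y)
    v1 <- (colSums(x * x) - n1 * m1^2) / (n1 - 1)
    v2 <- (colSums(y * y) - n2 * m2^2) / (n2 - 1)
    v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
    if (var.equal) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2, length(m1))
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tstat <- (m1 - m2) / se
    2 * pt(-abs(tstat), df)
}

#' Monte-Carlo bootstrap power of the two-sample t-test
#'
#' Each iteration resamples n values with replacement from each source and
#' runs a two-sided two-sample t-test; the estimate is the fraction of
#' iterations with p < alpha. Resamples where both groups have zero
#' variance give an undefined statistic and are counted non-significant
#' (with a message). Deterministic given a seed.
#'
#' @param source1,source2 Nonempty numeric vectors to resample from (e.g.
#'   observed per-group data, or \code{\link{normalSources}}).
#' @param n Per-group sample size (>= 2).
#' @param iterations Monte-Carlo iterations (default 10000).
#' @param alpha Two-sided significance level.
#' @param seed Optional seed.
#' @param var.equal Pooled-variance Student t (default) or Welch.
#' @return Estimated power in [0, 1].
#' @export
estimatePower <- function(source1, source2, n, iterations = 10000L,
                          alpha = 0.05, seed = NULL, var.equal = TRUE) {
    if (length(source1) == 0 || length(source2) == 0)
        stop("sources must be nonempty")
    if (n < 2) stop("n must be >= 2")
    if (!is.null(seed)) set.seed(seed)
    x <- matrix(sample(source1, n * iterations, replace = TRUE), nrow = n)
    y <- matrix(sample(source2, n * iterations, replace = TRUE), nrow = n)
    p <- .columnTTestP(x, y, var.equal = var.equal)
    bad <- !is.finite(p)
    if (any(bad))
        message(sum(bad), " degenerate resamples (zero variance in both ",
                "groups) counted non-significant")
    sum(p[!bad] < alpha) / iterations
}

#' Standardized normal sources for power simulation
#'
#' Draws two large normal samples and rescales them so the empirical pooled
#' Cohen's d between them equals \code{d} exactly (each source is centered
#' and scaled to unit SD, means 0 and d). Stand-in for unavailable raw
#' per-group data in power replication.
#'
#' @param d Target pooled Cohen's d (source1 - source2 ... source1 has the
#'   higher mean when d > 0).
#' @param size Values per source.
#' @param seed Optional seed.
#' @return List with \code{source1}, \code{source2}.
#' @export
normalSources <- function(d, size = 10000L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    std <- function(v) (v - mean(v)) / sd(v)
    list(source1 = std(rnorm(size)) + d, source2 = std(rnorm(size)))
}

#' Monte-Carlo power curve over a sample-size grid
#'
#' Estimates power at every n on the grid, with an independently derived
#' sub-seed per n so single cells are reproducible in isolation, and
#' appends an isotonic (nondecreasing in n) projection of the raw curve to
#' suppress Monte-Carlo jitter before thresholding.
#'
#' @inheritParams estimatePower
#' @param grid Integer grid of per-group sample sizes (default 4..30).
#' @return data.frame with columns \code{n}, \code{power},
#'   \code{power_smoothed}.
#' @export
powerCurve <- function(source1, source2, grid = 4:30,
                       iterations = 10000L, alpha = 0.05, seed = NULL,
                       var.equal = TRUE) {
    grid <- as.integer(grid)
    if (!is.null(seed)) set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, length(grid))
    pw <- vapply(seq_along(grid), function(i) {
        estimatePower(source1, source2, grid[i], iterations = iterations,
                      alpha = alpha, seed = subSeeds[i],
                      var.equal = var.equal)
    }, numeric(1))
    smoothed <- if (length(grid) > 1) isoreg(grid, pw)$yf else pw
    data.frame(n = grid, power = pw, power_smoothed = smoothed)
}

#' Minimum n reaching a target power
#'
#' Smallest grid n whose (isotonically smoothed) power reaches the target;
#' \code{Inf} when no grid value suffices (rendered as e.g. ">30").
#'
#' @param curve data.frame from \code{\link{powerCurve}}.
#' @param target Target power in (0, 1).
#' @param smoothed Use the isotonic column (default) or the raw estimates.
#' @return Integer n, or \code{Inf} when the requirement exceeds the grid.
#' @export
minNForPower <- function(curve, target, smoothed = TRUE) {
    stopifnot(target > 0, target < 1)
    pw <- if (smoothed && "power_smoothed" %in% names(curve))
        curve$power_smoothed else curve$power
    hit <- which(pw >= target)
    if (length(hit) == 0) Inf else as.numeric(curve$n[min(hit)])
}

#' Build a sample-size planning table
#'
#' For each measure: pooled Cohen's d of its two sources, a Monte-Carlo
#' power curve over the grid, and the minimum per-group n for each target
#' power. Measures may be given as named numeric effect sizes (synthetic
#' standardized normal sources are built via \code{\link{normalSources}})
#' or as named lists \code{list(source1 =, source2 =)} holding real
#' per-group data. Per-measure sub-seeds derive deterministically from the
#' master seed. A measure whose computation fails is reported with a
#' warning and an NA row; the table is still emitted.
#'
#' @param measures Named numeric vector of Cohen's d values, or named list
#'   of \code{list(source1, source2)}.
#' @param powers Target power levels (default 0.8, 0.9, 0.95).
#' @param alpha Significance level.
#' @param iterations Monte-Carlo iterations per grid point.
#' @param grid Per-group sample-size grid.
#' @param seed Master seed.
#' @param sourceSize Size of synthetic sources when \code{measures} is
#'   numeric.
#' @param var.equal Pooled-variance t (default) or Welch.
#' @return A \linkS4class{SampleSizeTable}.
#' @examples
#' tab <- buildSampleSizeTable(c(rotarod_d1 = 1.64), iterations = 500,
#'                             seed = 1)
#' sampleSizes(tab, rendered = TRUE)
#' @export
buildSampleSizeTable <- function(measures, powers = c(0.8, 0.9, 0.95),
                                 alpha = 0.05, iterations = 10000L,
                                 grid = 4:30, seed,
                                 sourceSize = 10000L, var.equal = TRUE) {
    if (missing(seed)) stop("a master seed is required")
    stopifnot(length(measures) > 0, !is.null(names(measures)))
    set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, length(measures))
    rows <- list(); curves <- list()
    for (i in seq_along(measures)) {
        nm <- names(measures)[i]
        res <- tryCatch({
            if (is.numeric(measures[[i]]) && length(measures[[i]]) == 1) {
                src <- normalSources(measures[[i]], size = sourceSize,
                                     seed = subSeeds[i])
            } else {
                src <- measures[[i]]
                stopifnot(all(c("source1", "source2") %in% names(src)))
            }
            d <- cohensD(src$source1, src$source2)
            cv <- powerCurve(src$source1, src$source2, grid = grid,
                             iterations = iterations, alpha = alpha,
                             seed = subSeeds[i], var.equal = var.equal)
            mins <- vapply(powers, function(tp) minNForPower(cv, tp),
                           numeric(1))
            list(d = d, curve = cv, mins = mins)
        }, error = function(e) {
            warning("measure '", nm, "' failed: ", conditionMessage(e))
            NULL
        })
        if (is.null(res)) {
            rows[[nm]] <- c(cohens_d = NA_real_,
                            stats::setNames(rep(NA_real_, length(powers)),
                                            paste0("n_", powers)))
        } else {
            rows[[nm]] <- c(cohens_d = res$d,
                            stats::setNames(res$mins,
                                            paste0("n_", powers)))
            curves[[nm]] <- res$curve
        }
    }
    tab <- data.frame(measure = names(rows),
                      do.call(rbind, rows), row.names = NULL,
                      check.names = FALSE)
    new("SampleSizeTable", table = tab, curves = curves,
        grid = as.integer(grid), alpha = alpha, powers = powers,
        iterations = as.integer(iterations), seed = as.integer(seed))
}

#' Study effect sizes for the sample-size table
#'
#' The achieved genotype effect sizes (pooled Cohen's d magnitudes) of the
#' three operant measures and five battery measures used for sample-size
#' planning: days to acquisition 0.84, accuracy at criteria 0.89,
#' extinction day 1 (normalized) 0.91, rotarod day 1 1.64, rotarod day 5
#' 1.22, open-field distance 0.07, marbles buried 1.62, nest building 1.52.
#'
#' @return Named numeric vector, operant measures first.
#' @export
defaultEffectSizes <- function() {
    c(days_to_criteria = 0.84,
      accuracy_at_criteria = 0.89,
      norm_cued_E1 = 0.91,
      rotarod_d1 = 1.64,
      rotarod_d5 = 1.22,
      of_distance = 0.07,
      marbles_buried = 1.62,
      nest_used_d5 = 1.52)
}
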
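## Multidimensional phenotyping: z-standardization (optionally within sex),
## PCA, k-means genotype clustering, centroid distances, PC1 correlations.

#' Z-standardize a feature table
#'
#' Each measure is z-scored (sample SD, n - 1 denominator). Measures listed
#' in \code{sexSplit} are z-scored within each sex separately, removing sex
#' main effects for tests where a sex difference is observed; all other
#' measures are standardized over all mice.
#'
#' @param raw Numeric matrix or data.frame, mice x measures (rownames =
#'   mouse ids).
#' @param roster Roster data.frame with \code{mouse_id} and \code{sex};
#'   required when \code{sexSplit} is nonempty.
#' @param sexSplit Character vector of measures to standardize within sex.
#' @return Numeric matrix, mice x measures, with per-stratum mean 0 and
#'   SD 1; attribute \code{"sexSplit"} records the split measures.
#' @examples
#' standardizeFeatures(cbind(m = c(1, 2, 3)))
#' @export
standardizeFeatures <- function(raw, roster = NULL,
                                sexSplit = character()) {
    raw <- as.matrix(raw)
    if (!is.numeric(raw)) stop("feature table must be numeric")
    if (any(is.na(raw)))
        stop("feature table has missing cells; drop incomplete mice first")
    if (length(sexSplit) > 0) {
        if (is.null(roster))
            stop("a roster with a 'sex' column is needed for sex-split ",
                 "standardization")
        bad <- setdiff(sexSplit, colnames(raw))
        if (length(bad) > 0)
            stop("sexSplit names not in the feature table: ",
                 paste(bad, collapse = ", "))
        sex <- as.character(roster$sex[match(rownames(raw),
                                             roster$mouse_id)])
        if (any(is.na(sex)))
            stop("feature rows missing from the roster")
    }
    z <- raw
    for (m in colnames(raw)) {
        strata <- if (m %in% sexSplit) split(seq_len(nrow(raw)), sex)
                  else list(all = seq_len(nrow(raw)))
        for (sn in names(strata)) {
            idx <- strata[[sn]]
            if (length(idx) < 2)
                stop("stratum '", sn, "' for measure '", m,
                     "' has fewer than 2 mice")
            s <- sd(raw[idx, m])
            if (!is.finite(s) || s == 0)
                stop("measure '", m, "' has zero variance",
                     if (m %in% sexSplit) paste0(" within sex ", sn))
            z[idx, m] <- (raw[idx, m] - mean(raw[idx, m])) / s
        }
    }
    attr(z, "sexSplit") <- sexSplit
    z
}

#' Auto-detect measures with a sex difference
#'
#' Fits a two-way genotype + sex model per measure and flags measures whose
#' sex main effect is significant at \code{alpha}, mirroring the convention
#' of standardizing male and female data separately for tests where a sex
#' difference was observed.
#'
#' @param raw Mice x measures matrix/data.frame.
#' @param roster Roster with \code{mouse_id}, \code{genotype}, \code{sex}.
#' @param alpha Significance threshold for the sex main effect.
#' @return Character vector of measure names to sex-split.
#' @export
detectSexSplitMeasures <- function(raw, roster, alpha = 0.05) {
    raw <- as.matrix(raw)
    idx <- match(rownames(raw), roster$mouse_id)
    geno <- factor(as.character(roster$genotype[idx]))
    sex <- factor(as.character(roster$sex[idx]))
    hit <- vapply(colnames(raw), function(m) {
        fit <- lm(raw[, m] ~ geno + sex)
        p <- anova(fit)["sex", "Pr(>F)"]
        is.finite(p) && p < alpha
    }, logical(1))
    colnames(raw)[hit]
}

#' Principal component analysis of a standardized feature matrix
#'
#' Covariance PCA of the (already standardized) matrix: components are
#' eigenvectors of the covariance matrix ordered by decreasing variance,
#' scores are the centered data projected onto them. For reproducible
#' loading tables each component's sign is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param fm Mice x measures matrix from \code{\link{standardizeFeatures}}.
#' @param nComponents Components to retain; must not exceed the matrix rank
#'   (nor min(mice - 1, measures)).
#' @return List with \code{scores} (mice x components), \code{loadings}
#'   (measures x components, unit columns) and \code{varianceExplained}
#'   (fractions over all components, length \code{nComponents}).
#' @export
runPCA <- function(fm, nComponents = 2L) {
    fm <- as.matrix(fm)
    pr <- prcomp(fm, center = TRUE, scale. = FALSE)
    rank <- sum(pr$sdev > max(pr$sdev) * 1e-8)
    if (nComponents > min(nrow(fm) - 1L, ncol(fm)) || nComponents > rank)
        stop("nComponents (", nComponents,
             ") exceeds the rank of the feature matrix (", rank, ")")
    keep <- seq_len(nComponents)
    loadings <- pr$rotation[, keep, drop = FALSE]
    scores <- pr$x[, keep, drop = FALSE]
    flip <- vapply(keep, function(j) {
        v <- loadings[, j]
        sign(v[which.max(abs(v))])
    }, numeric(1))
    loadings <- sweep(loadings, 2, flip, `*`)
    scores <- sweep(scores, 2, flip, `*`)
    ve <- pr$sdev^2 / sum(pr$sdev^2)
    list(scores = scores, loadings = loadings,
         varianceExplained = ve[keep])
}

.bestPermutationAccuracy <- function(labels, truth) {
    labs <- sort(unique(labels))
    truth <- as.character(truth)
    lev <- unique(truth)
    if (length(labs) <= length(lev)) {
        perms <- function(v) {
            if (length(v) <= 1) return(list(v))
            out <- list()
            for (i in seq_along(v))
                for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
            out
        }
        best <- 0
        for (p in perms(lev)) {
            map <- stats::setNames(p[seq_along(labs)], labs)
            best <- max(best, mean(map[as.character(labels)] == truth))
        }
        best
    } else {
        # more clusters than classes: majority genotype per cluster
        maj <- ave(truth, labels,
                   FUN = function(t) names(which.max(table(t))))
        mean(maj == truth)
    }
}

#' k-means clustering in PC space with genotype validation
#'
#' Runs seeded k-means (squared Euclidean, best inertia over
#' \code{nRestarts} restarts) on the first two PC score columns, then
#' validates against the true genotypes: accuracy is the fraction of
#' correct assignments under the best cluster-to-genotype mapping.
#' Genotype centroids are computed from the true labels (not the clusters)
#' as the mean x and y position per genotype, and their Euclidean distance
#' \code{sqrt((x1 - x2)^2 + (y1 - y2)^2)} is reported.
#'
#' @param pca Result of \code{\link{runPCA}} (needs >= 2 components).
#' @param genotype Factor of true genotypes (levels WT, AS), one per mouse.
#' @param k Number of clusters (default 2).
#' @param nRestarts Random restarts (default 50).
#' @param seed Optional seed for the restarts.
#' @return List with \code{labels}, \code{accuracy}, \code{centroids}
#'   (2 x 2 matrix, rows WT/AS), \code{centroidDistance}.
#' @export
clusterAndScore <- function(pca, genotype, k = 2L, nRestarts = 50L,
                            seed = NULL) {
    scores <- pca$scores
    if (ncol(scores) < 2)
        stop("clustering runs in 2-PC space; retain at least 2 components")
    xy <- scores[, 1:2, drop = FALSE]
    if (nrow(xy) < k) stop("need at least k mice to form k clusters")
    if (max(dist(xy)) == 0)
        stop("degenerate clustering: all mice identical in PC space")
    genotype <- factor(as.character(genotype), levels = .GENOTYPES)
    if (!is.null(seed)) set.seed(seed)
    km <- kmeans(xy, centers = k, nstart = nRestarts)
    accuracy <- .bestPermutationAccuracy(km$cluster, genotype)
    cen <- rbind(WT = colMeans(xy[genotype == "WT", , drop = FALSE]),
                 AS = colMeans(xy[genotype == "AS", , drop = FALSE]))
    colnames(cen) <- colnames(xy)[1:2]
    d <- sqrt(sum((cen["WT", ] - cen["AS", ])^2))
    list(labels = as.integer(km$cluster), accuracy = accuracy,
         centroids = cen, centroidDistance = d)
}

#' Multidimensional phenotyping of a cohort
#'
#' The full five-step analysis: data selection (the seven battery measures,
#' optionally plus the three operant metrics days-to-criteria,
#' accuracy-at-criteria and normalized extinction day 1), z-standardization
#' (optionally within sex), PCA, k-means clustering with k = 2, and
#' genotype validation. Mice lacking operant metrics (criteria never
#' reached) are dropped from the operant-inclusive run with a message.
#'
#' @param cohort A \linkS4class{BehaviorCohort}.
#' @param includeOperant Add the operant metrics to the feature set.
#' @param operantMetrics Optional precomputed \code{\link{summarizeOperant}}
#'   table (recomputed when NULL and needed).
#' @param sexSplit Character vector of measures to standardize within sex,
#'   or \code{"auto"} to pick measures with a significant sex main effect
#'   via \code{\link{detectSexSplitMeasures}}.
#' @param nComponents Retained PCs (default 2).
#' @param nRestarts k-means restarts.
#' @param seed Seed for the k-means restarts.
#' @param k Number of clusters.
#' @return A \linkS4class{PhenotypeResult}.
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 3))
#' phenotype(coh, seed = 1)
#' @export
phenotype <- function(cohort, includeOperant = FALSE, operantMetrics = NULL,
                      sexSplit = character(), nComponents = 2L,
                      nRestarts = 50L, seed = NULL, k = 2L) {
    stopifnot(is(cohort, "BehaviorCohort"))
    ros <- roster(cohort)
    feats <- t(batteryMatrix(cohort))  # mice x measures

    if (includeOperant) {
        if (is.null(operantMetrics))
            operantMetrics <- summarizeOperant(cohort)
        om <- operantMetrics[match(rownames(feats),
                                   operantMetrics$mouse_id),
                             c("days_to_criteria", "accuracy_at_criteria",
                               "norm_cued_E1")]
        feats <- cbind(feats, as.matrix(om))
        keep <- stats::complete.cases(feats)
        if (any(!keep))
            message(sum(!keep), " mice dropped from the operant-inclusive ",
                    "analysis (criteria not reached): ",
                    paste(rownames(feats)[!keep], collapse = ", "))
        feats <- feats[keep, , drop = FALSE]
        ros <- ros[keep, , drop = FALSE]
    }
    dropped <- setdiff(colnames(cohort), rownames(feats))

    if (identical(sexSplit, "auto"))
        sexSplit <- detectSexSplitMeasures(feats, ros)
    fm <- standardizeFeatures(feats, roster = ros, sexSplit = sexSplit)
    pca <- runPCA(fm, nComponents = nComponents)
    cl <- clusterAndScore(pca, ros$genotype, k = k, nRestarts = nRestarts,
                          seed = seed)
    new("PhenotypeResult",
        scores = pca$scores, loadings = pca$loadings,
        varianceExplained = pca$varianceExplained,
        clusterLabels = cl$labels,
        genotype = factor(as.character(ros$genotype), levels = .GENOTYPES),
        accuracy = cl$accuracy, centroids = cl$centroids,
        centroidDistance = cl$centroidDistance,
        sexSplit = as.character(sexSplit),
        droppedMice = as.character(dropped))
}

#' Per-genotype correlations of operant metrics with the severity score
#'
#' For each operant metric and genotype, fits an ordinary least-squares
#' regression of the metric on PC1 and reports R-squared, the two-sided p
#' value of the slope, and the fitted line with a 95% confidence band.
#'
#' @param pc1 Named numeric vector of PC1 (severity) scores.
#' @param operantMetrics data.frame from \code{\link{summarizeOperant}}.
#' @param roster Roster with \code{mouse_id} and \code{genotype}.
#' @param metrics Metric columns to test.
#' @return List with \code{summary} (data.frame: metric, genotype, n,
#'   r_squared, p_value) and \code{fits} (per metric x genotype, a
#'   data.frame of pc1, fit, lwr, upr for plotting).
#' @export
pc1Correlations <- function(pc1, operantMetrics, roster,
                            metrics = c("days_to_criteria",
                                        "accuracy_at_criteria",
                                        "norm_cued_E1")) {
    geno <- as.character(roster$genotype[match(names(pc1),
                                               roster$mouse_id)])
    rows <- list(); fits <- list()
    for (m in metrics) {
        y <- operantMetrics[[m]][match(names(pc1),
                                       operantMetrics$mouse_id)]
        for (g in .GENOTYPES) {
            sel <- geno == g & !is.na(y) & !is.na(pc1)
            if (sum(sel) < 3) {
                warning("metric '", m, "' skipped for genotype ", g,
                        ": fewer than 3 complete mice")
                next
            }
            df <- data.frame(pc1 = pc1[sel], y = y[sel])
            fit <- lm(y ~ pc1, data = df)
            sm <- summary(fit)
            grid <- data.frame(pc1 = seq(min(df$pc1), max(df$pc1),
                                         length.out = 50))
            band <- predict(fit, grid, interval = "confidence",
                            level = 0.95)
            rows[[paste(m, g)]] <- data.frame(
                metric = m, genotype = g, n = sum(sel),
                r_squared = sm$r.squared,
                p_value = sm$coefficients["pc1", "Pr(>|t|)"],
                stringsAsFactors = FALSE)
            fits[[paste(m, g)]] <- cbind(grid, as.data.frame(band))
        }
    }
    list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         fits = fits)
}

#' Replicate-cohort clustering accuracy
#'
#' Repeatedly simulates a battery-only cohort (balanced genotypes, unit-SD
#' normal measures with the configured genotype shifts), standardizes,
#' reduces to two PCs and clusters with k-means, returning the
#' genotype-validation accuracy of every replicate. Used to estimate the
#' expected genotype-discrimination accuracy of a measure set.
#'
#' @param effects Effect table (rbind of \code{\link{effectSpec}} rows).
#' @param nReplicates Number of replicate cohorts.
#' @param nPerGenotype Mice per genotype (sexes balanced).
#' @param sexSplit Measures standardized within sex.
#' @param nRestarts k-means restarts per replicate.
#' @param seed Master seed; per-replicate sub-seeds derive from it.
#' @return Numeric vector of accuracies, one per replicate.
#' @examples
#' acc <- simulateClusteringAccuracy(defaultEffectSpecs(),
#'                                   nReplicates = 5, seed = 1)
#' mean(acc)
#' @export
simulateClusteringAccuracy <- function(effects, nReplicates = 100L,
                                       nPerGenotype = 28L,
                                       sexSplit = character(),
                                       nRestarts = 50L, seed) {
    if (missing(seed)) stop("a master seed is required")
    set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    half <- nPerGenotype %/% 2L
    ros <- data.frame(
        mouse_id = sprintf("m%04d", seq_len(2L * nPerGenotype)),
        genotype = rep(c("WT", "AS"), each = nPerGenotype),
        sex = rep(rep_len(c(rep("M", half), rep("F", nPerGenotype - half)),
                          nPerGenotype), 2),
        stringsAsFactors = FALSE)
    vapply(subSeeds, function(s) {
        bat <- t(simulateBattery(ros, effects, seed = s))
        fm <- standardizeFeatures(bat, ros, sexSplit = sexSplit)
        pca <- runPCA(fm, 2)
        clusterAndScore(pca, factor(ros$genotype, levels = .GENOTYPES),
                        nRestarts = nRestarts, seed = s)$accuracy
    }, numeric(1))
}
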
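test_that("z-standardization uses sample SD and honors sex strata", {
    z <- standardizeFeatures(cbind(m = c(1, 2, 3)))
    expect_equal(unname(z[, "m"]), c(-1, 0, 1))  # sd(1,2,3) = 1

    expect_error(standardizeFeatures(cbind(m = rep(2, 4))), "zero variance")

    # sex-split removes the sex main effect entirely
    ros <- data.frame(mouse_id = paste0("m", 1:4),
                      sex = c("M", "M", "F", "F"),
                      genotype = c("WT", "AS", "WT", "AS"))
    raw <- cbind(m = c(0, 2, 10, 12))
    rownames(raw) <- ros$mouse_id
    z <- standardizeFeatures(raw, ros, sexSplit = "m")
    expect_equal(unname(z[, "m"]),
                 rep(c(-1, 1) / sqrt(2), 2), tolerance = 1e-12)
    expect_equal(mean(z[ros$sex == "M", ]), 0)
    expect_equal(mean(z[ros$sex == "F", ]), 0)
    # without the split the sex shift dominates
    z0 <- standardizeFeatures(raw)
    expect_gt(mean(z0[3:4, ]) - mean(z0[1:2, ]), 1)

    # a stratum below 2 mice is refused
    expect_error(standardizeFeatures(raw[1:3, , drop = FALSE],
                                     ros[1:3, ], sexSplit = "m"),
                 "fewer than 2")
})

test_that("sex-difference auto-detection flags only shifted measures", {
    ros <- makeRoster(40)
    eff <- rbind(effectSpec("weight", 28, 3, cohens_d = 1.7, sex_d = -1.5),
                 effectSpec("marbles", 15, 4, cohens_d = -1.6, sex_d = 0))
    bat <- t(simulateBattery(ros, eff, seed = 31))
    found <- detectSexSplitMeasures(bat, ros)
    expect_true("weight" %in% found)
    expect_false("marbles" %in% found)
})

test_that("PCA returns ordered, sign-fixed, centered components", {
    set.seed(11)
    base <- rnorm(30)
    x <- cbind(a = base, b = base, c = base)  # rank-1 duplicates
    p <- runPCA(x, nComponents = 1)
    expect_gt(p$varianceExplained[1], 0.999)
    expect_equal(abs(unname(p$loadings[, 1])), rep(1 / sqrt(3), 3),
                 tolerance = 1e-8)
    expect_error(runPCA(x, nComponents = 2), "rank")

    # scores are centered and loadings unit-norm, largest loading positive
    x <- matrix(rnorm(200), 40, 5)
    p <- runPCA(x, 2)
    expect_equal(unname(colMeans(p$scores)), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(colSums(p$loadings^2)), c(1, 1), tolerance = 1e-12)
    for (j in 1:2) {
        v <- p$loadings[, j]
        expect_gt(v[which.max(abs(v))], 0)
    }
})

test_that("PCA matches an independent eigendecomposition on block data", {
    # two uncorrelated column blocks driven by independent factors
    set.seed(12)
    f1 <- rnorm(500); f2 <- 0.6 * rnorm(500)  # distinct block variances
    x <- cbind(f1, f1 + rnorm(500, sd = 0.05),
               f2, f2 + rnorm(500, sd = 0.05))
    p <- runPCA(x, 2)
    ev <- eigen(cov(x), symmetric = TRUE)  # independent route
    expect_equal(p$varianceExplained[1:2],
                 (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
    for (j in 1:2)
        expect_equal(abs(unname(p$loadings[, j])), abs(ev$vectors[, j]),
                     tolerance = 1e-6)
    # each component loads on one block only
    expect_lt(sum(abs(p$loadings[3:4, 1])), 0.15)
    expect_lt(sum(abs(p$loadings[1:2, 2])), 0.15)
})

test_that("standardize + PCA is invariant to affine rescaling of measures", {
    ros <- makeRoster(30)
    bat <- t(simulateBattery(ros, defaultEffectSpecs(), seed = 33))
    resc <- bat
    resc[, "weight"] <- 1000 * resc[, "weight"] - 5      # g -> mg, offset
    resc[, "of_distance"] <- resc[, "of_distance"] / 100
    z1 <- standardizeFeatures(bat, ros)
    z2 <- standardizeFeatures(resc, ros)
    expect_equal(z1, z2, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(runPCA(z1, 2)$scores, runPCA(z2, 2)$scores,
                 tolerance = 1e-8)
})

fakePCA <- function(scores) list(scores = scores,
                                 loadings = diag(ncol(scores)),
                                 varianceExplained = c(0.6, 0.2))

test_that("clustering validation scores and centroids behave", {
    # well-separated genotype blobs: perfect accuracy
    set.seed(13)
    xy <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
                matrix(rnorm(60, 5, 0.2), ncol = 2))
    geno <- factor(rep(c("WT", "AS"), each = 30), levels = c("WT", "AS"))
    cl <- clusterAndScore(fakePCA(xy), geno, seed = 1)
    expect_equal(cl$accuracy, 1.0)
    # accuracy is invariant to swapping the genotype labels
    cl2 <- clusterAndScore(fakePCA(xy), factor(rev(geno),
                           levels = c("WT", "AS")), seed = 1)
    expect_equal(cl2$accuracy, 1.0)

    # shuffled labels: accuracy hovers at the permutation null (~0.5)
    set.seed(14)
    accs <- replicate(100, {
        g <- factor(sample(as.character(geno)), levels = c("WT", "AS"))
        clusterAndScore(fakePCA(xy), g, seed = 1)$accuracy
    })
    expect_gt(mean(accs), 0.49)
    expect_lt(mean(accs), 0.62)

    # centroid distance: 3-4-5 triangle from true-genotype means
    xy <- rbind(c(-1, 0), c(1, 0), c(2, 4), c(4, 4))
    geno <- factor(c("WT", "WT", "AS", "AS"), levels = c("WT", "AS"))
    cl <- clusterAndScore(fakePCA(xy), geno, seed = 1)
    expect_equal(unname(cl$centroids["WT", ]), c(0, 0))
    expect_equal(unname(cl$centroids["AS", ]), c(3, 4))
    expect_equal(cl$centroidDistance, 5.0)

    # centroid distance is invariant to rigid rotation of the scores
    th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    clR <- clusterAndScore(fakePCA(xy %*% R), geno, seed = 1)
    expect_equal(clR$centroidDistance, 5.0, tolerance = 1e-12)

    expect_error(clusterAndScore(fakePCA(matrix(1, 4, 2)), geno),
                 "degenerate")
})

test_that("noise columns do not help accuracy; informative columns widen
           centroid separation (Monte-Carlo trend)", {
    dEff <- c(1.71, 1.64, 1.22, 0.07, 0.10, 1.62, 1.52)
    effBase <- do.call(rbind, lapply(seq_along(dEff), function(i)
        effectSpec(paste0("m", i), 0, 1, cohens_d = dEff[i])))
    effNoise <- rbind(effBase,
                      effectSpec("n1", 0, 1, 0), effectSpec("n2", 0, 1, 0),
                      effectSpec("n3", 0, 1, 0))
    effInfo <- rbind(effBase, effectSpec("extra", 0, 1, cohens_d = 1.5))
    ros <- makeRoster(28)
    run <- function(eff, seed) {
        bat <- t(simulateBattery(ros, eff, seed = seed))
        p <- runPCA(standardizeFeatures(bat, ros), 2)
        cl <- clusterAndScore(p, factor(ros$genotype,
                                        levels = c("WT", "AS")),
                              nRestarts = 20, seed = seed)
        c(acc = cl$accuracy, dist = cl$centroidDistance)
    }
    res <- vapply(1:100, function(s) c(base = run(effBase, s),
                                       noise = run(effNoise, s),
                                       info = run(effInfo, s)),
                  numeric(6))
    expect_lte(mean(res["noise.acc", ]), mean(res["base.acc", ]) + 0.01)
    expect_gte(mean(res["info.dist", ]), mean(res["base.dist", ]))
})

test_that("whole-cohort phenotyping composes the five steps", {
    coh <- simulateCohort(cohortConfig(seed = 41))
    ph <- phenotype(coh, sexSplit = "weight", seed = 5)
    expect_s4_class(ph, "PhenotypeResult")
    expect_identical(dim(pcScores(ph)), c(56L, 2L))
    expect_identical(rownames(pcLoadings(ph)), batteryMeasureNames())
    expect_gte(clusterAccuracy(ph), 0.8)
    expect_gt(centroidDistance(ph), 1)
    expect_identical(names(severityScore(ph)), roster(coh)$mouse_id)

    # operant-inclusive run adds the three operant measures
    om <- summarizeOperant(coh)
    ph10 <- phenotype(coh, includeOperant = TRUE, operantMetrics = om,
                      seed = 5)
    expect_identical(nrow(pcLoadings(ph10)), 10L)

    # mice without criteria are dropped from the operant-inclusive run
    om2 <- om
    om2$days_to_criteria[1:3] <- NA
    expect_message(
        ph9 <- phenotype(coh, includeOperant = TRUE, operantMetrics = om2,
                         seed = 5),
        "dropped")
    expect_identical(nrow(pcScores(ph9)), 53L)
    expect_identical(length(ph9@droppedMice), 3L)
})

test_that("PC1 correlations report per-genotype OLS fits", {
    ros <- makeRoster(20)
    pc1 <- setNames(rnorm(40), ros$mouse_id)
    om <- data.frame(mouse_id = ros$mouse_id,
                     days_to_criteria = 2 * pc1 + 1,   # exact line
                     accuracy_at_criteria = rnorm(40),
                     norm_cued_E1 = rnorm(40))
    r <- suppressWarnings(pc1Correlations(pc1, om, ros))  # exact-fit lm
    lin <- subset(r$summary, metric == "days_to_criteria")
    expect_equal(lin$r_squared, c(1, 1), tolerance = 1e-10)
    expect_true(all(lin$p_value < 1e-10))

    # hand-computed squared Pearson correlation on 5 fixed pairs
    x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 7)
    r2hand <- (sum((x - 3) * (y - mean(y))) /
               sqrt(sum((x - 3)^2) * sum((y - mean(y))^2)))^2
    ros5 <- data.frame(mouse_id = paste0("m", 1:5), genotype = "WT")
    om5 <- data.frame(mouse_id = ros5$mouse_id, days_to_criteria = y)
    r5 <- suppressWarnings(  # no AS mice in this fixture
        pc1Correlations(setNames(x, ros5$mouse_id), om5, ros5,
                        metrics = "days_to_criteria"))
    expect_equal(r5$summary$r_squared, r2hand, tolerance = 1e-12)

    # fewer than 3 mice in a genotype: metric skipped with a warning
    expect_warning(  # one warning per empty genotype stratum
        expect_warning(
            pc1Correlations(setNames(x[1:2], ros5$mouse_id[1:2]),
                            om5[1:2, ], ros5[1:2, ],
                            metrics = "days_to_criteria"),
            "fewer than 3"),
        "fewer than 3")
})
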
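test_that("response accuracy is the cued response rate", {
    expect_equal(responseAccuracy(30, 10), 0.75)
    expect_equal(responseAccuracy(17, 0), 1.0)
    expect_error(responseAccuracy(0, 0), "undefined")
    expect_equal(responseAccuracy(c(1, 3), c(1, 1)), c(0.5, 0.75))
})

makeAcq <- function(trials, cued, noncued) {
    data.frame(day = seq_along(trials), trials = trials,
               cued = cued, noncued = noncued)
}

test_that("criteria detection applies strict thresholds over a 5-day run", {
    # warm-up day then five passing days: criteria on day 6
    acq <- makeAcq(c(10, 20, 20, 20, 20, 20), rep(80, 6), rep(20, 6))
    r <- detectCriteria(acq)
    expect_identical(r$days_to_criteria, 6L)
    expect_identical(r$criterion_days, 2:6)

    # a broken run restarts the count
    acc <- c(0.8, 0.8, 0.7, 0.8, 0.8, 0.8, 0.8, 0.8)
    acq <- makeAcq(rep(20, 8), round(100 * acc), round(100 * (1 - acc)))
    r <- detectCriteria(acq)
    expect_identical(r$days_to_criteria, 8L)
    expect_identical(r$criterion_days, 4:8)

    # boundaries are strict: exactly 15 trials or exactly 75% never pass
    acq <- makeAcq(rep(15, 8), rep(80, 8), rep(20, 8))
    expect_true(is.na(detectCriteria(acq)$days_to_criteria))
    acq <- makeAcq(rep(20, 8), rep(75, 8), rep(25, 8))
    expect_true(is.na(detectCriteria(acq)$days_to_criteria))

    # fewer sessions than the run length: not reached, no exception
    acq <- makeAcq(rep(20, 3), rep(80, 3), rep(0, 3))
    expect_true(is.na(detectCriteria(acq)$days_to_criteria))

    # a zero-response day cannot pass (undefined accuracy)
    acq <- makeAcq(rep(20, 6), c(80, 0, 80, 80, 80, 80), rep(0, 6))
    expect_identical(detectCriteria(acq)$criterion_days, NULL)
})

test_that("criteria detection agrees with a brute-force window scan", {
    set.seed(314)
    for (rep in 1:200) {
        n <- sample(1:12, 1)
        # hover around the thresholds to exercise the boundaries
        acq <- makeAcq(sample(13:18, n, TRUE),
                       sample(c(0, 2, 3, 6, 9, 12), n, TRUE),
                       sample(0:4, n, TRUE))
        got <- detectCriteria(acq, minTrials = 15, minRate = 0.75,
                              runLength = 3)
        want <- bruteForceCriteria(acq, 15, 0.75, 3)
        expect_identical(got$days_to_criteria,
                         as.integer(want$days_to_criteria))
        expect_identical(got$criterion_days,
                         if (is.null(want$criterion_days)) NULL
                         else as.integer(want$criterion_days))
    }
})

test_that("criteria detection is invariant to post-criteria sessions and
           monotone in its thresholds", {
    set.seed(271)
    for (rep in 1:50) {
        acq <- makeAcq(sample(10:25, 9, TRUE), sample(10:90, 9, TRUE),
                       sample(0:20, 9, TRUE))
        base <- detectCriteria(acq)
        # appending sessions never changes an already-reached outcome
        more <- rbind(acq, makeAcq(sample(10:25, 3, TRUE),
                                   sample(10:90, 3, TRUE),
                                   sample(0:20, 3, TRUE)))
        more$day <- seq_len(nrow(more))
        if (!is.na(base$days_to_criteria))
            expect_identical(detectCriteria(more), base)
        # raising a threshold never lowers days-to-criteria
        for (alt in list(detectCriteria(acq, minRate = 0.85),
                         detectCriteria(acq, minTrials = 20))) {
            d0 <- base$days_to_criteria; d1 <- alt$days_to_criteria
            expect_true(is.na(d1) || (!is.na(d0) && d1 >= d0))
        }
    }
})

test_that("at-criteria summaries average exactly the five criterion days", {
    acq <- makeAcq(rep(20, 5), c(20, 20, 20, 20, 20), rep(5, 5))
    s <- acquisitionAtCriteria(acq, 1:5)
    expect_equal(s$cued_at_criteria, 20)
    expect_equal(s$noncued_at_criteria, 5)
    expect_equal(s$accuracy_at_criteria, 0.8)

    acq <- makeAcq(rep(20, 5), c(10, 20, 30, 20, 20), rep(0, 5))
    s <- acquisitionAtCriteria(acq, 1:5)
    expect_equal(s$cued_at_criteria, 20)
    expect_equal(s$accuracy_at_criteria, 1.0)

    # daily accuracies (1, .5, 1, 1, 1): mean-of-days 0.9, pooled 34/36
    acq <- makeAcq(rep(20, 5), c(8, 2, 8, 8, 8), c(0, 2, 0, 0, 0))
    expect_equal(acquisitionAtCriteria(acq, 1:5)$accuracy_at_criteria, 0.9)
    expect_equal(acquisitionAtCriteria(acq, 1:5,
                     accuracyMethod = "pooled")$accuracy_at_criteria,
                 34 / 36)

    # not-reached mice propagate missing values, never imputation
    s <- acquisitionAtCriteria(acq, NULL, mouse_id = "mx")
    expect_false(s$reached)
    expect_true(is.na(s$days_to_criteria))
    expect_true(is.na(s$accuracy_at_criteria))

    expect_error(acquisitionAtCriteria(acq, 1:4), "exactly 5")
})

test_that("extinction normalization divides by the acquisition baseline", {
    ext <- data.frame(day = 1:3, cued = c(20, 10, 5), noncued = c(4, 2, 1))
    s <- normalizeExtinction(ext, 20, 4)
    expect_equal(unlist(s[paste0("norm_cued_E", 1:3)], use.names = FALSE),
                 c(1.0, 0.5, 0.25))
    expect_equal(unlist(s[paste0("norm_noncued_E", 1:3)],
                        use.names = FALSE), c(1.0, 0.5, 0.25))
    # accuracy stays on the raw counts
    expect_equal(unlist(s[paste0("accuracy_E", 1:3)], use.names = FALSE),
                 c(20 / 24, 10 / 12, 5 / 6))

    # an extinction burst (> baseline responding on day 1) is representable
    s <- normalizeExtinction(data.frame(day = 1:3, cued = c(30, 10, 5),
                                        noncued = c(4, 2, 1)), 20, 4)
    expect_gt(s$norm_cued_E1, 1)

    # scale equivariance: doubling counts and baselines changes nothing
    ext2 <- transform(ext, cued = cued * 2, noncued = noncued * 2)
    expect_equal(normalizeExtinction(ext2, 40, 8)[-1],
                 normalizeExtinction(ext, 20, 4)[-1])

    expect_error(normalizeExtinction(ext, 0, 4), "positive")
    expect_error(normalizeExtinction(ext[1:2, ], 20, 4), "3 extinction")
})

test_that("cohort-level operant summary wires baselines by group", {
    coh <- simulateCohort(cohortConfig(seed = 21,
                                       groupSizes = smallGroupSizes(8)))
    om <- summarizeOperant(coh)
    expect_identical(om$mouse_id, roster(coh)$mouse_id)
    expect_true(all(c("days_to_criteria", "cued_at_criteria",
                      "noncued_at_criteria", "accuracy_at_criteria",
                      paste0("norm_cued_E", 1:3),
                      paste0("norm_noncued_E", 1:3),
                      paste0("accuracy_E", 1:3), "reached") %in% names(om)))
    expect_true(all(om$norm_cued_E1 >= 0, na.rm = TRUE))

    # reconstruct one genotype baseline by hand
    g <- as.character(genotypes(coh))
    baseWT <- mean(om$cued_at_criteria[g == "WT"], na.rm = TRUE)
    sess <- sessions(coh)
    id <- om$mouse_id[g == "WT"][1]
    e1 <- sess$cued[sess$mouse_id == id & sess$phase == "EXT" &
                    sess$day == 1]
    expect_equal(om$norm_cued_E1[om$mouse_id == id], e1 / baseWT)

    # a group that never reaches criteria has no baseline: named error
    p0 <- learnerParams(0, 0.5, 5, 1e-9, 0.5, 0)
    cfg <- cohortConfig(seed = 22, groupSizes = smallGroupSizes(2),
                        learners = list(WT = defaultLearnerParams("WT"),
                                        AS = p0), maxAcqDays = 25)
    expect_error(summarizeOperant(simulateCohort(cfg)), "group 'AS'")
})
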
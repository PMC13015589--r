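test_that("cohort simulation is deterministic given its seed", {
    cfg <- cohortConfig(seed = 101)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(batteryMatrix(a), batteryMatrix(b))
    expect_identical(sessions(a), sessions(b))
    expect_identical(roster(a), roster(b))
    # and a different seed changes the draws
    c2 <- simulateCohort(cohortConfig(seed = 102))
    expect_false(identical(batteryMatrix(a), batteryMatrix(c2)))
})

test_that("battery sampling model recovers the configured effect sizes", {
    # null effects: standardized group difference ~ 0 at 1000/group
    ros <- makeRoster(1000)
    eff <- rbind(effectSpec("a", 10, 2, cohens_d = 0),
                 effectSpec("b", 5, 1, cohens_d = 0))
    bat <- simulateBattery(ros, eff, seed = 5)
    for (m in c("a", "b")) {
        d <- cohensD(bat[m, ros$genotype == "AS"],
                     bat[m, ros$genotype == "WT"])
        expect_lt(abs(d), 0.1)
    }

    # configured effect recovered within +/-0.05 at 1e4/group; cross-check
    # the target against an independent one-line Monte-Carlo estimate
    ros <- makeRoster(10000)
    eff <- effectSpec("rotarod_day1", 120, 50, cohens_d = 1.64)
    bat <- simulateBattery(ros, eff, seed = 6)
    dHat <- cohensD(bat[1, ros$genotype == "AS"],
                    bat[1, ros$genotype == "WT"])
    expect_lt(abs(dHat - 1.64), 0.05)
    set.seed(99)
    dMC <- cohensD(rnorm(10000, 1.64), rnorm(10000))  # independent oracle
    expect_lt(abs(dHat - dMC), 0.1)

    # sex shift enters with the configured sign and size
    eff <- effectSpec("weight", 28, 3, cohens_d = 0, sex_d = -1)
    bat <- simulateBattery(ros, eff, seed = 7)
    dSex <- cohensD(bat[1, ros$sex == "F"], bat[1, ros$sex == "M"])
    expect_lt(abs(dSex - (-1)), 0.05)
})

test_that("configuration errors are caught", {
    expect_error(cohortConfig(seed = 1,
        effects = data.frame(measure_name = "x", control_mean = 0,
                             control_sd = 0, cohens_d = 1, sex_d = 0)),
        "control_sd")
    expect_error(effectSpec("x", 0, -1), "positive")
    gs <- smallGroupSizes(); gs$n[gs$genotype == "AS"] <- 0L
    expect_error(cohortConfig(seed = 1, groupSizes = gs), "at least 2 AS")
    expect_error(cohortConfig(), "seed")
    expect_error(simulateOperantMouse(defaultLearnerParams("WT"),
                                      maxAcqDays = 4, seed = 1), ">= 5")
})

test_that("FR1/VR2 schedule matches an event-replay oracle", {
    # FR1 segment: every cued response up to 10 pays
    set.seed(1)
    expect_identical(scheduleRewards(0), 0L)
    expect_identical(scheduleRewards(7), 7L)
    expect_identical(scheduleRewards(10), 10L)

    # 37 responses: 10 FR1 rewards + VR2 rewards from the remaining 27;
    # mean total ~ 10 + 27/2 = 23.5
    set.seed(42)
    sim <- replicate(10000, scheduleRewards(37))
    expect_lt(abs(mean(sim) - 23.5), 0.5)

    # independent oracle: replay response by response, drawing each VR2
    # requirement as it is needed
    replay <- function(cued) {
        rewards <- 0; need <- 1; fr1 <- 10
        for (r in seq_len(cued)) {
            need <- need - 1
            if (need == 0) {
                rewards <- rewards + 1
                need <- if (rewards < fr1) 1 else 1 + rgeom(1, 0.5)
            }
        }
        rewards
    }
    set.seed(43)
    orc <- replicate(10000, replay(37))
    expect_lt(abs(mean(sim) - mean(orc)), 0.5)
    expect_lt(abs(sd(sim) - sd(orc)), 0.5)
})

test_that("simulated sessions respect the task structure", {
    cfg <- cohortConfig(seed = 8, groupSizes = smallGroupSizes(6))
    sess <- sessions(simulateCohort(cfg))

    expect_true(all(sess$rewards[sess$phase == "EXT"] == 0))
    expect_true(all(table(sess$mouse_id[sess$phase == "EXT"]) == 3))
    expect_true(all(table(sess$mouse_id[sess$phase == "MAG"]) >= 2))

    acq <- sess[sess$phase == "ACQ", ]
    # schedule conservation: rewards never exceed cued responses, and the
    # FR1 segment always pays in full
    expect_true(all(acq$rewards <= acq$cued))
    expect_true(all(acq$rewards >= pmin(acq$cued, 10)))
    expect_identical(acq$trials, acq$rewards)

    # priming: first two acquisition days and any day after a <5-trial day
    for (id in unique(acq$mouse_id)) {
        a <- acq[acq$mouse_id == id, ]
        a <- a[order(a$day), ]
        prev <- c(Inf, a$trials[-nrow(a)])
        expect_identical(a$primed, a$day <= 2 | prev < 5)
    }
})

test_that("a degenerate learner never responds or reaches criteria", {
    p <- learnerParams(0, 0.5, 5, 1e-9, 0.5, 0)
    s <- simulateOperantMouse(p, maxAcqDays = 10, seed = 3)
    acq <- s[s$phase == "ACQ", ]
    expect_identical(nrow(acq), 10L)  # runs to the cap
    expect_true(all(acq$cued == 0))
    expect_true(all(acq$rewards == 0))
    expect_false(attr(s, "reached"))
})

test_that("default learners reproduce the genotype phenotype directions", {
    gs <- smallGroupSizes(50)  # 100 WT + 100 AS
    coh <- simulateCohort(cohortConfig(seed = 9, groupSizes = gs))
    om <- summarizeOperant(coh)
    g <- as.character(genotypes(coh))
    expect_gt(mean(om$days_to_criteria[g == "AS"], na.rm = TRUE),
              mean(om$days_to_criteria[g == "WT"], na.rm = TRUE))
    expect_lt(mean(om$norm_cued_E1[g == "AS"], na.rm = TRUE),
              mean(om$norm_cued_E1[g == "WT"], na.rm = TRUE))
    expect_gt(mean(om$accuracy_at_criteria[g == "AS"], na.rm = TRUE),
              mean(om$accuracy_at_criteria[g == "WT"], na.rm = TRUE))
})

test_that("F-statistic conversion reproduces the derived effect sizes", {
    expect_equal(dFromF(40.69, 30, 26), 1.709, tolerance = 1e-3)
    expect_equal(dFromF(0.1391, 30, 26), 0.09993, tolerance = 1e-3)
})
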
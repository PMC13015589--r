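## Synthetic cohort generation: roster, battery measures with specified
## standardized effect sizes, and trial-level operant sessions under the
## FR1/VR2 task contingencies.

#' Effect specification for one battery measure
#'
#' Describes how a battery measure is drawn: a control (WT male) normal
#' distribution plus standardized mean shifts for genotype and sex. Mouse i
#' is drawn \code{Normal(control_mean + I(AS) * cohens_d * control_sd +
#' I(F) * sex_d * control_sd, control_sd)}.
#'
#' @param measure_name Measure name (unique within a config).
#' @param control_mean Control-group mean, native units.
#' @param control_sd Control-group SD, native units (> 0).
#' @param cohens_d Standardized AS - WT shift; sign gives the direction of
#'   the AS effect.
#' @param sex_d Standardized F - M shift.
#' @return One-row data.frame; rbind several to form an effect table.
#' @examples
#' effectSpec("weight", 28, 3, cohens_d = 1.71, sex_d = -1)
#' @export
effectSpec <- function(measure_name, control_mean, control_sd,
                       cohens_d = 0, sex_d = 0) {
    stopifnot(is.character(measure_name), length(measure_name) == 1)
    if (!is.finite(control_sd) || control_sd <= 0)
        stop("control_sd must be a positive real for measure '",
             measure_name, "'")
    data.frame(measure_name = measure_name, control_mean = control_mean,
               control_sd = control_sd, cohens_d = cohens_d, sex_d = sex_d,
               stringsAsFactors = FALSE)
}

#' Convert an ANOVA F statistic to Cohen's d
#'
#' For a two-group comparison, \code{d = sqrt(F * (1/n1 + 1/n2))}. Used to
#' derive effect sizes for measures whose d is not tabulated but whose
#' genotype main-effect F is reported (body weight, open-field center time).
#'
#' @param f F statistic of the two-group (genotype) main effect.
#' @param n1,n2 Group sizes.
#' @return Cohen's d (magnitude).
#' @examples
#' dFromF(40.69, 30, 26)   # ~1.71
#' dFromF(0.1391, 30, 26)  # ~0.10
#' @export
dFromF <- function(f, n1, n2) {
    stopifnot(f >= 0, n1 > 0, n2 > 0)
    sqrt(f * (1 / n1 + 1 / n2))
}

#' Default battery effect specifications
#'
#' Effect table for the seven standard battery measures using the study's
#' achieved genotype effect sizes: rotarod day 1 d = 1.64, rotarod day 5
#' d = 1.22, open-field distance d = 0.07, marbles buried d = 1.62, nest
#' building d = 1.52; weight and open-field center time use F-derived
#' values via \code{\link{dFromF}} (F = 40.69 and F = 0.1391 with groups of
#' 30 and 26). Signs encode the direction of the AS effect (heavier, worse
#' motor performance, less burying/nesting). Control means/SDs are
#' plausible native-unit values for adult C57BL/6J mice; weight carries a
#' female - male shift of -1 SD to exercise sex-split standardization.
#'
#' @return data.frame of \code{\link{effectSpec}} rows.
#' @export
defaultEffectSpecs <- function() {
    rbind(
        effectSpec("weight",         28,  3.0, cohens_d =  dFromF(40.69, 30, 26),
                   sex_d = -1),
        effectSpec("rotarod_d1",    120, 50,   cohens_d = -1.64),
        effectSpec("rotarod_d5",    200, 60,   cohens_d = -1.22),
        effectSpec("of_distance",    20,  5,   cohens_d = -0.07),
        effectSpec("of_center_time", 100, 40,  cohens_d = -dFromF(0.1391, 30, 26)),
        effectSpec("marbles_buried", 15,  4,   cohens_d = -1.62),
        effectSpec("nest_used_d5",    9,  2,   cohens_d = -1.52))
}

#' Parametric operant learner
#'
#' A minimal generative stand-in for a mouse performing the operant task:
#' expected cued responses per acquisition session follow a logistic
#' learning curve \code{asymptote_cued / (1 + exp(-learning_rate * (day -
#' start_day_shift)))}; non-cued responses are a flat Poisson; extinction
#' day 1 responding is \code{burst_gain} times the final acquisition
#' expectation and then decays by \code{extinction_decay} per day. The task
#' contingencies (FR1 then VR2 reward schedule, priming) are fixed by the
#' protocol, not by these parameters.
#'
#' @param asymptote_cued Asymptotic cued responses per session (> 0 unless
#'   deliberately degenerate).
#' @param learning_rate Logistic growth rate, 1/days (> 0).
#' @param start_day_shift Day of the logistic midpoint.
#' @param noncued_rate Expected non-cued responses per session (> 0).
#' @param extinction_decay Per-day multiplicative retention during
#'   extinction, in (0, 1].
#' @param burst_gain Extinction day-1 multiplier (>= 0); < 1 means
#'   responding collapses immediately, > 1 an extinction burst.
#' @return List of class \code{"LearnerParams"}.
#' @export
learnerParams <- function(asymptote_cued, learning_rate, start_day_shift,
                          noncued_rate, extinction_decay, burst_gain) {
    p <- list(asymptote_cued = asymptote_cued, learning_rate = learning_rate,
              start_day_shift = start_day_shift, noncued_rate = noncued_rate,
              extinction_decay = extinction_decay, burst_gain = burst_gain)
    if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                        is.finite(v), logical(1))))
        stop("all learner parameters must be finite scalars")
    if (asymptote_cued < 0 || learning_rate <= 0 || noncued_rate <= 0 ||
        burst_gain < 0)
        stop("rates must be positive (asymptote_cued and burst_gain may be 0)")
    if (extinction_decay <= 0 || extinction_decay > 1)
        stop("extinction_decay must lie in (0, 1]")
    structure(p, class = "LearnerParams")
}

#' Default learner parameters by genotype
#'
#' Defaults chosen so simulated cohorts reproduce the qualitative operant
#' phenotype of the Angelman model: AS learners have a lower asymptote and
#' later learning (more days to criteria, fewer cued responses at
#' criteria), a lower non-cued rate (higher accuracy at criteria), and a
#' sub-unity extinction burst (fewer normalized cued responses on
#' extinction day 1). The AS offsets were calibrated once, on large
#' simulated groups, so the standardized genotype differences on the three
#' planning metrics (days to criteria, accuracy at criteria, normalized
#' extinction day 1) fall near the achieved effect sizes 0.84, 0.89 and
#' 0.91.
#'
#' @param genotype \code{"WT"} or \code{"AS"}.
#' @return A \code{\link{learnerParams}} object.
#' @export
defaultLearnerParams <- function(genotype = c("WT", "AS")) {
    genotype <- match.arg(genotype)
    if (genotype == "WT")
        learnerParams(asymptote_cued = 60, learning_rate = 0.50,
                      start_day_shift = 5, noncued_rate = 12,
                      extinction_decay = 0.50, burst_gain = 1.0)
    else
        learnerParams(asymptote_cued = 40, learning_rate = 0.42,
                      start_day_shift = 7, noncued_rate = 7,
                      extinction_decay = 0.45, burst_gain = 0.87)
}

#' Default cohort group sizes
#'
#' Mirrors the study design: two cohorts, both genotypes and sexes; 24 mice
#' in cohort 1 (WT M 8, AS M 6, WT F 5, AS F 5) and 30 in cohort 2 (WT M 8,
#' AS M 6, WT F 9, AS F 9) for 30 WT and 26 AS in total.
#'
#' @return data.frame with columns \code{genotype}, \code{sex},
#'   \code{cohort}, \code{n}.
#' @export
defaultGroupSizes <- function() {
    data.frame(
        genotype = rep(c("WT", "AS"), 4),
        sex = rep(c("M", "M", "F", "F"), 2),
        cohort = rep(c("1", "2"), each = 4),
        n = c(8L, 6L, 5L, 5L, 8L, 6L, 9L, 9L))
}

#' Cohort simulation configuration
#'
#' Bundles everything \code{\link{simulateCohort}} needs. The seed is
#' mandatory: identical configs give byte-identical cohorts.
#'
#' @param groupSizes data.frame(genotype, sex, cohort, n); defaults to the
#'   study design (\code{\link{defaultGroupSizes}}).
#' @param effects Effect table (rbind of \code{\link{effectSpec}} rows).
#' @param learners Named list \code{list(WT = , AS = )} of
#'   \code{\link{learnerParams}}.
#' @param seed Integer seed (mandatory).
#' @param nMagDays Magazine-training days (>= 2).
#' @param maxAcqDays Acquisition cap; mice not reaching criteria by then are
#'   flagged, not dropped.
#' @param minTrials,minRate,runLength Acquisition criteria used to decide
#'   when a simulated mouse advances to extinction (strict \code{>}
#'   thresholds sustained \code{runLength} consecutive days).
#' @param ageRange Inclusive range (days) from which ages are drawn
#'   uniformly per cohort; a list with elements "1" and "2".
#' @param dispersion Optional negative-binomial size parameter for response
#'   counts; NULL (default) uses Poisson counts.
#' @return List of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(groupSizes = defaultGroupSizes(),
                         effects = defaultEffectSpecs(),
                         learners = list(WT = defaultLearnerParams("WT"),
                                         AS = defaultLearnerParams("AS")),
                         seed,
                         nMagDays = 2L, maxAcqDays = 40L,
                         minTrials = 15L, minRate = 0.75, runLength = 5L,
                         ageRange = list("1" = c(60L, 155L),
                                         "2" = c(83L, 114L)),
                         dispersion = NULL) {
    if (missing(seed) || is.null(seed))
        stop("a seed is mandatory for cohort simulation")
    groupSizes <- as.data.frame(groupSizes)
    stopifnot(all(c("genotype", "sex", "cohort", "n") %in% names(groupSizes)))
    if (any(groupSizes$n < 0)) stop("group sizes must be >= 0")
    if (anyDuplicated(effects$measure_name))
        stop("measure names must be unique within a config")
    if (any(effects$control_sd <= 0))
        stop("control_sd must be positive for all measures")
    for (g in c("WT", "AS")) {
        tot <- sum(groupSizes$n[groupSizes$genotype == g])
        if (tot < 2)
            stop("need at least 2 ", g,
                 " mice; downstream statistics are undefined below that")
    }
    structure(list(groupSizes = groupSizes, effects = effects,
                   learners = learners, seed = as.integer(seed),
                   nMagDays = as.integer(nMagDays),
                   maxAcqDays = as.integer(maxAcqDays),
                   minTrials = as.integer(minTrials), minRate = minRate,
                   runLength = as.integer(runLength), ageRange = ageRange,
                   dispersion = dispersion),
              class = "CohortConfig")
}

.rcount <- function(n, mu, dispersion = NULL) {
    if (is.null(dispersion)) rpois(n, mu)
    else rnbinom(n, mu = mu, size = dispersion)
}

#' Rewards earned from cued responses under the FR1/VR2 schedule
#'
#' The first 10 cued responses each earn a reward (fixed-ratio 1); further
#' rewards require a variable number of responses drawn from a geometric
#' distribution on 1, 2, ... with mean 2 (variable-ratio 2). Draws come
#' from the current RNG stream.
#'
#' @param cued Number of cued responses in the session.
#' @return Integer rewards earned (= trials completed).
#' @export
scheduleRewards <- function(cued) {
    stopifnot(length(cued) == 1, cued >= 0, cued == round(cued))
    if (cued <= 10) return(as.integer(cued))
    rem <- cued - 10
    reqs <- 1L + rgeom(rem, prob = 0.5)  # at most `rem` requirements can complete
    as.integer(10L + sum(cumsum(reqs) <= rem))
}

#' Simulate one mouse's operant sessions
#'
#' Generates magazine training, acquisition and extinction session rows for
#' a single learner. Acquisition continues until the criteria (strict
#' \code{> minTrials} trials and \code{> minRate} accuracy for
#' \code{runLength} consecutive days) are met or \code{maxAcqDays} is
#' reached; extinction always lasts 3 days with 0 rewards. A \code{primed}
#' flag marks acquisition days 1-2 and any day following a < 5-trial day.
#'
#' @param params A \code{\link{learnerParams}} object.
#' @param nMagDays Magazine-training days (>= 2).
#' @param maxAcqDays Acquisition cap (>= 5, else a criteria run is
#'   impossible).
#' @param seed Optional seed; when NULL the current RNG stream is used (as
#'   \code{\link{simulateCohort}} does).
#' @param mouse_id Mouse identifier for the output rows.
#' @param minTrials,minRate,runLength Acquisition criteria.
#' @param magRate Expected magazine pellets per training session.
#' @param primeThreshold Trial count below which the next session is primed.
#' @param dispersion Optional negative-binomial size; NULL = Poisson.
#' @return data.frame of sessions (mouse_id, phase, day, trials, cued,
#'   noncued, rewards, primed) with attribute \code{"reached"} (logical).
#' @examples
#' simulateOperantMouse(defaultLearnerParams("WT"), seed = 1)
#' @export
simulateOperantMouse <- function(params, nMagDays = 2L, maxAcqDays = 40L,
                                 seed = NULL, mouse_id = "m1",
                                 minTrials = 15L, minRate = 0.75,
                                 runLength = 5L, magRate = 20,
                                 primeThreshold = 5L, dispersion = NULL) {
    if (!inherits(params, "LearnerParams"))
        params <- do.call(learnerParams, as.list(params))
    if (nMagDays < 2) stop("at least 2 magazine-training days are required")
    if (maxAcqDays < 5)
        stop("maxAcqDays must be >= 5; a 5-day criteria run is impossible")
    if (!is.null(seed)) set.seed(seed)

    rows <- vector("list", nMagDays + maxAcqDays + 3L)
    ri <- 0L
    addRow <- function(phase, day, trials, cued, noncued, rewards, primed) {
        ri <<- ri + 1L
        rows[[ri]] <<- data.frame(
            mouse_id = mouse_id, phase = phase, day = as.integer(day),
            trials = as.integer(trials), cued = as.integer(cued),
            noncued = as.integer(noncued), rewards = as.integer(rewards),
            primed = primed, stringsAsFactors = FALSE)
    }

    for (d in seq_len(nMagDays)) {
        pellets <- .rcount(1, magRate, dispersion)
        addRow("MAG", d, pellets, 0L, 0L, pellets, FALSE)
    }

    run <- 0L
    prevTrials <- Inf
    lastMu <- 0
    for (d in seq_len(maxAcqDays)) {
        mu <- params$asymptote_cued /
            (1 + exp(-params$learning_rate * (d - params$start_day_shift)))
        cued <- .rcount(1, mu, dispersion)
        noncued <- .rcount(1, params$noncued_rate, dispersion)
        rewards <- scheduleRewards(cued)
        trials <- rewards
        primed <- d <= 2L || prevTrials < primeThreshold
        addRow("ACQ", d, trials, cued, noncued, rewards, primed)
        lastMu <- mu
        pass <- trials > minTrials && (cued + noncued) > 0 &&
            cued / (cued + noncued) > minRate
        run <- if (pass) run + 1L else 0L
        prevTrials <- trials
        if (run >= runLength) break
    }

    for (d in 1:3) {
        mu <- params$burst_gain * lastMu * params$extinction_decay^(d - 1)
        cued <- .rcount(1, mu, dispersion)
        noncued <- .rcount(1, params$noncued_rate, dispersion)
        addRow("EXT", d, 0L, cued, noncued, 0L, FALSE)
    }

    out <- do.call(rbind, rows[seq_len(ri)])
    attr(out, "reached") <- run >= runLength
    out
}

#' Simulate a full behavioral cohort
#'
#' Draws the roster (genotype x sex x cohort cells with configured sizes and
#' uniform ages), the battery table (independent normal measures with the
#' configured standardized genotype and sex shifts), and per-mouse operant
#' session logs. Deterministic given the config seed.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @return A \linkS4class{BehaviorCohort}.
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 11))
#' coh
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    set.seed(config$seed)

    gs <- config$groupSizes
    roster <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i) {
        n <- gs$n[i]
        if (n == 0) return(NULL)
        data.frame(genotype = rep(gs$genotype[i], n),
                   sex = rep(gs$sex[i], n),
                   cohort = rep(as.character(gs$cohort[i]), n),
                   stringsAsFactors = FALSE)
    }))
    roster$mouse_id <- sprintf("C%s_%s%s_%02d", roster$cohort,
                               roster$genotype, roster$sex,
                               ave(seq_len(nrow(roster)),
                                   paste(roster$cohort, roster$genotype,
                                         roster$sex),
                                   FUN = seq_along))
    roster$age_days <- vapply(roster$cohort, function(co) {
        r <- config$ageRange[[co]]
        as.integer(sample(seq(r[1], r[2]), 1))
    }, integer(1))
    roster <- roster[, c("mouse_id", "genotype", "sex", "cohort", "age_days")]

    battery <- simulateBattery(roster, config$effects)

    learners <- config$learners
    sess <- vector("list", nrow(roster))
    reached <- logical(nrow(roster))
    for (i in seq_len(nrow(roster))) {
        s <- simulateOperantMouse(
            learners[[roster$genotype[i]]],
            nMagDays = config$nMagDays, maxAcqDays = config$maxAcqDays,
            mouse_id = roster$mouse_id[i],
            minTrials = config$minTrials, minRate = config$minRate,
            runLength = config$runLength, dispersion = config$dispersion)
        reached[i] <- attr(s, "reached")
        sess[[i]] <- s
    }
    sessions <- do.call(rbind, sess)
    rownames(sessions) <- NULL

    coh <- BehaviorCohort(battery, roster, sessions)
    metadata(coh)$config <- config
    metadata(coh)$reached <- stats::setNames(reached, roster$mouse_id)
    coh
}

#' Simulate the battery table alone
#'
#' Draws one value per mouse and measure from the configured normal model:
#' \code{Normal(control_mean + I(AS) d sd + I(F) sex_d sd, sd)}. Measures
#' are independent by default; an optional correlation matrix induces a
#' shared Gaussian copula across measures.
#'
#' @param roster data.frame with at least \code{mouse_id}, \code{genotype},
#'   \code{sex}.
#' @param effects Effect table (rbind of \code{\link{effectSpec}} rows).
#' @param seed Optional seed; NULL uses the current stream.
#' @param correlation Optional measures x measures correlation matrix.
#' @return Numeric matrix, measures x mice.
#' @export
simulateBattery <- function(roster, effects, seed = NULL,
                            correlation = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (any(effects$control_sd <= 0))
        stop("control_sd must be positive for all measures")
    n <- nrow(roster)
    p <- nrow(effects)
    if (is.null(correlation)) {
        z <- matrix(rnorm(p * n), nrow = p)
    } else {
        stopifnot(identical(dim(correlation), c(p, p)))
        ch <- chol(correlation)
        z <- t(ch) %*% matrix(rnorm(p * n), nrow = p)
    }
    gi <- as.numeric(roster$genotype == "AS")
    si <- as.numeric(roster$sex == "F")
    bat <- matrix(NA_real_, nrow = p, ncol = n,
                  dimnames = list(effects$measure_name, roster$mouse_id))
    for (j in seq_len(p)) {
        e <- effects[j, ]
        mu <- e$control_mean + gi * e$cohens_d * e$control_sd +
            si * e$sex_d * e$control_sd
        bat[j, ] <- mu + e$control_sd * z[j, ]
    }
    bat
}
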
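## Scoring of operant session logs: accuracy, criteria detection,
## at-criteria summaries, acquisition-normalized extinction.

#' Cued response accuracy
#'
#' Accuracy of a session is the cued response rate,
#' \code{cued / (cued + noncued)}. Undefined when no responses were made.
#'
#' @param cued,noncued Nonnegative response counts (vectorized).
#' @return Accuracy in [0, 1].
#' @examples
#' responseAccuracy(30, 10)  # 0.75
#' @export
responseAccuracy <- function(cued, noncued) {
    stopifnot(length(cued) == length(noncued))
    if (any(cued < 0 | noncued < 0))
        stop("response counts must be nonnegative")
    if (any(cued + noncued == 0))
        stop("accuracy undefined: session with no responses ",
             "(cued + noncued = 0)")
    cued / (cued + noncued)
}

.dayPasses <- function(trials, cued, noncued, minTrials, minRate) {
    # a no-response day has undefined accuracy and cannot pass
    acc <- ifelse(cued + noncued == 0, -Inf, cued / (cued + noncued))
    trials > minTrials & acc > minRate
}

#' Detect acquisition criteria
#'
#' A day passes when the mouse completes strictly more than \code{minTrials}
#' trials and its accuracy strictly exceeds \code{minRate}; criteria are met
#' on the first run of \code{runLength} consecutive passing days.
#' \code{days_to_criteria} is the last day of that run, i.e. the total
#' number of acquisition days before advancing to extinction. The procedural
#' default threshold is 0.75 (the protocol's ">75% cued response rate").
#'
#' @param acq data.frame of acquisition sessions for one mouse, sorted by
#'   day and contiguous, with columns \code{day}, \code{trials},
#'   \code{cued}, \code{noncued}.
#' @param minTrials Trial threshold (strict >).
#' @param minRate Accuracy threshold (strict >).
#' @param runLength Required consecutive passing days.
#' @return List with \code{days_to_criteria} (integer, or \code{NA} when
#'   never reached) and \code{criterion_days} (the \code{runLength} day
#'   indices of the first qualifying run, or NULL).
#' @examples
#' acq <- data.frame(day = 1:6, trials = c(10, 20, 20, 20, 20, 20),
#'                   cued = 80, noncued = 20)
#' detectCriteria(acq)  # reached on day 6, criterion days 2..6
#' @export
detectCriteria <- function(acq, minTrials = 15L, minRate = 0.75,
                           runLength = 5L) {
    acq <- as.data.frame(acq)
    notReached <- list(days_to_criteria = NA_integer_, criterion_days = NULL)
    n <- nrow(acq)
    if (n < runLength) return(notReached)
    if (is.unsorted(acq$day, strictly = TRUE))
        stop("acquisition sessions must be sorted by day")
    if (!identical(as.integer(acq$day), seq_len(n)))
        stop("acquisition days must be contiguous from 1")
    pass <- .dayPasses(acq$trials, acq$cued, acq$noncued, minTrials, minRate)
    run <- 0L
    for (i in seq_len(n)) {
        run <- if (pass[i]) run + 1L else 0L
        if (run >= runLength) {
            days <- acq$day[(i - runLength + 1L):i]
            return(list(days_to_criteria = as.integer(acq$day[i]),
                        criterion_days = as.integer(days)))
        }
    }
    notReached
}

#' Acquisition summary at criteria
#'
#' Mean cued responses, non-cued responses and accuracy over the five
#' criterion days (which are, by protocol, the last five days of
#' acquisition). Accuracy defaults to the mean of daily accuracies;
#' \code{accuracyMethod = "pooled"} instead pools the counts across the run
#' (\code{sum(cued) / sum(cued + noncued)}).
#'
#' @param acq Acquisition data.frame (columns \code{day}, \code{trials},
#'   \code{cued}, \code{noncued}).
#' @param criterionDays Day indices of the criterion run (from
#'   \code{\link{detectCriteria}}), or NULL for a mouse that never reached
#'   criteria.
#' @param mouse_id Identifier carried into the output.
#' @param accuracyMethod "days" (mean of daily accuracies, default) or
#'   "pooled".
#' @return One-row data.frame: \code{mouse_id}, \code{days_to_criteria},
#'   \code{cued_at_criteria}, \code{noncued_at_criteria},
#'   \code{accuracy_at_criteria}, \code{reached}. Not-reached mice carry
#'   \code{NA} in all at-criteria fields.
#' @export
acquisitionAtCriteria <- function(acq, criterionDays, mouse_id = "m1",
                                  accuracyMethod = c("days", "pooled")) {
    accuracyMethod <- match.arg(accuracyMethod)
    if (is.null(criterionDays) || all(is.na(criterionDays)))
        return(data.frame(mouse_id = mouse_id,
                          days_to_criteria = NA_integer_,
                          cued_at_criteria = NA_real_,
                          noncued_at_criteria = NA_real_,
                          accuracy_at_criteria = NA_real_,
                          reached = FALSE, stringsAsFactors = FALSE))
    if (length(criterionDays) != 5L)
        stop("criterionDays must contain exactly 5 day indices")
    acq <- as.data.frame(acq)
    sel <- acq[match(criterionDays, acq$day), ]
    if (any(is.na(sel$day)))
        stop("criterionDays not all present in the acquisition sessions")
    accuracy <- if (accuracyMethod == "days")
        mean(responseAccuracy(sel$cued, sel$noncued))
    else
        sum(sel$cued) / sum(sel$cued + sel$noncued)
    data.frame(mouse_id = mouse_id,
               days_to_criteria = as.integer(max(criterionDays)),
               cued_at_criteria = mean(sel$cued),
               noncued_at_criteria = mean(sel$noncued),
               accuracy_at_criteria = accuracy,
               reached = TRUE, stringsAsFactors = FALSE)
}

#' Normalize extinction responding to an acquisition baseline
#'
#' Cued and non-cued counts on each of the three extinction days are divided
#' by the group-average responding over the last five days of acquisition
#' (the criterion run); accuracy is computed from the raw counts and is not
#' normalized. Values above 1 on day 1 represent an extinction burst.
#'
#' @param ext data.frame of exactly 3 extinction sessions (columns
#'   \code{day} in 1..3, \code{cued}, \code{noncued}).
#' @param baselineCued,baselineNoncued Positive group-average baselines.
#' @param mouse_id Identifier carried into the output.
#' @return One-row data.frame: \code{norm_cued_E1..E3},
#'   \code{norm_noncued_E1..E3}, \code{accuracy_E1..E3}.
#' @examples
#' ext <- data.frame(day = 1:3, cued = c(20, 10, 5), noncued = c(5, 5, 5))
#' normalizeExtinction(ext, baselineCued = 20, baselineNoncued = 5)
#' @export
normalizeExtinction <- function(ext, baselineCued, baselineNoncued,
                                mouse_id = "m1") {
    ext <- as.data.frame(ext)
    if (!is.finite(baselineCued) || baselineCued <= 0 ||
        !is.finite(baselineNoncued) || baselineNoncued <= 0)
        stop("group acquisition baselines must be positive ",
             "(mouse '", mouse_id, "')")
    if (nrow(ext) != 3L || !setequal(ext$day, 1:3))
        stop("exactly 3 extinction days (1, 2, 3) are required ",
             "(mouse '", mouse_id, "')")
    ext <- ext[order(ext$day), ]
    acc <- ifelse(ext$cued + ext$noncued == 0, NA_real_,
                  ext$cued / (ext$cued + ext$noncued))
    out <- data.frame(mouse_id = mouse_id, stringsAsFactors = FALSE)
    out[paste0("norm_cued_E", 1:3)] <- as.list(ext$cued / baselineCued)
    out[paste0("norm_noncued_E", 1:3)] <- as.list(ext$noncued / baselineNoncued)
    out[paste0("accuracy_E", 1:3)] <- as.list(acc)
    out
}

#' Derived operant metrics for a whole cohort
#'
#' Runs criteria detection, at-criteria summaries and acquisition-normalized
#' extinction for every mouse. Extinction baselines are the group averages
#' of the at-criteria cued and non-cued responding, where "group" defaults
#' to genotype (sexes and cohorts pooled); mice that never reached criteria
#' contribute neither to the baselines nor receive at-criteria values
#' (\code{NA} propagates, nothing is imputed).
#'
#' @param x A \linkS4class{BehaviorCohort}, or a session data.frame.
#' @param roster Roster data.frame (required when \code{x} is a
#'   data.frame); must contain \code{mouse_id} and the \code{groupBy}
#'   column.
#' @param groupBy Roster column defining the extinction-normalization
#'   group (default \code{"genotype"}).
#' @param minTrials,minRate,runLength Acquisition criteria.
#' @param accuracyMethod Passed to \code{\link{acquisitionAtCriteria}}.
#' @return data.frame, one row per mouse: \code{mouse_id},
#'   \code{days_to_criteria}, \code{cued_at_criteria},
#'   \code{noncued_at_criteria}, \code{accuracy_at_criteria},
#'   \code{norm_cued_E1..E3}, \code{norm_noncued_E1..E3},
#'   \code{accuracy_E1..E3}, \code{reached}.
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 7))
#' head(summarizeOperant(coh))
#' @export
setGeneric("summarizeOperant", function(x, ...)
    standardGeneric("summarizeOperant"))

#' @rdname summarizeOperant
#' @param ... passed between methods.
#' @export
setMethod("summarizeOperant", "BehaviorCohort", function(x, ...) {
    summarizeOperant(sessions(x), roster = roster(x), ...)
})

#' @rdname summarizeOperant
#' @export
setMethod("summarizeOperant", "data.frame",
function(x, roster, groupBy = "genotype", minTrials = 15L, minRate = 0.75,
         runLength = 5L, accuracyMethod = c("days", "pooled"), ...) {
    accuracyMethod <- match.arg(accuracyMethod)
    msg <- .validateSessions(x)
    if (!is.null(msg)) stop(msg)
    if (!groupBy %in% names(roster))
        stop("grouping column '", groupBy, "' not found in the roster")
    ids <- roster$mouse_id
    grp <- as.character(roster[[groupBy]])

    acqSummaries <- do.call(rbind, lapply(seq_along(ids), function(i) {
        acq <- x[x$mouse_id == ids[i] & x$phase == "ACQ", , drop = FALSE]
        acq <- acq[order(acq$day), ]
        crit <- detectCriteria(acq, minTrials, minRate, runLength)
        acquisitionAtCriteria(acq, crit$criterion_days, mouse_id = ids[i],
                              accuracyMethod = accuracyMethod)
    }))

    # group baselines: mean at-criteria responding among mice that reached
    baseCued <- tapply(acqSummaries$cued_at_criteria, grp,
                       mean, na.rm = TRUE)
    baseNoncued <- tapply(acqSummaries$noncued_at_criteria, grp,
                          mean, na.rm = TRUE)

    extSummaries <- do.call(rbind, lapply(seq_along(ids), function(i) {
        ext <- x[x$mouse_id == ids[i] & x$phase == "EXT", , drop = FALSE]
        g <- grp[i]
        if (!is.finite(baseCued[[g]]) || baseCued[[g]] <= 0 ||
            !is.finite(baseNoncued[[g]]) || baseNoncued[[g]] <= 0)
            stop("acquisition baseline for group '", g,
                 "' is zero or undefined; cannot normalize extinction")
        normalizeExtinction(ext, baseCued[[g]], baseNoncued[[g]],
                            mouse_id = ids[i])
    }))

    out <- merge(acqSummaries, extSummaries, by = "mouse_id", sort = FALSE)
    reached <- out$reached
    out$reached <- NULL
    out$reached <- reached
    out[match(ids, out$mouse_id), , drop = FALSE]
})
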
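## CSV formats: session logs, battery/roster tables, whole-cohort
## read/write, and the run configuration (YAML).

.BATTERY_HEADER <- c("mouse_id", "genotype", "sex", "cohort", "age_days",
                     "weight", "rotarod_d1", "rotarod_d5", "of_distance",
                     "of_center_time", "marbles_buried", "nest_used_d5")

#' Read an operant session log
#'
#' Reads and validates a session CSV (columns \code{mouse_id, phase, day,
#' trials, cued, noncued, rewards, primed}; \code{primed} optional,
#' defaults to 0). Per-day exports from operant-chamber software with other
#' column names can be mapped via \code{columnMap}. Validation enforces the
#' session invariants — phases in MAG/ACQ/EXT, nonnegative integer counts,
#' extinction rewards 0, days contiguous from 1 per mouse and phase — and
#' cites the offending row.
#'
#' @param path CSV file path.
#' @param columnMap Optional named character vector mapping required names
#'   to the file's column names, e.g. \code{c(cued = "CuedPokes")}.
#' @return Validated session data.frame.
#' @export
readSessionLog <- function(path, columnMap = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(columnMap)) {
        for (std in names(columnMap)) {
            src <- columnMap[[std]]
            if (!src %in% names(raw))
                stop("mapped column '", src, "' (for '", std,
                     "') not found in ", path)
            names(raw)[names(raw) == src] <- std
        }
    }
    if (!"primed" %in% names(raw)) raw$primed <- 0L
    missing <- setdiff(.SESSION_COLS, names(raw))
    if (length(missing) > 0)
        stop("session log lacks columns: ", paste(missing, collapse = ", "))
    raw <- raw[, .SESSION_COLS]
    raw$primed <- as.logical(raw$primed)
    for (cc in c("day", "trials", "cued", "noncued", "rewards"))
        raw[[cc]] <- as.integer(raw[[cc]])
    msg <- .validateSessions(raw)
    if (!is.null(msg)) stop("invalid session log ", path, ": ", msg)
    raw
}

#' Write an operant session log
#'
#' @param sessions Session data.frame (validated before writing).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSessionLog <- function(sessions, path) {
    sessions <- as.data.frame(sessions)
    msg <- .validateSessions(sessions)
    if (!is.null(msg)) stop("refusing to write invalid sessions: ", msg)
    out <- sessions[, .SESSION_COLS]
    out$primed <- as.integer(out$primed)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write the combined roster + battery table
#'
#' One row per mouse with the fixed header \code{mouse_id, genotype, sex,
#' cohort, age_days, weight, rotarod_d1, rotarod_d5, of_distance,
#' of_center_time, marbles_buried, nest_used_d5}.
#'
#' @param path CSV path.
#' @return data.frame with the fixed columns.
#' @export
readBattery <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(cohort = "character"))
    missing <- setdiff(.BATTERY_HEADER, names(tab))
    if (length(missing) > 0)
        stop("battery table lacks columns: ",
             paste(missing, collapse = ", "))
    tab[, .BATTERY_HEADER]
}

#' @rdname readBattery
#' @param cohort A \linkS4class{BehaviorCohort}.
#' @export
writeBattery <- function(cohort, path) {
    tab <- cbind(roster(cohort), as.data.frame(t(batteryMatrix(cohort))))
    tab <- tab[, .BATTERY_HEADER[.BATTERY_HEADER %in% names(tab)]]
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write / read a whole cohort as plain CSV files
#'
#' \code{writeCohort} writes \code{battery.csv} (roster + battery, fixed
#' header) and \code{sessions.csv} into a directory; \code{readCohort}
#' reconstructs the \linkS4class{BehaviorCohort}.
#'
#' @param cohort A \linkS4class{BehaviorCohort}.
#' @param dir Directory (created if absent).
#' @return \code{writeCohort}: the directory, invisibly;
#'   \code{readCohort}: a \linkS4class{BehaviorCohort}.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeBattery(cohort, file.path(dir, "battery.csv"))
    writeSessionLog(sessions(cohort), file.path(dir, "sessions.csv"))
    invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
    tab <- readBattery(file.path(dir, "battery.csv"))
    roster <- tab[, c("mouse_id", "genotype", "sex", "cohort", "age_days")]
    bat <- t(as.matrix(tab[, batteryMeasureNames()]))
    colnames(bat) <- tab$mouse_id
    sess <- readSessionLog(file.path(dir, "sessions.csv"))
    BehaviorCohort(bat, roster, sess)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline: cohort simulation, operant
#' scoring thresholds, phenotyping options and power-analysis options.
#' Serializes to YAML and round-trips losslessly.
#'
#' @param seed Master seed (mandatory).
#' @param groupSizes,effects Passed to \code{\link{cohortConfig}}.
#' @param nMagDays,maxAcqDays Cohort simulation settings.
#' @param minTrials,minRate,runLength Operant criteria thresholds.
#' @param sexSplit Measures to sex-split, or "auto".
#' @param includeOperant Run the operant-inclusive phenotyping too.
#' @param nRestarts k-means restarts.
#' @param grid,iterations,alpha,powers Power-analysis settings.
#' @return List of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed,
                      groupSizes = defaultGroupSizes(),
                      effects = defaultEffectSpecs(),
                      nMagDays = 2L, maxAcqDays = 40L,
                      minTrials = 15L, minRate = 0.75, runLength = 5L,
                      sexSplit = "auto", includeOperant = TRUE,
                      nRestarts = 50L,
                      grid = 4:30, iterations = 10000L,
                      alpha = 0.05, powers = c(0.8, 0.9, 0.95)) {
    if (missing(seed) || is.null(seed)) stop("seed is mandatory")
    structure(list(
        seed = as.integer(seed),
        cohort = list(groupSizes = as.data.frame(groupSizes),
                      effects = as.data.frame(effects),
                      nMagDays = as.integer(nMagDays),
                      maxAcqDays = as.integer(maxAcqDays)),
        operant = list(minTrials = as.integer(minTrials),
                       minRate = minRate, runLength = as.integer(runLength)),
        phenotyping = list(sexSplit = sexSplit,
                           includeOperant = includeOperant,
                           nRestarts = as.integer(nRestarts)),
        power = list(grid = as.integer(grid), iterations = as.integer(iterations),
                     alpha = alpha, powers = powers)),
        class = "RunConfig")
}

#' @rdname runConfig
#' @param config A \code{"RunConfig"}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    obj <- unclass(config)
    obj$cohort$groupSizes <- as.list(config$cohort$groupSizes)
    obj$cohort$effects <- as.list(config$cohort$effects)
    yaml::write_yaml(obj, path, precision = 15)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    obj <- yaml::read_yaml(path)
    ss <- unlist(obj$phenotyping$sexSplit)
    if (is.null(ss)) ss <- character()
    obj$phenotyping$sexSplit <- ss
    runConfig(seed = obj$seed,
              groupSizes = as.data.frame(obj$cohort$groupSizes),
              effects = as.data.frame(obj$cohort$effects),
              nMagDays = obj$cohort$nMagDays,
              maxAcqDays = obj$cohort$maxAcqDays,
              minTrials = obj$operant$minTrials,
              minRate = obj$operant$minRate,
              runLength = obj$operant$runLength,
              sexSplit = obj$phenotyping$sexSplit,
              includeOperant = obj$phenotyping$includeOperant,
              nRestarts = obj$phenotyping$nRestarts,
              grid = obj$power$grid,
              iterations = obj$power$iterations,
              alpha = obj$power$alpha,
              powers = obj$power$powers)
}
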
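#' @import methods
#' @importFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

.GENOTYPES <- c("WT", "AS")
.SEXES <- c("M", "F")
.COHORTS <- c("1", "2")
.PHASES <- c("MAG", "ACQ", "EXT")

#' Fixed column order of the battery table
#'
#' The seven standard battery measures, in the canonical file/column order
#' used throughout the package: body weight (g), rotarod latency to fall on
#' days 1 and 5 (s), open-field distance travelled (m) and center time (s),
#' marbles buried (count), and nest material used by day 5 (g).
#'
#' @return Character vector of measure names.
#' @export
batteryMeasureNames <- function() {
    c("weight", "rotarod_d1", "rotarod_d5", "of_distance",
      "of_center_time", "marbles_buried", "nest_used_d5")
}

.SESSION_COLS <- c("mouse_id", "phase", "day", "trials", "cued", "noncued",
                   "rewards", "primed")

.validateSessions <- function(sessions) {
    sessions <- as.data.frame(sessions)
    missing <- setdiff(.SESSION_COLS, names(sessions))
    if (length(missing) > 0)
        return(paste0("session table lacks columns: ",
                      paste(missing, collapse = ", ")))
    if (!all(sessions$phase %in% .PHASES))
        return("session phase must be one of MAG, ACQ, EXT")
    counts <- c("day", "trials", "cued", "noncued", "rewards")
    for (cc in counts) {
        v <- sessions[[cc]]
        if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
            return(paste0("session column '", cc,
                          "' must hold nonnegative integers"))
    }
    if (any(sessions$day < 1))
        return("session days are 1-based within each phase")
    bad <- sessions$phase == "EXT" & sessions$rewards > 0
    if (any(bad))
        return(paste0("extinction sessions must have 0 rewards (row ",
                      which(bad)[1], ")"))
    if (any(sessions$phase == "EXT" & !(sessions$day %in% 1:3)))
        return("extinction days must lie in 1..3")
    # days contiguous from 1 within mouse x phase
    key <- paste(sessions$mouse_id, sessions$phase, sep = "\r")
    for (k in unique(key)) {
        d <- sort(sessions$day[key == k])
        if (!identical(as.integer(d), seq_along(d)))
            return(paste0("days not contiguous from 1 for mouse '",
                          sub("\r.*", "", k), "' phase ",
                          sub(".*\r", "", k)))
    }
    NULL
}

#' BehaviorCohort: container for one behavioral cohort
#'
#' A \linkS4class{SummarizedExperiment} holding the battery measurements
#' (assay \code{"battery"}: measures in rows, mice in columns), the mouse
#' roster as \code{colData} (\code{mouse_id}, \code{genotype}, \code{sex},
#' \code{cohort}, \code{age_days}), and the per-mouse-per-day operant session
#' log in the \code{sessions} slot.
#'
#' @slot sessions A \code{DataFrame} of operant sessions, one row per mouse
#'   and day, with columns \code{mouse_id}, \code{phase} (MAG/ACQ/EXT),
#'   \code{day} (1-based within phase), \code{trials}, \code{cued},
#'   \code{noncued}, \code{rewards}, \code{primed}.
#'
#' @seealso \code{\link{simulateCohort}}, \code{\link{summarizeOperant}},
#'   \code{\link{phenotype}}
#' @export
setClass("BehaviorCohort",
    contains = "SummarizedExperiment",
    representation(sessions = "DataFrame"))

setValidity("BehaviorCohort", function(object) {
    cd <- colData(object)
    need <- c("mouse_id", "genotype", "sex", "cohort", "age_days")
    missing <- setdiff(need, names(cd))
    if (length(missing) > 0)
        return(paste0("colData lacks: ", paste(missing, collapse = ", ")))
    if (!"battery" %in% assayNames(object))
        return("assay 'battery' is required")
    if (anyDuplicated(paste(cd$mouse_id, cd$cohort)))
        return("mouse_id must be unique within a cohort")
    if (!all(as.character(cd$genotype) %in% .GENOTYPES))
        return("genotype must be WT or AS")
    if (!all(as.character(cd$sex) %in% .SEXES))
        return("sex must be M or F")
    if (!all(as.character(cd$cohort) %in% .COHORTS))
        return("cohort must be 1 or 2")
    if (any(cd$age_days <= 0))
        return("age_days must be positive")
    if (nrow(object@sessions) > 0) {
        msg <- .validateSessions(object@sessions)
        if (!is.null(msg)) return(msg)
        extra <- setdiff(unique(object@sessions$mouse_id), cd$mouse_id)
        if (length(extra) > 0)
            return(paste0("sessions reference unknown mice: ",
                          paste(extra, collapse = ", ")))
    }
    TRUE
})

#' Construct a BehaviorCohort
#'
#' @param battery Numeric matrix of battery measurements, either measures x
#'   mice or mice x measures (detected from dimnames against the roster).
#' @param roster data.frame with columns \code{mouse_id}, \code{genotype},
#'   \code{sex}, \code{cohort}, \code{age_days}.
#' @param sessions data.frame of operant sessions (may be empty); see
#'   \linkS4class{BehaviorCohort}.
#'
#' @return A \linkS4class{BehaviorCohort}.
#' @examples
#' ros <- data.frame(mouse_id = c("m1", "m2"), genotype = c("WT", "AS"),
#'                   sex = c("M", "F"), cohort = "1", age_days = 90L)
#' bat <- matrix(rnorm(14), nrow = 7,
#'               dimnames = list(batteryMeasureNames(), ros$mouse_id))
#' BehaviorCohort(bat, ros)
#' @export
BehaviorCohort <- function(battery, roster, sessions = NULL) {
    roster <- as.data.frame(roster)
    if (!is.null(colnames(battery)) &&
        !all(roster$mouse_id %in% colnames(battery)) &&
        all(roster$mouse_id %in% rownames(battery)))
        battery <- t(battery)
    if (is.null(colnames(battery)))
        colnames(battery) <- roster$mouse_id
    battery <- battery[, roster$mouse_id, drop = FALSE]
    if (is.null(sessions))
        sessions <- data.frame(mouse_id = character(), phase = character(),
                               day = integer(), trials = integer(),
                               cued = integer(), noncued = integer(),
                               rewards = integer(), primed = logical())
    roster$genotype <- factor(as.character(roster$genotype),
                              levels = .GENOTYPES)
    roster$sex <- factor(as.character(roster$sex), levels = .SEXES)
    roster$cohort <- factor(as.character(roster$cohort), levels = .COHORTS)
    se <- SummarizedExperiment(
        assays = list(battery = battery),
        colData = DataFrame(roster, row.names = roster$mouse_id))
    new("BehaviorCohort", se, sessions = DataFrame(as.data.frame(sessions)))
}

#' PhenotypeResult: multidimensional phenotyping output
#'
#' Holds the standardized-feature PCA (scores, loadings, variance explained),
#' the k-means cluster labels and genotype-validation accuracy, and the
#' genotype centroids and centroid distance in two-PC space. PC1 of the
#' battery serves as a composite behavioral severity score.
#'
#' @slot scores mice x components PC score matrix.
#' @slot loadings measures x components loading matrix (unit-norm columns,
#'   sign fixed so the largest-magnitude loading of each component is
#'   positive).
#' @slot varianceExplained fraction of variance per retained component.
#' @slot clusterLabels integer k-means cluster per mouse (1-based).
#' @slot genotype true genotype factor used for validation.
#' @slot accuracy fraction of mice whose cluster matches genotype under the
#'   best label permutation.
#' @slot centroids 2 x 2 matrix (rows WT, AS) of genotype mean positions in
#'   2-PC space, computed from true genotypes.
#' @slot centroidDistance Euclidean distance between the genotype centroids.
#' @slot sexSplit measures that were z-scored within sex.
#' @slot droppedMice mice excluded for missing operant metrics.
#' @export
setClass("PhenotypeResult", representation(
    scores = "matrix",
    loadings = "matrix",
    varianceExplained = "numeric",
    clusterLabels = "integer",
    genotype = "factor",
    accuracy = "numeric",
    centroids = "matrix",
    centroidDistance = "numeric",
    sexSplit = "character",
    droppedMice = "character"))

setValidity("PhenotypeResult", function(object) {
    n <- nrow(object@scores)
    if (length(object@clusterLabels) != n || length(object@genotype) != n)
        return("scores, clusterLabels and genotype disagree on mouse count")
    if (object@accuracy < 0.5 - 1e-12 || object@accuracy > 1)
        return("accuracy must lie in [0.5, 1] after label alignment")
    if (object@centroidDistance < 0)
        return("centroidDistance must be nonnegative")
    if (!identical(dim(object@centroids), c(2L, 2L)))
        return("centroids must be a 2 x 2 matrix")
    TRUE
})

#' SampleSizeTable: per-measure minimum sample sizes by power level
#'
#' Machine twin of a sample-size planning table: one row per behavioral
#' measure with its pooled Cohen's d and the minimum per-group n reaching
#' each target power on the search grid (Inf when no grid n suffices,
#' rendered as e.g. ">30").
#'
#' @slot table data.frame with columns \code{measure}, \code{cohens_d}, and
#'   one \code{n_<power>} column per target power (numeric; Inf = beyond
#'   grid).
#' @slot curves named list of data.frames (\code{n}, \code{power},
#'   \code{power_smoothed}) per measure.
#' @slot grid integer grid of candidate per-group sample sizes.
#' @slot alpha significance level of the two-sample t-test.
#' @slot powers target power levels.
#' @slot iterations Monte-Carlo iterations per grid point.
#' @slot seed master seed.
#' @export
setClass("SampleSizeTable", representation(
    table = "data.frame",
    curves = "list",
    grid = "integer",
    alpha = "numeric",
    powers = "numeric",
    iterations = "integer",
    seed = "integer"))

setValidity("SampleSizeTable", function(object) {
    ncols <- grep("^n_", names(object@table), value = TRUE)
    if (length(ncols) != length(object@powers))
        return("one n_ column per target power is required")
    for (i in seq_len(nrow(object@table))) {
        v <- as.numeric(object@table[i, ncols])
        v[is.infinite(v)] <- .Machine$integer.max  # sentinel ordering: ">30" > 30
        if (any(diff(v[!is.na(v)]) < 0))
            return("minimum n must be nondecreasing in target power")
    }
    TRUE
})
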
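#' @rdname BehaviorCohort-class
#' @param object,x A \linkS4class{BehaviorCohort}.
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))

#' @rdname BehaviorCohort-class
#' @export
setMethod("sessions", "BehaviorCohort",
          function(x) as.data.frame(x@sessions))

#' @rdname BehaviorCohort-class
#' @export
setGeneric("batteryMatrix", function(x) standardGeneric("batteryMatrix"))

#' @rdname BehaviorCohort-class
#' @export
setMethod("batteryMatrix", "BehaviorCohort",
          function(x) assay(x, "battery"))

#' @rdname BehaviorCohort-class
#' @export
setGeneric("roster", function(x) standardGeneric("roster"))

#' @rdname BehaviorCohort-class
#' @export
setMethod("roster", "BehaviorCohort",
          function(x) as.data.frame(colData(x))[
              , c("mouse_id", "genotype", "sex", "cohort", "age_days")])

#' @rdname BehaviorCohort-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname BehaviorCohort-class
#' @export
setMethod("genotypes", "BehaviorCohort", function(x) colData(x)$genotype)

setMethod("show", "BehaviorCohort", function(object) {
    cd <- colData(object)
    cat("BehaviorCohort with", ncol(object), "mice,",
        nrow(object), "battery measures\n")
    tab <- table(genotype = cd$genotype, sex = cd$sex)
    cat("  genotype x sex:\n")
    print(tab)
    ns <- nrow(object@sessions)
    if (ns > 0) {
        ph <- table(object@sessions$phase)
        cat("  operant sessions:", ns, "rows (",
            paste(names(ph), as.integer(ph), sep = "=", collapse = ", "),
            ")\n")
    } else {
        cat("  operant sessions: none\n")
    }
})

## ---- PhenotypeResult accessors ----

#' @rdname PhenotypeResult-class
#' @param x,object A \linkS4class{PhenotypeResult}.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("pcScores", "PhenotypeResult", function(x) x@scores)

#' @rdname PhenotypeResult-class
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("pcLoadings", "PhenotypeResult", function(x) x@loadings)

#' @rdname PhenotypeResult-class
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("varianceExplained", "PhenotypeResult",
          function(x) x@varianceExplained)

#' @rdname PhenotypeResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("clusterLabels", "PhenotypeResult", function(x) x@clusterLabels)

#' @rdname PhenotypeResult-class
#' @export
setGeneric("clusterAccuracy", function(x) standardGeneric("clusterAccuracy"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("clusterAccuracy", "PhenotypeResult", function(x) x@accuracy)

#' @rdname PhenotypeResult-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("centroids", "PhenotypeResult", function(x) x@centroids)

#' @rdname PhenotypeResult-class
#' @export
setGeneric("centroidDistance", function(x) standardGeneric("centroidDistance"))

#' @rdname PhenotypeResult-class
#' @export
setMethod("centroidDistance", "PhenotypeResult",
          function(x) x@centroidDistance)

#' Composite severity score (PC1)
#'
#' Returns the first-PC score of each mouse on the standardized feature
#' matrix. With the battery measures this is the composite behavioral
#' severity score; its orientation follows the largest-loading-positive sign
#' convention and should be interpreted against the loading table.
#'
#' @param x A \linkS4class{PhenotypeResult}.
#' @return Named numeric vector of PC1 scores.
#' @export
setGeneric("severityScore", function(x) standardGeneric("severityScore"))

#' @rdname severityScore
#' @export
setMethod("severityScore", "PhenotypeResult", function(x) x@scores[, 1])

setMethod("show", "PhenotypeResult", function(object) {
    cat("PhenotypeResult:", nrow(object@scores), "mice,",
        nrow(object@loadings), "measures,",
        ncol(object@scores), "components\n")
    cat(sprintf("  variance explained: %s\n",
        paste(sprintf("PC%d %.1f%%", seq_along(object@varianceExplained),
                      100 * object@varianceExplained), collapse = ", ")))
    cat(sprintf("  genotype clustering accuracy: %.1f%%\n",
                100 * object@accuracy))
    cat(sprintf("  centroid distance (2-PC space): %.3f\n",
                object@centroidDistance))
    if (length(object@sexSplit) > 0)
        cat("  sex-split measures:",
            paste(object@sexSplit, collapse = ", "), "\n")
    if (length(object@droppedMice) > 0)
        cat("  dropped mice:", length(object@droppedMice), "\n")
})

## ---- SampleSizeTable accessors ----

#' @rdname SampleSizeTable-class
#' @param x,object A \linkS4class{SampleSizeTable}.
#' @param rendered If TRUE, beyond-grid cells are rendered as ">max(grid)"
#'   character strings (table layout used in print); otherwise numeric with
#'   Inf sentinels.
#' @export
setGeneric("sampleSizes",
           function(x, rendered = FALSE) standardGeneric("sampleSizes"))

#' @rdname SampleSizeTable-class
#' @export
setMethod("sampleSizes", "SampleSizeTable", function(x, rendered = FALSE) {
    tab <- x@table
    if (rendered) {
        over <- paste0(">", max(x@grid))
        for (cc in grep("^n_", names(tab), value = TRUE))
            tab[[cc]] <- ifelse(is.infinite(tab[[cc]]), over,
                                as.character(tab[[cc]]))
    }
    tab
})

#' @rdname SampleSizeTable-class
#' @export
setGeneric("powerCurves", function(x) standardGeneric("powerCurves"))

#' @rdname SampleSizeTable-class
#' @export
setMethod("powerCurves", "SampleSizeTable", function(x) x@curves)

setMethod("show", "SampleSizeTable", function(object) {
    cat(sprintf(
        "SampleSizeTable: %d measures, n grid %d..%d, alpha = %g, %d iterations\n",
        nrow(object@table), min(object@grid), max(object@grid),
        object@alpha, object@iterations))
    print(sampleSizes(object, rendered = TRUE), row.names = FALSE)
})
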
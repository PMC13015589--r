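## End-to-end driver: simulate -> operant scoring -> phenotyping (battery
## only and battery + operant) -> power table, with CSV outputs, a text
## report and a manifest.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.writePhenotypeCSVs <- function(ph, dir, tag) {
    utils::write.csv(
        data.frame(mouse_id = rownames(pcScores(ph)), pcScores(ph),
                   cluster = clusterLabels(ph),
                   genotype = as.character(ph@genotype)),
        file.path(dir, paste0("pc_scores_", tag, ".csv")),
        row.names = FALSE)
    utils::write.csv(
        data.frame(measure = rownames(pcLoadings(ph)), pcLoadings(ph)),
        file.path(dir, paste0("pc_loadings_", tag, ".csv")),
        row.names = FALSE)
    utils::write.csv(
        data.frame(component = seq_along(varianceExplained(ph)),
                   variance_explained = varianceExplained(ph)),
        file.path(dir, paste0("pc_variance_", tag, ".csv")),
        row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, scores the operant sessions, runs
#' battery-only and (optionally) operant-inclusive phenotyping, bootstraps
#' the power / sample-size table from the cohort's own per-genotype values,
#' and writes CSV outputs, a plain-text report and a YAML manifest (config
#' hash, seeds, package version, file list) into \code{outDir}. All
#' randomness derives from \code{config$seed}, so a rerun with the same
#' config is numerically identical. Stage failures abort with the stage
#' name; files written by completed stages persist.
#'
#' @param config A \code{\link{runConfig}}.
#' @param outDir Output directory (created).
#' @param cohort Optional pre-built \linkS4class{BehaviorCohort}; when NULL
#'   one is simulated from the config.
#' @return Invisible list: \code{cohort}, \code{operant} (derived-metric
#'   table), \code{phenoBattery}, \code{phenoOperant} (or NULL),
#'   \code{sampleSizes}, \code{files}.
#' @examples
#' cfg <- runConfig(seed = 1, iterations = 200, maxAcqDays = 30)
#' res <- runPipeline(cfg, tempfile("run"))
#' sampleSizes(res$sampleSizes, rendered = TRUE)
#' @export
runPipeline <- function(config, outDir, cohort = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    set.seed(config$seed)
    seeds <- as.list(sample.int(.Machine$integer.max - 1L, 4))
    names(seeds) <- c("cohort", "phenoBattery", "phenoOperant", "power")

    cohort <- .stage("simulate", {
        if (is.null(cohort)) {
            cc <- cohortConfig(
                groupSizes = config$cohort$groupSizes,
                effects = config$cohort$effects,
                seed = seeds$cohort,
                nMagDays = config$cohort$nMagDays,
                maxAcqDays = config$cohort$maxAcqDays,
                minTrials = config$operant$minTrials,
                minRate = config$operant$minRate,
                runLength = config$operant$runLength)
            simulateCohort(cc)
        } else cohort
    })
    if (ncol(cohort) == 0)
        stop("pipeline stage 'simulate' failed: empty cohort")
    writeCohort(cohort, outDir)

    operant <- .stage("operant", summarizeOperant(
        cohort, minTrials = config$operant$minTrials,
        minRate = config$operant$minRate,
        runLength = config$operant$runLength))
    utils::write.csv(operant, file.path(outDir, "operant_metrics.csv"),
                     row.names = FALSE)

    phB <- .stage("phenotype-battery", phenotype(
        cohort, includeOperant = FALSE,
        sexSplit = config$phenotyping$sexSplit,
        nRestarts = config$phenotyping$nRestarts,
        seed = seeds$phenoBattery))
    .writePhenotypeCSVs(phB, outDir, "battery")

    phO <- NULL
    if (isTRUE(config$phenotyping$includeOperant)) {
        phO <- .stage("phenotype-operant", phenotype(
            cohort, includeOperant = TRUE, operantMetrics = operant,
            sexSplit = config$phenotyping$sexSplit,
            nRestarts = config$phenotyping$nRestarts,
            seed = seeds$phenoOperant))
        .writePhenotypeCSVs(phO, outDir, "battery_operant")
    }

    sst <- .stage("power", {
        geno <- as.character(genotypes(cohort))
        bat <- batteryMatrix(cohort)
        src <- list()
        for (m in rownames(bat))
            src[[m]] <- list(source1 = bat[m, geno == "WT"],
                             source2 = bat[m, geno == "AS"])
        for (m in c("days_to_criteria", "accuracy_at_criteria",
                    "norm_cued_E1")) {
            v <- operant[[m]]
            src[[m]] <- list(
                source1 = v[geno == "WT" & !is.na(v)],
                source2 = v[geno == "AS" & !is.na(v)])
        }
        buildSampleSizeTable(src, powers = config$power$powers,
                             alpha = config$power$alpha,
                             iterations = config$power$iterations,
                             grid = config$power$grid, seed = seeds$power)
    })
    utils::write.csv(sampleSizes(sst, rendered = TRUE),
                     file.path(outDir, "sample_sizes.csv"),
                     row.names = FALSE)

    reportPath <- file.path(outDir, "report.txt")
    .stage("report", .writeReport(reportPath, cohort, operant, phB, phO,
                                  sst, config))

    cfgPath <- file.path(outDir, "config.yaml")
    writeRunConfig(config, cfgPath)
    files <- sort(list.files(outDir))
    manifest <- list(
        package = "operantPheno",
        version = as.character(utils::packageVersion("operantPheno")),
        master_seed = config$seed,
        stage_seeds = seeds,
        config_hash = unname(tools::md5sum(cfgPath)),
        files = files)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

    invisible(list(cohort = cohort, operant = operant, phenoBattery = phB,
                   phenoOperant = phO, sampleSizes = sst,
                   files = list.files(outDir, full.names = TRUE)))
}

.writeReport <- function(path, cohort, operant, phB, phO, sst, config) {
    geno <- as.character(genotypes(cohort))
    con <- file(path, "w"); on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("operantPheno pipeline report")
    w("============================")
    w("master seed: %d", config$seed)
    w("cohort: %d mice (WT %d, AS %d)", ncol(cohort),
      sum(geno == "WT"), sum(geno == "AS"))
    w("")
    w("Operant metrics (group means):")
    for (m in c("days_to_criteria", "cued_at_criteria",
                "noncued_at_criteria", "accuracy_at_criteria",
                "norm_cued_E1")) {
        v <- operant[[m]]
        w("  %-22s WT %8.3f   AS %8.3f", m,
          mean(v[geno == "WT"], na.rm = TRUE),
          mean(v[geno == "AS"], na.rm = TRUE))
    }
    w("  mice not reaching criteria: %d", sum(!operant$reached))
    w("")
    w("Phenotyping (battery only, %d measures):", nrow(pcLoadings(phB)))
    w("  genotype accuracy: %.1f%%", 100 * clusterAccuracy(phB))
    w("  centroid distance: %.3f", centroidDistance(phB))
    if (!is.null(phO)) {
        w("Phenotyping (battery + operant, %d measures):",
          nrow(pcLoadings(phO)))
        w("  genotype accuracy: %.1f%%", 100 * clusterAccuracy(phO))
        w("  centroid distance: %.3f", centroidDistance(phO))
    }
    w("")
    w("Sample-size table (alpha = %g, %d iterations):",
      sst@alpha, sst@iterations)
    tab <- sampleSizes(sst, rendered = TRUE)
    hdr <- c(formatC("measure", width = -22), formatC("cohens_d", width = 9),
             formatC(paste0("n", sst@powers * 100), width = 6))
    w("  %s", paste(hdr, collapse = " "))
    for (i in seq_len(nrow(tab))) {
        cells <- c(formatC(tab$measure[i], width = -22),
                   formatC(tab$cohens_d[i], digits = 2, format = "f",
                           width = 9),
                   formatC(unlist(tab[i, -(1:2)]), width = 6))
        w("  %s", paste(cells, collapse = " "))
    }
    invisible(path)
}
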
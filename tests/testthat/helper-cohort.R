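# shared fixtures, built in code

smallGroupSizes <- function(n = 4L) {
    data.frame(genotype = rep(c("WT", "AS"), each = 2),
               sex = rep(c("M", "F"), 2),
               cohort = "1", n = as.integer(n))
}

# roster without sessions, for battery-only sampling-model checks
makeRoster <- function(nPerGenotype, sexes = c("M", "F")) {
    n <- nPerGenotype
    data.frame(
        mouse_id = sprintf("m%05d", seq_len(2 * n)),
        genotype = rep(c("WT", "AS"), each = n),
        sex = rep_len(sexes, 2 * n),
        cohort = "1",
        age_days = 90L, stringsAsFactors = FALSE)
}

# independent brute-force criteria scan over all run-length windows
bruteForceCriteria <- function(acq, minTrials = 15, minRate = 0.75,
                               runLength = 5) {
    n <- nrow(acq)
    for (start in seq_len(max(0, n - runLength + 1))) {
        idx <- start:(start + runLength - 1)
        ok <- TRUE
        for (i in idx) {
            tot <- acq$cued[i] + acq$noncued[i]
            acc <- if (tot == 0) NA_real_ else acq$cued[i] / tot
            if (!(acq$trials[i] > minTrials) || is.na(acc) ||
                !(acc > minRate)) { ok <- FALSE; break }
        }
        if (ok) return(list(days_to_criteria = acq$day[idx[runLength]],
                            criterion_days = acq$day[idx]))
    }
    list(days_to_criteria = NA_integer_, criterion_days = NULL)
}
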
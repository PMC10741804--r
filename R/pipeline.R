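## Cohort-level orchestration: geometric and dosimetric arms, rank tests,
## Likert tallies, time savings, interobserver variability, CSV reports.
## A cohort is a list with fields `site`, `seed` and `patients`; each
## patient is a list with `id`, `manual`, `ai`, `adjusted` (list of
## StructureSets, one per observer), `doses` (list: `manual` a DoseGrid,
## `adjusted` a list of DoseGrids per observer), `timing` (data.frame with
## arm, observer, minutes), `likert` (rating string). makeCohort()
## produces exactly this shape.

likertLevels <- c("severe correction", "medium correction",
                  "slight correction", "no correction")

#' Summarize a per-patient metric table into cohort rows
#'
#' Produces the mean (SD) / median (range) layout used in contour-QA
#' reports: one row per structure x metric with \code{mean}, \code{sd}
#' (n-1 denominator), \code{median}, \code{min}, \code{max}, \code{n} and
#' the count of excluded undefined (NA) values.
#'
#' @param df data.frame with columns \code{structure}, \code{metric},
#'   \code{value} (NA = undefined).
#' @return the summary data.frame.
#' @export
summarizeCohort <- function(df) {
    if (!nrow(df)) stop("nothing to summarize: empty cohort table")
    key <- interaction(df$structure, df$metric, drop = TRUE)
    out <- lapply(split(df, key), function(g) {
        v <- g$value
        excl <- sum(is.na(v))
        v <- v[!is.na(v)]
        data.frame(structure = g$structure[1], metric = g$metric[1],
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                   median = if (length(v)) stats::median(v) else NA_real_,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_,
                   n = length(v), n_excluded = excl)
    })
    out <- do.call(rbind, out)
    out <- out[order(out$structure, out$metric), ]
    rownames(out) <- NULL
    out
}

geometryLong <- function(rep, patient) {
    ## wide comparison report -> long (structure, metric, value); RVD
    ## summarized as magnitude, sign kept in the raw output
    data.frame(
        patient = patient,
        structure = rep(rep$structure, 3),
        metric = rep(c("dsc", "hd_mm", "rvd_abs"), each = nrow(rep)),
        value = c(rep$dsc, rep$hd_mm, rep$rvd_abs))
}

#' Cohort geometric comparison arm
#'
#' Runs \code{\link{compareStructureSets}} for every patient for the
#' requested comparison and summarizes DSC, Hausdorff distance and |RVD|
#' per structure. Undefined metrics (flagged or missing structures) are
#' excluded from the summaries and counted.
#'
#' @param cohort a cohort list (see \code{\link{makeCohort}}).
#' @param comparison \code{"ai_vs_adjusted"} (review effect) or
#'   \code{"manual_vs_adjusted"} (workflow difference); the first named
#'   set is the reference.
#' @param observer which adjusted set to use (default 1).
#' @return list with \code{raw} (per-patient wide reports, signed RVD
#'   included) and \code{summary} (cohort rows).
#' @export
runGeometricArm <- function(cohort,
                            comparison = c("ai_vs_adjusted",
                                           "manual_vs_adjusted"),
                            observer = 1) {
    comparison <- match.arg(comparison)
    if (!length(cohort$patients)) stop("nothing to summarize: empty cohort")
    raws <- list(); longs <- list()
    for (p in cohort$patients) {
        ref <- if (comparison == "ai_vs_adjusted") p$ai else p$manual
        rep <- compareStructureSets(ref, p$adjusted[[observer]])
        rep <- cbind(patient = p$id, rep)
        raws[[p$id]] <- rep
        longs[[p$id]] <- geometryLong(rep, p$id)
    }
    raw <- do.call(rbind, raws); rownames(raw) <- NULL
    list(raw = raw, summary = summarizeCohort(do.call(rbind, longs)))
}

patientDoseDeltas <- function(p, observer, targetName = "PTV") {
    manSet <- p$manual; adjSet <- p$adjusted[[observer]]
    doseMan <- resampleDose(p$doses$manual, voxelGrid(manSet))
    doseAdj <- resampleDose(p$doses$adjusted[[observer]],
                            voxelGrid(adjSet))
    common <- intersect(structureNames(manSet), structureNames(adjSet))
    rows <- list()
    for (nm in common) {
        mMan <- getStructure(manSet, nm); mAdj <- getStructure(adjSet, nm)
        if (!any(mMan@voxels) || !any(mAdj@voxels)) {
            rows[[nm]] <- data.frame(patient = p$id, structure = nm,
                metric = c("delta_d_mean", "delta_d_min",
                           "delta_d_0_03cc"),
                ref = NA_real_, test = NA_real_, value = NA_real_)
            next
        }
        isTarget <- nm == targetName
        dm <- doseMetrics(doseMan, mMan, target = isTarget)
        da <- doseMetrics(doseAdj, mAdj, target = isTarget)
        met <- c("delta_d_mean", "delta_d_min", "delta_d_0_03cc")
        refv <- c(dm$d_mean, dm$d_min, dm$d_0_03cc)
        tstv <- c(da$d_mean, da$d_min, da$d_0_03cc)
        if (isTarget) {
            met <- c(met, "delta_hi", "delta_ci")
            refv <- c(refv, dm$hi, dm$ci)
            tstv <- c(tstv, da$hi, da$ci)
        }
        val <- ifelse(refv == 0, NA_real_, (tstv - refv) / refv)
        rows[[nm]] <- data.frame(patient = p$id, structure = nm,
                                 metric = met, ref = refv, test = tstv,
                                 value = val)
    }
    do.call(rbind, rows)
}

#' Cohort dosimetric comparison arm
#'
#' For every patient, evaluates D_mean, D_min and D_0.03cc on the manual
#' and AI-adjusted arms (each plan on its own contours), plus HI and CI
#' for the target, and forms relative deltas
#' \code{(adjusted - manual) / manual}. Deltas with a zero reference are
#' logged as undefined and excluded. Per structure x metric a two-sided
#' rank-based test compares the achieved values between arms at
#' alpha = 0.05: the two-sample Wilcoxon rank-sum test by default, or the
#' paired signed-rank test with \code{paired = TRUE}.
#'
#' @param cohort a cohort list.
#' @param observer which adjusted arm to use (default 1).
#' @param targetName the target structure name (default \code{"PTV"}).
#' @param paired use the signed-rank (paired) test instead of the
#'   rank-sum test? Default FALSE.
#' @return list with \code{raw} (per-patient deltas, signed),
#'   \code{summary} (cohort rows over |delta|) and \code{tests}
#'   (data.frame structure, metric, test, p_value, significant).
#' @export
runDosimetricArm <- function(cohort, observer = 1, targetName = "PTV",
                             paired = FALSE) {
    if (!length(cohort$patients)) stop("nothing to summarize: empty cohort")
    raw <- do.call(rbind, lapply(cohort$patients, patientDoseDeltas,
                                 observer = observer,
                                 targetName = targetName))
    rownames(raw) <- NULL
    long <- data.frame(patient = raw$patient, structure = raw$structure,
                       metric = raw$metric, value = abs(raw$value))
    testName <- if (paired) "wilcoxon-signed-rank" else "wilcoxon-rank-sum"
    key <- interaction(raw$structure, raw$metric, drop = TRUE)
    tests <- do.call(rbind, lapply(split(raw, key), function(g) {
        ok <- !is.na(g$ref) & !is.na(g$test)
        p <- if (sum(ok) < 1) NA_real_
             else suppressWarnings(stats::wilcox.test(
                 g$test[ok], g$ref[ok], paired = paired,
                 alternative = "two.sided")$p.value)
        data.frame(structure = g$structure[1], metric = g$metric[1],
                   test = testName, p_value = p,
                   significant = !is.na(p) & p < 0.05)
    }))
    rownames(tests) <- NULL
    tests <- tests[order(tests$structure, tests$metric), ]
    rownames(tests) <- NULL
    list(raw = raw, summary = summarizeCohort(long), tests = tests)
}

#' Fractional reduction in contouring time
#'
#' \code{(t_manual - t_adjusted) / t_manual}: 0 when the AI-assisted
#' workflow takes as long as manual contouring, negative if it takes
#' longer.
#'
#' @param tManual manual contouring time, minutes (> 0); vectorized.
#' @param tAdjusted AI-assisted (review + adjustment) time, minutes.
#' @return fraction of time saved.
#' @examples
#' timeSavings(23, 6 + 25 / 60)           # 0.721 -> 72%
#' timeSavings(150, 23 + 35 / 60)         # 0.843 -> 84%
#' @export
timeSavings <- function(tManual, tAdjusted) {
    if (any(tManual <= 0)) stop("invalid timing: manual time must be > 0")
    (tManual - tAdjusted) / tManual
}

#' Interobserver variability report
#'
#' Compares the two observers' adjusted structure sets geometrically
#' (DSC, HD, |RVD|) and dosimetrically, with observer 2 as the delta
#' denominator: \code{(D_1 - D_2) / D_2}.
#'
#' @param cohort a cohort list whose patients carry two adjusted sets and
#'   doses.
#' @return list with \code{geometry} and \code{dose} elements, each a
#'   list of \code{raw} and \code{summary} data.frames.
#' @export
interobserverReport <- function(cohort) {
    if (!length(cohort$patients)) stop("nothing to summarize: empty cohort")
    graws <- list(); glongs <- list(); drows <- list()
    for (p in cohort$patients) {
        if (length(p$adjusted) < 2)
            stop("interobserver report needs two adjusted sets per patient")
        rep <- compareStructureSets(p$adjusted[[1]], p$adjusted[[2]])
        rep <- cbind(patient = p$id, rep)
        graws[[p$id]] <- rep
        glongs[[p$id]] <- geometryLong(rep, p$id)
        s1 <- p$adjusted[[1]]; s2 <- p$adjusted[[2]]
        d1 <- resampleDose(p$doses$adjusted[[1]], voxelGrid(s1))
        d2 <- resampleDose(p$doses$adjusted[[2]], voxelGrid(s2))
        for (nm in intersect(structureNames(s1), structureNames(s2))) {
            m1 <- getStructure(s1, nm); m2 <- getStructure(s2, nm)
            if (!any(m1@voxels) || !any(m2@voxels)) next
            v1 <- doseMetrics(d1, m1); v2 <- doseMetrics(d2, m2)
            for (met in c("d_mean", "d_min", "d_0_03cc")) {
                ref <- v2[[met]]
                drows[[length(drows) + 1L]] <- data.frame(
                    patient = p$id, structure = nm,
                    metric = paste0("delta_", met),
                    value = if (ref == 0) NA_real_
                            else (v1[[met]] - ref) / ref)
            }
        }
    }
    draw <- do.call(rbind, drows); rownames(draw) <- NULL
    dlong <- draw; dlong$value <- abs(dlong$value)
    graw <- do.call(rbind, graws); rownames(graw) <- NULL
    list(geometry = list(raw = graw,
                         summary = summarizeCohort(do.call(rbind, glongs))),
         dose = list(raw = draw, summary = summarizeCohort(dlong)))
}

#' Tally Likert ratings of automated contours
#'
#' @param ratings character vector of ratings on the four-level scale
#'   \code{"severe correction"}, \code{"medium correction"},
#'   \code{"slight correction"}, \code{"no correction"}.
#' @return data.frame with \code{rating}, \code{count},
#'   \code{proportion} (counts sum to the cohort size, proportions to 1).
#' @export
likertTally <- function(ratings) {
    if (!length(ratings)) stop("empty cohort: no ratings to tally")
    bad <- setdiff(unique(ratings), likertLevels)
    if (length(bad))
        stop("invalid rating label(s): ", paste(bad, collapse = ", "))
    f <- factor(ratings, levels = likertLevels)
    tab <- table(f)
    data.frame(rating = names(tab), count = as.integer(tab),
               proportion = as.numeric(tab) / length(ratings))
}

#' Plan-quality comparison between contouring arms
#'
#' Evaluates the site scorecard on each patient's manual and adjusted
#' plans and reports nPQM per arm plus the relative difference (adjusted
#' vs manual; magnitude summarized, sign kept in the raw output).
#'
#' @param cohort a cohort list.
#' @param card a \linkS4class{Scorecard}; defaults to the bundled card
#'   for the cohort's site.
#' @param observer which adjusted arm to use.
#' @return list with \code{raw} and \code{summary}.
#' @export
runPlanQualityArm <- function(cohort, card = NULL, observer = 1) {
    if (is.null(card))
        card <- bundledScorecard(
            if (cohort$site == "prostate") "prostate" else "head_and_neck")
    rows <- lapply(cohort$patients, function(p) {
        rMan <- evaluatePQM(card, p$doses$manual, p$manual)
        rAdj <- evaluatePQM(card, p$doses$adjusted[[observer]],
                            p$adjusted[[observer]])
        data.frame(patient = p$id, npqm_manual = rMan@npqm,
                   npqm_adjusted = rAdj@npqm,
                   delta_npqm = if (rMan@npqm == 0) NA_real_
                                else (rAdj@npqm - rMan@npqm) / rMan@npqm)
    })
    raw <- do.call(rbind, rows); rownames(raw) <- NULL
    long <- data.frame(patient = raw$patient, structure = "plan",
                       metric = "delta_npqm_abs",
                       value = abs(raw$delta_npqm))
    list(raw = raw, summary = summarizeCohort(long))
}

writeReport <- function(df, dir, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full study pipeline on a cohort
#'
#' Executes the geometric arm (AI vs adjusted and manual vs adjusted),
#' the dosimetric arm with rank tests, the plan-quality comparison, the
#' time-savings and Likert tallies and the interobserver report, and
#' writes each raw and summary table as CSV under \code{outDir}. Outputs
#' are a pure function of the cohort, so a fixed seeded cohort yields
#' byte-identical reports across runs.
#'
#' @param cohort a cohort list (see \code{\link{makeCohort}}).
#' @param outDir output directory (created if missing).
#' @param card optional \linkS4class{Scorecard} override.
#' @return invisibly, a list of all result tables.
#' @export
runStudy <- function(cohort, outDir, card = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    geoAI <- runGeometricArm(cohort, "ai_vs_adjusted")
    geoMan <- runGeometricArm(cohort, "manual_vs_adjusted")
    dosi <- runDosimetricArm(cohort)
    pqm <- runPlanQualityArm(cohort, card = card)
    inter <- if (all(vapply(cohort$patients,
                            function(p) length(p$adjusted) >= 2, TRUE)))
        interobserverReport(cohort) else NULL
    savings <- do.call(rbind, lapply(cohort$patients, function(p) {
        tman <- p$timing$minutes[p$timing$arm == "manual"][1]
        tadj <- p$timing$minutes[p$timing$arm == "ai_adjusted" &
                                 p$timing$observer %in% 1][1]
        data.frame(patient = p$id, t_manual = tman, t_adjusted = tadj,
                   saved_fraction = timeSavings(tman, tadj))
    }))
    rownames(savings) <- NULL
    likert <- likertTally(vapply(cohort$patients, `[[`, "", "likert"))

    writeReport(geoAI$raw, outDir, "geometry_ai_vs_adj_raw.csv")
    writeReport(geoAI$summary, outDir, "geometry_ai_vs_adj_summary.csv")
    writeReport(geoMan$raw, outDir, "geometry_man_vs_adj_raw.csv")
    writeReport(geoMan$summary, outDir, "geometry_man_vs_adj_summary.csv")
    writeReport(dosi$raw, outDir, "dose_delta_raw.csv")
    writeReport(dosi$summary, outDir, "dose_delta_summary.csv")
    writeReport(dosi$tests, outDir, "wilcoxon.csv")
    writeReport(pqm$raw, outDir, "pqm_raw.csv")
    writeReport(pqm$summary, outDir, "pqm_summary.csv")
    writeReport(savings, outDir, "timing.csv")
    writeReport(likert, outDir, "likert.csv")
    if (!is.null(inter)) {
        writeReport(inter$geometry$raw, outDir,
                    "interobserver_geometry_raw.csv")
        writeReport(inter$geometry$summary, outDir,
                    "interobserver_geometry_summary.csv")
        writeReport(inter$dose$raw, outDir, "interobserver_dose_raw.csv")
        writeReport(inter$dose$summary, outDir,
                    "interobserver_dose_summary.csv")
    }
    invisible(list(geometry_ai = geoAI, geometry_manual = geoMan,
                   dose = dosi, pqm = pqm, interobserver = inter,
                   timing = savings, likert = likert))
}
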
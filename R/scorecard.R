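#' Load a plan-quality scorecard from YAML
#'
#' A scorecard is a list of dose-volume objectives, each with a structure
#' name, a statistic keyword (see \code{\link{doseStatistic}}), a
#' comparison direction, a scoring function (\code{threshold} with one
#' (value, score) pair, or \code{linear} with two) and the resulting
#' maximum score. The package bundles scorecards for a prostate plan
#' (60 Gy in 20 fractions) and a head-and-neck plan (70.95 Gy in 33
#' fractions); see \code{\link{bundledScorecard}}.
#'
#' @param path path to a YAML scorecard file.
#' @return a \linkS4class{Scorecard}.
#' @export
loadScorecard <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$objectives) || !length(cfg$objectives))
        stop("scorecard config has no objectives")
    rows <- lapply(seq_along(cfg$objectives), function(i) {
        o <- cfg$objectives[[i]]
        where <- paste0("objective ", i,
                        if (!is.null(o$structure))
                            paste0(" (", o$structure, ")"))
        for (f in c("structure", "statistic", "direction", "function"))
            if (is.null(o[[f]]))
                stop(where, ": missing field '", f, "'")
        if (!o[["function"]] %in% c("threshold", "linear"))
            stop(where, ": unknown function '", o[["function"]], "'")
        if (!validStatisticKeyword(o$statistic))
            stop(where, ": unknown statistic keyword '", o$statistic, "'")
        th <- o$thresholds
        if (o[["function"]] == "threshold" && length(th) != 1L)
            stop(where, ": threshold objectives need exactly one ",
                 "(value, score) pair")
        if (o[["function"]] == "linear" && length(th) != 2L)
            stop(where, ": linear objectives need exactly two ",
                 "(value, score) pairs")
        th <- lapply(th, function(t) {
            if (is.null(t$value) || is.null(t$score))
                stop(where, ": each threshold needs 'value' and 'score'")
            t
        })
        ## order linear pairs so t1 is the ideal (larger-score) threshold
        if (length(th) == 2L && th[[1]]$score < th[[2]]$score)
            th <- th[c(2, 1)]
        s1 <- th[[1]]$score
        s2 <- if (length(th) == 2L) th[[2]]$score else NA_real_
        if (s1 <= 0) stop(where, ": nonpositive max score")
        data.frame(structure = o$structure, statistic = o$statistic,
                   direction = o$direction, fun = o[["function"]],
                   t1 = th[[1]]$value, s1 = s1,
                   t2 = if (length(th) == 2L) th[[2]]$value else NA_real_,
                   s2 = s2, maxScore = s1)
    })
    ob <- do.call(rbind, rows)
    new("Scorecard", site = cfg$site %||% "unknown", objectives = ob,
        pqmMax = sum(ob$maxScore))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scorecard back to YAML
#'
#' Round-trip companion of \code{\link{loadScorecard}}: reloading the
#' written file yields identical scoring.
#'
#' @param card a \linkS4class{Scorecard}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScorecard <- function(card, path) {
    obj <- lapply(seq_len(nrow(card@objectives)), function(i) {
        r <- card@objectives[i, ]
        th <- list(list(value = r$t1, score = r$s1))
        if (!is.na(r$t2))
            th <- c(th, list(list(value = r$t2, score = r$s2)))
        list(structure = r$structure, statistic = r$statistic,
             direction = r$direction, `function` = r$fun,
             thresholds = th)
    })
    yaml::write_yaml(list(site = card@site, objectives = obj), path)
    invisible(path)
}

#' Paths to the bundled scorecards and constraint sets
#'
#' \code{bundledScorecard} returns the loaded scorecard for
#' \code{"prostate"} or \code{"head_and_neck"};
#' \code{bundledConstraints} the planning constraint set for the same
#' sites.
#'
#' @param site \code{"prostate"} or \code{"head_and_neck"}.
#' @return a \linkS4class{Scorecard}, or a constraints data.frame.
#' @export
bundledScorecard <- function(site = c("prostate", "head_and_neck")) {
    site <- match.arg(site)
    loadScorecard(system.file("extdata",
        paste0("scorecard_", site, ".yaml"), package = "AutoContourQA"))
}

#' @rdname bundledScorecard
#' @export
bundledConstraints <- function(site = c("prostate", "head_and_neck")) {
    site <- match.arg(site)
    cfg <- yaml::read_yaml(system.file("extdata",
        paste0("constraints_", site, ".yaml"), package = "AutoContourQA"))
    do.call(rbind, lapply(cfg$constraints, function(cn)
        data.frame(structure = cn$structure, statistic = cn$statistic,
                   direction = cn$direction, limit = cn$limit)))
}

setMethod("show", "Scorecard", function(object) {
    cat("Scorecard '", object@site, "': ", nrow(object@objectives),
        " objectives, PQM_max = ", object@pqmMax, "\n", sep = "")
})

#' Score one objective against an achieved statistic value
#'
#' Threshold objectives award the maximum score when the objective is met
#' and 0 otherwise. Linear objectives interpolate between two (threshold,
#' score) pairs: the full score at/beyond the ideal threshold, the lower
#' threshold's score at the minimally acceptable threshold, 0 strictly
#' beyond it. With \code{convention = "prose"} the lower threshold's score
#' is forced to 0, so the ramp runs from 0 at the minimally acceptable
#' threshold to the full score at the ideal one.
#'
#' @param objective a one-row slice of a scorecard's \code{objectives}
#'   data.frame (or an equivalent list).
#' @param achieved the achieved statistic value, in the objective's units.
#' @param convention \code{"two-point"} (default) or \code{"prose"}.
#' @return awarded points in [0, maxScore].
#' @export
scoreObjective <- function(objective, achieved,
                           convention = c("two-point", "prose")) {
    convention <- match.arg(convention)
    if (!is.finite(achieved)) stop("achieved value must be finite")
    o <- as.list(objective)
    better <- function(x, y)            # x at least as good as y?
        if (o$direction == "at-most") x <= y else x >= y
    if (o$fun == "threshold")
        return(if (better(achieved, o$t1)) o$s1 else 0)
    s2 <- if (convention == "prose") 0 else o$s2
    if (better(achieved, o$t1)) return(o$s1)
    if (!better(achieved, o$t2)) return(0)
    frac <- abs(achieved - o$t2) / abs(o$t1 - o$t2)
    pts <- s2 + frac * (o$s1 - s2)
    min(max(pts, 0), o$maxScore)
}

#' Evaluate a scorecard against a plan
#'
#' Resamples the dose onto the structure grid if necessary, extracts each
#' objective's statistic, scores it and totals the plan-quality metric.
#' Objectives whose structure is missing from the set (or empty) score 0
#' and are flagged; the evaluation continues.
#'
#' @param card a \linkS4class{Scorecard}.
#' @param dose a \linkS4class{DoseGrid}.
#' @param structures a \linkS4class{StructureSet}.
#' @param convention linear scoring convention, see
#'   \code{\link{scoreObjective}}.
#' @param binWidth DVH bin width in cGy.
#' @return a \linkS4class{PQMResult} with per-objective detail, total PQM
#'   and the normalized score \code{npqm = 100 * pqm / pqmMax}.
#' @export
evaluatePQM <- function(card, dose, structures,
                        convention = c("two-point", "prose"),
                        binWidth = 1) {
    convention <- match.arg(convention)
    grid <- voxelGrid(structures)
    dose <- resampleDose(dose, grid)
    ob <- card@objectives
    want <- standardizeStructureName(ob$structure)
    have <- structureNames(structures)
    rows <- lapply(seq_len(nrow(ob)), function(i) {
        row <- data.frame(structure = want[i], statistic = ob$statistic[i],
                          achieved = NA_real_, points = 0,
                          maxScore = ob$maxScore[i], flag = "")
        if (!want[i] %in% have) { row$flag <- "missing"; return(row) }
        m <- getStructure(structures, want[i])
        if (!any(m@voxels)) { row$flag <- "empty"; return(row) }
        row$achieved <- doseStatistic(ob$statistic[i], dose, m, binWidth)
        row$points <- scoreObjective(ob[i, ], row$achieved, convention)
        row
    })
    per <- do.call(rbind, rows)
    pqm <- sum(per$points)
    new("PQMResult", perObjective = per, pqm = pqm, pqmMax = card@pqmMax,
        npqm = 100 * pqm / card@pqmMax)
}

setMethod("show", "PQMResult", function(object) {
    cat("PQMResult: PQM = ", format(object@pqm, digits = 5), " / ",
        object@pqmMax, "  (nPQM = ", format(object@npqm, digits = 4),
        "%)\n", sep = "")
    flagged <- object@perObjective$flag != ""
    if (any(flagged))
        cat("  flagged objectives:", sum(flagged), "\n")
})

#' Check planning dose constraints against a plan
#'
#' Purely descriptive pass/fail evaluation of a constraint set (no
#' points). Constraints are strict inequalities as printed in planning
#' protocols (\code{at-most}: achieved < limit; \code{at-least}:
#' achieved > limit).
#'
#' @param constraints data.frame with columns \code{structure},
#'   \code{statistic}, \code{direction}, \code{limit} (e.g. from
#'   \code{\link{bundledConstraints}}).
#' @param dose a \linkS4class{DoseGrid}.
#' @param structures a \linkS4class{StructureSet}.
#' @param binWidth DVH bin width in cGy.
#' @return the input data.frame with added \code{achieved}, \code{pass}
#'   and \code{flag} columns.
#' @export
checkConstraints <- function(constraints, dose, structures, binWidth = 1) {
    grid <- voxelGrid(structures)
    dose <- resampleDose(dose, grid)
    want <- standardizeStructureName(constraints$structure)
    have <- structureNames(structures)
    constraints$achieved <- NA_real_
    constraints$pass <- NA
    constraints$flag <- ""
    for (i in seq_len(nrow(constraints))) {
        if (!want[i] %in% have) { constraints$flag[i] <- "missing"; next }
        m <- getStructure(structures, want[i])
        if (!any(m@voxels)) { constraints$flag[i] <- "empty"; next }
        a <- doseStatistic(constraints$statistic[i], dose, m, binWidth)
        constraints$achieved[i] <- a
        constraints$pass[i] <- if (constraints$direction[i] == "at-most")
            a < constraints$limit[i] else a > constraints$limit[i]
    }
    constraints
}
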
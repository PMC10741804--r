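#' Create a DoseGrid
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param dose numeric array of dose in cGy matching \code{dim3(grid)}.
#' @param prescription prescribed dose in cGy (> 0).
#' @return a \linkS4class{DoseGrid}.
#' @export
DoseGrid <- function(grid, dose, prescription) {
    if (is.null(dim(dose))) dim(dose) <- dim3(grid)
    storage.mode(dose) <- "double"
    new("DoseGrid", grid = grid, dose = dose,
        prescription = as.numeric(prescription))
}

#' @rdname doseArray
#' @export
setMethod("doseArray", "DoseGrid", function(x) x@dose)

#' @rdname doseArray
#' @export
setMethod("prescription", "DoseGrid", function(x) x@prescription)

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "DoseGrid", function(x) x@grid)

setMethod("show", "DoseGrid", function(object) {
    cat("DoseGrid:", paste(dim3(object@grid), collapse = " x "),
        "voxels, prescription", object@prescription, "cGy, max",
        format(max(object@dose), digits = 5), "cGy\n")
})

#' Resample a dose grid onto a target grid
#'
#' Trilinear interpolation of the dose at the target voxel centers. Target
#' voxels outside the source grid's support get dose 0 (with a warning);
#' the prescription is carried over unchanged.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param target the \linkS4class{VoxelGrid} to sample on.
#' @return a \linkS4class{DoseGrid} on \code{target}.
#' @export
resampleDose <- function(dose, target) {
    if (sameGrid(dose@grid, target)) return(dose)
    src <- dose@grid
    ## fractional 0-based source indices of target centers, per axis
    fr <- lapply(1:3, function(a)
        (axisCenters(target, a) - src@origin[a]) / src@spacing[a])
    dims <- dim3(target)
    fx <- rep(fr[[1]], times = dims[2] * dims[3])
    fy <- rep(rep(fr[[2]], each = dims[1]), times = dims[3])
    fz <- rep(fr[[3]], each = dims[1] * dims[2])
    sd <- dim3(src)
    inside <- fx >= 0 & fx <= sd[1] - 1 & fy >= 0 & fy <= sd[2] - 1 &
              fz >= 0 & fz <= sd[3] - 1
    if (!any(inside))
        stop("no overlap between the dose grid and the target grid")
    if (!all(inside))
        warning(sum(!inside),
                " target voxels lie outside the dose grid; set to 0")
    out <- numeric(prod(dims))
    fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
    i0 <- pmin(floor(fx), sd[1] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(fy), sd[2] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(fz), sd[3] - 2); k0 <- pmax(k0, 0)
    if (sd[1] == 1L) i0 <- rep(0, length(fx))
    if (sd[2] == 1L) j0 <- rep(0, length(fy))
    if (sd[3] == 1L) k0 <- rep(0, length(fz))
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    D <- dose@dose
    at <- function(di, dj, dk) {
        ii <- pmin(i0 + di, sd[1] - 1); jj <- pmin(j0 + dj, sd[2] - 1)
        kk <- pmin(k0 + dk, sd[3] - 1)
        D[1 + ii + sd[1] * (jj + sd[2] * kk)]
    }
    v <- at(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
         at(1, 0, 0) * tx * (1 - ty) * (1 - tz) +
         at(0, 1, 0) * (1 - tx) * ty * (1 - tz) +
         at(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
         at(1, 1, 0) * tx * ty * (1 - tz) +
         at(1, 0, 1) * tx * (1 - ty) * tz +
         at(0, 1, 1) * (1 - tx) * ty * tz +
         at(1, 1, 1) * tx * ty * tz
    out[inside] <- v
    DoseGrid(target, array(out, dims), dose@prescription)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Builds the cumulative DVH ("volume receiving at least dose d") over the
#' occupied voxels, with bin edges from 0 to just above the maximum dose.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a nonempty \linkS4class{StructureMask} on the same grid.
#' @param binWidth bin width in cGy (default 1).
#' @return a \linkS4class{DVH}.
#' @export
computeDVH <- function(dose, mask, binWidth = 1) {
    if (!sameGrid(dose@grid, mask@grid))
        stop("dose and mask must share one grid (resample the dose first)")
    if (!any(mask@voxels)) stop("empty structure: DVH undefined")
    if (binWidth <= 0) stop("binWidth must be > 0")
    d <- sort(dose@dose[mask@voxels])
    n <- length(d)
    vv <- voxelVolumeCC(mask@grid)
    edges <- seq(0, (floor(max(d) / binWidth) + 1) * binWidth,
                 by = binWidth)
    ## count of voxels with dose >= edge
    nAtLeast <- n - findInterval(edges - 1e-9, d)
    new("DVH", structure = mask@name, doseBins = edges,
        volumeCC = nAtLeast * vv, volumePct = 100 * nAtLeast / n,
        binWidth = binWidth, totalVolume = n * vv)
}

setMethod("show", "DVH", function(object) {
    cat("DVH '", object@structure, "': ",
        format(object@totalVolume, digits = 4), " cc, dose range 0-",
        max(object@doseBins), " cGy (", object@binWidth,
        " cGy bins)\n", sep = "")
})

## largest dose bin edge whose cumulative volume (curve `V`) still
## reaches v. The inversion is resolved at bin-edge precision: dose mass
## concentrated at a single value (a uniform field) then inverts exactly,
## and for continuous fields the result is within one bin width of the
## sorted-voxel answer; the default 1 cGy bin makes that negligible.
invertCumulative <- function(bins, V, v) {
    i <- which(V >= v - 1e-9)
    if (!length(i)) return(bins[1])
    bins[max(i)]
}

#' Dose covering a volume percentage (D_x%)
#'
#' The minimum dose received by the hottest x% of the structure: the
#' largest dose D such that at least x% of the volume receives >= D,
#' read off the cumulative curve at bin-edge resolution (make the bins
#' finer for finer resolution). Non-increasing in x;
#' D_98% <= D_50% <= D_2%.
#'
#' @param dvh a \linkS4class{DVH}.
#' @param x percentage in (0, 100].
#' @return dose in cGy.
#' @export
doseAtVolumePercent <- function(dvh, x) {
    if (!is.finite(x) || x <= 0 || x > 100)
        stop("invalid percentile: x must be in (0, 100]")
    invertCumulative(dvh@doseBins, dvh@volumePct, x)
}

#' Dose covering an absolute volume (D_cc)
#'
#' The highest dose encompassing v cc: the largest dose D such that at
#' least v cc receives >= D, read off the cumulative curve at bin-edge
#' resolution. \code{v = totalVolume} recovers the minimum dose; small v
#' (e.g. 0.03 cc) gives the near-maximum dose.
#'
#' @param dvh a \linkS4class{DVH}.
#' @param v volume in cc, 0 < v <= structure volume.
#' @return dose in cGy.
#' @export
doseAtAbsoluteVolume <- function(dvh, v) {
    if (!is.finite(v) || v <= 0 || v > dvh@totalVolume + 1e-9)
        stop("invalid volume: v must be in (0, structure volume]")
    invertCumulative(dvh@doseBins, dvh@volumeCC, v)
}

#' Mean and minimum dose over a structure
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a nonempty \linkS4class{StructureMask} on the same grid.
#' @return a list with \code{mean} and \code{min} in cGy.
#' @export
meanMinDose <- function(dose, mask) {
    if (!sameGrid(dose@grid, mask@grid))
        stop("dose and mask must share one grid")
    if (!any(mask@voxels)) stop("empty structure")
    d <- dose@dose[mask@voxels]
    list(mean = mean(d), min = min(d))
}

#' Homogeneity index of a target DVH
#'
#' \code{(D_2\% - D_98\%) / D_50\%}: 0 for a perfectly uniform target
#' dose, larger for more heterogeneous coverage. Invariant to uniform dose
#' scaling.
#'
#' @param dvh the target \linkS4class{DVH}.
#' @return unitless HI >= 0.
#' @export
homogeneityIndex <- function(dvh) {
    d50 <- doseAtVolumePercent(dvh, 50)
    if (d50 <= 0) stop("degenerate dose: D_50% is 0")
    (doseAtVolumePercent(dvh, 2) - doseAtVolumePercent(dvh, 98)) / d50
}

#' Paddick-style conformity index
#'
#' \code{CI = TV_PV^2 / (V_PTV * V_TV)} where \code{V_TV} is the volume
#' receiving at least 95% of the prescription, and \code{TV_PV} is the part
#' of the PTV inside it. CI is in (0, 1] and equals 1 iff the 95% isodose
#' region coincides with the PTV.
#'
#' @param dose a \linkS4class{DoseGrid} (prescription set).
#' @param ptv a nonempty \linkS4class{StructureMask} on the same grid.
#' @return unitless CI in (0, 1].
#' @export
conformityIndex <- function(dose, ptv) {
    if (!sameGrid(dose@grid, ptv@grid))
        stop("dose and PTV must share one grid")
    if (!any(ptv@voxels)) stop("empty PTV")
    iso <- dose@dose >= 0.95 * dose@prescription
    vTV <- sum(iso)
    if (vTV == 0) stop("no coverage: the 95% isodose region is empty")
    vPTV <- sum(ptv@voxels)
    tvPV <- sum(iso & ptv@voxels)
    tvPV^2 / (vPTV * vTV)
}

#' Relative difference between a test and a reference value
#'
#' \code{(test - ref) / ref}, the delta applied uniformly to dose
#' statistics, HI, CI and nPQM when comparing contouring arms.
#'
#' @param test,ref finite numeric values; \code{ref != 0}.
#' @return signed unitless ratio (vectorized).
#' @export
relativeDifference <- function(test, ref) {
    if (any(ref == 0))
        stop("undefined delta: reference value is 0")
    (test - ref) / ref
}

## does a keyword belong to the statistic grammar?
validStatisticKeyword <- function(keyword) {
    kw <- gsub("[_ ]", "", keyword)
    grepl("^D(mean|median|max|min)$", kw, ignore.case = TRUE) ||
        grepl("^D[0-9.]+%$", kw) || grepl("^D[0-9.]+cc$", kw) ||
        grepl("^V[0-9.]+cGy(%|cc)?$", kw)
}

#' Evaluate a dose-volume statistic by keyword
#'
#' Keywords follow the scorecard grammar: \code{"Dmean"}, \code{"Dmedian"},
#' \code{"Dmax"}, \code{"Dmin"}, \code{"D<x>\%"} (dose covering x% of the
#' volume), \code{"D<v>cc"} (dose covering v cc), \code{"V<d>cGy"} (volume
#' receiving >= d cGy, as % of the structure) and \code{"V<d>cGycc"} (the
#' same in cc). Underscores in keywords are ignored, so \code{"D_mean"}
#' works too.
#'
#' @param keyword statistic keyword.
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a nonempty \linkS4class{StructureMask} on the same grid.
#' @param binWidth DVH bin width in cGy for DVH-derived statistics.
#' @return the statistic value (cGy for D-type, % or cc for V-type).
#' @export
doseStatistic <- function(keyword, dose, mask, binWidth = 1) {
    if (!sameGrid(dose@grid, mask@grid))
        stop("dose and mask must share one grid")
    if (!any(mask@voxels)) stop("empty structure")
    kw <- gsub("[_ ]", "", keyword)
    d <- dose@dose[mask@voxels]
    if (grepl("^D(mean|median|max|min)$", kw, ignore.case = TRUE)) {
        f <- tolower(sub("^D", "", kw, ignore.case = TRUE))
        return(switch(f, mean = mean(d), median = stats::median(d),
                      max = max(d), min = min(d)))
    }
    m <- regmatches(kw, regexec("^D([0-9.]+)%$", kw))[[1]]
    if (length(m) == 2)
        return(doseAtVolumePercent(computeDVH(dose, mask, binWidth),
                                   as.numeric(m[2])))
    m <- regmatches(kw, regexec("^D([0-9.]+)cc$", kw))[[1]]
    if (length(m) == 2) {
        dvh <- computeDVH(dose, mask, binWidth)
        v <- min(as.numeric(m[2]), dvh@totalVolume)  # near-max capped at volume
        return(doseAtAbsoluteVolume(dvh, v))
    }
    m <- regmatches(kw, regexec("^V([0-9.]+)cGy(%|cc)?$", kw))[[1]]
    if (length(m) == 3) {
        thr <- as.numeric(m[2])
        nAtLeast <- sum(d >= thr)
        if (identical(m[3], "cc"))
            return(nAtLeast * voxelVolumeCC(mask@grid))
        return(100 * nAtLeast / length(d))
    }
    stop("unknown statistic keyword: '", keyword, "'")
}

#' Standard dose metrics for one structure
#'
#' Convenience wrapper collecting D_mean, D_min, D_0.03cc and, when
#' \code{target = TRUE}, HI and CI.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a nonempty \linkS4class{StructureMask} on the same grid.
#' @param target compute HI and CI as well?
#' @param binWidth DVH bin width in cGy.
#' @return a named list of metric values.
#' @export
doseMetrics <- function(dose, mask, target = FALSE, binWidth = 1) {
    mm <- meanMinDose(dose, mask)
    dvh <- computeDVH(dose, mask, binWidth)
    out <- list(d_mean = mm$mean, d_min = mm$min,
                d_0_03cc = doseAtAbsoluteVolume(
                    dvh, min(0.03, dvh@totalVolume)))
    if (target) {
        out$hi <- homogeneityIndex(dvh)
        out$ci <- conformityIndex(dose, mask)
    }
    out
}
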
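#' @import methods
NULL

#' VoxelGrid: shared geometry for masks and dose
#'
#' A regular 3D voxel lattice in patient space. Axial slices are stacked
#' along the third axis; the first two axes are in-plane. Voxel centers sit
#' at \code{origin + index * spacing} with 0-based indices, the convention
#' used by RT DOSE / RT STRUCT grids. The \code{posterior} flag names the
#' in-plane direction in which the patient's posterior lies, so that
#' direction-dependent margins (e.g. a reduced posterior margin) can be
#' resolved to grid axes.
#'
#' @slot origin numeric(3), mm position of the voxel with index (0,0,0).
#' @slot spacing numeric(3), mm per axis; all > 0. The third entry is the
#'   slice thickness.
#' @slot dims integer(3), voxel counts per axis; all >= 1.
#' @slot posterior one of \code{"+x"}, \code{"-x"}, \code{"+y"}, \code{"-y"}:
#'   the in-plane direction pointing posterior.
#' @export
setClass("VoxelGrid",
    representation(origin = "numeric", spacing = "numeric",
                   dims = "integer", posterior = "character"),
    prototype(origin = c(0, 0, 0), spacing = c(1, 1, 1),
              dims = c(1L, 1L, 1L), posterior = "+y"))

setValidity("VoxelGrid", function(object) {
    msg <- character(0)
    if (length(object@origin) != 3L || anyNA(object@origin))
        msg <- c(msg, "origin must be numeric(3) without NA")
    if (length(object@spacing) != 3L || anyNA(object@spacing) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be numeric(3), all > 0")
    if (length(object@dims) != 3L || anyNA(object@dims) ||
        any(object@dims < 1L))
        msg <- c(msg, "dims must be integer(3), all >= 1")
    if (length(object@posterior) != 1L ||
        !object@posterior %in% c("+x", "-x", "+y", "-y"))
        msg <- c(msg, "posterior must be one of '+x', '-x', '+y', '-y'")
    if (length(msg)) msg else TRUE
})

#' ContourSet: planar polygons per axial slice
#'
#' The RT-STRUCT-style representation of one structure: for each axial
#' slice, a list of closed planar polygons (holes are carried as separate
#' polygons and resolved by the even-odd rule at rasterization).
#'
#' @slot name structure name.
#' @slot slices a list; each element is a list with \code{z} (slice
#'   position, mm) and \code{polygons} (list of n x 2 numeric matrices of
#'   (x, y) vertices in mm, n >= 3, implicitly closed).
#' @export
setClass("ContourSet",
    representation(name = "character", slices = "list"),
    prototype(name = "structure", slices = list()))

setValidity("ContourSet", function(object) {
    for (sl in object@slices) {
        if (!is.list(sl) || is.null(sl$z) || is.null(sl$polygons))
            return("each slice needs fields 'z' and 'polygons'")
        for (p in sl$polygons) {
            if (!is.matrix(p) || ncol(p) != 2L)
                return("polygons must be n x 2 matrices of (x, y) mm")
            if (nrow(p) < 3L)
                return("degenerate polygon: fewer than 3 vertices")
        }
    }
    TRUE
})

#' StructureMask: a named binary volume on a VoxelGrid
#'
#' @slot name structure name.
#' @slot grid the \linkS4class{VoxelGrid} the mask lives on.
#' @slot voxels logical array with \code{dim == dims(grid)}; TRUE marks
#'   occupied voxels.
#' @export
setClass("StructureMask",
    representation(name = "character", grid = "VoxelGrid",
                   voxels = "array"))

setValidity("StructureMask", function(object) {
    if (!is.logical(object@voxels))
        return("voxels must be a logical array")
    if (!identical(dim(object@voxels), dim3(object@grid)))
        return("voxel array dimensions must match the grid dims")
    if (anyNA(object@voxels))
        return("voxels must not contain NA")
    TRUE
})

#' StructureSet: a provenance-labelled collection of masks on one grid
#'
#' @slot provenance one of \code{"manual"}, \code{"ai"},
#'   \code{"ai_adjusted"} -- the contouring workflow that produced the set.
#' @slot observer observer identifier (may be \code{""}).
#' @slot structures named list of \linkS4class{StructureMask}, all sharing
#'   one grid; names are standardized structure names, unique.
#' @export
setClass("StructureSet",
    representation(provenance = "character", observer = "character",
                   structures = "list"),
    prototype(provenance = "manual", observer = "", structures = list()))

setValidity("StructureSet", function(object) {
    if (!object@provenance %in% c("manual", "ai", "ai_adjusted"))
        return("provenance must be 'manual', 'ai' or 'ai_adjusted'")
    if (length(object@structures)) {
        if (is.null(names(object@structures)) ||
            anyDuplicated(names(object@structures)))
            return("structures must be uniquely named")
        g <- NULL
        for (m in object@structures) {
            if (!is(m, "StructureMask"))
                return("structures must be StructureMask objects")
            if (is.null(g)) g <- m@grid
            else if (!sameGrid(g, m@grid))
                return("all member masks must share one grid")
        }
    }
    TRUE
})

#' DoseGrid: scalar dose field with a prescription
#'
#' @slot grid the \linkS4class{VoxelGrid} the dose lives on.
#' @slot dose numeric array of dose per voxel, cGy, all >= 0.
#' @slot prescription prescribed dose in cGy, > 0.
#' @export
setClass("DoseGrid",
    representation(grid = "VoxelGrid", dose = "array",
                   prescription = "numeric"))

setValidity("DoseGrid", function(object) {
    if (!identical(dim(object@dose), dim3(object@grid)))
        return("dose array dimensions must match the grid dims")
    if (anyNA(object@dose) || any(object@dose < 0))
        return("dose must be >= 0 everywhere, no NA")
    if (length(object@prescription) != 1L || is.na(object@prescription) ||
        object@prescription <= 0)
        return("prescription must be a single value > 0 (cGy)")
    TRUE
})

#' DVH: cumulative dose-volume histogram
#'
#' \code{volumeCC[i]} is the absolute volume receiving at least
#' \code{doseBins[i]} cGy; \code{volumePct} is the same as a percentage of
#' the structure volume. The curve is non-increasing and starts at 100%.
#'
#' @slot structure structure name.
#' @slot doseBins ascending dose bin edges, cGy (starting at 0).
#' @slot volumeCC cumulative volume in cc per bin edge.
#' @slot volumePct cumulative volume in % per bin edge.
#' @slot binWidth bin width in cGy.
#' @slot totalVolume structure volume in cc.
#' @export
setClass("DVH",
    representation(structure = "character", doseBins = "numeric",
                   volumeCC = "numeric", volumePct = "numeric",
                   binWidth = "numeric", totalVolume = "numeric"))

setValidity("DVH", function(object) {
    if (length(object@doseBins) != length(object@volumeCC) ||
        length(object@doseBins) != length(object@volumePct))
        return("doseBins, volumeCC and volumePct must have equal length")
    if (is.unsorted(object@doseBins))
        return("doseBins must be ascending")
    if (any(diff(object@volumeCC) > 1e-9))
        return("cumulative volume must be non-increasing in dose")
    if (any(object@volumeCC < -1e-9))
        return("cumulative volume must be >= 0")
    TRUE
})

#' Scorecard: declarative plan-quality objectives
#'
#' Objectives are rows of a data.frame with columns \code{structure},
#' \code{statistic} (keyword such as \code{"Dmean"}, \code{"D99%"},
#' \code{"D0.1cc"}, \code{"V4500cGy"}, \code{"V5000cGycc"}),
#' \code{direction} (\code{"at-least"} / \code{"at-most"}), \code{fun}
#' (\code{"threshold"} / \code{"linear"}), \code{t1}, \code{s1} (ideal
#' threshold and its score), \code{t2}, \code{s2} (minimally acceptable
#' threshold and its score; NA for threshold objectives) and
#' \code{maxScore}.
#'
#' @slot site site label (e.g. \code{"prostate"}).
#' @slot objectives the objectives data.frame.
#' @slot pqmMax sum of per-objective maximum scores.
#' @export
setClass("Scorecard",
    representation(site = "character", objectives = "data.frame",
                   pqmMax = "numeric"))

setValidity("Scorecard", function(object) {
    need <- c("structure", "statistic", "direction", "fun",
              "t1", "s1", "t2", "s2", "maxScore")
    if (!all(need %in% names(object@objectives)))
        return(paste("objectives must have columns:",
                     paste(need, collapse = ", ")))
    ob <- object@objectives
    if (any(!ob$fun %in% c("threshold", "linear")))
        return("fun must be 'threshold' or 'linear'")
    if (any(!ob$direction %in% c("at-least", "at-most")))
        return("direction must be 'at-least' or 'at-most'")
    if (any(ob$maxScore <= 0))
        return("maxScore must be > 0")
    lin <- ob$fun == "linear"
    if (any(lin & (is.na(ob$t2) | is.na(ob$s2))))
        return("linear objectives need two thresholds with scores")
    if (any(lin & ob$t1 == ob$t2, na.rm = TRUE))
        return("linear objectives need two distinct thresholds")
    if (any(lin & ob$s1 < ob$s2, na.rm = TRUE))
        return("the ideal threshold must carry the larger score")
    if (any(ob$maxScore < ob$s1) ||
        any(ob$maxScore[lin] < ob$s2[lin]))
        return("maxScore must be >= every threshold score")
    if (abs(object@pqmMax - sum(ob$maxScore)) > 1e-9)
        return("pqmMax must equal the sum of maxScore")
    TRUE
})

#' PQMResult: achieved plan-quality scores
#'
#' @slot perObjective data.frame with the achieved statistic value, the
#'   awarded points and a flag per objective.
#' @slot pqm total awarded points.
#' @slot pqmMax peak achievable points.
#' @slot npqm \code{100 * pqm / pqmMax}, in [0, 100].
#' @export
setClass("PQMResult",
    representation(perObjective = "data.frame", pqm = "numeric",
                   pqmMax = "numeric", npqm = "numeric"))

setValidity("PQMResult", function(object) {
    if (object@npqm < -1e-9 || object@npqm > 100 + 1e-9)
        return("npqm must lie in [0, 100]")
    if (object@pqm < -1e-9 || object@pqm > object@pqmMax + 1e-9)
        return("pqm must lie in [0, pqmMax]")
    TRUE
})
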
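#' Create a ContourSet
#'
#' @param name structure name.
#' @param slices list of slices, each a list with \code{z} (mm) and
#'   \code{polygons} (list of n x 2 matrices of (x, y) mm vertices,
#'   n >= 3, implicitly closed).
#' @return a \linkS4class{ContourSet}.
#' @export
ContourSet <- function(name, slices = list()) {
    new("ContourSet", name = name, slices = slices)
}

#' Create a StructureMask
#'
#' @param name structure name.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param voxels logical array matching \code{dim3(grid)}; defaults to an
#'   all-FALSE mask.
#' @return a \linkS4class{StructureMask}.
#' @export
StructureMask <- function(name, grid, voxels = NULL) {
    if (is.null(voxels)) voxels <- array(FALSE, dim3(grid))
    storage.mode(voxels) <- "logical"
    if (is.null(dim(voxels))) dim(voxels) <- dim3(grid)
    new("StructureMask", name = name, grid = grid, voxels = voxels)
}

#' @rdname maskArray
#' @export
setMethod("maskArray", "StructureMask", function(x) x@voxels)

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "StructureMask", function(x) x@grid)

#' @rdname volumeCC
#' @export
setMethod("volumeCC", "StructureMask", function(x)
    sum(x@voxels) * voxelVolumeCC(x@grid))

setMethod("show", "StructureMask", function(object) {
    cat("StructureMask '", object@name, "': ",
        format(volumeCC(object), digits = 4), " cc (",
        sum(object@voxels), " voxels)\n", sep = "")
})

## even-odd point-in-polygon over many points; polys is a list of n x 2
## vertex matrices. A point is inside if a rightward ray crosses the union
## of polygon boundaries an odd number of times.
pointsInPolygonsEO <- function(px, py, polys) {
    inside <- rep(FALSE, length(px))
    for (p in polys) {
        n <- nrow(p)
        xs <- p[, 1]; ys <- p[, 2]
        xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
        crossings <- integer(length(px))
        for (e in seq_len(n)) {
            y1 <- ys[e]; y2 <- ye[e]
            if (y1 == y2) next                     # horizontal edge: no crossing
            straddles <- (y1 > py) != (y2 > py)
            if (any(straddles)) {
                t <- (py[straddles] - y1) / (y2 - y1)
                xint <- xs[e] + t * (xe[e] - xs[e])
                hit <- xint > px[straddles]
                crossings[straddles] <- crossings[straddles] + hit
            }
        }
        inside <- xor(inside, crossings %% 2L == 1L)
    }
    inside
}

#' Rasterize planar contours to a voxel mask
#'
#' A voxel is set iff its center lies inside an odd number of the slice's
#' polygons (even-odd rule), so holes carried as separate polygons are
#' respected. Contour z positions are attributed to the nearest grid slice
#' plane; a contour further than half a slice thickness from every plane
#' signals a coordinate mismatch.
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param grid the target \linkS4class{VoxelGrid}.
#' @return a \linkS4class{StructureMask} on \code{grid}.
#' @examples
#' g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(5, 5, 1))
#' sq <- rbind(c(0.5, 0.5), c(2.5, 0.5), c(2.5, 2.5), c(0.5, 2.5))
#' m <- rasterizeContours(ContourSet("roi", list(list(z = 0,
#'     polygons = list(sq)))), g)
#' volumeCC(m) * 1000  # mm^3
#' @export
rasterizeContours <- function(contours, grid) {
    stopifnot(is(contours, "ContourSet"), is(grid, "VoxelGrid"))
    validObject(contours)
    mask <- array(FALSE, dim3(grid))
    if (!length(contours@slices))
        return(StructureMask(contours@name, grid, mask))
    zc <- axisCenters(grid, 3)
    halfdz <- grid@spacing[3] / 2
    ## group polygons by the grid slice they belong to
    bySlice <- vector("list", grid@dims[3])
    for (sl in contours@slices) {
        k <- which.min(abs(zc - sl$z))
        if (abs(zc[k] - sl$z) > halfdz + 1e-9)
            stop("contour at z = ", sl$z,
                 " mm is not attributable to any slice plane ",
                 "(coordinate mismatch)")
        bySlice[[k]] <- c(bySlice[[k]], sl$polygons)
    }
    cx <- axisCenters(grid, 1)
    cy <- axisCenters(grid, 2)
    px <- rep(cx, times = grid@dims[2])
    py <- rep(cy, each = grid@dims[1])
    for (k in seq_len(grid@dims[3])) {
        if (is.null(bySlice[[k]])) next
        inside <- pointsInPolygonsEO(px, py, bySlice[[k]])
        mask[, , k] <- matrix(inside, grid@dims[1], grid@dims[2])
    }
    StructureMask(contours@name, grid, mask)
}

## offsets (in voxels) of a direction-dependent ellipsoidal structuring
## element; margins is the named 6-vector of reaches in mm
marginOffsets <- function(grid, margins) {
    sp <- grid@spacing
    ## per-axis radii, split by sign of the offset along that axis
    rpos <- c(0, 0, 0); rneg <- c(0, 0, 0)
    for (d in names(margins)) {
        da <- directionAxis(grid, d)
        if (da$sign > 0) rpos[da$axis] <- margins[[d]]
        else rneg[da$axis] <- margins[[d]]
    }
    rng <- function(a) {
        lo <- -floor(rneg[a] / sp[a]); hi <- floor(rpos[a] / sp[a])
        lo:hi
    }
    off <- expand.grid(i = rng(1), j = rng(2), k = rng(3))
    d2 <- matrix(0, nrow(off), 1)
    ok <- rep(TRUE, nrow(off))
    acc <- numeric(nrow(off))
    for (a in 1:3) {
        d <- off[[a]] * sp[a]
        r <- ifelse(d >= 0, rpos[a], rneg[a])
        term <- ifelse(d == 0, 0, ifelse(r > 0, (d / r)^2, Inf))
        acc <- acc + term
    }
    off[acc <= 1 + 1e-12, , drop = FALSE]
}

#' Expand a mask by anatomical margins
#'
#' Grows a structure by direction-dependent margins, the operation that
#' turns a clinical target volume into a planning target volume (e.g. 5 mm
#' in all directions except 3 mm posterior). The reach is an anisotropic
#' Euclidean ellipsoid split per half-axis: a voxel enters the expansion if
#' some occupied voxel center lies within the direction-dependent reach of
#' its center.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param margins named numeric vector or list with entries \code{left},
#'   \code{right}, \code{anterior}, \code{posterior}, \code{superior},
#'   \code{inferior} in mm (all >= 0). Missing names default to 0.
#' @return the expanded \linkS4class{StructureMask} (a superset of the
#'   input; identical when all margins are 0).
#' @seealso \code{\link{isotropicMargins}} for the common shorthand.
#' @export
expandMargin <- function(mask, margins) {
    stopifnot(is(mask, "StructureMask"))
    all6 <- c("left", "right", "anterior", "posterior",
              "superior", "inferior")
    m <- setNames(rep(0, 6), all6)
    m[names(margins)] <- unlist(margins)
    if (any(m < 0)) stop("margins must be >= 0")
    if (all(m == 0)) return(mask)
    off <- marginOffsets(mask@grid, as.list(m))
    dims <- dim3(mask@grid)
    src <- mask@voxels
    out <- array(FALSE, dims)
    for (r in seq_len(nrow(off))) {
        i <- off$i[r]; j <- off$j[r]; k <- off$k[r]
        ## destination <- source shifted by (i, j, k)
        dx <- seq(max(1, 1 + i), min(dims[1], dims[1] + i))
        dy <- seq(max(1, 1 + j), min(dims[2], dims[2] + j))
        dz <- seq(max(1, 1 + k), min(dims[3], dims[3] + k))
        if (!length(dx) || !length(dy) || !length(dz)) next
        out[dx, dy, dz] <- out[dx, dy, dz] |
            src[dx - i, dy - j, dz - k, drop = FALSE]
    }
    StructureMask(mask@name, mask@grid, out)
}

#' Uniform margins with a posterior exception
#'
#' @param mm margin applied left/right/anterior/superior/inferior, mm.
#' @param posterior posterior margin, mm; defaults to \code{mm}.
#' @return a named 6-vector suitable for \code{\link{expandMargin}}.
#' @export
isotropicMargins <- function(mm, posterior = mm) {
    c(left = mm, right = mm, anterior = mm, posterior = posterior,
      superior = mm, inferior = mm)
}

## logical array marking occupied voxels with a 6-connected unset or
## out-of-grid neighbour
surfaceArray <- function(voxels) {
    dims <- dim(voxels)
    interior <- array(TRUE, dims)
    shiftCovered <- function(axis, dir) {
        cov <- array(FALSE, dims)
        n <- dims[axis]
        if (n == 1L) return(cov)   # single layer: neighbour always out-of-grid
        idx <- lapply(dims, seq_len)
        src <- idx; dst <- idx
        if (dir > 0) { dst[[axis]] <- 2:n;       src[[axis]] <- 1:(n - 1) }
        else         { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
        cov <- do.call(`[<-`, c(list(cov), dst, list(
            do.call(`[`, c(list(voxels), src, list(drop = FALSE))))))
        cov
    }
    for (a in 1:3) for (s in c(-1, 1))
        interior <- interior & shiftCovered(a, s)
    voxels & !interior
}

#' Surface voxel centers of a mask
#'
#' Returns the mm centers of occupied voxels that have at least one
#' 6-connected unoccupied or out-of-grid neighbour. These are the points
#' Hausdorff distances are measured between.
#'
#' @param mask a nonempty \linkS4class{StructureMask}.
#' @return an n x 3 numeric matrix of (x, y, z) mm.
#' @export
surfacePoints <- function(mask) {
    stopifnot(is(mask, "StructureMask"))
    if (!any(mask@voxels)) stop("empty structure: no surface")
    voxelCenters(mask@grid, surfaceArray(mask@voxels))
}

#' Create a StructureSet
#'
#' Structure names are standardized through the alias table so that sets
#' from different sources line up (e.g. \code{"Femur_R"} and
#' \code{"Right Femur"} resolve to one name).
#'
#' @param structures list of \linkS4class{StructureMask} objects (named or
#'   carrying their own names).
#' @param provenance one of \code{"manual"}, \code{"ai"},
#'   \code{"ai_adjusted"}.
#' @param observer observer id (default \code{""}).
#' @param standardize standardize structure names through
#'   \code{\link{standardizeStructureName}}? Default TRUE.
#' @return a \linkS4class{StructureSet}.
#' @export
StructureSet <- function(structures, provenance = "manual", observer = "",
                         standardize = TRUE) {
    if (is.null(names(structures)))
        names(structures) <- vapply(structures, function(m) m@name, "")
    if (standardize) {
        nm <- standardizeStructureName(names(structures))
        names(structures) <- nm
        structures <- Map(function(m, n) { m@name <- n; m },
                          structures, nm)
    }
    new("StructureSet", provenance = provenance, observer = observer,
        structures = structures)
}

#' @rdname structureNames
#' @export
setMethod("structureNames", "StructureSet",
          function(x) names(x@structures))

#' @rdname getStructure
#' @export
setMethod("getStructure", "StructureSet", function(x, name) {
    if (!name %in% names(x@structures))
        stop("no structure named '", name, "' in this set")
    x@structures[[name]]
})

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "StructureSet", function(x) {
    if (!length(x@structures)) stop("empty structure set has no grid")
    x@structures[[1]]@grid
})

setMethod("show", "StructureSet", function(object) {
    cat("StructureSet (", object@provenance,
        if (nzchar(object@observer)) paste0(", observer ", object@observer),
        "): ", length(object@structures), " structures\n", sep = "")
    if (length(object@structures))
        cat(" ", paste(names(object@structures), collapse = ", "), "\n")
})

aliasEnv <- new.env(parent = emptyenv())

loadAliasTable <- function() {
    if (is.null(aliasEnv$tab)) {
        f <- system.file("extdata", "structure_aliases.csv",
                         package = "AutoContourQA")
        tab <- utils::read.csv(f, stringsAsFactors = FALSE)
        key <- gsub("[^a-z0-9]", "", tolower(tab$alias))
        aliasEnv$tab <- setNames(tab$canonical, key)
    }
    aliasEnv$tab
}

#' Standardize structure names
#'
#' Maps clinical naming variants (underscores, laterality abbreviations,
#' TPS-style short names) onto one canonical name per structure using the
#' bundled alias table; unknown names are returned unchanged apart from
#' whitespace trimming.
#'
#' @param x character vector of structure names.
#' @return character vector of standardized names.
#' @examples
#' standardizeStructureName(c("Femur_R", "Parotid_C", "AnalCanal"))
#' @export
standardizeStructureName <- function(x) {
    tab <- loadAliasTable()
    key <- gsub("[^a-z0-9]", "", tolower(x))
    out <- unname(tab[key])
    ifelse(is.na(out), trimws(x), out)
}
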
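#' Create a VoxelGrid
#'
#' @param origin mm position of voxel (0,0,0); numeric(3).
#' @param spacing mm per axis; numeric(3), all > 0. The third entry is the
#'   slice thickness.
#' @param dims voxel counts per axis; integer(3).
#' @param posterior in-plane direction pointing posterior: one of
#'   \code{"+x"}, \code{"-x"}, \code{"+y"}, \code{"-y"}. Defaults to
#'   \code{"+y"}, the usual head-first-supine DICOM convention.
#' @return a \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(10, 10, 10))
#' voxelVolumeCC(g)
#' @export
VoxelGrid <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      dims, posterior = "+y") {
    new("VoxelGrid", origin = as.numeric(origin),
        spacing = as.numeric(spacing), dims = as.integer(dims),
        posterior = posterior)
}

#' @rdname dim3
#' @export
setMethod("dim3", "VoxelGrid", function(x) x@dims)

#' @rdname dim3
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname dim3
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname dim3
#' @export
setMethod("voxelVolumeCC", "VoxelGrid", function(x) prod(x@spacing) / 1000)

setMethod("show", "VoxelGrid", function(object) {
    cat("VoxelGrid:", paste(object@dims, collapse = " x "), "voxels,",
        paste(format(object@spacing), collapse = " x "), "mm spacing\n")
    cat("  origin (mm):", paste(format(object@origin), collapse = ", "),
        " posterior:", object@posterior, "\n")
})

#' Do two grids describe the same lattice?
#'
#' @param a,b \linkS4class{VoxelGrid} objects.
#' @param tol absolute tolerance in mm for origin/spacing comparison.
#' @return logical.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
    identical(a@dims, b@dims) &&
        all(abs(a@spacing - b@spacing) < tol) &&
        all(abs(a@origin - b@origin) < tol) &&
        a@posterior == b@posterior
}

## per-axis voxel center coordinates (mm); 0-based index convention
axisCenters <- function(grid, axis) {
    grid@origin[axis] + (seq_len(grid@dims[axis]) - 1) * grid@spacing[axis]
}

#' Voxel center coordinates
#'
#' Returns the mm coordinates of voxel centers, either as three per-axis
#' vectors or as an n x 3 matrix for a subset of voxels.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param which optional logical array or integer vector of voxel indices;
#'   when given, an n x 3 matrix of centers for those voxels is returned.
#' @return a list of three vectors (default) or an n x 3 matrix.
#' @export
voxelCenters <- function(grid, which = NULL) {
    cx <- axisCenters(grid, 1)
    cy <- axisCenters(grid, 2)
    cz <- axisCenters(grid, 3)
    if (is.null(which)) return(list(x = cx, y = cy, z = cz))
    idx <- if (is.logical(which)) which(which) else as.integer(which)
    ai <- arrayInd(idx, grid@dims)
    cbind(x = cx[ai[, 1]], y = cy[ai[, 2]], z = cz[ai[, 3]])
}

## Resolve an anatomical direction to (axis, sign) on this grid.
## Superior is always +z (axial slices stack along the third axis).
directionAxis <- function(grid, direction) {
    post <- grid@posterior
    pa <- if (substr(post, 2, 2) == "x") 1L else 2L
    ps <- if (substr(post, 1, 1) == "+") 1 else -1
    la <- if (pa == 1L) 2L else 1L   # left-right axis: the other in-plane one
    switch(direction,
        posterior = list(axis = pa, sign = ps),
        anterior  = list(axis = pa, sign = -ps),
        left      = list(axis = la, sign = 1),
        right     = list(axis = la, sign = -1),
        superior  = list(axis = 3L, sign = 1),
        inferior  = list(axis = 3L, sign = -1),
        stop("unknown anatomical direction: ", direction))
}
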
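checkSharedGrid <- function(a, b) {
    if (!sameGrid(a@grid, b@grid))
        stop("incompatible grids: masks must share one VoxelGrid")
}

#' Dice similarity coefficient
#'
#' Volumetric overlap of two masks on one grid,
#' \code{2 |A intersect B| / (|A| + |B|)}: 1 for identical nonempty masks,
#' 0 for disjoint ones. Undefined (an error) when both masks are empty.
#'
#' @param a,b \linkS4class{StructureMask} objects on the same grid.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
    checkSharedGrid(a, b)
    na <- sum(a@voxels); nb <- sum(b@voxels)
    if (na + nb == 0L)
        stop("undefined metric: both masks are empty")
    2 * sum(a@voxels & b@voxels) / (na + nb)
}

## exact distance (mm) from every voxel center to the nearest TRUE voxel
## center of `feature` (squared EDT from the compiled backend)
distanceToFeature <- function(feature, grid) {
    sqrt(.cpp_edt_sq(as.vector(feature), dim3(grid), gridSpacing(grid)))
}

#' Directed Hausdorff distance
#'
#' \code{max} over surface voxel centers of \code{a} of the distance to the
#' nearest surface voxel center of \code{b}, in mm. Generally asymmetric.
#'
#' @param a,b nonempty \linkS4class{StructureMask} objects on one grid.
#' @return distance in mm (>= 0).
#' @export
directedHausdorff <- function(a, b) {
    checkSharedGrid(a, b)
    if (!any(a@voxels) || !any(b@voxels))
        stop("empty structure: Hausdorff distance undefined")
    sa <- surfaceArray(a@voxels)
    sb <- surfaceArray(b@voxels)
    db <- distanceToFeature(sb, a@grid)
    max(db[sa])
}

#' Hausdorff distance
#'
#' Bidirectional maximum surface-to-surface separation:
#' \code{max(h(a, b), h(b, a))} with \code{h} the directed distance between
#' surface voxel centers. Symmetric; 0 iff the surfaces coincide.
#'
#' @param a,b nonempty \linkS4class{StructureMask} objects on one grid.
#' @return distance in mm (>= 0).
#' @examples
#' g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(6, 6, 1))
#' A <- array(FALSE, c(6, 6, 1)); A[1, 1, 1] <- TRUE
#' B <- array(FALSE, c(6, 6, 1)); B[4, 5, 1] <- TRUE
#' hausdorff(StructureMask("a", g, A), StructureMask("b", g, B))  # 5 mm
#' @export
hausdorff <- function(a, b) {
    max(directedHausdorff(a, b), directedHausdorff(b, a))
}

#' Relative volume difference
#'
#' \code{(V_test - V_ref) / V_ref}: signed; 0 for equal volumes, positive
#' when the test structure is larger. Always > -1 for a nonempty test.
#'
#' @param test,ref \linkS4class{StructureMask} objects; \code{ref} must be
#'   nonempty.
#' @return signed unitless ratio.
#' @export
rvd <- function(test, ref) {
    vref <- volumeCC(ref)
    if (vref <= 0)
        stop("empty reference structure: relative volume undefined")
    (volumeCC(test) - vref) / vref
}

#' Compare two structure sets structure-by-structure
#'
#' Computes DSC, Hausdorff distance and signed/absolute relative volume
#' difference for every structure present in both sets. Structures present
#' in only one set are flagged and carry no metric values; structures empty
#' in both sets are flagged \code{both-empty} (metrics undefined); a
#' structure empty in exactly one set gets DSC 0 with HD undefined, and
#' RVD -1 (test empty) or undefined (reference empty).
#'
#' @param A the reference \linkS4class{StructureSet} (RVD denominator).
#' @param B the test \linkS4class{StructureSet}.
#' @return a data.frame with columns \code{structure}, \code{dsc},
#'   \code{hd_mm}, \code{rvd_signed}, \code{rvd_abs}, \code{flag}.
#' @export
compareStructureSets <- function(A, B) {
    nmA <- structureNames(A); nmB <- structureNames(B)
    allNames <- union(nmA, nmB)
    res <- lapply(allNames, function(nm) {
        row <- data.frame(structure = nm, dsc = NA_real_, hd_mm = NA_real_,
                          rvd_signed = NA_real_, rvd_abs = NA_real_,
                          flag = "")
        if (!nm %in% nmA) { row$flag <- "missing-in-A"; return(row) }
        if (!nm %in% nmB) { row$flag <- "missing-in-B"; return(row) }
        a <- getStructure(A, nm); b <- getStructure(B, nm)
        ea <- !any(a@voxels); eb <- !any(b@voxels)
        if (ea && eb) { row$flag <- "both-empty"; return(row) }
        if (ea || eb) {
            row$dsc <- 0
            if (!ea) {          # reference present, test empty
                row$rvd_signed <- -1; row$rvd_abs <- 1
                row$flag <- "empty-in-B"
            } else row$flag <- "empty-in-A"
            return(row)
        }
        row$dsc <- dice(a, b)
        row$hd_mm <- hausdorff(a, b)
        row$rvd_signed <- rvd(b, a)
        row$rvd_abs <- abs(row$rvd_signed)
        row
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
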
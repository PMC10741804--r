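#' @useDynLib AutoContourQA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Accessors for grid geometry
#'
#' \code{dim3} returns the voxel counts, \code{gridSpacing} the mm spacing,
#' \code{gridOrigin} the mm origin and \code{voxelVolumeCC} the volume of a
#' single voxel in cc (\code{prod(spacing) / 1000}).
#'
#' @param x a \linkS4class{VoxelGrid} (or an object carrying one).
#' @return numeric or integer vectors; a scalar for \code{voxelVolumeCC}.
#' @aliases dim3 gridSpacing gridOrigin voxelVolumeCC
#' @export
setGeneric("dim3", function(x) standardGeneric("dim3"))

#' @rdname dim3
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname dim3
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname dim3
#' @export
setGeneric("voxelVolumeCC", function(x) standardGeneric("voxelVolumeCC"))

#' Access the grid of a mask, set or dose object
#'
#' @param x a \linkS4class{StructureMask}, \linkS4class{StructureSet} or
#'   \linkS4class{DoseGrid}.
#' @return the shared \linkS4class{VoxelGrid}.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' Structure volume in cc
#'
#' Count of occupied voxels times the voxel volume.
#'
#' @param x a \linkS4class{StructureMask}.
#' @return volume in cc (>= 0).
#' @export
setGeneric("volumeCC", function(x) standardGeneric("volumeCC"))

#' Names of the structures in a set
#'
#' @param x a \linkS4class{StructureSet}.
#' @return character vector of standardized structure names.
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' Extract one structure mask from a set
#'
#' @param x a \linkS4class{StructureSet}.
#' @param name standardized structure name.
#' @return the \linkS4class{StructureMask}.
#' @export
setGeneric("getStructure", function(x, name) standardGeneric("getStructure"))

#' Logical occupancy array of a mask
#'
#' @param x a \linkS4class{StructureMask}.
#' @return logical 3D array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Dose array and prescription of a DoseGrid
#'
#' @param x a \linkS4class{DoseGrid}.
#' @return numeric 3D array of cGy for \code{doseArray}; scalar cGy for
#'   \code{prescription}.
#' @aliases doseArray prescription
#' @export
setGeneric("doseArray", function(x) standardGeneric("doseArray"))

#' @rdname doseArray
#' @export
setGeneric("prescription", function(x) standardGeneric("prescription"))
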
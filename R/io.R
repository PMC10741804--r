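## Plain-text exchange formats. Masks use a run-length-encoded body so a
## typical organ mask is a few kilobytes; dose grids store one value per
## line at full precision. All files are self-describing via a key: value
## header and are round-trip exact.

writeHeader <- function(con, kind, grid, extra = character(0)) {
    writeLines(c(
        paste0("# AutoContourQA ", kind, " v1"),
        paste0("dims: ", paste(dim3(grid), collapse = " ")),
        paste0("spacing: ", paste(sprintf("%.10g", gridSpacing(grid)),
                                  collapse = " ")),
        paste0("origin: ", paste(sprintf("%.10g", gridOrigin(grid)),
                                 collapse = " ")),
        paste0("posterior: ", grid@posterior),
        extra), con)
}

parseHeader <- function(lines) {
    kv <- list()
    for (ln in lines) {
        if (startsWith(ln, "#")) next
        m <- regmatches(ln, regexec("^([a-zA-Z_]+):\\s*(.*)$", ln))[[1]]
        if (length(m) == 3) kv[[m[2]]] <- m[3]
    }
    kv
}

headerGrid <- function(kv) {
    VoxelGrid(origin = as.numeric(strsplit(kv$origin, " +")[[1]]),
              spacing = as.numeric(strsplit(kv$spacing, " +")[[1]]),
              dims = as.integer(strsplit(kv$dims, " +")[[1]]),
              posterior = kv$posterior)
}

#' Write / read a structure mask in the text exchange format
#'
#' Header lines carry the grid (dims, spacing, origin, posterior flag) and
#' the structure name; the body is the run-length encoding of the logical
#' array in column-major order, starting with the length of the initial
#' FALSE run (possibly 0).
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param path file path.
#' @return \code{readMaskText} returns a \linkS4class{StructureMask};
#'   \code{writeMaskText} returns \code{path} invisibly.
#' @export
writeMaskText <- function(mask, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeHeader(con, "mask", mask@grid,
                c(paste0("name: ", mask@name)))
    r <- rle(as.vector(mask@voxels))
    runs <- r$lengths
    if (length(runs) == 0L) runs <- integer(0)
    else if (r$values[1]) runs <- c(0L, runs)
    writeLines(paste0("runs: ", paste(runs, collapse = " ")), con)
    invisible(path)
}

#' @rdname writeMaskText
#' @export
readMaskText <- function(path) {
    lines <- readLines(path)
    kv <- parseHeader(lines)
    grid <- headerGrid(kv)
    runs <- as.integer(strsplit(kv$runs, " +")[[1]])
    vals <- rep(rep(c(FALSE, TRUE), length.out = length(runs)), runs)
    n <- prod(dim3(grid))
    if (length(vals) < n) vals <- c(vals, rep(FALSE, n - length(vals)))
    StructureMask(kv$name, grid, array(vals, dim3(grid)))
}

#' Write / read a dose grid in the text exchange format
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param path file path.
#' @return \code{readDoseText} returns a \linkS4class{DoseGrid}.
#' @export
writeDoseText <- function(dose, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeHeader(con, "dose", dose@grid,
                c(paste0("prescription: ",
                         sprintf("%.10g", dose@prescription))))
    writeLines("values:", con)
    writeLines(sprintf("%.10g", as.vector(dose@dose)), con)
    invisible(path)
}

#' @rdname writeDoseText
#' @export
readDoseText <- function(path) {
    lines <- readLines(path)
    vstart <- which(lines == "values:")[1]
    kv <- parseHeader(lines[seq_len(vstart - 1)])
    grid <- headerGrid(kv)
    vals <- as.numeric(lines[(vstart + 1):length(lines)])
    DoseGrid(grid, array(vals, dim3(grid)),
             prescription = as.numeric(kv$prescription))
}

#' Write / read a contour set as CSV
#'
#' Columns: \code{structure}, \code{z} (mm), \code{polygon} (index within
#' the slice), \code{x}, \code{y} (mm vertex coordinates, in order).
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param path file path.
#' @return \code{readContourCSV} returns a \linkS4class{ContourSet}.
#' @export
writeContourCSV <- function(contours, path) {
    rows <- list()
    for (sl in contours@slices)
        for (pi in seq_along(sl$polygons)) {
            p <- sl$polygons[[pi]]
            rows[[length(rows) + 1L]] <- data.frame(
                structure = contours@name, z = sl$z, polygon = pi,
                x = p[, 1], y = p[, 2])
        }
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(structure = character(0), z = numeric(0),
                          polygon = integer(0), x = numeric(0),
                          y = numeric(0))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeContourCSV
#' @export
readContourCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) return(ContourSet("structure"))
    name <- df$structure[1]
    slices <- lapply(split(df, df$z), function(sl) {
        list(z = sl$z[1],
             polygons = lapply(split(sl, sl$polygon), function(p)
                 cbind(p$x, p$y)))
    })
    ContourSet(name, unname(slices))
}
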
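## Independent brute-force oracles and small fixture builders. Every
## oracle here recomputes a quantity from first principles, without
## touching the implementation path it checks.

## Dice by direct voxel enumeration
bruteDice <- function(va, vb) {
    2 * sum(va & vb) / (sum(va) + sum(vb))
}

## surface voxels by explicit 6-neighbour inspection
bruteSurface <- function(v) {
    dims <- dim(v)
    out <- array(FALSE, dims)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
        for (k in seq_len(dims[3])) {
            if (!v[i, j, k]) next
            nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                        c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
            surf <- FALSE
            for (r in seq_len(6)) {
                p <- nb[r, ]
                if (any(p < 1) || any(p > dims) || !v[p[1], p[2], p[3]]) {
                    surf <- TRUE; break
                }
            }
            out[i, j, k] <- surf
        }
    out
}

## mm coordinates of TRUE voxels (0-based index * spacing + origin)
voxelCoordsMM <- function(v, spacing, origin = c(0, 0, 0)) {
    ai <- which(v, arr.ind = TRUE)
    t(t(ai - 1) * spacing + origin)
}

## directed and bidirectional Hausdorff by all-pairs surface distances
bruteDirectedHausdorff <- function(va, vb, spacing) {
    pa <- voxelCoordsMM(bruteSurface(va), spacing)
    pb <- voxelCoordsMM(bruteSurface(vb), spacing)
    max(apply(pa, 1, function(p)
        sqrt(min(colSums((t(pb) - p)^2)))))
}

bruteHausdorff <- function(va, vb, spacing) {
    max(bruteDirectedHausdorff(va, vb, spacing),
        bruteDirectedHausdorff(vb, va, spacing))
}

## D_x% by descending sort: dose received by the coldest voxel among the
## hottest x% (voxel counts rounded up)
sortDoseAtPercent <- function(doses, x) {
    d <- sort(doses, decreasing = TRUE)
    d[ceiling(x / 100 * length(d))]
}

## D_vcc by descending sort with equal voxel volumes
sortDoseAtVolume <- function(doses, v, voxelCC) {
    d <- sort(doses, decreasing = TRUE)
    d[min(length(d), max(1, ceiling(v / voxelCC)))]
}

## exact two-sided rank-sum p-value by exhaustive enumeration of which
## combined ranks belong to x (no ties assumed); mirrors the two-sided
## doubling rule of the exact Mann-Whitney test
enumRankSumP <- function(x, y) {
    n <- length(x); m <- length(y)
    U <- sum(outer(x, y, ">"))
    r <- rank(c(x, y))
    sets <- utils::combn(n + m, n)
    Us <- apply(sets, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
    if (U > n * m / 2) p <- mean(Us >= U) else p <- mean(Us <= U)
    min(2 * p, 1)
}

## random blob mask: a few random ellipsoids on a small grid, never empty
randomBlob <- function(dims, spacing = c(1, 1, 1)) {
    v <- array(FALSE, dims)
    idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                       k = seq_len(dims[3]))
    for (b in seq_len(sample(1:2, 1))) {
        c0 <- runif(3, 1, dims)
        r0 <- runif(3, 1, pmax(2, dims / 2))
        v <- v | array(((idx$i - c0[1]) / r0[1])^2 +
                       ((idx$j - c0[2]) / r0[2])^2 +
                       ((idx$k - c0[3]) / r0[3])^2 <= 1, dims)
    }
    if (!any(v)) v[sample(length(v), 1)] <- TRUE
    v
}

## one-slice grid and a mask from explicit voxel indices
maskFromIndices <- function(grid, ind, name = "m") {
    v <- array(FALSE, dim3(grid))
    v[ind] <- TRUE
    StructureMask(name, grid, v)
}

## memoized shared fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

sharedCohort <- function() {
    if (is.null(.fixtures$cohort))
        .fixtures$cohort <- makeCohort(5, "prostate", seed = 42)
    .fixtures$cohort
}

## a tiny plan meeting every prostate scorecard objective: uniform
## 6100 cGy inside a box PTV, zero elsewhere, OARs far from the target
allMetProstatePlan <- function() {
    g <- VoxelGrid(spacing = c(2, 2, 2), dims = c(40L, 40L, 20L))
    ptv <- boxMask(g, "PTV", c(10, 10, 10), c(30, 30, 26))
    oars <- list(
        boxMask(g, "Rectum", c(44, 44, 10), c(58, 58, 26)),
        boxMask(g, "Bladder", c(10, 44, 10), c(26, 58, 26)),
        boxMask(g, "Anal Canal", c(44, 10, 10), c(58, 26, 26)),
        boxMask(g, "Left Femur", c(62, 30, 10), c(76, 44, 26)),
        boxMask(g, "Right Femur", c(2, 62, 10), c(16, 76, 26)))
    ss <- StructureSet(c(list(ptv), oars), provenance = "manual")
    dose <- array(0, dim3(g))
    dose[maskArray(ptv)] <- 6100
    list(dose = DoseGrid(g, dose, prescription = 6000), structures = ss)
}
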
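test_that("rasterization follows the even-odd voxel-center rule", {
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(5L, 5L, 1L))
    ## 2x2 mm square enclosing exactly the 4 centers (0.5..2.5 mm)
    sq <- rbind(c(0.5, 0.5), c(2.5, 0.5), c(2.5, 2.5), c(0.5, 2.5))
    m <- rasterizeContours(ContourSet("roi",
        list(list(z = 0, polygons = list(sq)))), g)
    expect_identical(sum(maskArray(m)), 4L)
    ## oracle: explicit point-in-polygon test over every voxel center
    inside <- sapply(0:4, function(i) sapply(0:4, function(j)
        i > 0.5 && i < 2.5 && j > 0.5 && j < 2.5))
    expect_identical(maskArray(m)[, , 1], t(inside))

    ## empty contour set -> all-false mask
    m0 <- rasterizeContours(ContourSet("empty"), g)
    expect_false(any(maskArray(m0)))

    ## square annulus: inner square punches a hole (even-odd counting)
    g2 <- VoxelGrid(spacing = c(1, 1, 1), dims = c(9L, 9L, 1L))
    outer <- rbind(c(0.5, 0.5), c(7.5, 0.5), c(7.5, 7.5), c(0.5, 7.5))
    inner <- rbind(c(2.5, 2.5), c(5.5, 2.5), c(5.5, 5.5), c(2.5, 5.5))
    mring <- rasterizeContours(ContourSet("ring",
        list(list(z = 0, polygons = list(outer, inner)))), g2)
    v <- maskArray(mring)[, , 1]
    expect_true(v[2, 2])            # inside outer only
    expect_false(v[5, 5])           # inside both -> hole
    expect_identical(sum(v), 49L - 9L)
})

test_that("rasterization agrees with an independent point-in-polygon test", {
    ## mgcv::in.out as the external even-odd oracle on irregular polygons
    set.seed(71)
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(12L, 12L, 1L))
    for (rep in 1:5) {
        ang <- sort(runif(7, 0, 2 * pi))
        r <- runif(7, 2, 5.3)
        poly <- cbind(5.5 + r * cos(ang), 5.5 + r * sin(ang))
        m <- rasterizeContours(ContourSet("p",
            list(list(z = 0, polygons = list(poly)))), g)
        pts <- as.matrix(expand.grid(x = 0:11, y = 0:11))
        oracle <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
        expect_identical(as.vector(maskArray(m)[, , 1]),
                         as.vector(matrix(oracle, 12, 12)))
    }
})

test_that("rasterization rejects degenerate and misplaced contours", {
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(5L, 5L, 1L))
    sq <- rbind(c(0.5, 0.5), c(2.5, 0.5), c(2.5, 2.5), c(0.5, 2.5))
    expect_error(rasterizeContours(ContourSet("far",
        list(list(z = 10, polygons = list(sq)))), g),
        "coordinate mismatch")
    expect_error(ContourSet("bad",
        list(list(z = 0, polygons = list(sq[1:2, ])))),
        "fewer than 3 vertices")
})

test_that("rasterized prism volume converges to the analytic volume", {
    ## right triangle, legs 30 mm: area 450 mm^2, one 2 mm slice
    tri <- rbind(c(5, 5), c(35, 5), c(5, 35))
    vols <- sapply(c(2, 0.5), function(h) {
        n <- as.integer(ceiling(42 / h))
        g <- VoxelGrid(spacing = c(h, h, 2), dims = c(n, n, 1L))
        volumeCC(rasterizeContours(ContourSet("tri",
            list(list(z = 0, polygons = list(tri)))), g)) * 1000
    })
    analytic <- 450 * 2
    err <- abs(vols - analytic)
    expect_lt(err[2], err[1])            # finer grid strictly better
    expect_lt(err[2] / analytic, 0.05)
})

test_that("volume is voxel count times voxel volume", {
    g1 <- VoxelGrid(spacing = c(1, 1, 1), dims = c(10L, 10L, 10L))
    m1 <- StructureMask("a", g1, array(TRUE, c(10, 10, 10)))
    expect_equal(volumeCC(m1), 1.0)      # 1000 mm^3
    expect_equal(volumeCC(StructureMask("e", g1)), 0)
    g5 <- VoxelGrid(spacing = c(5, 5, 5), dims = c(2L, 2L, 2L))
    m5 <- StructureMask("b", g5, array(TRUE, c(2, 2, 2)))
    expect_equal(volumeCC(m5), 1.0)      # 8 x 125 mm^3
})

test_that("margin expansion matches a brute-force distance check", {
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(13L, 13L, 13L))
    m <- maskFromIndices(g, cbind(7, 7, 7))
    ex <- expandMargin(m, isotropicMargins(5))
    ## oracle: every center within 5 mm of the seed center
    idx <- as.matrix(expand.grid(i = 1:13, j = 1:13, k = 1:13))
    d <- sqrt(rowSums((idx - 7)^2))
    expect_identical(as.vector(maskArray(ex)),
                     as.vector(array(d <= 5, c(13, 13, 13))))
})

test_that("margin expansion honours the reduced posterior margin", {
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(13L, 13L, 13L),
                   posterior = "+y")
    m <- maskFromIndices(g, cbind(7, 7, 7))
    ex <- expandMargin(m, isotropicMargins(5, posterior = 3))
    occ <- which(maskArray(ex), arr.ind = TRUE)
    expect_identical(max(occ[, 2]) - 7L, 3L)    # posterior (+y) reach
    expect_identical(7L - min(occ[, 2]), 5L)    # anterior reach
    expect_identical(max(occ[, 1]) - 7L, 5L)    # lateral unchanged
    ## flipping the posterior flag mirrors the asymmetry
    gflip <- VoxelGrid(spacing = c(1, 1, 1), dims = c(13L, 13L, 13L),
                       posterior = "-y")
    exf <- expandMargin(maskFromIndices(gflip, cbind(7, 7, 7)),
                        isotropicMargins(5, posterior = 3))
    occf <- which(maskArray(exf), arr.ind = TRUE)
    expect_identical(7L - min(occf[, 2]), 3L)
})

test_that("margin expansion is monotone and identity at zero", {
    set.seed(5)
    g <- VoxelGrid(spacing = c(1, 1, 2), dims = c(10L, 10L, 6L))
    for (rep in 1:5) {
        m <- StructureMask("b", g, randomBlob(c(10, 10, 6)))
        expect_identical(maskArray(expandMargin(m, isotropicMargins(0))),
                         maskArray(m))
        e2 <- expandMargin(m, isotropicMargins(2))
        e4 <- expandMargin(m, isotropicMargins(4))
        expect_true(all(maskArray(m) <= maskArray(e2)))   # superset
        expect_true(all(maskArray(e2) <= maskArray(e4)))  # monotone
        expect_identical(maskArray(expandMargin(e2, isotropicMargins(0))),
                         maskArray(e2))
    }
})

test_that("surface extraction matches explicit neighbour inspection", {
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(5L, 5L, 5L))
    ## isolated voxel: it is its own surface
    m1 <- maskFromIndices(g, cbind(3, 3, 3))
    expect_equal(surfacePoints(m1), cbind(x = 2, y = 2, z = 2))
    ## filled 3x3x3 cube: 26 surface voxels (all but the center)
    v <- array(FALSE, c(5, 5, 5)); v[2:4, 2:4, 2:4] <- TRUE
    sp <- surfacePoints(StructureMask("c", g, v))
    expect_identical(nrow(sp), 26L)
    ## 1-voxel-thick slab: every voxel is surface
    vs <- array(FALSE, c(5, 5, 5)); vs[1:5, 1:5, 3] <- TRUE
    expect_identical(nrow(surfacePoints(StructureMask("s", g, vs))), 25L)
    ## random blobs against the brute-force oracle
    set.seed(9)
    for (rep in 1:5) {
        vb <- randomBlob(c(5, 5, 5))
        got <- surfacePoints(StructureMask("r", g, vb))
        want <- voxelCoordsMM(bruteSurface(vb), c(1, 1, 1))
        expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ,
                         drop = FALSE],
                     unname(want[order(want[, 1], want[, 2],
                                       want[, 3]), , drop = FALSE]),
                     ignore_attr = TRUE)
    }
    expect_error(surfacePoints(StructureMask("e", g)), "empty")
})

test_that("removing surface voxels strictly shrinks a nonempty mask", {
    set.seed(11)
    g <- VoxelGrid(spacing = c(1, 1, 1), dims = c(8L, 8L, 8L))
    for (rep in 1:5) {
        v <- randomBlob(c(8, 8, 8))
        m <- StructureMask("b", g, v)
        eroded <- v & !bruteSurface(v)
        expect_lt(sum(eroded), sum(v))
    }
})

test_that("mask and dose text formats round-trip exactly", {
    set.seed(3)
    g <- VoxelGrid(origin = c(-10, 5, 0), spacing = c(1.5, 2, 3),
                   dims = c(7L, 6L, 4L), posterior = "-y")
    m <- StructureMask("Anal Canal", g, randomBlob(c(7, 6, 4)))
    f <- tempfile(fileext = ".txt")
    writeMaskText(m, f)
    m2 <- readMaskText(f)
    expect_identical(maskArray(m2), maskArray(m))
    expect_true(sameGrid(voxelGrid(m2), g))
    expect_identical(m2@name, "Anal Canal")

    d <- DoseGrid(g, array(runif(7 * 6 * 4, 0, 7000), c(7, 6, 4)), 6000)
    fd <- tempfile(fileext = ".txt")
    writeDoseText(d, fd)
    d2 <- readDoseText(fd)
    expect_equal(doseArray(d2), doseArray(d), tolerance = 1e-9)
    expect_equal(prescription(d2), 6000)

    cs <- ContourSet("roi", list(list(z = 0, polygons = list(
        rbind(c(0.5, 0.5), c(2.5, 0.5), c(2.5, 2.5))))))
    fc <- tempfile(fileext = ".csv")
    writeContourCSV(cs, fc)
    cs2 <- readContourCSV(fc)
    expect_equal(cs2@slices[[1]]$polygons[[1]],
                 cs@slices[[1]]$polygons[[1]], ignore_attr = TRUE)
})

test_that("structure names standardize through the alias table", {
    expect_identical(
        standardizeStructureName(c("Femur_R", "AnalCanal", "Parotid_C",
                                   "SpinalCord", "not a structure")),
        c("Right Femur", "Anal Canal", "Right Parotid", "Spinal Cord",
          "not a structure"))
})
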
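## a 1 cc/voxel line grid makes volume arithmetic transparent
lineGrid <- function(n) VoxelGrid(spacing = c(10, 10, 10),
                                  dims = c(as.integer(n), 1L, 1L))

lineDose <- function(doses, rx = 6000) {
    g <- lineGrid(length(doses))
    DoseGrid(g, array(doses, c(length(doses), 1, 1)), rx)
}

lineMask <- function(n, of = n) {
    maskFromIndices(lineGrid(of), cbind(seq_len(n), 1, 1), "s")
}

test_that("dose resampling is exact for identity, constants and ramps", {
    g <- VoxelGrid(spacing = c(2, 2, 2), dims = c(6L, 5L, 4L))
    d <- DoseGrid(g, array(runif(120, 0, 6000), c(6, 5, 4)), 6000)
    expect_identical(doseArray(resampleDose(d, g)), doseArray(d))
    ## constant field stays constant on a shifted overlapping grid
    dc <- DoseGrid(g, array(6000, c(6, 5, 4)), 6000)
    t1 <- VoxelGrid(origin = c(1, 1, 1), spacing = c(2, 2, 2),
                    dims = c(4L, 4L, 3L))
    expect_equal(unique(as.vector(doseArray(resampleDose(dc, t1)))), 6000)
    ## linear ramp along x: midpoint voxels average their neighbours
    ramp <- DoseGrid(g, array(rep(100 * (1:6), 20), c(6, 5, 4)), 6000)
    tm <- VoxelGrid(origin = c(1, 0, 0), spacing = c(2, 2, 2),
                    dims = c(5L, 5L, 4L))
    got <- doseArray(resampleDose(ramp, tm))
    expect_equal(got[, 1, 1], 100 * (1:5) + 50)
    ## disjoint grids signal
    far <- VoxelGrid(origin = c(1000, 0, 0), spacing = c(2, 2, 2),
                     dims = c(3L, 3L, 3L))
    expect_error(resampleDose(d, far), "no overlap")
    ## prescription preserved
    expect_equal(prescription(resampleDose(d, t1)), 6000)
})

test_that("the DVH conserves volume and counts correctly", {
    d <- lineDose(seq(100, 800, by = 100))
    m <- lineMask(8)
    dvh <- computeDVH(d, m)
    expect_equal(dvh@totalVolume, volumeCC(m))
    expect_equal(dvh@volumeCC[1], 8)                    # V(0) = full
    expect_equal(dvh@volumePct[1], 100)
    expect_true(all(diff(dvh@volumeCC) <= 1e-12))       # non-increasing
    ## V(>= 450 cGy) = 4 cc by direct counting
    expect_equal(doseStatistic("V450cGycc", d, m), 4)
    expect_equal(doseStatistic("V450cGy", d, m), 50)
    ## re-binning leaves bin-aligned V_x unchanged
    dvh2 <- computeDVH(d, m, binWidth = 0.5)
    i1 <- which(dvh@doseBins == 450); i2 <- which(dvh2@doseBins == 450)
    expect_equal(dvh@volumeCC[i1], dvh2@volumeCC[i2])
    ## uniform field: 100% up to the dose, then 0
    du <- lineDose(rep(6000, 8))
    dvhu <- computeDVH(du, m)
    expect_equal(dvhu@volumePct[dvhu@doseBins <= 6000], rep(100, 6001))
    expect_equal(dvhu@volumePct[dvhu@doseBins > 6000], 0)
    expect_error(computeDVH(d, StructureMask("e", lineGrid(8))), "empty")
})

test_that("DVH inversion agrees with the sort-and-scan oracle", {
    ## D_cc on the 100..800 line: 2 cc from the top -> 700 cGy
    d <- lineDose(seq(100, 800, by = 100))
    m <- lineMask(8)
    dvh <- computeDVH(d, m)
    expect_equal(doseAtAbsoluteVolume(dvh, 2), 700)
    expect_equal(doseAtAbsoluteVolume(dvh, dvh@totalVolume), 100) # = Dmin
    expect_error(doseAtAbsoluteVolume(dvh, 9), "invalid volume")
    expect_error(doseAtVolumePercent(dvh, 0), "invalid percentile")
    ## two-level target: half 5700, half 6300
    d2 <- lineDose(c(rep(5700, 4), rep(6300, 4)))
    dvh2 <- computeDVH(d2, m)
    expect_equal(doseAtVolumePercent(dvh2, 50),
                 sortDoseAtPercent(c(rep(5700, 4), rep(6300, 4)), 50))
    ## uniform field: same value at any percentile / volume
    du <- computeDVH(lineDose(rep(4200, 8)), m)
    for (x in c(2, 50, 98)) expect_equal(doseAtVolumePercent(du, x), 4200)
    expect_equal(doseAtAbsoluteVolume(du, 0.5), 4200)
    ## random fields: DVH statistics within one bin width of sorting,
    ## and D_98 <= D_50 <= D_2
    set.seed(13)
    for (rep in 1:10) {
        n <- sample(5:40, 1)
        doses <- runif(n, 0, 7000)
        dd <- lineDose(doses); mm <- lineMask(n)
        dvhr <- computeDVH(dd, mm)
        for (x in c(2, 50, 98))
            expect_lt(abs(doseAtVolumePercent(dvhr, x) -
                          sortDoseAtPercent(doses, x)), 1 + 1e-9)
        expect_lte(doseAtVolumePercent(dvhr, 98),
                   doseAtVolumePercent(dvhr, 50))
        expect_lte(doseAtVolumePercent(dvhr, 50),
                   doseAtVolumePercent(dvhr, 2))
        ## percent and absolute inversions agree when v = x% of volume
        expect_equal(doseAtVolumePercent(dvhr, 25),
                     doseAtAbsoluteVolume(dvhr, 0.25 * dvhr@totalVolume))
    }
})

test_that("mean/min dose and near-maximum behave as order statistics", {
    m2 <- lineMask(2)
    d <- lineDose(c(100, 300))
    mm <- meanMinDose(d, m2)
    expect_equal(mm$mean, 200)
    expect_equal(mm$min, 100)
    set.seed(17)
    for (rep in 1:5) {
        doses <- runif(12, 0, 7000)
        dd <- lineDose(doses); mk <- lineMask(12)
        r <- meanMinDose(dd, mk)
        expect_lte(r$min, r$mean)
        met <- doseMetrics(dd, mk)
        expect_lte(met$d_mean, met$d_0_03cc)
        expect_lte(met$d_min, met$d_mean)
        ## near-max within one bin of the sorted oracle at 0.03 cc
        expect_lt(abs(met$d_0_03cc - sortDoseAtVolume(doses, 0.03, 1)),
                  1 + 1e-9)
    }
})

test_that("homogeneity index is the normalized D2-D98 spread", {
    ## curve with exact D2 = 6300, D98 = 5700, D50 = 6000
    dvh <- new("DVH", structure = "PTV",
               doseBins = c(0, 5700, 6000, 6300, 6400),
               volumeCC = c(100, 98, 50, 2, 0),
               volumePct = c(100, 98, 50, 2, 0),
               binWidth = NA_real_, totalVolume = 100)
    expect_equal(doseAtVolumePercent(dvh, 2), 6300)
    expect_equal(doseAtVolumePercent(dvh, 98), 5700)
    expect_equal(homogeneityIndex(dvh), 0.1)
    ## uniform dose -> 0
    m <- lineMask(8)
    expect_equal(homogeneityIndex(computeDVH(lineDose(rep(6000, 8)), m)),
                 0)
    ## scale invariance of the ratio
    set.seed(19)
    doses <- runif(30, 5000, 7000)
    h1 <- homogeneityIndex(computeDVH(lineDose(doses), lineMask(30)))
    h2 <- homogeneityIndex(computeDVH(lineDose(3 * doses), lineMask(30)))
    expect_equal(h1, h2, tolerance = 2e-3)  # binning granularity only
})

test_that("conformity index follows the volume-ratio definition", {
    ## TV_PV = 80, V_PTV = 100, V_TV = 120 (1 cc voxels)
    n <- 300
    doses <- rep(0, n); doses[21:140] <- 6000
    d <- lineDose(doses, rx = 6000)
    ptv <- maskFromIndices(lineGrid(n), cbind(1:100, 1, 1), "PTV")
    expect_equal(conformityIndex(d, ptv), 6400 / 12000)
    ## perfect conformity: isodose region == PTV
    d2 <- rep(0, n); d2[1:100] <- 6000
    expect_equal(conformityIndex(lineDose(d2), ptv), 1.0)
    ## shrinking the isodose region lowers CI
    d3 <- rep(0, n); d3[1:80] <- 6000
    expect_lt(conformityIndex(lineDose(d3), ptv), 1.0)
    ## relabeling voxels outside PTV and isodose leaves CI unchanged
    d4 <- d2; d4[200:250] <- 100   # below the 95% level
    expect_equal(conformityIndex(lineDose(d4), ptv), 1.0)
    expect_error(conformityIndex(lineDose(rep(0, n) + 1), ptv),
                 "no coverage")
})

test_that("relative differences are signed ratios with a guarded zero", {
    expect_equal(relativeDifference(400, 400), 0)
    expect_equal(relativeDifference(500, 400), 0.25)
    expect_equal(relativeDifference(300, 400), -0.25)
    expect_error(relativeDifference(5, 0), "reference value is 0")
})

test_that("the statistic keyword grammar covers the scorecard forms", {
    d <- lineDose(seq(100, 800, by = 100))
    m <- lineMask(8)
    expect_equal(doseStatistic("Dmean", d, m), 450)
    expect_equal(doseStatistic("D_mean", d, m), 450)
    expect_equal(doseStatistic("Dmax", d, m), 800)
    expect_equal(doseStatistic("Dmin", d, m), 100)
    expect_equal(doseStatistic("Dmedian", d, m), 450)
    expect_equal(doseStatistic("V450cGy", d, m), 50)
    expect_equal(doseStatistic("V450cGycc", d, m), 4)
    expect_lt(abs(doseStatistic("D50%", d, m) - 500), 1 + 1e-9)
    expect_error(doseStatistic("Q95", d, m), "unknown statistic")
})
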
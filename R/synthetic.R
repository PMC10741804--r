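## Synthetic phantom cohorts: anatomically arranged organ primitives,
## smooth calibrated contour perturbations emulating AI-vs-human
## disagreement, conformal dose fields, timing records and Likert
## ratings. Everything is deterministic given the seeds.

## run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv)
    on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
            else if (exists(".Random.seed", envir = .GlobalEnv,
                            inherits = FALSE))
                rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
    force(expr)
}

## derived sub-seed, kept inside 32-bit integer range
derivedSeed <- function(seed, ...) {
    k <- c(...)
    s <- (as.double(seed) * 7919 + sum(k * 104729^(seq_along(k) - 1))) %%
        2147483629
    as.integer(s)
}

## per-axis voxel-center coordinate arrays of a grid
coordArrays <- function(grid) {
    d <- dim3(grid)
    list(x = array(rep(axisCenters(grid, 1), times = d[2] * d[3]), d),
         y = array(rep(rep(axisCenters(grid, 2), each = d[1]),
                       times = d[3]), d),
         z = array(rep(axisCenters(grid, 3), each = d[1] * d[2]), d))
}

#' Primitive mask builders
#'
#' \code{ellipsoidMask} fills an axis-aligned ellipsoid,
#' \code{tubeMask} a z-aligned elliptical cylinder between two z planes,
#' \code{boxMask} an axis-aligned box. Voxels whose centers lie inside
#' the primitive are set.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param name structure name for the resulting mask.
#' @param center (x, y, z) mm center (for the tube, only x and y used).
#' @param radii (rx, ry, rz) mm semi-axes; for \code{tubeMask} a 2-vector
#'   (rx, ry).
#' @param zRange (zmin, zmax) mm for \code{tubeMask}.
#' @param lower,upper (x, y, z) mm corners for \code{boxMask}.
#' @return a \linkS4class{StructureMask}.
#' @export
ellipsoidMask <- function(grid, name, center, radii) {
    cc <- coordArrays(grid)
    v <- ((cc$x - center[1]) / radii[1])^2 +
         ((cc$y - center[2]) / radii[2])^2 +
         ((cc$z - center[3]) / radii[3])^2 <= 1
    StructureMask(name, grid, v)
}

#' @rdname ellipsoidMask
#' @export
tubeMask <- function(grid, name, center, radii, zRange) {
    cc <- coordArrays(grid)
    v <- ((cc$x - center[1]) / radii[1])^2 +
         ((cc$y - center[2]) / radii[2])^2 <= 1 &
         cc$z >= zRange[1] & cc$z <= zRange[2]
    StructureMask(name, grid, v)
}

#' @rdname ellipsoidMask
#' @export
boxMask <- function(grid, name, lower, upper) {
    cc <- coordArrays(grid)
    v <- cc$x >= lower[1] & cc$x <= upper[1] &
         cc$y >= lower[2] & cc$y <= upper[2] &
         cc$z >= lower[3] & cc$z <= upper[3]
    StructureMask(name, grid, v)
}

## smooth random scalar field on the grid, normalized to max |g| = 1:
## a sum of low-frequency cosine modes with random directions and phases
## (wavelengths 25-80 mm), so boundary perturbations look like contour
## edits, not voxel speckle
smoothField <- function(grid, nModes = 6) {
    cc <- coordArrays(grid)
    g <- array(0, dim3(grid))
    for (m in seq_len(nModes)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        lambda <- stats::runif(1, 25, 80)
        phi <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.5, 1)
        g <- g + amp * cos(2 * pi * (cc$x * u[1] + cc$y * u[2] +
                                     cc$z * u[3]) / lambda + phi)
    }
    g / max(abs(g))
}

## signed distance (mm) to the mask surface: negative inside, positive
## outside; exactly 0/positive split reproduces the mask via sd <= 0
signedDistance <- function(voxels, grid) {
    din <- sqrt(.cpp_edt_sq(as.vector(voxels), dim3(grid),
                            gridSpacing(grid)))
    dout <- sqrt(.cpp_edt_sq(as.vector(!voxels), dim3(grid),
                             gridSpacing(grid)))
    din - dout
}

#' Perturbation specification for synthetic contour disagreement
#'
#' @param amplitude boundary noise amplitude in mm (>= 0): the boundary
#'   is displaced by a smooth random field scaled to this amplitude.
#' @param offset systematic (x, y, z) offset in mm.
#' @param bias uniform dilation (> 0) or erosion (< 0) in mm.
#' @param targetDSC optional Dice target in (0, 1]; when set, the
#'   amplitude is auto-calibrated by bisection so the achieved DSC lands
#'   within 0.05 of the target.
#' @param cropProb probability that the structure is truncated
#'   (superior third removed), emulating contours an AI omits or cuts.
#' @param seed integer seed; the perturbation is deterministic given it.
#' @return a list with class \code{"PerturbationSpec"}.
#' @export
perturbationSpec <- function(amplitude = 0, offset = c(0, 0, 0),
                             bias = 0, targetDSC = NULL, cropProb = 0,
                             seed = 1) {
    stopifnot(amplitude >= 0, length(offset) == 3, cropProb >= 0,
              cropProb <= 1)
    if (!is.null(targetDSC))
        stopifnot(targetDSC > 0, targetDSC <= 1)
    structure(list(amplitude = amplitude, offset = offset, bias = bias,
                   targetDSC = targetDSC, cropProb = cropProb,
                   seed = seed),
              class = "PerturbationSpec")
}

shiftMaskVoxels <- function(voxels, shift) {
    if (all(shift == 0L)) return(voxels)
    dims <- dim(voxels)
    out <- array(FALSE, dims)
    dx <- seq(max(1, 1 + shift[1]), min(dims[1], dims[1] + shift[1]))
    dy <- seq(max(1, 1 + shift[2]), min(dims[2], dims[2] + shift[2]))
    dz <- seq(max(1, 1 + shift[3]), min(dims[3], dims[3] + shift[3]))
    if (length(dx) && length(dy) && length(dz))
        out[dx, dy, dz] <- voxels[dx - shift[1], dy - shift[2],
                                  dz - shift[3], drop = FALSE]
    out
}

#' Perturb a structure mask with smooth boundary noise
#'
#' Emulates observer or AI contour disagreement: the mask boundary is
#' moved by a smooth random displacement field (plus an optional
#' systematic offset and dilation/erosion bias), implemented as a
#' threshold on the signed distance function. With \code{targetDSC} set,
#' the noise amplitude is calibrated by bisection until the measured DSC
#' against the input lies within 0.05 of the target (signalling a
#' calibration failure when the target is unreachable). Deterministic
#' given \code{spec$seed}.
#'
#' @param mask a nonempty \linkS4class{StructureMask}.
#' @param spec a \code{\link{perturbationSpec}}.
#' @return the perturbed \linkS4class{StructureMask}.
#' @export
perturbStructure <- function(mask, spec) {
    stopifnot(is(mask, "StructureMask"),
              inherits(spec, "PerturbationSpec"))
    if (!any(mask@voxels)) stop("empty structure cannot be perturbed")
    grid <- mask@grid
    identitySpec <- spec$amplitude == 0 && all(spec$offset == 0) &&
        spec$bias == 0 && is.null(spec$targetDSC) && spec$cropProb == 0
    if (identitySpec) return(mask)
    withSeed(spec$seed, {
        vox <- shiftMaskVoxels(mask@voxels,
                               as.integer(round(spec$offset /
                                                gridSpacing(grid))))
        sd <- signedDistance(vox, grid)
        g <- smoothField(grid)
        build <- function(a) sd <= spec$bias + a * g
        a <- spec$amplitude
        if (!is.null(spec$targetDSC)) {
            target <- spec$targetDSC
            measure <- function(a) {
                out <- build(a)
                if (!any(out)) return(0)
                2 * sum(out & mask@voxels) /
                    (sum(out) + sum(mask@voxels))
            }
            lo <- 0; hi <- 2
            while (measure(hi) > target && hi < 128) hi <- hi * 2
            for (it in 1:40) {
                mid <- (lo + hi) / 2
                if (measure(mid) > target) lo <- mid else hi <- mid
                if (hi - lo < 1e-3) break
            }
            a <- (lo + hi) / 2
            if (abs(measure(a) - target) > 0.05)
                stop("calibration failure: DSC target ", target,
                     " is not reachable for this shape")
        }
        out <- build(a)
        if (spec$cropProb > 0 && stats::runif(1) < spec$cropProb) {
            nz <- dim3(grid)[3]
            keep <- floor(nz * 2 / 3)
            if (keep < nz) out[, , (keep + 1):nz] <- FALSE
        }
        StructureMask(mask@name, grid, out)
    })
}

#' Conformal synthetic dose field around a target
#'
#' Dose equals the prescription inside the target (modulated by a smooth
#' low-amplitude heterogeneity so HI > 0) and decays outside as
#' \code{prescription * exp(-d / falloff)} with d the distance from the
#' target surface in mm. With the default heterogeneity the whole target
#' stays above the 95% isodose, so the conformity index of (target, dose)
#' is 1; no outside voxel reaches 95% for clinically plausible falloffs.
#'
#' @param target a nonempty \linkS4class{StructureMask}.
#' @param prescription prescribed dose, cGy (> 0).
#' @param falloff exponential falloff length in mm (> 0, default 10).
#' @param noiseAmp relative amplitude of the smooth in-target
#'   heterogeneity (default 0.04, i.e. the target sits within 96-104% of
#'   the prescription; 0 gives a perfectly uniform target and HI = 0).
#' @param seed integer seed for the heterogeneity field.
#' @return a \linkS4class{DoseGrid} on the target's grid.
#' @export
makeDose <- function(target, prescription, falloff = 10,
                     noiseAmp = 0.04, seed = 1) {
    stopifnot(is(target, "StructureMask"), prescription > 0, falloff > 0,
              noiseAmp >= 0)
    if (!any(target@voxels)) stop("empty target")
    grid <- target@grid
    d <- sqrt(.cpp_edt_sq(as.vector(target@voxels), dim3(grid),
                          gridSpacing(grid)))
    dose <- prescription * exp(-d / falloff)
    if (noiseAmp > 0) {
        g <- withSeed(seed, smoothField(grid))
        inside <- target@voxels
        dose[inside] <- prescription * (1 + noiseAmp * g[inside])
    }
    DoseGrid(grid, array(dose, dim3(grid)), prescription)
}

defaultGrid <- function(site) {
    if (site == "prostate")
        VoxelGrid(spacing = c(2.5, 2.5, 5), dims = c(64L, 64L, 28L))
    else
        VoxelGrid(spacing = c(2, 2, 2), dims = c(64L, 64L, 48L))
}

## subtract already-claimed voxels so organs never overlap
claimMask <- function(mask, claimed) {
    mask@voxels <- mask@voxels & !claimed
    if (!any(mask@voxels))
        stop("phantom spec infeasible: '", mask@name,
             "' has no voxels left after overlap removal")
    mask
}

#' Generate an anatomically arranged organ phantom
#'
#' Builds a \code{"manual"} structure set of non-overlapping organ
#' primitives on one grid. The prostate-like phantom has a target
#' ellipsoid (CTV) with a bladder-like ellipsoid antero-superior, a
#' rectum-like tube posterior, an anal-canal-like tube inferior and two
#' femur-like cylinders lateral; the PTV is the CTV expanded by 5 mm in
#' all directions except 3 mm posterior. The head-and-neck-like phantom
#' carries a reduced roster spanning large (oral cavity), mid (parotids,
#' brainstem), elongated (spinal cord) and paired small (cochleae)
#' structure regimes around a PTV. Sizes and positions are jittered per
#' seed; the same seed reproduces the identical phantom.
#'
#' @param site \code{"prostate"} or \code{"head_and_neck"}.
#' @param seed integer seed.
#' @param grid optional \linkS4class{VoxelGrid}; defaults to
#'   2.5 x 2.5 x 5 mm (prostate-like, 5 mm slices) or 2 x 2 x 2 mm
#'   (head-and-neck-like).
#' @return a list with \code{structures} (the manual
#'   \linkS4class{StructureSet}) and \code{grid}.
#' @export
makePhantom <- function(site = c("prostate", "head_and_neck"), seed = 1,
                        grid = NULL) {
    site <- match.arg(site)
    if (is.null(grid)) grid <- defaultGrid(site)
    ext <- (dim3(grid) - 1) * gridSpacing(grid)
    ctr <- gridOrigin(grid) + ext / 2
    withSeed(derivedSeed(seed, 1), {
        jit <- function(mm) stats::runif(1, -mm, mm)
        sc <- function() stats::runif(1, 0.9, 1.1)
        masks <- list()
        claimed <- array(FALSE, dim3(grid))
        add <- function(m) {
            m <- claimMask(m, claimed)
            claimed <<- claimed | m@voxels
            masks[[m@name]] <<- m
        }
        if (site == "prostate") {
            cz <- ctr[3] - 5
            add(ellipsoidMask(grid, "CTV",
                c(ctr[1] + jit(3), ctr[2] + jit(3), cz + jit(3)),
                c(22, 20, 17) * sc()))
            add(tubeMask(grid, "Rectum",
                c(ctr[1] + jit(3), ctr[2] + 32 + jit(3)),
                c(12, 12) * sc(), c(cz - 35, cz + 30)))
            add(ellipsoidMask(grid, "Bladder",
                c(ctr[1] + jit(3), ctr[2] - 18 + jit(3),
                  cz + 38 + jit(4)),
                c(27, 23, 21) * sc()))
            add(tubeMask(grid, "Anal Canal",
                c(ctr[1] + jit(2), ctr[2] + 32 + jit(2)),
                c(9, 9) * sc(), c(cz - 58, cz - 40)))
            add(ellipsoidMask(grid, "Left Femur",
                c(ctr[1] + 50 + jit(3), ctr[2] + 6 + jit(3),
                  cz + jit(4)),
                c(15, 15, 32) * sc()))
            add(ellipsoidMask(grid, "Right Femur",
                c(ctr[1] - 50 + jit(3), ctr[2] + 6 + jit(3),
                  cz + jit(4)),
                c(15, 15, 32) * sc()))
            ss <- StructureSet(masks, provenance = "manual")
        } else {
            cz <- ctr[3]
            add(ellipsoidMask(grid, "PTV",
                c(ctr[1] + jit(2), ctr[2] + jit(2), cz + jit(2)),
                c(17, 15, 13) * sc()))
            add(tubeMask(grid, "Spinal Cord",
                c(ctr[1] + jit(1), ctr[2] + 26 + jit(2)),
                c(5, 5) * sc(),
                c(gridOrigin(grid)[3], cz + 14)))
            add(tubeMask(grid, "Brainstem",
                c(ctr[1] + jit(1), ctr[2] + 24 + jit(2)),
                c(8, 8) * sc(),
                c(cz + 16, gridOrigin(grid)[3] + ext[3])))
            add(ellipsoidMask(grid, "Oral Cavity",
                c(ctr[1] + jit(2), ctr[2] - 32 + jit(3), cz + jit(3)),
                c(21, 15, 12) * sc()))
            add(ellipsoidMask(grid, "Left Parotid",
                c(ctr[1] + 40 + jit(2), ctr[2] + 8 + jit(2),
                  cz + 10 + jit(3)),
                c(9, 12, 14) * sc()))
            add(ellipsoidMask(grid, "Right Parotid",
                c(ctr[1] - 40 + jit(2), ctr[2] + 8 + jit(2),
                  cz + 10 + jit(3)),
                c(9, 12, 14) * sc()))
            add(ellipsoidMask(grid, "Left Cochlea",
                c(ctr[1] + 32 + jit(1), ctr[2] + 14 + jit(1),
                  cz + 28 + jit(2)),
                c(3.5, 3.5, 3.5) * sc()))
            add(ellipsoidMask(grid, "Right Cochlea",
                c(ctr[1] - 32 + jit(1), ctr[2] + 14 + jit(1),
                  cz + 28 + jit(2)),
                c(3.5, 3.5, 3.5) * sc()))
            ss <- StructureSet(masks, provenance = "manual")
        }
        list(structures = ss, grid = grid)
    })
}

sitePrescription <- function(site)
    if (site == "prostate") 6000 else 7095

## per-arm structure set for one patient: perturb every structure of
## `base`, then (prostate) derive the PTV from the perturbed CTV
perturbSet <- function(base, provenance, observer, targetDSC, seed,
                       site, cropProb = 0) {
    nm <- structureNames(base)
    nm <- setdiff(nm, "PTV_derived")
    masks <- list()
    for (i in seq_along(nm)) {
        m <- getStructure(base, nm[i])
        if (site == "prostate" && nm[i] == "PTV") next  # re-derived below
        masks[[nm[i]]] <- perturbStructure(m, perturbationSpec(
            targetDSC = targetDSC, cropProb = cropProb,
            seed = derivedSeed(seed, i)))
    }
    if (site == "prostate" && "CTV" %in% names(masks)) {
        ptv <- expandMargin(masks[["CTV"]],
                            isotropicMargins(5, posterior = 3))
        ptv@name <- "PTV"
        masks[["PTV"]] <- ptv
    }
    StructureSet(masks, provenance = provenance, observer = observer)
}

#' Generate a full synthetic study cohort
#'
#' For each patient: a manual phantom structure set; an AI set produced
#' by perturbing each manual structure towards a target DSC
#' (\code{aiDSC}); two AI-adjusted sets produced by small perturbations
#' of the AI set (\code{adjustDSC}) — so by construction
#' DSC(AI, adjusted) > DSC(manual, adjusted), the ordering observed when
#' physicians lightly edit AI contours; conformal dose fields per arm
#' (each plan optimized for its own target); timing records with the
#' AI-assisted workflow far faster than manual; and a Likert rating
#' drawn from a fixed categorical distribution (no 0.45 / slight 0.35 /
#' medium 0.15 / severe 0.05). Prostate-like patients get PTV = CTV +
#' 5 mm (3 mm posterior) per arm. Fully deterministic per \code{seed}.
#'
#' @param n number of patients (>= 1).
#' @param site \code{"prostate"} or \code{"head_and_neck"}.
#' @param seed integer master seed; all per-patient/per-structure seeds
#'   derive from it.
#' @param aiDSC Dice target of the AI-vs-manual perturbation
#'   (default 0.85).
#' @param adjustDSC Dice target of the adjusted-vs-AI perturbation
#'   (default 0.95).
#' @param grid optional \linkS4class{VoxelGrid} override.
#' @param observers number of adjusting observers (default 2).
#' @return a cohort list with \code{site}, \code{seed},
#'   \code{prescription} and \code{patients} (see
#'   \code{\link{runStudy}} for the patient fields).
#' @export
makeCohort <- function(n, site = c("prostate", "head_and_neck"),
                       seed = 1, aiDSC = 0.85, adjustDSC = 0.95,
                       grid = NULL, observers = 2) {
    site <- match.arg(site)
    stopifnot(n >= 1)
    rx <- sitePrescription(site)
    tMan0 <- if (site == "prostate") 23 else 150
    tAdj0 <- if (site == "prostate") 6.42 else 23.58
    patients <- lapply(seq_len(n), function(i) {
        ph <- makePhantom(site, seed = derivedSeed(seed, i, 1),
                          grid = grid)
        manual <- ph$structures
        if (site == "prostate") {
            ptv <- expandMargin(getStructure(manual, "CTV"),
                                isotropicMargins(5, posterior = 3))
            ptv@name <- "PTV"
            manual@structures[["PTV"]] <- ptv
        }
        ai <- perturbSet(manual, "ai", "", aiDSC,
                         derivedSeed(seed, i, 2), site)
        if (site == "prostate")        # AI does not contour the PTV
            ai@structures[["PTV"]] <- NULL
        adjusted <- lapply(seq_len(observers), function(ob)
            perturbSet(ai, "ai_adjusted", as.character(ob), adjustDSC,
                       derivedSeed(seed, i, 2 + ob), site))
        targetName <- "PTV"
        doses <- list(
            manual = makeDose(getStructure(manual, targetName), rx,
                              seed = derivedSeed(seed, i, 10)),
            adjusted = lapply(seq_len(observers), function(ob)
                makeDose(getStructure(adjusted[[ob]], targetName), rx,
                         seed = derivedSeed(seed, i, 10 + ob))))
        withSeed(derivedSeed(seed, i, 20), {
            tman <- max(5, stats::rnorm(1, tMan0, tMan0 * 0.15))
            tadj <- vapply(seq_len(observers), function(ob)
                min(0.6 * tman,
                    max(1, stats::rnorm(1, tAdj0, tAdj0 * 0.2))),
                0)
            likert <- sample(likertLevels, 1,
                             prob = c(0.05, 0.15, 0.35, 0.45))
            timing <- data.frame(
                arm = c("manual", rep("ai_adjusted", observers)),
                observer = c(NA_integer_, seq_len(observers)),
                minutes = c(tman, tadj))
            list(id = sprintf("P%02d", i), manual = manual, ai = ai,
                 adjusted = adjusted, doses = doses, timing = timing,
                 likert = likert)
        })
    })
    list(site = site, seed = seed, prescription = rx,
         patients = patients)
}
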
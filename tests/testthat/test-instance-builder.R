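semFromCores <- function(dims, corePos, edgePos = NULL, spacing = c(1, 1, 1)) {
    g <- array(0L, dims)
    for (p in corePos) g[p[1], p[2], p[3]] <- 3L
    if (!is.null(edgePos)) for (p in edgePos) g[p[1], p[2], p[3]] <- 2L
    SemanticMask(g, spacing)
}

test_that("core labeling respects the configured 3D connectivity", {
    # two isolated single-voxel cores
    sm <- semFromCores(c(7, 5, 5), list(c(2, 2, 2), c(6, 4, 4)))
    expect_length(instanceIds(labelCores(sm)), 2)

    # solid 3x3x3 block is one component of 27 voxels
    g <- array(0L, c(5, 5, 5)); g[2:4, 2:4, 2:4] <- 3L
    lc <- labelCores(SemanticMask(g, c(1, 1, 1)))
    expect_length(instanceIds(lc), 1)
    expect_equal(sum(voxelGrid(lc) == 1L), 27)

    # corner-touching voxels: joined under 26, separate under 6 and 18
    sm2 <- semFromCores(c(4, 4, 4), list(c(2, 2, 2), c(3, 3, 3)))
    expect_length(instanceIds(labelCores(sm2, instanceBuildConfig(connectivity = 26))), 1)
    expect_length(instanceIds(labelCores(sm2, instanceBuildConfig(connectivity = 18))), 2)
    expect_length(instanceIds(labelCores(sm2, instanceBuildConfig(connectivity = 6))), 2)

    # edge-touching voxels: joined under 18 and 26, separate under 6
    sm3 <- semFromCores(c(4, 4, 4), list(c(2, 2, 2), c(3, 3, 2)))
    expect_length(instanceIds(labelCores(sm3, instanceBuildConfig(connectivity = 18))), 1)
    expect_length(instanceIds(labelCores(sm3, instanceBuildConfig(connectivity = 6))), 2)
})

test_that("edge voxels join their geodesically nearest core, ties to lower id", {
    # single core wrapped in a full edge shell -> one instance, core + shell
    g <- array(0L, c(5, 5, 5))
    g[2:4, 2:4, 2:4] <- 2L; g[3, 3, 3] <- 3L
    im <- buildInstances(SemanticMask(g, c(1, 1, 1)))
    expect_identical(instanceIds(im), 1L)
    expect_equal(sum(voxelGrid(im) == 1L), 27)

    # two cores with an equidistant edge wall: wall goes to the lower id
    g2 <- array(0L, c(5, 1, 1))
    g2[1, 1, 1] <- 3L; g2[5, 1, 1] <- 3L; g2[2:4, 1, 1] <- 2L
    im2 <- buildInstances(SemanticMask(g2, c(1, 1, 1)))
    expect_equal(as.vector(voxelGrid(im2)), c(1L, 1L, 1L, 2L, 2L))

    # exhaustive check on a 5x5x1 slab: every edge voxel is assigned to the
    # core whose 26-geodesic distance within edge-plus-core is smallest
    g3 <- array(0L, c(5, 5, 1))
    g3[, , 1] <- 2L
    g3[1, 1, 1] <- 3L; g3[5, 5, 1] <- 3L
    im3 <- buildInstances(SemanticMask(g3, c(1, 1, 1)))
    gr <- voxelGrid(im3)[, , 1]
    for (i in 1:5) for (j in 1:5) {
        d1 <- max(abs(i - 1), abs(j - 1))  # chebyshev = 26-geodesic on a slab
        d2 <- max(abs(i - 5), abs(j - 5))
        expected <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L  # tie -> lower
        expect_identical(gr[i, j], expected)
    }

    # no edge voxels -> output equals the cores
    sm4 <- semFromCores(c(4, 4, 4), list(c(2, 2, 2)))
    expect_identical(voxelGrid(buildInstances(sm4)),
                     voxelGrid(labelCores(sm4)))
})

test_that("anisotropic spacing changes geodesic nearest-core assignment", {
    # contested edge voxel: 2 x-steps from core 1, 1 z-step from core 2
    g <- array(0L, c(3, 1, 2))
    g[1, 1, 1] <- 3L              # core 1
    g[3, 1, 2] <- 3L              # core 2
    g[2, 1, 1] <- 2L; g[3, 1, 1] <- 2L
    im <- buildInstances(SemanticMask(g, c(1, 1, 10)))
    expect_identical(voxelGrid(im)[3, 1, 1], 1L)  # 2 mm along x beats 10 mm along z
    im2 <- buildInstances(SemanticMask(g, c(10, 1, 1)))
    expect_identical(voxelGrid(im2)[3, 1, 1], 2L) # 20 mm along x loses to 1 mm along z
})

test_that("orphan edge components follow the configured policy", {
    g <- array(0L, c(9, 4, 4))
    g[2:3, 2:3, 2:3] <- 3L           # a core-bearing cyst (8 voxels = 0.008 ml)
    g[6:8, 2, 2] <- 2L               # an edge-only component, no core (0.003 ml)
    sm <- SemanticMask(g, c(1, 1, 1))
    promoted <- buildInstances(sm, instanceBuildConfig(orphanPolicy = "promote"))
    expect_length(instanceIds(promoted), 2)
    discarded <- buildInstances(sm, instanceBuildConfig(orphanPolicy = "discard"))
    expect_length(instanceIds(discarded), 1)
    # promoted orphan above a volume threshold survives; below it is removed
    kept <- buildInstances(sm, instanceBuildConfig(orphanPolicy = "promote",
                                                   minVolumeMl = 0.002))
    expect_length(instanceIds(kept), 2)
    filt <- buildInstances(sm, instanceBuildConfig(orphanPolicy = "promote",
                                                   minVolumeMl = 0.0035))
    expect_length(instanceIds(filt), 1)  # 3-voxel orphan = 0.003 ml < 0.0035
})

test_that("voxel conservation: promote + no filter reproduces edge-union-core", {
    set.seed(42)
    for (rep in 1:5) {
        g <- randomLabelGrid(c(6, 6, 6), 3, pZero = 0.5)
        sm <- SemanticMask(g, c(0.74, 0.74, 3.0))
        im <- buildInstances(sm, instanceBuildConfig(orphanPolicy = "promote"))
        expect_identical(voxelGrid(im) > 0L, g == 2L | g == 3L)
    }
})

test_that("build is deterministic and all-background input yields empty map", {
    empty <- buildInstances(SemanticMask(array(0L, c(4, 4, 4)), c(1, 1, 1)))
    expect_length(instanceIds(empty), 0)
    set.seed(7)
    g <- randomLabelGrid(c(7, 7, 7), 3, pZero = 0.4)
    sm <- SemanticMask(g, c(0.74, 0.74, 3.0))
    expect_identical(voxelGrid(buildInstances(sm)), voxelGrid(buildInstances(sm)))
})

test_that("minimum-volume filter is strict at the boundary and monotone in TCN", {
    # 0.5 ml and 1.5 ml instances at 1 ml: one survives
    g2 <- array(0L, c(24, 10, 10))
    g2[1:5, 1:10, 1:10] <- 1L   # 500 voxels = 0.5 ml
    g2[10:24, 1:10, 1:10] <- 2L # 1500 voxels = 1.5 ml
    im <- InstanceMap(g2, c(1, 1, 1))
    expect_identical(instanceIds(filterMinVolume(im, 1)), 2L)

    # exactly 1.0 ml is retained ("smaller than" is strict)
    g3 <- array(0L, c(10, 10, 10)); g3[, , ] <- 1L  # 1000 voxels = 1.0 ml
    im3 <- InstanceMap(g3, c(1, 1, 1))
    expect_identical(instanceIds(filterMinVolume(im3, 1)), 1L)

    # threshold 0 is the identity
    expect_identical(voxelGrid(filterMinVolume(im, 0)), voxelGrid(im))
    expect_error(filterMinVolume(im, -1), "non-negative")

    # raising the threshold never increases TCN
    thresholds <- c(0, 0.25, 0.5, 1, 1.5, 2)
    tcns <- vapply(thresholds,
                   function(t) tcnTcv(filterMinVolume(im, t))$tcn, numeric(1))
    expect_true(all(diff(tcns) <= 0))
})

test_that("instance building is idempotent on its own semantic re-encoding", {
    ph <- generatePhantom(roundTripSpec(seed = 21, target = 6))
    sem <- semanticFromInstances(ph$instances, ph$context)
    im1 <- buildInstances(sem)
    sem2 <- semanticFromInstances(im1, ph$context)
    im2 <- buildInstances(sem2)
    expect_true(samePartition(im1, im2))
})
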
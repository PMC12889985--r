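lineMap <- function(n, segs, spacing = c(1, 1, 1)) {
    # segs: list of id -> index range along x, on an n x 1 x 1 grid
    g <- array(0L, c(n, 1, 1))
    for (id in names(segs)) g[segs[[id]], 1, 1] <- as.integer(id)
    InstanceMap(g, spacing)
}

test_that("the dice threshold gates edges at exactly tau", {
    # |ref| = 11, |pred| = 10, intersection 1: dice = 2/21 < 0.1 -> no edge
    ref <- lineMap(30, list(`1` = 1:11))
    pred <- lineMap(30, list(`1` = 11:20))
    gph <- buildCorrespondenceGraph(ref, pred, correspondenceConfig(0.1))
    expect_equal(nrow(gph$edges), 0)
    rep0 <- classifyCorrespondences(gph)
    expect_equal(rep0$counts[["false_negative"]], 1L)
    expect_equal(rep0$counts[["false_positive"]], 1L)

    # |ref| = 8, |pred| = 10, intersection 1: dice = 2/18 > 0.1 -> edge
    ref2 <- lineMap(30, list(`1` = 1:8))
    pred2 <- lineMap(30, list(`1` = 8:17))
    gph2 <- buildCorrespondenceGraph(ref2, pred2, correspondenceConfig(0.1))
    expect_equal(nrow(gph2$edges), 1)
    expect_equal(classifyCorrespondences(gph2)$counts[["correct_detection"]], 1L)

    # dice exactly tau is an edge (>= tau)
    ref3 <- lineMap(30, list(`1` = 1:10))   # dice = 2*1/20 = 0.1
    pred3 <- lineMap(30, list(`1` = 10:19))
    expect_equal(nrow(buildCorrespondenceGraph(ref3, pred3,
                                               correspondenceConfig(0.1))$edges), 1)

    # raising tau never adds edges
    set.seed(3)
    rg <- randomLabelGrid(c(6, 6, 6), 4, pZero = 0.5)
    pg <- randomLabelGrid(c(6, 6, 6), 4, pZero = 0.5)
    refR <- InstanceMap(rg, c(1, 1, 1)); predR <- InstanceMap(pg, c(1, 1, 1))
    taus <- c(0.05, 0.1, 0.3, 0.6, 1)
    nEdges <- vapply(taus, function(t)
        nrow(buildCorrespondenceGraph(refR, predR, correspondenceConfig(t))$edges),
        numeric(1))
    expect_true(all(diff(nEdges) <= 0))
})

test_that("component patterns map to the six taxonomy categories", {
    # identical 3-instance maps: 3 correct detections only
    ref <- lineMap(30, list(`1` = 1:5, `2` = 10:14, `3` = 20:24))
    repIdent <- classifyCorrespondences(buildCorrespondenceGraph(ref, ref))
    expect_equal(repIdent$counts[["correct_detection"]], 3L)
    expect_equal(sum(repIdent$counts), 3L)

    # one 10-voxel ref cyst split into two halves: one split, nothing else
    refS <- lineMap(10, list(`1` = 1:10))
    predS <- lineMap(10, list(`1` = 1:5, `2` = 6:10))
    repS <- classifyCorrespondences(buildCorrespondenceGraph(refS, predS))
    expect_equal(repS$counts[["split"]], 1L)
    expect_equal(sum(repS$counts), 1L)

    # two ref cysts covered by one prediction: one merge
    refM <- lineMap(10, list(`1` = 1:5, `2` = 6:10))
    predM <- lineMap(10, list(`1` = 1:10))
    repM <- classifyCorrespondences(buildCorrespondenceGraph(refM, predM))
    expect_equal(repM$counts[["merge"]], 1L)
    expect_equal(sum(repM$counts), 1L)

    # M-N component: 2 refs vs 2 preds all cross-linked -> one split-merge,
    # counted once (no double counting as both a split and a merge)
    refX <- lineMap(20, list(`1` = 1:10, `2` = 11:20))
    predX <- lineMap(20, list(`1` = 6:15, `2` = c(1:5, 16:20)))
    repX <- classifyCorrespondences(buildCorrespondenceGraph(refX, predX))
    expect_equal(repX$counts[["split_merge"]], 1L)
    expect_equal(sum(repX$counts), 1L)

    # unmatched instances on either side
    refF <- lineMap(20, list(`1` = 1:5))
    predF <- lineMap(20, list(`1` = 11:15))
    repF <- classifyCorrespondences(buildCorrespondenceGraph(refF, predF))
    expect_equal(repF$counts[["false_negative"]], 1L)
    expect_equal(repF$counts[["false_positive"]], 1L)
})

test_that("classification matches brute-force component enumeration", {
    set.seed(23)
    for (rep in 1:12) {
        dims <- sample(4:8, 3, replace = TRUE)
        rg <- randomLabelGrid(dims, maxId = 4, pZero = 0.45)
        pg <- randomLabelGrid(dims, maxId = 4, pZero = 0.45)
        ref <- InstanceMap(rg, c(1, 1, 1)); pred <- InstanceMap(pg, c(1, 1, 1))
        tau <- sample(c(0.1, 0.2, 0.4), 1)
        gph <- buildCorrespondenceGraph(ref, pred, correspondenceConfig(tau))
        got <- classifyCorrespondences(gph)
        comps <- bruteComponents(instanceIds(ref), instanceIds(pred), gph$edges)
        wantCounts <- table(factor(vapply(comps, function(cc)
            bruteClassify(length(cc$ref_ids), length(cc$pred_ids)), character(1)),
            levels = names(got$counts)))
        expect_equal(as.integer(wantCounts), unname(got$counts))
    }
})

test_that("category membership conserves reference and prediction instances", {
    checkConservation <- function(ref, pred, tau = 0.1) {
        rep_ <- classifyCorrespondences(
            buildCorrespondenceGraph(ref, pred, correspondenceConfig(tau)))
        refSeen <- unlist(lapply(rep_$components, `[[`, "ref_ids"))
        predSeen <- unlist(lapply(rep_$components, `[[`, "pred_ids"))
        expect_identical(sort(as.integer(refSeen)), instanceIds(ref))
        expect_identical(sort(as.integer(predSeen)), instanceIds(pred))
        expect_false(anyDuplicated(refSeen) > 0)
        expect_false(anyDuplicated(predSeen) > 0)
        expect_equal(sum(vapply(rep_$components, function(cc)
            length(cc$ref_ids), numeric(1))), length(instanceIds(ref)))
    }
    ph <- generatePhantom(phantomSpec(cystCountTarget = 20, seed = 44))
    deg <- degrade(ph$instances, c(delete = 2, add = 2, merge = 2, split = 2,
                                   jitter = 2), seed = 45)
    checkConservation(ph$instances, deg$instances)
    set.seed(46)
    rg <- randomLabelGrid(c(7, 7, 7), 4, pZero = 0.5)
    pg <- randomLabelGrid(c(7, 7, 7), 4, pZero = 0.5)
    checkConservation(InstanceMap(rg, c(1, 1, 1)), InstanceMap(pg, c(1, 1, 1)))
})

test_that("case summaries use totals, n-1 SD and min-max range", {
    mkReport <- function(cd) {
        g <- array(0L, c(max(2, 2 * cd), 1, 1))
        if (cd > 0) for (i in seq_len(cd)) g[2 * i - 1, 1, 1] <- i
        im <- InstanceMap(g, c(1, 1, 1))
        classifyCorrespondences(buildCorrespondenceGraph(im, im))
    }
    one <- summarizeCases(list(mkReport(5)))
    cdRow <- one[one$category == "correct_detection", ]
    expect_equal(cdRow$total, 5)
    expect_equal(cdRow$mean, 5)
    expect_equal(cdRow$sd, 0)
    expect_false(cdRow$sd_defined)
    expect_equal(c(cdRow$min, cdRow$max), c(5, 5))

    two <- summarizeCases(list(mkReport(4), mkReport(6)))
    cdRow2 <- two[two$category == "correct_detection", ]
    expect_equal(cdRow2$total, 10)
    expect_equal(cdRow2$mean, 5)
    expect_equal(cdRow2$sd, sqrt(2))
    expect_equal(cdRow2$sd, 1.414, tolerance = 1e-3)
    expect_equal(c(cdRow2$min, cdRow2$max), c(4, 6))

    zeros <- summarizeCases(list(mkReport(0), mkReport(0)))
    expect_true(all(zeros$total == 0))
    expect_error(summarizeCases(list()), "at least one")
})
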
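#' @include agreement.R
NULL

# voxel-centre physical coordinate along one axis (mm)
.axisCoords <- function(n, d) (seq_len(n) - 0.5) * d

# run `expr` under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (hasSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# extract arr over (possibly out-of-range) index ranges, padding with `fill`
.subExtract <- function(arr, rx, ry, rz, fill) {
    d <- dim(arr)
    out <- array(fill, c(length(rx), length(ry), length(rz)))
    vx <- rx >= 1L & rx <= d[1]; vy <- ry >= 1L & ry <= d[2]; vz <- rz >= 1L & rz <= d[3]
    if (any(vx) && any(vy) && any(vz))
        out[vx, vy, vz] <- arr[rx[vx], ry[vy], rz[vz]]
    out
}

# Chebyshev (box) dilation by k voxels, separable along the three axes
.dilateBox <- function(mask, k) {
    if (k <= 0L) return(mask)
    for (ax in 1:3)
        for (i in seq_len(k))
            mask <- mask | .shiftGrid(mask, ax, 1L, FALSE) |
                           .shiftGrid(mask, ax, -1L, FALSE)
    mask
}

# solid ellipsoid mask over the full grid
.ellipsoidMask <- function(dims, spacing, center, radii) {
    qx <- ((.axisCoords(dims[1], spacing[1]) - center[1]) / radii[1])^2
    qy <- ((.axisCoords(dims[2], spacing[2]) - center[2]) / radii[2])^2
    qz <- ((.axisCoords(dims[3], spacing[3]) - center[3]) / radii[3])^2
    outer(outer(qx, qy, "+"), qz, "+") <= 1
}

#' Specification of a synthetic polycystic-organ phantom
#'
#' Describes a labeled-volume phantom: an ellipsoidal organ containing many
#' roughly ellipsoidal cysts placed by seeded rejection sampling. Cyst radii
#' follow a log-normal distribution so that, at the defaults, most cysts are
#' below 1 ml with a tail of larger ones — the size regime in which small
#' cysts dominate detection disagreement in polycystic kidney disease CT. A
#' configurable fraction of cysts is exophytic (intersecting the organ
#' boundary so part of their surface faces background); the rest are
#' endophytic with at least one voxel of parenchymal clearance.
#'
#' @param gridShape integer length 3, voxel grid extents. Default
#'   `c(72, 72, 52)`.
#' @param spacing voxel spacing in mm; default `c(0.74, 0.74, 3.0)`, the
#'   median CT in-plane pixel spacing and a typical slice thickness for
#'   abdominal series.
#' @param organSemiAxesMm ellipsoid semi-axes of the organ in mm.
#' @param cystCountTarget number of cysts to place.
#' @param radiusMeanLogMm,radiusSdLog log-normal parameters of the cyst
#'   radius in mm (defaults `log(3)` and 0.55).
#' @param radiusMinMm,radiusMaxMm clamp on sampled radii.
#' @param exophyticFraction fraction of cysts placed across the organ
#'   boundary, in `[0, 1]`.
#' @param edgeThicknessVoxels edge shell thickness used by
#'   [semanticFromInstances()], >= 1.
#' @param gapVoxels minimum empty-voxel clearance (Chebyshev) between
#'   distinct cysts; >= 1 keeps cysts non-adjacent under 26-connectivity.
#' @param seed integer random seed; all phantom output is a pure function of
#'   the spec including this seed.
#' @return An object of class `PhantomSpec`.
#' @export
phantomSpec <- function(gridShape = c(72L, 72L, 52L),
                        spacing = c(0.74, 0.74, 3.0),
                        organSemiAxesMm = c(22, 22, 70),
                        cystCountTarget = 50L,
                        radiusMeanLogMm = log(3),
                        radiusSdLog = 0.55,
                        radiusMinMm = 1.5,
                        radiusMaxMm = 12,
                        exophyticFraction = 0.25,
                        edgeThicknessVoxels = 1L,
                        gapVoxels = 1L,
                        seed = 1L) {
    stopifnot(length(gridShape) == 3L, all(gridShape >= 4),
              length(organSemiAxesMm) == 3L, all(organSemiAxesMm > 0),
              cystCountTarget >= 0,
              radiusMinMm > 0, radiusMaxMm >= radiusMinMm,
              exophyticFraction >= 0, exophyticFraction <= 1,
              edgeThicknessVoxels >= 1, gapVoxels >= 0)
    msg <- .checkSpacing(spacing)
    if (!is.null(msg)) stop(msg, call. = FALSE)
    structure(list(gridShape = as.integer(gridShape), spacing = as.numeric(spacing),
                   organSemiAxesMm = as.numeric(organSemiAxesMm),
                   cystCountTarget = as.integer(cystCountTarget),
                   radiusMeanLogMm = radiusMeanLogMm, radiusSdLog = radiusSdLog,
                   radiusMinMm = radiusMinMm, radiusMaxMm = radiusMaxMm,
                   exophyticFraction = exophyticFraction,
                   edgeThicknessVoxels = as.integer(edgeThicknessVoxels),
                   gapVoxels = as.integer(gapVoxels),
                   seed = as.integer(seed)),
              class = "PhantomSpec")
}

#' @export
print.PhantomSpec <- function(x, ...) {
    cat(sprintf("PhantomSpec: grid %s, spacing (%g, %g, %g) mm, target %d cysts, seed %d\n",
                paste(x$gridShape, collapse = "x"),
                x$spacing[1], x$spacing[2], x$spacing[3],
                x$cystCountTarget, x$seed))
    invisible(x)
}

# try to place one ellipsoidal cyst; returns the voxel-index ranges and
# local mask, or NULL if the candidate violates a constraint
.tryPlaceCyst <- function(center, radii, dims, spacing, occ, organVox,
                          gapVoxels, exophytic) {
    # reject candidates whose support leaves the grid
    for (ax in 1:3)
        if (center[ax] - radii[ax] < spacing[ax] ||
            center[ax] + radii[ax] > (dims[ax] - 1) * spacing[ax])
            return(NULL)
    k <- max(gapVoxels, 1L)
    lo <- pmax(1L, as.integer(floor((center - radii) / spacing + 0.5)) - k - 1L)
    hi <- pmin(dims, as.integer(ceiling((center + radii) / spacing + 0.5)) + k + 1L)
    rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
    qx <- ((.axisCoords(dims[1], spacing[1])[rx] - center[1]) / radii[1])^2
    qy <- ((.axisCoords(dims[2], spacing[2])[ry] - center[2]) / radii[2])^2
    qz <- ((.axisCoords(dims[3], spacing[3])[rz] - center[3]) / radii[3])^2
    cand <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    if (!any(cand)) return(NULL)
    occSub <- .subExtract(occ, rx, ry, rz, TRUE)  # out-of-grid treated occupied
    if (any(.dilateBox(cand, gapVoxels) & occSub)) return(NULL)
    orgSub <- .subExtract(organVox, rx, ry, rz, FALSE)
    if (exophytic) {
        if (!any(cand & !orgSub) || !any(cand & orgSub)) return(NULL)
    } else {
        if (any(.dilateBox(cand, 1L) & !orgSub)) return(NULL)
    }
    list(rx = rx, ry = ry, rz = rz, mask = cand)
}

#' Generate a synthetic polycystic-organ phantom
#'
#' Carves the organ ellipsoid and places cysts one by one with seeded
#' rejection sampling, first-placed-wins: a candidate is rejected if it
#' would come within `gapVoxels` (Chebyshev) of an already placed cyst,
#' leave the grid, or violate its endophytic/exophytic placement
#' constraint. Placement may undershoot the target when the organ is too
#' crowded; the achieved count is part of the returned ground truth.
#'
#' @param spec a [phantomSpec()].
#' @return A list of class `Phantom` with elements `instances`
#'   ([InstanceMap], ids `1..K` in placement order), `context`
#'   ([OrganContext]; organ = parenchyma ellipsoid plus all cyst voxels),
#'   and `truth`: `achieved` (K), `perCystVolumes` (ml, by id),
#'   `exophyticIds`, and the generating `spec`.
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(cystCountTarget = 5, seed = 7))
#' ph$truth$achieved
generatePhantom <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    dims <- spec$gridShape; sp <- spec$spacing
    organCenter <- dims * sp / 2
    organVox <- .ellipsoidMask(dims, sp, organCenter, spec$organSemiAxesMm)
    if (!any(organVox))
        stop("infeasible spec: organ ellipsoid contains no voxels", call. = FALSE)

    inst <- array(0L, dims)
    occ <- array(FALSE, dims)
    exoIds <- integer(0)

    .withSeed(spec$seed, {
        placed <- 0L
        attempts <- 0L
        maxAttempts <- max(2000L, 400L * spec$cystCountTarget)
        while (placed < spec$cystCountTarget && attempts < maxAttempts) {
            attempts <- attempts + 1L
            r <- min(max(stats::rlnorm(1, spec$radiusMeanLogMm, spec$radiusSdLog),
                         spec$radiusMinMm), spec$radiusMaxMm)
            radii <- r * stats::runif(3, 0.8, 1.25)
            exo <- stats::runif(1) < spec$exophyticFraction
            if (exo) {
                # centre near the organ surface along a random direction
                u <- stats::rnorm(3)
                u <- u / sqrt(sum(u^2))
                f <- stats::runif(1, 0.95, 1.02)
                center <- organCenter + f * u * spec$organSemiAxesMm
            } else {
                # uniform in the organ ellipsoid (rejection from the box)
                repeat {
                    p <- stats::runif(3, -1, 1)
                    if (sum(p^2) <= 1) break
                }
                center <- organCenter + p * spec$organSemiAxesMm
            }
            hit <- .tryPlaceCyst(center, radii, dims, sp, occ, organVox,
                                 spec$gapVoxels, exo)
            if (is.null(hit)) next
            placed <- placed + 1L
            sub <- inst[hit$rx, hit$ry, hit$rz]
            sub[hit$mask] <- placed
            inst[hit$rx, hit$ry, hit$rz] <- sub
            occ[hit$rx, hit$ry, hit$rz] <- occ[hit$rx, hit$ry, hit$rz] | hit$mask
            if (exo) exoIds <- c(exoIds, placed)
        }
    })

    instances <- InstanceMap(inst, sp)
    context <- OrganContext(organVox | inst > 0L, sp)
    truth <- list(achieved = length(instanceIds(instances)),
                  perCystVolumes = perCystVolumes(instances),
                  exophyticIds = exoIds,
                  spec = spec)
    structure(list(instances = instances, context = context, truth = truth),
              class = "Phantom")
}

#' @export
print.Phantom <- function(x, ...) {
    cat(sprintf("Phantom: %d cyst(s) (%d exophytic), TCV %.3g ml\n",
                x$truth$achieved, length(x$truth$exophyticIds),
                sum(x$truth$perCystVolumes)))
    invisible(x)
}

#' Derive an edge/core semantic mask from an instance map
#'
#' Re-encodes each cyst instance as a boundary "edge" shell plus an interior
#' "core": the edge is every instance voxel whose 6-connected erosion depth
#' (within its own instance) is less than `thickness`, the core is the
#' remainder. Parenchyma is the organ mask minus all cysts; everything else
#' is background. Instances too small to retain a core become all edge.
#' This is the inverse direction of [buildInstances()]: for well-separated
#' cysts with non-empty cores the two compose to the identity on the
#' instance partition.
#'
#' @param instances an [InstanceMap].
#' @param context an [OrganContext] on the same grid.
#' @param thickness edge shell thickness in voxels, >= 1.
#' @param labels label mapping for the output, see [SemanticMask()].
#' @return A [SemanticMask].
#' @export
semanticFromInstances <- function(instances, context, thickness = 1L,
                                  labels = .defaultLabelCodes) {
    stopifnot(is(instances, "InstanceMap"), is(context, "OrganContext"),
              thickness >= 1L)
    .checkSameGeometry(instances, context)
    g <- voxelGrid(instances)
    cur <- g
    edgeMask <- array(FALSE, dim(g))
    for (iter in seq_len(thickness)) {
        boundary <- cur > 0L
        inner <- boundary
        for (ax in 1:3)
            for (dir in c(1L, -1L))
                inner <- inner & .shiftGrid(cur, ax, dir, 0L) == cur
        peel <- boundary & !inner
        edgeMask <- edgeMask | peel
        cur[peel] <- 0L
    }
    sem <- array(labels[["background"]], dim(g))
    sem[organMask(context) & g == 0L] <- labels[["parenchyma"]]
    sem[edgeMask] <- labels[["edge"]]
    sem[cur > 0L] <- labels[["core"]]
    SemanticMask(sem, voxelSpacing(instances), labels = labels)
}

.logRecord <- function(op, ...) c(list(op = op), list(...))

#' Inject controlled segmentation errors into an instance map
#'
#' Simulates the disagreement modes seen between two segmentations of the
#' same organ: deleting instances (false negatives), adding spurious
#' non-overlapping instances (false positives), merging pairs (relabeling
#' one instance into its partner), splitting an instance by an axis-aligned
#' plane through its centroid, and jittering a boundary by one voxel of
#' erosion or dilation. Operations act on disjoint sets of instances, so
#' each requested error maps to exactly one taxonomy category when the
#' result is compared against the original. Merge partners are restricted
#' to volume ratio <= 10 so the merged instance keeps Dice >= 2/12 with both
#' originals; split planes are accepted only when both halves retain at
#' least 20% of the voxels, keeping each half's Dice against the original
#' at least 1/3. All randomness is governed by `seed`; an infeasible request
#' (not enough eligible instances) is an error, never silently dropped.
#'
#' @param instances an [InstanceMap] (typically phantom ground truth).
#' @param ops named counts among `delete`, `add`, `merge`, `split`,
#'   `jitter`; missing entries default to 0.
#' @param seed integer seed.
#' @param addRadiusMm range (min, max) of radii for added spurious cysts.
#' @return A list of class `DegradedInstanceMap` with `instances` (the
#'   degraded [InstanceMap]) and `log` (class `PerturbationLog`: `ops`, a
#'   list of applied operations in order, and `counts` per category).
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(cystCountTarget = 10, seed = 3))
#' deg <- degrade(ph$instances, c(delete = 2), seed = 4)
#' deg$log$counts
degrade <- function(instances, ops = c(delete = 0L), seed = 1L,
                    addRadiusMm = c(3, 6)) {
    stopifnot(is(instances, "InstanceMap"))
    want <- stats::setNames(integer(5), c("delete", "add", "merge", "split", "jitter"))
    if (length(ops)) {
        bad <- setdiff(names(ops), names(want))
        if (length(bad))
            stop("unknown degrade operation(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
        want[names(ops)] <- as.integer(ops)
    }
    if (any(want < 0)) stop("operation counts must be non-negative", call. = FALSE)

    g <- voxelGrid(instances)
    sp <- voxelSpacing(instances)
    dims <- dim(g)
    origOcc <- g > 0L
    vols <- perCystVolumes(instances)
    ids <- as.integer(names(vols))
    used <- integer(0)
    logOps <- list()

    .withSeed(seed, {
        # --- merges: pick volume-compatible disjoint pairs ---
        if (want[["merge"]] > 0) {
            avail <- ids[order(vols)]
            pairs <- list()
            i <- 1L
            while (length(pairs) < want[["merge"]] && i < length(avail)) {
                a <- avail[i]; b <- avail[i + 1L]
                if (max(vols[as.character(c(a, b))]) /
                    min(vols[as.character(c(a, b))]) <= 10) {
                    pairs[[length(pairs) + 1L]] <- c(a, b)
                    i <- i + 2L
                } else i <- i + 1L
            }
            if (length(pairs) < want[["merge"]])
                stop("infeasible degrade request: only ", length(pairs),
                     " volume-compatible merge pair(s) available", call. = FALSE)
            pairs <- pairs[sample.int(length(pairs))][seq_len(want[["merge"]])]
            for (pr in pairs) {
                keep <- min(pr); gone <- max(pr)
                g[g == gone] <- keep
                used <- c(used, pr)
                logOps[[length(logOps) + 1L]] <-
                    .logRecord("merge", id_a = keep, id_b = gone)
            }
        }

        # --- splits: axis-aligned plane through the centroid ---
        if (want[["split"]] > 0) {
            pool <- sample(setdiff(ids, used))
            done <- 0L
            nextId <- max(g) + 1L
            for (id in pool) {
                if (done >= want[["split"]]) break
                vox <- which(g == id, arr.ind = TRUE)
                if (nrow(vox) < 4L) next
                okAxis <- FALSE
                for (ax in sample(1:3)) {
                    cen <- mean(vox[, ax])
                    upper <- vox[, ax] > cen
                    f <- mean(upper)
                    if (f >= 0.2 && f <= 0.8) { okAxis <- TRUE; break }
                }
                if (!okAxis) next
                hi <- vox[upper, , drop = FALSE]
                g[hi] <- nextId
                used <- c(used, id)
                logOps[[length(logOps) + 1L]] <-
                    .logRecord("split", id = id, axis = ax, new_id = nextId)
                nextId <- nextId + 1L
                done <- done + 1L
            }
            if (done < want[["split"]])
                stop("infeasible degrade request: only ", done,
                     " instance(s) eligible for splitting", call. = FALSE)
        }

        # --- deletes ---
        if (want[["delete"]] > 0) {
            pool <- setdiff(ids, used)
            if (length(pool) < want[["delete"]])
                stop("infeasible degrade request: not enough instances to delete",
                     call. = FALSE)
            del <- sample(pool, want[["delete"]])
            for (id in del) {
                g[g == id] <- 0L
                used <- c(used, id)
                logOps[[length(logOps) + 1L]] <- .logRecord("delete", id = id)
            }
        }

        # --- jitter: erode or dilate a boundary by one voxel ---
        if (want[["jitter"]] > 0) {
            pool <- sample(setdiff(ids, used))
            if (length(pool) < want[["jitter"]])
                stop("infeasible degrade request: not enough instances to jitter",
                     call. = FALSE)
            for (id in pool[seq_len(want[["jitter"]])]) {
                grow <- stats::runif(1) < 0.5
                mask <- g == id
                if (!grow) {
                    inner <- mask
                    for (ax in 1:3)
                        for (dir in c(1L, -1L))
                            inner <- inner & .shiftGrid(mask, ax, dir, FALSE)
                    if (any(inner)) {
                        g[mask & !inner] <- 0L
                        used <- c(used, id)
                        logOps[[length(logOps) + 1L]] <-
                            .logRecord("jitter", id = id, kind = "erode")
                        next
                    }
                    grow <- TRUE  # too thin to erode: dilate instead
                }
                ring <- array(FALSE, dims)
                for (ax in 1:3)
                    for (dir in c(1L, -1L))
                        ring <- ring | .shiftGrid(mask, ax, dir, FALSE)
                g[ring & g == 0L] <- id
                used <- c(used, id)
                logOps[[length(logOps) + 1L]] <-
                    .logRecord("jitter", id = id, kind = "dilate")
            }
        }

        # --- adds: spurious cysts clear of every original instance ---
        if (want[["add"]] > 0) {
            occ <- origOcc | g > 0L
            anyVox <- array(TRUE, dims)
            added <- 0L
            tries <- 0L
            nextId <- max(g, 1L) + 1L
            while (added < want[["add"]] && tries < 4000L) {
                tries <- tries + 1L
                r <- stats::runif(1, addRadiusMm[1], addRadiusMm[2])
                radii <- r * stats::runif(3, 0.8, 1.25)
                center <- stats::runif(3) * dims * sp
                hit <- .tryPlaceCyst(center, radii, dims, sp, occ, anyVox,
                                     gapVoxels = 1L, exophytic = FALSE)
                if (is.null(hit)) next
                sub <- g[hit$rx, hit$ry, hit$rz]
                sub[hit$mask] <- nextId
                g[hit$rx, hit$ry, hit$rz] <- sub
                occ[hit$rx, hit$ry, hit$rz] <- occ[hit$rx, hit$ry, hit$rz] | hit$mask
                logOps[[length(logOps) + 1L]] <-
                    .logRecord("add", new_id = nextId, radius_mm = r)
                nextId <- nextId + 1L
                added <- added + 1L
            }
            if (added < want[["add"]])
                stop("infeasible degrade request: could not place ",
                     want[["add"]], " added instance(s)", call. = FALSE)
        }
    })

    counts <- stats::setNames(integer(5), names(want))
    for (rec in logOps) counts[rec$op] <- counts[rec$op] + 1L
    log <- structure(list(ops = logOps, counts = counts),
                     class = "PerturbationLog")
    structure(list(instances = InstanceMap(g, sp), log = log),
              class = "DegradedInstanceMap")
}

#' @export
print.PerturbationLog <- function(x, ...) {
    cat("PerturbationLog:",
        paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
    invisible(x)
}
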
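#' @include io.R
NULL

# Neighbour values along one axis. Returns an array of the same shape whose
# element [i] holds the value of the voxel one step in `dir` (+1/-1) along
# `axis`; out-of-grid neighbours take `fill`.
.shiftGrid <- function(a, axis, dir, fill = 0L) {
    d <- dim(a)
    out <- array(fill, d)
    n <- d[axis]
    if (n <= 1L && dir != 0L) return(out)
    src <- vector("list", 3); dst <- vector("list", 3)
    for (ax in 1:3) { src[[ax]] <- seq_len(d[ax]); dst[[ax]] <- seq_len(d[ax]) }
    if (dir == 1L) { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1L) }
    else           { src[[axis]] <- 1:(n - 1L); dst[[axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

#' Configuration for semantic-to-instance conversion
#'
#' Controls how an edge/core semantic mask is converted into an instance
#' map: the 3D neighbourhood used to find connected cyst cores, the policy
#' for edge components that reach no core, and an optional minimum instance
#' volume applied after construction.
#'
#' @param connectivity core component neighbourhood: 6 (faces), 18 (faces +
#'   edges) or 26 (faces + edges + corners). Default 26.
#' @param orphanPolicy what to do with edge components that contain no core
#'   voxel: `"promote"` (default) gives each its own instance id — a small
#'   cyst may be all edge at coarse resolution — or `"discard"` drops them.
#' @param minVolumeMl minimum instance volume in ml (default 0, no
#'   filtering); instances strictly below this volume are removed.
#' @return An object of class `InstanceBuildConfig`.
#' @export
#' @examples
#' instanceBuildConfig(connectivity = 6, orphanPolicy = "discard")
instanceBuildConfig <- function(connectivity = 26L,
                                orphanPolicy = c("promote", "discard"),
                                minVolumeMl = 0) {
    connectivity <- as.integer(connectivity)
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("connectivity must be 6, 18 or 26", call. = FALSE)
    orphanPolicy <- match.arg(orphanPolicy)
    if (!is.numeric(minVolumeMl) || length(minVolumeMl) != 1L || minVolumeMl < 0)
        stop("minVolumeMl must be a single non-negative number", call. = FALSE)
    structure(list(connectivity = connectivity, orphanPolicy = orphanPolicy,
                   minVolumeMl = as.numeric(minVolumeMl)),
              class = "InstanceBuildConfig")
}

#' @export
print.InstanceBuildConfig <- function(x, ...) {
    cat(sprintf("InstanceBuildConfig: connectivity %d, orphan policy '%s', min volume %g ml\n",
                x$connectivity, x$orphanPolicy, x$minVolumeMl))
    invisible(x)
}

#' Label connected cyst cores as instance seeds
#'
#' Each connected component of core-labeled voxels (under the configured
#' neighbourhood) receives a distinct positive instance id; all other voxels
#' are 0. Ids are assigned in column-major first-encounter order, so the
#' result is deterministic.
#'
#' @param mask a [SemanticMask].
#' @param config an [instanceBuildConfig()].
#' @return An [InstanceMap] covering exactly the core voxels.
#' @export
labelCores <- function(mask, config = instanceBuildConfig()) {
    stopifnot(is(mask, "SemanticMask"))
    g <- voxelGrid(mask)
    coreMask <- g == labelCodes(mask)[["core"]]
    lab <- .cc_label3d(as.vector(coreMask), dim(g), config$connectivity)
    InstanceMap(array(lab, dim(g)), voxelSpacing(mask))
}

#' Attach edge voxels to their geodesically nearest core
#'
#' Every edge voxel is assigned the id of the nearest core component, where
#' nearness is geodesic distance within the edge-union-core region (paths may
#' not leave cyst tissue, so two cysts separated by parenchyma or background
#' can never claim each other's edges). Steps connect 26-neighbours and are
#' weighted by their physical length under the anisotropic voxel spacing.
#' Distance ties are broken in favour of the smaller core id, making the
#' assignment deterministic. Edge voxels that reach no core (orphan edge
#' components) remain 0 here; [buildInstances()] applies the orphan policy.
#'
#' @param cores [InstanceMap] of labeled cores from [labelCores()].
#' @param mask the [SemanticMask] the cores were derived from.
#' @param config an [instanceBuildConfig()].
#' @return An [InstanceMap] covering core voxels plus all reachable edge
#'   voxels.
#' @export
assignEdges <- function(cores, mask, config = instanceBuildConfig()) {
    stopifnot(is(cores, "InstanceMap"), is(mask, "SemanticMask"))
    .checkSameGeometry(cores, mask)
    g <- voxelGrid(mask)
    codes <- labelCodes(mask)
    region <- g == codes[["edge"]] | g == codes[["core"]]
    assigned <- .geodesic_assign(as.vector(region), as.vector(voxelGrid(cores)),
                                 dim(g), voxelSpacing(mask))
    InstanceMap(array(assigned, dim(g)), voxelSpacing(mask))
}

#' Convert an edge/core semantic mask into a cyst instance map
#'
#' The post-processing stage of the pipeline: connected components of core
#' voxels seed the instances ([labelCores()]), edge voxels are attached to
#' their geodesically nearest core ([assignEdges()]), orphan edge components
#' are promoted to their own instances or discarded per the configured
#' policy, and instances below the configured minimum volume are removed
#' ([filterMinVolume()]). With orphan policy `"promote"` and minimum volume
#' 0, the returned cyst voxels are exactly the edge-union-core voxels of the
#' input.
#'
#' @param mask a [SemanticMask].
#' @param config an [instanceBuildConfig()].
#' @return An [InstanceMap].
#' @export
#' @examples
#' g <- array(0L, c(7, 5, 5))
#' g[2:4, 2:4, 2:4] <- 2L   # edge shell
#' g[3, 3, 3] <- 3L         # core
#' im <- buildInstances(SemanticMask(g, c(1, 1, 1)))
#' instanceIds(im)
buildInstances <- function(mask, config = instanceBuildConfig()) {
    cores <- labelCores(mask, config)
    inst <- assignEdges(cores, mask, config)
    g <- voxelGrid(inst)
    codes <- labelCodes(mask)
    sg <- voxelGrid(mask)
    orphan <- (sg == codes[["edge"]]) & g == 0L
    if (any(orphan)) {
        if (config$orphanPolicy == "promote") {
            lab <- .cc_label3d(as.vector(orphan), dim(g), config$connectivity)
            offset <- max(g)
            add <- array(lab, dim(g))
            g[add > 0L] <- add[add > 0L] + offset
        }
        # "discard": orphans stay 0
    }
    out <- InstanceMap(g, voxelSpacing(mask))
    if (config$minVolumeMl > 0)
        out <- filterMinVolume(out, config$minVolumeMl)
    out
}

#' Remove cyst instances smaller than a volume threshold
#'
#' Sets to 0 every instance whose volume is strictly less than `thresholdMl`;
#' instances with volume exactly equal to the threshold are retained. The
#' 1-ml threshold is the conventional cutoff below which small cysts
#' dominate detection disagreement.
#'
#' @param instances an [InstanceMap].
#' @param thresholdMl non-negative volume threshold in ml.
#' @return An [InstanceMap] with the surviving instances (ids unchanged).
#' @export
#' @examples
#' g <- array(0L, c(12, 12, 12))
#' g[1:10, 1:10, 1:10] <- 1L  # 1000 voxels = 1 ml at 1 mm spacing
#' g[12, 12, 12] <- 2L        # 0.001 ml
#' filterMinVolume(InstanceMap(g, c(1, 1, 1)), 1)
filterMinVolume <- function(instances, thresholdMl) {
    stopifnot(is(instances, "InstanceMap"))
    if (!is.numeric(thresholdMl) || length(thresholdMl) != 1L || thresholdMl < 0)
        stop("thresholdMl must be a single non-negative number", call. = FALSE)
    if (thresholdMl == 0) return(instances)
    vols <- perCystVolumes(instances)
    drop <- as.integer(names(vols))[vols < thresholdMl]
    if (!length(drop)) return(instances)
    g <- voxelGrid(instances)
    g[g %in% drop] <- 0L
    InstanceMap(g, voxelSpacing(instances))
}

#' Relabel instances with a permutation of their ids
#'
#' Utility mainly used to verify that biomarkers are invariant under the
#' arbitrary numbering of instances.
#'
#' @param instances an [InstanceMap].
#' @param map named integer vector: `map[["old"]] = new`. Ids not named are
#'   kept. Mapping two ids to the same value merges them.
#' @return An [InstanceMap].
#' @export
relabelInstances <- function(instances, map) {
    stopifnot(is(instances, "InstanceMap"))
    g <- voxelGrid(instances)
    old <- as.integer(names(map))
    newv <- as.integer(map)
    out <- g
    for (i in seq_along(old)) out[g == old[i]] <- newv[i]
    InstanceMap(out, voxelSpacing(instances))
}
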
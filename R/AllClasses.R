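#' @include AllGenerics.R
NULL

.defaultLabelCodes <- c(background = 0L, parenchyma = 1L, edge = 2L, core = 3L)

.checkSpacing <- function(spacing) {
    if (!is.numeric(spacing) || length(spacing) != 3L)
        return("spacing must be a numeric vector of length 3 (dx, dy, dz in mm)")
    if (!all(is.finite(spacing)) || any(spacing <= 0))
        return("spacing values must be strictly positive and finite")
    NULL
}

.checkGrid3d <- function(grid) {
    if (!is.array(grid) || length(dim(grid)) != 3L)
        return("grid must be a 3D array")
    if (!is.integer(grid))
        return("grid must have integer storage mode")
    if (anyNA(grid))
        return("grid must not contain NA")
    NULL
}

#' Labeled 3D volumes with physical voxel spacing
#'
#' `LabelVolume` is the virtual parent of the two labeled-volume classes.
#' A [SemanticMask] holds per-voxel tissue classes of a polycystic organ
#' segmentation (background, parenchyma, cyst edge, cyst core), with the
#' integer code of each class carried as explicit metadata in `labelCodes()`
#' rather than by positional convention. An [InstanceMap] holds per-voxel
#' cyst identities: 0 marks non-cyst tissue and each positive integer one
#' individual cyst. Both carry the voxel spacing in mm taken from the image
#' header; axes follow the array's (x, y, z) order with 1-based R indexing.
#'
#' @slot grid 3D integer array of voxel labels.
#' @slot spacing numeric length 3; voxel edge lengths (dx, dy, dz) in mm.
#' @slot labels (`SemanticMask` only) named integer vector mapping the roles
#'   `background`, `parenchyma`, `edge`, `core` to their integer codes.
#'
#' @param grid 3D integer array (numeric arrays holding whole numbers are
#'   coerced).
#' @param spacing numeric length 3, voxel edge lengths in mm.
#' @param labels named integer vector with entries `background`, `parenchyma`,
#'   `edge`, `core`; defaults to codes 0:3.
#'
#' @return `SemanticMask()` and `InstanceMap()` return validated objects of
#'   the corresponding class.
#' @seealso [readLabelVolume()], [buildInstances()], [voxelVolumeMl()]
#' @examples
#' g <- array(0L, c(4, 4, 4))
#' g[2:3, 2:3, 2:3] <- 3L
#' sm <- SemanticMask(g, spacing = c(0.74, 0.74, 3))
#' sm
#' @name LabelVolume-classes
#' @aliases LabelVolume-class SemanticMask-class InstanceMap-class
#' @exportClass LabelVolume SemanticMask InstanceMap
NULL

setClass("LabelVolume",
    representation("VIRTUAL", grid = "array", spacing = "numeric"),
    validity = function(object) {
        msg <- c(.checkGrid3d(object@grid), .checkSpacing(object@spacing))
        if (length(msg)) msg else TRUE
    })

setClass("SemanticMask",
    contains = "LabelVolume",
    representation(labels = "integer"),
    validity = function(object) {
        lb <- object@labels
        need <- c("background", "parenchyma", "edge", "core")
        if (!all(need %in% names(lb)))
            return("labels must name all of: background, parenchyma, edge, core")
        if (anyDuplicated(lb))
            return("label codes must be distinct")
        bad <- setdiff(unique(as.vector(object@grid)), unname(lb))
        if (length(bad))
            return(sprintf("grid contains values outside the label mapping: %s",
                           paste(bad, collapse = ", ")))
        TRUE
    })

setClass("InstanceMap",
    contains = "LabelVolume",
    validity = function(object) {
        if (any(object@grid < 0L))
            return("instance grid must be non-negative (0 = non-cyst)")
        TRUE
    })

#' Organ context for exophytic/endophytic surface accounting
#'
#' An `OrganContext` carries the organ mask — parenchyma together with all
#' cyst voxels — against which "outer" (background-facing) cyst surface is
#' determined. Kidney cysts may be exophytic, bulging beyond the organ
#' contour so that part of their surface faces background; that outer
#' surface is excluded from the cyst-parenchyma surface area (CPSA).
#'
#' @slot mask 3D logical array, `TRUE` inside the organ (parenchyma or cyst).
#' @slot spacing numeric length 3, voxel edge lengths in mm.
#' @param mask 3D logical array.
#' @param spacing numeric length 3 (mm).
#' @return An `OrganContext` object.
#' @seealso [surfaceAreas()], [cpsa()]
#' @examples
#' oc <- OrganContext(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 1))
#' oc
#' @aliases OrganContext-class
#' @exportClass OrganContext
#' @export OrganContext
setClass("OrganContext",
    representation(mask = "array", spacing = "numeric"),
    validity = function(object) {
        if (!is.array(object@mask) || length(dim(object@mask)) != 3L ||
            !is.logical(object@mask) || anyNA(object@mask))
            return("mask must be a 3D logical array without NA")
        msg <- .checkSpacing(object@spacing)
        if (length(msg)) msg else TRUE
    })

.asIntegerGrid <- function(grid) {
    if (is.integer(grid)) return(grid)
    if (!is.numeric(grid))
        stop("grid must be numeric", call. = FALSE)
    if (any(abs(grid - round(grid)) > 1e-6, na.rm = TRUE))
        stop("grid contains non-integer voxel values", call. = FALSE)
    storage.mode(grid) <- "integer"
    grid
}

#' @rdname LabelVolume-classes
#' @export
SemanticMask <- function(grid, spacing, labels = .defaultLabelCodes) {
    labels <- vapply(labels, as.integer, integer(1))
    new("SemanticMask", grid = .asIntegerGrid(grid),
        spacing = as.numeric(spacing), labels = labels)
}

#' @rdname LabelVolume-classes
#' @export
InstanceMap <- function(grid, spacing) {
    new("InstanceMap", grid = .asIntegerGrid(grid), spacing = as.numeric(spacing))
}

OrganContext <- function(mask, spacing) {
    if (is.numeric(mask)) mask <- array(mask != 0, dim(mask))
    new("OrganContext", mask = mask, spacing = as.numeric(spacing))
}

#' @rdname volume-accessors
#' @export
setMethod("voxelGrid", "LabelVolume", function(x) x@grid)

#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "OrganContext", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("labelCodes", "SemanticMask", function(x) x@labels)

#' @rdname volume-accessors
#' @export
setMethod("instanceIds", "InstanceMap", function(x) {
    ids <- sort(unique(as.vector(x@grid)))
    ids[ids > 0L]
})

#' @rdname volume-accessors
#' @export
setMethod("organMask", "OrganContext", function(x) x@mask)

setMethod("show", "SemanticMask", function(object) {
    d <- dim(object@grid)
    counts <- vapply(object@labels, function(code) sum(object@grid == code), numeric(1))
    cat(sprintf("SemanticMask %dx%dx%d, spacing (%.4g, %.4g, %.4g) mm\n",
                d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
})

setMethod("show", "InstanceMap", function(object) {
    d <- dim(object@grid)
    ids <- instanceIds(object)
    cat(sprintf("InstanceMap %dx%dx%d, spacing (%.4g, %.4g, %.4g) mm\n",
                d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  %d cyst instance(s), %d cyst voxel(s)\n",
                length(ids), sum(object@grid > 0L)))
})

setMethod("show", "OrganContext", function(object) {
    d <- dim(object@mask)
    cat(sprintf("OrganContext %dx%dx%d, %d organ voxel(s)\n",
                d[1], d[2], d[3], sum(object@mask)))
})

.checkSameGeometry <- function(a, b) {
    da <- if (is(a, "OrganContext")) dim(a@mask) else dim(a@grid)
    db <- if (is(b, "OrganContext")) dim(b@mask) else dim(b@grid)
    if (!identical(da, db))
        stop("grid shapes differ: (", paste(da, collapse = "x"), ") vs (",
             paste(db, collapse = "x"), ")", call. = FALSE)
    sa <- voxelSpacing(a); sb <- voxelSpacing(b)
    if (max(abs(sa - sb)) > 1e-6)
        stop("voxel spacings differ between inputs", call. = FALSE)
    invisible(TRUE)
}
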
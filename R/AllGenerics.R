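#' @include RcppExports.R
NULL

#' Accessor generics for labeled volumes
#'
#' `voxelGrid()` returns the underlying 3D integer array, `voxelSpacing()`
#' the per-axis voxel edge lengths in mm, `labelCodes()` the semantic label
#' mapping, `instanceIds()` the sorted positive instance ids present, and
#' `organMask()` the logical organ mask of an [OrganContext].
#'
#' @param x a [SemanticMask], [InstanceMap] or [OrganContext] object.
#' @return `voxelGrid`: a 3D integer array; `voxelSpacing`: numeric length 3
#'   (mm); `labelCodes`: named integer vector; `instanceIds`: integer vector;
#'   `organMask`: 3D logical array.
#' @name volume-accessors
#' @aliases voxelGrid voxelSpacing labelCodes instanceIds organMask
#' @examples
#' im <- InstanceMap(array(c(0L, 1L, 2L, 0L), c(1, 2, 2)), spacing = c(1, 1, 1))
#' voxelGrid(im)
#' voxelSpacing(im)
#' instanceIds(im)
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname volume-accessors
#' @export
setGeneric("labelCodes", function(x) standardGeneric("labelCodes"))

#' @rdname volume-accessors
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))

#' @rdname volume-accessors
#' @export
setGeneric("organMask", function(x) standardGeneric("organMask"))
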
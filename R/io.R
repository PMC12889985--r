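#' @include AllClasses.R
NULL

#' Read a labeled NIfTI volume as a SemanticMask or InstanceMap
#'
#' Reads an integer-typed NIfTI-1 volume and wraps it in the requested
#' labeled-volume class. Voxel spacing is always taken from the image header
#' (`pixdim`), never from a sidecar. For `role = "semantic"` the voxel values
#' are validated against the label mapping; for `role = "instance"` they must
#' be non-negative integers.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param role `"semantic"` or `"instance"`.
#' @param labels label mapping used when `role = "semantic"`; see
#'   [SemanticMask()].
#' @return A [SemanticMask] or [InstanceMap].
#' @export
#' @examples
#' im <- InstanceMap(array(c(0L, 1L, 1L, 2L), c(2, 2, 1)), c(0.74, 0.74, 3))
#' f <- tempfile(fileext = ".nii.gz")
#' writeLabelVolume(im, f)
#' readLabelVolume(f, role = "instance")
readLabelVolume <- function(path, role = c("semantic", "instance"),
                            labels = .defaultLabelCodes) {
    role <- match.arg(role)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path, internal = FALSE)
    vals <- as.vector(img)
    if (any(abs(vals - round(vals)) > 1e-6))
        stop("volume does not hold integer labels: ", path, call. = FALSE)
    d <- dim(img)
    if (length(d) > 3L) {
        if (prod(d[-(1:3)]) != 1L)
            stop("expected a single 3D volume, got dims ",
                 paste(d, collapse = "x"), call. = FALSE)
        d <- d[1:3]
    }
    grid <- array(as.integer(round(vals)), d)
    spacing <- as.numeric(RNifti::pixdim(img))[1:3]
    if (role == "semantic")
        SemanticMask(grid, spacing, labels = labels)
    else
        InstanceMap(grid, spacing)
}

#' Write a labeled volume to NIfTI
#'
#' Writes the integer grid of a [SemanticMask] or [InstanceMap] to a
#' NIfTI-1 file with the voxel spacing encoded in the header, so that
#' [readLabelVolume()] inverts it bit-exactly.
#'
#' @param volume a [SemanticMask] or [InstanceMap].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
    if (!is(volume, "LabelVolume"))
        stop("volume must be a SemanticMask or InstanceMap", call. = FALSE)
    validObject(volume)
    g <- voxelGrid(volume)
    if (any(g < 0L))
        stop("refusing to write negative label values", call. = FALSE)
    attr(g, "pixdim") <- voxelSpacing(volume)
    dtype <- if (max(g) <= 32767L) "int16" else "int32"
    RNifti::writeNifti(g, path, datatype = dtype)
    invisible(path)
}

#' Voxel volume in millilitres
#'
#' Converts voxel spacing (mm per axis) to the volume of one voxel in ml:
#' dx*dy*dz / 1000 (mm^3 to ml).
#'
#' @param spacing numeric length 3 (mm), or an object with a
#'   [voxelSpacing()] method.
#' @return single numeric, ml per voxel.
#' @export
#' @examples
#' voxelVolumeMl(c(1, 1, 1))          # 0.001 ml
#' voxelVolumeMl(c(0.74, 0.74, 3.0))  # typical CT spacing
voxelVolumeMl <- function(spacing) {
    if (is(spacing, "LabelVolume") || is(spacing, "OrganContext"))
        spacing <- voxelSpacing(spacing)
    msg <- .checkSpacing(spacing)
    if (!is.null(msg)) stop(msg, call. = FALSE)
    prod(spacing) / 1000
}
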
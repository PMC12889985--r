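#' @include instances.R
NULL

#' Per-cyst volumes in millilitres
#'
#' @param instances an [InstanceMap].
#' @return Named numeric vector, one entry per instance id (names are the
#'   ids), each the voxel count times the voxel volume in ml.
#' @export
#' @examples
#' g <- array(0L, c(10, 10, 10)); g[1:10, 1:10, 1:10] <- 1L
#' perCystVolumes(InstanceMap(g, c(1, 1, 1)))  # 1000 voxels -> 1 ml
perCystVolumes <- function(instances) {
    stopifnot(is(instances, "InstanceMap"))
    g <- voxelGrid(instances)
    ids <- instanceIds(instances)
    if (!length(ids))
        return(stats::setNames(numeric(0), character(0)))
    counts <- tabulate(g[g > 0L], nbins = max(ids))[ids]
    stats::setNames(counts * voxelVolumeMl(voxelSpacing(instances)), ids)
}

#' Total cyst number and total cyst volume
#'
#' TCN is the count of cyst instances; TCV is the sum of per-cyst volumes in
#' ml. Both are invariant under any relabeling of instance ids; merging two
#' instances decreases TCN by one and leaves TCV unchanged.
#'
#' @param instances an [InstanceMap].
#' @return A list with elements `tcn` (integer) and `tcv` (numeric, ml).
#' @export
tcnTcv <- function(instances) {
    vols <- perCystVolumes(instances)
    list(tcn = length(vols), tcv = sum(vols))
}

#' Per-cyst total and outer (background-facing) surface areas
#'
#' Surface is estimated by voxel-face counting: every face of a cyst voxel
#' whose 6-neighbour does not carry the same instance id is an exposed face,
#' weighted by the product of the two voxel spacings orthogonal to its
#' normal (so anisotropic voxels are handled exactly). Faces shared by two
#' different cysts count towards both cysts' totals. The outer area is the
#' subset of exposed faces whose neighbouring voxel lies outside the organ
#' mask (background; voxels beyond the grid boundary count as background) —
#' the surface with which an exophytic cyst faces the outside of the organ
#' rather than parenchyma.
#'
#' @param instances an [InstanceMap].
#' @param context an [OrganContext] on the same grid; every cyst voxel must
#'   lie inside its organ mask.
#' @return A data.frame with columns `id`, `total_mm2`, `outer_mm2`, one row
#'   per instance id in increasing order.
#' @seealso [cpsa()]
#' @export
#' @examples
#' g <- array(0L, c(4, 4, 4)); g[2:3, 2:3, 2:3] <- 1L
#' ctx <- OrganContext(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
#' surfaceAreas(InstanceMap(g, c(1, 1, 1)), ctx)  # 24 mm^2 cube, outer 0
surfaceAreas <- function(instances, context) {
    stopifnot(is(instances, "InstanceMap"), is(context, "OrganContext"))
    .checkSameGeometry(instances, context)
    g <- voxelGrid(instances)
    om <- organMask(context)
    if (any(g > 0L & !om))
        stop("instance map has cyst voxels outside the organ mask", call. = FALSE)
    ids <- instanceIds(instances)
    if (!length(ids))
        return(data.frame(id = integer(0), total_mm2 = numeric(0),
                          outer_mm2 = numeric(0)))
    sp <- voxelSpacing(instances)
    maxid <- max(ids)
    total <- numeric(maxid)
    outer <- numeric(maxid)
    for (axis in 1:3) {
        faceArea <- prod(sp[-axis])
        for (dir in c(1L, -1L)) {
            nb <- .shiftGrid(g, axis, dir, fill = 0L)
            nbOrgan <- .shiftGrid(om, axis, dir, fill = FALSE)
            exposed <- g > 0L & nb != g
            total <- total + tabulate(g[exposed], nbins = maxid) * faceArea
            outerFace <- exposed & !nbOrgan
            outer <- outer + tabulate(g[outerFace], nbins = maxid) * faceArea
        }
    }
    data.frame(id = ids, total_mm2 = total[ids], outer_mm2 = outer[ids])
}

#' Cyst-parenchyma surface area (CPSA)
#'
#' CPSA is the sum of all cyst surface areas minus the outer surface of
#' exophytic cysts — the total area over which cysts interface with the
#' organ rather than with background. For fully endophytic organs (e.g.
#' liver) it equals the summed total cyst surface.
#'
#' @inheritParams surfaceAreas
#' @return CPSA in cm^2 (single numeric).
#' @export
cpsa <- function(instances, context) {
    sa <- surfaceAreas(instances, context)
    sum(sa$total_mm2 - sa$outer_mm2) / 100
}

#' Linear predictors of the 8-year eGFR slope
#'
#' Affine models predicting the 8-year slope of estimated glomerular
#' filtration rate (ml/min per 1.73 m^2 over 8 years) from a kidney cyst
#' biomarker. The shipped defaults are
#' \deqn{slope = -0.792 - 0.007 \times TCN}
#' \deqn{slope = -1.075 - 0.002 \times CPSA}
#' with TCN a count and CPSA in cm^2.
#'
#' @param kind `"TCN"` or `"CPSA"`.
#' @param intercept,coefficient override the shipped coefficients.
#' @return An object of class `EgfrSlopeModel` with fields `kind`,
#'   `intercept`, `coefficient`.
#' @export
#' @examples
#' egfrSlope(egfrSlopeModel("TCN"), 100)   # -0.792 - 0.007*100
egfrSlopeModel <- function(kind = c("TCN", "CPSA"), intercept = NULL,
                           coefficient = NULL) {
    kind <- match.arg(kind)
    defaults <- list(TCN = c(-0.792, -0.007), CPSA = c(-1.075, -0.002))[[kind]]
    structure(list(kind = kind,
                   intercept = if (is.null(intercept)) defaults[1] else as.numeric(intercept),
                   coefficient = if (is.null(coefficient)) defaults[2] else as.numeric(coefficient)),
              class = "EgfrSlopeModel")
}

#' @export
print.EgfrSlopeModel <- function(x, ...) {
    cat(sprintf("EgfrSlopeModel: slope = %g + %g x %s  (per 8 years)\n",
                x$intercept, x$coefficient, x$kind))
    invisible(x)
}

#' Predict the 8-year eGFR slope from a biomarker value
#'
#' @param model an [egfrSlopeModel()].
#' @param value predictor value(s): TCN count or CPSA in cm^2; must be
#'   non-negative.
#' @return Predicted slope(s) in eGFR units per 8 years.
#' @export
egfrSlope <- function(model, value) {
    if (!inherits(model, "EgfrSlopeModel"))
        stop("model must be an EgfrSlopeModel", call. = FALSE)
    if (!is.numeric(value) || any(value < 0))
        stop("predictor value must be non-negative", call. = FALSE)
    model$intercept + model$coefficient * value
}

#' Full biomarker panel for one case
#'
#' Computes TCN, TCV, per-cyst volumes and — when an organ context is
#' supplied (kidney pipelines) — CPSA and both predicted 8-year eGFR slopes.
#' Without an organ context (liver pipelines, where cysts are endophytic and
#' no exophytic accounting applies) only TCN and TCV are computed and the
#' CPSA-dependent entries are `NA`.
#'
#' @param instances an [InstanceMap].
#' @param context an [OrganContext], or `NULL` to skip CPSA.
#' @param tcnModel,cpsaModel [egfrSlopeModel()] objects used for the slope
#'   predictions.
#' @return An object of class `BiomarkerSet`: a list with elements `tcn`,
#'   `tcv`, `perCyst`, `cpsa`, `egfrSlopeTCN`, `egfrSlopeCPSA`.
#' @export
#' @examples
#' g <- array(0L, c(6, 6, 6)); g[2:3, 2:3, 2:3] <- 1L
#' computeBiomarkers(InstanceMap(g, c(10, 10, 10)))
computeBiomarkers <- function(instances, context = NULL,
                              tcnModel = egfrSlopeModel("TCN"),
                              cpsaModel = egfrSlopeModel("CPSA")) {
    vols <- perCystVolumes(instances)
    tt <- tcnTcv(instances)
    cp <- NA_real_
    slopeCpsa <- NA_real_
    if (!is.null(context)) {
        cp <- cpsa(instances, context)
        slopeCpsa <- egfrSlope(cpsaModel, cp)
    }
    structure(list(tcn = tt$tcn, tcv = tt$tcv, perCyst = vols, cpsa = cp,
                   egfrSlopeTCN = egfrSlope(tcnModel, tt$tcn),
                   egfrSlopeCPSA = slopeCpsa),
              class = "BiomarkerSet")
}

#' @export
print.BiomarkerSet <- function(x, ...) {
    cat("BiomarkerSet\n")
    cat(sprintf("  TCN: %d cysts, TCV: %.4g ml\n", x$tcn, x$tcv))
    if (!is.na(x$cpsa))
        cat(sprintf("  CPSA: %.4g cm^2\n", x$cpsa))
    cat(sprintf("  predicted 8-year eGFR slope (TCN):  %.4g\n", x$egfrSlopeTCN))
    if (!is.na(x$egfrSlopeCPSA))
        cat(sprintf("  predicted 8-year eGFR slope (CPSA): %.4g\n", x$egfrSlopeCPSA))
    invisible(x)
}
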
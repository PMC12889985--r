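#' @include biomarkers.R
NULL

.asForeground <- function(x) {
    if (is(x, "InstanceMap")) return(voxelGrid(x) > 0L)
    if (is(x, "SemanticMask")) {
        codes <- labelCodes(x)
        g <- voxelGrid(x)
        return(g == codes[["edge"]] | g == codes[["core"]])
    }
    if (is.array(x) && is.logical(x)) return(x)
    if (is.array(x) && is.numeric(x)) return(x != 0)
    stop("expected an InstanceMap, SemanticMask or logical array", call. = FALSE)
}

#' Voxel-level overlap scores between two segmentations
#'
#' Computes Dice, Jaccard, precision and recall between the cyst foreground
#' of a reference and a prediction on the same grid. Instance maps and
#' semantic masks are flattened to their cyst foreground. Conventions: if
#' both masks are empty all four scores are 1; any ratio with an empty
#' denominator (e.g. recall against an empty reference) is reported as 0.
#'
#' @param reference,prediction [InstanceMap]s, [SemanticMask]s or logical 3D
#'   arrays on the same grid.
#' @return A list with elements `dice`, `jaccard`, `precision`, `recall`,
#'   each in `[0, 1]`. Dice and Jaccard satisfy dice = 2J / (1 + J).
#' @export
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); b <- a
#' a[1:4] <- TRUE; b[2:7] <- TRUE   # |A| = 4, |B| = 6, |A & B| = 3
#' overlapScores(a, b)
overlapScores <- function(reference, prediction) {
    A <- .asForeground(reference)
    B <- .asForeground(prediction)
    if (!identical(dim(A), dim(B)))
        stop("grid shapes differ between reference and prediction", call. = FALSE)
    nA <- sum(A); nB <- sum(B); nAB <- sum(A & B)
    if (nA == 0 && nB == 0)
        return(list(dice = 1, jaccard = 1, precision = 1, recall = 1))
    ratio0 <- function(num, den) if (den == 0) 0 else num / den
    list(dice = ratio0(2 * nAB, nA + nB),
         jaccard = ratio0(nAB, nA + nB - nAB),
         precision = ratio0(nAB, nB),
         recall = ratio0(nAB, nA))
}

#' Dice coefficient for every overlapping instance pair
#'
#' For each (reference id, prediction id) pair whose voxel sets intersect,
#' computes the Dice coefficient of the two single-instance masks. Pairs
#' with empty intersection are omitted.
#'
#' @param reference,prediction [InstanceMap]s on the same grid.
#' @return A data.frame with columns `ref_id`, `pred_id`, `dice`, ordered by
#'   `ref_id` then `pred_id`.
#' @export
pairwiseInstanceDice <- function(reference, prediction) {
    stopifnot(is(reference, "InstanceMap"), is(prediction, "InstanceMap"))
    .checkSameGeometry(reference, prediction)
    rg <- voxelGrid(reference); pg <- voxelGrid(prediction)
    sel <- rg > 0L & pg > 0L
    if (!any(sel))
        return(data.frame(ref_id = integer(0), pred_id = integer(0),
                          dice = numeric(0)))
    pairKey <- paste(rg[sel], pg[sel], sep = ":")
    inter <- table(pairKey)
    parts <- do.call(rbind, strsplit(names(inter), ":", fixed = TRUE))
    refIds <- as.integer(parts[, 1]); predIds <- as.integer(parts[, 2])
    nRef <- tabulate(rg[rg > 0L], nbins = max(rg))
    nPred <- tabulate(pg[pg > 0L], nbins = max(pg))
    out <- data.frame(ref_id = refIds, pred_id = predIds,
                      dice = 2 * as.numeric(inter) /
                          (nRef[refIds] + nPred[predIds]))
    out <- out[order(out$ref_id, out$pred_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
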
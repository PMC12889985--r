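#' @include overlap.R
NULL

.cqCategories <- c("correct_detection", "false_positive", "false_negative",
                   "split", "merge", "split_merge")

#' Configuration for instance correspondence analysis
#'
#' @param tau Dice threshold in (0, 1] above which (inclusive) a reference
#'   and a prediction instance are considered to correspond. Default 0.1,
#'   the conventional permissive threshold for cyst matching.
#' @return An object of class `CorrespondenceConfig`.
#' @export
correspondenceConfig <- function(tau = 0.1) {
    if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
        stop("tau must be a single number in (0, 1]", call. = FALSE)
    structure(list(tau = as.numeric(tau)), class = "CorrespondenceConfig")
}

#' Bipartite correspondence graph between two instance maps
#'
#' Nodes are all reference ids and all prediction ids; an edge joins a
#' (reference, prediction) pair iff their pairwise Dice coefficient is at
#' least `tau`. Connected components of this graph are the units the
#' split/merge taxonomy classifies, which guarantees each instance is
#' counted exactly once.
#'
#' @param reference,prediction [InstanceMap]s on the same grid.
#' @param config a [correspondenceConfig()].
#' @return A list of class `CorrespondenceGraph` with elements `refIds`,
#'   `predIds`, `edges` (data.frame `ref_id`, `pred_id`, `dice`), `tau`.
#' @export
buildCorrespondenceGraph <- function(reference, prediction,
                                     config = correspondenceConfig()) {
    pd <- pairwiseInstanceDice(reference, prediction)
    edges <- pd[pd$dice >= config$tau, , drop = FALSE]
    rownames(edges) <- NULL
    structure(list(refIds = instanceIds(reference),
                   predIds = instanceIds(prediction),
                   edges = edges, tau = config$tau),
              class = "CorrespondenceGraph")
}

#' Classify correspondences into the split/merge taxonomy
#'
#' Connected components of the correspondence graph are classified by their
#' (reference count M, prediction count N) pattern:
#' 1-1 correct detection, 1-0 false negative, 0-1 false positive,
#' 1-N split, M-1 merge, M-N split-merge. Each component is counted exactly
#' once in exactly one category, so no instance is double-counted across
#' categories.
#'
#' @param graph a `CorrespondenceGraph` from [buildCorrespondenceGraph()].
#' @return An object of class `CorrespondenceReport`: list with `counts`
#'   (named integer vector over the six categories) and `components`
#'   (list of `list(ref_ids, pred_ids, category)`).
#' @export
#' @examples
#' g <- array(0L, c(8, 2, 2))
#' g[1:4, , ] <- 1L; g[6:8, , ] <- 2L
#' ref <- InstanceMap(g, c(1, 1, 1))
#' classifyCorrespondences(buildCorrespondenceGraph(ref, ref))$counts
classifyCorrespondences <- function(graph) {
    stopifnot(inherits(graph, "CorrespondenceGraph"))
    refNodes <- if (length(graph$refIds)) paste0("r", graph$refIds) else character(0)
    predNodes <- if (length(graph$predIds)) paste0("p", graph$predIds) else character(0)
    counts <- stats::setNames(integer(length(.cqCategories)), .cqCategories)
    components <- list()
    if (length(refNodes) || length(predNodes)) {
        ed <- graph$edges
        edgeVec <- if (nrow(ed)) rbind(paste0("r", ed$ref_id), paste0("p", ed$pred_id)) else NULL
        ig <- igraph::make_empty_graph(directed = FALSE)
        ig <- igraph::add_vertices(ig, length(refNodes) + length(predNodes),
                                   name = c(refNodes, predNodes))
        if (!is.null(edgeVec))
            ig <- igraph::add_edges(ig, as.vector(edgeVec))
        comp <- igraph::components(ig)
        member <- split(igraph::V(ig)$name, comp$membership)
        for (nodes in member) {
            refs <- sort(as.integer(sub("^r", "", nodes[startsWith(nodes, "r")])))
            preds <- sort(as.integer(sub("^p", "", nodes[startsWith(nodes, "p")])))
            M <- length(refs); N <- length(preds)
            category <-
                if (M == 1 && N == 1) "correct_detection"
                else if (M == 1 && N == 0) "false_negative"
                else if (M == 0 && N == 1) "false_positive"
                else if (M == 1 && N > 1) "split"
                else if (M > 1 && N == 1) "merge"
                else "split_merge"
            counts[category] <- counts[category] + 1L
            components[[length(components) + 1L]] <-
                list(ref_ids = refs, pred_ids = preds, category = category)
        }
    }
    structure(list(counts = counts, components = components,
                   n_ref = length(graph$refIds), n_pred = length(graph$predIds),
                   tau = graph$tau),
              class = "CorrespondenceReport")
}

#' @export
print.CorrespondenceReport <- function(x, ...) {
    cat(sprintf("CorrespondenceReport (tau = %g): %d reference, %d predicted instance(s)\n",
                x$tau, x$n_ref, x$n_pred))
    for (cat_ in names(x$counts))
        cat(sprintf("  %-18s %d\n", cat_, x$counts[[cat_]]))
    invisible(x)
}

#' Compare two instance maps end to end
#'
#' Convenience wrapper running [overlapScores()] on the flattened cyst
#' foregrounds and the split/merge classification at the given Dice
#' threshold.
#'
#' @inheritParams buildCorrespondenceGraph
#' @param tau Dice threshold for instance correspondence.
#' @return A list with elements `overlap` (see [overlapScores()]) and
#'   `correspondence` (a `CorrespondenceReport`).
#' @export
compareInstanceMaps <- function(reference, prediction, tau = 0.1) {
    list(overlap = overlapScores(reference, prediction),
         correspondence = classifyCorrespondences(
             buildCorrespondenceGraph(reference, prediction,
                                      correspondenceConfig(tau))))
}

#' Aggregate correspondence reports over cases
#'
#' Per category: total, mean per case, standard deviation across cases
#' (n - 1 denominator; reported as 0 with `sd_defined = FALSE` for a single
#' case) and the min-max range.
#'
#' @param reports list of `CorrespondenceReport` objects (one per case).
#' @return data.frame with columns `category`, `total`, `mean`, `sd`,
#'   `min`, `max`, `n_cases`, `sd_defined`.
#' @export
summarizeCases <- function(reports) {
    if (!length(reports))
        stop("at least one report is required", call. = FALSE)
    ok <- vapply(reports, inherits, logical(1), "CorrespondenceReport")
    if (!all(ok))
        stop("all elements must be CorrespondenceReport objects", call. = FALSE)
    mat <- vapply(reports, function(r) as.numeric(r$counts[.cqCategories]),
                  numeric(length(.cqCategories)))
    mat <- matrix(mat, nrow = length(.cqCategories))
    n <- ncol(mat)
    sds <- if (n >= 2) apply(mat, 1, stats::sd) else rep(0, nrow(mat))
    data.frame(category = .cqCategories,
               total = rowSums(mat),
               mean = rowMeans(mat),
               sd = sds,
               min = apply(mat, 1, min),
               max = apply(mat, 1, max),
               n_cases = n,
               sd_defined = n >= 2)
}
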
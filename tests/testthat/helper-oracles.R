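# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# Surface areas by explicit enumeration of all 6-neighbour faces.
bruteSurfaceAreas <- function(grid, organ, spacing) {
    d <- dim(grid)
    offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    areas <- c(prod(spacing[c(2, 3)]), prod(spacing[c(2, 3)]),
               prod(spacing[c(1, 3)]), prod(spacing[c(1, 3)]),
               prod(spacing[c(1, 2)]), prod(spacing[c(1, 2)]))
    ids <- sort(unique(grid[grid > 0]))
    total <- stats::setNames(numeric(length(ids)), ids)
    outer <- total
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        id <- grid[i, j, k]
        if (id == 0) next
        for (n in seq_along(offs)) {
            ii <- i + offs[[n]][1]; jj <- j + offs[[n]][2]; kk <- k + offs[[n]][3]
            inGrid <- ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
                kk >= 1 && kk <= d[3]
            nbId <- if (inGrid) grid[ii, jj, kk] else 0L
            if (nbId != id) {
                key <- as.character(id)
                total[key] <- total[key] + areas[n]
                nbOrgan <- if (inGrid) organ[ii, jj, kk] else FALSE
                if (!nbOrgan) outer[key] <- outer[key] + areas[n]
            }
        }
    }
    list(total = total, outer = outer)
}

# Dice of two binary masks by direct counting.
bruteDice <- function(a, b) {
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0) return(1)
    2 * sum(a & b) / (na + nb)
}

# Connected components of a thresholded bipartite dice matrix, via
# label propagation to a fixed point (no graph library).
bruteComponents <- function(refIds, predIds, edges) {
    nodes <- c(paste0("r", refIds), paste0("p", predIds))
    lab <- stats::setNames(seq_along(nodes), nodes)
    repeat {
        changed <- FALSE
        if (nrow(edges)) for (e in seq_len(nrow(edges))) {
            a <- paste0("r", edges$ref_id[e]); b <- paste0("p", edges$pred_id[e])
            m <- min(lab[a], lab[b])
            if (lab[a] != m || lab[b] != m) {
                lab[a] <- m; lab[b] <- m; changed <- TRUE
            }
        }
        if (!changed) break
    }
    comps <- split(names(lab), lab)
    lapply(comps, function(nodes) {
        list(ref_ids = sort(as.integer(sub("^r", "", nodes[startsWith(nodes, "r")]))),
             pred_ids = sort(as.integer(sub("^p", "", nodes[startsWith(nodes, "p")]))))
    })
}

bruteClassify <- function(M, N) {
    if (M == 1 && N == 1) "correct_detection"
    else if (M == 1 && N == 0) "false_negative"
    else if (M == 0 && N == 1) "false_positive"
    else if (M == 1 && N > 1) "split"
    else if (M > 1 && N == 1) "merge"
    else "split_merge"
}

# A random small label grid with values 0..maxId.
randomLabelGrid <- function(dims, maxId, pZero = 0.6) {
    array(sample(0:maxId, prod(dims), replace = TRUE,
                 prob = c(pZero, rep((1 - pZero) / maxId, maxId))),
          dims)
}

# A well-separated multi-cyst phantom spec used by round-trip tests:
# coarse enough to be fast, cysts big enough to keep a core.
roundTripSpec <- function(seed, target = 8L) {
    phantomSpec(gridShape = c(48L, 48L, 48L),
                spacing = c(1.5, 1.5, 3.0),
                organSemiAxesMm = c(30, 30, 60),
                cystCountTarget = target,
                radiusMeanLogMm = log(8), radiusSdLog = 0.25,
                radiusMinMm = 6, radiusMaxMm = 14,
                exophyticFraction = 0.25,
                gapVoxels = 2L,
                seed = seed)
}

# Partition equality up to relabeling: same foreground and a one-to-one
# id correspondence on it.
samePartition <- function(a, b) {
    ga <- voxelGrid(a); gb <- voxelGrid(b)
    if (!identical(ga > 0L, gb > 0L)) return(FALSE)
    sel <- ga > 0L
    if (!any(sel)) return(TRUE)
    tb <- table(ga[sel], gb[sel])
    all(rowSums(tb > 0) == 1) && all(colSums(tb > 0) == 1)
}
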
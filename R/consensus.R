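# Consensus community detection: repeated seeded Leiden runs, co-assignment
# consensus, and a maximum clade-credibility tree over per-run hierarchical
# partitions. Leiden itself is delegated to igraph; the consensus stages are
# implemented here.

# One seeded Leiden run with one level of hierarchical refinement: clusters
# of >= 4 sites are re-clustered on their induced subgraph.
leidenRun <- function(graph, resolution, seed) {
    withr::with_seed(seed, {
        cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                     resolution = resolution,
                                     n_iterations = 5)
        mem <- setNames(igraph::membership(cl), igraph::V(graph)$name)
        sub <- list()
        for (k in sort(unique(mem))) {
            members <- names(mem)[mem == k]
            if (length(members) >= 4L) {
                sg <- igraph::induced_subgraph(graph, members)
                scl <- igraph::cluster_leiden(sg,
                    objective_function = "modularity",
                    resolution = resolution, n_iterations = 5)
                sm <- setNames(igraph::membership(scl), igraph::V(sg)$name)
                if (length(unique(sm)) > 1L)
                    sub[[as.character(k)]] <- sm
            }
        }
        list(membership = mem, sub = sub)
    })
}

# All non-trivial clades (leaf sets of size >= 2, excluding the full set)
# implied by a run's two-level partition.
runClades <- function(run) {
    allSites <- names(run$membership)
    clades <- list()
    for (k in sort(unique(run$membership))) {
        members <- sort(names(run$membership)[run$membership == k])
        if (length(members) >= 2L && length(members) < length(allSites))
            clades[[length(clades) + 1L]] <- members
        sm <- run$sub[[as.character(k)]]
        if (!is.null(sm))
            for (j in sort(unique(sm))) {
                ms <- sort(names(sm)[sm == j])
                if (length(ms) >= 2L && length(ms) < length(members))
                    clades[[length(clades) + 1L]] <- ms
            }
    }
    unique(clades)
}

# Canonical newick for a run's partition, children ordered by smallest leaf.
# `supports` (named by clade key) annotates internal nodes when provided.
runNewick <- function(run, supports = NULL) {
    lab <- function(members) {
        if (is.null(supports)) return("")
        s <- supports[[paste(sort(members), collapse = "|")]]
        if (is.null(s)) "" else format(round(s, 3))
    }
    renderGroup <- function(members) {
        members <- sort(members)
        if (length(members) == 1L) return(members)
        paste0("(", paste(members, collapse = ","), ")", lab(members))
    }
    renderCluster <- function(k) {
        members <- sort(names(run$membership)[run$membership == k])
        if (length(members) == 1L) return(members)
        sm <- run$sub[[as.character(k)]]
        inner <- if (is.null(sm)) members else {
            grp <- lapply(sort(unique(sm)), function(j)
                names(sm)[sm == j])
            grp <- grp[order(vapply(grp, function(g) sort(g)[1], ""))]
            vapply(grp, renderGroup, "")
        }
        if (length(inner) == 1L) return(inner)
        paste0("(", paste(inner, collapse = ","), ")", lab(members))
    }
    ks <- sort(unique(run$membership))
    parts <- vapply(ks, renderCluster, "")
    parts <- parts[order(vapply(seq_along(parts), function(i)
        sort(names(run$membership)[run$membership == ks[i]])[1], ""))]
    if (length(parts) == 1L) paste0(parts, ";")
    else paste0("(", paste(parts, collapse = ","), ");")
}

#' Pick a Leiden resolution by partition-count stability
#'
#' Scans a resolution grid, records the modal number of communities over a
#' few seeded runs at each value, and returns the midpoint of the longest
#' plateau (consecutive resolutions yielding the same count). The scan is
#' logged via `message()`.
#'
#' @param graph Weighted site graph.
#' @param resolutions Resolution grid to scan.
#' @param nProbe Seeded runs per resolution.
#' @param seed Base seed.
#' @return A single resolution value.
#' @export
chooseResolution <- function(graph, resolutions = seq(0.2, 2, by = 0.2),
                             nProbe = 3L, seed = 1L) {
    counts <- vapply(seq_along(resolutions), function(i) {
        ks <- vapply(seq_len(nProbe), function(j) {
            run <- leidenRun(graph, resolutions[i], seed + 100L * i + j)
            length(unique(run$membership))
        }, numeric(1))
        as.numeric(names(sort(table(ks), decreasing = TRUE))[1])
    }, numeric(1))
    rle_ <- rle(counts)
    ends <- cumsum(rle_$lengths)
    best <- which.max(rle_$lengths)
    ix <- seq(ends[best] - rle_$lengths[best] + 1L, ends[best])
    res <- resolutions[ix[ceiling(length(ix) / 2)]]
    message(sprintf(
        "resolution scan: plateau of %d value(s) at %s communities; using resolution %.2f",
        rle_$lengths[best], rle_$values[best], res))
    res
}

#' Consensus Leiden community detection
#'
#' Runs seeded Leiden community detection `nRuns` times on a weighted site
#' graph, builds the co-assignment matrix (fraction of runs placing two
#' sites together), derives the consensus partition as the connected
#' components of the co-assignment graph thresholded at 0.5, and summarises
#' the run-to-run hierarchy as a maximum clade-credibility tree: each run's
#' two-level partition is a tree whose clades are scored by their
#' log-frequency across runs, and the best-scoring run tree (ties broken by
#' canonical newick order) is annotated with clade supports.
#'
#' @param graph Weighted undirected graph from [buildSiteGraph()].
#' @param nRuns Number of seeded runs (>= 2 for a consensus; a single run is
#'   returned as its own partition with a warning).
#' @param resolution Leiden resolution; `NULL` selects one with
#'   [chooseResolution()].
#' @param seeds Integer seeds, one per run (default `1:nRuns`).
#' @return A [ConsensusClustering-class].
#' @export
consensusLeiden <- function(graph, nRuns = 100L, resolution = NULL,
                            seeds = NULL) {
    if (nRuns < 1L) stop("nRuns must be at least 1")
    if (is.null(seeds)) seeds <- seq_len(nRuns)
    if (length(seeds) != nRuns) stop("need one seed per run")
    seeds <- as.integer(seeds)
    if (is.null(resolution)) resolution <- chooseResolution(graph)
    sites <- igraph::V(graph)$name
    runs <- lapply(seeds, function(s) leidenRun(graph, resolution, s))
    mem <- vapply(runs, function(r) unname(r$membership[sites]),
                  numeric(length(sites)))
    mem <- matrix(as.integer(mem), nrow = length(sites),
                  dimnames = list(sites, paste0("run", seq_len(nRuns))))
    if (nRuns < 2L)
        warning("consensus requires at least 2 runs; returning the single run")
    co <- matrix(0, length(sites), length(sites),
                 dimnames = list(sites, sites))
    for (r in seq_len(nRuns))
        co <- co + outer(mem[, r], mem[, r], "==")
    co <- co / nRuns
    consensus <- thresholdPartition(co, 0.5)
    # clade supports across runs
    cladeTab <- list()
    for (r in runs)
        for (cl in runClades(r)) {
            k <- paste(cl, collapse = "|")
            cladeTab[[k]] <- (if (is.null(cladeTab[[k]])) 0 else cladeTab[[k]]) + 1
        }
    supports <- lapply(cladeTab, function(x) x / nRuns)
    score <- vapply(runs, function(r) {
        cls <- runClades(r)
        if (!length(cls)) return(0)
        sum(vapply(cls, function(cl)
            log(supports[[paste(cl, collapse = "|")]]), numeric(1)))
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1L) {
        nwk <- vapply(runs[best], runNewick, "")
        best <- best[order(nwk)[1]]
    }
    treeNewick <- runNewick(runs[[best]], supports)
    runTrees <- vapply(runs, runNewick, "")
    new("ConsensusClustering", memberships = mem, coassignment = co,
        consensus = consensus, treeNewick = treeNewick, runTrees = runTrees,
        resolution = resolution, seeds = seeds)
}

# Partition = connected components of the co-assignment graph at a threshold.
thresholdPartition <- function(co, threshold) {
    adj <- co >= threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    data.frame(site = rownames(co), cluster = unname(comp[rownames(co)]),
               stringsAsFactors = FALSE)
}

#' ConsensusClustering accessors
#'
#' @param object A [ConsensusClustering-class].
#' @param threshold Co-assignment threshold for `consensusPartition()`
#'   (1.0 gives the strict agreement partition).
#' @return `coassignment()`: the co-assignment matrix;
#'   `consensusClusters()`: the 0.5-threshold consensus partition with
#'   stable cluster ids (by decreasing size, ties by smallest site id);
#'   `consensusPartition()`: the partition at an arbitrary threshold;
#'   `consensusTree()`: the consensus tree as an [ape::phylo] object.
#' @export
coassignment <- function(object) object@coassignment

#' @rdname coassignment
#' @export
consensusClusters <- function(object) stableClusterIds(object@consensus)

#' @rdname coassignment
#' @export
consensusPartition <- function(object, threshold = 0.5) {
    stableClusterIds(thresholdPartition(object@coassignment, threshold))
}

#' @rdname coassignment
#' @export
consensusTree <- function(object) ape::read.tree(text = object@treeNewick)

# Stable cluster ids: ordered by decreasing size, ties by smallest site id.
stableClusterIds <- function(part) {
    sizes <- table(part$cluster)
    minSite <- tapply(part$site, part$cluster, function(x) sort(x)[1])
    ord <- order(-as.integer(sizes), minSite)
    remap <- setNames(seq_along(ord), names(sizes)[ord])
    part$cluster <- as.integer(remap[as.character(part$cluster)])
    part[order(part$cluster, part$site), , drop = FALSE]
}

setMethod("show", "ConsensusClustering", function(object) {
    cat("ConsensusClustering:", nrow(object@memberships), "sites,",
        ncol(object@memberships), "runs, resolution",
        format(object@resolution), "\n")
    k <- length(unique(object@consensus$cluster))
    cat("  consensus partition (0.5 threshold):", k, "cluster(s)\n")
})

#' Export consensus clusters and the consensus tree
#'
#' Writes the stable cluster table (optionally joined with site geography
#' from the metadata), the co-assignment matrix and the annotated consensus
#' tree.
#'
#' @param object A [ConsensusClustering-class].
#' @param dir Output directory (created if missing).
#' @param metadata Optional metadata; site-constant `latitude`/`longitude`
#'   columns are joined onto the cluster table when present.
#' @param prefix File name prefix.
#' @return Invisibly, the list of written paths and the cluster table.
#' @export
exportClusters <- function(object, dir = tempfile("clusters"),
                           metadata = NULL, prefix = "ibd") {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    clusters <- consensusClusters(object)
    if (!is.null(metadata)) {
        geo <- intersect(c("latitude", "longitude"), names(metadata))
        if (length(geo)) {
            bySite <- metadata[!duplicated(metadata$site),
                               c("site", geo), drop = FALSE]
            clusters <- merge(clusters, bySite, by = "site",
                              all.x = TRUE, sort = FALSE)
            clusters <- clusters[order(clusters$cluster, clusters$site), ,
                                 drop = FALSE]
        }
    }
    paths <- list(clusters = file.path(dir, paste0(prefix, "_clusters.csv")),
                  coassignment = file.path(dir, paste0(prefix, "_coassignment.csv")),
                  tree = file.path(dir, paste0(prefix, "_consensus.nwk")))
    write.csv(clusters, paths$clusters, row.names = FALSE, quote = FALSE)
    write.csv(data.frame(site = rownames(object@coassignment),
                         object@coassignment, check.names = FALSE),
              paths$coassignment, row.names = FALSE, quote = FALSE)
    writeLines(object@treeNewick, paths$tree)
    invisible(c(paths, list(clusterTable = clusters)))
}
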
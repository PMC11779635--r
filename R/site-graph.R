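#' Weighted inter-site IBD sharing graph
#'
#' Builds an undirected graph whose nodes are burial sites and whose edge
#' weights are the average pairwise IBD in cM between individuals of the two
#' sites: the sum of cross-pair total IBD divided by the number of cross
#' pairs (all pairs, including those sharing nothing). Pairs below
#' `minPairCm` total IBD are excluded from the numerator. The within-site
#' average is stored as a node attribute (`NA`, flagged, for single-
#' individual sites), and sites below `minSiteN` individuals carry a
#' `flagged` attribute.
#'
#' @param pairs Pair table from [mergeAndClassify()].
#' @param metadata Metadata with `id` and `site`.
#' @param minPairCm Minimum per-pair total IBD (cM) entering the averages.
#' @param minSiteN Minimum site sample size below which a site is flagged.
#' @return An [igraph::graph] with vertex attributes `name`, `n`,
#'   `within_avg`, `flagged` and edge attribute `weight`.
#' @export
buildSiteGraph <- function(pairs, metadata, minPairCm = 12, minSiteN = 2L) {
    siteOf <- setNames(metadata$site, metadata$id)
    sites <- sort(unique(metadata$site))
    nPer <- table(factor(metadata$site, sites))
    p <- pairs[pairs$id1 %in% names(siteOf) & pairs$id2 %in% names(siteOf), ,
               drop = FALSE]
    p <- p[p$total_ibd_cm >= minPairCm, , drop = FALSE]
    s1 <- unname(siteOf[p$id1]); s2 <- unname(siteOf[p$id2])
    lo <- pmin(s1, s2); hi <- pmax(s1, s2)
    cross <- lo != hi
    sums <- tapply(p$total_ibd_cm[cross], paste(lo[cross], hi[cross], sep = "\r"),
                   sum)
    within <- tapply(p$total_ibd_cm[!cross], lo[!cross], sum)
    withinAvg <- vapply(sites, function(s) {
        n <- nPer[[s]]
        if (n < 2L) return(NA_real_)
        tot <- if (s %in% names(within)) within[[s]] else 0
        tot / choose(n, 2)
    }, numeric(1))
    edges <- NULL
    if (length(sites) > 1L) {
        cmb <- utils::combn(sites, 2L)
        key <- paste(cmb[1, ], cmb[2, ], sep = "\r")
        tot <- ifelse(key %in% names(sums), sums[key], 0)
        w <- unname(tot) / (as.numeric(nPer[cmb[1, ]]) * as.numeric(nPer[cmb[2, ]]))
        keep <- w > 0
        edges <- data.frame(from = cmb[1, keep], to = cmb[2, keep],
                            weight = w[keep])
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(sites),
                              attr = list(name = sites,
                                          n = as.integer(nPer),
                                          within_avg = unname(withinAvg),
                                          flagged = as.integer(nPer) < minSiteN))
    if (!is.null(edges) && nrow(edges))
        g <- igraph::add_edges(g, rbind(edges$from, edges$to),
                               weight = edges$weight)
    g
}
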
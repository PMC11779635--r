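# Per-site uniparental haplotype diversity, first-degree pruning, the
# normalized relative-pair statistic and the diversity-relatedness screen.

#' @rdname matrilineReport
#' @export
rootLabel <- function(labels) sub("\\..*$", "", labels)

#' Haplotype diversity
#'
#' The probability that two haplotypes sampled without replacement from the
#' site differ: `h = (n/(n-1)) * (1 - sum(p_i^2))`, identically the fraction
#' of discordant unordered pairs. The biased (with-replacement) variant
#' `1 - sum(p_i^2)` is available with `corrected = FALSE`.
#'
#' @param labels Vector of haplotype labels (NAs dropped).
#' @param corrected Apply the without-replacement `n/(n-1)` correction.
#' @return Haplotype diversity in `[0, 1]`.
#' @examples
#' haplotypeDiversity(c("A", "A", "A", "B"))  # 3 of 6 pairs discordant
#' @export
haplotypeDiversity <- function(labels, corrected = TRUE) {
    labels <- labels[!is.na(labels)]
    n <- length(labels)
    if (n < 2L)
        stop(formatError("haplotype diversity is undefined for fewer than 2 haplotypes"))
    p <- table(labels) / n
    h <- 1 - sum(p^2)
    if (corrected) h <- h * n / (n - 1)
    unname(h)
}

#' Remove first-degree relative pairs greedily
#'
#' Repeatedly removes the individual involved in the most remaining
#' first-degree pairs (ties broken by ascending id) until none remain; this
#' retains, e.g., all children of a parent-children star while dropping only
#' the parent.
#'
#' @param pairs Pair table from [mergeAndClassify()] (column `degree`).
#' @param ids Panel ids.
#' @return Character vector of retained ids.
#' @export
pruneFirstDegree <- function(pairs, ids) {
    fd <- pairs[!is.na(pairs$degree) & pairs$degree == 1L, c("id1", "id2")]
    fd <- fd[fd$id1 %in% ids & fd$id2 %in% ids, , drop = FALSE]
    removed <- character(0)
    while (nrow(fd) > 0L) {
        cnt <- table(c(fd$id1, fd$id2))
        worst <- names(cnt)[cnt == max(cnt)]
        victim <- sort(worst)[1]
        removed <- c(removed, victim)
        fd <- fd[fd$id1 != victim & fd$id2 != victim, , drop = FALSE]
    }
    setdiff(ids, removed)
}

#' Per-site haplotype panels with diversity and relative-pair statistics
#'
#' Applies first-degree pruning across the whole panel, then computes for
#' each site the retained sample size, haplotype diversity `h` of the chosen
#' uniparental marker and the normalized number of relative pairs `r_norm`
#' (relative = degree seven or closer; 1 = all retained pairs related,
#' 0 = none). For the Y marker only males with a Y label are considered.
#'
#' @param metadata Metadata data.frame (`id`, `site`, `sex`, `mt_label`,
#'   `y_label`, optionally `period`/`region`).
#' @param pairs Pair table from [mergeAndClassify()].
#' @param marker `"mt"` or `"y"`.
#' @param prune Apply first-degree pruning first (as the screen requires).
#' @return data.frame with one row per site: `site`, `n`, `h`, `n_rel_pairs`,
#'   `r_norm` plus any `period`/`region` columns (site-constant).
#' @export
buildSitePanels <- function(metadata, pairs, marker = c("mt", "y"),
                            prune = TRUE) {
    marker <- match.arg(marker)
    md <- metadata
    if (marker == "y")
        md <- md[!is.na(md$y_label) & md$sex == "M", , drop = FALSE]
    keep <- if (prune) pruneFirstDegree(pairs, md$id) else md$id
    md <- md[md$id %in% keep, , drop = FALSE]
    lab <- if (marker == "mt") md$mt_label else md$y_label
    rel <- pairs[!is.na(pairs$degree) & pairs$degree <= 7L, , drop = FALSE]
    relKey <- pairKey(rel$id1, rel$id2)
    extra <- intersect(c("period", "region"), names(metadata))
    out <- lapply(split(seq_len(nrow(md)), md$site), function(ix) {
        ids <- md$id[ix]
        n <- length(ids)
        h <- if (n >= 2L) haplotypeDiversity(lab[ix]) else NA_real_
        cmb <- if (n >= 2L) utils::combn(sort(ids), 2L) else
            matrix(character(0), nrow = 2)
        nRel <- sum(pairKey(cmb[1, ], cmb[2, ]) %in% relKey)
        row <- data.frame(site = md$site[ix][1], n = n, h = h,
                          n_rel_pairs = nRel,
                          r_norm = if (n >= 2L) nRel / choose(n, 2) else NA_real_,
                          stringsAsFactors = FALSE)
        for (cl in extra) row[[cl]] <- metadata[[cl]][match(ids[1], metadata$id)]
        row
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Diversity-versus-relatedness correlation screen
#'
#' For each group of sites (by default the interaction of any `period` and
#' `region` columns present) computes the two-sided Pearson correlation
#' between haplotype diversity and the normalized relative-pair count, plus
#' the fitted line. Groups with fewer than `minSites` sites or degenerate
#' variance are reported as skipped with a reason rather than an error.
#'
#' @param siteTable Per-site table from [buildSitePanels()] or a supplied CSV
#'   with columns `site`, `h`, `r_norm` (and optionally `period`, `region`).
#' @param grouping Character vector of grouping columns (present ones used).
#' @param minSites Minimum sites per group for a correlation.
#' @return list with `groups` (one row per group: `group`, `n_sites`, `r`,
#'   `p`, `slope`, `intercept`, `note`) and `sites` (the input table with
#'   group labels).
#' @export
diversityRelatednessScreen <- function(siteTable,
                                       grouping = c("period", "region"),
                                       minSites = 3L) {
    st <- siteTable[!is.na(siteTable$h) & !is.na(siteTable$r_norm), ,
                    drop = FALSE]
    gcols <- intersect(grouping, names(st))
    st$group <- if (length(gcols))
        do.call(paste, c(st[gcols], sep = ":")) else "all"
    rows <- lapply(split(st, st$group), function(g) {
        base <- data.frame(group = g$group[1], n_sites = nrow(g),
                           r = NA_real_, p = NA_real_, slope = NA_real_,
                           intercept = NA_real_, note = "",
                           stringsAsFactors = FALSE)
        if (nrow(g) < minSites) {
            base$note <- sprintf("skipped: fewer than %d sites", minSites)
            return(base)
        }
        if (sd(g$h) == 0 || sd(g$r_norm) == 0) {
            base$note <- "skipped: degenerate variance"
            return(base)
        }
        ct <- stats::cor.test(g$r_norm, g$h, method = "pearson",
                              alternative = "two.sided")
        fit <- stats::lm(h ~ r_norm, data = g)
        base$r <- unname(ct$estimate)
        base$p <- ct$p.value
        base$slope <- unname(coef(fit)[2])
        base$intercept <- unname(coef(fit)[1])
        base
    })
    groups <- do.call(rbind, rows)
    rownames(groups) <- NULL
    list(groups = groups, sites = st)
}
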
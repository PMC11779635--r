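# Pairwise kinship from IBD segment tables: merging, IBD1/IBD2 fractions,
# degree classification, weighted relatedness, ROH and cross-site relatives.

# Merge intervals, bridging gaps <= gap. Returns matrix with columns s, e.
mergeIntervals <- function(s, e, gap = 0) {
    if (length(s) == 0L) return(cbind(s = numeric(0), e = numeric(0)))
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    cme <- cummax(e)
    newGrp <- c(TRUE, s[-1] > head(cme, -1) + gap)
    last <- c(which(newGrp[-1]), length(s))
    cbind(s = s[newGrp], e = cme[last])
}

intervalIntersectLen <- function(a, b) {
    if (nrow(a) == 0L || nrow(b) == 0L) return(0)
    tot <- 0; ia <- 1L; ib <- 1L
    while (ia <= nrow(a) && ib <= nrow(b)) {
        lo <- max(a[ia, 1], b[ib, 1]); hi <- min(a[ia, 2], b[ib, 2])
        if (hi > lo) tot <- tot + (hi - lo)
        if (a[ia, 2] < b[ib, 2]) ia <- ia + 1L else ib <- ib + 1L
    }
    tot
}

#' Map kinship coefficients to relationship degrees
#'
#' Degrees use power-of-two bins: degree \eqn{d} corresponds to kinship in
#' \eqn{(2^{-(d+3/2)}, 2^{-(d+1/2)}]}, so e.g. parent-offspring kinship 1/4
#' falls in degree 1 and kinship 0.05 in degree 3. Kinship at or below the
#' degree-7 lower edge is unrelated (`NA`); kinship above the degree-1 upper
#' edge (duplicates, identical twins) is reported as degree 0.
#'
#' @param kinship Numeric vector of kinship coefficients in `[0, 0.5]`.
#' @return Integer vector of degrees (`NA` = unrelated).
#' @examples
#' kinshipDegree(c(0.25, 0.05, 0.001))
#' @export
kinshipDegree <- function(kinship) {
    d <- floor(-log2(pmax(kinship, 1e-300)) - 0.5 + 1e-9)
    d[kinship <= 2^-8.5] <- NA_integer_
    d[!is.na(d) & d < 0] <- 0L
    as.integer(d)
}

#' Merge IBD segments and classify pairwise relationships
#'
#' Collapses a refinedIBD-style segment table into one row per unordered
#' sample pair. Within each haplotype-pair channel, segments closer than
#' `gapCm` are bridged; the union of channels on each of the first sample's
#' haplotypes gives the IBD1/IBD2 decomposition (IBD2 is the overlap of the
#' two per-haplotype unions). The kinship coefficient is
#' `f_ibd1/4 + f_ibd2/2` and degrees follow [kinshipDegree()]. X-chromosome
#' records are accepted but excluded from autosomal kinship; their summed
#' length is reported separately. Self-pairs (ROH) are excluded here; see
#' [summarizeROH()]. Degree-1 pairs are labelled parent-offspring when
#' `f_ibd2 < 0.02` and `f_ibd1 > 0.9`, full siblings otherwise.
#'
#' @param ibd data.frame from [readIBD()] or [emitIBDTable()].
#' @param model The [GenomeModel-class] defining chromosome names, total
#'   autosomal length and the bp-per-cM scale.
#' @param gapCm Gap (cM) bridged when merging segments within a channel.
#' @return data.frame with columns `id1`, `id2`, `total_ibd_cm`, `x_cm`,
#'   `longest_segment_cm`, `f_ibd1`, `f_ibd2`, `kinship`, `degree`,
#'   `relationship`.
#' @export
mergeAndClassify <- function(ibd, model = defaultGenomeModel(), gapCm = 1) {
    emptyOut <- data.frame(id1 = character(), id2 = character(),
        total_ibd_cm = numeric(), x_cm = numeric(),
        longest_segment_cm = numeric(), f_ibd1 = numeric(),
        f_ibd2 = numeric(), kinship = numeric(), degree = integer(),
        relationship = character(), stringsAsFactors = FALSE)
    if (nrow(ibd) == 0L) return(emptyOut)
    known <- c(names(autosomeLengths(model)), "X")
    if (!all(ibd$chrom %in% known))
        stop("IBD records reference chromosomes unknown to the genome model: ",
             paste(unique(setdiff(ibd$chrom, known)), collapse = ", "))
    swap <- ibd$sample2 < ibd$sample1
    if (any(swap)) {
        tmp <- ibd[swap, ]
        ibd[swap, c("sample1", "hap1", "sample2", "hap2")] <-
            tmp[, c("sample2", "hap2", "sample1", "hap1")]
    }
    ibd <- ibd[ibd$sample1 != ibd$sample2, , drop = FALSE]
    if (nrow(ibd) == 0L) return(emptyOut)
    bp <- model@bpPerCm
    L <- totalAutosomalCm(model)
    gapBp <- gapCm * bp
    key <- paste(ibd$sample1, ibd$sample2, sep = "|")
    vS <- ibd$start_bp; vE <- ibd$end_bp
    vChrom <- ibd$chrom; vH1 <- ibd$hap1; vH2 <- ibd$hap2
    chanCode <- paste(vChrom, vH1, vH2)
    groups <- split(seq_len(nrow(ibd)), key)
    nG <- length(groups)
    rId1 <- character(nG); rId2 <- character(nG)
    rTot <- rXcm <- rLong <- rF1 <- rF2 <- numeric(nG)
    for (gi in seq_len(nG)) {
        ix <- groups[[gi]]
        xcm <- 0; tot <- 0; longest <- 0
        chromU <- list()  # per-autosome list(U1 = rows, U2 = rows)
        for (ci in split(ix, chanCode[ix])) {
            chrom <- vChrom[ci[1]]
            m <- mergeIntervals(vS[ci], vE[ci], gapBp)
            len <- sum(m[, 2] - m[, 1]) / bp
            if (chrom == "X") { xcm <- xcm + len; next }
            tot <- tot + len
            longest <- max(longest, (m[, 2] - m[, 1]) / bp)
            side <- if (vH1[ci[1]] == 1L) "U1" else "U2"
            chromU[[chrom]][[side]] <-
                rbind(chromU[[chrom]][[side]], m)
        }
        u1len <- 0; u2len <- 0; i2 <- 0
        for (u in chromU) {
            U1 <- if (is.null(u$U1)) cbind(s = numeric(0), e = numeric(0))
                  else mergeIntervals(u$U1[, 1], u$U1[, 2], 0)
            U2 <- if (is.null(u$U2)) cbind(s = numeric(0), e = numeric(0))
                  else mergeIntervals(u$U2[, 1], u$U2[, 2], 0)
            u1len <- u1len + sum(U1[, 2] - U1[, 1]) / bp
            u2len <- u2len + sum(U2[, 2] - U2[, 1]) / bp
            i2 <- i2 + intervalIntersectLen(U1, U2) / bp
        }
        rId1[gi] <- ibd$sample1[ix[1]]
        rId2[gi] <- ibd$sample2[ix[1]]
        rTot[gi] <- tot; rXcm[gi] <- xcm; rLong[gi] <- longest
        rF2[gi] <- i2 / L
        rF1[gi] <- (u1len + u2len - 2 * i2) / L
    }
    out <- data.frame(id1 = rId1, id2 = rId2, total_ibd_cm = rTot,
                      x_cm = rXcm, longest_segment_cm = rLong, f_ibd1 = rF1,
                      f_ibd2 = rF2, kinship = rF1 / 4 + rF2 / 2,
                      stringsAsFactors = FALSE)
    out$degree <- kinshipDegree(out$kinship)
    rel <- ifelse(is.na(out$degree), "unrelated",
                  ifelse(out$degree == 0L, "identical",
                         paste0("deg", out$degree)))
    po <- !is.na(out$degree) & out$degree == 1L
    rel[po] <- ifelse(out$f_ibd2[po] < 0.02 & out$f_ibd1[po] > 0.9, "PO", "FS")
    out$relationship <- rel
    out
}

#' Degree-weighted relatedness scores
#'
#' For each individual, the sum over its relatives of degree seven or closer
#' of `1/degree` (degree-0 identical pairs count with weight 1). Duplicate
#' pair rows are de-duplicated before summing.
#'
#' @param pairs Pair table from [mergeAndClassify()].
#' @param ids Character vector of panel ids (individuals without relatives
#'   score 0).
#' @return data.frame with columns `id`, `score`, `n_links`.
#' @examples
#' p <- data.frame(id1 = "a", id2 = c("b", "c", "d"), degree = c(1L, 2L, 7L))
#' weightedRelatedness(p, c("a", "b", "c", "d"))
#' @export
weightedRelatedness <- function(pairs, ids) {
    rel <- pairs[!is.na(pairs$degree) & pairs$degree <= 7L, , drop = FALSE]
    rel <- rel[!duplicated(pairKey(rel$id1, rel$id2)), , drop = FALSE]
    score <- setNames(numeric(length(ids)), ids)
    links <- setNames(integer(length(ids)), ids)
    if (nrow(rel)) {
        w <- 1 / pmax(rel$degree, 1L)
        for (side in c("id1", "id2")) {
            hit <- rel[[side]] %in% ids
            sc <- tapply(w[hit], rel[[side]][hit], sum)
            cn <- tapply(w[hit], rel[[side]][hit], length)
            score[names(sc)] <- score[names(sc)] + sc
            links[names(cn)] <- links[names(cn)] + as.integer(cn)
        }
    }
    data.frame(id = ids, score = unname(score[ids]),
               n_links = unname(links[ids]), stringsAsFactors = FALSE)
}

#' Cross-site relative pairs
#'
#' Pairs sharing more than `minTotalCm` of autosomal IBD whose members are
#' buried at different sites, annotated with whether their mtDNA root
#' haplotypes match.
#'
#' @param pairs Pair table from [mergeAndClassify()].
#' @param metadata Metadata with `id`, `site` and optionally `mt_label`.
#' @param minTotalCm Total-IBD threshold in cM (default 24).
#' @return data.frame subset of `pairs` with `site1`, `site2`, `mt_match`.
#' @export
betweenSiteRelatives <- function(pairs, metadata, minTotalCm = 24) {
    if (nrow(pairs) == 0L) {
        out <- cbind(pairs, data.frame(site1 = character(0),
            site2 = character(0), mt_match = logical(0)))
        return(out)
    }
    site <- setNames(metadata$site, metadata$id)
    mt <- if ("mt_label" %in% names(metadata))
        setNames(metadata$mt_label, metadata$id) else NULL
    pairs$site1 <- unname(site[pairs$id1])
    pairs$site2 <- unname(site[pairs$id2])
    keep <- !is.na(pairs$site1) & !is.na(pairs$site2) &
        pairs$site1 != pairs$site2 & pairs$total_ibd_cm > minTotalCm
    out <- pairs[keep, , drop = FALSE]
    out$mt_match <- if (is.null(mt)) NA else
        rootLabel(unname(mt[out$id1])) == rootLabel(unname(mt[out$id2]))
    rownames(out) <- NULL
    out
}

#' Summarise runs of homozygosity
#'
#' Self-pair records (an individual's two haplotypes sharing founder
#' material) are merged per chromosome and summed. Individuals without
#' self-pair records report zero.
#'
#' @param ibd IBD segment table (self-pairs identified by
#'   `sample1 == sample2`); X records are excluded.
#' @param ids Panel ids to report (defaults to those present in the table).
#' @param model Genome model (bp-per-cM scale).
#' @param gapCm Merge gap in cM.
#' @return data.frame with `id`, `roh_cm`, `n_segments`, `f_roh` (fraction of
#'   the autosomal map).
#' @export
summarizeROH <- function(ibd, ids = NULL, model = defaultGenomeModel(),
                         gapCm = 1) {
    if (is.null(ids))
        ids <- sort(unique(c(ibd$sample1, ibd$sample2)))
    bp <- model@bpPerCm
    self <- ibd[ibd$sample1 == ibd$sample2 & ibd$chrom != "X", , drop = FALSE]
    roh <- setNames(numeric(length(ids)), ids)
    nseg <- setNames(integer(length(ids)), ids)
    for (d in split(self, self$sample1)) {
        id <- d$sample1[1]
        if (!id %in% ids) next
        tot <- 0; k <- 0L
        for (cd in split(d, d$chrom)) {
            m <- mergeIntervals(cd$start_bp, cd$end_bp, gapCm * bp)
            tot <- tot + sum(m[, 2] - m[, 1]) / bp
            k <- k + nrow(m)
        }
        roh[id] <- tot; nseg[id] <- k
    }
    data.frame(id = ids, roh_cm = unname(roh[ids]),
               n_segments = unname(nseg[ids]),
               f_roh = unname(roh[ids]) / totalAutosomalCm(model),
               stringsAsFactors = FALSE)
}
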
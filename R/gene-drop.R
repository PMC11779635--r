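#' Drop genomes through a pedigree
#'
#' Simulates the transmission of founder genome segments down a pedigree:
#' every non-founder receives one recombined haplotype per parent per
#' autosome (Poisson crossovers, uniform positions), mothers transmit a
#' recombined X to all children, fathers pass their single X intact to
#' daughters and transmit no X to sons. Each individual's genome is thereby a
#' mosaic of founder segments, from which realized IBD sharing can be read
#' off exactly.
#'
#' @param pedigree A [Pedigree-class] (or a data.frame with `id`, `sex`,
#'   `mother`, `father`, `generation` columns).
#' @param model A [GenomeModel-class]; positions are in cM.
#' @param seed Integer seed (NULL to use the current RNG state).
#' @return data.frame of segment inheritance paths with columns `id`, `hap`
#'   (1 or 2; males have a single X haplotype), `chrom` (autosome names plus
#'   `"X"`), `start`, `end` (cM, half-open) and `founder` (founder allele id).
#' @examples
#' ped <- generatePedigree(simConfig(seed = 3, depth = 2), retries = 10)
#' paths <- dropGenomes(ped, genomeModel(c(chr1 = 100), xCm = 50), seed = 1)
#' @export
dropGenomes <- function(pedigree, model = defaultGenomeModel(), seed = NULL) {
    nd <- if (is(pedigree, "Pedigree")) pedNodes(pedigree) else pedigree
    nd <- nd[order(nd$generation), , drop = FALSE]
    if (any(!is.na(nd$mother) & is.na(nd$father)) ||
        any(is.na(nd$mother) & !is.na(nd$father)))
        stop("every non-founder needs both parents in the pedigree")
    idx <- function(x) ifelse(is.na(x), 0L, match(x, nd$id)) - 1L
    res <- withSeed(seed, cpp_drop_genomes(
        idx(nd$mother), idx(nd$father), nd$sex == "M",
        unname(autosomeLengths(model)), xLength(model)))
    chromNames <- c(names(autosomeLengths(model)), "X")
    out <- data.frame(
        id = nd$id[res$ind], hap = res$hap, chrom = chromNames[res$chrom],
        start = res$start, end = res$end, founder = res$founder,
        stringsAsFactors = FALSE)
    attr(out, "chromLevels") <- chromNames
    out
}

#' Emit a refinedIBD-style segment table from inheritance paths
#'
#' Compares every pair of haplotypes (including an individual's own two
#' haplotypes, yielding ROH records as self-pairs) and writes one record per
#' maximal run of shared founder material at least `minCm` long. Physical
#' coordinates are synthesised from the genome model's bp-per-cM scale; the
#' LOD column is a monotone stand-in (the segment's cM length), since no
#' genotype likelihoods exist for simulated segments.
#'
#' @param paths Output of [dropGenomes()].
#' @param model The [GenomeModel-class] used to drop the genomes.
#' @param minCm Minimum segment genetic length to report (> 0).
#' @return data.frame with columns `sample1`, `hap1`, `sample2`, `hap2`,
#'   `chrom`, `start_bp`, `end_bp`, `lod`, `length_cm` (half-open bp
#'   coordinates; pairs ordered, `sample1 <= sample2`).
#' @export
emitIBDTable <- function(paths, model = defaultGenomeModel(), minCm = 1) {
    if (!is.numeric(minCm) || length(minCm) != 1L || minCm <= 0)
        stop("minCm must be a single positive number")
    chromNames <- attr(paths, "chromLevels")
    if (is.null(chromNames)) chromNames <- c(names(autosomeLengths(model)), "X")
    ids <- sort(unique(paths$id))
    ci <- match(paths$chrom, chromNames)
    res <- cpp_ibd_from_paths(match(paths$id, ids), paths$hap, ci,
                              paths$start, paths$end, paths$founder, minCm)
    bp <- model@bpPerCm
    data.frame(
        sample1 = ids[res$ind1], hap1 = res$hap1,
        sample2 = ids[res$ind2], hap2 = res$hap2,
        chrom = chromNames[res$chrom],
        start_bp = round(res$start * bp), end_bp = round(res$end * bp),
        lod = round(res$end - res$start, 3),
        length_cm = res$end - res$start, stringsAsFactors = FALSE)
}

#' Realized kinship over replicate gene drops
#'
#' Repeatedly drops genomes through a pedigree and returns, for each requested
#' pair and replicate, the realized autosomal kinship coefficient (mean
#' founder-sharing over the four haplotype channels), IBD1/IBD2 genome
#' fractions, and the realized X kinship (hemizygous males contribute their
#' single X with probability 1).
#'
#' @param pedigree A [Pedigree-class] or node data.frame.
#' @param pairs Two-column character matrix/data.frame of individual ids.
#' @param model A [GenomeModel-class].
#' @param nReps Number of replicate drops.
#' @param seed Integer seed.
#' @return List of `nReps` x `nPairs` matrices: `phi`, `f1`, `f2`, `phiX`.
#' @export
realizedKinship <- function(pedigree, pairs, model = defaultGenomeModel(),
                            nReps = 100L, seed = NULL) {
    nd <- if (is(pedigree, "Pedigree")) pedNodes(pedigree) else pedigree
    nd <- nd[order(nd$generation), , drop = FALSE]
    pairs <- as.matrix(pairs)
    pa <- match(pairs[, 1], nd$id) - 1L
    pb <- match(pairs[, 2], nd$id) - 1L
    if (anyNA(pa) || anyNA(pb)) stop("pair ids missing from pedigree")
    idx <- function(x) ifelse(is.na(x), 0L, match(x, nd$id)) - 1L
    res <- withSeed(seed, cpp_replicate_kinship(
        idx(nd$mother), idx(nd$father), nd$sex == "M",
        unname(autosomeLengths(model)), xLength(model), pa, pb,
        as.integer(nReps)))
    nm <- paste(pairs[, 1], pairs[, 2], sep = "|")
    for (k in names(res)) colnames(res[[k]]) <- nm
    res
}
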
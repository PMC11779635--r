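#' Generate a multi-site community fixture (metadata + IBD table)
#'
#' Simulates `nSites` independent communities under the configured residence
#' rule, gene-drops genomes, and writes the two analysis inputs: a metadata
#' CSV of the buried (resident) individuals and a refinedIBD-dialect segment
#' table restricted to pairs of buried individuals. Individual and haplotype
#' labels are namespaced per site, so each site carries its own founding
#' matriline (the pattern of a dominant maternal lineage with de novo
#' subclades emerges from the residence rule itself). A fraction of resident
#' men are buried away from their natal community (`relocateProb`), creating
#' between-site relative pairs. A JSON sidecar records the full
#' parameterisation.
#'
#' @param config A [SimConfig-class] template; per-site seeds are derived
#'   deterministically from `config@seed`.
#' @param nSites Number of burial sites.
#' @param relocateProb Probability a resident man is buried at another site.
#' @param maxSiteSample Sampled burials per site: communities larger than
#'   this are down-sampled (seeded), emulating the few dozen burials an
#'   excavated cemetery typically yields.
#' @param minCm Minimum IBD segment length emitted, in cM.
#' @param model A [GenomeModel-class].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, a list with the written `metadata`, `ibd` and
#'   `provenance` paths plus the in-memory tables.
#' @export
makeSiteFixture <- function(config = simConfig(), nSites = 1L,
                            relocateProb = 0.1, maxSiteSample = 40L, minCm = 1,
                            model = defaultGenomeModel(),
                            dir = tempfile("fixture"), prefix = "panel") {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    mdList <- list()
    ibdList <- list()
    seeds <- config@seed + 1000L * (seq_len(nSites) - 1L)
    for (s in seq_len(nSites)) {
        cfg <- config
        cfg@seed <- seeds[s]
        ped <- generatePedigree(cfg, retries = 100L)
        seeds[s] <- ped@seed
        nd <- pedNodes(ped)
        tag <- sprintf("S%d", s)
        relabel <- function(x, pre) ifelse(is.na(x), x, paste0(tag, pre, x))
        nd$id <- paste0(tag, "_", nd$id)
        nd$mother <- relabel(nd$mother, "_")
        nd$father <- relabel(nd$father, "_")
        nd$mt_label <- paste0(tag, nd$mt_label)
        nd$y_label <- relabel(nd$y_label, "")
        paths <- dropGenomes(nd, model, seed = seeds[s] + 1L)
        ibd <- emitIBDTable(paths, model, minCm = minCm)
        res <- nd[nd$resident, , drop = FALSE]
        if (nrow(res) > maxSiteSample)
            res <- withSeed(seeds[s] + 3L,
                            res[sort(sample(nrow(res), maxSiteSample)), ,
                                drop = FALSE])
        md <- withSeed(seeds[s] + 2L, data.frame(
            id = res$id, site = tag, sex = res$sex, mt_label = res$mt_label,
            y_label = res$y_label,
            coverage = round(exp(runif(nrow(res), log(0.3), log(4))), 2),
            period = "IA", stringsAsFactors = FALSE))
        keep <- ibd$sample1 %in% md$id & ibd$sample2 %in% md$id
        mdList[[s]] <- md
        ibdList[[s]] <- ibd[keep, , drop = FALSE]
    }
    metadata <- do.call(rbind, mdList)
    ibd <- do.call(rbind, ibdList)
    rownames(metadata) <- rownames(ibd) <- NULL
    if (nSites > 1L && relocateProb > 0) {
        metadata <- withSeed(config@seed + 7L, {
            men <- which(metadata$sex == "M")
            move <- men[runif(length(men)) < relocateProb]
            for (i in move) {
                others <- setdiff(unique(metadata$site), metadata$site[i])
                metadata$site[i] <- sample(others, 1L)
            }
            metadata
        })
    }
    paths <- list(metadata = file.path(dir, paste0(prefix, "_metadata.csv")),
                  ibd = file.path(dir, paste0(prefix, ".ibd")),
                  provenance = file.path(dir, paste0(prefix, "_provenance.json")))
    writeMetadata(metadata, paths$metadata)
    writeIBD(ibd, paths$ibd)
    prov <- list(
        generator = "matrikin::makeSiteFixture",
        version = as.character(packageVersion("matrikin")),
        n_sites = nSites, site_seeds = seeds, base_seed = config@seed,
        residence = config@residence, depth = config@depth,
        offspring_mean = config@offspringMean,
        mt_mutation_rate = config@mtMutationRate,
        founder_scheme = config@founderScheme, stay_prob = config@stayProb,
        relocate_prob = relocateProb, max_site_sample = maxSiteSample,
        min_cm = minCm,
        n_individuals = nrow(metadata), n_ibd_records = nrow(ibd))
    jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, list(metadataTable = metadata, ibdTable = ibd)))
}
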
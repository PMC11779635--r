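test_that("pedigree generator enforces inheritance, residence and determinism", {
    for (res in c("matrilocal", "patrilocal", "mixed")) {
        cfg <- simConfig(seed = 42, depth = 4, residence = res)
        ped <- generatePedigree(cfg, retries = 50)
        expect_true(validObject(ped))
        nd <- pedNodes(ped)
        expect_true(all(nd$generation <= 4))
        # bit-identical rerun under the same seed
        cfg2 <- cfg; cfg2@seed <- ped@seed
        ped2 <- generatePedigree(cfg2)
        expect_identical(pedNodes(ped2), nd)
    }

    # zero mutation rate: all matriline descendants share the founder label,
    # in-marrying men carry distinct labels under the all-distinct scheme
    cfg <- simConfig(seed = 7, depth = 4, mtMutationRate = 0)
    ped <- generatePedigree(cfg, retries = 50)
    nd <- pedNodes(ped)
    founderMt <- nd$mt_label[is.na(nd$mother) & nd$sex == "F" &
                                 nd$origin == "founder"][1]
    descendants <- nd[nd$origin == "descendant", ]
    expect_true(all(descendants$mt_label == founderMt))
    husbands <- nd$mt_label[nd$origin == "immigrant" & nd$sex == "M"]
    expect_false(anyDuplicated(husbands) > 0)
    expect_false(founderMt %in% husbands)

    # depth 1: every child carries the founding mother's label
    ped1 <- generatePedigree(simConfig(seed = 3, depth = 1,
                                       mtMutationRate = 0), retries = 50)
    nd1 <- pedNodes(ped1)
    kids <- nd1[!is.na(nd1$mother), ]
    expect_true(all(kids$mt_label ==
        nd1$mt_label[nd1$id == kids$mother[1]]))
})

test_that("residence rules shape who is resident", {
    ped <- generatePedigree(simConfig(seed = 9, depth = 5,
                                      residence = "matrilocal"), retries = 50)
    nd <- pedNodes(ped)
    resAdults <- nd[nd$resident & !is.na(nd$mother), ]
    # resident non-founders are matriline descendants (their mother is in the
    # pedigree); in-marrying spouses are the only parent-less residents
    expect_true(all(resAdults$mother %in% nd$id))
    inMarrying <- nd[nd$resident & is.na(nd$mother) & nd$generation > 0, ]
    expect_true(all(inMarrying$origin == "immigrant"))
    expect_true(all(inMarrying$sex == "M"))

    pedP <- generatePedigree(simConfig(seed = 9, depth = 5,
                                       residence = "patrilocal"), retries = 50)
    ndP <- pedNodes(pedP)
    inW <- ndP[ndP$resident & is.na(ndP$mother) & ndP$generation > 0, ]
    expect_true(all(inW$sex == "F"))
})

test_that("all-extinct lineages are signalled as retriable failures", {
    cfg <- simConfig(seed = 1, depth = 4, offspringMean = 0.05)
    expect_error(generatePedigree(cfg, retries = 0),
                 class = "matrikin_extinction")
    expect_error(generatePedigree(cfg, retries = 2),
                 class = "matrikin_extinction")
})

test_that("gene dropping is exact for forced transmissions", {
    rel <- canonicalRelationships()
    gm <- tinyGenome()
    # parent-offspring: realized IBD1 fraction exactly 1, IBD2 exactly 0
    rk <- realizedKinship(rel$PO$nodes, rbind(rel$PO$pair), gm,
                          nReps = 25, seed = 4)
    expect_equal(unname(rk$f1[, 1]), rep(1, 25))
    expect_equal(unname(rk$f2[, 1]), rep(0, 25))
    expect_equal(unname(rk$phi[, 1]), rep(0.25, 25))
    # father-son: no shared X material, ever
    fs <- rbind(nodeRow("mo", "F"), nodeRow("fa", "M"),
                nodeRow("son", "M", "mo", "fa", 1))
    rk <- realizedKinship(fs, rbind(c("fa", "son")), gm, nReps = 50, seed = 5)
    expect_equal(unname(rk$phiX[, 1]), rep(0, 50))
    # mother-son X kinship is exactly 1/2 (son's whole X is maternal)
    rk <- realizedKinship(fs, rbind(c("mo", "son")), gm, nReps = 25, seed = 6)
    expect_equal(unname(rk$phiX[, 1]), rep(0.5, 25))
})

test_that("realized full-sib kinship converges to the closed form", {
    rel <- canonicalRelationships()$FS
    rk <- realizedKinship(rel$nodes, rbind(rel$pair), defaultGenomeModel(),
                          nReps = 3000, seed = 11)
    m <- mean(rk$phi[, 1]); se <- sd(rk$phi[, 1]) / sqrt(3000)
    expect_lt(abs(m - 0.25), 3 * se + 1e-12)
})

test_that("IBD table emission behaves as a monotone filter with ROH support", {
    ped <- generatePedigree(simConfig(seed = 15, depth = 3), retries = 50)
    gm <- midGenome()
    paths <- dropGenomes(ped, gm, seed = 2)
    expect_error(emitIBDTable(paths, gm, minCm = 0), "positive")
    expect_error(emitIBDTable(paths, gm, minCm = -1), "positive")
    lo <- emitIBDTable(paths, gm, minCm = 1)
    hi <- emitIBDTable(paths, gm, minCm = 5)
    expect_true(all(hi$length_cm >= 5))
    keyOf <- function(x) paste(x$sample1, x$hap1, x$sample2, x$hap2, x$chrom,
                               x$start_bp, x$end_bp)
    expect_true(all(keyOf(hi) %in% keyOf(lo)))

    # unrelated founders share nothing
    founders <- founderIds(ped)
    f2 <- founders[1:2]
    cross <- lo$sample1 %in% f2 & lo$sample2 %in% f2 & lo$sample1 != lo$sample2
    expect_equal(sum(cross), 0)

    # a duplicated individual (monozygotic trick) is IBD2 across the map
    dup <- paths[paths$id == founders[1], ]
    dup$id <- "copy"
    both <- rbind(paths, dup)
    attr(both, "chromLevels") <- attr(paths, "chromLevels")
    ibd <- emitIBDTable(both, gm, minCm = 1)
    pr <- mergeAndClassify(ibd, gm)
    mz <- pr[(pr$id1 == founders[1] & pr$id2 == "copy") |
             (pr$id2 == founders[1] & pr$id1 == "copy"), ]
    expect_equal(mz$f_ibd2, 1)
    expect_equal(mz$kinship, 0.5)
    expect_equal(mz$relationship, "identical")
})

test_that("emitted tables round-trip through the readers bit-identically", {
    ped <- generatePedigree(simConfig(seed = 21, depth = 3), retries = 50)
    gm <- tinyGenome()
    ibd <- emitIBDTable(dropGenomes(ped, gm, seed = 1), gm, minCm = 1)
    f1 <- tempfile(); f2 <- tempfile()
    writeIBD(ibd, f1)
    back <- readIBD(f1)
    writeIBD(back, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(nrow(back), nrow(ibd))
})

test_that("de novo mtDNA labelling accumulates at the configured rate", {
    # 10,000 maternal transmissions at rate 0.05: de novo count within 3 SE
    rate <- 0.05
    mutations <- 0L
    transmissions <- 0L
    for (chunk in 1:10) {
        cfg <- simConfig(seed = chunk, depth = 1, offspringMean = 10,
                         founderCouples = 100L, mtMutationRate = rate)
        ped <- generatePedigree(cfg, retries = 20)
        nd <- pedNodes(ped)
        kids <- nd[!is.na(nd$mother), ]
        moLab <- nd$mt_label[match(kids$mother, nd$id)]
        mutations <- mutations + sum(kids$mt_label != moLab)
        transmissions <- transmissions + nrow(kids)
    }
    expect_gt(transmissions, 8000)
    se <- sqrt(transmissions * rate * (1 - rate))
    expect_lt(abs(mutations - transmissions * rate), 3 * se)
})

test_that("multi-site fixtures carry the expected dominance patterns", {
    fx <- makeSiteFixture(simConfig(seed = 31, depth = 5), nSites = 2,
                          relocateProb = 0, minCm = 4, model = midGenome())
    md <- fx$metadataTable
    for (s in unique(md$site)) {
        rep <- matrilineReport(md$mt_label[md$site == s])
        expect_gt(rep$frequency, 0.5)
    }
    # patrilocal fixture: dominant Y among resident males
    fy <- makeSiteFixture(simConfig(seed = 33, depth = 5,
                                    residence = "patrilocal"),
                          nSites = 1, minCm = 4, model = midGenome())
    men <- fy$metadataTable[fy$metadataTable$sex == "M", ]
    repY <- matrilineReport(men$y_label)
    expect_gt(repY$frequency, 0.5)

    # single-site panel has no between-site relatives
    ibd <- readIBD(fy$ibd)
    pairs <- mergeAndClassify(ibd, midGenome())
    expect_equal(nrow(betweenSiteRelatives(pairs, fy$metadataTable)), 0)

    # provenance sidecar records the parameterisation
    prov <- jsonlite::read_json(fx$provenance)
    expect_equal(prov$n_sites, 2)
    expect_equal(prov$residence, "matrilocal")
    expect_equal(prov$n_individuals, nrow(md))
})
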
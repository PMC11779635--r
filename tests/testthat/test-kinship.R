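test_that("the IBD reader validates the refinedIBD dialect", {
    f <- tempfile()
    writeLines(character(0), f)
    empty <- readIBD(f)
    expect_equal(nrow(empty), 0)
    expect_named(empty, c("sample1", "hap1", "sample2", "hap2", "chrom",
                          "start_bp", "end_bp", "lod", "length_cm"))
    # malformed column count reported with its line number
    writeLines(c("a\t1\tb\t1\tchr1\t0\t100\t3\t1.5",
                 "a\t1\tb\t1\tchr1\t0\t100\t3"), f)
    expect_error(readIBD(f), "line 2", class = "matrikin_format_error")
    # non-positive genetic length rejected
    writeLines(c("a\t1\tb\t1\tchr1\t0\t100\t3\t1.5",
                 "a\t1\tb\t2\tchr1\t0\t100\t3\t0"), f)
    expect_error(readIBD(f), "line 2", class = "matrikin_format_error")
    expect_error(readIBD(tempfile()), class = "matrikin_format_error")
})

test_that("degree bins follow the power-of-two kinship ranges", {
    expect_equal(kinshipDegree(0.25), 1L)
    # 0.05 sits inside the degree-3 bin (2^-4.5, 2^-3.5]
    expect_true(2^-4.5 < 0.05 && 0.05 <= 2^-3.5)
    expect_equal(kinshipDegree(0.05), 3L)
    expect_equal(kinshipDegree(0.5), 0L)
    expect_true(is.na(kinshipDegree(2^-8.5)))
    expect_true(is.na(kinshipDegree(0)))
    # exact bin edges belong to the lower-kinship degree's bin upper edge
    for (d in 1:7) {
        expect_equal(kinshipDegree(2^-(d + 0.5)), d)
        expect_equal(kinshipDegree(2^-(d + 1) ), d)
    }
    # monotone non-increasing in kinship
    ks <- sort(runif(200, 0, 0.5))
    dg <- kinshipDegree(ks)
    dg[is.na(dg)] <- 8L
    expect_true(all(diff(dg) <= 0 | diff(ks) == 0))
})

test_that("merge-and-classify recovers forced relationships", {
    ped <- generatePedigree(simConfig(seed = 5, depth = 3), retries = 50)
    gm <- midGenome()
    ibd <- emitIBDTable(dropGenomes(ped, gm, seed = 8), gm, minCm = 1)
    pairs <- mergeAndClassify(ibd, gm)
    nd <- pedNodes(ped)
    kid <- nd[!is.na(nd$mother), ][1, ]
    po <- pairs[pairKey(pairs$id1, pairs$id2) ==
                pairKey(kid$id, kid$mother), ]
    expect_equal(po$kinship, 0.25)
    expect_equal(po$degree, 1L)
    expect_equal(po$relationship, "PO")
    expect_lt(po$f_ibd2, 0.02)
    # unrelated founders produce no pair row at all
    founders <- founderIds(ped)[1:2]
    expect_equal(nrow(pairs[pairs$id1 %in% founders &
                            pairs$id2 %in% founders, ]), 0)
    # unknown chromosome rejected
    bad <- ibd[1, ]; bad$chrom <- "chr99"
    expect_error(mergeAndClassify(rbind(ibd, bad), gm), "chr99")
    # pair-relation bounds hold across the whole panel
    expect_true(all(pairs$f_ibd1 + pairs$f_ibd2 <= 1 + 1e-9))
    expect_true(all(pairs$kinship <= 0.5 + 1e-12))
    expect_true(all(pairs$kinship >= 0))
    expect_equal(pairs$kinship, pairs$f_ibd1 / 4 + pairs$f_ibd2 / 2)
})

test_that("X records feed the X summary but not autosomal kinship", {
    gm <- tinyGenome()
    ibd <- data.frame(sample1 = "a", hap1 = 1L, sample2 = "b", hap2 = 1L,
                      chrom = c("chr1", "X"),
                      start_bp = c(0, 0), end_bp = c(50e6, 40e6),
                      lod = 3, length_cm = c(50, 40),
                      stringsAsFactors = FALSE)
    pr <- mergeAndClassify(ibd, gm)
    expect_equal(pr$x_cm, 40)
    expect_equal(pr$total_ibd_cm, 50)
    expect_equal(pr$kinship, (50 / 270) / 4)
    # gap bridging: two 10 cM segments 0.5 cM apart merge into one
    near <- data.frame(sample1 = "a", hap1 = 1L, sample2 = "b", hap2 = 1L,
                       chrom = "chr1",
                       start_bp = c(0, 10.5e6), end_bp = c(10e6, 20.5e6),
                       lod = 3, length_cm = 10, stringsAsFactors = FALSE)
    pr1 <- mergeAndClassify(near, gm, gapCm = 1)
    expect_equal(pr1$longest_segment_cm, 20.5)
    pr0 <- mergeAndClassify(near, gm, gapCm = 0.1)
    expect_equal(pr0$longest_segment_cm, 10)
})

test_that("weighted relatedness sums inverse degrees without double counting", {
    ids <- c("a", "b", "c", "d", "e")
    pairs <- data.frame(id1 = c("a", "a", "a"), id2 = c("b", "c", "d"),
                        degree = c(1L, 2L, 7L), stringsAsFactors = FALSE)
    ws <- weightedRelatedness(pairs, ids)
    expect_equal(ws$score[ws$id == "a"], 1 + 1 / 2 + 1 / 7)
    expect_equal(ws$score[ws$id == "e"], 0)
    expect_equal(ws$n_links[ws$id == "e"], 0)
    # duplicated rows must not double-count
    ws2 <- weightedRelatedness(rbind(pairs, pairs[1, ]), ids)
    expect_equal(ws2$score, ws$score)
    # unrelated and degree > 7 rows are ignored
    pairs3 <- rbind(pairs, data.frame(id1 = "a", id2 = "e",
                                      degree = NA_integer_))
    expect_equal(weightedRelatedness(pairs3, ids)$score[1], ws$score[1])
})

test_that("sex-bias tests match their closed-form oracles", {
    md <- data.frame(id = letters[1:10], sex = rep(c("F", "M"), each = 5),
                     mt_label = c(rep("U5", 4), "H", "H", rep("J", 4)),
                     stringsAsFactors = FALSE)
    # identical score vectors: t = 0, p = 1
    sc <- data.frame(id = letters[1:10], score = rep(c(1, 2, 3, 2, 1), 2),
                     n_links = 1L)
    res <- sexBiasTests(sc, md)
    expect_equal(res$welch$statistic, 0)
    expect_equal(res$welch$p, 1)
    # Welch against the closed form on unequal scores
    sc$score <- c(3, 4, 5, 4, 3, 1, 2, 1, 0, 1)
    res <- sexBiasTests(sc, md)
    or <- welchOracle(sc$score[1:5], sc$score[6:10])
    expect_equal(res$welch$statistic, or$t)
    expect_equal(res$welch$p, or$p)
    # Fisher on the (8,2;2,8) table: enumerated two-sided tail
    mdF <- data.frame(id = sprintf("i%02d", 1:20),
                      sex = rep(c("F", "M"), each = 10),
                      mt_label = c(rep("U5", 8), "H", "J",
                                   rep("U5", 2), rep("H", 8)),
                      stringsAsFactors = FALSE)
    scF <- data.frame(id = mdF$id, score = rep(c(1, 0), 10), n_links = 0L)
    resF <- sexBiasTests(scF, mdF, dominantLabel = "U5")
    expect_equal(resF$fisher$p, fisherOracle(8, 2, 2, 8))
    expect_lt(abs(resF$fisher$p - 0.023), 5e-4)
    # empty stratum is skipped with a reason
    res1 <- sexBiasTests(sc[1:5, ], md[1:5, ])
    expect_true(res1$welch$skipped)
    expect_match(res1$welch$reason, "each sex")
})

test_that("between-site relatives respect the threshold monotonically", {
    md <- data.frame(id = c("a", "b", "c", "d"),
                     site = c("S1", "S1", "S2", "S2"),
                     mt_label = c("U5", "H", "U5.1", "J"),
                     stringsAsFactors = FALSE)
    pairs <- data.frame(id1 = c("a", "a", "a", "c"),
                        id2 = c("b", "c", "d", "d"),
                        total_ibd_cm = c(100, 30, 20, 50),
                        degree = 2L, stringsAsFactors = FALSE)
    b24 <- betweenSiteRelatives(pairs, md, 24)
    expect_equal(nrow(b24), 1)   # a-c crosses sites above 24; a-b is within-site
    expect_true(b24$mt_match)    # U5 vs U5.1 share the root
    b10 <- betweenSiteRelatives(pairs, md, 10)
    expect_true(all(pairKey(b24$id1, b24$id2) %in% pairKey(b10$id1, b10$id2)))
    expect_equal(nrow(betweenSiteRelatives(pairs, md, Inf)), 0)
    oneSite <- md; oneSite$site <- "S1"
    expect_equal(nrow(betweenSiteRelatives(pairs, oneSite, 10)), 0)
})

test_that("ROH summaries recover the inbreeding coefficient of cousin unions", {
    # no self-pairs: all zeros
    ibd <- data.frame(sample1 = "a", hap1 = 1L, sample2 = "b", hap2 = 1L,
                      chrom = "chr1", start_bp = 0, end_bp = 1e6, lod = 3,
                      length_cm = 1, stringsAsFactors = FALSE)
    z <- summarizeROH(ibd, c("a", "b"), tinyGenome())
    expect_equal(z$roh_cm, c(0, 0))
    # offspring of first cousins: mean ROH fraction ~ 1/16
    rel <- canonicalRelationships()$C1
    nodes <- rbind(rel$nodes,
                   nodeRow("kid", "F", "a", "b", 3))
    gm <- midGenome()
    fr <- replicate(150, NA_real_)
    withr::with_seed(19, {
        for (i in seq_along(fr)) {
            paths <- dropGenomes(nodes, gm)
            ibd <- emitIBDTable(paths, gm, minCm = 0.01)
            fr[i] <- summarizeROH(ibd, "kid", gm)$f_roh
        }
    })
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - 1 / 16), 3 * se + 0.003)
})
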
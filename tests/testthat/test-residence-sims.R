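test_that("deme populations conserve size and labels under migration", {
    # migration moves labels between demes but never creates them
    withr::with_seed(2, {
        rep <- matrikin:::cpp_deme_replicate(4L, 10L, 10L, 0.3, 0.3, 20L)
        expect_true(rep$ok)
        founders <- 0:(4 * 20 - 1)
        expect_true(all(rep$mtF %in% founders))
        expect_true(all(rep$mtM %in% founders))
        expect_true(all(rep$yM %in% 0:(4 * 10 - 1)))
        expect_length(rep$mtF, 40)
        expect_length(rep$mtM, 40)
    })
    # closed single deme: final haplotype set is a subset of the founders'
    withr::with_seed(3, {
        rep <- matrikin:::cpp_deme_replicate(1L, 15L, 15L, 0, 0, 30L)
        expect_true(length(unique(rep$mtF)) <= 30)
        expect_lt(length(unique(c(rep$mtF, rep$mtM))), 30)  # drift lost some
    })
    sim <- simulateDemes(demeConfig(nDemes = 3, femalesPerDeme = 10,
                                    malesPerDeme = 10, generations = 10,
                                    replicates = 5, seed = 4))
    expect_true(all(sim$n == 20))
    expect_true(all(sim$n_males == 10))
    # determinism
    sim2 <- simulateDemes(demeConfig(nDemes = 3, femalesPerDeme = 10,
                                     malesPerDeme = 10, generations = 10,
                                     replicates = 5, seed = 4))
    expect_identical(sim, sim2)
})

test_that("female philopatry with male migration depresses mtDNA diversity", {
    sim <- simulateDemes(demeConfig(mF = 0, mM = 0.5, replicates = 40,
                                    generations = 50, seed = 21))
    expect_lt(mean(sim$h_mt), mean(sim$h_y))
    # and the sexes swap symmetrically when rates are swapped
    simSwap <- simulateDemes(demeConfig(mF = 0.5, mM = 0, replicates = 40,
                                        generations = 50, seed = 22))
    expect_lt(mean(simSwap$h_y), mean(simSwap$h_mt))
    expect_lt(abs(mean(sim$h_mt) - mean(simSwap$h_y)), 0.08)
    expect_lt(abs(mean(sim$h_y) - mean(simSwap$h_mt)), 0.08)
})

test_that("rejection inference accepts planted cells and honours tolerance", {
    small <- demeConfig(nDemes = 5, femalesPerDeme = 12, malesPerDeme = 12,
                        generations = 25, replicates = 30, seed = 5)
    # observed summary generated from the cell (mF = 0, mM = 0.4)
    obsCfg <- small; obsCfg@mF <- 0; obsCfg@mM <- 0.4; obsCfg@seed <- 91L
    obsSim <- simulateDemes(obsCfg)
    obs <- c(mean(obsSim$h_mt), mean(obsSim$h_y))
    reg <- inferMigration(obs[1], obs[2], small, grid = c(0, 0.2, 0.4, 0.8))
    acc <- acceptedCells(reg)
    expect_gt(nrow(acc), 0)
    expect_true(any(acc$mF == 0 & acc$mM == 0.4))
    # low mtDNA diversity with high Y diversity pins the female rate at zero
    iv <- migrationIntervals(reg)
    expect_equal(iv$mF[1], 0)
    # infinite tolerance accepts every cell
    regAll <- inferMigration(obs[1], obs[2], small, grid = c(0, 0.5, 1),
                             tolerance = Inf)
    expect_true(all(regAll@grid$accepted))
    # empty acceptance is reported, not raised
    regNone <- inferMigration(0, 0, small, grid = c(0.5), coverage = 0.5)
    expect_true(is.na(migrationIntervals(regNone)$mF[1]))
    expect_error(inferMigration(-0.1, 0.5, small), "0, 1")
})

test_that("expected X kinship obeys the transmission rules", {
    fs <- rbind(nodeRow("mo", "F"), nodeRow("fa", "M"),
                nodeRow("son", "M", "mo", "fa", 1),
                nodeRow("dau", "F", "mo", "fa", 1))
    ek <- expectedKinship(fs, ids = fs$id)
    lookup <- function(i, j)
        ek[pairKey(ek$id1, ek$id2) == pairKey(i, j), ]
    expect_equal(lookup("mo", "son")$phiX, 0.5)
    expect_equal(lookup("fa", "son")$phiX, 0)
    expect_equal(lookup("fa", "dau")$phiX, 0.5)
    expect_equal(lookup("mo", "dau")$phiX, 0.25)
    expect_equal(lookup("son", "dau")$phiX, 0.25)
    expect_equal(lookup("mo", "son")$phi, 0.25)
})

test_that("residence regimes separate kinship by sex as expected", {
    simM <- simulateRegime(regimeConfig("matrilocal", generations = 6,
                                        replicates = 15, seed = 31))
    fdiff <- simM$features[, "mean_k_FF"] - simM$features[, "mean_k_MM"]
    expect_gt(mean(fdiff > 0, na.rm = TRUE), 0.9)
    simP <- simulateRegime(regimeConfig("patrilocal", generations = 6,
                                        replicates = 15, seed = 32))
    pdiff <- simP$features[, "mean_k_MM"] - simP$features[, "mean_k_FF"]
    expect_gt(mean(pdiff > 0, na.rm = TRUE), 0.9)
    # mixed residence shows no consistent sex bias
    simX <- simulateRegime(regimeConfig("mixed", generations = 6,
                                        replicates = 30, seed = 33))
    xfrac <- mean(simX$features[, "mean_k_FF"] >
                  simX$features[, "mean_k_MM"], na.rm = TRUE)
    expect_gt(xfrac, 0.2); expect_lt(xfrac, 0.8)
    # matrilocal communities carry elevated X relative to autosomal kinship
    expect_gt(mean(simM$features[, "x_auto_ratio"], na.rm = TRUE),
              mean(simP$features[, "x_auto_ratio"], na.rm = TRUE))
})

test_that("the regime classifier is symmetric and validates its inputs", {
    simM <- simulateRegime(regimeConfig("matrilocal", generations = 5,
                                        replicates = 10, seed = 41))
    ref <- list(matrilocal = simM$features, patrilocal = simM$features,
                mixed = simM$features)
    expect_error(classifyRegime(data.frame(), ref), "empty")
    expect_error(classifyRegime(NULL, ref), "empty")
    expect_error(
        classifyRegime(data.frame(sex1 = "F", sex2 = "F", kinship = 0.1),
                       ref[c("matrilocal", "mixed")]),
        "patrilocal")
    # sex-label swap maps matrilocal scores onto patrilocal scores exactly
    swapSex <- function(m) {
        sw <- m
        sw[, "mean_k_FF"] <- m[, "mean_k_MM"]
        sw[, "mean_k_MM"] <- m[, "mean_k_FF"]
        sw[, "frac_unrel_F"] <- m[, "frac_unrel_M"]
        sw[, "frac_unrel_M"] <- m[, "frac_unrel_F"]
        sw
    }
    obs <- data.frame(sex1 = c("F", "F", "M", "F"),
                      sex2 = c("F", "M", "M", "F"),
                      kinship = c(0.2, 0.05, 0.01, 0.1))
    refSym <- list(matrilocal = simM$features,
                   patrilocal = swapSex(simM$features),
                   mixed = (simM$features + swapSex(simM$features)) / 2)
    obsSwap <- obs
    obsSwap$sex1 <- chartr("FM", "MF", obs$sex1)
    obsSwap$sex2 <- chartr("FM", "MF", obs$sex2)
    a <- classifyRegime(obs, refSym)
    b <- classifyRegime(obsSwap, refSym)
    expect_equal(unname(a$scores["matrilocal"]),
                 unname(b$scores["patrilocal"]))
    expect_equal(unname(a$scores["mixed"]), unname(b$scores["mixed"]))
    expect_equal(sum(a$scores), 1)
})

test_that("the classifier recovers the generating regime on fresh draws", {
    refs <- list(
        matrilocal = simulateRegime(regimeConfig("matrilocal",
            generations = 6, replicates = 12, seed = 51)),
        patrilocal = simulateRegime(regimeConfig("patrilocal",
            generations = 6, replicates = 12, seed = 52)),
        mixed = simulateRegime(regimeConfig("mixed",
            generations = 6, replicates = 12, seed = 53)))
    hits <- 0; total <- 0
    for (rg in names(refs)) for (trial in 1:4) {
        obs <- simulateRegime(regimeConfig(rg, generations = 6,
            replicates = 1, seed = 600 + 10 * trial + match(rg, names(refs))))
        o <- data.frame(sex1 = substr(obs$pairs$sex_pair, 1, 1),
                        sex2 = substr(obs$pairs$sex_pair, 2, 2),
                        kinship = obs$pairs$phi, x_kinship = obs$pairs$phiX)
        cls <- classifyRegime(o, refs)
        hits <- hits + (cls$top == rg)
        total <- total + 1
    }
    expect_gte(hits / total, 0.75)
})
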
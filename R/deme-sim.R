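#' Configure the deme migration simulator
#'
#' Defaults: 10 demes of 25 females and 25 males, 50 non-overlapping
#' generations, 100 replicates, all demes and individuals sampled, founders
#' all carrying distinct haplotypes.
#'
#' @param nDemes,femalesPerDeme,malesPerDeme Deme structure.
#' @param mF,mM Per-generation migration probabilities by sex.
#' @param generations,replicates Run length and replicate count.
#' @param sampleSize Individuals sampled per deme for diversity
#'   (NA = everyone).
#' @param sampledDemes Demes sampled per replicate (default all).
#' @param seed Integer seed.
#' @return A [DemeConfig-class].
#' @export
demeConfig <- function(nDemes = 10L, femalesPerDeme = 25L, malesPerDeme = 25L,
                       mF = 0, mM = 0, generations = 50L, replicates = 100L,
                       sampleSize = NA_integer_, sampledDemes = nDemes,
                       seed = 1L) {
    new("DemeConfig", nDemes = as.integer(nDemes),
        femalesPerDeme = as.integer(femalesPerDeme),
        malesPerDeme = as.integer(malesPerDeme), mF = mF, mM = mM,
        generations = as.integer(generations),
        replicates = as.integer(replicates),
        sampleSize = as.integer(sampleSize),
        sampledDemes = as.integer(sampledDemes), seed = as.integer(seed))
}

#' Simulate sex-specific migration between demes
#'
#' Island model: each generation, females migrate with probability `mF` and
#' males with probability `mM` to a uniformly chosen other deme; individuals
#' then pair monogamously at random within demes and offspring replace the
#' parents at fixed deme sizes. mtDNA haplotypes are transmitted maternally
#' (to both sexes), Y haplotypes paternally. After the final generation,
#' haplotype diversity is computed per sampled deme with
#' [haplotypeDiversity()]. A replicate in which any deme loses one sex
#' entirely is flagged and resampled.
#'
#' @param config A [DemeConfig-class].
#' @return data.frame with columns `replicate`, `deme`, `h_mt`, `h_y`, `n`,
#'   `n_males`; the number of resampled replicates is attached as attribute
#'   `"resampled"`.
#' @export
simulateDemes <- function(config) {
    withSeed(config@seed, {
        out <- vector("list", config@replicates)
        resampled <- 0L
        for (r in seq_len(config@replicates)) {
            rep <- NULL
            for (try in 1:1000) {
                rep <- cpp_deme_replicate(config@nDemes, config@femalesPerDeme,
                                          config@malesPerDeme, config@mF,
                                          config@mM, config@generations)
                if (rep$ok) break
                resampled <- resampled + 1L
            }
            if (!rep$ok)
                stop(simFailure("demes repeatedly emptied of one sex"))
            nF <- config@femalesPerDeme; nM <- config@malesPerDeme
            demes <- if (config@sampledDemes >= config@nDemes)
                seq_len(config@nDemes) else
                sort(sample(config@nDemes, config@sampledDemes))
            rows <- lapply(demes, function(d) {
                fi <- (d - 1L) * nF + seq_len(nF)
                mi <- (d - 1L) * nM + seq_len(nM)
                mt <- c(rep$mtF[fi], rep$mtM[mi])
                isM <- c(rep(FALSE, nF), rep(TRUE, nM))
                y <- rep$yM[mi]
                if (!is.na(config@sampleSize) &&
                    config@sampleSize < length(mt)) {
                    pick <- sample(length(mt), config@sampleSize)
                    y <- y[match(intersect(which(isM), pick), which(isM))]
                    mt <- mt[pick]
                    isM <- isM[pick]
                }
                data.frame(replicate = r, deme = d,
                    h_mt = if (length(mt) >= 2)
                        haplotypeDiversity(mt) else NA_real_,
                    h_y = if (length(y) >= 2)
                        haplotypeDiversity(y) else NA_real_,
                    n = length(mt), n_males = length(y))
            })
            out[[r]] <- do.call(rbind, rows)
        }
        res <- do.call(rbind, out)
        rownames(res) <- NULL
        attr(res, "resampled") <- resampled
        res
    })
}

#' Rejection inference of sex-specific migration rates
#'
#' Runs the deme simulator over a grid of (female rate, male rate) cells and
#' accepts every cell whose central simulated envelopes (at `coverage`) of
#' mean mitochondrial and Y diversity both contain the observed values. The
#' marginal accepted intervals summarise the region. An empty acceptance
#' region is reported explicitly (NA intervals), not raised as an error.
#'
#' @param observedHmt,observedHy Observed diversities, both in `[0, 1]`.
#' @param config A [DemeConfig-class] template (its `mF`/`mM` are ignored;
#'   per-cell seeds are derived deterministically from its seed).
#' @param grid Numeric vector of migration rates forming the grid for both
#'   sexes (default `seq(0, 1, by = 0.05)`).
#' @param coverage Central envelope coverage (default 0.95); `1` accepts
#'   whenever the observed value is inside the simulated range.
#' @param tolerance Additive widening of every envelope before acceptance
#'   (same units as `h`); `Inf` accepts every cell.
#' @return An [AcceptanceRegion-class].
#' @export
inferMigration <- function(observedHmt, observedHy, config = demeConfig(),
                           grid = seq(0, 1, by = 0.05), coverage = 0.95,
                           tolerance = 0) {
    if (any(c(observedHmt, observedHy) < 0 | c(observedHmt, observedHy) > 1))
        stop("observed diversities must lie in [0, 1]")
    cells <- expand.grid(mF = grid, mM = grid)
    env <- vector("list", nrow(cells))
    alpha <- (1 - coverage) / 2
    for (i in seq_len(nrow(cells))) {
        cfg <- config
        cfg@mF <- cells$mF[i]
        cfg@mM <- cells$mM[i]
        cfg@seed <- config@seed + 13L * i
        sim <- simulateDemes(cfg)
        repMeans <- do.call(rbind, lapply(split(sim, sim$replicate), function(d)
            data.frame(h_mt = mean(d$h_mt, na.rm = TRUE),
                       h_y = mean(d$h_y, na.rm = TRUE))))
        qs <- function(x) unname(quantile(x, c(alpha, 1 - alpha), na.rm = TRUE))
        qm <- qs(repMeans$h_mt); qy <- qs(repMeans$h_y)
        env[[i]] <- data.frame(hMtLo = qm[1], hMtHi = qm[2],
                               hYLo = qy[1], hYHi = qy[2])
    }
    gridDf <- cbind(cells, do.call(rbind, env))
    gridDf$accepted <- observedHmt >= gridDf$hMtLo - tolerance &
        observedHmt <= gridDf$hMtHi + tolerance &
        observedHy >= gridDf$hYLo - tolerance &
        observedHy <= gridDf$hYHi + tolerance
    gridDf$accepted <- gridDf$accepted | is.infinite(tolerance)
    acc <- gridDf[gridDf$accepted, , drop = FALSE]
    iv <- function(x) if (nrow(acc)) range(x) else c(NA_real_, NA_real_)
    new("AcceptanceRegion", grid = gridDf,
        observed = c(h_mt = observedHmt, h_y = observedHy),
        coverage = coverage, mFInterval = iv(acc$mF), mMInterval = iv(acc$mM))
}

#' AcceptanceRegion accessors
#'
#' @param object An [AcceptanceRegion-class].
#' @return `acceptedCells()`: the accepted grid rows; `migrationIntervals()`:
#'   list with the marginal `mF` and `mM` accepted intervals (NA when empty).
#' @export
acceptedCells <- function(object) {
    object@grid[object@grid$accepted, , drop = FALSE]
}

#' @rdname acceptedCells
#' @export
migrationIntervals <- function(object) {
    list(mF = object@mFInterval, mM = object@mMInterval)
}

setMethod("show", "AcceptanceRegion", function(object) {
    nAcc <- sum(object@grid$accepted)
    cat("AcceptanceRegion:", nAcc, "of", nrow(object@grid),
        "grid cells accepted at", object@coverage, "coverage\n")
    if (nAcc) {
        cat("  female rate in [", paste(object@mFInterval, collapse = ", "),
            "]\n  male rate in [", paste(object@mMInterval, collapse = ", "),
            "]\n")
    } else cat("  acceptance region is empty\n")
})
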
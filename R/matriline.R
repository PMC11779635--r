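#' Dominant-matriline summary
#'
#' Haplotype labels carry subclade structure as dot suffixes (`"mt1"`,
#' `"mt1.2"`, `"mt1.2.1"` ...): `rootLabel()` strips the suffixes. The report
#' identifies the modal root label (ties broken lexicographically), its
#' frequency among the supplied individuals, and the number of distinct
#' de novo derivative labels of the dominant root that are present.
#'
#' @param labels Character vector of haplotype labels (NAs dropped).
#' @return list with `dominant`, `frequency`, `n`, `n_dominant`,
#'   `subclades` (distinct derivative labels) and `k` (their count).
#' @examples
#' matrilineReport(c("A", "A.1", "A.2", "A.1", "B"))
#' @export
matrilineReport <- function(labels) {
    labels <- labels[!is.na(labels)]
    if (length(labels) == 0L) stop("no haplotype labels supplied")
    roots <- rootLabel(labels)
    tab <- table(roots)
    dominant <- sort(names(tab)[tab == max(tab)])[1]
    inDom <- roots == dominant
    subclades <- sort(unique(labels[inDom & labels != dominant]))
    list(dominant = dominant,
         frequency = mean(inDom),
         n = length(labels),
         n_dominant = sum(inDom),
         subclades = subclades,
         k = length(subclades))
}

#' Minimum female births behind a dominant matriline
#'
#' Given `k` de novo mutations observed within a matriline, a per-site
#' per-generation mutation rate `mu` and a molecule length `L` (defaults:
#' the whole mitochondrial genome, 16,569 bp, at 4.72e-7 mutations per site
#' per generation), returns the smallest number of female births `N` to
#' lineage mothers such that the probability of at least `k` mutations,
#' `P(X >= k)` with `X ~ Poisson(N * mu * L)`, reaches `confidence`. The
#' default confidence 0.5 gives the median-consistent lower bound; the
#' estimate is non-decreasing in `k` and `confidence` and non-increasing in
#' `mu` and `L`. A Monte-Carlo backend cross-checks the Poisson tail by
#' simulation.
#'
#' @param k Observed de novo mutation count (>= 0).
#' @param mu Mutation rate per site per generation.
#' @param L Molecule length in bp (`mu * L` must be < 1).
#' @param confidence Required tail probability, in (0, 1).
#' @param method `"analytic"` (Poisson tail) or `"monte-carlo"`.
#' @param nSim Simulations per tail evaluation for the Monte-Carlo backend.
#' @param seed Seed for the Monte-Carlo backend.
#' @return Integer: the minimum number of female births.
#' @examples
#' minMatrilineBirths(k = 4)  # whole-mtDNA defaults
#' @export
minMatrilineBirths <- function(k, mu = 4.72e-7, L = 16569, confidence = 0.5,
                               method = c("analytic", "monte-carlo"),
                               nSim = 20000L, seed = NULL) {
    method <- match.arg(method)
    if (length(confidence) != 1L || is.na(confidence) ||
        confidence <= 0 || confidence >= 1)
        stop("confidence must be strictly inside (0, 1)")
    if (k < 0 || k != round(k)) stop("k must be a non-negative integer")
    rate <- mu * L
    if (rate <= 0 || rate >= 1)
        stop("mu * L must lie in (0, 1): one expected mutation per birth is unphysical")
    if (k == 0L) return(0L)
    tailProb <- function(N) {
        lambda <- N * rate
        if (method == "analytic")
            stats::ppois(k - 1, lambda, lower.tail = FALSE)
        else mean(stats::rpois(nSim, lambda) >= k)
    }
    run <- function() {
        hi <- 1L
        while (tailProb(hi) < confidence) {
            hi <- hi * 2L
            if (hi > .Machine$integer.max / 2) stop("search did not converge")
        }
        lo <- 0L
        while (hi - lo > 1L) {
            mid <- (lo + hi) %/% 2L
            if (tailProb(mid) >= confidence) hi <- mid else lo <- mid
        }
        hi
    }
    if (method == "monte-carlo") withSeed(seed, run()) else run()
}
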
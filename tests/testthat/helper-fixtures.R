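# Shared fixtures: hand-built pedigrees with closed-form kinship, a small
# genome for fast gene drops, and planted-partition graphs.

tinyGenome <- function() genomeModel(c(chr1 = 150, chr2 = 120), xCm = 80)

midGenome <- function() genomeModel(c(chr1 = 250, chr2 = 200, chr3 = 150,
                                      chr4 = 120), xCm = 120)

nodeRow <- function(id, sex, mother = NA_character_, father = NA_character_,
                    gen = 0L, resident = TRUE, mt = "m", y = NULL) {
    data.frame(id = id, sex = sex, mother = mother, father = father,
               generation = as.integer(gen), resident = resident,
               mt_label = mt,
               y_label = if (!is.null(y)) y else
                   if (sex == "M") "Y" else NA_character_,
               origin = "fixture", stringsAsFactors = FALSE)
}

# Canonical relationships with closed-form autosomal kinship coefficients.
canonicalRelationships <- function() {
    f <- nodeRow
    base <- rbind(f("gm", "F"), f("gf", "M"))
    list(
        PO = list(phi = 1 / 4, pair = c("gm", "c"),
            nodes = rbind(base, f("c", "F", "gm", "gf", 1))),
        FS = list(phi = 1 / 4, pair = c("c1", "c2"),
            nodes = rbind(base, f("c1", "F", "gm", "gf", 1),
                          f("c2", "M", "gm", "gf", 1))),
        HS = list(phi = 1 / 8, pair = c("c1", "c2"),
            nodes = rbind(base, f("gf2", "M"),
                          f("c1", "F", "gm", "gf", 1),
                          f("c2", "M", "gm", "gf2", 1))),
        GP = list(phi = 1 / 8, pair = c("gm", "c"),
            nodes = rbind(base, f("fa", "M"),
                          f("mo", "F", "gm", "gf", 1),
                          f("c", "M", "mo", "fa", 2))),
        AV = list(phi = 1 / 8, pair = c("un", "c"),
            nodes = rbind(base, f("fa", "M"),
                          f("mo", "F", "gm", "gf", 1),
                          f("un", "M", "gm", "gf", 1),
                          f("c", "F", "mo", "fa", 2))),
        C1 = list(phi = 1 / 16, pair = c("a", "b"),
            nodes = rbind(base, f("fa1", "M"), f("fa2", "M"),
                          f("mo1", "F", "gm", "gf", 1),
                          f("mo2", "F", "gm", "gf", 1),
                          f("a", "F", "mo1", "fa1", 2),
                          f("b", "M", "mo2", "fa2", 2))),
        GGP = list(phi = 1 / 16, pair = c("gm", "d"),
            nodes = rbind(base, f("fa", "M"), f("fa2", "M"),
                          f("mo", "F", "gm", "gf", 1),
                          f("c", "F", "mo", "fa", 2),
                          f("d", "M", "c", "fa2", 3))),
        HAV = list(phi = 1 / 16, pair = c("un", "c"),
            nodes = rbind(base, f("gf2", "M"), f("fa", "M"),
                          f("mo", "F", "gm", "gf", 1),
                          f("un", "M", "gm", "gf2", 1),
                          f("c", "F", "mo", "fa", 2))),
        C1R = list(phi = 1 / 32, pair = c("a", "d"),
            nodes = rbind(base, f("fa1", "M"), f("fa2", "M"), f("sp", "M"),
                          f("mo1", "F", "gm", "gf", 1),
                          f("mo2", "F", "gm", "gf", 1),
                          f("a", "F", "mo1", "fa1", 2),
                          f("b", "F", "mo2", "fa2", 2),
                          f("d", "M", "b", "sp", 3))),
        C2 = list(phi = 1 / 64, pair = c("a2", "b2"),
            nodes = rbind(base, f("fa1", "M"), f("fa2", "M"),
                          f("sp1", "M"), f("sp2", "M"),
                          f("mo1", "F", "gm", "gf", 1),
                          f("mo2", "F", "gm", "gf", 1),
                          f("a", "F", "mo1", "fa1", 2),
                          f("b", "F", "mo2", "fa2", 2),
                          f("a2", "F", "a", "sp1", 3),
                          f("b2", "M", "b", "sp2", 3))))
}

# Complete weighted graph with planted blocks; within-block edges ~`within`,
# between-block ~`between` (both jittered).
plantedGraph <- function(blocks, within = 10, between = 1, seed = 1) {
    withr::with_seed(seed, {
        sites <- unlist(mapply(function(b, i) paste0("B", i, "x", seq_len(b)),
                               blocks, seq_along(blocks), SIMPLIFY = FALSE))
        memb <- rep(seq_along(blocks), blocks)
        g <- igraph::make_full_graph(length(sites), directed = FALSE)
        igraph::V(g)$name <- sites
        e <- igraph::as_edgelist(g)
        same <- memb[match(e[, 1], sites)] == memb[match(e[, 2], sites)]
        igraph::E(g)$weight <- ifelse(same,
            within * runif(nrow(e), 0.8, 1.2),
            between * runif(nrow(e), 0.8, 1.2))
        list(graph = g, membership = setNames(memb, sites))
    })
}

# Brute-force discordant-pair fraction (the h oracle).
bruteForceH <- function(labels) {
    pairs <- utils::combn(length(labels), 2)
    mean(labels[pairs[1, ]] != labels[pairs[2, ]])
}

# All count partitions of n (label multisets up to relabelling).
countPartitions <- function(n, maxPart = n) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (k in seq_len(min(n, maxPart))) {
        for (rest in countPartitions(n - k, k))
            out[[length(out) + 1L]] <- c(k, rest)
    }
    out
}

# Two-sided Fisher exact oracle by hypergeometric enumeration.
fisherOracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Closed-form Welch two-sided t-test oracle.
welchOracle <- function(x, y) {
    v1 <- var(x) / length(x); v2 <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    list(t = t, p = 2 * stats::pt(-abs(t), df))
}
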
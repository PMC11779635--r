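#' Configure the residence-regime pedigree simulator
#'
#' @param residence `"matrilocal"`, `"patrilocal"` or `"mixed"`.
#' @param generations Total pedigree generations including the founders
#'   (default 7).
#' @param replicates Number of replicate communities.
#' @param offspringMean Poisson mean of offspring per couple.
#' @param stayProb Burial probability for non-inheriting-sex children.
#' @param seed Integer seed.
#' @return A [RegimeConfig-class].
#' @export
regimeConfig <- function(residence = c("matrilocal", "patrilocal", "mixed"),
                         generations = 7L, replicates = 100L,
                         offspringMean = 2.5, stayProb = 0.5, seed = 1L) {
    new("RegimeConfig", residence = match.arg(residence),
        generations = as.integer(generations),
        replicates = as.integer(replicates), offspringMean = offspringMean,
        stayProb = stayProb, seed = as.integer(seed))
}

#' Simulate kinship-coefficient distributions under a residence regime
#'
#' For each replicate, builds a community pedigree of the configured depth
#' with [generatePedigree()], computes expected autosomal and X kinship
#' coefficients for all resident pairs by path counting
#' ([expectedKinship()]), and realizes kinship by a single gene drop through
#' the pedigree. Pairs are stratified by sex combination.
#'
#' @param config A [RegimeConfig-class].
#' @param model A [GenomeModel-class] for the gene drop.
#' @return list of class `"regimeSim"` with elements `pairs` (per-replicate
#'   pair table: `replicate`, `id1`, `id2`, `sex_pair`, `phi_exp`,
#'   `phiX_exp`, `phi`, `f1`, `f2`, `phiX`), `features` (replicate x feature
#'   summary matrix, see [kinshipFeatures()]) and `residence`.
#' @export
simulateRegime <- function(config, model = defaultGenomeModel()) {
    out <- vector("list", config@replicates)
    for (r in seq_len(config@replicates)) {
        cfg <- simConfig(seed = config@seed + 17L * r,
                         depth = config@generations - 1L,
                         offspringMean = config@offspringMean,
                         residence = config@residence,
                         stayProb = config@stayProb)
        ped <- generatePedigree(cfg, retries = 200L)
        exp <- expectedKinship(ped)
        if (nrow(exp) == 0L) next
        rk <- realizedKinship(ped, exp[, c("id1", "id2")], model,
                              nReps = 1L, seed = ped@seed + 1L)
        out[[r]] <- data.frame(replicate = r, id1 = exp$id1, id2 = exp$id2,
            sex_pair = paste0(pmin(exp$sex1, exp$sex2),
                              pmax(exp$sex1, exp$sex2)),
            phi_exp = exp$phi, phiX_exp = exp$phiX,
            phi = rk$phi[1, ], f1 = rk$f1[1, ], f2 = rk$f2[1, ],
            phiX = rk$phiX[1, ], stringsAsFactors = FALSE, row.names = NULL)
    }
    pairs <- do.call(rbind, out)
    feats <- do.call(rbind, lapply(split(pairs, pairs$replicate), function(d)
        kinshipFeatures(data.frame(sex1 = substr(d$sex_pair, 1, 1),
                                   sex2 = substr(d$sex_pair, 2, 2),
                                   kinship = d$phi, x_kinship = d$phiX))))
    structure(list(pairs = pairs, features = feats,
                   residence = config@residence, config = config),
              class = "regimeSim")
}

#' Summary-statistic vector of a pairwise kinship table
#'
#' Features used to compare observed communities against simulated residence
#' regimes: mean kinship within female-female, male-male and female-male
#' pairs; the fraction of pairs involving a female (male) that are unrelated
#' (below the degree-7 kinship bin edge); and the ratio of mean X kinship to
#' mean autosomal kinship.
#'
#' @param pairTable data.frame with `sex1`, `sex2`, `kinship` and optionally
#'   `x_kinship`.
#' @return Named numeric vector of 6 features.
#' @export
kinshipFeatures <- function(pairTable) {
    sp <- paste0(pmin(pairTable$sex1, pairTable$sex2),
                 pmax(pairTable$sex1, pairTable$sex2))
    mk <- function(tag) {
        x <- pairTable$kinship[sp == tag]
        if (length(x)) mean(x) else NA_real_
    }
    unrel <- is.na(kinshipDegree(pairTable$kinship))
    fu <- function(sex) {
        inv <- pairTable$sex1 == sex | pairTable$sex2 == sex
        if (any(inv)) mean(unrel[inv]) else NA_real_
    }
    xk <- if ("x_kinship" %in% names(pairTable)) pairTable$x_kinship else NULL
    ratio <- if (!is.null(xk) && mean(pairTable$kinship) > 0)
        mean(xk, na.rm = TRUE) / mean(pairTable$kinship) else NA_real_
    c(mean_k_FF = mk("FF"), mean_k_MM = mk("MM"), mean_k_FM = mk("FM"),
      frac_unrel_F = fu("F"), frac_unrel_M = fu("M"), x_auto_ratio = ratio)
}

#' Build an observed pairwise kinship table from IBD-derived pairs
#'
#' Joins sexes onto the pair table from [mergeAndClassify()] and converts the
#' reported X sharing into an X kinship coefficient using the haplotype
#' counts implied by sex (males hemizygous).
#'
#' @param pairs Output of [mergeAndClassify()].
#' @param metadata Metadata with `id` and `sex`.
#' @param model Genome model (X length).
#' @param ids Optional panel ids; unrelated pairs absent from `pairs` are
#'   added with kinship 0 so fractions of unrelated pairs are meaningful.
#' @return data.frame with `id1`, `id2`, `sex1`, `sex2`, `kinship`,
#'   `x_kinship`.
#' @export
observedKinshipTable <- function(pairs, metadata,
                                 model = defaultGenomeModel(), ids = NULL) {
    sex <- setNames(metadata$sex, metadata$id)
    tab <- pairs[, c("id1", "id2", "kinship", "x_cm")]
    if (!is.null(ids) && length(ids) >= 2L) {
        cmb <- utils::combn(sort(ids), 2L)
        key <- pairKey(tab$id1, tab$id2)
        allKey <- pairKey(cmb[1, ], cmb[2, ])
        miss <- !(allKey %in% key)
        if (any(miss))
            tab <- rbind(tab, data.frame(id1 = cmb[1, miss],
                id2 = cmb[2, miss], kinship = 0, x_cm = 0))
    }
    tab$sex1 <- unname(sex[tab$id1])
    tab$sex2 <- unname(sex[tab$id2])
    nHap <- function(s) ifelse(s == "M", 1L, 2L)
    tab$x_kinship <- tab$x_cm /
        (nHap(tab$sex1) * nHap(tab$sex2) * xLength(model))
    tab[, c("id1", "id2", "sex1", "sex2", "kinship", "x_kinship")]
}

#' Score an observed community against simulated residence regimes
#'
#' Computes the [kinshipFeatures()] vector of the observed pair table and
#' scores each regime by a diagonal-Gaussian log-likelihood of those features
#' under the regime's simulated feature distribution (per-regime means and
#' standard deviations, with a small variance floor). Scores are the
#' normalized likelihoods and sum to 1; the reported distances are the
#' per-regime root-mean-square standardized residuals.
#'
#' @param observed Pair table as from [observedKinshipTable()] (at least one
#'   pair required).
#' @param reference Named list of `"regimeSim"` objects (or feature
#'   matrices), one per regime; all of `matrilocal`, `patrilocal` and
#'   `mixed` must be present.
#' @return list with `scores` (named, sums to 1), `distances`, `features`
#'   and `top` (the best-scoring regime).
#' @export
classifyRegime <- function(observed,
                           reference) {
    need <- c("matrilocal", "patrilocal", "mixed")
    if (!all(need %in% names(reference)))
        stop("reference must contain regimes: ",
             paste(setdiff(need, names(reference)), collapse = ", "))
    if (is.null(observed) || nrow(observed) == 0L)
        stop("observed pair table is empty")
    featMat <- lapply(reference[need], function(x)
        if (inherits(x, "regimeSim")) x$features else as.matrix(x))
    obs <- kinshipFeatures(observed)
    useCols <- names(obs)[!is.na(obs)]
    useCols <- Filter(function(cn)
        all(vapply(featMat, function(m) cn %in% colnames(m) &&
                       any(!is.na(m[, cn])), logical(1))), useCols)
    if (length(useCols) == 0L) stop("no comparable features available")
    # variance floor keeps near-constant features from dominating
    floorSd <- vapply(useCols, function(cn) {
        s <- sd(unlist(lapply(featMat, function(m) m[, cn])), na.rm = TRUE)
        if (is.na(s) || s == 0) 1 else 0.05 * s
    }, numeric(1))
    stats <- lapply(featMat, function(m) {
        x <- m[, useCols, drop = FALSE]
        mu <- colMeans(x, na.rm = TRUE)
        sg <- apply(x, 2, sd, na.rm = TRUE)
        sg[is.na(sg) | sg == 0] <- 1
        sg <- pmax(sg, floorSd)
        # shrink the sample covariance halfway towards its diagonal so small
        # reference sets stay well-conditioned
        cx <- sweep(x, 2, mu)
        cx[is.na(cx)] <- 0
        S <- crossprod(cx) / max(1, nrow(x) - 1)
        diag(S) <- pmax(diag(S), sg^2)
        S <- 0.5 * S + 0.5 * diag(diag(S), length(sg))
        list(mu = mu, sd = sg, Sinv = solve(S),
             logdet = determinant(S, logarithm = TRUE)$modulus[1])
    })
    z <- lapply(stats, function(s) (obs[useCols] - s$mu) / s$sd)
    loglik <- vapply(stats, function(s) {
        d <- obs[useCols] - s$mu
        -0.5 * drop(t(d) %*% s$Sinv %*% d) - 0.5 * s$logdet
    }, numeric(1))
    names(loglik) <- names(stats)
    dists <- vapply(z, function(x) sqrt(mean(x^2)), numeric(1))
    w <- exp(loglik - max(loglik))
    scores <- w / sum(w)
    list(scores = scores, distances = dists, features = obs,
         top = names(scores)[which.max(scores)])
}
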
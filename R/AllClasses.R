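#' @import methods
#' @importFrom stats rpois runif quantile sd cor var median setNames complete.cases coef
#' @importFrom utils read.table write.table read.csv write.csv head packageVersion
#' @useDynLib matrikin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Genetic map used for gene dropping and IBD arithmetic
#'
#' A `GenomeModel` holds an ordered autosomal genetic map (one length in
#' centimorgans per chromosome), the genetic length of the X chromosome and a
#' constant bp-per-cM scale used when physical coordinates have to be
#' synthesised or converted back to genetic lengths. Crossovers are modelled as
#' a Poisson count with mean `length/100` per transmission and uniform
#' positions (no interference). The X recombines only through females and is
#' never transmitted father to son.
#'
#' @slot autosomes Named numeric vector of autosomal lengths in cM.
#' @slot xCm Genetic length of the X chromosome in cM.
#' @slot bpPerCm Physical scale used for synthetic bp coordinates.
#' @export
setClass("GenomeModel",
    representation(autosomes = "numeric", xCm = "numeric", bpPerCm = "numeric"))

setValidity("GenomeModel", function(object) {
    msg <- NULL
    if (length(object@autosomes) < 1L || any(object@autosomes <= 0))
        msg <- c(msg, "autosome lengths must be positive")
    if (is.null(names(object@autosomes)) || anyDuplicated(names(object@autosomes)))
        msg <- c(msg, "autosomes must have unique names")
    if (length(object@xCm) != 1L || object@xCm <= 0)
        msg <- c(msg, "xCm must be a single positive length")
    if (length(object@bpPerCm) != 1L || object@bpPerCm <= 0)
        msg <- c(msg, "bpPerCm must be a single positive scale")
    if (is.null(msg)) TRUE else msg
})

#' Configuration of the pedigree/community simulator
#'
#' Parameterises [generatePedigree()]: pedigree depth, offspring distribution,
#' post-marital residence rule, the de novo mtDNA labelling rate per
#' transmission and the founder haplotype scheme. The same seed always yields
#' a bit-identical pedigree.
#'
#' @slot seed Integer seed governing all stochastic draws.
#' @slot depth Number of descendant generations below the founders (>= 1).
#' @slot offspringMean Mean of the Poisson offspring-count distribution.
#' @slot residence One of `"matrilocal"`, `"patrilocal"`, `"mixed"`.
#' @slot mtMutationRate Probability of a de novo mtDNA label per transmission.
#' @slot founderScheme `"all-distinct"` (every founder/immigrant gets a fresh
#'   label) or `"frequency"` (labels drawn from `founderFreqs`).
#' @slot founderFreqs Named numeric label frequencies (frequency scheme only).
#' @slot founderCouples Number of founding couples in generation 0.
#' @slot stayProb Probability that a child of the non-inheriting sex is buried
#'   at the natal site (resident without local offspring).
#' @export
setClass("SimConfig",
    representation(seed = "integer", depth = "integer", offspringMean = "numeric",
        residence = "character", mtMutationRate = "numeric",
        founderScheme = "character", founderFreqs = "numeric",
        founderCouples = "integer", stayProb = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
    if (object@offspringMean <= 0) msg <- c(msg, "offspringMean must be > 0")
    if (!object@residence %in% c("matrilocal", "patrilocal", "mixed"))
        msg <- c(msg, "residence must be matrilocal, patrilocal or mixed")
    if (object@mtMutationRate < 0 || object@mtMutationRate > 1)
        msg <- c(msg, "mtMutationRate must be in [0, 1]")
    if (!object@founderScheme %in% c("all-distinct", "frequency"))
        msg <- c(msg, "founderScheme must be all-distinct or frequency")
    if (object@founderScheme == "frequency" &&
        (length(object@founderFreqs) == 0 || any(object@founderFreqs < 0)))
        msg <- c(msg, "frequency scheme needs non-negative founderFreqs")
    if (object@founderCouples < 1L) msg <- c(msg, "founderCouples must be >= 1")
    if (object@stayProb < 0 || object@stayProb > 1)
        msg <- c(msg, "stayProb must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' A simulated community pedigree
#'
#' Container for the node table produced by [generatePedigree()]. Each row is
#' one individual with sex, parent identifiers (NA for founders and immigrant
#' spouses), generation index, residence flag (member of the burial community),
#' a strictly matrilineal mtDNA label and, for males, a strictly patrilineal
#' Y label. De novo mtDNA labels extend the maternal label with a dot suffix so
#' subclades remain reconstructible from the label string.
#'
#' @slot nodes data.frame with columns `id`, `sex`, `mother`, `father`,
#'   `generation`, `resident`, `mt_label`, `y_label`, `origin`.
#' @slot residence Residence rule the community practised.
#' @slot seed Seed used to generate it.
#' @export
setClass("Pedigree",
    representation(nodes = "data.frame", residence = "character", seed = "integer"))

setValidity("Pedigree", function(object) {
    nd <- object@nodes
    need <- c("id", "sex", "mother", "father", "generation", "resident",
              "mt_label", "y_label", "origin")
    if (!all(need %in% names(nd))) return("missing node columns")
    if (anyDuplicated(nd$id)) return("duplicate individual ids")
    rownames(nd) <- nd$id
    msg <- NULL
    has_m <- !is.na(nd$mother)
    has_f <- !is.na(nd$father)
    if (any(has_m != has_f)) msg <- c(msg, "non-founders need both parents")
    if (any(has_m)) {
        mo <- nd[nd$mother[has_m], ]
        fa <- nd[nd$father[has_m], ]
        if (any(mo$sex != "F") || any(fa$sex != "M"))
            msg <- c(msg, "mother must be female and father male")
        kid <- nd[has_m, ]
        if (any(kid$generation != 1L + pmax(mo$generation, fa$generation)))
            msg <- c(msg, "generation(child) must be 1 + max(parent generations)")
        okmt <- kid$mt_label == mo$mt_label |
            startsWith(kid$mt_label, paste0(mo$mt_label, "."))
        if (!all(okmt)) msg <- c(msg, "mt_label must derive from the mother's")
        sons <- kid$sex == "M"
        if (any(sons) && !all(kid$y_label[sons] == fa$y_label[sons]))
            msg <- c(msg, "sons must carry the father's y_label")
    }
    if (any(!is.na(nd$y_label) & nd$sex == "F"))
        msg <- c(msg, "females carry no y_label")
    if (is.null(msg)) TRUE else msg
})

#' Configuration of the sex-biased deme migration simulator
#'
#' Island model with `nDemes` demes of fixed size, discrete non-overlapping
#' generations, sex-specific per-generation migration probabilities and
#' monogamous within-deme mating. Mitochondrial labels follow mothers, Y labels
#' follow fathers; migration moves labels between demes but never creates them.
#'
#' @slot nDemes,femalesPerDeme,malesPerDeme Deme count and fixed sizes.
#' @slot mF,mM Per-generation migration probabilities for females and males.
#' @slot generations,replicates Run length and number of replicates.
#' @slot sampleSize Individuals sampled per deme for diversity (NA = all).
#' @slot sampledDemes Number of demes sampled per replicate.
#' @slot seed Integer seed.
#' @export
setClass("DemeConfig",
    representation(nDemes = "integer", femalesPerDeme = "integer",
        malesPerDeme = "integer", mF = "numeric", mM = "numeric",
        generations = "integer", replicates = "integer",
        sampleSize = "integer", sampledDemes = "integer", seed = "integer"))

setValidity("DemeConfig", function(object) {
    msg <- NULL
    if (object@mF < 0 || object@mF > 1 || object@mM < 0 || object@mM > 1)
        msg <- c(msg, "migration probabilities must be in [0, 1]")
    for (s in c("nDemes", "femalesPerDeme", "malesPerDeme", "generations",
                "replicates", "sampledDemes"))
        if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be positive"))
    if (object@sampledDemes > object@nDemes)
        msg <- c(msg, "cannot sample more demes than exist")
    if (is.null(msg)) TRUE else msg
})

#' Configuration of the pedigree residence-regime simulator
#'
#' @slot residence One of `"matrilocal"`, `"patrilocal"`, `"mixed"`.
#' @slot generations Total pedigree generations including founders (default 7).
#' @slot replicates Number of replicate communities.
#' @slot offspringMean Poisson mean for offspring counts.
#' @slot stayProb Burial probability for non-inheriting-sex children.
#' @slot seed Integer seed.
#' @export
setClass("RegimeConfig",
    representation(residence = "character", generations = "integer",
        replicates = "integer", offspringMean = "numeric",
        stayProb = "numeric", seed = "integer"))

setValidity("RegimeConfig", function(object) {
    msg <- NULL
    if (!object@residence %in% c("matrilocal", "patrilocal", "mixed"))
        msg <- c(msg, "residence must be matrilocal, patrilocal or mixed")
    if (object@generations < 2L) msg <- c(msg, "generations must be >= 2")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Rejection-inference acceptance region over migration-rate grids
#'
#' Result of [inferMigration()]: for every grid cell (female rate, male rate)
#' the central simulated envelope of mitochondrial and Y haplotype diversity,
#' whether the observed pair falls inside both envelopes, and the marginal
#' accepted intervals for each rate.
#'
#' @slot grid data.frame with columns `mF`, `mM`, `hMtLo`, `hMtHi`, `hYLo`,
#'   `hYHi`, `accepted`.
#' @slot observed Observed `(h_mt, h_Y)` pair.
#' @slot coverage Central envelope coverage used for acceptance.
#' @slot mFInterval,mMInterval Marginal min/max of accepted rates (NA if the
#'   acceptance region is empty).
#' @export
setClass("AcceptanceRegion",
    representation(grid = "data.frame", observed = "numeric",
        coverage = "numeric", mFInterval = "numeric", mMInterval = "numeric"))

#' Consensus of repeated Leiden community detection
#'
#' Holds the per-run memberships of repeated seeded Leiden runs on a weighted
#' site graph, the co-assignment matrix (fraction of runs placing two sites in
#' the same community), the consensus partition obtained by thresholding the
#' co-assignment graph at 0.5, and a maximum clade-credibility consensus tree
#' over the per-run hierarchical partitions.
#'
#' @slot memberships Integer matrix, sites x runs.
#' @slot coassignment Numeric matrix of co-assignment fractions (0 to 1),
#'   sites x sites, unit diagonal.
#' @slot consensus data.frame with columns `site`, `cluster`.
#' @slot treeNewick Newick string of the consensus tree with clade supports.
#' @slot runTrees Character vector of per-run partition trees (newick).
#' @slot resolution Resolution parameter used.
#' @slot seeds Integer seeds, one per run.
#' @export
setClass("ConsensusClustering",
    representation(memberships = "matrix", coassignment = "matrix",
        consensus = "data.frame", treeNewick = "character",
        runTrees = "character", resolution = "numeric", seeds = "integer"))

setValidity("ConsensusClustering", function(object) {
    co <- object@coassignment
    msg <- NULL
    if (nrow(co) != ncol(co)) msg <- c(msg, "coassignment must be square")
    if (nrow(co) > 0) {
        if (any(abs(diag(co) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
        if (any(co < -1e-12 | co > 1 + 1e-12)) msg <- c(msg, "entries must be in [0, 1]")
        if (any(abs(co - t(co)) > 1e-12)) msg <- c(msg, "matrix must be symmetric")
    }
    if (is.null(msg)) TRUE else msg
})
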
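#' Construct a simulator configuration
#'
#' Defaults describe a single founding couple whose community practises
#' matrilocality for six descendant generations (seven generations in total),
#' Poisson(2.5) offspring counts under monogamy, and a whole-molecule mtDNA
#' de novo labelling rate of 16,569 x 4.72e-7 per transmission, so subclade
#' labels accumulate at the empirical mitochondrial rate.
#'
#' @param seed Integer seed; identical seeds give bit-identical pedigrees.
#' @param depth Descendant generations below the founders (>= 1).
#' @param offspringMean Poisson mean of offspring per couple.
#' @param residence `"matrilocal"`, `"patrilocal"` or `"mixed"`.
#' @param mtMutationRate De novo mtDNA label probability per transmission.
#' @param founderScheme `"all-distinct"` or `"frequency"`.
#' @param founderFreqs Named label frequencies for the frequency scheme.
#' @param founderCouples Founding couples in generation 0.
#' @param stayProb Probability a child of the non-inheriting sex stays
#'   (is buried) in the community without reproducing locally.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, depth = 3)
#' ped <- generatePedigree(cfg)
#' @export
simConfig <- function(seed = 1L, depth = 6L, offspringMean = 2.5,
                      residence = c("matrilocal", "patrilocal", "mixed"),
                      mtMutationRate = 16569 * 4.72e-7,
                      founderScheme = c("all-distinct", "frequency"),
                      founderFreqs = numeric(0), founderCouples = 1L,
                      stayProb = 0.5) {
    new("SimConfig", seed = as.integer(seed), depth = as.integer(depth),
        offspringMean = offspringMean, residence = match.arg(residence),
        mtMutationRate = mtMutationRate,
        founderScheme = match.arg(founderScheme), founderFreqs = founderFreqs,
        founderCouples = as.integer(founderCouples), stayProb = stayProb)
}

#' Simulate a community pedigree under a residence rule
#'
#' Builds a pedigree of the configured depth by gene-alogical forward
#' simulation. Under matrilocality daughters remain resident and marry
#' in-migrating unrelated men (who become resident community members);
#' sons disperse, staying in the burial community with probability
#' `stayProb` but founding no local family. Under patrilocality the sex
#' roles are swapped; under mixed residence each child remains resident
#' with probability 0.5 and resident children of either sex marry
#' in-migrating spouses. mtDNA labels follow mothers (with de novo dot-suffix
#' derivatives at the configured rate) and Y labels follow fathers.
#'
#' @param config A [SimConfig-class].
#' @param retries Number of fresh attempts (with incremented seeds) when all
#'   lineages die out before the requested depth; `0` signals the failure.
#' @return A [Pedigree-class] object.
#' @seealso [dropGenomes()], [emitIBDTable()], [makeSiteFixture()]
#' @export
generatePedigree <- function(config, retries = 0L) {
    for (attempt in 0:retries) {
        ped <- tryCatch(
            withSeed(config@seed + attempt, buildPedigree(config)),
            matrikin_extinction = function(e) e)
        if (!inherits(ped, "condition"))
            return(new("Pedigree", nodes = ped, residence = config@residence,
                       seed = as.integer(config@seed + attempt)))
    }
    stop(simFailure(sprintf(
        "all lineages extinct before depth %d (after %d attempt(s)); retry with a new seed",
        config@depth, retries + 1L), class = "matrikin_extinction"))
}

# Forward-simulates the node table. RNG state is managed by the caller.
buildPedigree <- function(config) {
    counters <- new.env(parent = emptyenv())
    counters$ind <- 0L; counters$mt <- 0L; counters$y <- 0L
    counters$sub <- list()
    nextId <- function() {
        counters$ind <- counters$ind + 1L
        sprintf("I%03d", counters$ind)
    }
    freshMt <- function() {
        if (config@founderScheme == "frequency") {
            p <- config@founderFreqs / sum(config@founderFreqs)
            sample(names(p), 1L, prob = p)
        } else {
            counters$mt <- counters$mt + 1L
            paste0("mt", counters$mt)
        }
    }
    freshY <- function() {
        counters$y <- counters$y + 1L
        paste0("Y", counters$y)
    }
    transmitMt <- function(label) {
        if (runif(1) < config@mtMutationRate) {
            k <- counters$sub[[label]]
            k <- if (is.null(k)) 1L else k + 1L
            counters$sub[[label]] <- k
            paste0(label, ".", k)
        } else label
    }

    rows <- list()
    addNode <- function(id, sex, mother, father, gen, resident, mt, y, origin) {
        rows[[length(rows) + 1L]] <<- data.frame(
            id = id, sex = sex, mother = mother, father = father,
            generation = as.integer(gen), resident = resident,
            mt_label = mt, y_label = y, origin = origin,
            stringsAsFactors = FALSE)
    }

    couples <- list()
    for (k in seq_len(config@founderCouples)) {
        w <- nextId(); m <- nextId()
        addNode(w, "F", NA_character_, NA_character_, 0L, TRUE,
                freshMt(), NA_character_, "founder")
        addNode(m, "M", NA_character_, NA_character_, 0L, TRUE,
                freshMt(), freshY(), "founder")
        couples[[length(couples) + 1L]] <- list(mother = w, father = m)
    }
    lookup <- new.env(parent = emptyenv())
    for (r in rows) assign(r$id, r, envir = lookup)
    addNode2 <- function(...) {
        addNode(...)
        r <- rows[[length(rows)]]
        assign(r$id, r, envir = lookup)
    }

    inheritSex <- switch(config@residence, matrilocal = "F", patrilocal = "M",
                         mixed = NA_character_)

    for (g in seq_len(config@depth)) {
        newCouples <- list()
        for (cp in couples) {
            mo <- get(cp$mother, envir = lookup)
            fa <- get(cp$father, envir = lookup)
            n <- rpois(1L, config@offspringMean)
            if (n == 0L) next
            for (j in seq_len(n)) {
                sex <- if (runif(1) < 0.5) "F" else "M"
                mt <- transmitMt(mo$mt_label)
                y <- if (sex == "M") fa$y_label else NA_character_
                id <- nextId()
                stays <- if (is.na(inheritSex)) runif(1) < 0.5
                         else if (sex == inheritSex) TRUE
                         else runif(1) < config@stayProb
                reproduces <- g < config@depth && stays &&
                    (is.na(inheritSex) || sex == inheritSex)
                addNode2(id, sex, mo$id, fa$id, g, stays, mt, y, "descendant")
                if (reproduces) {
                    sp <- nextId()
                    spSex <- if (sex == "F") "M" else "F"
                    addNode2(sp, spSex, NA_character_, NA_character_, g, TRUE,
                             freshMt(),
                             if (spSex == "M") freshY() else NA_character_,
                             "immigrant")
                    newCouples[[length(newCouples) + 1L]] <-
                        if (sex == "F") list(mother = id, father = sp)
                        else list(mother = sp, father = id)
                }
            }
        }
        if (g < config@depth && length(newCouples) == 0L)
            stop(simFailure("lineage extinct", class = "matrikin_extinction"))
        couples <- newCouples
    }
    do.call(rbind, rows)
}

#' Pedigree accessors
#'
#' @param object A [Pedigree-class].
#' @return `pedNodes()` returns the node data.frame; `residents()` the ids of
#'   burial-community members; `founderIds()` the ids without parents.
#' @export
pedNodes <- function(object) object@nodes

#' @rdname pedNodes
#' @export
residents <- function(object) object@nodes$id[object@nodes$resident]

#' @rdname pedNodes
#' @export
founderIds <- function(object) object@nodes$id[is.na(object@nodes$mother)]

setMethod("show", "Pedigree", function(object) {
    nd <- object@nodes
    cat("Pedigree:", nrow(nd), "individuals,",
        max(nd$generation) + 1L, "generations,", sum(nd$resident),
        "resident;", object@residence, "residence (seed", paste0(object@seed, ")\n"))
})
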
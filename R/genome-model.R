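#' Construct a genome model
#'
#' @param autosomes Named numeric vector of autosomal genetic lengths (cM).
#' @param xCm Genetic length of the X chromosome in cM.
#' @param bpPerCm Physical bp per cM used for synthetic coordinates
#'   (default 1e6, i.e. a uniform 1 cM/Mb map).
#' @return A [GenomeModel-class] object.
#' @examples
#' gm <- genomeModel(c(chr1 = 100, chr2 = 80), xCm = 50)
#' totalAutosomalCm(gm)
#' @export
genomeModel <- function(autosomes, xCm = 180, bpPerCm = 1e6) {
    if (is.null(names(autosomes)))
        names(autosomes) <- paste0("chr", seq_along(autosomes))
    new("GenomeModel", autosomes = autosomes, xCm = as.numeric(xCm),
        bpPerCm = as.numeric(bpPerCm))
}

#' Default human-scale genome model
#'
#' Twenty-two autosomes with sex-averaged genetic lengths totalling
#' approximately 3,545 cM and an X chromosome of 180 cM. Interference is not
#' modelled; crossover counts are Poisson at 1 per 100 cM per transmission.
#'
#' @return A [GenomeModel-class] object.
#' @export
defaultGenomeModel <- function() {
    lens <- c(286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0, 166.4,
              181.0, 158.2, 174.7, 125.9, 120.8, 141.9, 134.0, 128.5, 117.2,
              107.3, 108.3, 62.8, 74.1)
    names(lens) <- as.character(1:22)
    genomeModel(lens, xCm = 180, bpPerCm = 1e6)
}

#' @describeIn genomeModel Autosomal lengths in cM (named vector).
#' @param object A `GenomeModel`.
#' @export
autosomeLengths <- function(object) object@autosomes

#' @describeIn genomeModel Genetic length of the X in cM.
#' @export
xLength <- function(object) object@xCm

#' @describeIn genomeModel Total autosomal map length in cM.
#' @export
totalAutosomalCm <- function(object) sum(object@autosomes)

setMethod("show", "GenomeModel", function(object) {
    cat("GenomeModel:", length(object@autosomes), "autosomes,",
        format(sum(object@autosomes), digits = 6), "cM total; X =",
        object@xCm, "cM;", object@bpPerCm, "bp/cM\n")
})
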
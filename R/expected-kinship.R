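#' Expected kinship coefficients by path counting
#'
#' Recursive computation of autosomal and X-chromosome kinship coefficients
#' on a pedigree. Founders are unrelated and non-inbred. For the X, males are
#' hemizygous: a male contributes his single X allele with probability 1, so
#' e.g. mother-son X kinship is 1/2 and father-son X kinship is 0.
#'
#' @param pedigree A [Pedigree-class] or node data.frame.
#' @param ids Individuals to include (default: residents for a `Pedigree`,
#'   all rows otherwise).
#' @return data.frame with one row per unordered pair: `id1`, `id2`, `phi`
#'   (autosomal kinship), `phiX` (X kinship), `sex1`, `sex2`.
#' @examples
#' ped <- generatePedigree(simConfig(seed = 2, depth = 2), retries = 20)
#' head(expectedKinship(ped))
#' @export
expectedKinship <- function(pedigree, ids = NULL) {
    nd <- if (is(pedigree, "Pedigree")) pedNodes(pedigree) else pedigree
    if (is.null(ids))
        ids <- if (is(pedigree, "Pedigree")) residents(pedigree) else nd$id
    rownames(nd) <- nd$id
    gen <- setNames(nd$generation, nd$id)
    mo <- setNames(nd$mother, nd$id)
    fa <- setNames(nd$father, nd$id)
    male <- setNames(nd$sex == "M", nd$id)
    cacheA <- new.env(parent = emptyenv())
    cacheX <- new.env(parent = emptyenv())

    phiA <- function(i, j) {
        k <- paste(min(i, j), max(i, j))
        got <- get0(k, envir = cacheA)
        if (!is.null(got)) return(got)
        v <- if (i == j) {
            if (is.na(mo[[i]])) 0.5 else 0.5 * (1 + phiA(mo[[i]], fa[[i]]))
        } else {
            c1 <- if (gen[[i]] > gen[[j]]) i
                  else if (gen[[j]] > gen[[i]]) j
                  else if (!is.na(mo[[i]])) i else j
            c2 <- if (c1 == i) j else i
            if (is.na(mo[[c1]])) 0
            else 0.5 * (phiA(mo[[c1]], c2) + phiA(fa[[c1]], c2))
        }
        assign(k, v, envir = cacheA)
        v
    }
    phiX <- function(i, j) {
        k <- paste(min(i, j), max(i, j))
        got <- get0(k, envir = cacheX)
        if (!is.null(got)) return(got)
        v <- if (i == j) {
            if (male[[i]]) 1
            else if (is.na(mo[[i]])) 0.5
            else 0.5 * (1 + phiX(mo[[i]], fa[[i]]))
        } else {
            c1 <- if (gen[[i]] > gen[[j]]) i
                  else if (gen[[j]] > gen[[i]]) j
                  else if (!is.na(mo[[i]])) i else j
            c2 <- if (c1 == i) j else i
            if (is.na(mo[[c1]])) 0
            else if (male[[c1]]) phiX(mo[[c1]], c2)
            else 0.5 * (phiX(mo[[c1]], c2) + phiX(fa[[c1]], c2))
        }
        assign(k, v, envir = cacheX)
        v
    }
    ids <- sort(ids)
    if (length(ids) < 2L)
        return(data.frame(id1 = character(), id2 = character(),
                          phi = numeric(), phiX = numeric(),
                          sex1 = character(), sex2 = character(),
                          stringsAsFactors = FALSE))
    cmb <- utils::combn(ids, 2L)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
               phi = mapply(phiA, cmb[1, ], cmb[2, ]),
               phiX = mapply(phiX, cmb[1, ], cmb[2, ]),
               sex1 = ifelse(male[cmb[1, ]], "M", "F"),
               sex2 = ifelse(male[cmb[2, ]], "M", "F"),
               stringsAsFactors = FALSE, row.names = NULL)
}
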
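#' Read and write refinedIBD-style segment tables
#'
#' The dialect is headerless tab-delimited text with nine columns: `sample1`,
#' `hap1`, `sample2`, `hap2`, `chrom`, `start_bp`, `end_bp`, `lod`,
#' `length_cm`. Coordinates are half-open. Malformed rows (wrong column
#' count, non-numeric coordinates, non-positive genetic length) raise an
#' error naming the offending line.
#'
#' @param path File to read or write.
#' @return `readIBD()` returns a typed data.frame of segment records (empty
#'   files give a zero-row table); `writeIBD()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".ibd")
#' ped <- generatePedigree(simConfig(seed = 5, depth = 2), retries = 20)
#' gm <- genomeModel(c(chr1 = 150), xCm = 60)
#' ibd <- emitIBDTable(dropGenomes(ped, gm, seed = 2), gm, minCm = 1)
#' writeIBD(ibd, tf)
#' nrow(readIBD(tf)) == nrow(ibd)
#' @export
readIBD <- function(path) {
    cols <- c("sample1", "hap1", "sample2", "hap2", "chrom", "start_bp",
              "end_bp", "lod", "length_cm")
    if (!file.exists(path))
        stop(formatError(paste("IBD file not found:", path)))
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw))]
    empty <- data.frame(sample1 = character(), hap1 = integer(),
                        sample2 = character(), hap2 = integer(),
                        chrom = character(), start_bp = numeric(),
                        end_bp = numeric(), lod = numeric(),
                        length_cm = numeric(), stringsAsFactors = FALSE)
    if (length(raw) == 0L) return(empty)
    parts <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 9L))
        stop(formatError(sprintf("line %d: expected 9 tab-separated fields, found %d",
                                 which(nf != 9L)[1], nf[nf != 9L][1])))
    m <- do.call(rbind, parts)
    out <- data.frame(sample1 = m[, 1], hap1 = suppressWarnings(as.integer(m[, 2])),
                      sample2 = m[, 3], hap2 = suppressWarnings(as.integer(m[, 4])),
                      chrom = m[, 5],
                      start_bp = suppressWarnings(as.numeric(m[, 6])),
                      end_bp = suppressWarnings(as.numeric(m[, 7])),
                      lod = suppressWarnings(as.numeric(m[, 8])),
                      length_cm = suppressWarnings(as.numeric(m[, 9])),
                      stringsAsFactors = FALSE)
    bad <- !complete.cases(out[c("hap1", "hap2", "start_bp", "end_bp", "length_cm")])
    if (any(bad))
        stop(formatError(sprintf("line %d: non-numeric coordinate fields", which(bad)[1])))
    if (any(out$length_cm <= 0))
        stop(formatError(sprintf("line %d: non-positive genetic length",
                                 which(out$length_cm <= 0)[1])))
    if (any(out$end_bp <= out$start_bp))
        stop(formatError(sprintf("line %d: end_bp must exceed start_bp",
                                 which(out$end_bp <= out$start_bp)[1])))
    names(out) <- cols
    out
}

#' @rdname readIBD
#' @param ibd data.frame of IBD records as produced by [emitIBDTable()].
#' @export
writeIBD <- function(ibd, path) {
    write.table(ibd, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read and write per-individual metadata
#'
#' Metadata is a CSV with one row per sampled individual and columns `id`,
#' `site`, `sex`, `mt_label`, `y_label`, `coverage`, `period`. Missing
#' optional columns are tolerated by downstream analyses where documented.
#'
#' @param path CSV file.
#' @return `readMetadata()` returns a data.frame; `writeMetadata()` returns
#'   `path` invisibly.
#' @export
readMetadata <- function(path) {
    if (!file.exists(path))
        stop(formatError(paste("metadata file not found:", path)))
    md <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "site")
    if (!all(need %in% names(md)))
        stop(formatError(paste("metadata must contain columns:",
                               paste(need, collapse = ", "))))
    if (anyDuplicated(md$id))
        stop(formatError("duplicate individual ids in metadata"))
    md
}

#' @rdname readMetadata
#' @param metadata data.frame of individual metadata.
#' @export
writeMetadata <- function(metadata, path) {
    write.csv(metadata, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
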
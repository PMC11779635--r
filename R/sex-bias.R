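#' Sex-bias tests on relatedness and matriline membership
#'
#' Two tests of male-biased dispersal within a burial community: a two-sided
#' Welch t-test comparing degree-weighted relatedness scores between males
#' and females, and a two-sided Fisher exact test on the 2x2 table of sex
#' against membership of the dominant matriline (root mtDNA label). A
#' stratum with fewer than two scored individuals of either sex skips the
#' corresponding test with a reason instead of erroring.
#'
#' @param scores Output of [weightedRelatedness()].
#' @param metadata Metadata with `id`, `sex` and (for the Fisher test)
#'   `mt_label`.
#' @param dominantLabel Root mtDNA label of the dominant matriline; defaults
#'   to the modal root label in `metadata`.
#' @return list with elements `welch` (`statistic`, `p`, `meanF`, `meanM`,
#'   `skipped`, `reason`), `fisher` (`p`, `table`, `odds_ratio`, `skipped`,
#'   `reason`) and `dominant_label`.
#' @export
sexBiasTests <- function(scores, metadata, dominantLabel = NULL) {
    m <- merge(scores, metadata[, intersect(c("id", "sex", "mt_label"),
                                            names(metadata)), drop = FALSE],
               by = "id")
    welch <- list(statistic = NA_real_, p = NA_real_, meanF = NA_real_,
                  meanM = NA_real_, skipped = TRUE, reason = "")
    if (!"sex" %in% names(m) || !all(c("F", "M") %in% m$sex) ||
        min(table(factor(m$sex, c("F", "M")))) < 2L) {
        welch$reason <- "need at least two scored individuals of each sex"
    } else {
        sf <- m$score[m$sex == "F"]; sm <- m$score[m$sex == "M"]
        welch$meanF <- mean(sf); welch$meanM <- mean(sm)
        if (sd(sf) == 0 && sd(sm) == 0 && mean(sf) == mean(sm)) {
            welch$statistic <- 0; welch$p <- 1; welch$skipped <- FALSE
        } else {
            tt <- stats::t.test(sf, sm, alternative = "two.sided",
                                var.equal = FALSE)
            welch$statistic <- unname(tt$statistic)
            welch$p <- tt$p.value
            welch$skipped <- FALSE
        }
    }
    fisher <- list(p = NA_real_, table = NULL, odds_ratio = NA_real_,
                   skipped = TRUE, reason = "")
    if (!"mt_label" %in% names(m) || !"sex" %in% names(m)) {
        fisher$reason <- "metadata lacks sex or mt_label"
    } else {
        mm <- m[!is.na(m$mt_label) & !is.na(m$sex), , drop = FALSE]
        if (is.null(dominantLabel))
            dominantLabel <- matrilineReport(mm$mt_label)$dominant
        if (nrow(mm) == 0L || length(unique(mm$sex)) < 2L) {
            fisher$reason <- "empty sex stratum"
        } else {
            tab <- table(factor(mm$sex, c("F", "M")),
                         factor(rootLabel(mm$mt_label) == dominantLabel,
                                c(TRUE, FALSE),
                                labels = c("dominant", "other")))
            ft <- stats::fisher.test(tab, alternative = "two.sided")
            fisher$p <- ft$p.value
            fisher$table <- tab
            fisher$odds_ratio <- unname(ft$estimate)
            fisher$skipped <- FALSE
        }
    }
    list(welch = welch, fisher = fisher, dominant_label = dominantLabel)
}
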
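#' Default origin grouping map
#'
#' The shipped merge map for sampling-origin labels used by the
#' heterogeneity test: the three Kazakh-origin labels are pooled into one
#' "Kazakh" group (they sample the same population under different names).
#' @return named character vector (original label -> group).
#' @export
defaultGroupingMap <- function() {
    readGroupingMap(system.file("extdata", "grouping_map.tsv",
                                package = "mtN1a", mustWork = TRUE))
}

#' Read a two-column origin grouping map
#' @param path TSV with columns origin, group.
#' @return named character vector.
#' @export
readGroupingMap <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("origin", "group") %in% names(d)))
        stop("grouping map must have columns origin, group")
    stats::setNames(d$group, d$origin)
}

#' @keywords internal
applyGrouping <- function(labels, groupingMap) {
    if (is.null(groupingMap)) return(labels)
    hit <- labels %in% names(groupingMap)
    labels[hit] <- groupingMap[labels[hit]]
    labels
}

#' Haplotype-by-origin contingency table for one clade
#'
#' Builds the distinct-haplotype x group contingency table entering the
#' heterogeneity test. Haplotype identity is the canonically formatted
#' HVS-I motif (HVS-II is ignored by default, so duplicate HVS-I motifs
#' with different HVS-II data merge); groups are the sampling-origin
#' labels after applying the grouping map.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param assignments result of \code{\link{classifyTable}} on
#'   \code{haps}.
#' @param clade clade whose records enter the table.
#' @param groupBy \code{"population"} or \code{"region"}.
#' @param groupingMap named character vector merging origin labels
#'   (default \code{\link{defaultGroupingMap}}); NULL for no merging.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @param tree optional \linkS4class{HaplogroupTree} to include descendant
#'   subclades of \code{clade}.
#' @param includeDescendants include records assigned to descendant
#'   subclades (needs \code{tree}).
#' @return integer matrix (haplotypes x groups).
#' @export
buildContingencyTable <- function(haps, assignments, clade,
                                  groupBy = c("population", "region"),
                                  groupingMap = defaultGroupingMap(),
                                  ref = rCRSAnnotation(), tree = NULL,
                                  includeDescendants = FALSE) {
    groupBy <- match.arg(groupBy)
    clades <- if (includeDescendants && !is.null(tree))
        descendantClades(tree, clade) else clade
    sel <- which(assignments$assigned %in% clades)
    if (!length(sel)) stop("no records assigned to clade ", clade)
    d <- haplotypes(haps)[sel, , drop = FALSE]
    key <- vapply(d$hvs1, motifKey, character(1), ref = ref)
    grp <- applyGrouping(assignments[[groupBy]][sel], groupingMap)
    tab <- stats::xtabs(n ~ key + grp,
                        data = data.frame(n = d$n, key = key, grp = grp))
    m <- matrix(as.integer(tab), base::nrow(tab), base::ncol(tab),
                dimnames = dimnames(tab))
    names(dimnames(m)) <- c("haplotype", "group")
    m
}

#' Pearson chi-square heterogeneity test
#'
#' Pearson chi-square with no continuity correction; the p value is the
#' upper tail of the chi-square distribution with
#' (rows - 1) x (cols - 1) degrees of freedom. Expected counts below 5
#' produce a small-count warning but never a refusal (sparse haplotype
#' tables are the normal case; the permutation check in the test suite
#' covers the well-behaved regime).
#'
#' @param tab contingency table (matrix, at least 2 x 2).
#' @return list with chi2, df, p, n (class \code{heterogeneityTest}).
#' @export
chiSquareHeterogeneity <- function(tab) {
    if (base::nrow(tab) < 2L || base::ncol(tab) < 2L)
        stop("heterogeneity test needs at least a 2 x 2 table")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 5))
        warning(sum(ct$expected < 5), " cell(s) with expected count < 5; ",
                "the chi-square approximation may be coarse")
    out <- list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                p = stats::pchisq(unname(ct$statistic),
                                  unname(ct$parameter),
                                  lower.tail = FALSE),
                n = sum(tab))
    class(out) <- "heterogeneityTest"
    out
}

#' @export
print.heterogeneityTest <- function(x, ...) {
    cat(sprintf(
        "Haplotype heterogeneity: n = %d; chi2 = %.3f; d.f. %d; p %s\n",
        x$n, x$chi2, x$df,
        if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p)))
    invisible(x)
}

#' Per-region clade frequency report
#'
#' The numeric table behind a frequency map: for every (clade, group)
#' combination the number of table rows, the weighted count (sum of N)
#' and the fraction of the clade total. Fractions within each clade sum
#' to 1.
#'
#' @param assignments result of \code{\link{classifyTable}}.
#' @param groupBy \code{"population"} or \code{"region"}.
#' @param groupingMap optional named character vector merging labels.
#' @return data.frame: clade, group, records, count, fraction.
#' @export
cladeFrequencyReport <- function(assignments,
                                 groupBy = c("population", "region"),
                                 groupingMap = NULL) {
    groupBy <- match.arg(groupBy)
    grp <- applyGrouping(assignments[[groupBy]], groupingMap)
    agg <- stats::aggregate(
        cbind(records = rep(1L, base::nrow(assignments)),
              count = assignments$n),
        by = list(clade = assignments$assigned, group = grp), FUN = sum)
    tot <- tapply(agg$count, agg$clade, sum)
    agg$fraction <- agg$count / as.numeric(tot[agg$clade])
    agg[order(agg$clade, agg$group), , drop = FALSE]
}
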
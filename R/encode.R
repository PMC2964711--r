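#' Binary-recode haplotypes for network construction
#'
#' Recodes a collection of mutation-call sets into the 0/1 matrix the
#' reduced median algorithm works on: one column per segregating binary
#' character keyed by (position, derived state), so a triallelic position
#' (e.g. 16147 with derived G and A) automatically splits into two binary
#' characters sharing the position tag. The reference state is 0. Constant
#' characters (carried by every haplotype) are removed and recorded in the
#' \code{"removedConstant"} attribute; duplicate haplotypes are collapsed
#' with their multiplicities summed. Calls at np 16519 and poly(C)-tract
#' indels never enter the matrix; a back-mutation call simply leaves the
#' character at 0.
#'
#' @param calls either a \linkS4class{HaplotypeSet} (HVS-I calls are
#'   encoded, plus HVS-II for records typed for it when
#'   \code{segments = c("HVS1","HVS2")}) or a named list of mutation-call
#'   data.frames (e.g. from \code{\link{callVariantsFasta}}).
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @param multiplicity per-haplotype counts; for a HaplotypeSet the table's
#'   N column is used.
#' @param segments for a HaplotypeSet, which segments to encode.
#' @param siteWeights optional named numeric, weights per site label
#'   (default 1).
#' @return a \linkS4class{BinaryMatrix}.
#' @export
encodeBinary <- function(calls, ref, multiplicity = NULL,
                         segments = "HVS1", siteWeights = NULL) {
    if (is(calls, "HaplotypeSet")) {
        d <- haplotypes(calls)
        lst <- lapply(seq_len(nrow(d)), function(i) {
            parts <- list()
            if ("HVS1" %in% segments) parts <- c(parts, list(d$hvs1[[i]]))
            if ("HVS2" %in% segments && !is.null(d$hvs2[[i]]))
                parts <- c(parts, list(d$hvs2[[i]]))
            do.call(rbind, parts)
        })
        names(lst) <- d$id
        if (is.null(multiplicity)) multiplicity <- d$n
        calls <- lst
    }
    if (is.null(multiplicity)) multiplicity <- rep(1, length(calls))
    if (is.null(names(calls)))
        names(calls) <- sprintf("T%03d", seq_along(calls))
    calls <- lapply(calls, function(x) {
        x <- dropExcludedCalls(x, ref)
        x[!x$back, , drop = FALSE]
    })
    allCalls <- do.call(rbind, c(calls, list(emptyCalls())))
    if (nrow(allCalls)) {
        siteTab <- unique(allCalls[, c("position", "ref", "event",
                                       "derived")])
        siteTab <- siteTab[order(siteTab$position, siteTab$derived), ,
                           drop = FALSE]
        lab <- siteLabel(siteTab)
        multi <- unique(siteTab$position[duplicated(siteTab$position)])
        if (length(multi))
            message("multi-allelic position(s) split into binary ",
                    "characters: ", paste(multi, collapse = ", "))
    } else {
        siteTab <- emptyCalls()[, c("position", "ref", "event", "derived")]
        lab <- character(0)
    }
    mat <- matrix(0L, nrow = length(calls), ncol = length(lab),
                  dimnames = list(names(calls), lab))
    for (i in seq_along(calls)) {
        cc <- calls[[i]]
        if (nrow(cc)) mat[i, siteLabel(cc)] <- 1L
    }
    # constant characters carry no information for the network
    if (ncol(mat)) {
        const <- colSums(mat) == nrow(mat)
        removed <- colnames(mat)[const]
        mat <- mat[, !const, drop = FALSE]
        siteTab <- siteTab[!const, , drop = FALSE]
        lab <- lab[!const]
    } else removed <- character(0)
    # collapse duplicate rows
    key <- apply(mat, 1L, paste, collapse = "")
    grp <- split(seq_along(key), key)
    ord <- order(vapply(grp, min, 1L))
    grp <- grp[ord]
    mat2 <- mat[vapply(grp, min, 1L), , drop = FALSE]
    taxa <- data.frame(
        key = vapply(grp, function(ix) names(calls)[min(ix)], character(1)),
        multiplicity = vapply(grp, function(ix) sum(multiplicity[ix]),
                              numeric(1)),
        stringsAsFactors = FALSE)
    taxa$ids <- lapply(grp, function(ix) names(calls)[ix])
    rownames(mat2) <- taxa$key
    w <- rep(1, length(lab))
    if (!is.null(siteWeights)) {
        hit <- lab %in% names(siteWeights)
        w[hit] <- siteWeights[lab[hit]]
    }
    sites <- data.frame(label = lab, position = siteTab$position,
                        derived = siteTab$derived, event = siteTab$event,
                        ref = siteTab$ref, weight = w,
                        stringsAsFactors = FALSE)
    rownames(sites) <- NULL
    bm <- new("BinaryMatrix", mat = mat2, taxa = taxa, sites = sites)
    attr(bm, "removedConstant") <- removed
    bm
}

# canonical site label, e.g. "16147G", "16223", "16193iC", "8281d"
#' @keywords internal
siteLabel <- function(calls) {
    vapply(seq_len(nrow(calls)), function(i) {
        p <- calls$position[i]
        switch(calls$event[i],
               transition = if (calls$derived[i] ==
                                transitionPartner(calls$ref[i]))
                   as.character(p) else paste0(p, calls$derived[i]),
               transversion = paste0(p, calls$derived[i]),
               deletion = paste0(p, "d"),
               insertion = paste0(p, "i", calls$derived[i]))
    }, character(1))
}

#' @describeIn encodeBinary number of distinct haplotypes.
#' @param x a \code{BinaryMatrix}.
#' @export
nHaplotypes <- function(x) base::nrow(x@mat)

#' @describeIn encodeBinary number of binary characters.
#' @export
nSites <- function(x) base::ncol(x@mat)

setMethod("show", "BinaryMatrix", function(object) {
    cat("BinaryMatrix:", base::nrow(object@mat), "distinct haplotypes (",
        sum(object@taxa$multiplicity), "individuals ) x",
        base::ncol(object@mat), "segregating binary characters\n")
})
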
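#' Classify mutations by functional class
#'
#' Assigns each mutation call to the class used by the molecular clocks:
#' \code{control} (outside the coding window), \code{indel},
#' \code{synonymous_transition} (a transition inside a protein-coding gene
#' leaving the encoded amino acid unchanged in every overlapping reading
#' frame), \code{nonsynonymous} (a protein-coding substitution changing
#' the protein in at least one frame), \code{rna} (within an rRNA or tRNA
#' gene only), or \code{other} (synonymous transversions, substitutions in
#' trailing partial codons, or coding-window positions in no annotated
#' feature; the last case is reported). Translation uses the vertebrate
#' mitochondrial genetic code; minus-strand genes are translated from the
#' reverse complement.
#'
#' @param calls mutation-call data.frame.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return character vector of classes, one per call.
#' @export
classifyMutation <- function(calls, ref) {
    vapply(seq_len(base::nrow(calls)), function(i) {
        classifyOne(calls$position[i], calls$event[i], calls$derived[i],
                    ref)
    }, character(1))
}

#' @keywords internal
mitoGeneticCode <- function() {
    Biostrings::getGeneticCode("SGC1")  # vertebrate mitochondrial
}

#' @keywords internal
classifyOne <- function(pos, event, derived, ref) {
    if (pos < ref@codingWindow[1] || pos > ref@codingWindow[2])
        return("control")
    if (event %in% c("insertion", "deletion")) return("indel")
    gm <- ref@geneMap
    hit <- gm[gm$start <= pos & gm$end >= pos, , drop = FALSE]
    if (!base::nrow(hit)) {
        message("position ", pos,
                " in no annotated feature; classified 'other'")
        return("other")
    }
    prot <- hit[hit$type == "protein", , drop = FALSE]
    if (!base::nrow(prot))
        return("rna")
    code <- mitoGeneticCode()
    synAll <- TRUE
    for (j in seq_len(base::nrow(prot))) {
        aa <- codonEffect(pos, derived, prot[j, ], ref, code)
        if (is.na(aa)) { synAll <- FALSE; break }   # partial codon
        if (!aa) { synAll <- FALSE; break }
    }
    if (synAll) {
        if (event == "transition") "synonymous_transition" else "other"
    } else "nonsynonymous"
}

# TRUE if the substitution is synonymous in this gene's frame, FALSE if
# not, NA if the position falls in a trailing partial codon.
#' @keywords internal
codonEffect <- function(pos, derived, gene, ref, code) {
    if (gene$strand == "+") {
        off <- pos - gene$start
        ci <- off %/% 3L
        c0 <- gene$start + 3L * ci
        if (c0 + 2L > gene$end) return(NA)
        codon <- refBase(ref, c0:(c0 + 2L))
        mut <- codon
        mut[off %% 3L + 1L] <- derived
    } else {
        off <- gene$end - pos
        ci <- off %/% 3L
        c0 <- gene$end - 3L * ci
        if (c0 - 2L < gene$start) return(NA)
        codon <- comp(refBase(ref, c0:(c0 - 2L)))
        mut <- codon
        mut[off %% 3L + 1L] <- comp(derived)
    }
    code[[paste(codon, collapse = "")]] == code[[paste(mut, collapse = "")]]
}

#' @keywords internal
comp <- function(base) chartr("ACGT", "TGCA", base)

#' Enumerate synonymous-transition sites
#'
#' All coding positions whose transition is synonymous in every
#' overlapping protein-coding frame: the legal site set of the synonymous
#' clock. The enumeration is exact (every coding position is translated)
#' and memoised on the reference object.
#'
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return integer vector of positions.
#' @export
synonymousTransitionSites <- function(ref) {
    if (!is.null(ref@cache$synSites)) return(ref@cache$synSites)
    gm <- ref@geneMap
    prot <- gm[gm$type == "protein", , drop = FALSE]
    cand <- sort(unique(unlist(lapply(seq_len(base::nrow(prot)),
                                      function(j)
        prot$start[j]:prot$end[j]))))
    code <- mitoGeneticCode()
    ok <- vapply(cand, function(pos) {
        derived <- transitionPartner(refBase(ref, pos))
        hit <- prot[prot$start <= pos & prot$end >= pos, , drop = FALSE]
        for (j in seq_len(base::nrow(hit))) {
            aa <- codonEffect(pos, derived, hit[j, ], ref, code)
            if (is.na(aa) || !aa) return(FALSE)
        }
        TRUE
    }, logical(1))
    ref@cache$synSites <- cand[ok]
    ref@cache$synSites
}

#' Mutation-class filters for the molecular clocks
#'
#' Returns a predicate over mutation-call data.frames selecting the calls
#' a clock counts: \code{"all_coding"} counts every base substitution in
#' the coding window (indels never count), \code{"synonymous_transition"}
#' counts synonymous transitions only, \code{"control"} counts
#' control-region substitutions. When the calls carry a precomputed
#' \code{class} column (simulator output) it is used directly.
#'
#' @param class one of \code{"all"}, \code{"all_coding"},
#'   \code{"synonymous_transition"}, \code{"control"}.
#' @param ref a \linkS4class{ReferenceAnnotation} (needed for
#'   \code{"synonymous_transition"} without precomputed classes).
#' @return function(calls) -> logical vector.
#' @export
classFilter <- function(class = c("all", "all_coding",
                                  "synonymous_transition", "control"),
                        ref = NULL) {
    class <- match.arg(class)
    force(ref)
    function(calls) {
        if (!base::nrow(calls)) return(logical(0))
        isSub <- !calls$event %in% c("insertion", "deletion")
        switch(class,
               all = rep(TRUE, base::nrow(calls)),
               all_coding = isSub &
                   calls$position >= ref@codingWindow[1] &
                   calls$position <= ref@codingWindow[2],
               control = isSub &
                   (calls$position < ref@codingWindow[1] |
                    calls$position > ref@codingWindow[2]),
               synonymous_transition = {
                   if ("class" %in% names(calls))
                       calls$class == "synonymous_transition"
                   else classifyMutation(calls, ref) ==
                       "synonymous_transition"
               })
    }
}
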
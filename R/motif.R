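#' Parse a mutation motif
#'
#' Parses the hyphen-separated mutation-motif nomenclature used for mtDNA
#' control-region haplotypes into a mutation-call data.frame. Tokens follow
#' the field's conventions: a bare number is a transition; a trailing base
#' is the derived base (a transversion when it is not the transition
#' partner of the reference base); a \code{d} suffix is a deletion;
#' \code{iX}/\code{+X} is an insertion of \code{X} after the position
#' (\code{iCC} inserts two Cs); an \code{@} prefix marks a back mutation
#' (reversion to the reference state). HVS-I tokens are written minus
#' 16000, so \code{147A} denotes np 16147.
#'
#' Parsing is literal: calls at excluded sites or inside poly(C) tracts are
#' retained so that formatting is the exact inverse (the exclusion rules
#' are applied by variant calling, encoding and simulation instead).
#'
#' @param motif character(1), e.g. \code{"147G-172-223-248"}; empty or NA
#'   gives an empty call set.
#' @param segment one of \code{"HVS1"}, \code{"HVS2"}, \code{"coding"};
#'   determines the +16000 offset (HVS1 only) and the admissible window.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return data.frame with columns \code{position}, \code{ref},
#'   \code{event}, \code{derived}, \code{back}, sorted by position.
#' @examples
#' ref <- rCRSAnnotation()
#' parseMotif("147G-172-223-248", "HVS1", ref)
#' @export
parseMotif <- function(motif, segment = c("HVS1", "HVS2", "coding"), ref) {
    segment <- match.arg(segment)
    if (is.null(motif) || is.na(motif) || !nzchar(trimws(motif)))
        return(emptyCalls())
    tokens <- strsplit(trimws(motif), "-", fixed = TRUE)[[1]]
    tokens <- tokens[nzchar(tokens)]
    m <- regmatches(tokens,
                    regexec("^(@?)([0-9]+)(d|i[ACGT]+|\\+[ACGT]+|[ACGT])?$",
                            tokens))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad))
        stop("cannot parse motif token(s): ",
             paste(tokens[bad], collapse = ", "))
    offset <- if (segment == "HVS1") 16000L else 0L
    window <- switch(segment, HVS1 = ref@hvs1Window, HVS2 = ref@hvs2Window,
                     coding = ref@codingWindow)
    rows <- lapply(m, function(g) {
        back <- g[2] == "@"
        pos <- as.integer(g[3]) + offset
        if (pos < window[1] || pos > window[2])
            stop("position ", pos, " outside the ", segment, " window [",
                 window[1], ", ", window[2], "]")
        rb <- refBase(ref, pos)
        suf <- g[4]
        if (suf == "") {
            event <- "transition"; derived <- transitionPartner(rb)
        } else if (suf == "d") {
            event <- "deletion"; derived <- ""
        } else if (startsWith(suf, "i") || startsWith(suf, "+")) {
            event <- "insertion"; derived <- substring(suf, 2L)
        } else {
            derived <- suf
            if (derived == rb)
                stop("token ", g[1], if (segment == "HVS1") " (np " else "",
                     if (segment == "HVS1") pos else "",
                     if (segment == "HVS1") ")" else "",
                     ": derived base equals the reference base")
            event <- if (derived == transitionPartner(rb)) "transition"
                     else "transversion"
        }
        data.frame(position = pos, ref = rb, event = event,
                   derived = derived, back = back, stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    calls[order(calls$position, calls$event == "insertion"), , drop = FALSE]
}

#' Format mutation calls as a motif
#'
#' The inverse of \code{\link{parseMotif}}: tokens are emitted sorted by
#' position, transitions as bare numbers, other substitutions with the
#' derived base, deletions with \code{d}, insertions with \code{i}, back
#' mutations with an \code{@} prefix; HVS-I positions are written minus
#' 16000.
#'
#' @param calls mutation-call data.frame.
#' @param segment one of \code{"HVS1"}, \code{"HVS2"}, \code{"coding"}.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return character(1) motif (empty string for no calls).
#' @export
formatMotif <- function(calls, segment = c("HVS1", "HVS2", "coding"), ref) {
    segment <- match.arg(segment)
    if (is.null(calls) || !nrow(calls)) return("")
    window <- switch(segment, HVS1 = ref@hvs1Window, HVS2 = ref@hvs2Window,
                     coding = ref@codingWindow)
    if (any(calls$position < window[1] | calls$position > window[2]))
        stop("call outside the ", segment, " window")
    calls <- calls[order(calls$position, calls$event == "insertion"), ,
                   drop = FALSE]
    offset <- if (segment == "HVS1") 16000L else 0L
    tok <- vapply(seq_len(nrow(calls)), function(i) {
        p <- calls$position[i] - offset
        core <- switch(calls$event[i],
                       transition = as.character(p),
                       transversion = paste0(p, calls$derived[i]),
                       deletion = paste0(p, "d"),
                       insertion = paste0(p, "i", calls$derived[i]),
                       stop("unknown event: ", calls$event[i]))
        # a non-partner derived base always carries its suffix, including
        # the rare case of an explicitly recorded non-partner "transition"
        if (calls$event[i] %in% c("transition", "transversion") &&
            calls$derived[i] != transitionPartner(calls$ref[i]) &&
            calls$event[i] == "transition")
            core <- paste0(p, calls$derived[i])
        if (calls$back[i]) paste0("@", core) else core
    }, character(1))
    paste(tok, collapse = "-")
}

#' Canonical motif key for haplotype identity
#'
#' Canonicalises a set of HVS-I calls into the formatted motif string used
#' as the haplotype identity key in frequency and heterogeneity tables.
#' @param calls mutation-call data.frame (HVS-I calls).
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return character(1).
#' @export
motifKey <- function(calls, ref) formatMotif(calls, "HVS1", ref)
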
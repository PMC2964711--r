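#' Call variants against the reference
#'
#' Aligns a complete (or near-complete) mitogenome to the reference with a
#' banded global aligner and reports the differences as mutation calls in
#' reference coordinates. Insertions and deletions are normalised to the 3'
#' end of homopolymer runs (the standard mtDNA nomenclature convention), so
#' calls are deterministic regardless of where the aligner placed the gap.
#' Calls at np 16519 and length variation inside the poly(C) tracts are
#' dropped.
#'
#' @param seq character(1) or \code{Biostrings::DNAString}; alphabet
#'   ACGTN, length within 50 nt of the reference.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @param band half-width of the alignment band; the default adapts to the
#'   length difference.
#' @return mutation-call data.frame (columns position, ref, event, derived,
#'   back).
#' @export
callVariants <- function(seq, ref, band = NULL) {
    if (is(seq, "DNAString") || is(seq, "DNAStringSet")) {
        if (is(seq, "DNAStringSet")) {
            if (length(seq) != 1L) stop("supply a single sequence")
            seq <- seq[[1]]
        }
        seq <- as.character(seq)
    }
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq))
        stop("sequence contains non-nucleotide characters")
    n <- nchar(ref@sequence)
    if (abs(nchar(seq) - n) > 50L)
        stop("sequence length ", nchar(seq), " too far from reference (",
             n, " +/- 50)")
    if (is.null(band))
        band <- max(32L, 2L * abs(nchar(seq) - n) + 16L)
    if (nchar(seq) == n) {
        # fast path: sparse positional mismatches mean no indels are in
        # play and the identity alignment is the optimal one
        a <- charToRaw(seq); b <- charToRaw(ref@sequence)
        mm <- which(a != b & a != charToRaw("N"))
        if (length(mm) <= 60L &&
            (length(mm) < 2L || min(diff(mm)) > 3L)) {
            qb <- strsplit(rawToChar(a[mm]), "")[[1]]
            calls <- if (length(mm)) {
                rb <- refBase(ref, mm)
                data.frame(position = mm, ref = rb,
                           event = ifelse(qb == transitionPartner(rb),
                                          "transition", "transversion"),
                           derived = qb, back = FALSE,
                           stringsAsFactors = FALSE)
            } else emptyCalls()
            calls <- dropExcludedCalls(calls, ref)
            return(calls[order(calls$position), , drop = FALSE])
        }
    }
    d <- .bandedAlignDiffs(seq, ref@sequence, as.integer(band))
    calls <- emptyCalls()
    if (length(d$type)) {
        ops <- data.frame(type = d$type, refpos = d$refpos, base = d$base,
                          stringsAsFactors = FALSE)
        sub <- ops[ops$type == 1L, , drop = FALSE]
        if (nrow(sub)) {
            rb <- refBase(ref, sub$refpos)
            calls <- rbind(calls, data.frame(
                position = sub$refpos, ref = rb,
                event = ifelse(sub$base == transitionPartner(rb),
                               "transition", "transversion"),
                derived = sub$base, back = FALSE, stringsAsFactors = FALSE))
        }
        calls <- rbind(calls, collapseIndels(ops, ref))
    }
    calls <- dropExcludedCalls(calls, ref)
    calls[order(calls$position, calls$event == "insertion"), , drop = FALSE]
}

# Merge per-base indel operations into runs, then right-shift each run to
# the 3' end of its homopolymer context.
#' @keywords internal
collapseIndels <- function(ops, ref) {
    out <- emptyCalls()
    seq <- ref@sequence
    n <- nchar(seq)
    for (ty in c(2L, 3L)) {
        o <- ops[ops$type == ty, , drop = FALSE]
        if (!nrow(o)) next
        # group consecutive operations (insertions share a refpos; deletions
        # occupy consecutive refpos)
        key <- if (ty == 2L) o$refpos else o$refpos - seq_len(nrow(o))
        for (g in split(o, key)) {
            motif <- paste(g$base, collapse = "")
            pos <- if (ty == 2L) g$refpos[1] else g$refpos[1]
            if (ty == 2L) {
                # insertion of `motif` after `pos`: shift right while the
                # following reference base equals the first motif base
                while (pos + 1L <= n &&
                       substring(seq, pos + 1L, pos + 1L) ==
                       substring(motif, 1L, 1L)) {
                    motif <- paste0(substring(motif, 2L),
                                    substring(motif, 1L, 1L))
                    pos <- pos + 1L
                }
                out <- rbind(out, data.frame(
                    position = pos, ref = refBase(ref, pos),
                    event = "insertion", derived = motif, back = FALSE,
                    stringsAsFactors = FALSE))
            } else {
                # deletion of reference run starting at pos: shift while the
                # base after the deleted run equals the first deleted base
                len <- nrow(g)
                while (pos + len <= n &&
                       substring(seq, pos + len, pos + len) ==
                       substring(seq, pos, pos)) {
                    pos <- pos + 1L
                }
                out <- rbind(out, data.frame(
                    position = pos:(pos + len - 1L),
                    ref = refBase(ref, pos:(pos + len - 1L)),
                    event = "deletion", derived = "", back = FALSE,
                    stringsAsFactors = FALSE))
            }
        }
    }
    out
}

#' Call variants for every record of a FASTA file
#' @param path FASTA file of mitogenomes.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return named list of mutation-call data.frames.
#' @export
callVariantsFasta <- function(path, ref) {
    if (!file.exists(path)) stop("input file not found: ", path)
    seqs <- Biostrings::readDNAStringSet(path)
    out <- lapply(seq_along(seqs),
                  function(i) callVariants(as.character(seqs[[i]]), ref))
    names(out) <- names(seqs)
    out
}
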
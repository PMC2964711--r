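#' Deterministic synthetic reference sequence
#'
#' Generates the 16,569-nt synthetic stand-in for the revised Cambridge
#' reference sequence that ships with the package
#' (\code{inst/extdata/rcrs_synthetic.fa}). The sequence is drawn from a
#' small multiplicative congruential generator (independent of R's RNG
#' state) with mtDNA-like base composition, with a handful of bases pinned
#' so that the explicit-base motif tokens occurring in the packaged
#' haplotype table (147G/147A, 114A, 183C, 187A and HVS-II 185C) are
#' transversions relative to the reference, as they are in the real
#' coordinate system. Coordinates, windows and the gene map are the real
#' ones; only the base sequence is synthetic.
#'
#' @param length sequence length; the mitochondrial genome length.
#' @return character(1) upper-case sequence.
#' @export
syntheticReferenceSequence <- function(length = 16569L) {
    x <- 48271
    m <- 2147483647
    vals <- numeric(length)
    for (i in seq_len(length)) {
        x <- (48271 * x) %% m
        vals[i] <- x / m
    }
    # mtDNA-like composition: A .31, C .31, G .13, T .25
    bases <- c("A", "C", "G", "T")[findInterval(vals, c(0.31, 0.62, 0.75)) + 1L]
    pin <- c(`16147` = "C", `16114` = "C", `16183` = "A", `16187` = "C",
             `185` = "G")
    bases[as.integer(names(pin))] <- pin
    paste(bases, collapse = "")
}

#' Load the reference annotation
#'
#' Builds the \linkS4class{ReferenceAnnotation} all other operations use.
#' With no arguments, the packaged synthetic reference sequence and the
#' standard human mitochondrial gene map are loaded, HVS-I is 16024-16569
#' (motifs written minus 16000), HVS-II is 1-576, the coding region is
#' 577-16023, np 16519 is excluded and the HVS-I/HVS-II poly(C) tracts are
#' 16180-16195 and 303-315. The control-region windows deliberately cover
#' the full control region: published motif tables contain tokens such as
#' 463 (np 16463) and HVS-II 41 that fall outside the narrower classical
#' sequencing windows.
#'
#' @param fasta path to a reference FASTA (single record); default the
#'   packaged synthetic reference.
#' @param geneMap path to a tab-separated gene map with columns
#'   gene/start/end/strand/type; default the packaged standard map.
#' @param hvs1Window,hvs2Window,codingWindow integer(2) coordinate ranges.
#' @param excludedSites positions never scored; 16519 is always added.
#' @param polyCTracts two-column matrix of tract ranges.
#' @return a \linkS4class{ReferenceAnnotation}.
#' @export
rCRSAnnotation <- function(fasta = NULL, geneMap = NULL,
                           hvs1Window = c(16024L, 16569L),
                           hvs2Window = c(1L, 576L),
                           codingWindow = c(577L, 16023L),
                           excludedSites = integer(0),
                           polyCTracts = rbind(c(16180L, 16195L),
                                               c(303L, 315L))) {
    if (is.null(fasta))
        fasta <- system.file("extdata", "rcrs_synthetic.fa", package = "mtN1a",
                             mustWork = TRUE)
    if (is.null(geneMap))
        geneMap <- system.file("extdata", "mt_gene_map.tsv", package = "mtN1a",
                               mustWork = TRUE)
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (length(seqs) != 1L)
        stop("reference FASTA must contain exactly one record")
    gm <- utils::read.delim(geneMap, stringsAsFactors = FALSE)
    colnames(polyCTracts) <- c("start", "end")
    new("ReferenceAnnotation",
        sequence = toupper(as.character(seqs[[1]])),
        hvs1Window = as.integer(hvs1Window),
        hvs2Window = as.integer(hvs2Window),
        codingWindow = as.integer(codingWindow),
        excludedSites = sort(unique(c(as.integer(excludedSites), 16519L))),
        polyCTracts = polyCTracts,
        geneMap = gm,
        cache = new.env(parent = emptyenv()))
}

#' @describeIn rCRSAnnotation reference sequence length.
#' @param x,object a \code{ReferenceAnnotation}.
#' @export
setMethod("length", "ReferenceAnnotation",
          function(x) nchar(x@sequence))

setMethod("show", "ReferenceAnnotation", function(object) {
    cat("ReferenceAnnotation:", nchar(object@sequence), "nt\n")
    cat("  HVS-I ", paste(object@hvs1Window, collapse = "-"),
        ", HVS-II ", paste(object@hvs2Window, collapse = "-"),
        ", coding ", paste(object@codingWindow, collapse = "-"), "\n",
        sep = "")
    cat("  excluded sites:", paste(object@excludedSites, collapse = ", "),
        "; poly(C) tracts:",
        paste(apply(object@polyCTracts, 1L,
                    function(r) paste(r, collapse = "-")), collapse = ", "),
        "\n")
    cat("  gene map:", nrow(object@geneMap), "features\n")
})

#' Reference base at given positions
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @param positions integer vector of 1-based coordinates.
#' @return character vector of bases.
#' @export
refBase <- function(ref, positions) {
    substring(ref@sequence, positions, positions)
}

#' Transition partner of a nucleotide
#'
#' A <-> G, C <-> T.
#' @param base character vector of bases.
#' @return character vector of partners.
#' @export
transitionPartner <- function(base) {
    chartr("ACGT", "GTAC", base)
}

#' Is a position inside a poly(C) tract?
#' @keywords internal
inPolyCTract <- function(ref, positions) {
    hit <- rep(FALSE, length(positions))
    for (i in seq_len(nrow(ref@polyCTracts)))
        hit <- hit | (positions >= ref@polyCTracts[i, 1] &
                      positions <= ref@polyCTracts[i, 2])
    hit
}

#' Drop calls that the scoring conventions exclude
#'
#' Removes calls at absolutely excluded sites (np 16519) and
#' insertion/deletion calls inside the poly(C) tracts. Substitutions at
#' tract positions are kept: sites such as 16183 and 16189 are ordinary
#' phylogenetic markers, only tract length variation is unreliable.
#'
#' @param calls a mutation-call data.frame.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return the filtered calls.
#' @export
dropExcludedCalls <- function(calls, ref) {
    if (!nrow(calls)) return(calls)
    drop <- calls$position %in% ref@excludedSites |
        (calls$event %in% c("insertion", "deletion") &
         inPolyCTract(ref, calls$position))
    calls[!drop, , drop = FALSE]
}

#' An empty mutation-call data.frame
#' @keywords internal
emptyCalls <- function() {
    data.frame(position = integer(0), ref = character(0),
               event = character(0), derived = character(0),
               back = logical(0), stringsAsFactors = FALSE)
}

#' Apply mutation calls to a sequence
#'
#' Returns the sequence obtained by applying substitutions, deletions and
#' insertions (in reference coordinates) to the reference. Back-mutation
#' calls (\code{back = TRUE}) leave the reference state untouched.
#'
#' @param ref a \linkS4class{ReferenceAnnotation} or a character sequence.
#' @param calls mutation-call data.frame (columns position, event, derived,
#'   back).
#' @return character(1) mutated sequence.
#' @export
applyMutations <- function(ref, calls) {
    seq <- if (is(ref, "ReferenceAnnotation")) ref@sequence else ref
    if (!nrow(calls)) return(seq)
    calls <- calls[!calls$back, , drop = FALSE]
    if (!nrow(calls)) return(seq)
    if (all(calls$event %in% c("transition", "transversion"))) {
        chars <- strsplit(seq, "")[[1]]
        chars[calls$position] <- calls$derived
        return(paste(chars, collapse = ""))
    }
    chars <- strsplit(seq, "")[[1]]
    out <- as.list(chars)
    for (i in seq_len(nrow(calls))) {
        p <- calls$position[i]
        switch(calls$event[i],
               transition = ,
               transversion = { out[[p]] <- calls$derived[i] },
               deletion = { out[[p]] <- "" },
               insertion = { out[[p]] <- paste0(chars[p], calls$derived[i]) },
               stop("unknown event: ", calls$event[i]))
    }
    paste(unlist(out), collapse = "")
}
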
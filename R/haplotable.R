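#' Read a haplotype table
#'
#' Reads a Table-1-style tab-separated haplotype survey: one row per
#' observed haplotype with its recorded haplogroup label, HVS-I motif
#' (minus 16000), optional HVS-II motif, count, sampling origin and source.
#' Following the usual table convention, HVS-II motifs are recorded
#' "73, 263 in addition": the two implicit transitions are appended to
#' every typed HVS-II motif. An empty HVS-II field means the segment was
#' not typed (not that it is reference-like); the classifier then skips
#' HVS-II diagnostics for that record.
#'
#' @param path TSV file with header columns \code{haplogroup},
#'   \code{hvs1_motif}, \code{hvs2_motif}, \code{n}, \code{population},
#'   \code{region}, \code{source}.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return a \linkS4class{HaplotypeSet}.
#' @export
readHaplotypeTable <- function(path, ref) {
    if (!file.exists(path)) stop("input file not found: ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
    need <- c("haplogroup", "hvs1_motif", "hvs2_motif", "n", "population",
              "region", "source")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop("haplotype table schema error: missing column(s) ",
             paste(missing, collapse = ", "))
    if (!nrow(d)) return(newHaplotypeSet(d[0, ], list(), list()))
    n <- suppressWarnings(as.integer(d$n))
    if (anyNA(n) || any(n < 1L))
        stop("column n must contain positive integers")
    hvs1 <- lapply(d$hvs1_motif, parseMotif, segment = "HVS1", ref = ref)
    hvs2 <- lapply(d$hvs2_motif, function(mot) {
        if (!nzchar(trimws(mot))) return(NULL)  # untyped
        calls <- parseMotif(mot, "HVS2", ref)
        for (p in c(73L, 263L))
            if (!p %in% calls$position)
                calls <- rbind(calls, data.frame(
                    position = p, ref = refBase(ref, p),
                    event = "transition",
                    derived = transitionPartner(refBase(ref, p)),
                    back = FALSE, stringsAsFactors = FALSE))
        calls[order(calls$position), , drop = FALSE]
    })
    for (h in hvs1)
        if (nrow(h) && any(duplicated(h$position[h$event != "insertion"])))
            stop("duplicate non-insertion positions within a motif")
    df <- data.frame(id = sprintf("H%03d", seq_len(nrow(d))),
                     recorded = d$haplogroup, n = n,
                     population = d$population, region = d$region,
                     source = d$source, stringsAsFactors = FALSE)
    newHaplotypeSet(df, hvs1, hvs2)
}

#' @keywords internal
newHaplotypeSet <- function(df, hvs1, hvs2) {
    if (!nrow(df)) {
        df <- data.frame(id = character(0), recorded = character(0),
                         n = integer(0), population = character(0),
                         region = character(0), source = character(0),
                         stringsAsFactors = FALSE)
        hvs1 <- list(); hvs2 <- list()
    }
    df$hvs1 <- hvs1
    df$hvs2 <- hvs2
    df <- df[, c("id", "recorded", "hvs1", "hvs2", "n", "population",
                 "region", "source")]
    new("HaplotypeSet", data = df)
}

#' @describeIn readHaplotypeTable number of records (rows).
#' @param x a \code{HaplotypeSet}.
#' @export
setMethod("length", "HaplotypeSet", function(x) nrow(x@data))

#' Access the records of a HaplotypeSet
#' @param x a \linkS4class{HaplotypeSet}.
#' @return data.frame with list-columns \code{hvs1}, \code{hvs2}.
#' @export
haplotypes <- function(x) x@data

setMethod("show", "HaplotypeSet", function(object) {
    d <- object@data
    cat("HaplotypeSet:", nrow(d), "records,", sum(d$n), "individuals\n")
    if (nrow(d)) {
        tab <- sort(tapply(d$n, d$recorded, sum), decreasing = TRUE)
        cat("  recorded labels:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
            "\n")
    }
})

#' Write clade assignments as TSV
#' @param assignments data.frame from \code{\link{classifyTable}}.
#' @param path output file.
#' @export
writeAssignments <- function(assignments, path) {
    utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
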
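#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib mtN1a, .registration = TRUE
NULL

#' Reference annotation for the mitochondrial coordinate system
#'
#' Bundles the 16,569-nt reference sequence with the coordinate conventions
#' every other operation relies on: the hypervariable-segment windows, the
#' coding-region window, the absolutely excluded sites (np 16519), the
#' poly(C) tracts whose length variation is never scored, and the gene map
#' used for codon-level mutation classification.
#'
#' @slot sequence character(1), the upper-case reference sequence.
#' @slot hvs1Window,hvs2Window,codingWindow integer(2), 1-based inclusive
#'   coordinate ranges.
#' @slot excludedSites integer, positions never scored by variant calling or
#'   encoding (np 16519 is always a member).
#' @slot polyCTracts integer matrix with columns \code{start}, \code{end};
#'   within these tracts insertions/deletions are never scored.
#' @slot geneMap data.frame with columns \code{gene}, \code{start},
#'   \code{end}, \code{strand}, \code{type} (\code{protein}, \code{rRNA},
#'   \code{tRNA}).
#' @slot cache environment used to memoise derived site sets.
#' @exportClass ReferenceAnnotation
setClass("ReferenceAnnotation", representation(
    sequence = "character",
    hvs1Window = "integer",
    hvs2Window = "integer",
    codingWindow = "integer",
    excludedSites = "integer",
    polyCTracts = "matrix",
    geneMap = "data.frame",
    cache = "environment"
))

setValidity("ReferenceAnnotation", function(object) {
    msg <- character(0)
    if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
        msg <- c(msg, "sequence must be a single non-empty string")
    if (!16519L %in% object@excludedSites)
        msg <- c(msg, "np 16519 must be among the excluded sites")
    for (w in list(object@hvs1Window, object@hvs2Window, object@codingWindow))
        if (length(w) != 2L || w[1] > w[2])
            msg <- c(msg, "coordinate windows must be increasing pairs")
    need <- c("gene", "start", "end", "strand", "type")
    if (!all(need %in% names(object@geneMap)))
        msg <- c(msg, "geneMap must have gene/start/end/strand/type columns")
    if (length(msg)) msg else TRUE
})

#' Nested haplogroup definition tree
#'
#' A rooted tree of clade definitions. Each non-root clade introduces a
#' level of diagnostic mutations (possibly split across HVS-I, HVS-II and
#' the coding region), back-mutation diagnostics (an ancestral diagnostic
#' expected to have reverted) and anti-diagnostics (mutations whose
#' presence argues against the clade). Accumulated root-to-clade profiles
#' are precomputed for the classifier.
#'
#' @slot clades data.frame with columns \code{name}, \code{parent},
#'   \code{depth}.
#' @slot levels named list; per clade a data.frame of the diagnostics that
#'   clade introduces (columns \code{segment}, \code{position},
#'   \code{derived}, \code{event}, \code{back}, \code{kind}, \code{weight}).
#' @slot profiles named list; per clade the accumulated expectation
#'   (\code{expect}, \code{backs}, \code{antis} data.frames).
#' @slot nearTolerance numeric(1), default per-level missing tolerance for
#'   near-matching.
#' @exportClass HaplogroupTree
setClass("HaplogroupTree", representation(
    clades = "data.frame",
    levels = "list",
    profiles = "list",
    nearTolerance = "numeric"
))

setValidity("HaplogroupTree", function(object) {
    cl <- object@clades
    msg <- character(0)
    if (anyDuplicated(cl$name)) msg <- c(msg, "duplicate clade names")
    root <- cl$name[is.na(cl$parent)]
    if (length(root) != 1L) msg <- c(msg, "tree must have exactly one root")
    orphans <- setdiff(stats::na.omit(cl$parent), cl$name)
    if (length(orphans)) msg <- c(msg, paste("unknown parent:", orphans[1]))
    if (any(!is.na(cl$parent) & cl$parent == cl$name))
        msg <- c(msg, "clade cannot be its own parent")
    if (length(msg)) msg else TRUE
})

#' Set of observed haplotype records
#'
#' Table-1-style haplotype records: parsed HVS-I calls, optional parsed
#' HVS-II calls (NULL when the segment was not typed), the observed count
#' and sampling metadata.
#'
#' @slot data data.frame with columns \code{id}, \code{recorded} (the
#'   recorded haplogroup label, kept for concordance checks but not
#'   trusted), list-columns \code{hvs1}, \code{hvs2} of mutation-call
#'   data.frames, \code{n}, \code{population}, \code{region}, \code{source}.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet", representation(data = "data.frame"))

setValidity("HaplotypeSet", function(object) {
    d <- object@data
    need <- c("id", "recorded", "hvs1", "hvs2", "n", "population",
              "region", "source")
    if (!all(need %in% names(d))) return("missing mandatory columns")
    if (nrow(d) && any(d$n < 1)) return("counts must be >= 1")
    TRUE
})

#' Binary recoding of haplotypes for network construction
#'
#' @slot mat 0/1 matrix, rows = distinct haplotypes, columns = segregating
#'   binary characters (0 = reference state).
#' @slot taxa data.frame with \code{key}, \code{multiplicity} and a
#'   list-column \code{ids} of member record ids.
#' @slot sites data.frame describing each column: \code{label},
#'   \code{position}, \code{derived}, \code{event}, \code{back},
#'   \code{weight}.
#' @exportClass BinaryMatrix
setClass("BinaryMatrix", representation(
    mat = "matrix", taxa = "data.frame", sites = "data.frame"
))

setValidity("BinaryMatrix", function(object) {
    m <- object@mat
    msg <- character(0)
    if (nrow(m) != nrow(object@taxa)) msg <- c(msg, "taxa/matrix mismatch")
    if (ncol(m) != nrow(object@sites)) msg <- c(msg, "sites/matrix mismatch")
    if (nrow(m) > 1L && ncol(m) > 0L) {
        rng <- apply(m, 2L, function(x) max(x) - min(x))
        if (any(rng == 0)) msg <- c(msg, "constant column present")
    }
    if (anyDuplicated(apply(m, 1L, paste, collapse = "")))
        msg <- c(msg, "duplicate rows must be collapsed")
    if (length(msg)) msg else TRUE
})

#' Haplotype network (reduced median network)
#'
#' Nodes are observed haplotypes plus inferred median/intermediate vectors;
#' every edge is labelled with exactly one binary character.
#'
#' @slot states 0/1 matrix of node state vectors (rows named by node id).
#' @slot observed logical, whether each node is an observed haplotype.
#' @slot multiplicity numeric, number of sampled individuals at each node.
#' @slot edges data.frame with \code{from}, \code{to} (node ids) and
#'   \code{site} (column index into \code{sites}).
#' @slot sites data.frame as in \linkS4class{BinaryMatrix}.
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork", representation(
    states = "matrix", observed = "logical", multiplicity = "numeric",
    edges = "data.frame", sites = "data.frame"
))

setValidity("HaplotypeNetwork", function(object) {
    msg <- character(0)
    n <- nrow(object@states)
    if (length(object@observed) != n || length(object@multiplicity) != n)
        msg <- c(msg, "per-node slots must align with states")
    if (n > 1L) {
        g <- igraph::graph_from_data_frame(
            object@edges[, c("from", "to")], directed = FALSE,
            vertices = rownames(object@states))
        if (igraph::components(g)$no != 1L)
            msg <- c(msg, "network must be connected")
        deg <- igraph::degree(g)
        if (any(deg[!object@observed] < 2L))
            msg <- c(msg, "inferred nodes must have degree >= 2")
    }
    if (length(msg)) msg else TRUE
})

#' Rooted mutation tree
#'
#' A rooted tree whose edges carry the mutations inferred on them. The root
#' is the inferred ancestral haplotype; sampled haplotypes sit at nodes
#' with \code{multiplicity > 0} (usually but not necessarily leaves).
#'
#' @slot nodeId character, unique node identifiers; element 1 is the root.
#' @slot parent integer, index of each node's parent (0 for the root).
#' @slot sampled logical, whether sampled individuals sit at the node.
#' @slot multiplicity numeric, number of sampled individuals at the node.
#' @slot edgeCalls list of mutation-call data.frames, one per node, the
#'   calls on the edge from the parent into the node (empty for the root).
#' @slot states optional 0/1 matrix of node states (for reconstruction
#'   checks); zero rows when not tracked.
#' @slot sites data.frame describing the binary characters (may have zero
#'   rows when the tree was built directly from planted calls).
#' @exportClass MutationTree
setClass("MutationTree", representation(
    nodeId = "character", parent = "integer", sampled = "logical",
    multiplicity = "numeric", edgeCalls = "list", states = "matrix",
    sites = "data.frame"
))

setValidity("MutationTree", function(object) {
    n <- length(object@nodeId)
    msg <- character(0)
    if (length(object@parent) != n || length(object@sampled) != n ||
        length(object@multiplicity) != n || length(object@edgeCalls) != n)
        msg <- c(msg, "slot lengths must agree")
    if (n > 0L) {
        if (object@parent[1] != 0L || any(object@parent[-1] == 0L))
            msg <- c(msg, "node 1 must be the unique root")
        if (any(object@parent[-1] >= seq_len(n)[-1]))
            msg <- c(msg, "nodes must be listed in preorder")
        if (anyDuplicated(object@nodeId)) msg <- c(msg, "duplicate node ids")
    }
    if (length(msg)) msg else TRUE
})

#' Simulated ground truth
#'
#' @slot tree a \linkS4class{MutationTree} with per-edge planted calls
#'   (including their mutation class).
#' @slot tmrcaYears numeric(1), the true age of the root.
#' @slot config the \code{\link{simulationConfig}} used.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    tree = "MutationTree", tmrcaYears = "numeric", config = "list"
))
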
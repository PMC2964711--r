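#' Reduced median network
#'
#' Builds the reduced median network of a set of binary haplotype vectors.
#' The construction follows the classical reduced-median scheme for binary
#' data: (1) pairs of incompatible characters (all four gametes present)
#' whose frequency support is lopsided by at least the reduction parameter
#' \code{r} are resolved in favour of the better-supported character - the
#' weaker character is treated as recurrent and split into two characters,
#' one per background; (2) the remaining conflicts are closed under
#' majority (median) vectors of node triples, adding inferred median nodes
#' until closure; (3) nodes are linked whenever no third node lies
#' geodesically between them, and multi-mutation links are subdivided by
#' inferred intermediate nodes so that every edge carries exactly one
#' character (sites in ascending order along the chain, making the network
#' bit-reproducible). The resulting network contains every
#' most-parsimonious tree of the (possibly reduced) data as a spanning
#' substructure; \code{\link{extractTree}} recovers the best one.
#'
#' @param bm a \linkS4class{BinaryMatrix}.
#' @param r reduction parameter (>= 1); larger values retain more
#'   alternative resolutions (more reticulation). Default 2, the
#'   conventional default of the algorithm's reference implementation.
#' @param maxNodes safety cap on median closure growth.
#' @return a \linkS4class{HaplotypeNetwork}.
#' @export
reducedMedianNetwork <- function(bm, r = 2, maxNodes = 512L) {
    if (r < 1) stop("reduction parameter r must be >= 1")
    mat <- bm@mat
    sites <- bm@sites
    mult <- bm@taxa$multiplicity
    if (!base::nrow(mat) || !base::ncol(mat)) {
        return(new("HaplotypeNetwork",
                   states = mat, observed = rep(TRUE, base::nrow(mat)),
                   multiplicity = as.numeric(mult),
                   edges = data.frame(from = character(0),
                                      to = character(0),
                                      site = integer(0),
                                      stringsAsFactors = FALSE),
                   sites = sites))
    }

    # --- step 1: frequency-ratio reduction of lopsided conflicts --------
    repeat {
        changed <- FALSE
        nc <- base::ncol(mat)
        freq <- as.numeric(mult %*% mat)  # weighted carrier frequency
        for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
            gi <- mat[, i]; gj <- mat[, j]
            gam <- c(any(mult[gi == 0 & gj == 0] > 0),
                     any(mult[gi == 0 & gj == 1] > 0),
                     any(mult[gi == 1 & gj == 0] > 0),
                     any(mult[gi == 1 & gj == 1] > 0))
            if (!all(gam)) next
            if (freq[i] >= r * freq[j]) { weak <- j; strong <- i }
            else if (freq[j] >= r * freq[i]) { weak <- i; strong <- j }
            else next
            # the weak character recurred on both backgrounds of the strong
            # one: split its carriers on the minority background into a new
            # character
            carriers <- mat[, weak] == 1
            bg <- mat[carriers, strong]
            w0 <- sum(mult[carriers][bg == 0]); w1 <- sum(mult[carriers][bg == 1])
            minority <- if (w1 < w0 || (w1 == w0 && TRUE)) 1 else 0
            moved <- carriers & mat[, strong] == minority
            if (!any(moved) || all(moved[carriers])) next
            newCol <- ifelse(moved, 1L, 0L)
            mat[moved, weak] <- 0L
            mat <- cbind(mat, newCol)
            colnames(mat)[base::ncol(mat)] <-
                paste0(colnames(mat)[weak], "'")
            dup <- sites[weak, , drop = FALSE]
            dup$label <- colnames(mat)[base::ncol(mat)]
            sites <- rbind(sites, dup)
            changed <- TRUE
            break
        }
        if (!changed) break
    }

    # --- step 2: median closure (frontier-based) ------------------------
    nodes <- mat
    nodeKeys <- apply(nodes, 1L, paste, collapse = "")
    observed <- rep(TRUE, base::nrow(nodes))
    nmult <- as.numeric(mult)
    capped <- FALSE
    frontier <- seq_len(base::nrow(nodes))  # triples must touch a new node
    repeat {
        n <- base::nrow(nodes)
        if (n >= maxNodes) { capped <- TRUE; break }
        newRows <- list()
        newKeys <- character(0)
        for (a in frontier) {
            others <- setdiff(seq_len(n), a)
            if (length(others) < 2L) next
            for (bi in seq_len(length(others) - 1L)) {
                b <- others[bi]
                ssum <- nodes[a, ] + nodes[b, ]
                for (ci in (bi + 1L):length(others)) {
                    cc <- others[ci]
                    med <- as.integer(ssum + nodes[cc, ] >= 2L)
                    k <- paste(med, collapse = "")
                    if (!k %in% nodeKeys && !k %in% newKeys) {
                        newRows[[length(newRows) + 1L]] <- med
                        newKeys <- c(newKeys, k)
                        if (n + length(newRows) >= maxNodes) break
                    }
                }
                if (n + length(newRows) >= maxNodes) break
            }
            if (n + length(newRows) >= maxNodes) break
        }
        if (!length(newRows)) break
        add <- do.call(rbind, newRows)
        colnames(add) <- colnames(nodes)
        frontier <- base::nrow(nodes) + seq_len(base::nrow(add))
        nodes <- rbind(nodes, add)
        nodeKeys <- c(nodeKeys, newKeys)
        observed <- c(observed, rep(FALSE, base::nrow(add)))
        nmult <- c(nmult, rep(0, base::nrow(add)))
    }
    if (capped)
        warning("median closure capped at ", maxNodes,
                " nodes; network may be incomplete")

    ids <- character(base::nrow(nodes))
    ids[observed] <- bm@taxa$key
    ids[!observed] <- paste0("mv", seq_len(sum(!observed)))
    rownames(nodes) <- ids

    net <- linkNodes(nodes, observed, nmult, sites)
    validObject(net)
    net
}

# Connect node set: u~v iff no third node lies geodesically between them;
# subdivide multi-site links with inferred intermediates (sites ascending).
#' @keywords internal
linkNodes <- function(nodes, observed, nmult, sites) {
    n <- base::nrow(nodes)
    edges <- data.frame(from = character(0), to = character(0),
                        site = integer(0), stringsAsFactors = FALSE)
    if (n > 1L) {
        D <- as.matrix(stats::dist(nodes, method = "manhattan"))
        extraNodes <- list()
        for (u in seq_len(n - 1L)) for (v in (u + 1L):n) {
            duv <- D[u, v]
            between <- FALSE
            for (w in seq_len(n)) {
                if (w == u || w == v) next
                if (D[u, w] + D[w, v] == duv) { between <- TRUE; break }
            }
            if (between) next
            diffSites <- which(nodes[u, ] != nodes[v, ])
            diffSites <- diffSites[order(sites$position[diffSites],
                                         sites$label[diffSites])]
            chain <- rownames(nodes)[u]
            cur <- nodes[u, ]
            for (k in seq_along(diffSites)) {
                s <- diffSites[k]
                if (k < length(diffSites)) {
                    cur[s] <- nodes[v, s]
                    nid <- paste0("iv", length(extraNodes) + 1L)
                    extraNodes[[nid]] <- cur
                    nxt <- nid
                } else nxt <- rownames(nodes)[v]
                edges <- rbind(edges, data.frame(
                    from = chain, to = nxt, site = s,
                    stringsAsFactors = FALSE))
                chain <- nxt
            }
        }
        if (length(extraNodes)) {
            add <- do.call(rbind, extraNodes)
            rownames(add) <- names(extraNodes)
            nodes <- rbind(nodes, add)
            observed <- c(observed, rep(FALSE, length(extraNodes)))
            nmult <- c(nmult, rep(0, length(extraNodes)))
        }
    }
    new("HaplotypeNetwork", states = nodes, observed = observed,
        multiplicity = nmult, edges = edges, sites = sites)
}

#' Number of independent cycles (reticulations) in a network
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @export
reticulations <- function(net) {
    if (!base::nrow(net@edges)) return(0L)
    g <- asIgraph(net)
    igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no
}

#' Convert a HaplotypeNetwork to an igraph object
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @return an undirected igraph graph with node attributes
#'   \code{observed}, \code{multiplicity} and edge attribute \code{site}
#'   (character label).
#' @export
asIgraph <- function(net) {
    v <- data.frame(name = rownames(net@states),
                    observed = net@observed,
                    multiplicity = net@multiplicity,
                    stringsAsFactors = FALSE)
    e <- net@edges
    e$site <- net@sites$label[e$site]
    igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Export a network as GraphML
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @param path output file.
#' @export
writeGraphML <- function(net, path) {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}

setMethod("show", "HaplotypeNetwork", function(object) {
    cat("HaplotypeNetwork:", sum(object@observed), "observed +",
        sum(!object@observed), "inferred nodes,",
        base::nrow(object@edges), "edges,", reticulations(object),
        "reticulation(s)\n")
})
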
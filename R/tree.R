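#' Construct a MutationTree
#'
#' Low-level constructor used by \code{\link{extractTree}} and the
#' simulator. Nodes must be listed in preorder (root first) with parent
#' indices referring to earlier nodes.
#'
#' @param nodeId character node ids.
#' @param parent integer parent indices (0 for the root).
#' @param edgeCalls list of mutation-call data.frames (calls on the edge
#'   into each node; empty for the root).
#' @param sampled logical, sampled individuals at the node.
#' @param multiplicity numeric counts of sampled individuals.
#' @param states optional node-state matrix (0/1, rows in node order).
#' @param sites optional site description data.frame.
#' @return a \linkS4class{MutationTree}.
#' @export
mutationTree <- function(nodeId, parent, edgeCalls, sampled = NULL,
                         multiplicity = NULL, states = NULL, sites = NULL) {
    n <- length(nodeId)
    if (is.null(sampled)) sampled <- !seq_len(n) %in% parent
    if (is.null(multiplicity)) multiplicity <- as.numeric(sampled)
    if (is.null(states)) states <- matrix(0L, nrow = 0L, ncol = 0L)
    if (is.null(sites))
        sites <- data.frame(label = character(0), stringsAsFactors = FALSE)
    new("MutationTree", nodeId = nodeId, parent = as.integer(parent),
        sampled = sampled, multiplicity = as.numeric(multiplicity),
        edgeCalls = edgeCalls, states = states, sites = sites)
}

#' Extract the most-parsimonious rooted tree from a network
#'
#' Selects, among the trees contained in a haplotype network, the one
#' connecting all observed haplotypes (and the outgroup attachment) with
#' minimum total weighted mutation count, then roots it at the outgroup
#' attachment node (the inferred ancestral haplotype). For up to
#' \code{maxExact} required nodes the minimum Steiner tree is found
#' exactly by Dreyfus-Wagner dynamic programming over the network graph;
#' beyond that a shortest-path/minimum-spanning-tree heuristic is used
#' (exact whenever the network is already a tree, which is always the case
#' for homoplasy-free data). Ties are broken deterministically by
#' lexicographic edge order. Manual homoplasy resolutions are supplied as
#' forced edges.
#'
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @param outgroupState 0/1 vector in network site order giving the
#'   outgroup (ancestral) state; default all reference (all zero).
#' @param root node id to root at, overriding outgroup attachment.
#' @param forceEdges optional data.frame/matrix with columns from,to: edges
#'   that must appear in the tree (a "manual" homoplasy resolution).
#' @param maxExact maximum number of required nodes for the exact search.
#' @return a \linkS4class{MutationTree}.
#' @export
extractTree <- function(net, outgroupState = NULL, root = NULL,
                        forceEdges = NULL, maxExact = 12L) {
    states <- net@states
    if (!base::nrow(states)) stop("empty network")
    ids <- rownames(states)
    if (is.null(root)) {
        if (is.null(outgroupState))
            outgroupState <- rep(0L, base::ncol(states))
        d <- colSums(abs(t(states) - outgroupState))
        cand <- ids[d == min(d)]
        if (length(cand) > 1L)
            stop("outgroup equally attachable to multiple nodes: ",
                 paste(cand, collapse = ", "),
                 "; disambiguate with root=")
        root <- cand
    }
    if (!root %in% ids) stop("unknown root node: ", root)

    terminals <- unique(c(root, ids[net@observed]))
    e <- net@edges
    w <- net@sites$weight[e$site]
    if (!is.null(forceEdges)) {
        forceEdges <- as.data.frame(forceEdges, stringsAsFactors = FALSE)
        fk <- edgeKey(forceEdges$from, forceEdges$to)
        ek <- edgeKey(e$from, e$to)
        if (!all(fk %in% ek))
            stop("forced edge not present in the network")
        terminals <- unique(c(terminals, forceEdges$from, forceEdges$to))
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = e$from, to = e$to, weight = w,
                   site = e$site, stringsAsFactors = FALSE),
        directed = FALSE, vertices = ids)

    treeEdges <- if (igraph::ecount(g) == igraph::vcount(g) - 1L) {
        e  # the network is already a tree
    } else if (length(terminals) <= maxExact) {
        steinerExact(g, terminals, e, w)
    } else {
        steinerHeuristic(g, terminals, e, w)
    }
    # enforce forced edges: add, then break the created cycle at its
    # heaviest non-forced edge
    if (!is.null(forceEdges)) {
        for (i in seq_len(base::nrow(forceEdges))) {
            fe <- edgeKey(forceEdges$from[i], forceEdges$to[i])
            tk <- edgeKey(treeEdges$from, treeEdges$to)
            if (fe %in% tk) next
            # the pre-existing tree path between the endpoints forms a
            # cycle with the forced edge: break it at its heaviest edge
            tg0 <- igraph::graph_from_data_frame(treeEdges,
                                                 directed = FALSE)
            path <- igraph::shortest_paths(
                tg0, forceEdges$from[i], forceEdges$to[i],
                output = "epath",
                weights = rep(1, igraph::ecount(tg0)))$epath[[1]]
            pe <- igraph::as_ids(path)
            pk <- edgeKey(sub("\\|.*", "", pe), sub(".*\\|", "", pe))
            tw <- net@sites$weight[treeEdges$site[match(pk, tk)]]
            drop1 <- pk[order(-tw, pk)][1]
            idx <- which(edgeKey(e$from, e$to) == fe)[1]
            treeEdges <- rbind(treeEdges[tk != drop1, , drop = FALSE],
                               e[idx, ])
        }
    }
    # prune inferred leaves not needed (heuristic safety), keep terminals
    repeat {
        tg <- igraph::graph_from_data_frame(treeEdges, directed = FALSE)
        deg <- igraph::degree(tg)
        dropV <- setdiff(names(deg)[deg <= 1L], terminals)
        if (!length(dropV)) break
        treeEdges <- treeEdges[!(treeEdges$from %in% dropV |
                                 treeEdges$to %in% dropV), , drop = FALSE]
    }
    buildMutationTree(net, treeEdges, root)
}

#' @keywords internal
edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Dreyfus-Wagner exact minimum Steiner tree; returns the edge subset.
#' @keywords internal
steinerExact <- function(g, terminals, e, w) {
    ids <- igraph::V(g)$name
    m <- length(ids)
    D <- igraph::distances(g)
    t <- length(terminals)
    ti <- match(terminals, ids)
    full <- bitwShiftL(1L, t) - 1L
    dp <- matrix(Inf, nrow = full, ncol = m)
    mergeChoice <- matrix(0L, nrow = full, ncol = m)   # subset T, 0 = walk
    walkChoice <- matrix(0L, nrow = full, ncol = m)    # source node u
    for (i in seq_len(t))
        dp[bitwShiftL(1L, i - 1L), ] <- D[ti[i], ]
    popcount <- vapply(seq_len(full), function(S)
        sum(bitwAnd(S, bitwShiftL(1L, 0:(t - 1L))) > 0L), 0L)
    for (S in order(popcount, seq_len(full))) {
        if (popcount[S] < 2L) next
        low <- bitwAnd(S, -S)
        rest <- S - low
        best <- rep(Inf, m); bestT <- rep(0L, m)
        # enumerate proper subsets of S containing its lowest bit
        Tsub <- 0L
        repeat {
            Tset <- Tsub + low
            comp <- S - Tset
            if (comp > 0L) {
                v <- dp[Tset, ] + dp[comp, ]
                better <- v < best
                best[better] <- v[better]
                bestT[better] <- Tset
            }
            if (Tsub == rest) break
            Tsub <- bitwAnd(Tsub - rest, rest)
        }
        # relaxation through the metric: dp[S,v] = min_u best[u] + D[u,v]
        M <- best + D      # D[u, v] + best[u], recycled down columns
        uBest <- max.col(-t(M), ties.method = "first")
        val <- M[cbind(uBest, seq_len(m))]
        dp[S, ] <- val
        mergeChoice[S, ] <- bestT[uBest]
        walkChoice[S, ] <- uBest
    }
    # traceback
    edges <- list()
    addPath <- function(u, v) {
        if (u == v) return()
        p <- igraph::shortest_paths(g, ids[u], ids[v],
                                    output = "epath")$epath[[1]]
        for (eid in igraph::as_ids(p)) edges[[eid]] <<- eid
    }
    recover <- function(S, v) {
        nbits <- sum(bitwAnd(S, bitwShiftL(1L, 0:(t - 1L))) > 0L)
        if (nbits == 1L) {
            i <- which(bitwAnd(S, bitwShiftL(1L, 0:(t - 1L))) > 0L)
            addPath(ti[i], v)
            return()
        }
        u <- walkChoice[S, v]
        Tset <- mergeChoice[S, v]
        addPath(u, v)
        recover(Tset, u)
        recover(S - Tset, u)
    }
    rootIdx <- ti[1]
    recover(full, rootIdx)
    eids <- names(edges)
    sel <- match(eids, paste(e$from, e$to, sep = "|"))
    sel2 <- match(eids, paste(e$to, e$from, sep = "|"))
    sel[is.na(sel)] <- sel2[is.na(sel)]
    unique(e[sel, , drop = FALSE])
}

# Shortest-path MST heuristic Steiner tree.
#' @keywords internal
steinerHeuristic <- function(g, terminals, e, w) {
    D <- igraph::distances(g, v = terminals, to = terminals)
    cg <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
    mstc <- igraph::mst(cg)
    keep <- list()
    me <- igraph::as_data_frame(mstc, "edges")
    for (i in seq_len(base::nrow(me))) {
        p <- igraph::shortest_paths(g, me$from[i], me$to[i],
                                    output = "epath")$epath[[1]]
        for (eid in igraph::as_ids(p)) keep[[eid]] <- eid
    }
    eids <- names(keep)
    sel <- match(eids, paste(e$from, e$to, sep = "|"))
    sel2 <- match(eids, paste(e$to, e$from, sep = "|"))
    sel[is.na(sel)] <- sel2[is.na(sel)]
    sub <- unique(e[sel, , drop = FALSE])
    # the union of paths may contain cycles: take its MST
    sg <- igraph::graph_from_data_frame(
        data.frame(from = sub$from, to = sub$to,
                   weight = w[match(edgeKey(sub$from, sub$to),
                                    edgeKey(e$from, e$to))],
                   site = sub$site), directed = FALSE)
    ms <- igraph::as_data_frame(igraph::mst(sg), "edges")
    ms[, c("from", "to", "site")]
}

# Orient the chosen edges from the root and assemble the MutationTree.
#' @keywords internal
buildMutationTree <- function(net, treeEdges, root) {
    treeEdges <- treeEdges[!duplicated(edgeKey(treeEdges$from,
                                               treeEdges$to)), ,
                           drop = FALSE]
    adj <- split(c(treeEdges$to, treeEdges$from),
                 c(treeEdges$from, treeEdges$to))
    siteOf <- c(stats::setNames(treeEdges$site,
                                edgeKey(treeEdges$from, treeEdges$to)))
    ord <- root
    parent <- c(0L)
    edgeSite <- c(NA_integer_)
    seen <- root
    queue <- root
    while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        nb <- sort(setdiff(adj[[cur]], seen))
        for (x in nb) {
            ord <- c(ord, x)
            parent <- c(parent, match(cur, ord))
            edgeSite <- c(edgeSite, siteOf[edgeKey(cur, x)])
            seen <- c(seen, x)
            queue <- c(queue, x)
        }
    }
    idx <- match(ord, rownames(net@states))
    states <- net@states[idx, , drop = FALSE]
    calls <- vector("list", length(ord))
    calls[[1]] <- cbind(emptyCalls(),
                        data.frame(site = character(0),
                                   stringsAsFactors = FALSE))
    for (i in seq_along(ord)[-1]) {
        s <- edgeSite[i]
        gain <- states[i, s] == 1L
        si <- net@sites[s, ]
        calls[[i]] <- data.frame(position = si$position, ref = si$ref,
                                 event = si$event, derived = si$derived,
                                 back = !gain, site = si$label,
                                 stringsAsFactors = FALSE)
    }
    mt <- mutationTree(nodeId = ord, parent = parent, edgeCalls = calls,
                       sampled = net@observed[idx],
                       multiplicity = net@multiplicity[idx],
                       states = states, sites = net@sites)
    stopifnot(reconstructionIdentity(mt))
    mt
}

#' Root-to-tip reconstruction identity
#'
#' Checks that flipping each edge's sites along every root-to-node path
#' reproduces the node's recorded state vector exactly.
#' @param tree a \linkS4class{MutationTree} carrying states.
#' @return logical(1).
#' @export
reconstructionIdentity <- function(tree) {
    if (!base::nrow(tree@states)) return(TRUE)
    n <- length(tree@nodeId)
    lab <- tree@sites$label
    for (i in seq_len(n)[-1]) {
        p <- tree@parent[i]
        st <- tree@states[p, ]
        cc <- tree@edgeCalls[[i]]
        for (j in seq_len(base::nrow(cc))) {
            s <- match(cc$site[j], lab)
            st[s] <- if (cc$back[j]) 0L else 1L
        }
        if (!all(st == tree@states[i, ])) return(FALSE)
    }
    TRUE
}

#' Total weighted mutation count (parsimony score) of a tree
#' @param tree a \linkS4class{MutationTree}.
#' @param weights optional named weights by site label (default 1 each).
#' @export
parsimonyScore <- function(tree, weights = NULL) {
    tot <- 0
    for (cc in tree@edgeCalls) {
        if (!base::nrow(cc)) next
        w <- rep(1, base::nrow(cc))
        if (!is.null(weights) && "site" %in% names(cc)) {
            hit <- cc$site %in% names(weights)
            w[hit] <- weights[cc$site[hit]]
        }
        tot <- tot + sum(w)
    }
    tot
}

#' Number of sampled mtDNAs in a tree
#' @param tree a \linkS4class{MutationTree}.
#' @export
nSampled <- function(tree) sum(tree@multiplicity[tree@sampled])

#' Subtree rooted at a node
#' @param tree a \linkS4class{MutationTree}.
#' @param nodeId id of the new root; its incoming edge is discarded.
#' @return a \linkS4class{MutationTree}.
#' @export
subtreeAt <- function(tree, nodeId) {
    i0 <- match(nodeId, tree@nodeId)
    if (is.na(i0)) stop("unknown node: ", nodeId)
    keep <- i0
    for (i in seq_along(tree@nodeId)) {
        if (i <= i0) next
        if (tree@parent[i] %in% keep) keep <- c(keep, i)
    }
    remap <- match(tree@parent[keep], keep)
    remap[1] <- 0L
    calls <- tree@edgeCalls[keep]
    calls[[1]] <- calls[[1]][0, , drop = FALSE]
    mutationTree(nodeId = tree@nodeId[keep], parent = remap,
                 edgeCalls = calls, sampled = tree@sampled[keep],
                 multiplicity = tree@multiplicity[keep],
                 states = if (base::nrow(tree@states))
                     tree@states[keep, , drop = FALSE]
                 else NULL,
                 sites = tree@sites)
}

#' Most recent common ancestor of a set of sampled nodes
#' @param tree a \linkS4class{MutationTree}.
#' @param nodeIds ids of sampled nodes.
#' @return node id of the MRCA.
#' @export
mrcaNode <- function(tree, nodeIds) {
    ix <- match(nodeIds, tree@nodeId)
    if (anyNA(ix)) stop("unknown node(s): ",
                        paste(nodeIds[is.na(ix)], collapse = ", "))
    pathOf <- function(i) {
        p <- i
        while (tree@parent[p[1]] > 0L) p <- c(tree@parent[p[1]], p)
        p
    }
    common <- Reduce(intersect, lapply(ix, pathOf))
    tree@nodeId[common[length(common)]]
}

#' Convert a MutationTree to an ape phylo object
#'
#' Sampled non-leaf nodes receive a zero-length pendant tip so that every
#' sampled haplotype is a tip of the returned tree; edge lengths are
#' mutation counts.
#' @param tree a \linkS4class{MutationTree}.
#' @return an \code{ape::phylo}.
#' @export
asPhylo <- function(tree) {
    ape::read.tree(text = writeNewickString(tree, comments = FALSE))
}

#' @keywords internal
writeNewickString <- function(tree, comments = TRUE) {
    children <- split(seq_along(tree@nodeId)[-1],
                      factor(tree@parent[-1],
                             levels = seq_along(tree@nodeId)))
    rec <- function(i) {
        kids <- children[[as.character(i)]]
        pend <- if (tree@sampled[i] && length(kids))
            paste0(tree@nodeId[i], "_s:0") else character(0)
        parts <- c(vapply(kids, rec, character(1)), pend)
        lab <- tree@nodeId[i]
        len <- base::nrow(tree@edgeCalls[[i]])
        com <- if (comments && i != 1L && len > 0) {
            cc <- tree@edgeCalls[[i]]
            paste0("[&mut={",
                   paste0(ifelse(cc$back, "@", ""), cc$site,
                          collapse = ","), "}]")
        } else ""
        if (length(parts))
            paste0("(", paste(parts, collapse = ","), ")", lab, ":", len,
                   com)
        else paste0(lab, ":", len, com)
    }
    paste0(sub(":[0-9]+$", "", rec(1L)), ";")
}

#' Write a tree as Newick with per-edge mutation comments
#' @param tree a \linkS4class{MutationTree}.
#' @param path output file.
#' @export
writeNewickTree <- function(tree, path) {
    writeLines(writeNewickString(tree), path)
    invisible(path)
}

#' Parse an absolute-coordinate site label into a mutation call
#' @keywords internal
parseSiteLabel <- function(lab, ref, back = FALSE) {
    g <- regmatches(lab, regexec("^([0-9]+)(d|i[ACGT]+|[ACGT])?('*)$",
                                 lab))[[1]]
    if (!length(g)) stop("cannot parse site label: ", lab)
    pos <- as.integer(g[2])
    rb <- refBase(ref, pos)
    suf <- g[3]
    if (suf == "") {
        event <- "transition"; derived <- transitionPartner(rb)
    } else if (suf == "d") {
        event <- "deletion"; derived <- ""
    } else if (startsWith(suf, "i")) {
        event <- "insertion"; derived <- substring(suf, 2L)
    } else {
        event <- if (suf == transitionPartner(rb)) "transition"
                 else "transversion"
        derived <- suf
    }
    data.frame(position = pos, ref = rb, event = event, derived = derived,
               back = back, site = lab, stringsAsFactors = FALSE)
}

#' Read a Newick tree with per-edge mutation comments
#'
#' Reads the rooted Newick format written by \code{\link{writeNewickTree}}
#' (edge comments \code{[&mut={site,...}]}, \code{@}-prefixed sites being
#' back mutations, sampled internal nodes carrying an \code{_s} pendant)
#' back into a \linkS4class{MutationTree}.
#'
#' @param path input file.
#' @param ref a \linkS4class{ReferenceAnnotation}.
#' @return a \linkS4class{MutationTree}.
#' @export
readNewickTree <- function(path, ref) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    txt <- gsub("[[:space:]]", "", txt)
    pos <- 1L
    n <- nchar(txt)
    peek <- function() substring(txt, pos, pos)
    nodes <- list()  # list of (id, parentIdx, sites)
    parseNode <- function(parentIdx) {
        idx <- length(nodes) + 1L
        nodes[[idx]] <<- list(id = NA_character_, parent = parentIdx,
                              sites = character(0))
        if (peek() == "(") {
            pos <<- pos + 1L
            repeat {
                parseNode(idx)
                if (peek() == ",") { pos <<- pos + 1L; next }
                if (peek() == ")") { pos <<- pos + 1L; break }
                stop("malformed newick near position ", pos)
            }
        }
        m <- regmatches(substring(txt, pos),
                        regexec(paste0("^([^():,;\\[]*)(:[0-9.eE+-]+)?",
                                       "(\\[&mut=\\{([^}]*)\\}\\])?"),
                                substring(txt, pos)))[[1]]
        nodes[[idx]]$id <<- if (nzchar(m[2])) m[2] else paste0("nd", idx)
        if (length(m) >= 5 && nzchar(m[5]))
            nodes[[idx]]$sites <<- strsplit(m[5], ",", fixed = TRUE)[[1]]
        pos <<- pos + nchar(m[1])
        idx
    }
    parseNode(0L)
    if (peek() != ";") stop("newick must end with ';'")
    ids <- vapply(nodes, `[[`, character(1), "id")
    parent <- vapply(nodes, `[[`, integer(1), "parent")
    # collapse sampled-pendant tips
    pend <- which(endsWith(ids, "_s") &
                  sub("_s$", "", ids) == ids[pmax(parent, 1L)])
    hasKids <- seq_along(ids) %in% parent
    sampled <- (!hasKids & !seq_along(ids) %in% pend) |
        seq_along(ids) %in% parent[pend]
    keep <- setdiff(seq_along(ids), pend)
    # re-index in preorder (parser already emits preorder)
    remap <- match(parent[keep], keep)
    remap[is.na(remap)] <- 0L
    calls <- lapply(keep, function(i) {
        s <- nodes[[i]]$sites
        if (!length(s))
            return(cbind(emptyCalls(),
                         data.frame(site = character(0),
                                    stringsAsFactors = FALSE)))
        do.call(rbind, lapply(s, function(x)
            parseSiteLabel(sub("^@", "", x), ref,
                           back = startsWith(x, "@"))))
    })
    mutationTree(nodeId = ids[keep], parent = remap, edgeCalls = calls,
                 sampled = sampled[keep],
                 multiplicity = as.numeric(sampled[keep]))
}

setMethod("show", "MutationTree", function(object) {
    cat("MutationTree:", length(object@nodeId), "nodes, root ",
        object@nodeId[1], ",", nSampled(object), "sampled mtDNAs,",
        parsimonyScore(object), "mutations\n")
})
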
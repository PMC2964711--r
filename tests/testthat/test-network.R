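test_that("homoplasy-free data give the unique perfect phylogeny", {
    # a nested clade structure: sites gained along a ladder
    mat <- rbind(A = c(0, 0, 0, 0), B = c(1, 0, 0, 0), C = c(1, 1, 0, 0),
                 D = c(1, 1, 1, 0), E = c(1, 0, 0, 1))
    bm <- binaryInstance(mat)
    net <- reducedMedianNetwork(bm)
    expect_equal(reticulations(net), 0L)
    expect_equal(sum(!net@observed), 0L)
    mt <- extractTree(net)
    expect_equal(parsimonyScore(mt), 4)
    expect_true(reconstructionIdentity(mt))
})

test_that("the classic four-gamete conflict yields a cycle, reduced when support is lopsided", {
    mat <- rbind(A = c(0, 0), B = c(0, 1), C = c(1, 0), D = c(1, 1))
    # balanced support (r = 2 not reached): the 4-cycle survives
    bm <- binaryInstance(mat, multiplicity = c(3, 2, 2, 1))
    net <- reducedMedianNetwork(bm, r = 2)
    expect_equal(reticulations(net), 1L)
    mt <- extractTree(net, root = "A")
    expect_equal(parsimonyScore(mt), 3)  # one site must recur
    # lopsided support: the weak character is split, no cycle remains
    bm2 <- binaryInstance(mat, multiplicity = c(5, 1, 5, 1))
    net2 <- reducedMedianNetwork(bm2, r = 2)
    expect_equal(reticulations(net2), 0L)
    mt2 <- extractTree(net2, root = "A")
    expect_equal(parsimonyScore(mt2), 3)
})

test_that("tree extraction reaches the exhaustive parsimony minimum", {
    set.seed(909)
    for (case in 1:12) {
        nt <- sample(4:7, 1)
        ns <- sample(4:9, 1)
        mat <- matrix(rbinom(nt * ns, 1, 0.4), nt, ns,
                      dimnames = list(c("OUT", paste0("T", seq_len(nt - 1))),
                                      NULL))
        mat["OUT", ] <- 0L
        # drop duplicate taxa rows for the oracle's sake
        mat <- mat[!duplicated(apply(mat, 1, paste, collapse = "")), ,
                   drop = FALSE]
        mat <- mat[, apply(mat, 2, function(x) length(unique(x))) > 1L,
                   drop = FALSE]
        if (nrow(mat) < 4L || ncol(mat) < 2L) next
        bm <- suppressMessages(binaryInstance(mat))
        net <- reducedMedianNetwork(bm, r = 1e9)  # no reduction: keep all
        mt <- extractTree(net, root = "OUT")
        expect_equal(parsimonyScore(mt), oracleParsimonyMin(mat),
                     label = paste("case", case))
        expect_true(reconstructionIdentity(mt))
    }
})

test_that("an 8-taxon instance with one homoplastic site matches the oracle", {
    mat <- rbind(OUT = c(0, 0, 0, 0, 0, 0),
                 A = c(1, 0, 0, 0, 0, 0), B = c(1, 1, 0, 0, 0, 0),
                 C = c(1, 1, 0, 0, 0, 1), D = c(0, 0, 1, 0, 0, 0),
                 E = c(0, 0, 1, 1, 0, 0), F = c(0, 0, 1, 1, 0, 1),
                 G = c(0, 0, 0, 0, 1, 0))
    bm <- binaryInstance(mat)
    net <- reducedMedianNetwork(bm, r = 1e9)
    mt <- extractTree(net, root = "OUT")
    expect_equal(parsimonyScore(mt), oracleParsimonyMin(mat))
})

test_that("every observed haplotype is a network node and inferred nodes have degree >= 2", {
    cfg <- simulationConfig(seed = 21L, topology = "yule", nTips = 12L)
    gt <- simulateGenealogy(cfg, refA)
    calls <- tipCallSets(gt@tree)
    bm <- encodeBinary(calls, refA)
    net <- reducedMedianNetwork(bm)
    expect_true(all(bm@taxa$key %in% rownames(net@states)))
    g <- asIgraph(net)
    deg <- igraph::degree(g)
    expect_true(all(deg[!net@observed] >= 2L))
    expect_error(validObject(net), NA)
})

test_that("simulated topologies are recovered from sequence data", {
    nwk <- "(((a:1,b:1):1,(c:1.5,d:0.5):1):1,(e:1,f:1):2);"
    cfg <- simulationConfig(seed = 5L, topology = "newick", newick = nwk,
                            nTips = 6L, tmrcaYears = 40000)
    gt <- simulateGenealogy(cfg, refA)
    em <- emitSequences(gt, refA)
    calls <- lapply(em$sequences, callVariants, ref = refA)
    bm <- encodeBinary(calls, refA)
    net <- reducedMedianNetwork(bm)
    mt <- extractTree(net)
    expect_equal(parsimonyScore(mt), parsimonyScore(gt@tree))
    # same unrooted topology on the shared tips
    skip_if_not_installed("phangorn")
    t1 <- ape::unroot(asPhylo(mt))
    t2 <- ape::unroot(asPhylo(gt@tree))
    t1 <- ape::keep.tip(t1, intersect(t1$tip.label, t2$tip.label))
    t2 <- ape::keep.tip(t2, t1$tip.label)
    expect_equal(phangorn::RF.dist(t1, t2), 0)
})

test_that("forced edges appear in the tree at no better score", {
    mat <- rbind(A = c(0, 0), B = c(0, 1), C = c(1, 0), D = c(1, 1))
    bm <- binaryInstance(mat, multiplicity = c(3, 2, 2, 1))
    net <- reducedMedianNetwork(bm, r = 2)
    free <- extractTree(net, root = "A")
    e <- net@edges
    inTree <- function(mt, from, to) {
        for (i in seq_along(mt@nodeId)[-1]) {
            p <- mt@nodeId[mt@parent[i]]; c2 <- mt@nodeId[i]
            if ((p == from && c2 == to) || (p == to && c2 == from))
                return(TRUE)
        }
        FALSE
    }
    missingEdge <- NULL
    for (i in seq_len(nrow(e)))
        if (!inTree(free, e$from[i], e$to[i])) {
            missingEdge <- e[i, ]; break
        }
    forced <- extractTree(net, root = "A",
                          forceEdges = missingEdge[, c("from", "to")])
    expect_true(inTree(forced, missingEdge$from, missingEdge$to))
    expect_gte(parsimonyScore(forced), parsimonyScore(free))
})

test_that("network and tree exports are written and read back", {
    mat <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(1, 1, 0),
                 D = c(1, 1, 1))
    bm <- binaryInstance(mat)
    net <- reducedMedianNetwork(bm)
    gp <- tempfile(fileext = ".graphml")
    writeGraphML(net, gp)
    g <- igraph::read_graph(gp, format = "graphml")
    expect_equal(igraph::vcount(g), nrow(net@states))
    mt <- extractTree(net, root = "A")
    np <- tempfile(fileext = ".nwk")
    writeNewickTree(mt, np)
    mt2 <- readNewickTree(np, refA)
    expect_equal(parsimonyScore(mt2), parsimonyScore(mt))
    f <- classFilter("all", refA)
    expect_equal(unname(rhoStatistic(mt2, f)["rho"]),
                 unname(rhoStatistic(mt, f)["rho"]))
})

test_that("outgroup attachment ambiguity is reported with candidates", {
    # B and C are both one step from the (absent) all-reference vector
    mat <- rbind(B = c(0, 1), C = c(1, 0), D = c(1, 1))
    bm <- binaryInstance(mat)
    net <- reducedMedianNetwork(bm)
    expect_error(extractTree(net), "multiple")
    # an explicit root resolves it
    mt <- extractTree(net, root = "B")
    expect_equal(mt@nodeId[1], "B")
})
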
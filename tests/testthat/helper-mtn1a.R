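# Shared fixtures (built once per test run) and independent oracles.

refA <- rCRSAnnotation()
cladeTreeA <- suppressWarnings(loadCladeTree(ref = refA))
table1Path <- system.file("extdata", "table1_n1a.tsv", package = "mtN1a")
table1 <- readHaplotypeTable(table1Path, refA)
table1Raw <- utils::read.delim(table1Path, colClasses = "character")

classifyFixture <- local({
    memo <- NULL
    function() {
        if (is.null(memo))
            memo <<- suppressMessages(
                classifyTable(table1, cladeTreeA, "near", quiet = TRUE))
        memo
    }
})

# convenience: transition calls at absolute positions
transCallsAt <- function(positions, ref = refA) {
    if (!length(positions)) return(mtN1a:::emptyCalls())
    rb <- refBase(ref, positions)
    data.frame(position = as.integer(positions), ref = rb,
               event = "transition", derived = transitionPartner(rb),
               back = FALSE, stringsAsFactors = FALSE)
}

# independent oracle: rho/sigma recomputed by explicit path enumeration
# over the tree slots (never through rhoStatistic / sigmaSaillard)
oracleRhoSigma <- function(tree, filter = NULL) {
    n <- length(tree@nodeId)
    cnt <- vapply(tree@edgeCalls, function(cc) {
        if (is.null(cc) || !nrow(cc)) 0
        else if (is.null(filter)) nrow(cc) else sum(filter(cc))
    }, numeric(1))
    pathTo <- function(i) {
        p <- integer(0)
        while (i > 0L) { p <- c(p, i); i <- tree@parent[i] }
        p
    }
    w <- ifelse(tree@sampled, tree@multiplicity, 0)
    tot <- sum(w)
    paths <- vapply(seq_len(n), function(i) sum(cnt[setdiff(pathTo(i), 1L)]),
                    numeric(1))
    rho <- sum(w * paths) / tot
    # sigma: per edge, fraction of sampled mtDNAs below
    below <- w
    for (i in rev(seq_len(n)[-1]))
        below[tree@parent[i]] <- below[tree@parent[i]] + below[i]
    sg <- sqrt(sum(vapply(seq_len(n)[-1], function(i)
        (below[i] / tot)^2 * cnt[i], numeric(1))))
    c(rho = rho, sigma = sg)
}

# exhaustive maximum-parsimony oracle via phangorn (independent of the
# network code); exact for <= 8 taxa, ratchet search above
oracleParsimonyMin <- function(mat) {
    skip_if_not_installed("phangorn")
    stopifnot(nrow(mat) >= 3L)
    dat <- phangorn::phyDat(mat, type = "USER", levels = c(0L, 1L))
    if (nrow(mat) <= 8L) {
        trees <- phangorn::allTrees(nrow(mat), rooted = FALSE,
                                    tip.label = rownames(mat))
        min(vapply(trees, phangorn::parsimony, numeric(1), data = dat))
    } else {
        tr <- suppressMessages(phangorn::pratchet(dat, trace = 0L,
                                                  minit = 50L))
        if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
        phangorn::parsimony(tr, dat)
    }
}

# build a BinaryMatrix instance directly from a 0/1 matrix (positions are
# arbitrary distinct HVS-I sites)
binaryInstance <- function(mat, multiplicity = NULL, ref = refA) {
    pos <- 16090L + 2L * seq_len(ncol(mat))
    calls <- lapply(seq_len(nrow(mat)), function(i)
        transCallsAt(pos[mat[i, ] == 1L], ref))
    names(calls) <- rownames(mat)
    encodeBinary(calls, ref, multiplicity = multiplicity)
}
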
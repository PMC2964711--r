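test_that("identical seeds give byte-identical outputs", {
    cfg <- simulationConfig(seed = 9L, nTips = 5L,
                            cladePlan = c(N1a1a1a = 3L))
    f1 <- tempfile(); f2 <- tempfile()
    t1 <- tempfile(); t2 <- tempfile()
    emitSequences(simulateGenealogy(cfg, refA), refA, f1, t1)
    emitSequences(simulateGenealogy(cfg, refA), refA, f2, t2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(readLines(t1), readLines(t2))
    m1 <- tempfile(); m2 <- tempfile()
    emitMotifTable(cfg, cladeTreeA, refA, m1)
    emitMotifTable(cfg, cladeTreeA, refA, m2)
    expect_identical(readLines(m1), readLines(m2))
})

test_that("zero TMRCA plants no mutations and emits reference sequences", {
    cfg <- simulationConfig(seed = 2L, tmrcaYears = 0, nTips = 3L)
    gt <- simulateGenealogy(cfg, refA)
    expect_equal(parsimonyScore(gt@tree), 0)
    em <- emitSequences(gt, refA)
    expect_true(all(em$sequences == refA@sequence))
    expect_equal(nrow(em$truth), 0L)
})

test_that("per-class planted counts match Poisson expectations within 3 SE", {
    reps <- 300L
    counts <- matrix(0, reps, 3,
                     dimnames = list(NULL, c("control",
                                             "synonymous_transition",
                                             "coding_substitution")))
    for (r in seq_len(reps)) {
        cfg <- simulationConfig(seed = 5000L + r, topology = "star",
                                nTips = 2L)
        gt <- simulateGenealogy(cfg, refA)
        cc <- do.call(rbind, gt@tree@edgeCalls)
        counts[r, "control"] <- sum(cc$class == "control")
        counts[r, "synonymous_transition"] <-
            sum(cc$class == "synonymous_transition")
        counts[r, "coding_substitution"] <-
            sum(!cc$class %in% c("control", "synonymous_transition"))
    }
    cfg <- simulationConfig()
    for (k in colnames(counts)) {
        lambda <- 2 * cfg$tmrcaYears / cfg$rates[[k]]  # 2 lineages
        se <- sqrt(lambda / reps)
        expect_lt(abs(mean(counts[, k]) - lambda), 3 * se,
                  label = paste("class", k))
    }
})

test_that("a fixed 19-tip genealogy reproduces its clade sizes", {
    sub <- function(n, tag)
        paste0("(", paste0(tag, seq_len(n), ":1", collapse = ","), "):1")
    nwk <- paste0("(", sub(10, "a"), ",", sub(3, "b"), ",(",
                  sub(4, "c"), ",", sub(2, "d"), "):1);")
    cfg <- simulationConfig(seed = 8L, topology = "newick", newick = nwk,
                            nTips = 19L)
    gt <- simulateGenealogy(cfg, refA)
    expect_equal(nSampled(gt@tree), 19)
    tips <- gt@tree@nodeId[gt@tree@sampled]
    expect_equal(sum(startsWith(tips, "a")), 10L)
    expect_equal(sum(startsWith(tips, "b")), 3L)
    expect_equal(sum(startsWith(tips, "c")), 4L)
})

test_that("emitted FASTA round-trips through variant calling and has full-length records", {
    cfg <- simulationConfig(seed = 12L, topology = "yule", nTips = 7L)
    gt <- simulateGenealogy(cfg, refA)
    fa <- tempfile(fileext = ".fa")
    emitSequences(gt, refA, fa)
    seqs <- Biostrings::readDNAStringSet(fa)
    expect_equal(length(seqs), 7L)
    expect_true(all(Biostrings::width(seqs) == 16569L))
    calls <- callVariantsFasta(fa, refA)
    truth <- tipCallSets(gt@tree)
    for (id in names(truth))
        expect_identical(calls[[id]]$position, truth[[id]]$position)
})

test_that("motif-table emission respects the plan and the classifier recovers it", {
    cfg <- simulationConfig(seed = 6L, cladePlan = c(N1a1a1a = 42L))
    tf <- tempfile(fileext = ".tsv")
    out <- emitMotifTable(cfg, cladeTreeA, refA, tf)
    expect_equal(nrow(out), 42L)
    haps <- readHaplotypeTable(tf, refA)
    res <- suppressMessages(classifyTable(haps, cladeTreeA, quiet = TRUE))
    expect_true(all(res$assigned == "N1a1a1a"))

    emptyP <- simulationConfig(seed = 6L, cladePlan = integer(0))
    tf2 <- tempfile(fileext = ".tsv")
    emitMotifTable(emptyP, cladeTreeA, refA, tf2)
    expect_equal(length(readHaplotypeTable(tf2, refA)), 0L)

    expect_error(emitMotifTable(
        simulationConfig(seed = 1L, cladePlan = c(Nxx = 2L)),
        cladeTreeA, refA), "unknown clade")
})

test_that("the full pipeline recovers the TMRCA within rho +/- 2 sigma in >= 93% of replicates", {
    reps <- 400L
    hits <- 0L
    for (r in seq_len(reps)) {
        cfg <- simulationConfig(seed = 9000L + r, topology = "star",
                                nTips = 19L)
        gt <- simulateGenealogy(cfg, refA)
        em <- emitSequences(gt, refA)
        calls <- lapply(em$sequences, callVariants, ref = refA)
        bm <- encodeBinary(calls, refA)
        net <- reducedMedianNetwork(bm)
        mt <- extractTree(net)
        f <- classFilter("synonymous_transition", refA)
        rho <- rhoStatistic(mt, f)["rho"]
        sg <- sigmaSaillard(mt, f)
        rate <- impliedYearsPerMutation(cfg, "synonymous_transition")
        est <- rho * rate
        half <- 2 * sg * rate
        if (abs(est - cfg$tmrcaYears) <= half) hits <- hits + 1L
    }
    expect_gte(hits / reps, 0.93)
})
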
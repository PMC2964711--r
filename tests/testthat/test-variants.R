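test_that("identity and single-substitution calls", {
    expect_equal(nrow(callVariants(refA@sequence, refA)), 0L)
    s <- refA@sequence
    rb <- substr(s, 5000, 5000)
    substr(s, 5000, 5000) <- transitionPartner(rb)
    v <- callVariants(s, refA)
    expect_equal(v$position, 5000L)
    expect_equal(v$event, "transition")
})

test_that("alphabet and length preconditions are enforced", {
    s <- refA@sequence
    substr(s, 10, 10) <- "X"
    expect_error(callVariants(s, refA), "non-nucleotide")
    expect_error(callVariants(substr(refA@sequence, 1, 16000), refA),
                 "length")
    # N bases are treated as unknown, not as variants
    s2 <- refA@sequence
    substr(s2, 777, 777) <- "N"
    expect_equal(nrow(callVariants(s2, refA)), 0L)
})

test_that("indels are right-shifted to the 3' end of homopolymer runs", {
    seqc <- strsplit(refA@sequence, "")[[1]]
    r <- rle(seqc)
    ends <- cumsum(r$lengths)
    run <- which(r$lengths >= 3L & ends > 1000L & ends < 16000L)[1]
    st <- ends[run] - r$lengths[run] + 1L
    # delete the FIRST base of the run: the call must sit at its 3' end
    s <- paste0(substr(refA@sequence, 1, st - 1L),
                substr(refA@sequence, st + 1L, 16569L))
    v <- callVariants(s, refA)
    expect_equal(v$event, "deletion")
    expect_equal(v$position, ends[run])
    # insert an extra copy at the START of the run: same 3' placement
    s2 <- paste0(substr(refA@sequence, 1, st - 1L), r$values[run],
                 substr(refA@sequence, st, 16569L))
    v2 <- callVariants(s2, refA)
    expect_equal(v2$event, "insertion")
    expect_equal(v2$position, ends[run])
    expect_equal(v2$derived, r$values[run])
})

test_that("calls at 16519 and tract indels are never emitted", {
    s <- refA@sequence
    substr(s, 16519, 16519) <- transitionPartner(substr(s, 16519, 16519))
    expect_equal(nrow(callVariants(s, refA)), 0L)
})

test_that("apply-then-call is the identity on 1000 seeded random cases", {
    set.seed(4242)
    legal <- setdiff(seq_len(16569L), refA@excludedSites)
    legal <- legal[!mtN1a:::inPolyCTract(refA, legal)]
    for (case in seq_len(1000L)) {
        k <- sample(1:12, 1)
        pos <- sort(sample(legal, k))
        calls <- transCallsAt(pos)
        # mix in transversions
        tv <- runif(k) < 0.3
        calls$derived[tv] <- vapply(which(tv), function(i) {
            setdiff(c("A", "C", "G", "T"),
                    c(calls$ref[i], calls$derived[i]))[1]
        }, character(1))
        calls$event[tv] <- "transversion"
        got <- callVariants(applyMutations(refA, calls), refA)
        expect_identical(got$position, calls$position)
        expect_identical(got$derived, calls$derived)
        expect_identical(got$event, calls$event)
    }
})

test_that("simulator-planted mutations are recovered exactly", {
    cfg <- simulationConfig(seed = 11L, topology = "star", nTips = 6L)
    gt <- simulateGenealogy(cfg, refA)
    em <- emitSequences(gt, refA)
    truthSets <- tipCallSets(gt@tree)
    for (id in names(truthSets)) {
        got <- callVariants(em$sequences[[id]], refA)
        expect_identical(got$position, truthSets[[id]]$position)
        expect_identical(got$derived, truthSets[[id]]$derived)
    }
})
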
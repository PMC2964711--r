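test_that("positions outside the coding window are control", {
    expect_equal(classifyMutation(parseMotif("147A", "HVS1", refA), refA),
                 "control")
    expect_equal(classifyMutation(parseMotif("73", "HVS2", refA), refA),
                 "control")
})

test_that("codon translation decides synonymy, matching a Biostrings oracle", {
    skip_if_not_installed("Biostrings")
    code <- Biostrings::getGeneticCode("SGC1")
    gm <- refA@geneMap
    oracle <- function(pos, derived, gene) {
        wt <- substr(refA@sequence, gene$start, gene$end)
        s2 <- refA@sequence
        substr(s2, pos, pos) <- derived
        mu <- substr(s2, gene$start, gene$end)
        if (gene$strand == "-") {
            wt <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(wt)))
            mu <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(mu)))
        }
        trim <- 3L * (nchar(wt) %/% 3L)
        aaW <- Biostrings::translate(
            Biostrings::DNAString(substr(wt, 1, trim)),
            genetic.code = code, no.init.codon = TRUE)
        aaM <- Biostrings::translate(
            Biostrings::DNAString(substr(mu, 1, trim)),
            genetic.code = code, no.init.codon = TRUE)
        as.character(aaW) == as.character(aaM)
    }
    set.seed(31)
    genes <- gm[gm$gene %in% c("ND1", "CO1", "ND5", "ND6", "CYB"), ]
    for (g in seq_len(nrow(genes))) {
        gene <- genes[g, ]
        for (pos in sample(gene$start:(gene$end - 3L), 20L)) {
            # only positions in a single protein gene (no overlap caveats)
            inProt <- gm[gm$type == "protein" & gm$start <= pos &
                         gm$end >= pos, ]
            if (nrow(inProt) != 1L) next
            der <- transitionPartner(refBase(refA, pos))
            got <- classifyMutation(data.frame(
                position = pos, ref = refBase(refA, pos),
                event = "transition", derived = der, back = FALSE), refA)
            syn <- oracle(pos, der, gene)
            if (got %in% c("synonymous_transition", "nonsynonymous"))
                expect_equal(got == "synonymous_transition", syn,
                             label = paste("position", pos))
        }
    }
    # 3336 sits in ND1: a coding substitution either way
    got3336 <- classifyMutation(parseMotif("3336", "coding", refA), refA)
    expect_true(got3336 %in% c("synonymous_transition", "nonsynonymous",
                               "other"))
    nd1 <- gm[gm$gene == "ND1", ]
    expect_true(nd1$start <= 3336 && 3336 <= nd1$end)
})

test_that("overlapping genes require synonymy in every frame", {
    gm <- refA@geneMap
    overlap <- 8527:8572  # ATP8/ATP6 dual-frame window
    syn <- synonymousTransitionSites(refA)
    code <- Biostrings::getGeneticCode("SGC1")
    for (pos in overlap) {
        inSyn <- pos %in% syn
        prot <- gm[gm$type == "protein" & gm$start <= pos & gm$end >= pos, ]
        expect_equal(nrow(prot), 2L)
        each <- vapply(seq_len(nrow(prot)), function(j) {
            r <- mtN1a:::codonEffect(pos,
                                     transitionPartner(refBase(refA, pos)),
                                     prot[j, ], refA, code)
            isTRUE(r)
        }, logical(1))
        expect_equal(inSyn, all(each), label = paste("position", pos))
    }
})

test_that("rna, indel and unannotated positions are classed correctly", {
    expect_equal(classifyMutation(transCallsAt(1000L), refA), "rna")
    ins <- data.frame(position = 6000L, ref = refBase(refA, 6000L),
                      event = "insertion", derived = "A", back = FALSE)
    expect_equal(classifyMutation(ins, refA), "indel")
    # 3305-3306 sit between TRNL1 and ND1 in the standard map
    expect_message(
        got <- classifyMutation(transCallsAt(3305L), refA),
        "no annotated feature")
    expect_equal(got, "other")
})

test_that("simulated mutation classes agree with the classifier", {
    cfg <- simulationConfig(seed = 77L, nTips = 4L)
    gt <- simulateGenealogy(cfg, refA)
    for (cc in gt@tree@edgeCalls) {
        if (!nrow(cc)) next
        expect_equal(cc$class, classifyMutation(cc, refA))
    }
})
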
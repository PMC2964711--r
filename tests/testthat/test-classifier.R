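test_that("reference haplotypes assign to their published subclades", {
    cases <- list(
        list(hvs1 = "147G-172-223-248-355", hvs2 = NULL, clade = "N1a"),
        list(hvs1 = "147A-172-223-248-320-355", hvs2 = NULL,
             clade = "N1a1a1"),
        list(hvs1 = "147A-172-223-248-355", hvs2 = NULL, clade = "N1a1b"),
        list(hvs1 = "86-147A-223-248-320-355", hvs2 = "152-199-204-207",
             clade = "N1a1a2"),
        list(hvs1 = "147A-154-172-223-320-355", hvs2 = NULL,
             clade = "N1a1a3"),
        list(hvs1 = "147A-172-189-223-248-320-355", hvs2 = NULL,
             clade = "N1a1a1a"))
    for (cs in cases) {
        h <- haplotypeFromMotifs(cs$hvs1, cs$hvs2, ref = refA)
        a <- assignClade(h, cladeTreeA, "near")
        expect_equal(a$clade, cs$clade,
                     label = paste("near assignment of", cs$hvs1))
    }
})

test_that("strict mode demands a perfect visible profile", {
    exact <- assignClade(haplotypeFromMotifs("147G-172-223-248-355",
                                             ref = refA),
                         cladeTreeA, "strict")
    expect_equal(exact$clade, "N1a")
    expect_equal(exact$status, "exact")
    nearOnly <- assignClade(haplotypeFromMotifs("172-223-248-320-355",
                                                ref = refA),
                            cladeTreeA, "strict")
    expect_equal(nearOnly$status, "unassigned")
})

test_that("classifying the packaged survey reproduces recorded labels", {
    res <- classifyFixture()
    expect_gte(concordance(res), 0.95)
    expect_equal(nrow(res), 115L)
    single <- suppressMessages(classifyTable(
        newSet <- local({
            p <- tempfile(fileext = ".tsv")
            utils::write.table(table1Raw[1, ], p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            readHaplotypeTable(p, refA)
        }), cladeTreeA, quiet = TRUE))
    expect_true(concordance(single) %in% c(0, 1))
})

test_that("planted clade profiles are recovered in near mode", {
    # clades indistinguishable from HVS-only data collapse to one class:
    # N1a1a's visible profile equals N1a1a1's (whose diagnostics are all
    # coding), and N1a1's equals N1a1b's (defined by the absence of 16320)
    equivalent <- list(N1a1a = "N1a1a1", N1a1 = "N1a1b")
    clades <- setdiff(cladeNames(cladeTreeA), "N")
    for (cl in clades) {
        cfg <- simulationConfig(seed = 100L + match(cl, clades),
                                cladePlan = stats::setNames(100L, cl))
        tf <- tempfile(fileext = ".tsv")
        emitMotifTable(cfg, cladeTreeA, refA, tf)
        haps <- readHaplotypeTable(tf, refA)
        res <- suppressMessages(classifyTable(haps, cladeTreeA,
                                              quiet = TRUE))
        want <- c(cl, equivalent[[cl]])
        expect_true(all(res$assigned %in% want),
                    label = paste("recovery of", cl, "->",
                                  paste(unique(res$assigned),
                                        collapse = ",")))
    }
})

test_that("adding a child's diagnostics never moves the assignment to a non-descendant", {
    cl <- cladeTreeA@clades
    for (i in which(cl$depth > 0L)) {
        child <- cl$name[i]
        parent <- cl$parent[i]
        if (parent == "N") next
        profP <- cladeTreeA@profiles[[parent]]
        profC <- cladeTreeA@profiles[[child]]
        mk <- function(prof) {
            ex <- prof$expect[prof$expect$segment == "HVS1", ]
            list(hvs1 = data.frame(position = ex$position,
                                   ref = refBase(refA, ex$position),
                                   event = ex$event, derived = ex$derived,
                                   back = FALSE, stringsAsFactors = FALSE),
                 hvs2 = NULL, coding = NULL)
        }
        # compare modulo the HVS-indistinguishable pairs (N1a1 ~ N1a1b,
        # N1a1a ~ N1a1a1): deeper members are chosen by the tie-break
        canon <- c(N1a1b = "N1a1", N1a1a1 = "N1a1a")
        cn <- function(x) if (x %in% names(canon)) canon[[x]] else x
        aP <- cn(assignClade(mk(profP), cladeTreeA)$clade)
        aC <- cn(assignClade(mk(profC), cladeTreeA)$clade)
        expect_true(aC %in% descendantClades(cladeTreeA, aP) ||
                    aP %in% descendantClades(cladeTreeA, aC),
                    label = paste(parent, "->", child, ":", aP, "->", aC))
    }
})

test_that("unassignable haplotypes fall back to the root with status unassigned", {
    a <- assignClade(haplotypeFromMotifs("69-91-126", ref = refA),
                     cladeTreeA)
    expect_equal(a$status, "unassigned")
})
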
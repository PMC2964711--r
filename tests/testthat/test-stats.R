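test_that("chi-square matches closed forms and is permutation-invariant", {
    tab <- matrix(c(10, 0, 0, 10), 2, 2)
    het <- chiSquareHeterogeneity(tab)
    expect_equal(het$chi2, 20)
    expect_equal(het$df, 1L)
    uni <- suppressWarnings(
        chiSquareHeterogeneity(matrix(c(5, 5, 5, 5), 2, 2)))
    expect_equal(uni$chi2, 0)
    expect_equal(uni$p, 1)
    tab3 <- matrix(c(8, 2, 4, 5, 9, 3), 2, 3)
    a <- suppressWarnings(chiSquareHeterogeneity(tab3))
    b <- suppressWarnings(chiSquareHeterogeneity(tab3[, c(3, 1, 2)]))
    cc <- suppressWarnings(chiSquareHeterogeneity(tab3[c(2, 1), ]))
    expect_equal(a$chi2, b$chi2)
    expect_equal(a$chi2, cc$chi2)
    expect_error(chiSquareHeterogeneity(matrix(1:3, 1)), "2 x 2")
})

test_that("the analytic p agrees with a Monte-Carlo null when counts are healthy", {
    set.seed(818)
    for (case in 1:4) {
        tab <- matrix(rpois(6, 30) + 10, 2, 3)
        het <- chiSquareHeterogeneity(tab)
        mc <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 10000)
        expect_lt(abs(het$p - mc$p.value), 0.01)
    }
})

test_that("the N1a1a1a haplotype-by-origin table has the published size", {
    res <- classifyFixture()
    tab <- suppressWarnings(
        buildContingencyTable(table1, res, "N1a1a1a", ref = refA))
    expect_equal(sum(tab), 42L)
    expect_equal(nrow(tab), 10L)  # distinct HVS-I haplotypes
    expect_equal(ncol(tab), 10L)  # origin groups under the default map
})

test_that("frequency reports sum to one within clades and respect totals", {
    res <- classifyFixture()
    rep <- cladeFrequencyReport(res)
    sums <- tapply(rep$fraction, rep$clade, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_equal(sum(rep$count), 166)
    n1 <- rep[rep$clade %in% c("N1a1a1", "N1a1a1a"), ]
    expect_equal(sum(n1$count), 82)
    # single-region input: all fractions are 1
    one <- res[res$population == "Setoland", , drop = FALSE]
    r1 <- cladeFrequencyReport(one)
    expect_true(all(r1$fraction == 1))
})

test_that("frequencies are invariant to row order and row splitting", {
    res <- classifyFixture()
    shuffled <- res[sample(nrow(res)), ]
    a <- cladeFrequencyReport(res)
    b <- cladeFrequencyReport(shuffled)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
    # splitting one row into two with the same keys leaves counts intact
    split1 <- res
    i <- which(split1$n > 1)[1]
    extra <- split1[i, ]; extra$n <- 1L
    split1$n[i] <- split1$n[i] - 1L
    cc <- cladeFrequencyReport(rbind(split1, extra))
    rownames(cc) <- NULL
    expect_equal(a$count, cc$count)
})

test_that("empty clade selections are errors", {
    res <- classifyFixture()
    expect_error(buildContingencyTable(table1, res, "Nxx", ref = refA),
                 "no records")
})
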
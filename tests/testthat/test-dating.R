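# a small hand-built tree used across the dating tests:
# root - A (1 mutation), A subtends tips 1 (1 more) and 2 (0 more);
# root - tip3 (2 mutations); root - tip4 (0 mutations)
fiveEdgeTree <- function() {
    mutationTree(
        nodeId = c("root", "A", "t1", "t2", "t3", "t4"),
        parent = c(0L, 1L, 2L, 2L, 1L, 1L),
        edgeCalls = list(transCallsAt(integer(0)),
                         transCallsAt(16111L),
                         transCallsAt(16113L),
                         transCallsAt(integer(0)),
                         transCallsAt(c(16115L, 16117L)),
                         transCallsAt(integer(0))),
        sampled = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
        multiplicity = c(0, 0, 1, 1, 1, 1))
}

starTree <- function(k = 4L, mutsPerTip = 1L) {
    calls <- c(list(transCallsAt(integer(0))),
               lapply(seq_len(k), function(i)
                   transCallsAt(16100L + 2L * seq_len(mutsPerTip) +
                                20L * i)))
    mutationTree(nodeId = c("root", paste0("t", seq_len(k))),
                 parent = c(0L, rep(1L, k)), edgeCalls = calls)
}

test_that("rho matches direct path enumeration", {
    expect_equal(unname(rhoStatistic(starTree(4L, 1L))["rho"]), 1.0)
    tr <- fiveEdgeTree()
    expect_equal(unname(rhoStatistic(tr)["rho"]), 1.25)
    expect_equal(unname(rhoStatistic(tr)["n"]), 4)
    # all tips identical to root
    tr0 <- starTree(3L, 0L)
    expect_equal(unname(rhoStatistic(tr0)["rho"]), 0)
    expect_error(rhoStatistic(mutationTree(character(0), integer(0),
                                           list())), "empty")
})

test_that("sigma follows the Saillard edge formula", {
    expect_equal(sigmaSaillard(starTree(4L, 1L)), 0.5)
    expect_equal(sigmaSaillard(fiveEdgeTree()), sqrt(0.4375))
    expect_equal(sigmaSaillard(starTree(4L, 0L)), 0)
})

test_that("rho and sigma equal brute-force recomputation on simulated trees", {
    for (seed in c(2L, 13L, 44L)) {
        cfg <- simulationConfig(seed = seed, topology = "yule",
                                nTips = 9L)
        gt <- simulateGenealogy(cfg, refA)
        for (cl in c("all", "synonymous_transition")) {
            f <- classFilter(cl, refA)
            want <- oracleRhoSigma(gt@tree, f)
            expect_equal(unname(rhoStatistic(gt@tree, f)["rho"]),
                         unname(want["rho"]))
            expect_equal(sigmaSaillard(gt@tree, f),
                         unname(want["sigma"]))
        }
    }
})

test_that("rho +/- 2 sigma covers the true expectation in >= 93% of star replicates", {
    cfg0 <- simulationConfig(seed = 1L)
    muT <- cfg0$tmrcaYears / impliedYearsPerMutation(cfg0,
                                                     "synonymous_transition")
    set.seed(20260923)
    hits <- 0L
    reps <- 1000L
    n <- cfg0$nTips
    for (r in seq_len(reps)) {
        k <- stats::rpois(n, muT)   # star genealogy: iid Poisson per lineage
        rho <- mean(k)
        sigma <- sqrt(sum(k)) / n
        if (abs(rho - muT) <= 2 * sigma) hits <- hits + 1L
    }
    expect_gte(hits / reps, 0.93)
})

test_that("ages are exact multiples of the calibration rate", {
    cal <- data.frame(label = c("a", "syn"),
                      class = c("coding_substitution",
                                "synonymous_transition"),
                      years_per_mutation = c(5140, 6764),
                      citation = "")
    tr <- starTree(4L, 1L)   # rho 1, sigma 0.5; sites are control region
    # relabel the star's mutations as coding by moving them there
    coding <- mutationTree(
        nodeId = tr@nodeId, parent = tr@parent,
        edgeCalls = lapply(tr@edgeCalls, function(cc) {
            if (!nrow(cc)) return(cc)
            transCallsAt(cc$position - 16100L + 5000L)
        }),
        sampled = tr@sampled, multiplicity = tr@multiplicity)
    ages <- suppressWarnings(estimateAges(list(X = coding), cal, refA))
    a <- ages[ages$calibration == "a", ]
    expect_equal(a$ageYears, 1.0 * 5140)
    expect_equal(a$ageSEYears, 0.5 * 5140)
    # doubling the rate doubles the age exactly
    cal2 <- cal; cal2$years_per_mutation <- cal$years_per_mutation * 2
    ages2 <- suppressWarnings(estimateAges(list(X = coding), cal2, refA))
    expect_equal(ages2$ageYears, ages$ageYears * 2)
    expect_equal(ages2$ageSEYears, ages$ageSEYears * 2)
})

test_that("clades with no qualifying mutations age to 0 +/- 0 with a warning", {
    tr <- starTree(3L, 1L)  # control-region mutations only
    warns <- capture_warnings(
        ages <- estimateAges(list(X = tr), defaultCalibrations(), refA))
    expect_true(any(grepl("no qualifying", warns)))
    expect_true(all(ages$ageYears == 0))
    expect_true(all(ages$ageSEYears == 0))
})

test_that("the default calibration table is internally consistent", {
    cal <- defaultCalibrations()
    expect_equal(nrow(cal), 6L)
    expect_setequal(unique(cal$class),
                    c("coding_substitution", "synonymous_transition"))
    expect_true(all(cal$years_per_mutation > 0))
})
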
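panel <- examplePanel()

test_that("log-likelihood is the sum of log genotype probabilities", {
    expect_equal(logLikelihood(SampleProfile("S", c(rs2856838 = "CC")), panel$A),
                 log(0.562))
    expect_identical(logLikelihood(SampleProfile("S"), panel$A), 0)
    expect_equal(logLikelihood(SampleProfile("S", c(rs2856838 = "CC", rs8193036 = "TT")),
                               panel$A),
                 log(0.562) + log(0.089))
    # equals direct-product arithmetic on a small case
    pr <- SampleProfile("S", c(rs2856838 = "CT", rs20541 = "TT", rs741344 = "AG"))
    expect_equal(exp(logLikelihood(pr, panel$A)), 0.379 * 0.097 * 0.465,
                 tolerance = 1e-9)
})

test_that("missing and unmodelled markers are skipped, bad genotypes error", {
    pr <- SampleProfile("S", c(rs2856838 = "CC", rs20541 = NA, rsX = "AA"))
    r <- classifyLikelihoodRatio(pr, panel$A, panel$B)
    expect_identical(nMarkersUsed(r), 1L)
    expect_identical(nMarkersSkipped(r), 2L)
    expect_error(
        logLikelihood(SampleProfile("S", c(rs2856838 = "AG")), panel$A),
        "inconsistent")
})

test_that("likelihood-ratio rule assigns by L(A)/L(B) > 1 with ties to B", {
    rCC <- classifyLikelihoodRatio(SampleProfile("S", c(rs2856838 = "CC")),
                                   panel$A, panel$B)
    expect_identical(assignedLabel(rCC), "A")
    expect_equal(exp(logRatio(rCC)), 0.562 / 0.460, tolerance = 1e-9)

    rTT <- classifyLikelihoodRatio(SampleProfile("S", c(rs2856838 = "TT")),
                                   panel$A, panel$B)
    expect_identical(assignedLabel(rTT), "B")
    expect_equal(exp(logRatio(rTT)), 0.059 / 0.141, tolerance = 1e-9)

    # identical models: every profile ties, and ties go to B
    A2 <- makeModel("A", list(rs1 = c(0.2, 0.5, 0.3)))
    B2 <- makeModel("B", list(rs1 = c(0.2, 0.5, 0.3)))
    r <- classifyLikelihoodRatio(SampleProfile("S", c(rs1 = "CT")), A2, B2)
    expect_identical(logRatio(r), 0)
    expect_identical(assignedLabel(r), "B")
})

test_that("a marker modelled in only one population is an error", {
    A2 <- makeModel("A", list(rs1 = c(0.2, 0.5, 0.3), rs2 = c(0.3, 0.3, 0.4)))
    B2 <- makeModel("B", list(rs1 = c(0.2, 0.5, 0.3)))
    expect_error(
        classifyLikelihoodRatio(SampleProfile("S", c(rs2 = "CC")), A2, B2),
        "rs2")
})

test_that("expected-count rule weights likelihoods by population size", {
    withN <- function(m, n) PopulationModel(populationLabel(m), markers(m),
                                            distributions(m), sizeN = n)
    pr <- SampleProfile("S", c(rs2856838 = "CC"))

    # equal sizes reduce exactly to the likelihood-ratio rule
    r1 <- classifyExpectedCounts(pr, withN(panel$A, 1000), withN(panel$B, 1000))
    expect_identical(assignedLabel(r1),
                     assignedLabel(classifyLikelihoodRatio(pr, panel$A, panel$B)))

    # E(A)/E(B) = (100 x 0.562)/(900 x 0.460) < 1: sizes overturn the LR label
    r2 <- classifyExpectedCounts(pr, withN(panel$A, 100), withN(panel$B, 900))
    expect_identical(assignedLabel(r2), "B")
    expect_gt(logRatio(r2), 0)  # logRatio stays the unweighted log L(A)/L(B)

    # empty profile: only the sizes decide
    r3 <- classifyExpectedCounts(SampleProfile("S"), withN(panel$A, 2),
                                 withN(panel$B, 1))
    expect_identical(assignedLabel(r3), "A")

    noSize <- PopulationModel("A", markers(panel$A), distributions(panel$A))
    expect_error(classifyExpectedCounts(pr, noSize, withN(panel$B, 10)),
                 "sizeN")
})

test_that("equal-size expected-count rule agrees with LR on random profiles", {
    set.seed(21)
    mp <- randomModelPair(4)
    A <- PopulationModel("A", markers(mp$A), distributions(mp$A), sizeN = 77)
    B <- PopulationModel("B", markers(mp$B), distributions(mp$B), sizeN = 77)
    ds <- simulateProfiles(mp$A, n = 100, seed = 99)
    for (i in seq_len(100)) {
        pr <- profileAt(ds, i)
        expect_identical(assignedLabel(classifyExpectedCounts(pr, A, B)),
                         assignedLabel(classifyLikelihoodRatio(pr, mp$A, mp$B)))
    }
})

test_that("labels are invariant to marker order within a profile", {
    set.seed(22)
    mp <- randomModelPair(5)
    ds <- simulateProfiles(mp$A, n = 30, seed = 7)
    for (i in seq_len(30)) {
        cl <- calls(profileAt(ds, i))
        shuffled <- SampleProfile("S", cl[sample(length(cl))])
        expect_identical(
            assignedLabel(classifyLikelihoodRatio(SampleProfile("S", cl), mp$A, mp$B)),
            assignedLabel(classifyLikelihoodRatio(shuffled, mp$A, mp$B)))
    }
})

test_that("zero floor yields -Inf log-likelihoods with tie-to-B semantics", {
    A2 <- makeModel("A", list(rs1 = c(1, 0, 0)))
    B2 <- makeModel("B", list(rs1 = c(0, 0, 1)))
    cfg <- ClassifierConfig(floor = 0)
    r <- classifyLikelihoodRatio(SampleProfile("S", c(rs1 = "CT")), A2, B2, cfg)
    expect_identical(logLikA(r), -Inf)
    expect_identical(logLikB(r), -Inf)
    expect_identical(assignedLabel(r), "B")
})

test_that("batch classification preserves order and tallies labels", {
    empty <- classifyBatch(list(), panel$A, panel$B)
    expect_identical(nrow(empty$results), 0L)
    expect_identical(unname(empty$tally), c(0L, 0L))

    three <- lapply(1:3, function(i) SampleProfile("S", c(rs2856838 = "CC")))
    r <- classifyBatch(three, panel$A, panel$B)
    expect_identical(r$results$label, rep("A", 3))
    expect_identical(unname(r$tally), c(3L, 0L))

    ds <- simulateTwoPopulationStudy(panel$A, panel$B, 20, 20, seed = 5)
    rb <- classifyBatch(ds, panel$A, panel$B)
    expect_identical(rb$results$sample_id, sampleIds(ds))
    expect_identical(unname(rb$tally),
                     c(sum(rb$results$label == "A"), sum(rb$results$label == "B")))
})
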
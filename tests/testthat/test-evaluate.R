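panel <- examplePanel()

test_that("identical models make every genotype vector a tie to B", {
    A2 <- makeModel("A", list(rs1 = c(0.2, 0.5, 0.3), rs2 = c(0.4, 0.4, 0.2)))
    B2 <- makeModel("B", list(rs1 = c(0.2, 0.5, 0.3), rs2 = c(0.4, 0.4, 0.2)))
    r <- exactAccuracy(A2, B2)
    expect_identical(accuracyUnderA(r), 0)
    expect_equal(accuracyUnderB(r), 1, tolerance = 1e-12)
    expect_equal(balancedAccuracy(r), 0.5, tolerance = 1e-12)
})

test_that("two-marker panel accuracy matches the 9-pair hand enumeration", {
    ids <- c("rs2856838", "rs8193036")
    r <- exactAccuracy(panel$A, panel$B, ids)
    # the four pairs with likelihood ratio > 1 are CC/CC, CC/CT, CT/CC, TT/CC
    handA <- 0.562 * 0.504 + 0.562 * 0.407 + 0.379 * 0.504 + 0.059 * 0.504
    expect_equal(accuracyUnderA(r), handA, tolerance = 1e-9)
    oracle <- enumAccuracyOracle(panel$A, panel$B, ids)
    expect_equal(accuracyUnderA(r), unname(oracle["underA"]), tolerance = 1e-12)
    expect_equal(accuracyUnderB(r), unname(oracle["underB"]), tolerance = 1e-12)
})

test_that("a perfectly separating marker classifies both populations exactly", {
    A2 <- makeModel("A", list(rs1 = c(1, 0, 0)))
    B2 <- makeModel("B", list(rs1 = c(0, 0, 1)))
    r <- exactAccuracy(A2, B2, "rs1")
    expect_equal(accuracyUnderA(r), 1, tolerance = 1e-12)
    expect_equal(accuracyUnderB(r), 1, tolerance = 1e-12)
})

test_that("enumeration conserves probability mass and ignores marker order", {
    set.seed(31)
    for (i in 1:5) {
        mp <- randomModelPair(3)
        r <- exactAccuracy(mp$A, mp$B)
        # mass labelled B under A is the complement of accuracy under A
        massB <- 1 - accuracyUnderA(r)
        expect_equal(accuracyUnderA(r) + massB, 1, tolerance = 1e-12)
        perm <- sample(markerIds(mp$A))
        rp <- exactAccuracy(mp$A, mp$B, perm)
        expect_equal(accuracyUnderA(rp), accuracyUnderA(r), tolerance = 1e-12)
        expect_equal(accuracyUnderB(rp), accuracyUnderB(r), tolerance = 1e-12)
    }
})

test_that("enumeration guard and missing markers are explicit errors", {
    expect_error(exactAccuracy(panel$A, panel$B, character(0)), "at least one")
    expect_error(exactAccuracy(panel$A, panel$B, c(panelOrder(), "rsX")), "rsX")
})

test_that("Monte-Carlo accuracy is deterministic given the seed", {
    ids <- c("rs2856838", "rs8193036")
    r1 <- monteCarloAccuracy(panel$A, panel$B, ids, nSims = 2000, seed = 42)
    r2 <- monteCarloAccuracy(panel$A, panel$B, ids, nSims = 2000, seed = 42)
    expect_identical(accuracyUnderA(r1), accuracyUnderA(r2))
    expect_identical(accuracyUnderB(r1), accuracyUnderB(r2))
    expect_identical(accuracyMethod(r1), "monte_carlo")
})

test_that("Monte-Carlo accuracy converges on the exact value", {
    ids <- c("rs2856838", "rs8193036")
    exact <- exactAccuracy(panel$A, panel$B, ids)
    mc <- monteCarloAccuracy(panel$A, panel$B, ids, nSims = 20000, seed = 7)
    se <- sqrt(accuracyUnderA(exact) * (1 - accuracyUnderA(exact)) / 20000)
    expect_lt(abs(accuracyUnderA(mc) - accuracyUnderA(exact)), 4 * se)
})

test_that("identical models drive Monte-Carlo accuracy under A to zero", {
    A2 <- makeModel("A", list(rs1 = c(0.2, 0.5, 0.3)))
    B2 <- makeModel("B", list(rs1 = c(0.2, 0.5, 0.3)))
    r <- monteCarloAccuracy(A2, B2, "rs1", nSims = 500, seed = 1)
    expect_identical(accuracyUnderA(r), 0)
    expect_identical(accuracyUnderB(r), 1)
})

test_that("nested panels grow by step and full-width equals exactAccuracy", {
    reports <- nestedPanelAccuracies(panel$A, panel$B, panelOrder(), step = 2)
    expect_length(reports, 4)
    expect_identical(vapply(reports, function(r) length(markerIds(r)), integer(1)),
                     c(2L, 4L, 6L, 8L))
    bal <- vapply(reports, balancedAccuracy, numeric(1))
    expect_true(all(diff(bal) >= -1e-12))

    single <- nestedPanelAccuracies(panel$A, panel$B, panelOrder(), step = 8)
    expect_length(single, 1)
    expect_equal(accuracyUnderA(single[[1]]),
                 accuracyUnderA(exactAccuracy(panel$A, panel$B, panelOrder())),
                 tolerance = 1e-12)
})

test_that("accuracyTable flattens reports to one row per panel", {
    tab <- accuracyTable(nestedPanelAccuracies(panel$A, panel$B, panelOrder(),
                                               step = 4))
    expect_identical(tab$n_markers, c(4L, 8L))
    expect_identical(tab$method, rep("exact", 2))
    expect_equal(tab$balanced, (tab$acc_under_A + tab$acc_under_B) / 2)
})
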
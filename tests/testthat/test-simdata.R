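panel <- examplePanel()

test_that("degenerate trinomials always emit the first homozygote", {
    m <- makeModel("A", list(rs1 = c(1, 0, 0), rs2 = c(1, 0, 0)))
    ds <- simulateProfiles(m, n = 50, seed = 1)
    expect_true(all(genotypes(ds) == "CC"))
})

test_that("simulation is byte-identical under the same seed", {
    d1 <- simulateProfiles(panel$A, n = 100, seed = 123, missingRate = 0.1)
    d2 <- simulateProfiles(panel$A, n = 100, seed = 123, missingRate = 0.1)
    expect_identical(genotypes(d1), genotypes(d2))
    s1 <- simulateTwoPopulationStudy(panel$A, panel$B, 30, 20, seed = 9)
    s2 <- simulateTwoPopulationStudy(panel$A, panel$B, 30, 20, seed = 9)
    expect_identical(genotypes(s1), genotypes(s2))
    expect_identical(trueLabels(s1), trueLabels(s2))
})

test_that("simulated genotype proportions track the generating model", {
    n <- 10000
    ds <- simulateProfiles(panel$A, n = n, seed = 2024)
    g <- genotypes(ds)
    for (j in seq_along(panelOrder())) {
        id <- panelOrder()[j]
        cats <- genotypeCategories(markers(panel$A)[[j]])
        p <- probs(distributions(panel$A)[[j]])
        for (k in 1:3) {
            phat <- mean(g[, id] == cats[k])
            se <- sqrt(p[k] * (1 - p[k]) / n)
            expect_lt(abs(phat - p[k]), 3 * se + 1e-12,
                      label = sprintf("%s %s", id, cats[k]))
        }
    }
})

test_that("missingness is applied at the requested rate", {
    rate <- 0.15
    ds <- simulateProfiles(panel$A, n = 2000, seed = 31, missingRate = rate)
    frac <- mean(is.na(genotypes(ds)))
    se <- sqrt(rate * (1 - rate) / length(genotypes(ds)))
    expect_lt(abs(frac - rate), 3 * se)
})

test_that("two-population study labels align with their source model", {
    onlyB <- simulateTwoPopulationStudy(panel$A, panel$B, 0, 10, seed = 4)
    expect_identical(trueLabels(onlyB), rep("B", 10))
    both <- simulateTwoPopulationStudy(panel$A, panel$B, 5, 7, seed = 4)
    expect_identical(trueLabels(both), c(rep("A", 5), rep("B", 7)))
    expect_identical(length(sampleIds(both)), 12L)
})

test_that("model estimation reproduces empirical proportions and add-alpha", {
    g <- matrix(c(rep("CC", 4), rep("CT", 4), rep("TT", 2)), ncol = 1,
                dimnames = list(paste0("S", 1:10), "rs1"))
    m <- estimateModel(GenotypeDataset(g), label = "hat")
    expect_equal(probs(distributions(m)[[1]]), c(0.4, 0.4, 0.2))

    gg <- matrix(rep("GG", 10), ncol = 1,
                 dimnames = list(paste0("S", 1:10), "rs1"))
    tmpl <- list(Marker("rs1", c("A", "G")))
    m2 <- estimateModel(GenotypeDataset(gg), pseudocount = 1, markers = tmpl)
    expect_equal(probs(distributions(m2)[[1]]), c(1, 1, 11) / 13)
    # allele pair is not inferable from a single observed allele
    expect_error(estimateModel(GenotypeDataset(gg)), "allele")

    gNA <- matrix(NA_character_, 3, 1, dimnames = list(paste0("S", 1:3), "rs1"))
    expect_error(estimateModel(GenotypeDataset(gNA), markers = tmpl),
                 "never observed")
})

test_that("estimation recovers the generating frequencies as n grows", {
    n <- 10000
    ds <- simulateProfiles(panel$A, n = n, seed = 77)
    est <- estimateModel(ds, label = "Ahat", markers = markers(panel$A))
    for (j in seq_along(panelOrder())) {
        p <- probs(distributions(panel$A)[[j]])
        phat <- probs(distributions(est)[[j]])
        se <- sqrt(p * (1 - p) / n)
        expect_true(all(abs(phat - p) < 3 * se + 1e-12))
    }
    # round trip preserves MAF within the same binomial bound
    mafTrue <- vapply(distributions(panel$A), minorAlleleFrequency, numeric(1))
    mafHat <- vapply(distributions(est), minorAlleleFrequency, numeric(1))
    expect_true(all(abs(mafTrue - mafHat) < 3 * sqrt(0.25 / n) + 0.005))

    # estimated distributions always satisfy the sum-to-one invariant
    sums <- vapply(distributions(est), function(d) sum(probs(d)), numeric(1))
    expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("missing calls are excluded from the estimation denominator", {
    g <- matrix(c("CC", "CT", NA, "TT", NA), ncol = 1,
                dimnames = list(paste0("S", 1:5), "rs1"))
    m <- estimateModel(GenotypeDataset(g))
    expect_equal(probs(distributions(m)[[1]]), c(1, 1, 1) / 3)
    expect_identical(unname(markerCounts(m)), 3)
})
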
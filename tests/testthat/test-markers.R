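panel <- examplePanel()

test_that("allele frequencies follow p + q/2, r + q/2 and sum to one", {
    # rs2243191 carries alleles T:C, hom-first = TT
    d <- distributions(panel$A)[[match("rs2243191", markerIds(panel$A))]]
    m <- markers(panel$A)[[match("rs2243191", markerIds(panel$A))]]
    f <- alleleFrequencies(d, m)
    expect_equal(unname(f), c(0.724, 0.276), tolerance = 1e-9)
    expect_named(f, c("T", "C"))

    expect_equal(alleleFrequencies(GenotypeDistribution("m", c(1, 0, 0))),
                 c(1, 0))
    expect_equal(alleleFrequencies(GenotypeDistribution("m", c(0.25, 0.5, 0.25))),
                 c(0.5, 0.5))

    set.seed(11)
    for (i in 1:25) {
        f <- alleleFrequencies(GenotypeDistribution("m", randomTriple()))
        expect_equal(sum(f), 1, tolerance = 1e-9)
    }
})

test_that("minor allele frequency is min(f1, f2), zero iff monomorphic", {
    expect_equal(minorAlleleFrequency(GenotypeDistribution("rs20541", c(0.477, 0.426, 0.097))),
                 0.310, tolerance = 1e-9)
    expect_equal(minorAlleleFrequency(GenotypeDistribution("rs2227306", c(0.407, 0.476, 0.117))),
                 0.355, tolerance = 1e-9)
    expect_identical(minorAlleleFrequency(GenotypeDistribution("m", c(1, 0, 0))), 0)
    set.seed(12)
    for (i in 1:25) {
        maf <- minorAlleleFrequency(GenotypeDistribution("m", randomTriple()))
        expect_lte(maf, 0.5)
        expect_gt(maf, 0)
    }
})

test_that("observed heterozygosity returns the middle trinomial parameter", {
    expect_equal(observedHeterozygosity(GenotypeDistribution("rs2227306", c(0.407, 0.476, 0.117))),
                 0.476)
    expect_equal(observedHeterozygosity(GenotypeDistribution("rs741344", c(0.427, 0.465, 0.108))),
                 0.465)
    expect_identical(observedHeterozygosity(GenotypeDistribution("m", c(0.5, 0, 0.5))), 0)
})

test_that("HWE projection squares allele frequencies and is idempotent", {
    fp <- GenotypeDistribution("m", c(0.25, 0.5, 0.25))
    expect_equal(probs(hweExpected(fp)), c(0.25, 0.5, 0.25), tolerance = 1e-12)
    expect_equal(probs(hweExpected(GenotypeDistribution("m", c(0.5, 0, 0.5)))),
                 c(0.25, 0.5, 0.25), tolerance = 1e-12)

    d <- GenotypeDistribution("rs2856838", c(0.562, 0.379, 0.059))
    expect_equal(probs(hweExpected(d)), c(0.56475225, 0.37349550, 0.06175225),
                 tolerance = 1e-8)

    set.seed(13)
    for (i in 1:25) {
        d <- GenotypeDistribution("m", randomTriple())
        once <- hweExpected(d)
        expect_equal(probs(hweExpected(once)), probs(once), tolerance = 1e-12)
    }
})

test_that("MAF filter selects markers inside the window, in model order", {
    all8 <- mafFilter(panel$A, 0.249, 0.355)
    expect_identical(all8, markerIds(panel$A))
    expect_identical(mafFilter(panel$A, 0, 0.5), markerIds(panel$A))
    expect_identical(mafFilter(panel$A, 0.30, 0.36),
                     c("rs20541", "rs2227306", "rs741344"))
    # strict bounds exclude the marker whose unrounded MAF is 0.2485
    expect_identical(setdiff(markerIds(panel$A), mafFilter(panel$A, 0.249, 0.355, tol = 0)),
                     "rs2856838")
})

test_that("marker summary assembles MAF, ObsHET and HWE screening p-values", {
    s <- markerSummary(panel$B)
    expect_identical(s$marker, markerIds(panel$B))
    expect_false(anyNA(s$hwe_pvalue))  # population B stores per-marker counts
    sA <- markerSummary(panel$A)
    expect_true(all(is.na(sA$hwe_pvalue)))  # population A has none
    expect_equal(sA$obs_het,
                 vapply(distributions(panel$A), observedHeterozygosity, numeric(1)))
})
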
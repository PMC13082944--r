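test_that("signed ranks follow the zero / min-tie / sign rules", {
    expect_equal(signedRanks(c(3, -1, 0, 3)), c(2, -1, 0, 2))
    expect_equal(signedRanks(c(0, 0, 0)), c(0, 0, 0))
    expect_equal(signedRanks(5), 1)
    expect_equal(signedRanks(c(-2, -2, -2)), c(-1, -1, -1))
    expect_error(signedRanks(c(1, NA)), "finite")
    expect_error(signedRanks(numeric(0)), "non-empty")
    # property: matches the independent sort-based oracle
    set.seed(11)
    for (i in 1:50) {
        d <- round(rnorm(sample(1:12, 1)), sample(0:1, 1))
        expect_equal(signedRanks(d), oracleSignedRanks(d))
    }
})

test_that("rearrangement counts are the closed-form universe sizes", {
    expect_equal(countRearrangements("umcw", nA = 2, nB = 2), 6)
    expect_equal(countRearrangements("mbmcw", nA = 3, nB = 2), 10)
    expect_equal(countRearrangements("bmcw_whole", n = 3), 8)
    expect_equal(countRearrangements("bmcw_subset", n = 5, subsetSize = 2),
                 10)
    # large inputs stay comparable against any budget without overflow
    expect_gt(countRearrangements("bmcw_whole", n = 500), 1e10)
})

test_that("uMCW bias index matches hand-derived and boundary cases", {
    expect_equal(biasIndex(umcwTest(c(2, 3), c(0, 1))), 1)
    expect_equal(biasIndex(umcwTest(c(1, 2), c(1, 2))), 0)
    r <- umcwTest(c(3, 1), c(2, 0))
    expect_equal(biasIndex(r), 5 / 7)
    expect_equal(rearrangementPath(r), "exact")
    expect_equal(nRearrangements(r), 6L)
    # identical constant sets: no information, BI 0 and both p-values 1
    rc <- umcwTest(c(2, 2), c(2, 2))
    expect_equal(biasIndex(rc), 0)
    expect_equal(pUpper(rc), 1)
    expect_equal(pLower(rc), 1)
    expect_error(umcwTest(numeric(0), 1), "non-empty")
})

test_that("mbMCW bias index matches hand-derived and boundary cases", {
    expect_equal(biasIndex(mbmcwTest(rbind(c(5, 1), c(6, 1)),
                                     rbind(c(1, 5), c(1, 6)))), 1)
    expect_equal(biasIndex(mbmcwTest(rbind(c(2, 1), c(3, 1)),
                                     rbind(c(2, 1), c(3, 1)))), 0)
    expect_equal(biasIndex(mbmcwTest(rbind(c(4, 1)), rbind(c(2, 1)))),
                 1 / 3)
    expect_error(mbmcwTest(matrix(0, 0, 2), rbind(c(1, 2))), "one pair")
})

test_that("bMCW whole-set and subset indexes match hand computation", {
    v <- c(e1 = 0.5, e2 = -0.2, e3 = 0.9)
    res <- bmcwTest(v, list(s = c("e1", "e3")))
    expect_equal(biasIndex(wholeSetResult(res)), 4 / 6)
    expect_equal(biasIndex(subsetResults(res)$s), 1)
    # all positive -> complete positive bias
    allPos <- bmcwTest(c(a = 1, b = 2, c = 3))
    expect_equal(biasIndex(wholeSetResult(allPos)), 1)
    # antisymmetric values cancel
    expect_equal(biasIndex(wholeSetResult(bmcwTest(c(3, -3)))), 0)
    expect_error(bmcwTest(v, list(s = c("e1", "nope"))), "unknown")
    expect_error(bmcwTest(v, list(s = 1:4)), "out of range")
})

test_that("exact-path results equal the exhaustive oracles exactly", {
    set.seed(42)
    cfg <- mcwConfig(10000, 1)
    for (i in 1:25) {
        a <- round(rnorm(sample(2:4, 1)), 1)
        b <- round(rnorm(sample(2:4, 1)), 1)
        r <- umcwTest(a, b, cfg)
        o <- oracleUmcw(a, b)
        expect_equal(rearrangementPath(r), "exact")
        expect_equal(biasIndex(r), o$bi)
        expect_equal(pUpper(r), o$pUpper)
        expect_equal(pLower(r), o$pLower)
    }
    for (i in 1:15) {
        x <- matrix(round(rnorm(2 * sample(1:3, 1)), 1), ncol = 2)
        y <- matrix(round(rnorm(2 * sample(1:3, 1)), 1), ncol = 2)
        r <- mbmcwTest(x, y, cfg)
        o <- oracleMbmcw(x, y)
        expect_equal(biasIndex(r), o$bi)
        expect_equal(pUpper(r), o$pUpper)
        expect_equal(pLower(r), o$pLower)
    }
    for (i in 1:15) {
        n <- sample(3:9, 1)
        v <- round(rnorm(n), 1)
        names(v) <- paste0("e", seq_len(n))
        k <- sample(seq_len(n - 1), 1)
        idx <- sample(n, k)
        r <- bmcwTest(v, list(s = names(v)[idx]), cfg)
        o <- oracleBmcw(v, idx)
        expect_equal(biasIndex(wholeSetResult(r)), o$wBI)
        expect_equal(pUpper(wholeSetResult(r)), o$wPUpper)
        expect_equal(pLower(wholeSetResult(r)), o$wPLower)
        expect_equal(biasIndex(subsetResults(r)$s), o$sBI)
        expect_equal(pUpper(subsetResults(r)$s), o$sPUpper)
        expect_equal(pLower(subsetResults(r)$s), o$sPLower)
    }
})

test_that("bias indexes are antisymmetric, bounded, with pU + pL >= 1", {
    set.seed(7)
    for (i in 1:40) {
        a <- rnorm(sample(2:6, 1))
        b <- rnorm(sample(2:6, 1))
        cfg <- mcwConfig(500, i)
        rab <- umcwTest(a, b, cfg)
        rba <- umcwTest(b, a, cfg)
        expect_equal(biasIndex(rab), -biasIndex(rba))
        expect_gte(biasIndex(rab), -1)
        expect_lte(biasIndex(rab), 1)
        expect_gte(pUpper(rab) + pLower(rab), 1)
    }
    # mbMCW swap symmetry, enforced by the shared normalizer
    set.seed(8)
    for (i in 1:20) {
        x <- matrix(rnorm(2 * sample(2:4, 1)), ncol = 2)
        y <- matrix(rnorm(2 * sample(2:4, 1)), ncol = 2)
        expect_equal(biasIndex(mbmcwTest(x, y)),
                     -biasIndex(mbmcwTest(y, x)))
    }
})

test_that("Monte-Carlo p-values converge to exact values", {
    a <- c(3.2, 1.1, 4.0, 2.2, 5.1)
    b <- c(0.4, 2.0, 1.5, 0.9, 3.3)
    exact <- umcwTest(a, b, mcwConfig(100000, 1))
    expect_equal(rearrangementPath(exact), "exact")
    # a budget equal to the rearrangement count takes the MC path
    # (the exact path triggers strictly below the budget)
    approx <- umcwTest(a, b, mcwConfig(252, 99))
    expect_equal(rearrangementPath(approx), "approximate")
    expect_equal(nRearrangements(approx), 252L)
    # 8-vs-8: C(16,8) = 12870 is enumerable with a larger budget but takes
    # the MC path at the default 10,000; the estimates agree within 3
    # binomial standard errors
    set.seed(5)
    a8 <- rnorm(8); b8 <- rnorm(8, 0.5)
    exact8 <- umcwTest(a8, b8, mcwConfig(20000, 1))
    expect_equal(rearrangementPath(exact8), "exact")
    mc8 <- umcwTest(a8, b8, mcwConfig(10000, 31))
    expect_equal(rearrangementPath(mc8), "approximate")
    for (tail in c(pUpper, pLower)) {
        pe <- tail(exact8)
        se <- sqrt(pe * (1 - pe) / 10000)
        expect_lt(abs(tail(mc8) - pe), 3 * se + 1e-9)
    }
})

test_that("identical input, config and seed reproduce identical results", {
    set.seed(123)
    a <- rnorm(9); b <- rnorm(9)
    r1 <- umcwTest(a, b, mcwConfig(2000, 77))
    r2 <- umcwTest(a, b, mcwConfig(2000, 77))
    expect_equal(rearrangementPath(r1), "approximate")
    expect_identical(pUpper(r1), pUpper(r2))
    expect_identical(pLower(r1), pLower(r2))
    v <- stats::setNames(rnorm(20), paste0("g", 1:20))
    b1 <- bmcwTest(v, list(s = paste0("g", 1:6)), mcwConfig(500, 5))
    b2 <- bmcwTest(v, list(s = paste0("g", 1:6)), mcwConfig(500, 5))
    expect_identical(mcwAsDataFrame(b1), mcwAsDataFrame(b2))
    # the caller's RNG stream is left untouched
    set.seed(42); before <- rnorm(1)
    set.seed(42); invisible(umcwTest(a, b, mcwConfig(50, 1)))
    expect_identical(rnorm(1), before)
})
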
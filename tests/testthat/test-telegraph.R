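test_that("mean expression follows the ON-occupancy closed form", {
    expect_equal(meanExpression(promoterKinetics(1, 1, C = 1)), 0.5)
    expect_equal(meanExpression(promoterKinetics(1, 0, C = 2)), 2)
    expect_equal(meanExpression(promoterKinetics(0.3, 0.7, C = 1)), 0.3)
})

test_that("mean is monotone in the switching rates", {
    set.seed(7)
    for (i in 1:50) {
        kOn <- runif(1, 0.01, 2); kOff <- runif(1, 0.01, 2)
        d <- runif(1, 0.01, 0.5)
        base <- meanExpression(promoterKinetics(kOn, kOff))
        expect_gt(meanExpression(promoterKinetics(kOn + d, kOff, kOnWt = kOn + d)), base)
        expect_lt(meanExpression(promoterKinetics(kOn, kOff + d, kOffWt = kOff + d)), base)
    }
})

test_that("noise is the two-term sum and collapses to 1/mean when always ON", {
    expect_equal(noiseExpression(promoterKinetics(1, 0, C = 2)), 0.5)
    expect_equal(noiseExpression(promoterKinetics(1, 1, C = 1), mean = 1),
                 1 + 1 / 3)
    ## hand-evaluated: 1/(4/3) + (1/2) * 1/(1*(2+1)+1)
    kin <- promoterKinetics(2, 1, tau = 1, C = 2)
    expect_equal(noiseExpression(kin), 0.875)
    expect_error(noiseExpression(promoterKinetics(1, 1), mean = 0),
                 "invalid summary")
})

test_that("noise dominates the small-number bound, equality only when never OFF", {
    set.seed(11)
    for (i in 1:50) {
        kin <- promoterKinetics(runif(1, 0.01, 2), runif(1, 0, 2), C = 10)
        m <- meanExpression(kin)
        if (kOff(kin) == 0) expect_equal(noiseExpression(kin), 1 / m)
        else expect_gt(noiseExpression(kin), 1 / m)
    }
})

test_that("rate modulation reproduces hand-evaluated occupancy arithmetic", {
    wt <- promoterKinetics()
    ## same strand: K_r = 0.01*(1 + 0.5/10) = 0.0105
    kin <- applyCrisprar(wt, crisprParams(kR = 0.5), 0.5, 0.5, "same")
    expect_equal(kOn(kin), 1 - 0.5 * 0.5 / 0.5105, tolerance = 1e-12)
    expect_equal(kOn(kin), 0.51028404, tolerance = 1e-7)
    ## opposite strand: int2 = 1/(1 + 2*0.5) = 0.5
    kin2 <- applyCrisprar(wt, crisprParams(kA = 0.8), 0.5, 0.5, "opposite")
    expect_equal(kOff(kin2), 1 - 0.8 * (0.5 / 0.52) * 0.5, tolerance = 1e-12)
    expect_equal(kOff(kin2), 8 / 13, tolerance = 1e-12)
})

test_that("rate modulation is the identity without sgRNA", {
    wt <- promoterKinetics(kOn = 0.8, kOff = 1.2)
    p <- crisprParams(kR = 0.9, kA = 0.9)
    for (rel in c("same", "opposite")) {
        kin <- applyCrisprar(wt, p, 0, 0, rel)
        expect_equal(kOn(kin), 0.8)
        expect_equal(kOff(kin), 1.2)
    }
    ## one-sided regulation leaves the other rate at wild type
    expect_equal(kOn(applyCrisprar(wt, p, concA = 1, concR = 0, "same")), 0.8)
    expect_equal(kOff(applyCrisprar(wt, p, concA = 0, concR = 1, "same")), 1.2)
})

test_that("modulated rates never exceed wild type and stay positive", {
    set.seed(13)
    for (i in 1:50) {
        p <- crisprParams(kR = runif(1), kA = runif(1))
        cA <- runif(1); cR <- runif(1)
        rel <- sample(c("same", "opposite"), 1)
        kin <- applyCrisprar(promoterKinetics(), p, cA, cR, rel)
        expect_true(kOn(kin) > 0 && kOn(kin) <= 1)
        expect_true(kOff(kin) >= 0 && kOff(kin) <= 1)
    }
})

test_that("matched-mean comparison reduces to the switching term", {
    r <- compareNoiseAtMatchedMean(promoterKinetics(1, 1), promoterKinetics(2, 2))
    expect_equal(r$term1, 1 / 3)
    expect_equal(r$term2, 1 / 5)
    expect_identical(r$noisier, "kin1")

    tie <- compareNoiseAtMatchedMean(promoterKinetics(0.5, 0.5),
                                     promoterKinetics(0.5, 0.5))
    expect_identical(tie$noisier, "tie")

    r2 <- compareNoiseAtMatchedMean(promoterKinetics(1, 2, kOffWt = 2),
                                    promoterKinetics(2, 4, kOffWt = 4))
    expect_equal(c(r2$term1, r2$term2), c(1 / 4, 1 / 7))
    expect_identical(r2$noisier, "kin1")

    expect_error(compareNoiseAtMatchedMean(promoterKinetics(1, 1),
                                           promoterKinetics(1, 2, kOffWt = 2)),
                 "not matched")
})

test_that("kinetics with equal rate ratios share one mean", {
    set.seed(17)
    for (i in 1:20) {
        kOn <- runif(1, 0.05, 1); ratio <- runif(1, 0.1, 5); f <- runif(1, 1, 4)
        m1 <- meanExpression(promoterKinetics(kOn, kOn * ratio, C = 3))
        m2 <- meanExpression(promoterKinetics(kOn * f, kOn * f * ratio, C = 3))
        expect_equal(m1, m2)
    }
})

test_that("contour grid evaluates the surfaces pointwise", {
    g <- contourGrid(c(1, 2), c(1, 2), tau = 1, C = 1)
    expect_equal(meanSurface(g),
                 matrix(c(0.5, 1 / 3, 2 / 3, 0.5), 2, 2, byrow = TRUE))
    ## symmetric rates always give the half-maximal mean
    g2 <- contourGrid(seq(0.2, 1.4, by = 0.3), seq(0.2, 1.4, by = 0.3), C = 4)
    expect_equal(diag(meanSurface(g2)), rep(2, 5))
    ## pointwise: noise never below the small-number bound
    v <- seq(0.01, 2, length.out = 50)
    g3 <- contourGrid(v, v, C = 10)
    expect_true(all(noiseSurface(g3) >= 1 / meanSurface(g3)))
    expect_error(contourGrid(1, c(1, 2)), "configuration error")
})

test_that("contour TSV serialization round-trips", {
    g <- contourGrid(c(0.2, 0.7, 1.1), c(0.1, 0.9), tau = 1, C = 5)
    path <- withr::local_tempfile(fileext = ".tsv")
    df <- writeContourGrid(g, path)
    expect_equal(nrow(df), 6)
    expect_named(df, c("k_on", "k_off", "mean", "noise"))
    g2 <- readContourGrid(path)
    expect_equal(g2@kOnValues, g@kOnValues)
    expect_equal(meanSurface(g2), meanSurface(g), tolerance = 1e-12)
    expect_equal(noiseSurface(g2), noiseSurface(g), tolerance = 1e-12)
})

test_that("kinetics validity rejects out-of-domain rates", {
    expect_error(promoterKinetics(kOn = 0), "kOn")
    expect_error(promoterKinetics(kOn = 2, kOnWt = 1), "wild-type")
    expect_error(promoterKinetics(tau = -1), "tau")
})
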
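test_that("strength estimators invert the fold-change maps exactly", {
    expect_equal(estimateRepressionStrength(1), 0)
    expect_equal(estimateRepressionStrength(0.5), 2 / 3)
    expect_gt(estimateRepressionStrength(1e-9), 0.999)
    expect_equal(estimateActivationStrength(1), 0)
    expect_equal(estimateActivationStrength(2), 1)
    expect_equal(estimateActivationStrength(4 / 3), 0.5)

    ## round trips: forward(inverse(f)) = f across the valid domain
    for (f in seq(0.02, 1, length.out = 21))
        expect_equal(repressionFoldChange(estimateRepressionStrength(f)), f,
                     tolerance = 1e-12)
    for (f in seq(1, 1.98, length.out = 21))
        expect_equal(activationFoldChange(estimateActivationStrength(f)), f,
                     tolerance = 1e-12)

    ## and under asymmetric wild-type rates
    wt <- promoterKinetics(kOn = 0.6, kOff = 1.7)
    for (k in seq(0, 0.95, length.out = 11)) {
        expect_equal(estimateRepressionStrength(repressionFoldChange(k, wt), wt),
                     k, tolerance = 1e-12)
        expect_equal(estimateActivationStrength(activationFoldChange(k, wt), wt),
                     k, tolerance = 1e-12)
    }
})

test_that("estimators reject or flag out-of-domain fold changes", {
    expect_error(estimateRepressionStrength(1.2), "not a repressor")
    expect_error(estimateRepressionStrength(0), "domain error")
    expect_error(estimateActivationStrength(0.8), "not an activator")
    expect_warning(k <- estimateActivationStrength(2.5), "saturation")
    expect_equal(k, 1)
})

test_that("strengths are recovered from noisy replicate fold changes", {
    ## 5% multiplicative replicate noise, n = 6, over repeated trials
    set.seed(1234)
    truth <- c(R2 = NA, R3 = NA, A1 = NA, A2 = NA)
    mods <- defaultSingleModules()[names(truth)]
    errs <- c()
    for (trial in 1:100) {
        for (nm in names(truth)) {
            m <- mods[[nm]]
            k <- m@regulationStrength
            f <- if (m@role == "repressor") repressionFoldChange(k)
                 else activationFoldChange(k)
            fHat <- mean(f * rlnorm(6, -0.5 * log(1 + 0.05^2),
                                    sqrt(log(1 + 0.05^2))))
            kHat <- if (m@role == "repressor")
                estimateRepressionStrength(min(fHat, 1))
            else estimateActivationStrength(max(fHat, 1))
            errs <- c(errs, abs(kHat - k) / k)
        }
    }
    expect_lt(median(errs), 0.05)
})

test_that("construct predictions compose allocation, strands and rate laws", {
    mods <- defaultCrisprarModules()
    wt <- promoterKinetics(C = 10)

    ## null regulation is wild type
    a0 <- mods$activation$pStr_A1; a0@regulationStrength <- 0
    r0 <- mods$repression$pStr_R2; r0@regulationStrength <- 0
    p0 <- predictConstructRates(crisprarConstruct(a0, r0), wt = wt)
    expect_equal(p0$mean, 5)
    expect_equal(p0$noise, 2 / 10 + 1 / 3)

    ## same-strand worked arithmetic at kR = kA = 0.9, equal promoters
    a <- mods$activation$pStr_A1; a@regulationStrength <- 0.9
    r <- mods$repression$pStr_R2; r@regulationStrength <- 0.9
    pred <- predictConstructRates(crisprarConstruct(a, r), wt = wt)
    expect_equal(kOn(pred$kinetics), 1 - 0.9 * 0.5 / (0.0105 + 0.5),
                 tolerance = 1e-12)
    expect_equal(kOff(pred$kinetics), 1 - 0.9 * 0.5 / (0.021 + 0.5),
                 tolerance = 1e-12)

    ## transcription order has no model term
    f1 <- predictConstructRates(crisprarConstruct(a, r, "act_first"), wt = wt)
    f2 <- predictConstructRates(crisprarConstruct(a, r, "rep_first"), wt = wt)
    expect_equal(f1$mean, f2$mean)
    expect_equal(f1$noise, f2$noise)

    aNA <- mods$activation$pStr_A1; aNA@regulationStrength <- NA_real_
    expect_error(predictConstructRates(crisprarConstruct(aNA, r), wt = wt),
                 "incomplete estimation")
})

test_that("noise-line fit matches closed-form least squares", {
    exact <- data.frame(inv_norm_mean = c(0.5, 1, 2, 4),
                        noise = 2 * c(0.5, 1, 2, 4) + 0.1)
    ## lm warns that an exactly collinear fit's R^2 summary is unreliable
    f <- suppressWarnings(fitNoiseLine(exact))
    expect_equal(fitSlope(f), 2, tolerance = 1e-10)
    expect_equal(fitIntercept(f), 0.1, tolerance = 1e-10)
    expect_equal(rSquared(f), 1, tolerance = 1e-10)

    tri <- data.frame(inv_norm_mean = c(0, 1, 2), noise = c(0, 1, 1))
    f2 <- fitNoiseLine(tri)
    expect_equal(fitSlope(f2), 0.5)
    expect_equal(fitIntercept(f2), 1 / 6)
    expect_equal(rSquared(f2), 0.75)

    ## normal-equations oracle on random points
    set.seed(5)
    pts <- data.frame(inv_norm_mean = runif(20, 0.2, 3))
    pts$noise <- 0.3 * pts$inv_norm_mean + rnorm(20, 0, 0.05)
    X <- cbind(1, pts$inv_norm_mean)
    beta <- solve(t(X) %*% X, t(X) %*% pts$noise)
    f3 <- fitNoiseLine(pts)
    expect_equal(fitIntercept(f3), beta[1], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fitSlope(f3), beta[2], tolerance = 1e-10, ignore_attr = TRUE)

    expect_error(fitNoiseLine(tri[1:2, ]), "insufficient data")
    expect_error(fitNoiseLine(data.frame(inv_norm_mean = c(1, 1, 1),
                                         noise = 1:3)), "degenerate")
})

test_that("average deviation is the region-wise mean absolute residual", {
    f <- new("LinearNoiseFit", slope = 2, intercept = 0.1, rSquared = 1,
             n = 4L)
    onLine <- data.frame(inv_norm_mean = c(0.5, 1, 2),
                         noise = 2 * c(0.5, 1, 2) + 0.1,
                         region = c("low_expression", "low_expression",
                                    "high_expression"))
    expect_equal(as.numeric(averageDeviation(onLine, f)), c(0, 0))

    off <- data.frame(inv_norm_mean = c(1, 2),
                      noise = c(2 * 1 + 0.1 + 0.1, 2 * 2 + 0.1 - 0.3),
                      region = "low_expression")
    d <- averageDeviation(off, f)
    expect_equal(as.numeric(d), 0.2)
    expect_equal(names(d), "low_expression")
})

test_that("matched-mean pairing is tolerance-gated, greedy and symmetric", {
    gA <- data.frame(construct_id = c("a1", "a2"),
                     inv_norm_mean = c(0.50, 0.80), noise = c(1, 2))
    gB <- data.frame(construct_id = c("b1", "b2"),
                     inv_norm_mean = c(0.52, 1.00), noise = c(0.5, 3))
    r <- matchedMeanComparison(gA, gB, matchTolerance = 0.03)
    expect_equal(r$n_pairs, 1L)
    expect_equal(r$pairs$id_a, "a1")
    expect_equal(r$pairs$id_b, "b1")
    expect_equal(r$mean_noise_diff, 0.5)

    ## identical groups: everything pairs with itself
    rSelf <- matchedMeanComparison(gA, gA)
    expect_equal(rSelf$n_pairs, 2L)
    expect_equal(rSelf$mean_noise_diff, 0)

    ## symmetry up to the sign of the difference
    set.seed(9)
    gC <- data.frame(construct_id = paste0("c", 1:6),
                     inv_norm_mean = runif(6, 0.5, 1.5),
                     noise = runif(6, 0.2, 2))
    gD <- data.frame(construct_id = paste0("d", 1:6),
                     inv_norm_mean = runif(6, 0.5, 1.5),
                     noise = runif(6, 0.2, 2))
    r1 <- matchedMeanComparison(gC, gD, 0.2)
    r2 <- matchedMeanComparison(gD, gC, 0.2)
    expect_equal(r1$n_pairs, r2$n_pairs)
    expect_equal(r1$mean_noise_diff, -r2$mean_noise_diff)

    ## disjoint supports: the no-overlap signal
    far <- data.frame(construct_id = "z", inv_norm_mean = 50, noise = 1)
    r0 <- matchedMeanComparison(gA, far)
    expect_equal(r0$n_pairs, 0L)
    expect_true(is.na(r0$mean_noise_diff))
})

test_that("module strengths are estimated from normalized summaries", {
    summ <- data.frame(
        construct_id = c("single_R2", "single_R2", "single_A2", "single_A2"),
        norm_mean = c(repressionFoldChange(0.6) * c(0.99, 1.01),
                      activationFoldChange(0.6) * c(0.99, 1.01)))
    mods <- defaultSingleModules()[c("R2", "A2")]
    est <- estimateModuleStrengths(summ, mods)
    expect_equal(est[["R2"]], 0.6, tolerance = 0.02)
    expect_equal(est[["A2"]], 0.6, tolerance = 0.05)
    expect_error(estimateModuleStrengths(summ, defaultSingleModules()["A1"]),
                 "no summaries")
})
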
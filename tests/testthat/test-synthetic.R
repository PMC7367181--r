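test_that("ground truth composes the analytic model per group", {
    d <- smallDesign()
    gt <- groundTruth(d)
    ctrl <- gt[gt$construct_id == "control", ]
    expect_equal(ctrl$true_mean, 5)                 # C/2 with C = 10
    expect_equal(ctrl$true_noise, 2 / 10 + 1 / 3)
    expect_equal(nrow(gt), 1 + 4 + length(d@library))
    ## single variants are constitutive: noise exactly 1/mean
    singles <- gt[gt$group_type == "single_sgRNA", ]
    expect_equal(singles$true_noise, 1 / singles$true_mean)
    expect_false(any(gt$degenerate))
})

test_that("equal rate ratios imply equal means across the library", {
    gt <- groundTruth(syntheticDesign(wt = promoterKinetics(C = 10)))
    cr <- gt[gt$group_type == "crisprar", ]
    ratio <- cr$k_off / cr$k_on
    for (i in seq_len(nrow(cr) - 1)) for (j in seq(i + 1, nrow(cr))) {
        if (abs(ratio[i] - ratio[j]) < 1e-12)
            expect_equal(cr$true_mean[i], cr$true_mean[j], tolerance = 1e-10)
    }
})

test_that("event generation is deterministic, byte for byte", {
    d <- smallDesign(nEvents = 200L, nReplicates = 2L)
    e1 <- generateEvents(d)
    e2 <- generateEvents(d)
    expect_identical(e1, e2)
    expect_true(all(e1$intensity > 0))

    p1 <- withr::local_tempfile(fileext = ".csv")
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeEventTable(e1, p1)
    writeEventTable(e2, p2)
    expect_identical(readLines(p1), readLines(p2))

    ## a different base seed changes the data
    d2 <- smallDesign(seed = 43L, nEvents = 200L, nReplicates = 2L)
    expect_false(identical(generateEvents(d2)$intensity, e1$intensity))
})

test_that("generated noise respects the law of total variance", {
    d <- syntheticDesign(library = list(),
                         singleModules = list(),
                         wt = promoterKinetics(C = 10),
                         nReplicates = 50L, nEvents = 2000L,
                         measurementCv = 0.05, replicateCv = 0.05,
                         seed = 7L)
    ev <- generateEvents(d)
    x <- ev$intensity[ev$construct_id == "control"]
    eta2 <- 2 / 10 + 1 / 3
    expected <- (1 + 0.05^2) * (1 + 0.05^2) * (1 + eta2) - 1
    pooled <- var(x) / mean(x)^2
    expect_equal(pooled, expected, tolerance = 0.05)
})

test_that("recovered noise is consistent with truth absent measurement noise", {
    d <- syntheticDesign(library = list(), singleModules = list(),
                         wt = promoterKinetics(C = 10),
                         nReplicates = 1L, nEvents = 100000L,
                         measurementCv = 0, replicateCv = 0, seed = 5L)
    ev <- generateEvents(d)
    s <- summarizeEvents(ev[ev$construct_id == "control", ])
    expect_equal(s$eta2, 2 / 10 + 1 / 3, tolerance = 0.05)
    expect_equal(s$mu, 5, tolerance = 0.05)
})

test_that("gamma and ssa modes agree at matched rates", {
    d <- smallDesign(nEvents = 4000L, nReplicates = 1L,
                     measurementCv = 0, replicateCv = 0)
    d@library <- d@library[1]
    d@singleModules <- list()
    truth <- groundTruth(d)
    evG <- generateEvents(d, mode = "gamma_approx", truth = truth)
    evS <- generateEvents(d, mode = "ssa", truth = truth)
    for (id in unique(truth$construct_id)) {
        sg <- summarizeEvents(evG[evG$construct_id == id, ])
        ss <- summarizeEvents(evS[evS$construct_id == id, ])
        se <- sqrt(sg$sigma^2 + ss$sigma^2) / sqrt(4000)
        expect_lt(abs(sg$mu - ss$mu), 3 * se)
        expect_equal(ss$eta2, sg$eta2, tolerance = 0.15)
    }
})

test_that("a full study bundle is complete and self-consistent", {
    d <- smallDesign(nEvents = 200L, nReplicates = 2L)
    dir <- withr::local_tempdir()
    res <- generateStudy(d, dir = dir)
    ids <- unique(res$events$construct_id)
    expect_true(all(c("control", "blank", "single_A1", "single_R2") %in% ids))
    expect_equal(length(ids), 1 + 1 + 4 + length(d@library))
    ## files exist and the written truth matches groundTruth() exactly
    expect_true(all(file.exists(unlist(res$paths))))
    back <- utils::read.delim(res$paths$truth)
    expect_equal(back$true_mean, groundTruth(d)$true_mean, tolerance = 1e-10)
    ## the library config round-trips to the same construct set
    lc <- readLibraryConfig(res$paths$library)
    expect_equal(sort(vapply(lc$library, constructId, character(1))),
                 sort(vapply(d@library, constructId, character(1))),
                 ignore_attr = TRUE)
})

test_that("the constitutive single-variant set reproduces the linear law", {
    d <- syntheticDesign(library = list(), wt = promoterKinetics(C = 10),
                         nEvents = 5000L, seed = 2L)
    ev <- generateEvents(d)
    gated <- gateEvents(ev[ev$construct_id != "blank", ],
                        ev[ev$construct_id == "blank", ])
    summ <- normalizeToControl(summarizeEvents(gated))
    singles <- summ[grepl("^single_", summ$construct_id), ]
    invByGroup <- tapply(singles$inv_norm_mean, singles$construct_id, mean)
    pts <- data.frame(
        construct_id = names(invByGroup),
        inv_norm_mean = as.numeric(invByGroup),
        noise = as.numeric(tapply(singles$eta2, singles$construct_id, mean)))
    f <- fitNoiseLine(pts)
    expect_gte(rSquared(f), 0.95)
    ## slope close to 1/(control mean), intercept near zero
    expect_equal(fitSlope(f), 0.2, tolerance = 0.1)
})
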
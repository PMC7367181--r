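test_that("concentration allocation is proportional and scale-invariant", {
    expect_equal(allocateConcentrations(1, 1), c(concA = 0.5, concR = 0.5))
    expect_equal(allocateConcentrations(12, 1),
                 c(concA = 12 / 13, concR = 1 / 13))
    expect_equal(allocateConcentrations(12, 2.4),
                 c(concA = 12 / 14.4, concR = 2.4 / 14.4))
    set.seed(3)
    for (i in 1:20) {
        s <- runif(2, 0.1, 20); f <- runif(1, 0.01, 100)
        expect_equal(allocateConcentrations(s[1], s[2]),
                     allocateConcentrations(f * s[1], f * s[2]))
    }
    expect_error(allocateConcentrations(0, 1), "configuration error")
})

test_that("rule classification matches the construct's geometry", {
    mods <- defaultCrisprarModules()
    c1 <- crisprarConstruct(mods$activation$pStr_A2, mods$repression$pStr_R2)
    expect_equal(classifyConstruct(c1),
                 c(rule1 = "a_noncoding", rule2 = "opposite_strand",
                   rule3 = "equal_conc"))
    c2 <- crisprarConstruct(mods$activation$pStr_A1, mods$repression$pWeak_R2)
    expect_equal(classifyConstruct(c2),
                 c(rule1 = "a_coding", rule2 = "same_strand",
                   rule3 = "unequal_conc"))
    ## determinism
    expect_identical(classifyConstruct(c2), classifyConstruct(c2))
    ## a tolerance band can admit near-equal promoters
    c3 <- crisprarConstruct(mods$activation$pMed_A1, mods$repression$pStr_R2)
    expect_equal(classifyConstruct(c3)[["rule3"]], "unequal_conc")
    expect_equal(classifyConstruct(c3, equalTolerance = 0.9)[["rule3"]],
                 "equal_conc")
})

test_that("every construct gets exactly one label per rule", {
    lib <- enumerateLibrary()
    labels <- t(vapply(lib, classifyConstruct, character(3)))
    expect_true(all(labels[, "rule1"] %in% c("a_noncoding", "a_coding")))
    expect_true(all(labels[, "rule2"] %in% c("same_strand", "opposite_strand")))
    expect_true(all(labels[, "rule3"] %in% c("equal_conc", "unequal_conc")))
})

test_that("library enumeration yields 36 unique pairings plus 12 order swaps", {
    lib <- enumerateLibrary()
    expect_length(lib, 48)
    pairKey <- vapply(lib, function(x)
        paste(actModule(x)@promoter, actModule(x)@name,
              repModule(x)@promoter, repModule(x)@name), character(1))
    expect_equal(length(unique(pairKey)), 36)
    orders <- vapply(lib, function(x) x@transcriptionOrder, character(1))
    expect_equal(sum(orders == "rep_first"), 12)
    conc <- vapply(lib, function(x) x@concA + x@concR, numeric(1))
    expect_true(all(abs(conc - 1) < 1e-12))
    ## re-running is deterministic
    expect_identical(names(lib), names(enumerateLibrary()))
})

test_that("degenerate enumerations behave", {
    mods <- defaultCrisprarModules()
    one <- enumerateLibrary(mods$activation["pStr_A1"],
                            mods$repression["pMed_R2"],
                            swapEqualPromoter = FALSE)
    expect_length(one, 1)
    dup <- c(mods$activation["pStr_A1"], mods$activation["pStr_A1"])
    expect_error(enumerateLibrary(dup, mods$repression), "duplicate")
})

test_that("construct invariants are enforced", {
    mods <- defaultCrisprarModules()
    expect_error(crisprarConstruct(mods$repression$pStr_R2,
                                   mods$repression$pMed_R3),
                 "activator")
    expect_error(crisprarConstruct(mods$activation$pStr_A1,
                                   mods$repression$pMed_R3,
                                   concA = 0.6, concR = 0.6),
                 "capacity")
})

test_that("same-mean selection orders one construct per leaf by noise", {
    s <- data.frame(
        construct_id = c("oe", "ou", "se", "su"),
        mean = rep(2, 4),
        noise = c(0.2, 0.3, 0.4, 0.5),
        region = "low_expression",
        rule1 = "a_coding",
        rule2 = c("opposite_strand", "opposite_strand", "same_strand",
                  "same_strand"),
        rule3 = c("equal_conc", "unequal_conc", "equal_conc", "unequal_conc"))
    sel <- decisionTreeSelect(s, "same_mean_diff_noise")
    expect_equal(sel$construct_id, c("oe", "ou", "se", "su"))
    expect_equal(sel$leaf_rank, 1:4)
    expect_equal(sel$selection_rank, 1:4)
    expect_true(all(diff(sel$noise) > 0))
})

test_that("identical summaries all qualify in stable input order", {
    s <- data.frame(construct_id = paste0("c", 1:5), mean = 1, noise = 0.5,
                    region = "low_expression", rule1 = "a_coding",
                    rule2 = "same_strand", rule3 = "equal_conc")
    sel <- decisionTreeSelect(s, "same_mean_diff_noise", minSelection = 2)
    expect_equal(sel$construct_id, paste0("c", 1:5))
})

test_that("selection returns the empty signal when nothing matches", {
    s <- data.frame(construct_id = paste0("c", 1:4),
                    mean = c(1, 2, 4, 8), noise = 1:4,
                    region = "low_expression", rule1 = "a_coding",
                    rule2 = "same_strand", rule3 = "equal_conc")
    sel <- decisionTreeSelect(s, "same_mean_diff_noise")
    expect_equal(nrow(sel), 0)
    expect_true(all(c("leaf_rank", "selection_rank") %in% names(sel)))
})

test_that("selected windows respect tolerances on the predicted library", {
    s <- defaultPredictedSummaries()
    sm <- decisionTreeSelect(s, "same_mean_diff_noise", distinct = TRUE)
    expect_gte(nrow(sm), 4)
    expect_lte(max(sm$mean) / min(sm$mean) - 1, 0.05)
    expect_true(all(diff(sm$noise) > 0))
    expect_true(all(sm$region == "low_expression"))
    sn <- decisionTreeSelect(s, "same_noise_diff_mean", distinct = TRUE)
    expect_gte(nrow(sn), 4)
    expect_lte(max(sn$noise) / min(sn$noise) - 1, 0.10)
    expect_true(all(diff(sn$mean) > 0))
})

test_that("library config round-trips through YAML", {
    path <- withr::local_tempfile(fileext = ".yaml")
    writeLibraryConfig(defaultLibraryConfig(), path)
    lc <- readLibraryConfig(path)
    expect_length(lc$singleModules, 9)
    expect_length(lc$library, 48)
    expect_equal(lc$singleModules$R2@regulationStrength,
                 defaultSingleModules()$R2@regulationStrength)
    expect_equal(vapply(lc$library, constructId, character(1)),
                 vapply(enumerateLibrary(), constructId, character(1)),
                 ignore_attr = TRUE)

    bad <- defaultLibraryConfig()
    bad$typo <- 1
    writeLibraryConfig(bad, path)
    expect_error(readLibraryConfig(path), "unknown key")
})

test_that("module windows tie the role to the PAM position", {
    expect_error(sgRNAModule("X", "repressor", "coding", 80),
                 "repression window")
    expect_error(sgRNAModule("X", "activator", "coding", 50),
                 "activation window")
})
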
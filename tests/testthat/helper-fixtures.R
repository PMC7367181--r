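# shared fixtures, built in code

# a small, fast study design: four library constructs, four single variants
smallDesign <- function(seed = 42L, nEvents = 1000L, nReplicates = 3L,
                        measurementCv = 0.05, replicateCv = 0.05) {
    mods <- defaultCrisprarModules()
    lib <- enumerateLibrary(mods$activation[c("pStr_A1", "pWeak_A2")],
                            mods$repression[c("pStr_R2", "pMed_R3")],
                            swapEqualPromoter = FALSE)
    syntheticDesign(library = lib,
                    singleModules = defaultSingleModules()[c("A1", "A2",
                                                             "R2", "R3")],
                    wt = promoterKinetics(C = 10),
                    nReplicates = nReplicates, nEvents = nEvents,
                    measurementCv = measurementCv, replicateCv = replicateCv,
                    seed = seed)
}

# predicted summaries of the full default library under default parameters
defaultPredictedSummaries <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- predictLibrarySummaries(enumerateLibrary(),
                                              wt = promoterKinetics(C = 10))
        cache
    }
})
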
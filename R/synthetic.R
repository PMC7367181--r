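#' Construct a SyntheticDesign
#'
#' Defaults emulate the study's measurement design: the 48-construct
#' CRISPRar library, the nine single-sgRNA variants, six replicates of at
#' least 20,000 events per group, a no-sgRNA control and a blank, with 5%
#' multiplicative lognormal measurement noise and 5% between-replicate
#' scale jitter.
#'
#' @param library list of [CrisprarConstruct-class]; default the enumerated
#'   48-construct library.
#' @param singleModules list of [SgRNAModule-class]; default the nine
#'   variants.
#' @param params [CrisprParams-class].
#' @param wt wild-type [PromoterKinetics-class]; the default uses expression
#'   scale \code{C = 10} so the control mean is 5 and single-cell noise
#'   magnitudes span roughly 0.1-3.
#' @param nReplicates,nEvents replication of the design.
#' @param measurementCv,replicateCv multiplicative noise CVs.
#' @param blankFraction blank mean relative to the control mean.
#' @param seed integer base seed; per-group seeds are derived from it (see
#'   [generateEvents()]).
#' @return A [SyntheticDesign-class].
#' @export
syntheticDesign <- function(library = enumerateLibrary(),
                            singleModules = defaultSingleModules(),
                            params = crisprParams(),
                            wt = promoterKinetics(C = 10),
                            nReplicates = 6L, nEvents = 20000L,
                            measurementCv = 0.05, replicateCv = 0.05,
                            blankFraction = 0.01, seed = 1L) {
    new("SyntheticDesign", library = library, singleModules = singleModules,
        params = params, wt = wt, nReplicates = as.integer(nReplicates),
        nEvents = as.integer(nEvents), measurementCv = measurementCv,
        replicateCv = replicateCv, blankFraction = blankFraction,
        seed = as.integer(seed))
}

#' Analytic ground truth of a synthetic study
#'
#' One row per measured group. CRISPRar constructs follow the two-state
#' model with modulated rates; the control is the unregulated two-state
#' promoter (mean \code{C/2}); the single-sgRNA variants follow the
#' constitutive regime their measured linearity implies (always-ON promoter
#' whose scale is the control mean times the variant's saturated fold
#' change, so noise is exactly 1/mean before measurement noise). Groups
#' whose mean collapses below \code{1e-6 * C} are flagged degenerate.
#'
#' @param design a [SyntheticDesign-class].
#' @return data.frame with columns \code{construct_id}, \code{group_type}
#'   (\code{control}/\code{single_sgRNA}/\code{crisprar}), \code{k_on},
#'   \code{k_off}, \code{true_mean}, \code{true_noise}, \code{norm_mean},
#'   \code{degenerate}.
#' @export
groundTruth <- function(design) {
    stopifnot(is(design, "SyntheticDesign"))
    wt <- design@wt
    controlMean <- meanExpression(wt)
    rows <- list(data.frame(
        construct_id = "control", group_type = "control",
        k_on = wt@kOn, k_off = wt@kOff, true_mean = controlMean,
        true_noise = noiseExpression(wt, controlMean),
        norm_mean = 1))
    for (m in design@singleModules) {
        ks <- m@regulationStrength
        if (is.na(ks))
            stop("incomplete estimation: single module ", m@name,
                 " has no regulation strength")
        fold <- if (m@role == "repressor") repressionFoldChange(ks, wt)
                else activationFoldChange(ks, wt)
        mu <- controlMean * fold
        rows[[length(rows) + 1L]] <- data.frame(
            construct_id = paste0("single_", m@name),
            group_type = "single_sgRNA", k_on = wt@kOnWt, k_off = 0,
            true_mean = mu, true_noise = 1 / mu, norm_mean = fold)
    }
    for (cstr in design@library) {
        pred <- predictConstructRates(cstr, design@params, wt)
        rows[[length(rows) + 1L]] <- data.frame(
            construct_id = constructId(cstr), group_type = "crisprar",
            k_on = kOn(pred$kinetics), k_off = kOff(pred$kinetics),
            true_mean = pred$mean, true_noise = pred$noise,
            norm_mean = pred$mean / controlMean)
    }
    out <- do.call(rbind, rows)
    out$degenerate <- out$true_mean < 1e-6 * wt@C
    rownames(out) <- NULL
    out
}

## deterministic per-(group, replicate) seed expansion from the base seed
.groupSeed <- function(baseSeed, groupIndex, replicate) {
    as.integer((as.double(baseSeed) + 7919 * groupIndex +
                104729 * replicate) %% 2147483647)
}

.lnormSdlog <- function(cv) sqrt(log(1 + cv^2))

## event intensities for one (group, replicate): gamma with the target mean
## and CV^2, times multiplicative lognormal measurement noise
.drawGammaEvents <- function(n, mu, eta2, measurementCv) {
    base <- if (eta2 > 0) {
        shape <- 1 / eta2
        stats::rgamma(n, shape = shape, rate = shape / mu)
    } else rep(mu, n)
    if (measurementCv > 0) {
        s <- .lnormSdlog(measurementCv)
        base <- base * stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    }
    base
}

#' Generate a synthetic event table
#'
#' Draws per-cell intensities for every group of the design (control,
#' single-sgRNA variants, CRISPRar constructs, blank) and every replicate.
#' In \code{"gamma_approx"} mode events are gamma-distributed with the
#' group's true mean (times a per-replicate lognormal jitter) and CV^2
#' equal to the true noise - the standard steady-state protein-distribution
#' approximation - then multiplied by lognormal measurement noise. In
#' \code{"ssa"} mode the protein counts come from the exact simulator
#' ([sampleSteadyState()]); smaller \code{nEvents} is recommended there.
#' The blank is a dim gamma noise floor (mean \code{blankFraction} of the
#' control mean, CV^2 = 0.25) used only to exercise gating.
#'
#' Each (group, replicate) pair draws from its own seed, derived from the
#' design's base seed by a fixed affine counter scheme
#' (\code{(seed + 7919*group + 104729*replicate) mod (2^31 - 1)}), so any
#' subset of the study can be regenerated in isolation.
#'
#' @param design a [SyntheticDesign-class].
#' @param mode \code{"gamma_approx"} (fast, default) or \code{"ssa"}.
#' @param truth optionally a precomputed [groundTruth()] table.
#' @return Event table (data.frame: \code{construct_id}, \code{replicate},
#'   \code{intensity}) covering all groups plus \code{"blank"}.
#' @export
generateEvents <- function(design, mode = c("gamma_approx", "ssa"),
                           truth = groundTruth(design)) {
    stopifnot(is(design, "SyntheticDesign"))
    mode <- match.arg(mode)
    if (mode == "ssa" && design@nEvents > 1e5)
        warning("ssa mode with more than 1e5 events per replicate is costly")
    sRep <- .lnormSdlog(design@replicateCv)
    blankMean <- design@blankFraction *
        truth$true_mean[truth$construct_id == "control"]
    groups <- rbind(
        truth[, c("construct_id", "true_mean", "true_noise", "k_on", "k_off")],
        data.frame(construct_id = "blank", true_mean = blankMean,
                   true_noise = 0.25, k_on = NA_real_, k_off = NA_real_))
    chunks <- vector("list", nrow(groups) * design@nReplicates)
    idx <- 1L
    for (i in seq_len(nrow(groups))) {
        g <- groups[i, ]
        for (r in seq_len(design@nReplicates)) {
            seed <- .groupSeed(design@seed, i, r)
            set.seed(seed)
            jitter <- if (design@replicateCv > 0)
                stats::rlnorm(1, meanlog = -sRep^2 / 2, sdlog = sRep) else 1
            if (mode == "gamma_approx" || g$construct_id == "blank") {
                x <- .drawGammaEvents(design@nEvents, g$true_mean * jitter,
                                      g$true_noise, design@measurementCv)
            } else {
                kin <- promoterKinetics(
                    kOn = g$k_on, kOff = g$k_off,
                    kOnWt = max(g$k_on, design@wt@kOnWt),
                    kOffWt = max(g$k_off, design@wt@kOffWt),
                    tau = design@wt@tau,
                    C = g$true_mean * (g$k_on + g$k_off) / g$k_on)
                counts <- proteinCounts(sampleSteadyState(
                    reactionSystem(kin), design@nEvents, seed = seed))
                x <- counts * jitter
                if (design@measurementCv > 0) {
                    s <- .lnormSdlog(design@measurementCv)
                    x <- x * stats::rlnorm(design@nEvents,
                                           meanlog = -s^2 / 2, sdlog = s)
                }
            }
            chunks[[idx]] <- data.frame(construct_id = g$construct_id,
                                        replicate = r, intensity = x)
            idx <- idx + 1L
        }
    }
    out <- do.call(rbind, chunks)
    rownames(out) <- NULL
    out
}

#' Generate a complete synthetic study bundle
#'
#' One call yields everything the analysis pipeline consumes end-to-end:
#' the event table over the CRISPRar library, the single-sgRNA variant set,
#' the control and the blank; the ground-truth table; the library
#' configuration; and a manifest recording all parameters and the seed
#' scheme. When \code{dir} is given, writes \code{events.csv},
#' \code{ground_truth.tsv}, \code{library.yaml} and \code{manifest.yaml}
#' there.
#'
#' @param design a [SyntheticDesign-class].
#' @param dir output directory (created if missing); NULL for in-memory
#'   only.
#' @param mode event-generation mode, see [generateEvents()].
#' @return List with \code{events}, \code{truth}, \code{manifest} (list)
#'   and, if written, \code{paths}.
#' @export
generateStudy <- function(design, dir = NULL,
                          mode = c("gamma_approx", "ssa")) {
    stopifnot(is(design, "SyntheticDesign"))
    mode <- match.arg(mode)
    truth <- groundTruth(design)
    events <- generateEvents(design, mode = mode, truth = truth)
    manifest <- list(
        seed = design@seed,
        seed_scheme = "(seed + 7919*group_index + 104729*replicate) mod (2^31-1); group_index is the ground-truth row, blank is last",
        mode = mode,
        n_replicates = design@nReplicates,
        n_events = design@nEvents,
        measurement_cv = design@measurementCv,
        replicate_cv = design@replicateCv,
        blank_fraction = design@blankFraction,
        model = list(k_on_wt = design@wt@kOnWt, k_off_wt = design@wt@kOffWt,
                     tau = design@wt@tau, C = design@wt@C,
                     K_ro = design@params@KRo, K_ao = design@params@KAo,
                     K_i = design@params@Ki, K_int1 = design@params@Kint1,
                     K_int2 = design@params@Kint2))
    out <- list(events = events, truth = truth, manifest = manifest)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- list(events = file.path(dir, "events.csv"),
                      truth = file.path(dir, "ground_truth.tsv"),
                      library = file.path(dir, "library.yaml"),
                      manifest = file.path(dir, "manifest.yaml"))
        writeEventTable(events, paths$events)
        utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        writeLibraryConfig(.designLibraryConfig(design), paths$library)
        yaml::write_yaml(manifest, paths$manifest)
        out$paths <- paths
    }
    out
}

## serialize the design's module sets in the library-config schema
.designLibraryConfig <- function(design) {
    mods <- c(design@singleModules,
              lapply(design@library, actModule),
              lapply(design@library, repModule))
    sgSeen <- list()
    promSeen <- list()
    for (m in mods) {
        if (is.null(sgSeen[[m@name]]))
            sgSeen[[m@name]] <- list(name = m@name, role = m@role,
                                     strand = m@targetStrand,
                                     pam_position = m@pamPosition,
                                     regulation_strength = m@regulationStrength)
        promSeen[[m@promoter]] <- list(name = m@promoter,
                                       strength = m@promoterStrength)
    }
    moduleEntries <- function(getter) {
        keys <- character()
        out <- list()
        for (cstr in design@library) {
            m <- getter(cstr)
            key <- paste(m@promoter, m@name, sep = "_")
            if (!key %in% keys) {
                keys <- c(keys, key)
                out[[length(out) + 1L]] <- list(promoter = m@promoter,
                                                sgrna = m@name)
            }
        }
        out
    }
    hasSwap <- any(vapply(design@library,
                          function(x) x@transcriptionOrder == "rep_first",
                          logical(1)))
    cfg <- list(promoters = unname(promSeen), sgrnas = unname(sgSeen),
                single_variants = unname(lapply(design@singleModules,
                                                function(m) m@name)))
    if (length(design@library))
        cfg$crisprar <- list(activation = moduleEntries(actModule),
                             repression = moduleEntries(repModule),
                             swap_equal_promoter = hasSwap)
    cfg
}
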
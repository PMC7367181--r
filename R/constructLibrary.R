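#' Split the unit sgRNA pool between the two modules
#'
#' The sgRNA pool in a cell has unit capacity, shared by the two sgRNAs in
#' proportion to the strengths of their constitutive promoters:
#' \code{concA = sA/(sA+sR)}, \code{concR = sR/(sA+sR)}. Scale-invariant in
#' the strengths.
#'
#' @param strengthA,strengthR promoter strengths of the activating and
#'   repressing modules (> 0).
#' @return Named numeric vector \code{c(concA=, concR=)} summing to 1.
#' @examples
#' allocateConcentrations(12, 1)   # strong vs weak promoter: 12/13, 1/13
#' @export
allocateConcentrations <- function(strengthA, strengthR) {
    if (!is.numeric(strengthA) || !is.numeric(strengthR) ||
        strengthA <= 0 || strengthR <= 0)
        stop("configuration error: promoter strengths must be positive")
    s <- strengthA + strengthR
    c(concA = strengthA / s, concR = strengthR / s)
}

#' Strand relation of a construct's two modules
#'
#' @param construct a [CrisprarConstruct-class].
#' @return \code{"same"} if both sgRNAs target the same DNA strand, else
#'   \code{"opposite"}.
#' @export
strandRelation <- function(construct) {
    stopifnot(is(construct, "CrisprarConstruct"))
    if (construct@actModule@targetStrand == construct@repModule@targetStrand)
        "same" else "opposite"
}

#' Classify a construct by the three empirical rules
#'
#' Rule 1: does the activating sgRNA target the non-coding strand
#' (associated with higher expression mean) or the coding strand?
#' Rule 2: do the two sgRNAs target the same strand (competition, higher
#' noise) or opposite strands? Rule 3: are the two sgRNA concentrations
#' (promoter strengths) approximately equal (lower noise at low expression)
#' or unequal?
#'
#' @param construct a [CrisprarConstruct-class].
#' @param equalTolerance relative promoter-strength tolerance for rule 3;
#'   the default 0 calls concentrations equal only for identical strengths
#'   (i.e. the same promoter).
#' @return Named character vector with elements \code{rule1}
#'   (\code{"a_noncoding"}/\code{"a_coding"}), \code{rule2}
#'   (\code{"same_strand"}/\code{"opposite_strand"}) and \code{rule3}
#'   (\code{"equal_conc"}/\code{"unequal_conc"}).
#' @export
classifyConstruct <- function(construct, equalTolerance = 0) {
    stopifnot(is(construct, "CrisprarConstruct"))
    rule1 <- if (construct@actModule@targetStrand == "non_coding")
        "a_noncoding" else "a_coding"
    rule2 <- if (strandRelation(construct) == "same")
        "same_strand" else "opposite_strand"
    sA <- construct@actModule@promoterStrength
    sR <- construct@repModule@promoterStrength
    equal <- abs(sA - sR) <= equalTolerance * max(sA, sR)
    rule3 <- if (equal) "equal_conc" else "unequal_conc"
    c(rule1 = rule1, rule2 = rule2, rule3 = rule3)
}

#' Default promoter strengths
#'
#' Relative transcription strengths of the three constitutive sgRNA
#' promoters: the strong promoter is 12-fold stronger than the weak one and
#' 5-fold stronger than the medium one (pWeak = 1, pMed = 12/5, pStr = 12).
#'
#' @return Named numeric vector of strengths.
#' @export
defaultPromoterStrengths <- function() {
    c(pWeak = 1, pMed = 2.4, pStr = 12, consensus = 1)
}

#' Default single-sgRNA variant set
#'
#' The nine sgRNA variants targeting the reporter promoter region from the
#' consensus constitutive promoter: three repressors (PAM 40-60 bp upstream
#' of +1) and six activators (60-100 bp, with activation peaking around
#' 80 bp). Regulation strengths are the package's synthetic ground-truth
#' defaults; strand assignments of A1/A2/R2/R3 follow the library design
#' (A1, R2 coding; A2, R3 non-coding).
#'
#' @return Named list of nine [SgRNAModule-class] objects.
#' @export
defaultSingleModules <- function() {
    spec <- list(
        list("R1", "repressor", "coding",      42, 0.70),
        list("R2", "repressor", "coding",      50, 0.60),
        list("R3", "repressor", "non_coding",  56, 0.40),
        list("A1", "activator", "coding",      65, 0.40),
        list("A2", "activator", "non_coding",  70, 0.60),
        list("A3", "activator", "coding",      80, 0.70),
        list("A4", "activator", "non_coding",  84, 0.65),
        list("A5", "activator", "coding",      92, 0.50),
        list("A6", "activator", "non_coding", 100, 0.25))
    mods <- lapply(spec, function(s)
        sgRNAModule(name = s[[1]], role = s[[2]], targetStrand = s[[3]],
                    pamPosition = s[[4]], promoter = "consensus",
                    promoterStrength = 1, regulationStrength = s[[5]]))
    names(mods) <- vapply(mods, function(m) m@name, character(1))
    mods
}

#' Default CRISPRar module sets
#'
#' The twelve promoter-sgRNA modules of the combinatorial library: the
#' selected variants A1, A2 (activators) and R2, R3 (repressors), each
#' paired with the strong, medium and weak constitutive promoters.
#'
#' @return List with elements \code{activation} and \code{repression}, each
#'   a list of six [SgRNAModule-class] objects.
#' @export
defaultCrisprarModules <- function() {
    singles <- defaultSingleModules()
    strengths <- defaultPromoterStrengths()
    promoters <- c("pStr", "pMed", "pWeak")
    withPromoter <- function(m, p) {
        m@promoter <- p
        m@promoterStrength <- unname(strengths[p])
        m
    }
    act <- unlist(lapply(promoters, function(p)
        lapply(singles[c("A1", "A2")], withPromoter, p = p)), recursive = FALSE)
    rep_ <- unlist(lapply(promoters, function(p)
        lapply(singles[c("R2", "R3")], withPromoter, p = p)), recursive = FALSE)
    names(act) <- vapply(act, function(m) paste(m@promoter, m@name, sep = "_"),
                         character(1))
    names(rep_) <- vapply(rep_, function(m) paste(m@promoter, m@name, sep = "_"),
                          character(1))
    list(activation = act, repression = rep_)
}

#' Enumerate the CRISPRar construct library
#'
#' All activation x repression module pairings (transcription order
#' act-first), plus order-swapped duplicates for the pairings whose two
#' modules use the same promoter. With the default six-by-six module sets
#' this yields 36 unique pairings plus 12 swaps = 48 constructs.
#'
#' @param actModules,repModules lists of [SgRNAModule-class] with the
#'   matching roles; module names must be unique within each list after
#'   combining with the promoter.
#' @param swapEqualPromoter if TRUE (default), add a rep-first duplicate of
#'   every pairing whose modules share one promoter.
#' @return List of [CrisprarConstruct-class], deterministic order and ids.
#' @examples
#' mods <- defaultCrisprarModules()
#' length(enumerateLibrary(mods$activation, mods$repression))  # 48
#' @export
enumerateLibrary <- function(actModules = defaultCrisprarModules()$activation,
                             repModules = defaultCrisprarModules()$repression,
                             swapEqualPromoter = TRUE) {
    keyOf <- function(m) paste(m@promoter, m@name, sep = "_")
    aKeys <- vapply(actModules, keyOf, character(1))
    rKeys <- vapply(repModules, keyOf, character(1))
    if (anyDuplicated(aKeys) || anyDuplicated(rKeys))
        stop("configuration error: duplicate module names")
    lib <- list()
    for (a in actModules) for (r in repModules)
        lib[[length(lib) + 1L]] <- crisprarConstruct(a, r, "act_first")
    if (swapEqualPromoter)
        for (a in actModules) for (r in repModules)
            if (a@promoter == r@promoter)
                lib[[length(lib) + 1L]] <- crisprarConstruct(a, r, "rep_first")
    names(lib) <- vapply(lib, constructId, character(1))
    if (anyDuplicated(names(lib)))
        stop("configuration error: duplicate construct ids")
    lib
}

#' Select constructs with a three-layer decision tree
#'
#' Two selection modes mirroring the two ways mean and noise can be tuned
#' independently. Mode \code{"same_mean_diff_noise"}: layer 1 restricts to
#' the low-expression region (where noise decouples from mean), then the
#' densest window of constructs whose means agree within
#' \code{meanTolerance} (relative) is returned sorted by increasing noise;
#' layers 2 and 3 (opposite before same strand, equal before unequal
#' concentration) are reported as the leaf rank of each construct. Mode
#' \code{"same_noise_diff_mean"}: layer 1 restricts to the low-noise region
#' (noise at or below the \code{noiseRegionQuantile} quantile), then the
#' densest window agreeing within \code{noiseTolerance} is returned sorted
#' by increasing mean, with leaf ranks from coding-strand-activator before
#' non-coding (layer 2) and opposite before same strand (layer 3).
#'
#' @param summaries data.frame with columns \code{construct_id},
#'   \code{mean}, \code{noise}, \code{region} (\code{"high_expression"} /
#'   \code{"low_expression"}), \code{rule1}, \code{rule2}, \code{rule3}
#'   (see [predictLibrarySummaries()]).
#' @param mode \code{"same_mean_diff_noise"} or \code{"same_noise_diff_mean"}.
#' @param meanTolerance,noiseTolerance relative agreement tolerances for the
#'   matched quantity.
#' @param minSelection smallest selection worth returning (default 4); if no
#'   window reaches it a zero-row data.frame is returned (empty-selection
#'   signal, not an error).
#' @param noiseRegionQuantile quantile of library noise defining the
#'   low-noise region in mode \code{"same_noise_diff_mean"}.
#' @param distinct collapse rows with exactly duplicated (mean, noise)
#'   before selection (e.g. transcription-order twins, which the model
#'   cannot distinguish). Keeps the first occurrence in input order.
#' @return data.frame of selected constructs, ordered by the varied
#'   quantity, with columns of \code{summaries} plus \code{leaf_rank} and
#'   \code{selection_rank}.
#' @export
decisionTreeSelect <- function(summaries,
                               mode = c("same_mean_diff_noise",
                                        "same_noise_diff_mean"),
                               meanTolerance = 0.05, noiseTolerance = 0.10,
                               minSelection = 4L, noiseRegionQuantile = 0.5,
                               distinct = FALSE) {
    mode <- match.arg(mode)
    need <- c("construct_id", "mean", "noise", "region",
              "rule1", "rule2", "rule3")
    if (!is.data.frame(summaries) || nrow(summaries) == 0L)
        stop("summaries must be a nonempty data.frame")
    if (!all(need %in% names(summaries)))
        stop("summaries must have columns: ", paste(need, collapse = ", "))
    s <- summaries
    if (distinct)
        s <- s[!duplicated(s[, c("mean", "noise")]), , drop = FALSE]

    empty <- s[0, , drop = FALSE]
    empty$leaf_rank <- integer(0)
    empty$selection_rank <- integer(0)

    if (mode == "same_mean_diff_noise") {
        s <- s[s$region == "low_expression", , drop = FALSE]
        matchedVar <- "mean"
        tol <- meanTolerance
        s$leaf_rank <- 1L + 2L * (s$rule2 == "same_strand") +
            (s$rule3 == "unequal_conc")
        orderVar <- "noise"
    } else {
        thr <- stats::quantile(s$noise, noiseRegionQuantile, names = FALSE)
        s <- s[s$noise <= thr, , drop = FALSE]
        matchedVar <- "noise"
        tol <- noiseTolerance
        s$leaf_rank <- 1L + 2L * (s$rule1 == "a_noncoding") +
            (s$rule2 == "same_strand")
        orderVar <- "mean"
    }
    if (nrow(s) == 0L) return(empty)

    ## densest window of the matched variable with pairwise relative
    ## agreement within tol: sort, then two-pointer scan
    v <- s[[matchedVar]]
    o <- order(v)
    v <- v[o]
    best <- c(0L, 0L)
    lo <- 1L
    for (hi in seq_along(v)) {
        while (v[hi] - v[lo] > tol * v[lo]) lo <- lo + 1L
        if (hi - lo > best[2] - best[1]) best <- c(lo, hi)
    }
    sel <- s[o[best[1]:best[2]], , drop = FALSE]
    if (nrow(sel) < minSelection) return(empty)
    sel <- sel[order(sel[[orderVar]], sel$construct_id), , drop = FALSE]
    sel$selection_rank <- seq_len(nrow(sel))
    rownames(sel) <- NULL
    sel
}

#' Write a decision-tree selection as TSV
#'
#' @param selection data.frame from [decisionTreeSelect()].
#' @param path output path.
#' @return The selection, invisibly.
#' @export
writeSelections <- function(selection, path) {
    utils::write.table(selection, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(selection)
}

## ---- library configuration files ----

.assertKnownKeys <- function(x, known, where) {
    extra <- setdiff(names(x), known)
    if (length(extra))
        stop(sprintf("configuration error: unknown key(s) %s in %s",
                     paste(sQuote(extra), collapse = ", "), where))
}

#' Read a construct-library configuration (YAML)
#'
#' The file declares promoters (\code{name}, \code{strength}), sgRNAs
#' (\code{name}, \code{role}, \code{strand}, \code{pam_position}, optional
#' \code{regulation_strength}), the single-variant set
#' (\code{single_variants}, measured individually from the consensus
#' promoter) and the CRISPRar enumeration block (\code{crisprar} with
#' \code{activation}/\code{repression} module lists of
#' \code{{promoter, sgrna}} pairs, crossed into the construct library, and
#' \code{swap_equal_promoter}).
#'
#' @param path YAML file path.
#' @return List with \code{singleModules} (list of [SgRNAModule-class]) and
#'   \code{library} (list of [CrisprarConstruct-class]).
#' @seealso [writeLibraryConfig()], [defaultLibraryConfig()]
#' @export
readLibraryConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    .assertKnownKeys(cfg, c("promoters", "sgrnas", "single_variants",
                            "crisprar"), "library config")
    strengths <- vapply(cfg$promoters, function(p) {
        .assertKnownKeys(p, c("name", "strength"), "promoters")
        as.numeric(p$strength)
    }, numeric(1))
    names(strengths) <- vapply(cfg$promoters, `[[`, character(1), "name")

    sgSpecs <- cfg$sgrnas
    names(sgSpecs) <- vapply(sgSpecs, `[[`, character(1), "name")
    buildModule <- function(name, promoter) {
        sp <- sgSpecs[[name]]
        if (is.null(sp)) stop("configuration error: unknown sgRNA ", name)
        .assertKnownKeys(sp, c("name", "role", "strand", "pam_position",
                               "regulation_strength"), "sgrnas")
        if (!promoter %in% names(strengths))
            stop("configuration error: unknown promoter ", promoter)
        sgRNAModule(name = sp$name, role = sp$role, targetStrand = sp$strand,
                    pamPosition = sp$pam_position, promoter = promoter,
                    promoterStrength = unname(strengths[promoter]),
                    regulationStrength =
                        if (is.null(sp$regulation_strength)) NA_real_
                        else as.numeric(sp$regulation_strength))
    }

    singleModules <- lapply(cfg$single_variants, buildModule,
                            promoter = "consensus")
    names(singleModules) <- unlist(cfg$single_variants)

    lib <- list()
    if (!is.null(cfg$crisprar)) {
        .assertKnownKeys(cfg$crisprar, c("activation", "repression",
                                         "swap_equal_promoter"), "crisprar")
        expand <- function(block) {
            mods <- list()
            for (e in block) {
                .assertKnownKeys(e, c("promoter", "sgrna"), "crisprar module")
                mods[[paste(e$promoter, e$sgrna, sep = "_")]] <-
                    buildModule(e$sgrna, e$promoter)
            }
            mods
        }
        act <- expand(cfg$crisprar$activation)
        rep_ <- expand(cfg$crisprar$repression)
        swap <- isTRUE(cfg$crisprar$swap_equal_promoter)
        lib <- enumerateLibrary(act, rep_, swapEqualPromoter = swap)
    }
    list(singleModules = singleModules, library = lib)
}

#' The package's default library configuration
#'
#' @return The configuration list (serializable to YAML) describing the
#'   default promoters, nine single-sgRNA variants and the 48-construct
#'   CRISPRar enumeration.
#' @export
defaultLibraryConfig <- function() {
    singles <- defaultSingleModules()
    strengths <- defaultPromoterStrengths()
    list(
        promoters = lapply(names(strengths), function(n)
            list(name = n, strength = unname(strengths[n]))),
        sgrnas = lapply(unname(singles), function(m)
            list(name = m@name, role = m@role, strand = m@targetStrand,
                 pam_position = m@pamPosition,
                 regulation_strength = m@regulationStrength)),
        single_variants = as.list(names(singles)),
        crisprar = list(
            activation = unlist(lapply(c("pStr", "pMed", "pWeak"), function(p)
                lapply(c("A1", "A2"), function(g)
                    list(promoter = p, sgrna = g))), recursive = FALSE),
            repression = unlist(lapply(c("pStr", "pMed", "pWeak"), function(p)
                lapply(c("R2", "R3"), function(g)
                    list(promoter = p, sgrna = g))), recursive = FALSE),
            swap_equal_promoter = TRUE))
}

#' Write a library configuration to YAML
#'
#' @param config a configuration list as returned by
#'   [defaultLibraryConfig()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLibraryConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
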
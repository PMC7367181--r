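#' Regulation-strength estimators from expression fold changes
#'
#' At saturating sgRNA concentration a lone repressing module reduces the
#' ON-rate to \code{kOnWt * (1 - kR)}, so the measured control-normalized
#' fold change is
#' \deqn{f = \frac{k_{on,wt}(1-k_r)}{k_{on,wt}(1-k_r)+k_{off,wt}} \Big/
#'            \frac{k_{on,wt}}{k_{on,wt}+k_{off,wt}},}
#' which is inverted for \eqn{k_r}; with wild-type rates 1 this is
#' \eqn{k_r = (2-2f)/(2-f)}. The activating analogue lowers the OFF-rate to
#' \code{kOffWt * (1 - kA)}; with wild-type rates 1, \eqn{f = 2/(2-k_a)} and
#' \eqn{k_a = 2 - 2/f}. Estimates are clamped to [0, 1]; an activation fold
#' change beyond the model's ceiling (2 at wild-type rates 1) triggers a
#' saturation warning.
#'
#' @param foldChange regulated/control mean expression ratio. Must be in
#'   (0, 1] for repression and >= 1 for activation.
#' @param wt wild-type [PromoterKinetics-class] (its \code{kOnWt},
#'   \code{kOffWt} enter the inversion).
#' @return numeric(1) estimated strength in [0, 1].
#' @examples
#' estimateRepressionStrength(0.5)          # 2/3
#' estimateActivationStrength(4 / 3)        # 0.5
#' @name strengthEstimation
NULL

#' @rdname strengthEstimation
#' @export
estimateRepressionStrength <- function(foldChange, wt = promoterKinetics()) {
    stopifnot(is(wt, "PromoterKinetics"))
    if (!is.numeric(foldChange) || length(foldChange) != 1L ||
        !is.finite(foldChange) || foldChange <= 0)
        stop("domain error: fold change must be a positive finite number")
    if (foldChange > 1)
        stop("not a repressor: fold change > 1")
    a <- wt@kOnWt; b <- wt@kOffWt
    m0 <- a / (a + b)
    ## f * m0 = x / (x + b) with x = a * (1 - kR)
    x <- foldChange * m0 * b / (1 - foldChange * m0)
    min(max(1 - x / a, 0), 1)
}

#' @rdname strengthEstimation
#' @export
estimateActivationStrength <- function(foldChange, wt = promoterKinetics()) {
    stopifnot(is(wt, "PromoterKinetics"))
    if (!is.numeric(foldChange) || length(foldChange) != 1L ||
        !is.finite(foldChange) || foldChange <= 0)
        stop("domain error: fold change must be a positive finite number")
    if (foldChange < 1)
        stop("not an activator: fold change < 1")
    a <- wt@kOnWt; b <- wt@kOffWt
    m0 <- a / (a + b)
    fMax <- 1 / m0  # fold change of a never-OFF promoter
    if (foldChange > fMax + 1e-12) {
        warning(sprintf(
            "saturation: fold change %.4g exceeds the model ceiling %.4g; strength clamped to 1",
            foldChange, fMax))
        return(1)
    }
    ## f * m0 = a / (a + b * (1 - kA))
    kA <- 1 - a * (1 / (foldChange * m0) - 1) / b
    min(max(kA, 0), 1)
}

#' Forward fold-change maps (the estimators' inverses)
#'
#' Predicted control-normalized fold change of a lone, saturated repressing
#' or activating module with the given strength. Used to verify the
#' estimators are exact inverses and to build synthetic ground truth.
#'
#' @param kR,kA regulation strength in [0, 1].
#' @param wt wild-type [PromoterKinetics-class].
#' @return numeric(1) fold change.
#' @name foldChangeMaps
NULL

#' @rdname foldChangeMaps
#' @export
repressionFoldChange <- function(kR, wt = promoterKinetics()) {
    a <- wt@kOnWt; b <- wt@kOffWt
    (a * (1 - kR) / (a * (1 - kR) + b)) / (a / (a + b))
}

#' @rdname foldChangeMaps
#' @export
activationFoldChange <- function(kA, wt = promoterKinetics()) {
    a <- wt@kOnWt; b <- wt@kOffWt
    (a / (a + b * (1 - kA))) / (a / (a + b))
}

#' Predict kinetics, mean and noise of a CRISPRar construct
#'
#' Composes the sgRNA concentration allocation, the strand relation of the
#' two modules and the rate-modulation law into the modulated promoter
#' kinetics and the analytic (mean, noise) pair. The constants of
#' \code{params} are used with the regulation strengths carried by the
#' construct's modules.
#'
#' @param construct a [CrisprarConstruct-class] whose modules have
#'   \code{regulationStrength} set.
#' @param params [CrisprParams-class] (its \code{kR}/\code{kA} slots are
#'   overridden by the module strengths).
#' @param wt wild-type [PromoterKinetics-class].
#' @return List with \code{kinetics} ([PromoterKinetics-class]),
#'   \code{mean} and \code{noise}.
#' @export
predictConstructRates <- function(construct, params = crisprParams(),
                                  wt = promoterKinetics()) {
    stopifnot(is(construct, "CrisprarConstruct"))
    kA <- construct@actModule@regulationStrength
    kR <- construct@repModule@regulationStrength
    if (is.na(kA) || is.na(kR))
        stop("incomplete estimation: both modules need a regulation strength")
    p <- crisprParams(kR = kR, kA = kA, KRo = params@KRo, KAo = params@KAo,
                      Ki = params@Ki, Kint1 = params@Kint1,
                      Kint2 = params@Kint2)
    kin <- applyCrisprar(wt, p, concA = construct@concA,
                         concR = construct@concR,
                         strandRelation = strandRelation(construct))
    m <- meanExpression(kin)
    list(kinetics = kin, mean = m, noise = noiseExpression(kin, m))
}

#' Model-predicted summaries of a construct library
#'
#' One row per construct with predicted kinetics, mean, noise, normalized
#' mean (relative to the unregulated control mean \code{C/2}), its inverse,
#' the expression region and the three empirical-rule labels: the input the
#' decision-tree selector and the contour projection work from.
#'
#' @param library list of [CrisprarConstruct-class].
#' @param params [CrisprParams-class].
#' @param wt wild-type [PromoterKinetics-class].
#' @param regionThreshold low-expression region is
#'   \code{inv_norm_mean > regionThreshold} (default 1, i.e. below-control
#'   expression).
#' @return data.frame with columns \code{construct_id}, \code{k_on},
#'   \code{k_off}, \code{mean}, \code{noise}, \code{norm_mean},
#'   \code{inv_norm_mean}, \code{region}, \code{rule1}, \code{rule2},
#'   \code{rule3}.
#' @export
predictLibrarySummaries <- function(library, params = crisprParams(),
                                    wt = promoterKinetics(),
                                    regionThreshold = 1) {
    stopifnot(length(library) > 0)
    controlMean <- meanExpression(wt)
    rows <- lapply(library, function(cstr) {
        pred <- predictConstructRates(cstr, params, wt)
        labels <- classifyConstruct(cstr)
        nm <- pred$mean / controlMean
        data.frame(construct_id = constructId(cstr),
                   k_on = kOn(pred$kinetics), k_off = kOff(pred$kinetics),
                   mean = pred$mean, noise = pred$noise,
                   norm_mean = nm, inv_norm_mean = 1 / nm,
                   region = if (1 / nm > regionThreshold) "low_expression"
                            else "high_expression",
                   rule1 = labels[["rule1"]], rule2 = labels[["rule2"]],
                   rule3 = labels[["rule3"]])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Fit the noise versus inverse-mean line
#'
#' Ordinary least squares of noise on 1/normalized mean, both on linear
#' scales. For a constitutive promoter (always ON) the model predicts an
#' exact line through the origin with slope equal to the inverse control
#' mean, so the fit's R-squared measures how constitutive-like a point set
#' is; two-state switching shows up as upward deviations.
#'
#' @param points data.frame with columns \code{inv_norm_mean} and
#'   \code{noise} (finite, positive); at least 3 rows.
#' @return A [LinearNoiseFit-class] object.
#' @examples
#' pts <- data.frame(inv_norm_mean = 0:2, noise = c(0, 1, 1))
#' fitNoiseLine(pts)   # slope 0.5, intercept 1/6, R^2 = 0.75
#' @export
fitNoiseLine <- function(points) {
    if (!is.data.frame(points) ||
        !all(c("inv_norm_mean", "noise") %in% names(points)))
        stop("points must have columns inv_norm_mean and noise")
    if (nrow(points) < 3)
        stop("insufficient data: at least 3 points required")
    if (stats::var(points$inv_norm_mean) == 0)
        stop("degenerate fit: zero variance in inv_norm_mean")
    fit <- stats::lm(noise ~ inv_norm_mean, data = points)
    new("LinearNoiseFit",
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        rSquared = summary(fit)$r.squared,
        n = nrow(points))
}

#' Region-wise average deviation from a reference noise line
#'
#' Mean absolute vertical (noise-axis) residual of each point from the
#' reference line, computed separately for each expression region. Scored
#' against the fit from a single-sgRNA (constitutive-regime) reference set,
#' this quantifies how strongly CRISPRar constructs decouple noise from
#' mean, region by region.
#'
#' @param points data.frame with \code{inv_norm_mean}, \code{noise} and
#'   \code{region} columns.
#' @param fit a [LinearNoiseFit-class], typically from the reference set.
#' @return Named numeric vector of mean absolute deviations, one element
#'   per region present in \code{points}.
#' @export
averageDeviation <- function(points, fit) {
    stopifnot(is(fit, "LinearNoiseFit"))
    if (!all(c("inv_norm_mean", "noise", "region") %in% names(points)))
        stop("points must have columns inv_norm_mean, noise and region")
    resid <- abs(points$noise -
                 (fit@slope * points$inv_norm_mean + fit@intercept))
    tapply(resid, points$region, mean)
}

#' Compare noise between two groups at matched mean expression
#'
#' Pairs points across the two groups whose 1/normalized-mean values differ
#' by at most \code{matchTolerance} (default 0.03), greedily closest-first
#' with each point used at most once, then reports the per-pair noise
#' differences, their mean, and a two-way ANOVA (factors: group and matched
#' pair) on the matched subset.
#'
#' @param groupA,groupB data.frames with \code{construct_id},
#'   \code{inv_norm_mean} and \code{noise} columns.
#' @param matchTolerance maximum |x_A - x_B| for a pair.
#' @return List with \code{pairs} (data.frame: ids, x and noise values,
#'   \code{noise_diff} = A - B), \code{mean_noise_diff}, \code{n_pairs},
#'   and \code{p_value} of the group factor (NA with fewer than 2 pairs).
#'   Zero matched pairs gives \code{n_pairs = 0} (no-overlap signal).
#' @export
matchedMeanComparison <- function(groupA, groupB, matchTolerance = 0.03) {
    for (g in list(groupA, groupB))
        if (!is.data.frame(g) || nrow(g) == 0L ||
            !all(c("construct_id", "inv_norm_mean", "noise") %in% names(g)))
            stop("groups must be nonempty with construct_id, inv_norm_mean, noise")
    d <- abs(outer(groupA$inv_norm_mean, groupB$inv_norm_mean, "-"))
    cand <- which(d <= matchTolerance, arr.ind = TRUE)
    if (nrow(cand)) {
        ## greedy closest-first; ties resolved by row order in each group
        cand <- cand[order(d[cand], cand[, 1], cand[, 2]), , drop = FALSE]
        usedA <- logical(nrow(groupA)); usedB <- logical(nrow(groupB))
        keep <- logical(nrow(cand))
        for (i in seq_len(nrow(cand))) {
            a <- cand[i, 1]; b <- cand[i, 2]
            if (!usedA[a] && !usedB[b]) {
                keep[i] <- TRUE; usedA[a] <- TRUE; usedB[b] <- TRUE
            }
        }
        cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) == 0L)
        return(list(pairs = data.frame(), mean_noise_diff = NA_real_,
                    n_pairs = 0L, p_value = NA_real_))
    pairs <- data.frame(
        id_a = groupA$construct_id[cand[, 1]],
        id_b = groupB$construct_id[cand[, 2]],
        x_a = groupA$inv_norm_mean[cand[, 1]],
        x_b = groupB$inv_norm_mean[cand[, 2]],
        noise_a = groupA$noise[cand[, 1]],
        noise_b = groupB$noise[cand[, 2]])
    pairs$noise_diff <- pairs$noise_a - pairs$noise_b
    pValue <- NA_real_
    if (nrow(pairs) >= 2L) {
        long <- data.frame(
            noise = c(pairs$noise_a, pairs$noise_b),
            group = factor(rep(c("A", "B"), each = nrow(pairs))),
            pair = factor(rep(seq_len(nrow(pairs)), 2)))
        av <- stats::aov(noise ~ group + pair, data = long)
        pValue <- summary(av)[[1]][["Pr(>F)"]][1]
    }
    list(pairs = pairs, mean_noise_diff = mean(pairs$noise_diff),
         n_pairs = nrow(pairs), p_value = pValue)
}

#' Estimate regulation strengths of single-sgRNA modules from summaries
#'
#' For every module, takes the replicate-averaged control-normalized mean of
#' its single-sgRNA group (\code{single_<name>}) as the saturated fold
#' change and inverts it with the matching estimator. Fold changes that
#' cross 1 by measurement noise (a nominally repressing module measuring
#' just above control, or vice versa) are clamped to 1, giving strength 0.
#'
#' @param summaries normalized summary table (see [normalizeToControl()])
#'   containing the \code{single_<name>} groups.
#' @param modules list of [SgRNAModule-class] to estimate.
#' @param wt wild-type [PromoterKinetics-class].
#' @return Named numeric vector of estimated strengths (kR for repressors,
#'   kA for activators).
#' @export
estimateModuleStrengths <- function(summaries, modules,
                                    wt = promoterKinetics()) {
    out <- vapply(modules, function(m) {
        id <- paste0("single_", m@name)
        nm <- summaries$norm_mean[summaries$construct_id == id]
        if (!length(nm))
            stop("no summaries for module group ", id)
        fold <- mean(nm)
        if (m@role == "repressor")
            estimateRepressionStrength(min(fold, 1), wt)
        else
            estimateActivationStrength(max(fold, 1), wt)
    }, numeric(1))
    names(out) <- vapply(modules, function(m) m@name, character(1))
    out
}

#' Strand-rule comparison of noise terms at matched analytic mean
#'
#' The model-level analog of the second empirical rule: among construct
#' pairs (one targeting the same strand with both sgRNAs, one targeting
#' opposite strands) whose analytic means agree within a ratio tolerance,
#' compare the switching noise term \eqn{1/(\tau (k_{on}+k_{off}) + 1)}.
#' Competition on the same strand barely weakens either module (the
#' binding constants are far below the sgRNA concentrations), so both
#' switching rates stay low and the noise term stays high; opposite-strand
#' interference weakens both modules, pushing the rates back toward
#' wild-type and the noise term down.
#'
#' @param summaries predicted library summaries from
#'   [predictLibrarySummaries()] (duplicated (mean, noise) rows, e.g.
#'   transcription-order twins, are collapsed).
#' @param ratioTolerance maximum |mean ratio - 1| for a matched pair.
#' @param tau protein lifetime.
#' @return data.frame of matched pairs (ids, means, the two noise terms,
#'   \code{same_noisier}); the fraction of pairs with the same-strand term
#'   at or above the opposite-strand term is attached as attribute
#'   \code{"fraction_same_noisier"}.
#' @export
strandMatchedNoiseComparison <- function(summaries, ratioTolerance = 0.01,
                                         tau = 1) {
    s <- summaries[!duplicated(summaries[, c("mean", "noise")]), , drop = FALSE]
    same <- s[s$rule2 == "same_strand", , drop = FALSE]
    opp <- s[s$rule2 == "opposite_strand", , drop = FALSE]
    term <- function(g) 1 / (tau * (g$k_on + g$k_off) + 1)
    rows <- list()
    for (i in seq_len(nrow(same))) for (j in seq_len(nrow(opp))) {
        if (abs(same$mean[i] / opp$mean[j] - 1) <= ratioTolerance) {
            rows[[length(rows) + 1L]] <- data.frame(
                id_same = same$construct_id[i], id_opp = opp$construct_id[j],
                mean_same = same$mean[i], mean_opp = opp$mean[j],
                term_same = term(same[i, ]), term_opp = term(opp[j, ]))
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id_same = character(), id_opp = character(),
                   mean_same = numeric(), mean_opp = numeric(),
                   term_same = numeric(), term_opp = numeric())
    out$same_noisier <- out$term_same >= out$term_opp
    attr(out, "fraction_same_noisier") <-
        if (nrow(out)) mean(out$same_noisier) else NA_real_
    out
}

#' @describeIn fitNoiseLine slope accessor.
#' @param object a LinearNoiseFit.
#' @export
setGeneric("fitSlope", function(object) standardGeneric("fitSlope"))
#' @describeIn fitNoiseLine intercept accessor.
#' @export
setGeneric("fitIntercept", function(object) standardGeneric("fitIntercept"))
#' @describeIn fitNoiseLine R-squared accessor.
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @export
setMethod("fitSlope", "LinearNoiseFit", function(object) object@slope)
#' @export
setMethod("fitIntercept", "LinearNoiseFit", function(object) object@intercept)
#' @export
setMethod("rSquared", "LinearNoiseFit", function(object) object@rSquared)
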
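#' Analytic mean of the two-state promoter
#'
#' For a telegraph promoter switching between OFF and ON at rates kOn and
#' kOff, the steady-state expression mean is
#' \deqn{\mathrm{mean} = C \cdot \frac{k_{on}}{k_{on} + k_{off}},}
#' i.e. the expression scale times the ON-state occupancy. Strictly
#' increasing in kOn and strictly decreasing in kOff.
#'
#' @param kin a [PromoterKinetics-class] object.
#' @return numeric(1) mean expression, in the units of \code{C}.
#' @examples
#' meanExpression(promoterKinetics(kOn = 1, kOff = 0, C = 2))  # always ON: 2
#' @export
setGeneric("meanExpression", function(kin) standardGeneric("meanExpression"))

#' @export
setMethod("meanExpression", "PromoterKinetics", function(kin) {
    if (kin@kOn + kin@kOff <= 0)
        stop("invalid kinetics: kOn + kOff must be > 0")
    kin@C * kin@kOn / (kin@kOn + kin@kOff)
})

#' Analytic noise (eta squared) of the two-state promoter
#'
#' The squared coefficient of variation of expression,
#' \deqn{\eta^2 = \frac{1}{\mathrm{mean}} +
#'   \frac{k_{off}}{k_{on}} \cdot \frac{1}{\tau (k_{on}+k_{off}) + 1},}
#' the sum of a Poisson-like small-number term and a promoter-switching term
#' low-pass filtered by the protein lifetime \eqn{\tau}. Reduces to
#' \code{1/mean} for an always-ON (constitutive) promoter.
#'
#' @param kin a [PromoterKinetics-class] object.
#' @param mean the expression mean; defaults to [meanExpression()] of
#'   \code{kin}. Must be > 0.
#' @return numeric(1) dimensionless noise.
#' @examples
#' kin <- promoterKinetics(kOn = 1, kOff = 1, tau = 1, C = 2)
#' noiseExpression(kin)   # 1/1 + 1 * 1/3 = 4/3
#' @export
setGeneric("noiseExpression", function(kin, mean) standardGeneric("noiseExpression"))

#' @export
setMethod("noiseExpression", "PromoterKinetics", function(kin, mean) {
    if (missing(mean)) mean <- meanExpression(kin)
    if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
        stop("invalid summary: mean must be a positive finite number")
    1 / mean + (kin@kOff / kin@kOn) / (kin@tau * (kin@kOn + kin@kOff) + 1)
})

#' Modulate promoter switching rates with a CRISPRar construct
#'
#' The repressing module lowers the ON-rate and the activating module lowers
#' the OFF-rate, each through a saturable occupancy of its binding site:
#' \deqn{k_{on} = k_{on,wt}\Big(1 - \frac{k_r [R]}{K_r + [R]}\,int_1\Big),
#'  \qquad
#'  k_{off} = k_{off,wt}\Big(1 - \frac{k_a [A]}{K_a + [A]}\,int_2\Big).}
#' When the two sgRNAs target the same DNA strand they compete for
#' overlapping binding sites (competitive inhibition):
#' \eqn{K_r = K_{ro}(1 + [A]/K_i)}, \eqn{K_a = K_{ao}(1 + [R]/K_i)},
#' \eqn{int_1 = int_2 = 1}. When they target opposite strands each reduces
#' the other's activity: \eqn{int_1 = 1/(1 + K_{int1}[A])},
#' \eqn{int_2 = 1/(1 + K_{int2}[R])}, with \eqn{K_r = K_{ro}},
#' \eqn{K_a = K_{ao}}.
#'
#' @param wt wild-type [PromoterKinetics-class] (regulation-free rates).
#' @param params [CrisprParams-class] with the regulation strengths
#'   \code{kR}, \code{kA} and binding/interaction constants.
#' @param concA,concR relative sgRNA concentrations in [0, 1] (the unit pool
#'   split between the two sgRNAs).
#' @param strandRelation \code{"same"} or \code{"opposite"}: whether the two
#'   modules target the same DNA strand. Derive it from a construct with
#'   [strandRelation()].
#' @return A [PromoterKinetics-class] with the modulated rates (wild-type
#'   rates, tau and C carried over). Identity when both concentrations are 0.
#' @examples
#' wt <- promoterKinetics(kOn = 1, kOff = 1)
#' applyCrisprar(wt, crisprParams(kR = 0.5, kA = 0.8), 0.5, 0.5, "opposite")
#' @export
applyCrisprar <- function(wt, params, concA, concR,
                          strandRelation = c("same", "opposite")) {
    stopifnot(is(wt, "PromoterKinetics"), is(params, "CrisprParams"))
    strandRelation <- match.arg(strandRelation)
    if (!is.numeric(concA) || !is.numeric(concR) || concA < 0 || concR < 0)
        stop("concA and concR must be non-negative")
    if (strandRelation == "same") {
        Kr <- params@KRo * (1 + concA / params@Ki)
        Ka <- params@KAo * (1 + concR / params@Ki)
        int1 <- 1
        int2 <- 1
    } else {
        Kr <- params@KRo
        Ka <- params@KAo
        int1 <- 1 / (1 + params@Kint1 * concA)
        int2 <- 1 / (1 + params@Kint2 * concR)
    }
    occR <- if (concR > 0) concR / (Kr + concR) else 0
    occA <- if (concA > 0) concA / (Ka + concA) else 0
    kOnNew <- wt@kOnWt * (1 - params@kR * occR * int1)
    kOffNew <- wt@kOffWt * (1 - params@kA * occA * int2)
    if (kOnNew <= 0 || kOffNew < 0)
        stop("parameter domain error: modulated rate fell to or below zero")
    promoterKinetics(kOn = kOnNew, kOff = kOffNew, kOnWt = wt@kOnWt,
                     kOffWt = wt@kOffWt, tau = wt@tau, C = wt@C)
}

#' Compare noise between two kinetics with matched means
#'
#' Two telegraph promoters have the same mean exactly when their kOff/kOn
#' ratios are equal. On that matched-mean locus the noise difference reduces
#' to the switching term \eqn{1/(\tau (k_{on}+k_{off}) + 1)}: the kinetics
#' with the smaller total switching rate is noisier (its promoter state
#' fluctuates more slowly than the protein can average out).
#'
#' @param kin1,kin2 [PromoterKinetics-class] objects with (approximately)
#'   equal kOff/kOn ratios. \code{tau} is taken from \code{kin1}.
#' @param tolerance maximum allowed |ratio1 - ratio2| before the comparison
#'   is refused.
#' @return A list with \code{term1}, \code{term2} (the two switching-term
#'   values), \code{noisier} (\code{"kin1"}, \code{"kin2"} or \code{"tie"})
#'   and the two ratios.
#' @examples
#' compareNoiseAtMatchedMean(promoterKinetics(1, 1), promoterKinetics(2, 2))
#' @export
compareNoiseAtMatchedMean <- function(kin1, kin2, tolerance = 1e-6) {
    stopifnot(is(kin1, "PromoterKinetics"), is(kin2, "PromoterKinetics"))
    r1 <- kin1@kOff / kin1@kOn
    r2 <- kin2@kOff / kin2@kOn
    if (abs(r1 - r2) > tolerance)
        stop(sprintf(
            "not matched: kOff/kOn ratios differ by %.3g (tolerance %.3g)",
            abs(r1 - r2), tolerance))
    tau <- kin1@tau
    term1 <- 1 / (tau * (kin1@kOn + kin1@kOff) + 1)
    term2 <- 1 / (tau * (kin2@kOn + kin2@kOff) + 1)
    noisier <- if (term1 > term2) "kin1" else if (term2 > term1) "kin2" else "tie"
    list(term1 = term1, term2 = term2, noisier = noisier,
         ratio1 = r1, ratio2 = r2)
}

#' Evaluate mean and noise surfaces over a switching-rate grid
#'
#' Computes the analytic mean and noise at every (kOn, kOff) combination.
#' Iso-mean contours of the resulting surface are exactly the loci of
#' constant kOff/kOn ratio; noise decreases along each such locus as the
#' total switching rate grows.
#'
#' @param kOnValues,kOffValues strictly ascending positive grids
#'   (length >= 2).
#' @param tau protein lifetime.
#' @param C expression scale.
#' @return A [ContourGrid-class] object.
#' @examples
#' g <- contourGrid(c(1, 2), c(1, 2), tau = 1, C = 1)
#' meanSurface(g)
#' @export
contourGrid <- function(kOnValues, kOffValues, tau = 1, C = 1) {
    if (length(kOnValues) < 2 || length(kOffValues) < 2)
        stop("configuration error: grids must have length >= 2")
    occ <- outer(kOnValues, kOffValues, function(a, b) a / (a + b))
    meanS <- C * occ
    noiseS <- 1 / meanS + outer(kOnValues, kOffValues, function(a, b)
        (b / a) / (tau * (a + b) + 1))
    .newContourGrid(as.numeric(kOnValues), as.numeric(kOffValues),
                    meanS, noiseS, tau, C)
}

## assemble slot-wise: an argument named C would partially match new()'s
## Class formal
.newContourGrid <- function(kOnValues, kOffValues, meanS, noiseS, tau, Cval) {
    obj <- new("ContourGrid", kOnValues = kOnValues, kOffValues = kOffValues,
               meanSurface = meanS, noiseSurface = noiseS, tau = tau)
    obj@C <- Cval
    validObject(obj)
    obj
}

#' @describeIn contourGrid mean-surface accessor.
#' @param object a ContourGrid.
#' @export
setGeneric("meanSurface", function(object) standardGeneric("meanSurface"))
#' @describeIn contourGrid noise-surface accessor.
#' @export
setGeneric("noiseSurface", function(object) standardGeneric("noiseSurface"))
#' @export
setMethod("meanSurface", "ContourGrid", function(object) object@meanSurface)
#' @export
setMethod("noiseSurface", "ContourGrid", function(object) object@noiseSurface)

#' Serialize a ContourGrid to long-format TSV
#'
#' Columns: \code{k_on}, \code{k_off}, \code{mean}, \code{noise}; one row per
#' grid point, kOff varying fastest.
#'
#' @param grid a [ContourGrid-class].
#' @param path output file path.
#' @return The data.frame written, invisibly.
#' @export
writeContourGrid <- function(grid, path) {
    stopifnot(is(grid, "ContourGrid"))
    df <- data.frame(
        k_on = rep(grid@kOnValues, each = length(grid@kOffValues)),
        k_off = rep(grid@kOffValues, times = length(grid@kOnValues)),
        mean = as.vector(t(grid@meanSurface)),
        noise = as.vector(t(grid@noiseSurface)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Read a long-format contour TSV back into a ContourGrid
#'
#' @param path TSV written by [writeContourGrid()].
#' @return A [ContourGrid-class].
#' @export
readContourGrid <- function(path) {
    df <- utils::read.delim(path)
    kOnValues <- sort(unique(df$k_on))
    kOffValues <- sort(unique(df$k_off))
    o <- order(df$k_on, df$k_off)
    meanS <- matrix(df$mean[o], nrow = length(kOnValues),
                    ncol = length(kOffValues), byrow = TRUE)
    noiseS <- matrix(df$noise[o], nrow = length(kOnValues),
                     ncol = length(kOffValues), byrow = TRUE)
    ## tau is not stored in the TSV; C is recovered from the corner point
    ## with the largest occupancy (max kOn, min kOff).
    occCorner <- max(kOnValues) / (max(kOnValues) + min(kOffValues))
    .newContourGrid(kOnValues, kOffValues, meanS, noiseS, tau = 1,
                    Cval = max(df$mean) / occCorner)
}
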
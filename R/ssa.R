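#' @useDynLib crisprarNoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' A sample of steady-state protein counts
#'
#' @slot proteinCounts numeric vector of end-point protein copy numbers, one
#'   per simulated cell.
#' @slot seed integer seed the sample was drawn with.
#' @slot tEnd simulated duration per cell (burn-in).
#' @seealso [sampleSteadyState()]
#' @export
setClass("SsaSample",
    representation(proteinCounts = "numeric", seed = "integer",
                   tEnd = "numeric"))

setMethod("show", "SsaSample", function(object) {
    cat(sprintf("SsaSample: %d cells, t_end = %g, seed = %d\n",
                length(object@proteinCounts), object@tEnd, object@seed))
    m <- mean(object@proteinCounts)
    cat(sprintf("  mean = %.4g, CV^2 = %.4g\n", m,
                stats::var(object@proteinCounts) / m^2))
})

#' @describeIn sampleSteadyState protein-count accessor.
#' @param object an SsaSample.
#' @export
setGeneric("proteinCounts", function(object) standardGeneric("proteinCounts"))
#' @export
setMethod("proteinCounts", "SsaSample", function(object) object@proteinCounts)

#' Build the simulated reaction system for a promoter
#'
#' Chooses mRNA-tier rates that put the system in the fast-mRNA regime where
#' the two-moment analytic formulas hold: mRNA turnover \code{gammaM} much
#' faster than switching and protein turnover, and a small translational
#' burst (\code{kP/(gammaM+gammaP)} well below 1). The transcription rate is
#' set so the coarse-grained expression scale
#' \code{kM*kP/(gammaM*gammaP)} equals the kinetics' \code{C}.
#'
#' @param kin a [PromoterKinetics-class].
#' @param gammaM mRNA degradation rate (default 10).
#' @param kP translation rate per mRNA (default 0.5).
#' @return A [ReactionSystem-class].
#' @export
reactionSystem <- function(kin, gammaM = 10, kP = 0.5) {
    stopifnot(is(kin, "PromoterKinetics"))
    gammaP <- 1 / kin@tau
    kM <- kin@C * gammaM * gammaP / kP
    new("ReactionSystem", kOn = kin@kOn, kOff = kin@kOff, kM = kM,
        gammaM = gammaM, kP = kP, gammaP = gammaP)
}

#' Simulate one exact trajectory
#'
#' Gillespie direct method: every reaction event is realized, event times
#' are strictly increasing, and each event changes exactly one species by
#' one unit (or toggles the promoter state). Reproducible given a seed.
#'
#' @param sys a [ReactionSystem-class].
#' @param tEnd simulated duration (> 0).
#' @param seed integer seed.
#' @param dOnInit,mrnaInit,proteinInit initial state (default: OFF promoter,
#'   no molecules).
#' @param maxEvents guard against runaway trajectories.
#' @return data.frame with columns \code{time}, \code{d_on}, \code{mrna},
#'   \code{protein}; attribute \code{absorbed} is TRUE if all propensities
#'   hit zero before \code{tEnd}.
#' @export
runTrajectory <- function(sys, tEnd, seed, dOnInit = 0L, mrnaInit = 0,
                          proteinInit = 0, maxEvents = 1e7) {
    stopifnot(is(sys, "ReactionSystem"), tEnd > 0)
    if (sys@kOn + sys@kOff + sys@kM + sys@gammaM + sys@kP + sys@gammaP <= 0)
        stop("at least one rate must be positive")
    set.seed(as.integer(seed))
    res <- .ssaTrajectoryCpp(sys@kOn, sys@kOff, sys@kM, sys@gammaM, sys@kP,
                             sys@gammaP, tEnd, as.integer(dOnInit),
                             mrnaInit, proteinInit, as.integer(maxEvents))
    out <- data.frame(time = res$time, d_on = res$d_on, mrna = res$mrna,
                      protein = res$protein)
    attr(out, "absorbed") <- res$absorbed
    out
}

#' Sample independent steady-state protein counts
#'
#' Runs \code{nCells} independent trajectories (not a thinned single path,
#' so standard errors are straightforward) and records the end-point protein
#' count of each. Each cell's promoter is initialized from its stationary
#' occupancy \code{kOn/(kOn+kOff)} so that a burn-in of a few protein
#' lifetimes suffices even for slowly switching promoters; mRNA and protein
#' start at zero.
#'
#' @param sys a [ReactionSystem-class].
#' @param nCells number of cells (>= 1).
#' @param burnIn duration per cell; default 10 protein lifetimes. A value
#'   below 3 lifetimes triggers a non-stationarity warning.
#' @param seed integer seed; same (system, seed, nCells) gives identical
#'   samples.
#' @return An [SsaSample-class].
#' @export
sampleSteadyState <- function(sys, nCells, burnIn = NULL, seed = 1L) {
    stopifnot(is(sys, "ReactionSystem"), nCells >= 1)
    tau <- 1 / sys@gammaP
    if (is.null(burnIn)) burnIn <- 10 * tau
    if (burnIn < 3 * tau)
        warning("burn-in shorter than 3 protein lifetimes: sample may not be stationary")
    set.seed(as.integer(seed))
    pOn <- if (sys@kOn + sys@kOff > 0) sys@kOn / (sys@kOn + sys@kOff) else 0
    dInit <- stats::rbinom(nCells, 1L, pOn)
    counts <- .ssaEndpointsCpp(sys@kOn, sys@kOff, sys@kM, sys@gammaM,
                               sys@kP, sys@gammaP, burnIn,
                               as.integer(dInit))
    new("SsaSample", proteinCounts = counts, seed = as.integer(seed),
        tEnd = burnIn)
}

#' Time-averaged ON occupancy of the bare promoter
#'
#' Simulates the two-state promoter alone and returns the fraction of time
#' spent ON, whose expectation is \code{kOn/(kOn+kOff)}. Used by the
#' exactness tests of the simulator.
#'
#' @param kOn,kOff switching rates.
#' @param tEnd duration.
#' @param seed integer seed.
#' @param dOnInit initial state (0 = OFF).
#' @return numeric(1) occupancy in [0, 1].
#' @export
promoterOccupancy <- function(kOn, kOff, tEnd, seed = 1L, dOnInit = 0L) {
    set.seed(as.integer(seed))
    .ssaOccupancyCpp(kOn, kOff, tEnd, as.integer(dOnInit))
}

#' Validate a simulated sample against the analytic moments
#'
#' Checks that the empirical mean is within \code{seMultiple} standard
#' errors of \code{C * kOn/(kOn+kOff)} and the empirical squared coefficient
#' of variation within \code{relTol} relative error of the analytic noise.
#' Valid when the sample's system has the coarse-grained rates of \code{kin}
#' and sits in the fast-mRNA regime.
#'
#' @param sample an [SsaSample-class].
#' @param kin the [PromoterKinetics-class] the sample should agree with.
#' @param relTol relative tolerance on the noise (default 0.10).
#' @param seMultiple standard-error multiple for the mean (default 3).
#' @return List with \code{empirical_mean}, \code{empirical_cv2},
#'   \code{analytic_mean}, \code{analytic_noise}, \code{mean_se},
#'   \code{mean_ok}, \code{noise_ok}, \code{pass}.
#' @export
validateAgainstAnalytic <- function(sample, kin, relTol = 0.10,
                                    seMultiple = 3) {
    stopifnot(is(sample, "SsaSample"), is(kin, "PromoterKinetics"))
    x <- sample@proteinCounts
    if (length(x) < 100)
        stop("insufficient sample: need at least 100 cells for a stable SE")
    empMean <- mean(x)
    empCv2 <- stats::var(x) / empMean^2
    anaMean <- meanExpression(kin)
    anaNoise <- noiseExpression(kin, anaMean)
    se <- stats::sd(x) / sqrt(length(x))
    meanOk <- abs(empMean - anaMean) <= seMultiple * se
    noiseOk <- abs(empCv2 - anaNoise) / anaNoise <= relTol
    list(empirical_mean = empMean, empirical_cv2 = empCv2,
         analytic_mean = anaMean, analytic_noise = anaNoise,
         mean_se = se, mean_ok = meanOk, noise_ok = noiseOk,
         pass = meanOk && noiseOk)
}
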
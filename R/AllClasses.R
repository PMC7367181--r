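#' @import methods
NULL

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Two-state promoter kinetics
#'
#' Holds the switching rates of a telegraph promoter together with the
#' wild-type (unregulated) rates, the protein lifetime and the expression
#' scale. The promoter toggles between an OFF state and an ON state at rates
#' \code{kOn} (OFF to ON) and \code{kOff} (ON to OFF); expression occurs from
#' the ON state. \code{tau} is the protein lifetime (inverse degradation
#' rate), so \code{tau * (kOn + kOff)} is dimensionless. \code{C} is the
#' expression-scale constant: the mean of an always-ON promoter in
#' fluorescence-equivalent units.
#'
#' @slot kOn numeric(1), OFF-to-ON switching rate, > 0.
#' @slot kOff numeric(1), ON-to-OFF switching rate, >= 0.
#' @slot kOnWt numeric(1), wild-type ON-rate (no regulation).
#' @slot kOffWt numeric(1), wild-type OFF-rate.
#' @slot tau numeric(1), protein lifetime, > 0.
#' @slot C numeric(1), expression scale, > 0.
#' @seealso [promoterKinetics()], [meanExpression()], [noiseExpression()]
#' @export
setClass("PromoterKinetics",
    representation(kOn = "numeric", kOff = "numeric",
                   kOnWt = "numeric", kOffWt = "numeric",
                   tau = "numeric", C = "numeric"),
    prototype(kOn = 1, kOff = 1, kOnWt = 1, kOffWt = 1, tau = 1, C = 1))

setValidity("PromoterKinetics", function(object) {
    msg <- character()
    for (s in c("kOn", "kOff", "kOnWt", "kOffWt", "tau", "C"))
        if (!.scalarNum(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
    if (length(msg)) return(msg)
    if (object@kOn <= 0) msg <- c(msg, "kOn must be > 0")
    if (object@kOff < 0) msg <- c(msg, "kOff must be >= 0")
    if (object@kOn > object@kOnWt + 1e-12)
        msg <- c(msg, "kOn must not exceed the wild-type rate kOnWt")
    if (object@kOff > object@kOffWt + 1e-12)
        msg <- c(msg, "kOff must not exceed the wild-type rate kOffWt")
    if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
    if (object@C <= 0) msg <- c(msg, "C must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a PromoterKinetics object
#'
#' @param kOn,kOff modulated switching rates (per unit time).
#' @param kOnWt,kOffWt wild-type rates; default to \code{kOn}/\code{kOff}
#'   (i.e. an unregulated promoter). The default wild-type promoter has both
#'   rates equal to 1.
#' @param tau protein lifetime (inverse degradation rate).
#' @param C expression scale (mean of an always-ON promoter).
#' @return A [PromoterKinetics-class] object.
#' @examples
#' wt <- promoterKinetics()          # kOn = kOff = 1, tau = 1, C = 1
#' meanExpression(wt)                # 0.5
#' @export
promoterKinetics <- function(kOn = 1, kOff = 1, kOnWt = kOn, kOffWt = kOff,
                             tau = 1, C = 1) {
    ## slot-wise assembly: an argument named C would partially match new()'s
    ## Class formal
    obj <- new("PromoterKinetics")
    obj@kOn <- kOn; obj@kOff <- kOff; obj@kOnWt <- kOnWt
    obj@kOffWt <- kOffWt; obj@tau <- tau; obj@C <- C
    validObject(obj)
    obj
}

#' CRISPRar regulation parameters
#'
#' Strengths and binding constants of the paired activation/repression
#' modules. \code{kR} is the maximal fractional reduction of the promoter's
#' ON-rate by the repressing module; \code{kA} the maximal fractional
#' reduction of the OFF-rate by the activating module (both dimensionless in
#' [0, 1]). \code{KRo}/\code{KAo} are the half-saturation constants of the
#' repressor/activator occupancy in sgRNA concentration units, \code{Ki} the
#' competitive-inhibition constant used when the two sgRNAs target the same
#' DNA strand, and \code{Kint1}/\code{Kint2} the interaction constants
#' (activator-on-repressor and repressor-on-activator) used when they target
#' opposite strands.
#'
#' @slot kR,kA numeric(1) in [0, 1].
#' @slot KRo,KAo,Ki,Kint1,Kint2 numeric(1), >= 0.
#' @seealso [crisprParams()], [applyCrisprar()]
#' @export
setClass("CrisprParams",
    representation(kR = "numeric", kA = "numeric", KRo = "numeric",
                   KAo = "numeric", Ki = "numeric", Kint1 = "numeric",
                   Kint2 = "numeric"),
    prototype(kR = 0, kA = 0, KRo = 0.01, KAo = 0.02, Ki = 10,
              Kint1 = 0.5, Kint2 = 2))

setValidity("CrisprParams", function(object) {
    msg <- character()
    for (s in c("kR", "kA", "KRo", "KAo", "Ki", "Kint1", "Kint2")) {
        v <- slot(object, s)
        if (!.scalarNum(v) || v < 0)
            msg <- c(msg, sprintf("'%s' must be a non-negative numeric scalar", s))
    }
    if (length(msg)) return(msg)
    if (object@kR > 1) msg <- c(msg, "kR must be <= 1")
    if (object@kA > 1) msg <- c(msg, "kA must be <= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a CrisprParams object
#'
#' Defaults are the binding/interaction constants used throughout the model
#' analysis: \code{KRo = 0.01}, \code{KAo = 0.02}, \code{Ki = 10},
#' \code{Kint1 = 0.5}, \code{Kint2 = 2}. Regulation strengths outside [0, 1]
#' are clamped with a warning (the rate laws would otherwise produce negative
#' switching rates).
#'
#' @param kR,kA maximal fractional repression/activation strengths.
#' @param KRo,KAo,Ki,Kint1,Kint2 binding and interaction constants.
#' @return A [CrisprParams-class] object.
#' @export
crisprParams <- function(kR = 0, kA = 0, KRo = 0.01, KAo = 0.02, Ki = 10,
                         Kint1 = 0.5, Kint2 = 2) {
    if (kR > 1 || kR < 0 || kA > 1 || kA < 0) {
        warning("regulation strengths clamped to [0, 1]")
        kR <- min(max(kR, 0), 1)
        kA <- min(max(kA, 0), 1)
    }
    new("CrisprParams", kR = kR, kA = kA, KRo = KRo, KAo = KAo, Ki = Ki,
        Kint1 = Kint1, Kint2 = Kint2)
}

#' A promoter-sgRNA module
#'
#' One sgRNA expressed from a constitutive promoter, directing dCas9-omega to
#' a PAM site upstream of the reporter's transcriptional start site (+1).
#' PAM positions within the repression window (40-60 bp upstream by default)
#' block RNA polymerase assembly (role \code{"repressor"}); positions beyond
#' it (60-100 bp) let the fused omega subunit stabilize RNAP (role
#' \code{"activator"}).
#'
#' @slot name character(1) identifier, e.g. \code{"A1"}, \code{"R2"}.
#' @slot role \code{"activator"} or \code{"repressor"}.
#' @slot targetStrand \code{"coding"} or \code{"non_coding"}.
#' @slot pamPosition integer bp upstream of +1, positive.
#' @slot promoter character(1) promoter identifier (e.g. \code{"pStr"}).
#' @slot promoterStrength numeric(1) relative transcription strength, > 0.
#' @slot regulationStrength numeric(1) estimated kR or kA in [0, 1], or NA
#'   until estimated.
#' @seealso [sgRNAModule()], [crisprarConstruct()]
#' @export
setClass("SgRNAModule",
    representation(name = "character", role = "character",
                   targetStrand = "character", pamPosition = "numeric",
                   promoter = "character", promoterStrength = "numeric",
                   regulationStrength = "numeric"),
    prototype(name = NA_character_, role = "repressor",
              targetStrand = "coding", pamPosition = 50,
              promoter = "consensus", promoterStrength = 1,
              regulationStrength = NA_real_))

.REPRESSION_WINDOW <- c(40, 60)
.ACTIVATION_WINDOW <- c(60, 100)

setValidity("SgRNAModule", function(object) {
    msg <- character()
    if (!object@role %in% c("activator", "repressor"))
        msg <- c(msg, "role must be 'activator' or 'repressor'")
    if (!object@targetStrand %in% c("coding", "non_coding"))
        msg <- c(msg, "targetStrand must be 'coding' or 'non_coding'")
    if (!.scalarNum(object@pamPosition) || object@pamPosition <= 0)
        msg <- c(msg, "pamPosition must be a positive number (bp upstream of +1)")
    if (!.scalarNum(object@promoterStrength) || object@promoterStrength <= 0)
        msg <- c(msg, "promoterStrength must be > 0")
    if (!is.na(object@regulationStrength) &&
        (object@regulationStrength < 0 || object@regulationStrength > 1))
        msg <- c(msg, "regulationStrength must be in [0, 1] or NA")
    if (length(msg)) return(msg)
    p <- object@pamPosition
    if (object@role == "repressor" &&
        (p < .REPRESSION_WINDOW[1] || p > .REPRESSION_WINDOW[2]))
        msg <- c(msg, sprintf(
            "repressor PAM position %g outside the repression window [%g, %g] bp",
            p, .REPRESSION_WINDOW[1], .REPRESSION_WINDOW[2]))
    if (object@role == "activator" &&
        (p <= .ACTIVATION_WINDOW[1] || p > .ACTIVATION_WINDOW[2]))
        msg <- c(msg, sprintf(
            "activator PAM position %g outside the activation window (%g, %g] bp",
            p, .ACTIVATION_WINDOW[1], .ACTIVATION_WINDOW[2]))
    if (length(msg)) msg else TRUE
})

#' Construct a promoter-sgRNA module
#'
#' @param name identifier.
#' @param role \code{"activator"} or \code{"repressor"}.
#' @param targetStrand \code{"coding"} or \code{"non_coding"}.
#' @param pamPosition bp upstream of the transcriptional start site.
#' @param promoter promoter identifier.
#' @param promoterStrength relative transcription strength.
#' @param regulationStrength estimated kR or kA (NA until estimated).
#' @return An [SgRNAModule-class] object.
#' @export
sgRNAModule <- function(name, role, targetStrand, pamPosition,
                        promoter = "consensus", promoterStrength = 1,
                        regulationStrength = NA_real_) {
    new("SgRNAModule", name = name, role = role, targetStrand = targetStrand,
        pamPosition = as.numeric(pamPosition), promoter = promoter,
        promoterStrength = promoterStrength,
        regulationStrength = as.numeric(regulationStrength))
}

#' A CRISPRar construct
#'
#' One activating and one repressing promoter-sgRNA module carried in the
#' same cell. The sgRNA pool has unit capacity, split between the two sgRNAs
#' in proportion to their promoter strengths (\code{concA + concR == 1}).
#' Transcription order of the two modules on the plasmid is bookkeeping only:
#' the model has no order term.
#'
#' @slot constructId character(1) identifier.
#' @slot actModule,repModule [SgRNAModule-class] with the matching roles.
#' @slot transcriptionOrder \code{"act_first"} or \code{"rep_first"}.
#' @slot concA,concR allocated sgRNA concentrations, positive, summing to 1.
#' @seealso [crisprarConstruct()], [enumerateLibrary()]
#' @export
setClass("CrisprarConstruct",
    representation(constructId = "character", actModule = "SgRNAModule",
                   repModule = "SgRNAModule", transcriptionOrder = "character",
                   concA = "numeric", concR = "numeric"))

setValidity("CrisprarConstruct", function(object) {
    msg <- character()
    if (object@actModule@role != "activator")
        msg <- c(msg, "actModule must have role 'activator'")
    if (object@repModule@role != "repressor")
        msg <- c(msg, "repModule must have role 'repressor'")
    if (!object@transcriptionOrder %in% c("act_first", "rep_first"))
        msg <- c(msg, "transcriptionOrder must be 'act_first' or 'rep_first'")
    if (!.scalarNum(object@concA) || !.scalarNum(object@concR) ||
        object@concA <= 0 || object@concR <= 0)
        msg <- c(msg, "concA and concR must be positive")
    else if (abs(object@concA + object@concR - 1) > 1e-9)
        msg <- c(msg, "concA + concR must equal 1 (unit sgRNA pool capacity)")
    if (length(msg)) msg else TRUE
})

#' Construct a CrisprarConstruct
#'
#' Concentrations default to the promoter-strength allocation of
#' [allocateConcentrations()].
#'
#' @param actModule,repModule the activating and repressing modules.
#' @param transcriptionOrder \code{"act_first"} (default) or
#'   \code{"rep_first"}.
#' @param constructId identifier; a deterministic default is derived from the
#'   module names, promoters and order.
#' @param concA,concR explicit concentrations (must sum to 1); by default
#'   allocated from promoter strengths.
#' @return A [CrisprarConstruct-class] object.
#' @export
crisprarConstruct <- function(actModule, repModule,
                              transcriptionOrder = "act_first",
                              constructId = NULL, concA = NULL, concR = NULL) {
    if (is.null(concA) || is.null(concR)) {
        cc <- allocateConcentrations(actModule@promoterStrength,
                                     repModule@promoterStrength)
        concA <- cc[["concA"]]; concR <- cc[["concR"]]
    }
    if (is.null(constructId))
        constructId <- paste(actModule@promoter, actModule@name,
                             repModule@promoter, repModule@name,
                             transcriptionOrder, sep = "_")
    new("CrisprarConstruct", constructId = constructId, actModule = actModule,
        repModule = repModule, transcriptionOrder = transcriptionOrder,
        concA = concA, concR = concR)
}

#' Mean/noise surfaces over the switching-rate plane
#'
#' Pointwise analytic expression mean and noise over a grid of
#' (kOn, kOff) values; iso-mean contours are loci of constant kOff/kOn ratio.
#'
#' @slot kOnValues,kOffValues ascending positive grids (length >= 2).
#' @slot meanSurface,noiseSurface matrices of dimension
#'   \code{length(kOnValues) x length(kOffValues)}.
#' @slot tau,C the lifetime and scale the surfaces were evaluated at.
#' @seealso [contourGrid()]
#' @export
setClass("ContourGrid",
    representation(kOnValues = "numeric", kOffValues = "numeric",
                   meanSurface = "matrix", noiseSurface = "matrix",
                   tau = "numeric", C = "numeric"))

setValidity("ContourGrid", function(object) {
    msg <- character()
    if (length(object@kOnValues) < 2 || length(object@kOffValues) < 2)
        msg <- c(msg, "grids must have length >= 2")
    if (is.unsorted(object@kOnValues, strictly = TRUE) ||
        is.unsorted(object@kOffValues, strictly = TRUE))
        msg <- c(msg, "grids must be strictly ascending")
    if (any(object@kOnValues <= 0) || any(object@kOffValues < 0))
        msg <- c(msg, "kOn grid must be positive and kOff grid non-negative")
    dims <- c(length(object@kOnValues), length(object@kOffValues))
    if (!identical(dim(object@meanSurface), dims) ||
        !identical(dim(object@noiseSurface), dims))
        msg <- c(msg, "surfaces must be |kOnValues| x |kOffValues| matrices")
    if (length(msg)) msg else TRUE
})

#' The simulated reaction network
#'
#' Species: promoter state (OFF/ON), mRNA count, protein count. Reactions:
#' OFF -> ON (kOn), ON -> OFF (kOff), ON -> ON + mRNA (kM),
#' mRNA -> 0 (gammaM per molecule), mRNA -> mRNA + protein (kP per molecule),
#' protein -> 0 (gammaP per molecule). The coarse-grained expression scale is
#' \code{C = kM * kP / (gammaM * gammaP)}.
#'
#' @slot kOn,kOff,kM,gammaM,kP,gammaP non-negative rate constants.
#' @seealso [reactionSystem()], [sampleSteadyState()]
#' @export
setClass("ReactionSystem",
    representation(kOn = "numeric", kOff = "numeric", kM = "numeric",
                   gammaM = "numeric", kP = "numeric", gammaP = "numeric"))

setValidity("ReactionSystem", function(object) {
    msg <- character()
    for (s in c("kOn", "kOff", "kM", "gammaM", "kP", "gammaP")) {
        v <- slot(object, s)
        if (!.scalarNum(v) || v < 0)
            msg <- c(msg, sprintf("'%s' must be a non-negative numeric scalar", s))
    }
    if (length(msg)) msg else TRUE
})

#' Design of a synthetic cytometry study
#'
#' Everything needed to emulate the study's measurements: the CRISPRar
#' construct library, the single-sgRNA variant set, model parameters,
#' replication and event counts, and the noise knobs of the measurement
#' process.
#'
#' @slot library list of [CrisprarConstruct-class].
#' @slot singleModules list of [SgRNAModule-class] (single-sgRNA variants).
#' @slot params [CrisprParams-class] binding/interaction constants.
#' @slot wt [PromoterKinetics-class] wild-type promoter.
#' @slot nReplicates integer, biological replicates per group (default 6).
#' @slot nEvents integer, cytometry events per replicate (default 20000).
#' @slot measurementCv multiplicative lognormal measurement noise CV.
#' @slot replicateCv between-replicate scale jitter CV.
#' @slot blankFraction blank mean as a fraction of the control mean.
#' @slot seed integer base seed.
#' @seealso [syntheticDesign()], [generateStudy()]
#' @export
setClass("SyntheticDesign",
    representation(library = "list", singleModules = "list",
                   params = "CrisprParams", wt = "PromoterKinetics",
                   nReplicates = "integer", nEvents = "integer",
                   measurementCv = "numeric", replicateCv = "numeric",
                   blankFraction = "numeric", seed = "integer"))

setValidity("SyntheticDesign", function(object) {
    msg <- character()
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@nEvents < 100L) msg <- c(msg, "nEvents must be >= 100")
    if (object@measurementCv < 0 || object@replicateCv < 0)
        msg <- c(msg, "noise CVs must be >= 0")
    if (object@blankFraction <= 0 || object@blankFraction >= 1)
        msg <- c(msg, "blankFraction must be in (0, 1)")
    if (!all(vapply(object@library, is, TRUE, "CrisprarConstruct")))
        msg <- c(msg, "library must be a list of CrisprarConstruct")
    if (!all(vapply(object@singleModules, is, TRUE, "SgRNAModule")))
        msg <- c(msg, "singleModules must be a list of SgRNAModule")
    if (length(msg)) msg else TRUE
})

#' Linear fit of noise against inverse normalized mean
#'
#' Ordinary least squares of eta-squared on 1/normalized mean, both on
#' linear scales: the constitutive-promoter reference model against which
#' two-state deviations are scored.
#'
#' @slot slope,intercept,rSquared numeric(1).
#' @slot n integer(1), number of points fitted.
#' @seealso [fitNoiseLine()], [averageDeviation()]
#' @export
setClass("LinearNoiseFit",
    representation(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", n = "integer"))

## ---- show methods ----

setMethod("show", "PromoterKinetics", function(object) {
    cat("PromoterKinetics\n")
    cat(sprintf("  kOn = %.6g (wt %.6g)   kOff = %.6g (wt %.6g)\n",
                object@kOn, object@kOnWt, object@kOff, object@kOffWt))
    cat(sprintf("  tau = %.6g   C = %.6g\n", object@tau, object@C))
    cat(sprintf("  mean = %.6g   noise (eta^2) = %.6g\n",
                meanExpression(object), noiseExpression(object)))
})

setMethod("show", "CrisprParams", function(object) {
    cat("CrisprParams\n")
    cat(sprintf("  kR = %.3g  kA = %.3g\n", object@kR, object@kA))
    cat(sprintf("  KRo = %.3g  KAo = %.3g  Ki = %.3g  Kint1 = %.3g  Kint2 = %.3g\n",
                object@KRo, object@KAo, object@Ki, object@Kint1, object@Kint2))
})

setMethod("show", "SgRNAModule", function(object) {
    cat(sprintf("SgRNAModule %s: %s, %s strand, PAM -%g bp, promoter %s (strength %.3g)",
                object@name, object@role, object@targetStrand,
                object@pamPosition, object@promoter, object@promoterStrength))
    if (!is.na(object@regulationStrength))
        cat(sprintf(", regulation strength %.3g", object@regulationStrength))
    cat("\n")
})

setMethod("show", "CrisprarConstruct", function(object) {
    cat(sprintf("CrisprarConstruct %s\n", object@constructId))
    cat(sprintf("  act: %s/%s ([A] = %.3g)   rep: %s/%s ([R] = %.3g)   order: %s\n",
                object@actModule@promoter, object@actModule@name, object@concA,
                object@repModule@promoter, object@repModule@name, object@concR,
                object@transcriptionOrder))
})

setMethod("show", "ContourGrid", function(object) {
    cat(sprintf("ContourGrid: %d x %d points, kOn in [%.3g, %.3g], kOff in [%.3g, %.3g]\n",
                length(object@kOnValues), length(object@kOffValues),
                min(object@kOnValues), max(object@kOnValues),
                min(object@kOffValues), max(object@kOffValues)))
    cat(sprintf("  mean in [%.4g, %.4g], noise in [%.4g, %.4g] (tau = %g, C = %g)\n",
                min(object@meanSurface), max(object@meanSurface),
                min(object@noiseSurface), max(object@noiseSurface),
                object@tau, object@C))
})

setMethod("show", "ReactionSystem", function(object) {
    cat("ReactionSystem (two-state promoter, mRNA, protein)\n")
    cat(sprintf("  kOn = %g  kOff = %g  kM = %g  gammaM = %g  kP = %g  gammaP = %g\n",
                object@kOn, object@kOff, object@kM, object@gammaM,
                object@kP, object@gammaP))
    cat(sprintf("  coarse-grained scale C = %g\n",
                object@kM * object@kP / (object@gammaM * object@gammaP)))
})

setMethod("show", "SyntheticDesign", function(object) {
    cat("SyntheticDesign\n")
    cat(sprintf("  %d CRISPRar constructs, %d single-sgRNA variants\n",
                length(object@library), length(object@singleModules)))
    cat(sprintf("  %d replicates x %d events; measurement CV %.3g, replicate CV %.3g\n",
                object@nReplicates, object@nEvents, object@measurementCv,
                object@replicateCv))
    cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "LinearNoiseFit", function(object) {
    cat(sprintf("LinearNoiseFit: noise = %.6g * x + %.6g  (R^2 = %.4f, n = %d)\n",
                object@slope, object@intercept, object@rSquared, object@n))
})

## ---- accessors ----

#' @describeIn promoterKinetics ON-switching rate accessor.
#' @param object an object of the relevant class.
#' @export
setGeneric("kOn", function(object) standardGeneric("kOn"))
#' @describeIn promoterKinetics OFF-switching rate accessor.
#' @export
setGeneric("kOff", function(object) standardGeneric("kOff"))
#' @describeIn promoterKinetics protein lifetime accessor.
#' @export
setGeneric("tauLifetime", function(object) standardGeneric("tauLifetime"))
#' @describeIn promoterKinetics expression-scale accessor.
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))

#' @export
setMethod("kOn", "PromoterKinetics", function(object) object@kOn)
#' @export
setMethod("kOff", "PromoterKinetics", function(object) object@kOff)
#' @export
setMethod("tauLifetime", "PromoterKinetics", function(object) object@tau)
#' @export
setMethod("exprScale", "PromoterKinetics", function(object) object@C)
#' @export
setMethod("kOn", "ReactionSystem", function(object) object@kOn)
#' @export
setMethod("kOff", "ReactionSystem", function(object) object@kOff)

#' Identifier accessor
#' @param object a [CrisprarConstruct-class] or [SgRNAModule-class].
#' @return character(1) identifier.
#' @export
setGeneric("constructId", function(object) standardGeneric("constructId"))
#' @export
setMethod("constructId", "CrisprarConstruct", function(object) object@constructId)

#' @describeIn crisprarConstruct activating module accessor.
#' @param object a CrisprarConstruct.
#' @export
setGeneric("actModule", function(object) standardGeneric("actModule"))
#' @describeIn crisprarConstruct repressing module accessor.
#' @export
setGeneric("repModule", function(object) standardGeneric("repModule"))
#' @export
setMethod("actModule", "CrisprarConstruct", function(object) object@actModule)
#' @export
setMethod("repModule", "CrisprarConstruct", function(object) object@repModule)
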
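#' Read / write event-level intensity tables
#'
#' The event table is the package's cytometry interchange format: one row
#' per recorded cell with columns \code{construct_id}, \code{replicate}
#' (integer) and \code{intensity} (fluorescence a.u., >= 0). The reserved
#' ids \code{"control"} (reporter with dCas9 but no sgRNA) and
#' \code{"blank"} (fixative only) carry the normalization reference and the
#' gating reference.
#'
#' @param path CSV path with header \code{construct_id,replicate,intensity}.
#' @param events data.frame in the same schema.
#' @return \code{readEventTable}: the validated data.frame.
#' @name eventTableIO
NULL

#' @rdname eventTableIO
#' @export
readEventTable <- function(path) {
    events <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateEventTable(events)
    events
}

#' @rdname eventTableIO
#' @export
writeEventTable <- function(events, path) {
    validateEventTable(events)
    utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname eventTableIO
#' @export
validateEventTable <- function(events) {
    need <- c("construct_id", "replicate", "intensity")
    if (!is.data.frame(events) || !all(need %in% names(events)))
        stop("event table must have columns: ", paste(need, collapse = ", "))
    if (!is.numeric(events$intensity) || any(!is.finite(events$intensity)))
        stop("intensities must be finite numbers")
    if (any(events$intensity < 0))
        stop("intensities must be >= 0")
    invisible(events)
}

#' Gate out non-specific low-intensity events
#'
#' Removes events at or below an intensity threshold set by the blank
#' sample's upper quantile (default 0.99): a single-channel surrogate for
#' scatter-based gating against fixative-only background. The threshold is
#' a fixed function of the blank, so gating is idempotent. A warning is
#' emitted for any (construct, replicate) group losing more than half of
#' its events, and when the blank is empty gating is disabled.
#'
#' @param events event table to gate (the blank itself is usually excluded).
#' @param blank event table of the blank sample.
#' @param quantile gating quantile of the blank intensities (default 0.99).
#' @return The gated event table, with the threshold as attribute
#'   \code{"threshold"}.
#' @export
gateEvents <- function(events, blank, quantile = 0.99) {
    validateEventTable(events)
    if (is.null(blank) || nrow(blank) == 0L) {
        warning("empty blank: gating disabled, events passed through")
        attr(events, "threshold") <- -Inf
        return(events)
    }
    validateEventTable(blank)
    threshold <- stats::quantile(blank$intensity, quantile, names = FALSE)
    keep <- events$intensity > threshold
    before <- table(paste(events$construct_id, events$replicate))
    after <- table(paste(events$construct_id[keep], events$replicate[keep]))
    frac <- 1 - as.numeric(after[names(before)]) / as.numeric(before)
    frac[is.na(frac)] <- 1
    if (any(frac > 0.5))
        warning(sprintf("gating removed >50%% of events in %d group(s)",
                        sum(frac > 0.5)))
    out <- events[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "threshold") <- threshold
    out
}

#' Per-group expression mean and noise
#'
#' For every (construct, replicate) group: arithmetic mean \code{mu}, sample
#' standard deviation \code{sigma} (n-1 denominator) and the expression
#' noise \code{eta2 = sigma^2 / mu^2} (squared coefficient of variation).
#'
#' @param events a gated event table.
#' @return data.frame with columns \code{construct_id}, \code{replicate},
#'   \code{n_events}, \code{mu}, \code{sigma}, \code{eta2}; one row per
#'   group, ordered by construct then replicate.
#' @examples
#' ev <- data.frame(construct_id = "x", replicate = 1L, intensity = c(2, 4))
#' summarizeEvents(ev)   # mu = 3, sigma = sqrt(2), eta2 = 2/9
#' @export
summarizeEvents <- function(events) {
    validateEventTable(events)
    grp <- interaction(events$construct_id, events$replicate, drop = TRUE)
    rows <- lapply(split(events, grp), function(g) {
        if (nrow(g) < 2)
            stop(sprintf("insufficient events: group %s/%s has %d event(s)",
                         g$construct_id[1], g$replicate[1], nrow(g)))
        mu <- mean(g$intensity)
        if (mu == 0)
            stop(sprintf("undefined noise: zero mean in group %s/%s",
                         g$construct_id[1], g$replicate[1]))
        sigma <- stats::sd(g$intensity)
        data.frame(construct_id = g$construct_id[1],
                   replicate = g$replicate[1], n_events = nrow(g),
                   mu = mu, sigma = sigma, eta2 = sigma^2 / mu^2)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$construct_id, out$replicate), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Normalize summaries to the no-sgRNA control
#'
#' Adds \code{norm_mean = mu / mu_control} and its inverse to an expression
#' summary table. By default the control mean is pooled across the control's
#' replicates; \code{mode = "replicate"} divides each replicate by the
#' control replicate with the same number. Noise is scale-invariant and is
#' left untouched.
#'
#' @param summaries data.frame from [summarizeEvents()].
#' @param controlId construct id of the control group (default
#'   \code{"control"}).
#' @param mode \code{"pooled"} or \code{"replicate"}.
#' @return \code{summaries} with \code{norm_mean} and \code{inv_norm_mean}
#'   columns added.
#' @export
normalizeToControl <- function(summaries, controlId = "control",
                               mode = c("pooled", "replicate")) {
    mode <- match.arg(mode)
    ctrl <- summaries[summaries$construct_id == controlId, , drop = FALSE]
    if (nrow(ctrl) == 0L)
        stop("normalization error: no control group '", controlId, "' present")
    if (any(ctrl$mu <= 0))
        stop("normalization error: control mean must be > 0")
    if (mode == "pooled") {
        summaries$norm_mean <- summaries$mu / mean(ctrl$mu)
    } else {
        ref <- ctrl$mu[match(summaries$replicate, ctrl$replicate)]
        if (any(is.na(ref)))
            stop("normalization error: control is missing replicate(s) ",
                 paste(unique(summaries$replicate[is.na(ref)]), collapse = ", "))
        summaries$norm_mean <- summaries$mu / ref
    }
    summaries$inv_norm_mean <- 1 / summaries$norm_mean
    summaries
}
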
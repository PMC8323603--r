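#' @useDynLib contigDamage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Per-contig C-to-T transition counts by distance from the read 5' end
#'
#' Holds, for one reference sequence (typically a contig), the number of
#' apparent C-to-T transitions \code{ctCounts} and conserved C-to-C sites
#' \code{ccCounts} observed at each distance \code{i = 0..k} from the 5' end
#' of the aligned reads, together with the read count, reference length and
#' total number of aligned bases.
#'
#' Reverse-strand alignments are folded into the same 5' statistic: they are
#' evaluated in read orientation, so a reference G read as A on the forward
#' reference strand counts as a C-to-T transition at the corresponding
#' distance from that read's 5' end.
#'
#' @slot reference single character, the reference (contig) name.
#' @slot ctCounts integer vector of length \code{k + 1}; C-to-T observations.
#' @slot ccCounts integer vector of length \code{k + 1}; C-to-C observations.
#' @slot nReads number of alignments contributing to the counts.
#' @slot referenceLength reference length in base pairs.
#' @slot alignedBases total matched (non-indel, non-clipped) read bases.
#'
#' @seealso [countTransitions()], [damageProportions()], [meanCoverage()]
#' @export
setClass("TransitionCounts",
    representation(
        reference = "character",
        ctCounts = "integer",
        ccCounts = "integer",
        nReads = "integer",
        referenceLength = "numeric",
        alignedBases = "numeric"
    )
)

setValidity("TransitionCounts", function(object) {
    msg <- NULL
    if (length(object@reference) != 1L)
        msg <- c(msg, "'reference' must be a single name")
    if (length(object@ctCounts) != length(object@ccCounts))
        msg <- c(msg, "'ctCounts' and 'ccCounts' must have equal length")
    if (length(object@ctCounts) < 2L)
        msg <- c(msg, "counts must cover at least positions 0 and 1 (k >= 1)")
    if (any(object@ctCounts < 0L) || any(object@ccCounts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (object@nReads < 0L || object@alignedBases < 0)
        msg <- c(msg, "'nReads' and 'alignedBases' must be non-negative")
    if (any(object@ctCounts + object@ccCounts > object@alignedBases))
        msg <- c(msg, "counts at a position cannot exceed total aligned bases")
    if (is.null(msg)) TRUE else msg
})

#' Fitted damage and null models for one contig
#'
#' The null model is a constant C-to-T probability \code{p0} across the
#' window. The damage model is a geometric decay
#' \code{base(i) = (1 - p_d)^i * p_d} rescaled from its natural range
#' \code{[base(k), base(0)]} to \code{[d_pmin, d_pmax]}, so that the fitted
#' curve equals \code{d_pmax} at the 5' terminus and \code{d_pmin} at the far
#' edge of the window.
#'
#' @slot p0 null-model constant probability.
#' @slot nullLoglik binomial log-likelihood of the null model.
#' @slot pD geometric decay parameter of the damage model.
#' @slot dPmin,dPmax damage probability at the window edge / 5' terminus.
#' @slot loglik binomial log-likelihood of the damage model.
#' @slot fittedCurve fitted damage-model probabilities at distances 0..k.
#' @slot rmse root-mean-square residual over informative positions.
#' @slot converged logical flags for the null and damage optimisations.
#'
#' @export
setClass("DamageFit",
    representation(
        p0 = "numeric",
        nullLoglik = "numeric",
        pD = "numeric",
        dPmin = "numeric",
        dPmax = "numeric",
        loglik = "numeric",
        fittedCurve = "numeric",
        rmse = "numeric",
        converged = "logical"
    )
)

setValidity("DamageFit", function(object) {
    msg <- NULL
    if (object@p0 < 0 || object@p0 > 1)
        msg <- c(msg, "'p0' must lie in [0, 1]")
    if (object@dPmax < object@dPmin - 1e-12)
        msg <- c(msg, "'dPmax' must be >= 'dPmin'")
    if (length(object@converged) != 2L)
        msg <- c(msg, "'converged' must hold one flag per model")
    if (is.null(msg)) TRUE else msg
})

#' Logistic model predicting per-contig call accuracy
#'
#' Maps per-contig features (by default the fitted 5'-terminal damage, mean
#' coverage and contig length) to a predicted probability that the
#' damaged/undamaged call for that contig is correct.
#'
#' @slot predictors ordered predictor names.
#' @slot coefficients numeric vector: intercept followed by one coefficient
#'   per predictor, in \code{predictors} order.
#' @slot transforms per-predictor transform labels; one of \code{"identity"},
#'   \code{"log10"} or \code{"log10p1"} (\code{log10(x + 1)}).
#' @slot provenance free-text descriptor of the training data.
#'
#' @seealso [predictAccuracy()], [fitAccuracyGLM()], [loadAccuracyModel()]
#' @export
setClass("AccuracyModel",
    representation(
        predictors = "character",
        coefficients = "numeric",
        transforms = "character",
        provenance = "character"
    )
)

setValidity("AccuracyModel", function(object) {
    msg <- NULL
    if (length(object@coefficients) != length(object@predictors) + 1L)
        msg <- c(msg, "need one coefficient per predictor plus an intercept")
    if (length(object@transforms) != length(object@predictors))
        msg <- c(msg, "need one transform per predictor")
    if (!all(object@transforms %in% c("identity", "log10", "log10p1")))
        msg <- c(msg, "unknown transform label")
    if (anyDuplicated(object@predictors))
        msg <- c(msg, "duplicated predictor names")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TransitionCounts", function(object) {
    k <- length(object@ctCounts) - 1L
    p0 <- if (sum(object@ctCounts[1L] + object@ccCounts[1L]) > 0)
        object@ctCounts[1L] / (object@ctCounts[1L] + object@ccCounts[1L]) else NA_real_
    cat("TransitionCounts for", object@reference,
        sprintf("(%d bp, %d reads, window 0..%d)\n",
                as.integer(object@referenceLength), object@nReads, k))
    cat(sprintf("  terminal C->T proportion: %s\n",
                ifelse(is.na(p0), "NA", format(p0, digits = 3))))
    cat(sprintf("  mean coverage: %.2f\n",
                object@alignedBases / max(object@referenceLength, 1)))
})

setMethod("show", "DamageFit", function(object) {
    cat("DamageFit\n")
    cat(sprintf("  null:   p0 = %.4g (loglik %.3f)\n", object@p0, object@nullLoglik))
    cat(sprintf("  damage: p_d = %.4g, d_pmin = %.4g, d_pmax = %.4g (loglik %.3f)\n",
                object@pD, object@dPmin, object@dPmax, object@loglik))
})

setMethod("show", "AccuracyModel", function(object) {
    cat("AccuracyModel:", paste(object@predictors, collapse = " + "), "\n")
    lab <- c("(Intercept)", paste0(object@predictors, " [", object@transforms, "]"))
    for (i in seq_along(object@coefficients))
        cat(sprintf("  %-28s % .5f\n", lab[i], object@coefficients[i]))
    if (nzchar(object@provenance)) cat("  trained on:", object@provenance, "\n")
})
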
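#' Null (position-independent) damage curve
#'
#' Under the null model the probability of observing a C-to-T transition is
#' the same at every distance from the 5' end.
#'
#' @param p0 constant probability in \code{[0, 1]}.
#' @param k window extent; the curve covers distances \code{0..k}.
#' @return numeric vector of \code{k + 1} copies of \code{p0}.
#' @examples nullModelCurve(0.1, 3)
#' @export
nullModelCurve <- function(p0, k) {
    if (!is.finite(p0) || p0 < 0 || p0 > 1)
        stop("'p0' must lie in [0, 1]")
    rep(p0, k + 1L)
}

#' Geometrically decaying damage curve
#'
#' The damage model assumes the C-to-T probability decays geometrically with
#' distance from the 5' end: \code{base(i) = (1 - p_d)^i * p_d}. The base
#' curve is rescaled from its natural range \code{[base(k), base(0)]} to the
#' interval \code{[d_pmin, d_pmax]}, so that the returned curve equals
#' \code{d_pmax} at \code{i = 0} and \code{d_pmin} at \code{i = k}, and is
#' non-increasing in between.
#'
#' @param pD decay parameter in \code{(0, 1)}.
#' @param dPmin,dPmax damage probability at the window edge / 5' terminus,
#'   with \code{0 <= dPmin <= dPmax <= 1}.
#' @param k window extent.
#' @return numeric vector of length \code{k + 1}.
#' @examples damageModelCurve(0.5, 0, 0.3, 2)  # (0.3, 0.1, 0.0)
#' @export
damageModelCurve <- function(pD, dPmin, dPmax, k) {
    if (!is.finite(pD) || pD <= 0 || pD >= 1)
        stop("'pD' must lie strictly inside (0, 1)")
    if (dPmin < 0 || dPmax > 1 || dPmax < dPmin)
        stop("need 0 <= dPmin <= dPmax <= 1")
    i <- 0:k
    base <- (1 - pD)^i * pD
    pmin_ <- (1 - pD)^k * pD
    pmax_ <- pD
    denom <- pmax_ - pmin_
    if (denom <= 0)        # unreachable for pD in (0,1), k >= 1; guard anyway
        return(rep(dPmin, k + 1L))
    curve <- (base - pmin_) / denom * (dPmax - dPmin) + dPmin
    # endpoints are d_pmax / d_pmin by construction; pin them so the
    # identity is exact rather than within rounding
    curve[1L] <- dPmax
    curve[k + 1L] <- dPmin
    curve
}

## Huber rho: quadratic within delta, linear beyond. Residuals are in
## proportion units so with the default delta = 1 the loss is effectively
## least squares; delta is exposed for robustified fits.
huberLoss <- function(r, delta) {
    a <- abs(r)
    ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

#' Fit the null and damage models to per-position transition proportions
#'
#' Both models are fit by bounded minimisation of the Huber loss of the model
#' curve against the observed proportions over informative positions
#' (L-BFGS-B box-constrained optimisation). Bounds are
#' \code{p_d in [1e-6, 0.99]}, \code{d_pmin, d_pmax in [0, 1]}; starting
#' values are \code{p0 = mean(pHat)}, \code{p_d = 0.1},
#' \code{d_pmin = min(pHat)}, \code{d_pmax = max(pHat)}. If the fit returns
#' \code{d_pmax < d_pmin} the two are swapped and the fit re-run once from
#' the swapped values. Binomial log-likelihoods of both fitted curves are
#' evaluated against the counts.
#'
#' @param counts a \linkS4class{TransitionCounts} object.
#' @param minPositions minimum number of informative positions required to
#'   attempt a fit (default 3).
#' @param huberDelta Huber loss scale on residuals in proportion units
#'   (default 1.0).
#' @return a \linkS4class{DamageFit}, or \code{NULL} with attribute-free
#'   signalling: the function returns \code{NA} (class "insufficientData")
#'   is avoided -- instead a list \code{list(status=, fit=)} with status one
#'   of \code{"ok"}, \code{"insufficient_data"}, \code{"fit_failed"}.
#' @examples
#' tc <- new("TransitionCounts", reference = "c", ctCounts = c(20L, 10L, 5L, 2L),
#'           ccCounts = c(80L, 90L, 95L, 98L), nReads = 100L,
#'           referenceLength = 1000, alignedBases = 400)
#' fitDamageModels(tc)$fit
#' @export
fitDamageModels <- function(counts, minPositions = 3L, huberDelta = 1.0) {
    props <- damageProportions(counts)
    inf <- props$informative
    k <- nrow(props) - 1L
    if (sum(inf) < minPositions || counts@nReads < 1L)
        return(list(status = "insufficient_data", fit = NULL))
    p <- props$pHat[inf]
    pos <- props$position[inf]

    objNull <- function(theta)
        sum(huberLoss(p - theta[1L], huberDelta))
    objDam <- function(theta) {
        curve <- damageModelCurve(theta[1L], min(theta[2L], theta[3L]),
                                  max(theta[2L], theta[3L]), k)
        sum(huberLoss(p - curve[pos + 1L], huberDelta))
    }

    res <- tryCatch({
        fit0 <- stats::optim(mean(p), objNull, method = "L-BFGS-B",
                             lower = 0, upper = 1)
        start <- c(pD = 0.1, dPmin = min(p), dPmax = max(p))
        lower <- c(1e-6, 0, 0)
        upper <- c(0.99, 1, 1)
        fit1 <- stats::optim(start, objDam, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 500L))
        if (fit1$par[3L] < fit1$par[2L]) {   # ordering guard: swap + refit
            start2 <- c(fit1$par[1L], fit1$par[3L], fit1$par[2L])
            fit1 <- stats::optim(start2, objDam, method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(maxit = 500L))
        }
        list(fit0 = fit0, fit1 = fit1)
    }, error = function(e) e)
    if (inherits(res, "error"))
        return(list(status = "fit_failed", fit = NULL,
                    reason = conditionMessage(res)))

    p0 <- unname(res$fit0$par)
    pD <- unname(res$fit1$par[1L])
    dmin <- unname(min(res$fit1$par[2L], res$fit1$par[3L]))
    dmax <- unname(max(res$fit1$par[2L], res$fit1$par[3L]))
    curve <- damageModelCurve(pD, dmin, dmax, k)
    ll0 <- binomialLogLik(nullModelCurve(p0, k), counts)
    ll1 <- binomialLogLik(curve, counts)
    if (!is.finite(ll0) || !is.finite(ll1))
        return(list(status = "fit_failed", fit = NULL,
                    reason = "non-finite log-likelihood"))
    fit <- new("DamageFit",
               p0 = p0, nullLoglik = ll0,
               pD = pD, dPmin = dmin, dPmax = dmax, loglik = ll1,
               fittedCurve = curve,
               rmse = sqrt(mean((p - curve[pos + 1L])^2)),
               converged = c(null = res$fit0$convergence == 0L,
                             damage = res$fit1$convergence == 0L))
    list(status = "ok", fit = fit)
}

#' Binomial log-likelihood of a damage curve given transition counts
#'
#' Sum over positions of the log binomial probability of observing
#' \code{N[i]} C-to-T transitions out of \code{N[i] + M[i]} reference-C sites
#' with success probability \code{curve[i]}. Computed in log space; curve
#' values are clamped to \code{[1e-9, 1 - 1e-9]} before taking logs, and
#' positions with no observations contribute 0.
#'
#' @param curve probabilities at distances 0..k, values in \code{[0, 1]}.
#' @param counts a \linkS4class{TransitionCounts} with count vectors of the
#'   same length.
#' @param eps probability clamp applied before taking logs (default 1e-9).
#' @return the log-likelihood (a single number, \code{<= 0}).
#' @examples
#' tc <- new("TransitionCounts", reference = "c", ctCounts = c(1L, 0L),
#'           ccCounts = c(1L, 0L), nReads = 1L, referenceLength = 10,
#'           alignedBases = 2)
#' binomialLogLik(c(0.5, 0.5), tc)  # log(0.5)
#' @export
binomialLogLik <- function(curve, counts, eps = 1e-9) {
    N <- counts@ctCounts
    M <- counts@ccCounts
    if (length(curve) != length(N))
        stop("curve length (", length(curve),
             ") does not match count vectors (", length(N), ")")
    if (any(curve < 0 | curve > 1, na.rm = TRUE))
        stop("curve values must lie in [0, 1]")
    pi <- pmin(pmax(curve, eps), 1 - eps)
    tot <- N + M
    keep <- tot > 0L
    sum(lchoose(tot[keep], N[keep]) +
        N[keep] * log(pi[keep]) + M[keep] * log(1 - pi[keep]))
}

#' Likelihood-ratio test of damage versus the position-independent null
#'
#' The statistic is \code{lambda = -2 (loglik0 - loglik1)}, referred to a
#' chi-squared distribution with two degrees of freedom (the damage model has
#' two extra parameters). Because the model parameters are obtained by robust
#' least squares rather than maximum likelihood, the damage-model likelihood
#' is not guaranteed to dominate; a negative statistic is clamped to zero
#' (p-value 1), preserving the direction of the nested comparison.
#'
#' @param fit a \linkS4class{DamageFit}.
#' @return list with elements \code{lambda} and \code{pvalue}.
#' @examples
#' f <- new("DamageFit", p0 = .1, nullLoglik = -60, pD = .3, dPmin = 0,
#'          dPmax = .2, loglik = -50, fittedCurve = numeric(36), rmse = 0,
#'          converged = c(TRUE, TRUE))
#' damageLRT(f)   # lambda 20, p = exp(-10)
#' @export
damageLRT <- function(fit) {
    ll0 <- fit@nullLoglik
    ll1 <- fit@loglik
    if (!is.finite(ll0) || !is.finite(ll1))
        stop("non-finite log-likelihoods; fit failed upstream")
    lambda <- max(0, -2 * (ll0 - ll1))
    list(lambda = lambda,
         pvalue = stats::pchisq(lambda, df = 2, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false-discovery-rate adjustment across the family of all
#' contigs tested in one run. Thin wrapper over
#' \code{stats::p.adjust(method = "BH")} kept as the module surface.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted q-values, each \code{>=} its raw p-value and \code{<= 1}.
#' @examples adjustPvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustPvalues <- function(pvalues) {
    if (length(pvalues) == 0L) return(numeric(0))
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}
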
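## Logistic accuracy model: predicting how reliable the damaged/undamaged
## call is for a contig, given its damage level, coverage and length.

applyTransform <- function(x, transform) {
    switch(transform,
           identity = x,
           log10 = log10(x),
           log10p1 = log10(x + 1),
           stop("unknown transform '", transform, "'"))
}

defaultTransforms <- function(predictors) {
    vapply(predictors, function(p)
        switch(p,
               coverage = "log10p1",
               contig_length = "log10",
               "identity"),
        character(1))
}

#' Predict per-contig call accuracy
#'
#' Evaluates the logistic model
#' \code{plogis(b0 + sum_m b_m t_m(x_m))} with the model's stored
#' per-predictor transforms. With the packaged model (positive coefficients
#' on damage, log10(coverage + 1) and log10(contig length)), predicted
#' accuracy increases in each of the three features.
#'
#' @param model an \linkS4class{AccuracyModel}.
#' @param features a data.frame (or coercible) holding one column per model
#'   predictor; extra columns are ignored.
#' @return numeric vector of predicted accuracies in \code{(0, 1)}.
#' @examples
#' m <- new("AccuracyModel", predictors = "damage", coefficients = c(0, 0),
#'          transforms = "identity", provenance = "")
#' predictAccuracy(m, data.frame(damage = 0.5))  # 0.5
#' @rdname predictAccuracy
#' @export
setMethod("predictAccuracy", "AccuracyModel", function(model, features) {
    features <- as.data.frame(features)
    missing <- setdiff(model@predictors, colnames(features))
    if (length(missing))
        stop("missing required feature(s): ", paste(missing, collapse = ", "))
    eta <- rep(model@coefficients[1L], nrow(features))
    for (j in seq_along(model@predictors)) {
        x <- applyTransform(features[[model@predictors[j]]],
                            model@transforms[j])
        eta <- eta + model@coefficients[j + 1L] * x
    }
    stats::plogis(eta)
})

#' Fit a logistic accuracy model with class balancing
#'
#' Fits \code{correct ~ predictors} by maximum-likelihood logistic regression
#' (\code{stats::glm}, convergence tolerance \code{1e-14}, iteration cap
#' \code{1e3}). Because simulated grids typically contain unequal numbers of
#' damaged and undamaged contigs, the data are first balanced by
#' down-sampling the majority class to the minority size; the down-sampling
#' is repeated \code{repeats} times with distinct derived seeds and the
#' coefficient vectors are aggregated.
#'
#' @param training data.frame with a logical (or 0/1) column \code{correct}
#'   and one column per predictor.
#' @param predictors predictor column names (default
#'   \code{c("damage", "coverage", "contig_length")}).
#' @param transforms per-predictor transform labels; defaults to
#'   \code{log10p1} for coverage, \code{log10} for contig_length and
#'   \code{identity} otherwise.
#' @param repeats number of down-sampling repetitions (default 10).
#' @param seed base seed for the repetition seeds.
#' @param aggregate \code{"mean"} (default): average the coefficients over
#'   repetitions; \code{"refit"}: single fit on the pooled balanced rows of
#'   all repetitions.
#' @param balance set \code{FALSE} to fit once on the data as given.
#' @return an \linkS4class{AccuracyModel}. Perfect separation is flagged
#'   with a warning; coefficients are still returned.
#' @export
fitAccuracyGLM <- function(training,
                           predictors = c("damage", "coverage",
                                          "contig_length"),
                           transforms = defaultTransforms(predictors),
                           repeats = 10L, seed = 1L,
                           aggregate = c("mean", "refit"),
                           balance = TRUE) {
    aggregate <- match.arg(aggregate)
    if (anyDuplicated(predictors)) stop("duplicated predictor names")
    missing <- setdiff(c("correct", predictors), colnames(training))
    if (length(missing))
        stop("training data lacks column(s): ",
             paste(missing, collapse = ", "))
    y <- as.logical(training$correct)
    if (anyNA(y)) stop("NA labels in 'correct'")
    if (length(unique(y)) < 2L)
        stop("both correct and incorrect labels are required for balancing")

    X <- as.data.frame(lapply(seq_along(predictors), function(j)
        applyTransform(training[[predictors[j]]], transforms[j])))
    names(X) <- predictors
    dat <- cbind(correct = y, X)

    fitOnce <- function(d) {
        fit <- withCallingHandlers(
            stats::glm(correct ~ ., data = d, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-14,
                                                    maxit = 1000L)),
            warning = function(w) {
                if (grepl("fitted probabilities numerically 0 or 1",
                          conditionMessage(w)))
                    warning("possible perfect separation in accuracy GLM",
                            call. = FALSE)
                invokeRestart("muffleWarning")
            })
        stats::coef(fit)
    }

    if (!balance) {
        beta <- fitOnce(dat)
    } else {
        nMin <- min(table(y))
        idxPos <- which(y)
        idxNeg <- which(!y)
        samples <- lapply(seq_len(repeats), function(r) {
            set.seed(seed + r - 1L)
            c(sample(idxPos, nMin), sample(idxNeg, nMin))
        })
        if (aggregate == "mean") {
            betas <- vapply(samples, function(idx) fitOnce(dat[idx, ]),
                            numeric(length(predictors) + 1L))
            beta <- rowMeans(betas)
        } else {
            beta <- fitOnce(dat[unlist(samples), ])
        }
    }
    new("AccuracyModel",
        predictors = predictors,
        coefficients = unname(beta),
        transforms = unname(transforms),
        provenance = sprintf("fitAccuracyGLM on %d rows (%s, %d repeats)",
                             nrow(dat), if (balance) "balanced" else
                             "unbalanced", if (balance) repeats else 1L))
}

#' Enumerate candidate predictor subsets for model selection
#'
#' All subsets of the given predictors, including the empty
#' (intercept-only) model: \code{2^p} candidates, in deterministic order
#' (by subset size, then lexicographically).
#'
#' @param predictors character vector of predictor names (no duplicates).
#' @return list of character vectors; the first element is
#'   \code{character(0)} (the intercept-only model).
#' @examples length(enumerateCandidateModels(letters[1:5]))  # 32
#' @export
enumerateCandidateModels <- function(predictors) {
    if (anyDuplicated(predictors)) stop("duplicated predictor names")
    p <- length(predictors)
    subsets <- lapply(0:(2^p - 1L), function(mask)
        predictors[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L])
    ord <- order(lengths(subsets),
                 vapply(subsets, function(s) paste(s, collapse = "|"),
                        character(1)))
    subsets[ord]
}

#' F1 score of a binary classification
#'
#' \code{2 * precision * recall / (precision + recall)}; by convention 0
#' when no positives are predicted (or none exist) and the score is
#' undefined.
#'
#' @param predicted,truth logical vectors of equal length.
#' @return a number in \code{[0, 1]}.
#' @examples f1Score(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))  # 0.5
#' @export
f1Score <- function(predicted, truth) {
    stopifnot(length(predicted) == length(truth))
    predicted <- as.logical(predicted)
    truth <- as.logical(truth)
    tp <- sum(predicted & truth)
    fp <- sum(predicted & !truth)
    fn <- sum(!predicted & truth)
    if (2 * tp + fp + fn == 0L) return(0)
    2 * tp / (2 * tp + fp + fn)
}

#' Nagelkerke's R-squared
#'
#' \code{(1 - exp(2 (l0 - l1) / n)) / (1 - exp(2 l0 / n))} for null and
#' model log-likelihoods \code{l0}, \code{l1} on \code{n} observations;
#' reaches 1 for a saturated model on binary data.
#'
#' @param loglikNull,loglikModel log-likelihoods of the intercept-only and
#'   fitted models.
#' @param n number of observations.
#' @return a number in \code{[0, 1]} (clamped against tiny negative
#'   rounding).
#' @export
nagelkerkeR2 <- function(loglikNull, loglikModel, n) {
    cox <- 1 - exp(2 * (loglikNull - loglikModel) / n)
    maxr2 <- 1 - exp(2 * loglikNull / n)
    if (maxr2 <= 0) return(0)
    min(1, max(0, cox / maxr2))
}

## Bernoulli log-likelihood of predicted probabilities against labels.
bernoulliLoglik <- function(p, y, eps = 1e-12) {
    p <- pmin(pmax(p, eps), 1 - eps)
    sum(ifelse(y, log(p), log(1 - p)))
}

#' Evaluate candidate logistic models by repeated down-sampled fits
#'
#' Splits the data into fit and test halves (seeded), then for each
#' candidate subset repeats: balance the fit half by down-sampling, fit the
#' logistic model, and score F1 (threshold 0.5) and Nagelkerke's R-squared
#' on a balanced down-sample of the held-out half (class balancing on both
#' sides keeps the intercept calibrated and stops the majority class from
#' dominating either metric). Reports per-candidate means and standard
#' deviations over the repetitions. The intercept-only candidate scores 0.
#'
#' @param training data.frame with \code{correct} plus predictor columns.
#' @param candidates list of predictor subsets, e.g. from
#'   [enumerateCandidateModels()].
#' @param repeats down-sampling repetitions per candidate (default 10).
#' @param seed seed for the split and the repetition seeds.
#' @return data.frame with columns \code{model}, \code{n_predictors},
#'   \code{f1}, \code{r2}, \code{sd_f1}, \code{sd_r2}, sorted by descending
#'   \code{f1}.
#' @export
evaluateCandidateModels <- function(training, candidates, repeats = 10L,
                                    seed = 1L) {
    y <- as.logical(training$correct)
    set.seed(seed)
    idxFit <- sample(seq_along(y), floor(length(y) / 2))
    idxTest <- setdiff(seq_along(y), idxFit)
    fitHalf <- training[idxFit, , drop = FALSE]
    testHalf <- training[idxTest, , drop = FALSE]
    yTestAll <- as.logical(testHalf$correct)
    nMinTest <- min(sum(yTestAll), sum(!yTestAll))
    if (nMinTest == 0L)
        stop("test half contains a single class; cannot balance")
    balancedTestIdx <- function(s) {
        set.seed(s)
        c(sample(which(yTestAll), nMinTest),
          sample(which(!yTestAll), nMinTest))
    }

    rows <- lapply(seq_along(candidates), function(ci) {
        preds <- candidates[[ci]]
        label <- if (length(preds)) paste(preds, collapse = "/") else
            "(intercept)"
        if (length(preds) == 0L)
            return(data.frame(model = label, n_predictors = 0L,
                              f1 = 0, r2 = 0, sd_f1 = 0, sd_r2 = 0))
        f1s <- r2s <- numeric(repeats)
        for (r in seq_len(repeats)) {
            m <- fitAccuracyGLM(fitHalf, predictors = preds,
                                repeats = 1L, seed = seed + 100L * ci + r)
            ti <- balancedTestIdx(seed + r)   # same test sample per rep
            yTest <- yTestAll[ti]
            p <- predictAccuracy(m, testHalf[ti, , drop = FALSE])
            ll0 <- bernoulliLoglik(rep(mean(yTest), length(yTest)), yTest)
            f1s[r] <- f1Score(p >= 0.5, yTest)
            r2s[r] <- nagelkerkeR2(ll0, bernoulliLoglik(p, yTest),
                                   length(yTest))
        }
        data.frame(model = label, n_predictors = length(preds),
                   f1 = mean(f1s), r2 = mean(r2s),
                   sd_f1 = stats::sd(f1s), sd_r2 = stats::sd(r2s))
    })
    out <- do.call(rbind, rows)
    out[order(-out$f1), , drop = FALSE]
}

#' Relative weights of predictors in a logistic accuracy model
#'
#' Johnson-style relative weights adapted to a logistic outcome: the
#' standardised predictor matrix is replaced by its closest orthogonal
#' counterpart (via the eigendecomposition of the predictor correlation
#' matrix), the outcome is regressed on the orthogonal variables by logistic
#' regression, and each original predictor's weight is the sum of its
#' squared loadings times the squared orthogonal coefficients. Weights are
#' rescaled to sum to the model's Nagelkerke R-squared and also reported as
#' percentages.
#'
#' @param training data.frame with \code{correct} plus predictor columns.
#' @param predictors predictor names to decompose.
#' @param transforms per-predictor transforms (defaults as in
#'   [fitAccuracyGLM()]).
#' @return data.frame with columns \code{predictor}, \code{weight} (share of
#'   R-squared) and \code{percent}.
#' @export
relativeWeights <- function(training,
                            predictors = c("damage", "coverage",
                                           "contig_length"),
                            transforms = defaultTransforms(predictors)) {
    y <- as.logical(training$correct)
    X <- vapply(seq_along(predictors), function(j)
        applyTransform(training[[predictors[j]]], transforms[j]),
        numeric(nrow(training)))
    colnames(X) <- predictors
    Xs <- scale(X)
    p <- ncol(Xs)
    if (p == 1L) {
        m <- fitAccuracyGLM(training, predictors, transforms,
                            repeats = 1L, balance = FALSE)
        pr <- predictAccuracy(m, training)
        r2 <- nagelkerkeR2(bernoulliLoglik(rep(mean(y), length(y)), y),
                           bernoulliLoglik(pr, y), length(y))
        return(data.frame(predictor = predictors, weight = r2,
                          percent = 100))
    }
    R <- stats::cor(Xs)
    ev <- eigen(R, symmetric = TRUE)
    lam <- ev$vectors %*% diag(sqrt(pmax(ev$values, 1e-12))) %*% t(ev$vectors)
    Z <- Xs %*% solve(lam)                 # uncorrelated, unit-variance
    fit <- suppressWarnings(
        stats::glm(y ~ Z, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-14,
                                                maxit = 1000L)))
    b <- stats::coef(fit)[-1L]
    raw <- as.numeric(lam^2 %*% b^2)
    pr <- stats::fitted(fit)
    r2 <- nagelkerkeR2(bernoulliLoglik(rep(mean(y), length(y)), y),
                       bernoulliLoglik(pr, y), length(y))
    w <- if (sum(raw) > 0) raw / sum(raw) * r2 else rep(0, p)
    data.frame(predictor = predictors, weight = w,
               percent = if (r2 > 0) 100 * w / r2 else rep(NA_real_, p))
}

#' Knee point of a decreasing threshold curve
#'
#' Locates the knee as the point of maximum vertical deviation from the
#' chord joining the first and last points after min-max normalisation of
#' both axes (the kneedle construction). Used to choose the
#' predicted-accuracy filtering threshold from the curve of contig counts
#' surviving at each accuracy cutoff.
#'
#' @param x threshold grid (monotone increasing).
#' @param y curve values at \code{x} (e.g. surviving contig counts).
#' @param sensitivity minimum normalised deviation to accept a knee
#'   (default 0.01); below it the curve is considered knee-free and
#'   \code{NA} is returned with a warning.
#' @return the \code{x} value at the knee, or \code{NA}.
#' @examples
#' x <- seq(0, 1, 0.01)
#' kneedleThreshold(x, ifelse(x < 0.3, 1 - 0.5 * x, 0.85 - 2.5 * (x - 0.3)))
#' @export
kneedleThreshold <- function(x, y, sensitivity = 0.01) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (is.unsorted(x)) stop("'x' must be increasing")
    xr <- diff(range(x)); yr <- diff(range(y))
    if (xr == 0 || yr == 0) {
        warning("degenerate curve; no knee")
        return(NA_real_)
    }
    xn <- (x - min(x)) / xr
    yn <- (y - min(y)) / yr
    chord <- yn[1L] + (yn[length(yn)] - yn[1L]) * xn
    dev <- abs(yn - chord)
    if (max(dev) < sensitivity) {
        warning("curve is close to straight; no knee found")
        return(NA_real_)
    }
    x[which.max(dev)]
}

#' Filter per-contig damage results
#'
#' Keeps rows passing all three inclusive thresholds: significant damage
#' (\code{qvalue <= qMax}), a shallow enough decay (\code{p_d <= pdMax},
#' appropriate for libraries without uracil-DNA-glycosylase treatment), and
#' sufficient predicted call accuracy
#' (\code{predicted_accuracy >= accMin}). Rows with NA in any tested field
#' (e.g. untested contigs) are dropped. Order is preserved.
#'
#' @param results a DataFrame/data.frame carrying \code{qvalue}, \code{p_d}
#'   and \code{predicted_accuracy} columns.
#' @param qMax,pdMax,accMin thresholds (defaults 0.05, 0.6, 0.67).
#' @return the passing subset, same class as the input.
#' @export
filterContigs <- function(results, qMax = 0.05, pdMax = 0.6,
                          accMin = 0.67) {
    need <- c("qvalue", "p_d", "predicted_accuracy")
    missing <- setdiff(need, colnames(results))
    if (length(missing))
        stop("results lack column(s): ", paste(missing, collapse = ", "))
    keep <- !is.na(results$qvalue) & !is.na(results$p_d) &
        !is.na(results$predicted_accuracy) &
        results$qvalue <= qMax & results$p_d <= pdMax &
        results$predicted_accuracy >= accMin
    results[keep, , drop = FALSE]
}

#' Load a packaged or user-supplied accuracy model
#'
#' Reads the plain-text coefficients format written by
#' [writeAccuracyModel()]: \code{key\tvalue} lines with
#' \code{predictor/coefficient/transform} triplets, an \code{intercept} and
#' a \code{provenance} line. The default is the model shipped with the
#' package, trained on this package's simulator grid.
#'
#' @param path coefficients file; default the packaged model.
#' @return an \linkS4class{AccuracyModel}.
#' @export
loadAccuracyModel <- function(path = system.file("extdata",
                                                 "accuracy_glm.txt",
                                                 package = "contigDamage")) {
    if (!nzchar(path) || !file.exists(path))
        stop("accuracy model file not found: '", path, "'")
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "\t", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    intercept <- as.numeric(kv[[which(keys == "intercept")]][2L])
    prov <- if ("provenance" %in% keys)
        kv[[which(keys == "provenance")]][2L] else ""
    isPred <- keys == "predictor"
    preds <- vapply(kv[isPred], `[`, character(1), 2L)
    coefs <- as.numeric(vapply(kv[isPred], `[`, character(1), 3L))
    trans <- vapply(kv[isPred], `[`, character(1), 4L)
    new("AccuracyModel", predictors = preds,
        coefficients = c(intercept, coefs),
        transforms = trans, provenance = prov)
}

#' Write an accuracy model to the plain-text coefficients format
#'
#' @param model an \linkS4class{AccuracyModel}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeAccuracyModel <- function(model, path) {
    lines <- c(
        "# contigDamage logistic accuracy model",
        sprintf("intercept\t%.17g", model@coefficients[1L]),
        vapply(seq_along(model@predictors), function(j)
            sprintf("predictor\t%s\t%.17g\t%s", model@predictors[j],
                    model@coefficients[j + 1L], model@transforms[j]),
            character(1)),
        sprintf("provenance\t%s", model@provenance))
    writeLines(lines, path)
    invisible(path)
}
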
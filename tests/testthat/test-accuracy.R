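make_model <- function(coefs, predictors, transforms = NULL) {
    if (is.null(transforms)) transforms <- rep("identity", length(predictors))
    new("AccuracyModel", predictors = predictors, coefficients = coefs,
        transforms = transforms, provenance = "test")
}

test_that("accuracy prediction is a transformed logistic", {
    m <- make_model(c(0, 0), "damage")
    expect_equal(predictAccuracy(m, data.frame(damage = 0.7)), 0.5)
    m <- make_model(c(50, 0), "damage")
    expect_equal(predictAccuracy(m, data.frame(damage = 0)), 1)
    m <- make_model(c(0, 1, 2), c("damage", "coverage"),
                    c("identity", "log10p1"))
    expect_equal(predictAccuracy(m, data.frame(damage = 0.5, coverage = 9)),
                 plogis(0.5 + 2 * 1))
    expect_error(predictAccuracy(m, data.frame(damage = 0.5)), "coverage")
})

test_that("the packaged model is monotone in damage, coverage and length", {
    m <- loadAccuracyModel()
    expect_true(all(m@coefficients[-1] > 0))
    lo <- predictAccuracy(m, data.frame(damage = 0.01, coverage = 1,
                                        contig_length = 1000))
    hi <- predictAccuracy(m, data.frame(damage = 0.20, coverage = 100,
                                        contig_length = 50000))
    expect_gt(hi, lo)
    # monotone along each axis separately
    grid <- data.frame(damage = c(0.02, 0.1), coverage = 10,
                       contig_length = 5000)
    p <- predictAccuracy(m, grid)
    expect_gt(p[2], p[1])
    expect_true(all(p > 0 & p < 1))
})

test_that("logistic fitting recovers a known generating law", {
    set.seed(31)
    n <- 5000
    x <- runif(n, -2, 2)
    eta <- -1 + 2 * x
    y <- runif(n) < plogis(eta)
    training <- data.frame(damage = x, correct = y)
    m <- fitAccuracyGLM(training, predictors = "damage",
                        transforms = "identity", balance = FALSE)
    ref <- glm(y ~ x, family = binomial())
    se <- sqrt(diag(vcov(ref)))
    expect_lt(abs(m@coefficients[1] - (-1)), 2 * se[1] + 0.1)
    expect_lt(abs(m@coefficients[2] - 2), 2 * se[2] + 0.1)
})

test_that("balancing is seed-stable and rejects one-class data", {
    set.seed(8)
    training <- data.frame(damage = runif(200),
                           correct = rep(c(TRUE, FALSE), c(150, 50)))
    m1 <- fitAccuracyGLM(training, "damage", repeats = 3L, seed = 5)
    m2 <- fitAccuracyGLM(training, "damage", repeats = 3L, seed = 5)
    expect_identical(m1@coefficients, m2@coefficients)
    # duplicating every row leaves the balanced-fit estimate close
    m3 <- fitAccuracyGLM(rbind(training, training), "damage",
                         repeats = 10L, seed = 5)
    expect_lt(abs(m3@coefficients[2] - m1@coefficients[2]),
              2 * abs(m1@coefficients[2]) + 1)
    expect_error(fitAccuracyGLM(data.frame(damage = 1:5,
                                           correct = rep(TRUE, 5)),
                                "damage"),
                 "both")
    # perfect separation is flagged but coefficients are still returned
    sep <- data.frame(damage = c(1:5, 11:15),
                      correct = rep(c(FALSE, TRUE), each = 5))
    expect_warning(msep <- fitAccuracyGLM(sep, "damage", repeats = 1L),
                   "separation")
    expect_length(msep@coefficients, 2L)
})

test_that("candidate enumeration covers all subsets deterministically", {
    five <- enumerateCandidateModels(c("damage", "contig_length",
                                       "coverage", "gc", "read_length"))
    expect_length(five, 32L)
    expect_identical(five[[1]], character(0))        # intercept-only
    expect_identical(enumerateCandidateModels(c("a", "b")),
                     list(character(0), "a", "b", c("a", "b")))
    expect_error(enumerateCandidateModels(c("a", "a")), "duplicated")
})

test_that("F1 follows its definition including degenerate conventions", {
    expect_equal(f1Score(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
    expect_equal(f1Score(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)), 0.5)
    expect_equal(f1Score(c(FALSE, FALSE), c(TRUE, TRUE)), 0)
    expect_equal(f1Score(logical(0), logical(0)), 0)
    # brute-force oracle over random vectors
    set.seed(12)
    for (rep in 1:20) {
        pred <- runif(30) < 0.5
        truth <- runif(30) < 0.5
        tp <- sum(pred & truth); fp <- sum(pred & !truth)
        fn <- sum(!pred & truth)
        prec <- if (tp + fp > 0) tp / (tp + fp) else NA
        rec <- if (tp + fn > 0) tp / (tp + fn) else NA
        oracle <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0 else
            2 * prec * rec / (prec + rec)
        expect_equal(f1Score(pred, truth), oracle)
    }
})

test_that("Nagelkerke R2 matches its closed form and limits", {
    expect_equal(nagelkerkeR2(-69.3, -69.3, 100), 0)
    # saturated model on binary data: loglik 0
    expect_equal(nagelkerkeR2(-69.3, 0, 100), 1)
    val <- nagelkerkeR2(-69.3, -50, 100)
    oracle <- (1 - exp(2 * (-69.3 + 50) / 100)) / (1 - exp(2 * -69.3 / 100))
    expect_equal(val, oracle)
    expect_true(val >= 0 && val <= 1)
})

test_that("relative weights decompose R2 sensibly", {
    set.seed(44)
    n <- 4000
    # orthogonal predictors with equal effects share R2 equally
    a <- rnorm(n); b <- rnorm(n)
    y <- runif(n) < plogis(a + b)
    tr <- data.frame(a = a, b = b, correct = y)
    rw <- relativeWeights(tr, c("a", "b"), c("identity", "identity"))
    expect_equal(rw$weight[1], rw$weight[2], tolerance = 0.05)
    expect_equal(sum(rw$percent), 100, tolerance = 1e-6)
    # single predictor takes 100% of R2
    rw1 <- relativeWeights(tr, "a", "identity")
    expect_equal(rw1$percent, 100)
    # correlated pair, only one causal: causal predictor dominates
    z <- 0.6 * a + 0.8 * rnorm(n)
    y2 <- runif(n) < plogis(1.5 * a)
    tr2 <- data.frame(a = a, z = z, correct = y2)
    rw2 <- relativeWeights(tr2, c("a", "z"), c("identity", "identity"))
    expect_gt(rw2$weight[rw2$predictor == "a"],
              rw2$weight[rw2$predictor == "z"])
    # weights sum to the model R2
    m <- fitAccuracyGLM(tr2, c("a", "z"), c("identity", "identity"),
                        balance = FALSE)
    p <- predictAccuracy(m, tr2)
    ll0 <- sum(dbinom(y2, 1, mean(y2), log = TRUE))
    ll1 <- sum(dbinom(y2, 1, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
    expect_equal(sum(rw2$weight), nagelkerkeR2(ll0, ll1, n),
                 tolerance = 0.02)
})

test_that("kneedle finds breakpoints and flags straight lines", {
    x <- seq(0, 1, by = 0.01)
    # two-slope piecewise line: knee exactly at the breakpoint
    y <- ifelse(x <= 0.3, 1 - 0.5 * x, 0.85 - 3 * (x - 0.3))
    expect_equal(kneedleThreshold(x, y), 0.3)
    expect_warning(k0 <- kneedleThreshold(x, 1 - x), "straight")
    expect_true(is.na(k0))
    # sigmoid: agreement with a brute-force max-chord-distance oracle
    y <- 1 / (1 + exp(10 * (x - 0.5)))
    xn <- (x - min(x)) / diff(range(x))
    yn <- (y - min(y)) / diff(range(y))
    oracle <- x[which.max(abs(yn - (yn[1] + (yn[length(yn)] - yn[1]) * xn)))]
    expect_equal(kneedleThreshold(x, y), oracle)
    expect_error(kneedleThreshold(rev(x), y), "increasing")
})

test_that("result filtering applies inclusive thresholds in order", {
    tab <- data.frame(
        reference = paste0("c", 1:6),
        qvalue = c(0.05, 0.051, 0.01, 0.01, 0.01, NA),
        p_d = c(0.6, 0.1, 0.61, 0.2, 0.6, 0.1),
        predicted_accuracy = c(0.67, 0.9, 0.9, 0.669, 0.7, 0.9))
    out <- filterContigs(tab)
    # by hand: c1 passes on all inclusive bounds; c2 fails q; c3 fails p_d;
    # c4 fails accuracy; c5 passes; c6 untested
    expect_identical(out$reference, c("c1", "c5"))
    # thresholds are configurable
    expect_identical(nrow(filterContigs(tab, qMax = 1, pdMax = 1,
                                        accMin = 0)), 5L)
    expect_error(filterContigs(tab[, 1:2]), "lack")
})

test_that("accuracy model files round-trip through the text format", {
    m <- make_model(c(-1.5, 3, 0.25), c("damage", "coverage"),
                    c("identity", "log10p1"))
    path <- tempfile(fileext = ".txt")
    writeAccuracyModel(m, path)
    m2 <- loadAccuracyModel(path)
    expect_identical(m2@predictors, m@predictors)
    expect_identical(m2@coefficients, m@coefficients)
    expect_identical(m2@transforms, m@transforms)
    expect_error(loadAccuracyModel(tempfile()), "not found")
})
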
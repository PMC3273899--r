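makeDs <- function(X, y, subset = c("intensity", "curvature")) {
    df <- data.frame(label = y)
    for (i in seq_along(subset)) df[[subset[i]]] <- X[, i]
    populationDataset(df, subset)
}

test_that("dataset invariants are enforced", {
    expect_error(makeDs(matrix(rnorm(8), 4), rep("a", 4)),
                 ">= 2 distinct labels")
    expect_error(makeDs(matrix(rnorm(10), 5), c("a", "a", "a", "b", "b")),
                 ">= 3 cells per label")
    df <- data.frame(label = rep(c("a", "b"), each = 3),
                     intensity = c(1, 2, NA, 4, 5, 6))
    expect_error(populationDataset(df, "intensity"), "missing")
    expect_error(populationDataset(df, character(0)), "nonempty subset")
})

test_that("1-D symmetric LDA puts the threshold midway between the means", {
    ds <- makeDs(matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1),
                 rep(c("a", "b"), each = 3), "intensity")
    b <- fitLinear(ds, standardize = FALSE)
    pair <- b$fit$pairs[[1]]
    expect_equal(unname(pair$offset / pair$w), 1.0)
    expect_equal(predictLabels(b, data.frame(intensity = c(0.9, 1.1))),
                 c("a", "b"))
})

test_that("2-D LDA boundary direction matches the analytic discriminant", {
    set.seed(31)
    n <- 50
    X <- rbind(matrix(rnorm(2 * n), ncol = 2),
               matrix(rnorm(2 * n, mean = 3), ncol = 2))
    ds <- makeDs(X, rep(c("a", "b"), each = n))
    b <- fitLinear(ds, standardize = FALSE)
    w <- b$fit$pairs[[1]]$w
    ang <- acos(abs(sum(w * c(1, 1))) / sqrt(sum(w^2) * 2)) * 180 / pi
    expect_lt(ang, 10)
})

test_that("implementation agrees with MASS::lda on two balanced classes", {
    set.seed(7)
    n <- 40
    X <- rbind(matrix(rnorm(2 * n), ncol = 2),
               sweep(matrix(rnorm(2 * n), ncol = 2), 2, c(2, 1), "+"))
    y <- rep(c("a", "b"), each = n)
    ds <- makeDs(X, y)
    ours <- predictLabels(fitLinear(ds, standardize = FALSE),
                          data.frame(intensity = X[, 1], curvature = X[, 2]))
    ref <- as.character(stats::predict(
        MASS::lda(X, grouping = y, prior = c(0.5, 0.5)))$class)
    expect_equal(ours, ref)
})

test_that("perfectly separated clusters give zero LOO error and p = 1/(B+1)", {
    set.seed(5)
    n <- 15
    X <- rbind(matrix(rnorm(2 * n, sd = 0.2), ncol = 2),
               sweep(matrix(rnorm(2 * n, sd = 0.2), ncol = 2), 2,
                     c(10, 10), "+"))
    ds <- makeDs(X, rep(c("a", "b"), each = n))
    res <- loocvError(ds)
    expect_equal(res@errorRate, 0)
    expect_equal(res@errorSD, 0)
    expect_equal(sum(res@confusion), 2L * n)
    p <- permutationP(ds, nPerm = 199, seed = 3)
    expect_equal(as.numeric(p), 1 / 200)
})

test_that("random labels on one cloud sit at chance; worst case gives p = 1", {
    set.seed(11)
    n <- 100
    X <- matrix(rnorm(2 * n), ncol = 2)
    ds <- makeDs(X, sample(rep(c("a", "b"), each = n / 2)))
    res <- loocvError(ds)
    expect_lt(abs(res@errorRate - 0.5), 3 * sqrt(0.25 / n))
    # observed LOO error of 1 cannot be beaten by any permutation
    worst <- makeDs(matrix(c(-0.39, -0.06, 1.10, 0.76, -0.16, -0.25),
                           ncol = 1),
                    rep(c("a", "b"), each = 3), "intensity")
    expect_equal(loocvError(worst, standardize = FALSE)@errorRate, 1)
    p <- permutationP(worst, nPerm = 99, seed = 1, standardize = FALSE)
    expect_equal(as.numeric(p), 1.0)
})

test_that("LOO error is invariant to row order", {
    set.seed(13)
    n <- 20
    X <- rbind(matrix(rnorm(2 * n), ncol = 2),
               sweep(matrix(rnorm(2 * n), ncol = 2), 2, c(1.5, 0), "+"))
    y <- rep(c("a", "b"), each = n)
    e1 <- loocvError(makeDs(X, y))@errorRate
    ord <- sample(2 * n)
    e2 <- loocvError(makeDs(X[ord, ], y[ord]))@errorRate
    expect_equal(e1, e2)
})

test_that("error SD follows the binomial formula and published pairs", {
    expect_equal(errorSD(0, 25), 0)
    expect_equal(errorSD(1, 25), 0)
    expect_equal(errorSD(0.5, 100), 0.05)
    expect_equal(round(100 * errorSD(0.061, 68), 1), 2.9)
    expect_equal(round(100 * errorSD(0.13, 68), 1), 4.1)
    expect_error(errorSD(1.2, 10), "0, 1")
})

test_that("LOO error matches the Bayes rate for equal-covariance Gaussians", {
    set.seed(17)
    n <- 100                       # per class, N = 200
    delta <- 2                     # Mahalanobis separation
    X <- rbind(matrix(rnorm(2 * n), ncol = 2),
               sweep(matrix(rnorm(2 * n), ncol = 2), 2, c(delta, 0), "+"))
    ds <- makeDs(X, rep(c("a", "b"), each = n))
    bayes <- pnorm(-delta / 2)
    res <- loocvError(ds)
    expect_lt(abs(res@errorRate - bayes), 3 * sqrt(bayes * (1 - bayes) / (2 * n)))
})

test_that("three-class voting resolves and fractions behave at the edges", {
    set.seed(19)
    n <- 10
    X <- rbind(matrix(rnorm(2 * n, sd = 0.3), ncol = 2),
               sweep(matrix(rnorm(2 * n, sd = 0.3), ncol = 2), 2,
                     c(8, 0), "+"),
               sweep(matrix(rnorm(2 * n, sd = 0.3), ncol = 2), 2,
                     c(0, 8), "+"))
    y <- rep(c("a", "b", "c"), each = n)
    ds <- makeDs(X, y)
    expect_equal(loocvError(ds)@errorRate, 0)
    expect_equal(fractionInClassRegion(ds, "a", "b"), 0)
    expect_equal(fractionInClassRegion(ds, "a", "a"), 1)
    expect_error(fractionInClassRegion(ds, "nope", "a"), "unknown source")
})

test_that("permutation p-values are valid under the null (type I error)", {
    nRep <- 25
    n <- 20
    pvals <- vapply(seq_len(nRep), function(r) {
        set.seed(100 + r)
        X <- matrix(rnorm(2 * n), ncol = 2)
        ds <- makeDs(X, rep(c("a", "b"), each = n / 2))
        as.numeric(permutationP(ds, nPerm = 99, seed = r))
    }, numeric(1))
    expect_lte(mean(pvals < 0.05), 0.16)  # binomial band around 0.05
    expect_gt(min(pvals), 0)
})

test_that("population trend report summarizes means and SDs", {
    df <- data.frame(label = rep(c("a", "b"), each = 4),
                     intensity = c(rep(2, 4), 1:4),
                     curvature = c(rep(1, 4), 2:5))
    ds <- populationDataset(df, c("intensity", "curvature"))
    rep_ <- populationTrendReport(ds)
    tab <- rep_$table
    expect_equal(tab$sd[tab$population == "a" & tab$feature == "intensity"], 0)
    expect_equal(tab$mean[tab$population == "b" & tab$feature == "intensity"],
                 2.5)
    expect_s3_class(rep_$plot, "ggplot")
    expect_error(populationTrendReport(list()), "at least one")
})

test_that("chance binomial report is consistent", {
    expect_lt(chanceBinomialP(0, 20, 2), 1e-5)
    expect_gt(chanceBinomialP(0.5, 20, 2), 0.4)
})
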
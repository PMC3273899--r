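#' Assemble a labeled PopulationDataset
#'
#' @param features a data.frame with columns \code{label} (and optionally
#'   \code{cell_id}) plus feature columns, or a list of
#'   \linkS4class{LaminaFeatures}.
#' @param featureSubset nonempty subset of
#'   c("intensity", "skewness", "curvature") to classify on.
#' @return a \linkS4class{PopulationDataset}.
#' @examples
#' df <- data.frame(label = rep(c("a", "b"), each = 5),
#'                  intensity = c(rnorm(5), rnorm(5, 3)),
#'                  curvature = c(rnorm(5, 1), rnorm(5, 2)))
#' populationDataset(df, c("intensity", "curvature"))
#' @export
populationDataset <- function(features,
                              featureSubset = c("intensity", "skewness",
                                                "curvature")) {
    if (is.list(features) && !is.data.frame(features) &&
        all(vapply(features, is, logical(1), "LaminaFeatures")))
        features <- featureTable(features)
    if (!"cell_id" %in% names(features))
        features$cell_id <- sprintf("cell_%03d", seq_len(nrow(features)))
    features$label <- as.character(features$label)
    new("PopulationDataset", features = features,
        featureSubset = featureSubset)
}

.datasetMatrix <- function(dataset) {
    X <- as.matrix(dataset@features[dataset@featureSubset])
    storage.mode(X) <- "double"
    list(X = X, y = dataset@features$label)
}

# Standardization parameters from training rows; zero-variance columns get
# unit scale so constants pass through.
.zfit <- function(X) {
    n <- nrow(X)
    mu <- colMeans(X)
    sd <- sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
    sd[!is.finite(sd) | sd == 0] <- 1
    list(mu = mu, sd = sd)
}
.zapply <- function(X, z) sweep(sweep(X, 2, z$mu), 2, z$sd, "/")

# Fisher pairwise linear discriminant on a numeric matrix. Pooled
# within-class covariance with ridge term lambda * trace(S); per class pair
# w = S^-1 (mu_i - mu_j) with the offset at the midpoint of the projected
# class means. Multiclass prediction is by pairwise voting, ties broken by
# the smallest Mahalanobis distance to the class mean.
.ldaCore <- function(X, y, lambda = 1e-6) {
    labs <- sort(unique(y))
    k <- length(labs)
    d <- ncol(X)
    if (any(table(y) < 2L))
        stop("a class has fewer than 2 training members", call. = FALSE)
    mus <- matrix(0, k, d, dimnames = list(labs, colnames(X)))
    S <- matrix(0, d, d)
    for (i in seq_len(k)) {
        Xi <- X[y == labs[i], , drop = FALSE]
        mus[i, ] <- colMeans(Xi)
        S <- S + crossprod(sweep(Xi, 2, mus[i, ]))
    }
    S <- S / (nrow(X) - k)
    S <- S + diag(lambda * sum(diag(S)), d)
    Sinv <- tryCatch(solve(S), error = function(e)
        stop("singular pooled covariance after regularization",
             call. = FALSE))
    pairs <- list()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        w <- drop(Sinv %*% (mus[i, ] - mus[j, ]))
        off <- sum(w * (mus[i, ] + mus[j, ]) / 2)
        pairs[[length(pairs) + 1L]] <-
            list(i = labs[i], j = labs[j], w = w, offset = off)
    }
    list(labels = labs, means = mus, Sinv = Sinv, pairs = pairs)
}

.ldaPredictCore <- function(fit, X) {
    labs <- fit$labels
    k <- length(labs)
    votes <- matrix(0L, nrow(X), k, dimnames = list(NULL, labs))
    for (p in fit$pairs) {
        s <- drop(X %*% p$w) - p$offset
        votes[, p$i] <- votes[, p$i] + (s > 0)
        votes[, p$j] <- votes[, p$j] + (s <= 0)
    }
    top <- max.col(votes, ties.method = "first")
    nmax <- rowSums(votes == votes[cbind(seq_len(nrow(X)), top)])
    tied <- which(nmax > 1)
    if (length(tied)) {
        md <- matrix(Inf, length(tied), k)
        for (i in seq_len(k)) {
            D <- X[tied, , drop = FALSE] -
                matrix(fit$means[i, ], length(tied), ncol(X), byrow = TRUE)
            md[, i] <- rowSums((D %*% fit$Sinv) * D)
        }
        vmax <- votes[tied, , drop = FALSE] ==
            votes[cbind(tied, top[tied])]
        md[!vmax] <- Inf
        top[tied] <- max.col(-md, ties.method = "first")
    }
    labs[top]
}

#' Fit the Fisher linear discriminant boundary
#'
#' Pairwise Fisher linear discriminant with pooled within-class covariance
#' (ridge-regularized by 1e-6 of its trace when near-singular): for each
#' class pair, \eqn{w \propto S_w^{-1} (\mu_1 - \mu_2)} with the decision
#' offset at the midpoint of the projected class means. Multiclass decisions
#' are made by pairwise voting with ties broken by the smallest Mahalanobis
#' distance to a tied class mean. Features are z-scored on the training data
#' first by default.
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param standardize z-score features before fitting (recomputed within
#'   every training fold downstream, so no leakage into held-out cells).
#' @return a boundary object (list) for \code{\link{predictLabels}}, with
#'   per-pair coefficients \code{w} and \code{offset} in standardized
#'   feature space.
#' @export
fitLinear <- function(dataset, standardize = TRUE) {
    validObject(dataset)
    dm <- .datasetMatrix(dataset)
    z <- if (standardize) .zfit(dm$X) else
        list(mu = rep(0, ncol(dm$X)), sd = rep(1, ncol(dm$X)))
    fit <- .ldaCore(.zapply(dm$X, z), dm$y)
    structure(list(fit = fit, z = z,
                   featureSubset = dataset@featureSubset,
                   standardize = standardize),
              class = "laminaBoundary")
}

#' Predict population labels from a fitted boundary
#'
#' @param boundary a boundary from \code{\link{fitLinear}}.
#' @param newdata data.frame or matrix containing the boundary's feature
#'   columns.
#' @return character vector of predicted labels.
#' @export
predictLabels <- function(boundary, newdata) {
    X <- as.matrix(as.data.frame(newdata)[boundary$featureSubset])
    storage.mode(X) <- "double"
    .ldaPredictCore(boundary$fit, .zapply(X, boundary$z))
}

#' Binomial standard deviation of a classification error
#'
#' \code{sqrt(e (1 - e) / n)}: the standard deviation attached to a
#' leave-one-out error estimated from n cells. Reproduces the printed
#' uncertainty of published error rates, e.g. an error of 6.1\% over 68
#' cells carries +/- 2.9\%.
#'
#' @param errorRate error fraction in [0, 1].
#' @param nCells number of cells tested.
#' @return standard deviation as a fraction.
#' @examples
#' errorSD(0.061, 68)  # ~0.029
#' errorSD(0.13, 68)   # ~0.041
#' @export
errorSD <- function(errorRate, nCells) {
    .stopIfNot(all(errorRate >= 0 & errorRate <= 1),
               "errorRate must lie in [0, 1]")
    .stopIfNot(all(nCells >= 1), "nCells must be >= 1")
    sqrt(errorRate * (1 - errorRate) / nCells)
}

# Internal LOO error on a matrix/labels, refitting standardization and the
# discriminant within every fold. Uses the closed-form equivalence of
# midpoint-offset pairwise voting with the argmax of the equal-prior
# discriminant scores g_i = x' S^-1 mu_i - mu_i' S^-1 mu_i / 2 (label i
# beats j in the pairwise test iff g_i > g_j), which avoids materializing
# the pairwise boundaries in this hot loop; the equivalence with
# .ldaCore/.ldaPredictCore is asserted in the test suite.
.looCore <- function(X, y, standardize = TRUE, lambda = 1e-6) {
    yf <- factor(y)
    yi <- as.integer(yf)
    k <- nlevels(yf)
    n <- nrow(X)
    d <- ncol(X)
    pred <- integer(n)
    for (i in seq_len(n)) {
        Xi <- X[-i, , drop = FALSE]
        yii <- yi[-i]
        x0 <- X[i, ]
        if (standardize) {
            m <- nrow(Xi)
            mu <- colMeans(Xi)
            sdv <- sqrt(pmax(colSums(Xi^2) - m * mu^2, 0) / (m - 1))
            sdv[!is.finite(sdv) | sdv == 0] <- 1
            Xi <- sweep(sweep(Xi, 2, mu), 2, sdv, "/")
            x0 <- (x0 - mu) / sdv
        }
        counts <- tabulate(yii, k)
        if (any(counts < 2L))
            stop("leave-one-out fold with a single-member class",
                 call. = FALSE)
        mus <- rowsum(Xi, yii) / counts
        S <- crossprod(Xi - mus[yii, , drop = FALSE]) / (nrow(Xi) - k)
        S <- S + diag(lambda * sum(diag(S)), d)
        SimMu <- solve(S, t(mus))              # d x k
        g <- drop(x0 %*% SimMu) - 0.5 * colSums(t(mus) * SimMu)
        pred[i] <- which.max(g)
    }
    levels(yf)[pred]
}

#' Leave-one-out cross-validated classification error
#'
#' Each cell is classified by a Fisher linear discriminant trained on the
#' remaining N - 1 cells (feature standardization refit within every fold);
#' the error is the fraction of the N cells classified wrongly and its
#' standard deviation is the binomial \code{\link{errorSD}}. All cells are
#' included; no outlier removal is performed.
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param standardize z-score features within each training fold.
#' @return a \linkS4class{ClassificationResult} (pValue is NA until
#'   \code{\link{permutationP}} is run).
#' @export
loocvError <- function(dataset, standardize = TRUE) {
    validObject(dataset)
    dm <- .datasetMatrix(dataset)
    pred <- .looCore(dm$X, dm$y, standardize)
    n <- length(dm$y)
    err <- mean(pred != dm$y)
    new("ClassificationResult", errorRate = err,
        errorSD = errorSD(err, n), pValue = NA_real_, nCells = as.integer(n),
        featureSubset = dataset@featureSubset,
        boundary = unclass(fitLinear(dataset, standardize)),
        confusion = table(true = dm$y,
                          predicted = factor(pred, levels = sort(unique(dm$y)))))
}

#' Permutation significance of the LOO classification error
#'
#' Permutes the population labels across all cells \code{nPerm} times,
#' recomputes the leave-one-out error for each permutation, and reports
#' \deqn{p = (1 + \#\{e_{perm} \le e_{obs}\}) / (1 + n_{perm}),}
#' the add-one permutation p-value. Deterministic for a fixed seed.
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param standardize z-score features within folds.
#' @return numeric p-value in (0, 1]; the observed error is attached as
#'   attribute \code{observedError}.
#' @export
permutationP <- function(dataset, nPerm = 999L, seed = 1, standardize = TRUE) {
    validObject(dataset)
    .stopIfNot(nPerm >= 99L, "nPerm must be >= 99")
    dm <- .datasetMatrix(dataset)
    obs <- mean(.looCore(dm$X, dm$y, standardize) != dm$y)
    hits <- .withSeed(seed, {
        h <- 0L
        for (b in seq_len(nPerm)) {
            yp <- sample(dm$y)
            ep <- mean(.looCore(dm$X, yp, standardize) != yp)
            if (ep <= obs) h <- h + 1L
        }
        h
    })
    p <- (1 + hits) / (1 + nPerm)
    attr(p, "observedError") <- obs
    p
}

#' Binomial test of the LOO error against chance
#'
#' Secondary significance report: one-sided exact binomial test that the
#' number of misclassified cells is below the chance rate
#' \code{1 - 1/nClasses}.
#'
#' @param errorRate observed LOO error fraction.
#' @param nCells number of cells.
#' @param nClasses number of populations.
#' @return p-value from \code{\link[stats]{binom.test}}.
#' @export
chanceBinomialP <- function(errorRate, nCells, nClasses = 2L) {
    stats::binom.test(round(errorRate * nCells), nCells,
                      p = 1 - 1 / nClasses,
                      alternative = "less")$p.value
}

#' Fraction of one population classified into another's region
#'
#' Trains the multiclass boundary on the full dataset (unless one is
#' supplied) and reports the fraction of \code{sourceLabel} cells whose
#' predicted label is \code{targetLabel}. Used to estimate, e.g., the
#' fraction of a senescent cohort whose lamina descriptors fall in the
#' apoptotic region.
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param sourceLabel label whose cells are examined.
#' @param targetLabel label whose decision region is counted.
#' @param boundary optional boundary from \code{\link{fitLinear}}; fitted on
#'   \code{dataset} when NULL.
#' @param standardize passed to \code{\link{fitLinear}} when fitting.
#' @return fraction in [0, 1].
#' @export
fractionInClassRegion <- function(dataset, sourceLabel, targetLabel,
                                  boundary = NULL, standardize = TRUE) {
    validObject(dataset)
    labs <- unique(dataset@features$label)
    .stopIfNot(sourceLabel %in% labs,
               sprintf("unknown source label '%s'", sourceLabel))
    if (is.null(boundary)) boundary <- fitLinear(dataset, standardize)
    .stopIfNot(targetLabel %in% boundary$fit$labels,
               sprintf("unknown target label '%s'", targetLabel))
    rows <- dataset@features$label == sourceLabel
    pred <- predictLabels(boundary, dataset@features[rows, , drop = FALSE])
    mean(pred == targetLabel)
}

#' Scatter plot of two features with the linear decision boundaries
#'
#' Plots the cells of a dataset in the plane of two features, coloured by
#' label, with the fitted pairwise discriminant boundaries drawn as lines
#' (each pairwise rule is linear in feature space, so its zero level is a
#' straight line in any two-feature view when the dataset has exactly
#' those two features).
#'
#' @param dataset a \linkS4class{PopulationDataset} with exactly two
#'   features in its subset.
#' @param boundary optional boundary from \code{\link{fitLinear}}; fitted
#'   on the dataset when NULL.
#' @param standardize passed to \code{\link{fitLinear}} when fitting.
#' @return a ggplot object.
#' @export
plotClassification <- function(dataset, boundary = NULL,
                               standardize = TRUE) {
    .stopIfNot(length(dataset@featureSubset) == 2,
               "plotClassification needs exactly two features")
    if (is.null(boundary)) boundary <- fitLinear(dataset, standardize)
    fx <- dataset@featureSubset[1]
    fy <- dataset@featureSubset[2]
    df <- dataset@features
    lines <- do.call(rbind, lapply(boundary$fit$pairs, function(p) {
        # w . (x - mu)/sd = offset in standardized space -> raw-space line
        wr <- p$w / boundary$z$sd
        cr <- p$offset + sum(p$w * boundary$z$mu / boundary$z$sd)
        if (abs(wr[2]) < 1e-12) return(NULL)
        data.frame(slope = -wr[1] / wr[2], intercept = cr / wr[2],
                   pair = paste(p$i, "vs", p$j))
    }))
    plt <- ggplot2::ggplot(df, ggplot2::aes(
            x = .data[[fx]], y = .data[[fy]], colour = label)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::labs(x = fx, y = fy) +
        ggplot2::theme_minimal()
    if (!is.null(lines) && nrow(lines))
        plt <- plt + ggplot2::geom_abline(
            data = lines,
            ggplot2::aes(slope = slope, intercept = intercept,
                         linetype = pair),
            colour = "grey30")
    plt
}

#' Population trend report: per-population mean and SD of each feature
#'
#' Summarizes one or more labeled datasets into a per-population table of
#' feature means and standard deviations, plus a centroid scatter plot with
#' error bars in the plane of the first two features (the
#' intensity-by-curvature trend view when both are present).
#'
#' @param datasets a \linkS4class{PopulationDataset} or list of them.
#' @return list with \code{table} (data.frame: population, feature, mean,
#'   sd, n) and \code{plot} (a ggplot object, or NULL with fewer than two
#'   features).
#' @export
populationTrendReport <- function(datasets) {
    if (is(datasets, "PopulationDataset")) datasets <- list(datasets)
    .stopIfNot(length(datasets) >= 1, "need at least one dataset")
    fs <- unique(unlist(lapply(datasets, function(d) d@featureSubset)))
    .stopIfNot(length(fs) >= 1, "empty feature subset")
    df <- do.call(rbind, lapply(datasets, function(d)
        d@features[c("label", intersect(fs, names(d@features)))]))
    long <- do.call(rbind, lapply(fs, function(f) data.frame(
        population = df$label, feature = f, value = df[[f]],
        stringsAsFactors = FALSE)))
    tab <- do.call(rbind, lapply(split(long, list(long$population,
                                                  long$feature), drop = TRUE),
        function(g) data.frame(population = g$population[1],
                               feature = g$feature[1],
                               mean = mean(g$value),
                               sd = stats::sd(g$value), n = nrow(g),
                               stringsAsFactors = FALSE)))
    rownames(tab) <- NULL
    plt <- NULL
    if (length(fs) >= 2) {
        fx <- fs[1]; fy <- fs[2]
        wide <- merge(tab[tab$feature == fx, c("population", "mean", "sd")],
                      tab[tab$feature == fy, c("population", "mean", "sd")],
                      by = "population", suffixes = c("_x", "_y"))
        plt <- ggplot2::ggplot(wide, ggplot2::aes(
                x = mean_x, y = mean_y, colour = population)) +
            ggplot2::geom_point(size = 3) +
            ggplot2::geom_errorbar(ggplot2::aes(
                ymin = mean_y - sd_y, ymax = mean_y + sd_y), width = 0) +
            ggplot2::geom_errorbarh(ggplot2::aes(
                xmin = mean_x - sd_x, xmax = mean_x + sd_x), height = 0) +
            ggplot2::labs(x = fx, y = fy,
                          title = "Population means +/- SD") +
            ggplot2::theme_minimal()
    }
    list(table = tab, plot = plt)
}
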
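#' Per-vertex normalized lamina intensities
#'
#' Divides the raw intensity sampled at each mesh vertex by the mean raw
#' intensity over the whole filled nucleus (shell plus interior). This
#' normalization makes the descriptor invariant to global intensity scaling
#' (laser power, expression level) and decreases when lamin redistributes
#' from the shell into intranuclear structures, which is exactly the
#' senescence-associated behaviour the descriptor is meant to capture.
#'
#' @param surface a successful \linkS4class{LaminaSurface}.
#' @param stack the \linkS4class{ImageStack} the surface was segmented from.
#' @return numeric vector of dimensionless normalized intensities, one per
#'   vertex.
#' @export
normalizedIntensityValues <- function(surface, stack) {
    .stopIfNot(segmentationSuccess(surface),
               "surface comes from a failed segmentation")
    m <- mean(voxels(stack)[nucleusMask(surface)])
    .stopIfNot(is.finite(m) && m > 0, "zero mean intensity over the nucleus mask")
    vertexIntensity(surface) / m
}

#' Mean normalized intensity descriptor
#'
#' Arithmetic mean of the per-vertex normalized intensities; the paper-style
#' "intensity" feature. Reduced when lamin leaves the shell for the
#' nucleoplasm.
#'
#' @param values per-vertex normalized intensities.
#' @return dimensionless scalar.
#' @export
featureIntensity <- function(values) {
    .stopIfNot(length(values) > 0, "empty intensity vector")
    mean(values)
}

#' Intensity skewness descriptor
#'
#' Sample skewness in the biased moment form g1 = m3 / m2^(3/2) of the
#' per-vertex normalized intensities; invariant under positive affine
#' transforms of the values. Elevated when bright local accumulations give
#' the intensity distribution a heavy right tail.
#'
#' @param values per-vertex normalized intensities (n >= 3, nonzero
#'   variance).
#' @return dimensionless scalar.
#' @export
featureSkewness <- function(values) {
    .stopIfNot(length(values) >= 3, "need at least 3 values for skewness")
    if (stats::var(values) == 0)
        stop("degenerate distribution: zero variance", call. = FALSE)
    e1071::skewness(values, type = 1)
}

#' Per-vertex Gaussian curvature by local quadric fitting
#'
#' For each vertex, neighbours within \code{neighborhoodRadius} (graph
#' neighbourhood filtered by Euclidean distance) are projected into the
#' tangent frame spanned by two directions orthogonal to the area-weighted
#' vertex normal, and the height function is fit by least squares to
#' \deqn{z = \tfrac12(a x^2 + 2 b x y + c y^2) + d x + e y,}
#' giving \eqn{K = (a c - b^2) / (1 + d^2 + e^2)^2}.
#'
#' @param surface a successful \linkS4class{LaminaSurface}, or a list with
#'   \code{vertices} and \code{faces} (e.g. from \code{\link{truthMesh}}).
#' @param neighborhoodRadius fitting radius in vertex units (nm); default 3
#'   mean edge lengths, and at least 2 mean edge lengths is recommended.
#' @return numeric vector of Gaussian curvature (nm^-2) per vertex.
#' @export
gaussianCurvature <- function(surface, neighborhoodRadius = NULL) {
    if (is(surface, "LaminaSurface")) {
        .stopIfNot(segmentationSuccess(surface),
                   "surface comes from a failed segmentation")
        v <- vertices(surface); f <- faces(surface)
    } else {
        v <- surface$vertices; f <- surface$faces
    }
    el <- .meanEdgeLength(v, f)
    if (is.null(neighborhoodRadius)) neighborhoodRadius <- 3 * el
    nrings <- max(2L, ceiling(neighborhoodRadius / el) + 1L)
    A <- .meshAdjacency(nrow(v), f)
    reach <- A
    acc <- A
    for (r in seq_len(nrings - 1L)) {
        reach <- reach %*% A
        acc <- acc + reach
    }
    acc <- methods::as(acc, "generalMatrix")
    nb <- Matrix::summary(acc)
    nb <- nb[nb$i != nb$j, , drop = FALSE]
    d2 <- rowSums((v[nb$i, , drop = FALSE] - v[nb$j, , drop = FALSE])^2)
    keep <- d2 <= neighborhoodRadius^2
    nbl <- split(nb$j[keep], nb$i[keep])
    nrm <- .vertexNormals(v, f)
    tb <- .tangentBasis(nrm)
    K <- numeric(nrow(v))
    for (i in seq_len(nrow(v))) {
        jj <- nbl[[as.character(i)]]
        if (is.null(jj) || length(jj) < 6L)
            stop(sprintf(
                "under-determined neighborhood at vertex %d (< 6 points); ",
                i), "increase neighborhoodRadius", call. = FALSE)
        P <- v[jj, , drop = FALSE] -
            matrix(v[i, ], length(jj), 3, byrow = TRUE)
        xl <- P %*% tb$e1[i, ]
        yl <- P %*% tb$e2[i, ]
        zl <- P %*% nrm[i, ]
        X <- cbind(0.5 * xl^2, xl * yl, 0.5 * yl^2, xl, yl)
        beta <- stats::.lm.fit(X, zl)$coefficients
        K[i] <- (beta[1] * beta[3] - beta[2]^2) /
            (1 + beta[4]^2 + beta[5]^2)^2
    }
    K
}

#' Total curvature (Gauss-Bonnet check)
#'
#' Area-weighted integral of signed Gaussian curvature over a closed mesh;
#' equals 4 pi for any closed genus-0 surface, which makes it a sanity
#' check for the curvature estimator.
#'
#' @param vertices n x 3 vertex matrix.
#' @param faces m x 3 face index matrix.
#' @param K per-vertex signed Gaussian curvature.
#' @return the surface integral of K.
#' @export
gaussBonnetTotal <- function(vertices, faces, K) {
    sum(K * .vertexAreas(vertices, faces))
}

#' Normalized average absolute Gaussian curvature descriptor
#'
#' Area-weighted mean of |K| over the shell, multiplied by the squared
#' equivalent-sphere radius \eqn{R_{eq} = (3 V / 4\pi)^{1/3}} computed from
#' the enclosed mesh volume. The normalization makes the descriptor
#' dimensionless and invariant to uniform spatial rescaling, and anchors a
#' perfect sphere at exactly 1; wrinkling and folding push it above 1.
#'
#' @param surface a successful \linkS4class{LaminaSurface} or a
#'   vertices/faces list.
#' @param K per-vertex Gaussian curvature from
#'   \code{\link{gaussianCurvature}}.
#' @return dimensionless scalar >= 0.
#' @export
featureCurvature <- function(surface, K) {
    if (is(surface, "LaminaSurface")) {
        v <- vertices(surface); f <- faces(surface)
    } else {
        v <- surface$vertices; f <- surface$faces
    }
    vol <- meshVolume(v, f)
    .stopIfNot(vol > 0, "zero enclosed volume")
    a <- .vertexAreas(v, f)
    req2 <- (3 * vol / (4 * pi))^(2 / 3)
    sum(abs(K) * a) / sum(a) * req2
}

#' Compute the three lamina descriptors for one cell
#'
#' Full per-cell pipeline: resample to an isotropic grid if needed, segment
#' the lamina, and evaluate the intensity, skewness and curvature
#' descriptors. If segmentation fails a condition of class
#' \code{laminaSegmentationError} is raised so callers can catch it and
#' exclude the cell, mirroring the exclusion of cells whose lamina contour
#' cannot be completely found.
#'
#' @param stack an \linkS4class{ImageStack} (any spacing).
#' @param cellId identifier stored in the result.
#' @param label population label stored in the result ("" if unknown).
#' @param smoothingSigma,threshold,minVolume,closingIter,subdiv,intensityProbeDepth
#'   passed to \code{\link{segmentLamina}}.
#' @param neighborhoodRadius passed to \code{\link{gaussianCurvature}}.
#' @return a \linkS4class{LaminaFeatures}.
#' @examples
#' gt <- makeSurface(phenotypeTemplates()$fresh, seed = 3)
#' fe <- computeFeatures(rasterizeNucleus(gt), cellId = "demo")
#' fe
#' @export
computeFeatures <- function(stack, cellId = "", label = "",
                            smoothingSigma = 100, threshold = "otsu",
                            minVolume = 1e10, closingIter = 2L,
                            subdiv = 4L, intensityProbeDepth = 300,
                            neighborhoodRadius = NULL) {
    if (!isIsotropic(stack)) stack <- resampleIsotropic(stack)
    surf <- segmentLamina(stack, smoothingSigma = smoothingSigma,
                          threshold = threshold, minVolume = minVolume,
                          closingIter = closingIter, subdiv = subdiv,
                          intensityProbeDepth = intensityProbeDepth)
    if (!segmentationSuccess(surf)) {
        cond <- structure(class = c("laminaSegmentationError", "error",
                                    "condition"),
                          list(message = sprintf(
                              "cell %s excluded: %s",
                              if (nzchar(cellId)) cellId else "<unnamed>",
                              failureReason(surf)),
                              call = sys.call()))
        stop(cond)
    }
    vals <- normalizedIntensityValues(surf, stack)
    K <- gaussianCurvature(surf, neighborhoodRadius)
    # a perfectly constant distribution (noiseless synthetic shells) has no
    # asymmetry; record 0 rather than propagate the zero-variance error
    skw <- if (stats::var(vals) == 0) 0 else featureSkewness(vals)
    new("LaminaFeatures",
        intensity = featureIntensity(vals),
        skewness = skw,
        curvature = featureCurvature(surf, K),
        cellId = cellId, label = label,
        volume = meshVolume(vertices(surf), faces(surf)),
        area = meshArea(vertices(surf), faces(surf)))
}

#' Tabulate per-cell features
#'
#' @param featuresList list of \linkS4class{LaminaFeatures}.
#' @return data.frame with columns cell_id, label, intensity, skewness,
#'   curvature, volume, area.
#' @export
featureTable <- function(featuresList) {
    do.call(rbind, lapply(featuresList, function(f) data.frame(
        cell_id = f@cellId, label = f@label, intensity = f@intensity,
        skewness = f@skewness, curvature = f@curvature,
        volume = f@volume, area = f@area,
        stringsAsFactors = FALSE)))
}
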
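#' @import methods
NULL

#' ImageStack: a 3D confocal intensity grid with physical voxel spacing
#'
#' Container for a single-channel Z-stack. Voxels are stored as a numeric
#' array in (z, y, x) order; coordinates are voxel-centred and 0-based, so
#' the voxel at index (i, j, k) (1-based in R) sits at physical position
#' ((i-1), (j-1), (k-1)) * spacing nanometres.
#'
#' @slot voxels numeric 3D array (z, y, x) of non-negative intensities.
#' @slot spacing numeric length-3 vector of per-axis voxel size in nm,
#'   ordered (z, y, x).
#' @slot channelLabel free-text channel description.
#'
#' @exportClass ImageStack
setClass("ImageStack",
    representation(voxels = "array", spacing = "numeric",
                   channelLabel = "character"),
    prototype(channelLabel = ""))

setValidity("ImageStack", function(object) {
    v <- object@voxels
    s <- object@spacing
    msg <- character()
    if (length(dim(v)) != 3L)
        msg <- c(msg, "voxels must be a 3D array (z, y, x)")
    if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
        msg <- c(msg, "spacing must be three positive finite values (nm)")
    if (anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "voxel values must be finite")
    else if (any(v < 0))
        msg <- c(msg, "voxel values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' NucleusPhenotype: template parameters for a synthetic lamina shell
#'
#' Describes one population template for the nucleus simulator: an ellipsoid
#' deformed by a band-limited spherical-harmonic wrinkle field and Gaussian
#' radial blebs, carrying a lamina shell of given thickness and intensity
#' contrast, optionally with bright hotspot patches.
#'
#' @slot semiaxes ellipsoid semi-axes (a, b, c) in nm.
#' @slot wrinkleAmplitude RMS wrinkle amplitude as a fraction of the local
#'   radius; must lie in [0, 0.5).
#' @slot wrinkleDegreeMax highest spherical-harmonic degree carrying wrinkle
#'   power (degrees 2..max are populated).
#' @slot nBlebs number of Gaussian radial bump protrusions.
#' @slot hotspotFraction fraction of the shell surface covered by
#'   elevated-intensity cap patches.
#' @slot hotspotGain multiplicative intensity factor inside hotspots (>= 1).
#' @slot laminaToNucleoplasmRatio shell / interior intensity ratio (> 1).
#' @slot shellThickness lamina shell thickness in nm.
#'
#' @exportClass NucleusPhenotype
setClass("NucleusPhenotype",
    representation(semiaxes = "numeric", wrinkleAmplitude = "numeric",
                   wrinkleDegreeMax = "integer", nBlebs = "integer",
                   hotspotFraction = "numeric", hotspotGain = "numeric",
                   laminaToNucleoplasmRatio = "numeric",
                   shellThickness = "numeric"))

setValidity("NucleusPhenotype", function(object) {
    msg <- character()
    if (length(object@semiaxes) != 3L || any(object@semiaxes <= 0))
        msg <- c(msg, "semiaxes must be three positive lengths (nm)")
    if (object@wrinkleAmplitude < 0 || object@wrinkleAmplitude >= 0.5)
        msg <- c(msg, "wrinkleAmplitude must lie in [0, 0.5)")
    if (object@wrinkleDegreeMax < 2L)
        msg <- c(msg, "wrinkleDegreeMax must be >= 2")
    if (object@nBlebs < 0L) msg <- c(msg, "nBlebs must be >= 0")
    if (object@hotspotFraction < 0 || object@hotspotFraction > 0.5)
        msg <- c(msg, "hotspotFraction must lie in [0, 0.5]")
    if (object@hotspotGain < 1) msg <- c(msg, "hotspotGain must be >= 1")
    if (object@laminaToNucleoplasmRatio <= 1)
        msg <- c(msg, "laminaToNucleoplasmRatio must exceed 1")
    if (object@shellThickness <= 0)
        msg <- c(msg, "shellThickness must be positive (nm)")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: analytic description of a simulated nuclear surface
#'
#' A star-shaped closed surface given as a radial function over unit
#' directions, with an analytic (or finite-difference) Gaussian curvature
#' field and the population label it was generated under.
#'
#' @slot radialFun function taking an n x 3 matrix of unit directions and
#'   returning the surface radius (nm) along each.
#' @slot curvatureFun function taking an n x 3 matrix of unit directions and
#'   returning Gaussian curvature (nm^-2) at the surface point along each.
#' @slot label population name.
#' @slot enclosedVolume enclosed volume in nm^3.
#' @slot phenotype the generating \linkS4class{NucleusPhenotype}.
#' @slot seed integer seed the surface was drawn with.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(radialFun = "function", curvatureFun = "function",
                   label = "character", enclosedVolume = "numeric",
                   phenotype = "NucleusPhenotype", seed = "integer"))

setValidity("GroundTruth", function(object) {
    if (length(object@enclosedVolume) != 1L || object@enclosedVolume <= 0)
        "enclosedVolume must be a single positive number (nm^3)" else TRUE
})

#' LaminaSurface: segmented lamina as a closed triangulated shell
#'
#' Result of lamina segmentation. On success the mesh is a closed,
#' consistently oriented 2-manifold of genus 0 tracing the outer boundary of
#' the filled nucleus mask, with raw image intensities sampled at the
#' vertices. On failure `success` is FALSE and `failureReason` says why; the
#' mesh slots may then be empty.
#'
#' @slot vertices n x 3 matrix of vertex positions (nm, axes ordered z, y, x).
#' @slot faces m x 3 integer matrix of triangle vertex indices (1-based),
#'   consistently oriented outwards.
#' @slot vertexIntensity raw (pre-smoothing) intensity interpolated at each
#'   vertex.
#' @slot nucleusMask logical 3D array: filled nucleus (shell + interior).
#' @slot spacing voxel spacing (nm) of the stack the mask refers to.
#' @slot success logical segmentation flag.
#' @slot failureReason empty string on success, else a short reason.
#'
#' @exportClass LaminaSurface
setClass("LaminaSurface",
    representation(vertices = "matrix", faces = "matrix",
                   vertexIntensity = "numeric", nucleusMask = "array",
                   spacing = "numeric", success = "logical",
                   failureReason = "character"))

setValidity("LaminaSurface", function(object) {
    msg <- character()
    if (object@success) {
        if (nrow(object@vertices) < 4L)
            msg <- c(msg, "successful surface needs >= 4 vertices")
        if (length(object@vertexIntensity) != nrow(object@vertices))
            msg <- c(msg, "vertexIntensity length must equal vertex count")
        if (ncol(object@faces) != 3L)
            msg <- c(msg, "faces must have 3 columns")
    }
    if (length(msg)) msg else TRUE
})

#' LaminaFeatures: the three per-cell lamina shape descriptors
#'
#' Holds the mean normalized intensity, the skewness of the normalized
#' intensity distribution, and the normalized average absolute Gaussian
#' curvature for one cell, together with bookkeeping fields.
#'
#' @slot intensity dimensionless mean normalized intensity over the shell.
#' @slot skewness dimensionless sample skewness (g1) of the normalized
#'   intensities.
#' @slot curvature dimensionless normalized average absolute Gaussian
#'   curvature (1 for a perfect sphere).
#' @slot cellId cell identifier.
#' @slot label population label, or "" if unknown.
#' @slot volume enclosed mesh volume (nm^3).
#' @slot area mesh surface area (nm^2).
#'
#' @exportClass LaminaFeatures
setClass("LaminaFeatures",
    representation(intensity = "numeric", skewness = "numeric",
                   curvature = "numeric", cellId = "character",
                   label = "character", volume = "numeric", area = "numeric"),
    prototype(label = "", volume = NA_real_, area = NA_real_))

setValidity("LaminaFeatures", function(object) {
    msg <- character()
    for (nm in c("intensity", "skewness", "curvature"))
        if (!is.finite(slot(object, nm)))
            msg <- c(msg, sprintf("%s must be finite", nm))
    if (is.finite(object@curvature) && object@curvature < 0)
        msg <- c(msg, "curvature must be >= 0")
    if (length(msg)) msg else TRUE
})

#' PopulationDataset: labeled per-cell features for classification
#'
#' A labeled collection of per-cell descriptors restricted to a chosen
#' feature subset. Requires at least two distinct labels with at least three
#' cells each and no missing values.
#'
#' @slot features data.frame with columns cell_id, label and one column per
#'   feature in `featureSubset`.
#' @slot featureSubset character subset of
#'   c("intensity", "skewness", "curvature").
#'
#' @exportClass PopulationDataset
setClass("PopulationDataset",
    representation(features = "data.frame", featureSubset = "character"))

setValidity("PopulationDataset", function(object) {
    msg <- character()
    fs <- object@featureSubset
    if (length(fs) < 1L ||
        !all(fs %in% c("intensity", "skewness", "curvature")))
        msg <- c(msg, paste("featureSubset must be a nonempty subset of",
                            "intensity/skewness/curvature"))
    df <- object@features
    if (!all(c("label", fs) %in% names(df)))
        msg <- c(msg, "features must contain 'label' and the subset columns")
    else {
        tab <- table(df$label)
        if (length(tab) < 2L)
            msg <- c(msg, "need >= 2 distinct labels")
        if (any(tab < 3L))
            msg <- c(msg, "need >= 3 cells per label")
        if (anyNA(df[fs]))
            msg <- c(msg, "feature values must not be missing")
    }
    if (length(msg)) msg else TRUE
})

#' ClassificationResult: LOO cross-validated linear classification summary
#'
#' @slot errorRate leave-one-out misclassification fraction in [0, 1].
#' @slot errorSD binomial standard deviation of the error rate.
#' @slot pValue permutation p-value (NA until computed).
#' @slot nCells number of cells tested.
#' @slot featureSubset features used.
#' @slot boundary fitted pairwise linear discriminant (as returned by
#'   \code{\link{fitLinear}}).
#' @slot confusion contingency table of true x predicted labels.
#'
#' @exportClass ClassificationResult
setClass("ClassificationResult",
    representation(errorRate = "numeric", errorSD = "numeric",
                   pValue = "numeric", nCells = "integer",
                   featureSubset = "character", boundary = "list",
                   confusion = "table"))

setValidity("ClassificationResult", function(object) {
    msg <- character()
    e <- object@errorRate
    if (e < 0 || e > 1) msg <- c(msg, "errorRate must lie in [0, 1]")
    sd_expect <- sqrt(e * (1 - e) / object@nCells)
    if (abs(object@errorSD - sd_expect) > 1e-12)
        msg <- c(msg, "errorSD must equal sqrt(e(1-e)/n)")
    if (sum(object@confusion) != object@nCells)
        msg <- c(msg, "confusion counts must sum to nCells")
    if (length(msg)) msg else TRUE
})

#' FRAPTrace: a fluorescence-recovery-after-photobleaching time series
#'
#' Per-frame intensities of the bleached region of interest, an unbleached
#' reference region (for acquisition-fading correction) and the background,
#' with the number of pre-bleach frames.
#'
#' @slot times frame times in seconds, strictly increasing.
#' @slot roi bleach-ROI mean intensity per frame (counts).
#' @slot reference unbleached reference-region intensity per frame (counts).
#' @slot background background intensity (single value or per frame, counts).
#' @slot nPre number of pre-bleach frames (>= 1).
#'
#' @exportClass FRAPTrace
setClass("FRAPTrace",
    representation(times = "numeric", roi = "numeric", reference = "numeric",
                   background = "numeric", nPre = "integer"))

setValidity("FRAPTrace", function(object) {
    msg <- character()
    n <- length(object@times)
    if (any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (length(object@roi) != n || length(object@reference) != n)
        msg <- c(msg, "roi and reference must match times in length")
    if (!length(object@background) %in% c(1L, n))
        msg <- c(msg, "background must be scalar or per-frame")
    if (object@nPre < 1L || object@nPre >= n)
        msg <- c(msg, "nPre must be in [1, length(times) - 1]")
    if (length(msg)) msg else TRUE
})

#' FRAPFit: fitted recovery parameters for one FRAP trace
#'
#' Single-exponential recovery fit \eqn{I(t) = I_0 + A (1 - e^{-t/\tau})} on
#' the post-bleach frames of a normalized trace.
#'
#' @slot tHalf recovery half-time tau * ln 2 in seconds.
#' @slot tau fitted exponential time constant (s).
#' @slot immobileFraction fraction of bleached signal that never recovers.
#' @slot mobileFraction 1 - immobileFraction.
#' @slot plateau fitted normalized plateau intensity I0 + A.
#' @slot bleachDepth first post-bleach normalized intensity.
#' @slot tHalfEmpirical model-free half-time: first crossing of the midpoint
#'   between bleach depth and the late-frame plateau.
#' @slot rss residual sum of squares of the fit.
#'
#' @exportClass FRAPFit
setClass("FRAPFit",
    representation(tHalf = "numeric", tau = "numeric",
                   immobileFraction = "numeric", mobileFraction = "numeric",
                   plateau = "numeric", bleachDepth = "numeric",
                   tHalfEmpirical = "numeric", rss = "numeric"))

setValidity("FRAPFit", function(object) {
    msg <- character()
    if (is.finite(object@tHalf) && object@tHalf <= 0)
        msg <- c(msg, "tHalf must be positive")
    for (nm in c("immobileFraction", "mobileFraction")) {
        v <- slot(object, nm)
        if (is.finite(v) && (v < -1e-9 || v > 1 + 1e-9))
            msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
    }
    if (length(msg)) msg else TRUE
})
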
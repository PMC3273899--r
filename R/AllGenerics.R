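#' @include AllClasses.R
NULL

#' Access the voxel array of an ImageStack
#' @param x an \linkS4class{ImageStack}.
#' @return numeric 3D array in (z, y, x) order.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Access the voxel spacing of an object
#' @param x an \linkS4class{ImageStack} or \linkS4class{LaminaSurface}.
#' @return numeric length-3 vector (z, y, x) in nm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Is a stack sampled isotropically?
#'
#' TRUE when all three voxel spacings agree to within 0.1 percent.
#' @param x an \linkS4class{ImageStack}.
#' @return logical scalar.
#' @export
setGeneric("isIsotropic", function(x) standardGeneric("isIsotropic"))

#' Access mesh vertices
#' @param x a \linkS4class{LaminaSurface}.
#' @return n x 3 numeric matrix of positions in nm.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Access mesh faces
#' @param x a \linkS4class{LaminaSurface}.
#' @return m x 3 integer matrix of 1-based vertex indices.
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' Access per-vertex raw intensities
#' @param x a \linkS4class{LaminaSurface}.
#' @return numeric vector, one value per vertex.
#' @export
setGeneric("vertexIntensity", function(x) standardGeneric("vertexIntensity"))

#' Access the filled nucleus voxel mask
#' @param x a \linkS4class{LaminaSurface}.
#' @return logical 3D array (shell + interior).
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))

#' Did segmentation succeed?
#' @param x a \linkS4class{LaminaSurface}.
#' @return logical scalar; see \code{failureReason} for the reason when FALSE.
#' @export
setGeneric("segmentationSuccess",
           function(x) standardGeneric("segmentationSuccess"))

#' Why did segmentation fail?
#' @param x a \linkS4class{LaminaSurface}.
#' @return character reason, or "" on success.
#' @export
setGeneric("failureReason", function(x) standardGeneric("failureReason"))

setMethod("voxels", "ImageStack", function(x) x@voxels)
setMethod("spacing", "ImageStack", function(x) x@spacing)
setMethod("isIsotropic", "ImageStack", function(x) {
    s <- x@spacing
    max(s) / min(s) - 1 < 1e-3
})
setMethod("spacing", "LaminaSurface", function(x) x@spacing)
setMethod("vertices", "LaminaSurface", function(x) x@vertices)
setMethod("faces", "LaminaSurface", function(x) x@faces)
setMethod("vertexIntensity", "LaminaSurface", function(x) x@vertexIntensity)
setMethod("nucleusMask", "LaminaSurface", function(x) x@nucleusMask)
setMethod("segmentationSuccess", "LaminaSurface", function(x) x@success)
setMethod("failureReason", "LaminaSurface", function(x) x@failureReason)

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("ImageStack: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
    cat(sprintf("  spacing (nm): z=%.3g y=%.3g x=%.3g%s\n",
        object@spacing[1], object@spacing[2], object@spacing[3],
        if (isIsotropic(object)) "  [isotropic]" else ""))
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
        min(object@voxels), max(object@voxels)))
    if (nzchar(object@channelLabel))
        cat("  channel:", object@channelLabel, "\n")
})

setMethod("show", "NucleusPhenotype", function(object) {
    cat("NucleusPhenotype\n")
    cat(sprintf("  semiaxes (nm): %.0f x %.0f x %.0f, shell %.0f nm\n",
        object@semiaxes[1], object@semiaxes[2], object@semiaxes[3],
        object@shellThickness))
    cat(sprintf("  wrinkles: amplitude %.3g, degrees 2..%d; blebs: %d\n",
        object@wrinkleAmplitude, object@wrinkleDegreeMax, object@nBlebs))
    cat(sprintf("  hotspots: %.0f%% of surface, gain %.2g; shell/interior %.2g\n",
        100 * object@hotspotFraction, object@hotspotGain,
        object@laminaToNucleoplasmRatio))
})

setMethod("show", "LaminaSurface", function(object) {
    if (object@success) {
        cat(sprintf("LaminaSurface: %d vertices, %d faces [segmentation OK]\n",
            nrow(object@vertices), nrow(object@faces)))
        cat(sprintf("  enclosed volume: %.3g um^3, area: %.3g um^2\n",
            meshVolume(object@vertices, object@faces) / 1e9,
            meshArea(object@vertices, object@faces) / 1e6))
    } else {
        cat("LaminaSurface: segmentation FAILED:", object@failureReason, "\n")
    }
})

setMethod("show", "LaminaFeatures", function(object) {
    cat(sprintf("LaminaFeatures [%s%s]\n", object@cellId,
        if (nzchar(object@label)) paste0(", ", object@label) else ""))
    cat(sprintf("  intensity=%.4g  skewness=%.4g  curvature=%.4g\n",
        object@intensity, object@skewness, object@curvature))
})

setMethod("show", "PopulationDataset", function(object) {
    tab <- table(object@features$label)
    cat(sprintf("PopulationDataset: %d cells, features {%s}\n",
        nrow(object@features), paste(object@featureSubset, collapse = ", ")))
    for (l in names(tab)) cat(sprintf("  %s: %d cells\n", l, tab[[l]]))
})

setMethod("show", "ClassificationResult", function(object) {
    cat(sprintf(
        "ClassificationResult: LOO error %.1f%% +/- %.1f%% (N = %d)\n",
        100 * object@errorRate, 100 * object@errorSD, object@nCells))
    if (is.finite(object@pValue))
        cat(sprintf("  permutation p = %.4g\n", object@pValue))
    cat("  features:", paste(object@featureSubset, collapse = ", "), "\n")
    print(object@confusion)
})

setMethod("show", "FRAPTrace", function(object) {
    cat(sprintf("FRAPTrace: %d frames (%d pre-bleach), t = %.3g..%.3g s\n",
        length(object@times), object@nPre, min(object@times),
        max(object@times)))
})

setMethod("show", "FRAPFit", function(object) {
    cat(sprintf(
        "FRAPFit: T/2 = %.3g s (tau = %.3g s), immobile = %.3g, plateau = %.3g\n",
        object@tHalf, object@tau, object@immobileFraction, object@plateau))
})
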
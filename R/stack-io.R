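#' Read a single-channel Z-stack from TIFF / OME-TIFF
#'
#' Planes are stacked into a (z, y, x) array. Voxel spacing is resolved, in
#' order of precedence, from an explicit \code{spacingOverride}, a sidecar
#' JSON written by \code{\link{writeStack}} (\code{<path>.json}), or OME-XML
#' \code{PhysicalSizeZ/Y/X} attributes found in the TIFF ImageDescription
#' (interpreted in micrometres and converted to nm, the OME default unit).
#' If none is available the read fails: downstream geometry is meaningless
#' without a physical scale.
#'
#' @param path TIFF or OME-TIFF file with one channel.
#' @param spacingOverride optional per-axis spacing (z, y, x) in nm.
#' @param channel channel index to extract when planes carry multiple
#'   samples per pixel; reading a multi-channel file without one is an
#'   error.
#' @return an \linkS4class{ImageStack}.
#' @seealso \code{\link{writeStack}}, \code{\link{resampleIsotropic}}
#' @export
readStack <- function(path, spacingOverride = NULL, channel = NULL) {
    .stopIfNot(file.exists(path), sprintf("file not found: %s", path))
    planes <- tiff::readTIFF(path, all = TRUE, info = TRUE,
                             as.is = FALSE)
    if (!is.list(planes)) planes <- list(planes)
    if (length(dim(planes[[1]])) > 2L) {
        if (is.null(channel))
            stop("multi-channel TIFF without a channel selector",
                 call. = FALSE)
        planes <- lapply(planes, function(p) p[, , channel])
    }
    d <- dim(planes[[1]])
    vox <- array(0, c(length(planes), d[1], d[2]))
    for (k in seq_along(planes)) vox[k, , ] <- planes[[k]]
    scale <- 1
    sidecar <- paste0(path, ".json")
    meta <- NULL
    if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    }
    vox <- vox * scale
    spc <- spacingOverride
    if (is.null(spc) && !is.null(meta$spacing_nm))
        spc <- as.numeric(meta$spacing_nm)
    if (is.null(spc)) {
        desc <- attr(planes[[1]], "description")
        if (!is.null(desc) && nzchar(desc))
            spc <- .parseOmeSpacing(desc)
    }
    if (is.null(spc))
        stop("spacing unresolved: no override, sidecar or OME metadata",
             call. = FALSE)
    if (length(spc) == 1L) spc <- rep(spc, 3L)
    lab <- if (!is.null(meta$channel_label)) meta$channel_label else ""
    imageStack(vox, spc, channelLabel = lab)
}

# Extract (z, y, x) spacing in nm from an OME-XML ImageDescription string.
# Returns NULL when no PhysicalSize attributes are present.
.parseOmeSpacing <- function(description) {
    doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
    if (is.null(doc)) return(NULL)
    px <- xml2::xml_find_first(doc, "//*[local-name() = 'Pixels']")
    if (inherits(px, "xml_missing")) return(NULL)
    get1 <- function(att, unitAtt) {
        v <- xml2::xml_attr(px, att)
        if (is.na(v)) return(NA_real_)
        v <- as.numeric(v)
        unit <- xml2::xml_attr(px, unitAtt)
        mult <- switch(ifelse(is.na(unit), "µm", unit),
                       "nm" = 1, "µm" = 1e3, "um" = 1e3, "mm" = 1e6,
                       1e3)
        v * mult
    }
    spc <- c(get1("PhysicalSizeZ", "PhysicalSizeZUnit"),
             get1("PhysicalSizeY", "PhysicalSizeYUnit"),
             get1("PhysicalSizeX", "PhysicalSizeXUnit"))
    if (all(is.na(spc))) return(NULL)
    # fall back to the lateral value for a missing axis, as OME writers
    # sometimes omit PhysicalSizeZ for single-plane data
    if (anyNA(spc)) spc[is.na(spc)] <- stats::median(spc, na.rm = TRUE)
    spc
}

#' Write an ImageStack as a multi-plane 32-bit TIFF with a metadata sidecar
#'
#' Intensities are rescaled into [0, 1] for storage (the TIFF writer's
#' representable range) and the scale factor, voxel spacing and channel
#' label are recorded in \code{<path>.json}, which \code{\link{readStack}}
#' uses to restore the stack exactly.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return invisibly, the path.
#' @export
writeStack <- function(stack, path) {
    vox <- voxels(stack)
    scale <- max(vox, 1e-300)
    planes <- lapply(seq_len(dim(vox)[1]),
                     function(k) vox[k, , ] / scale)
    suppressWarnings(
        tiff::writeTIFF(planes, path, bits.per.sample = 32L,
                        compression = "none"))
    jsonlite::write_json(
        list(spacing_nm = spacing(stack), intensity_scale = scale,
             channel_label = stack@channelLabel),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

# Dense interpolation matrix mapping samples at `xin` to natural cubic
# spline values at `xout` (spline interpolation is linear in the data).
.splineMatrix <- function(xin, xout) {
    n <- length(xin)
    W <- matrix(0, length(xout), n)
    basis <- diag(n)
    for (i in seq_len(n))
        W[, i] <- stats::spline(xin, basis[, i], xout = xout,
                                method = "natural")$y
    W
}

#' Resample an anisotropic stack onto an isotropic grid
#'
#' Each axis whose spacing differs from the target is resampled with a
#' natural cubic spline (applied separably), preserving the physical extent
#' to within one voxel. Interpolated values are clipped at zero because
#' intensities are physical counts. The number of output samples per axis is
#' \code{round(n * spacing / target)}.
#'
#' @param stack an \linkS4class{ImageStack} with at least 4 voxels per axis.
#' @param targetNm isotropic target spacing in nm; defaults to the smallest
#'   input spacing so the better-sampled lateral axes are never degraded.
#' @return an isotropic \linkS4class{ImageStack}.
#' @examples
#' s <- imageStack(array(runif(8 * 16 * 16), c(8, 16, 16)),
#'                 spacing = c(122, 50, 50))
#' iso <- resampleIsotropic(s)
#' spacing(iso)
#' @export
resampleIsotropic <- function(stack, targetNm = NULL) {
    d <- dim(voxels(stack))
    .stopIfNot(all(d >= 4L), "degenerate stack: every axis needs >= 4 voxels")
    spc <- spacing(stack)
    if (is.null(targetNm)) targetNm <- min(spc)
    .stopIfNot(targetNm > 0, "targetNm must be positive")
    out <- voxels(stack)
    for (ax in 1:3) {
        if (abs(spc[ax] / targetNm - 1) < 1e-9) next
        n_in <- dim(out)[ax]
        n_out <- max(4L, as.integer(round(n_in * spc[ax] / targetNm)))
        xin <- (seq_len(n_in) - 1) * spc[ax]
        xout <- (seq_len(n_out) - 1) * targetNm
        W <- .splineMatrix(xin, xout)
        perm <- c(ax, setdiff(1:3, ax))
        m <- matrix(aperm(out, perm), nrow = n_in)
        res <- W %*% m
        dn <- dim(out)[perm]
        dn[1] <- n_out
        out <- aperm(array(res, dn), order(perm))
    }
    out[out < 0] <- 0
    imageStack(out, rep(targetNm, 3L), channelLabel = stack@channelLabel)
}
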
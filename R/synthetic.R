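#' Construct a NucleusPhenotype
#'
#' Parameter record for one population template of the nucleus simulator.
#' See \linkS4class{NucleusPhenotype} for slot meanings and constraints.
#'
#' @param semiaxes ellipsoid semi-axes (a, b, c) in nm, along the physical
#'   x, y and z axes respectively.
#' @param wrinkleAmplitude RMS relative amplitude of the spherical-harmonic
#'   wrinkle field, in [0, 0.5).
#' @param wrinkleDegreeMax highest harmonic degree carrying wrinkle power.
#' @param nBlebs number of Gaussian radial protrusions.
#' @param hotspotFraction fraction of shell surface with elevated intensity.
#' @param hotspotGain multiplicative intensity gain inside hotspots.
#' @param laminaToNucleoplasmRatio shell / interior intensity ratio.
#' @param shellThickness lamina shell thickness in nm.
#' @return a \linkS4class{NucleusPhenotype}.
#' @export
nucleusPhenotype <- function(semiaxes = c(2000, 1700, 1400),
                             wrinkleAmplitude = 0.01,
                             wrinkleDegreeMax = 6L,
                             nBlebs = 0L,
                             hotspotFraction = 0,
                             hotspotGain = 1,
                             laminaToNucleoplasmRatio = 4.5,
                             shellThickness = 250) {
    new("NucleusPhenotype", semiaxes = as.numeric(semiaxes),
        wrinkleAmplitude = wrinkleAmplitude,
        wrinkleDegreeMax = as.integer(wrinkleDegreeMax),
        nBlebs = as.integer(nBlebs), hotspotFraction = hotspotFraction,
        hotspotGain = hotspotGain,
        laminaToNucleoplasmRatio = laminaToNucleoplasmRatio,
        shellThickness = shellThickness)
}

#' Built-in population templates
#'
#' Three phenotype templates emulating the qualitative lamina morphologies
#' of the cell states the method is designed to separate: "fresh" cells with
#' a smooth elliptical shell and strong shell/nucleoplasm contrast;
#' "senescent" cells with moderate wrinkling, coherent bright hotspot
#' patches and lamin redistributed into the nucleoplasm (lower shell
#' contrast, hence lower mean normalized intensity); and "apoptotic" cells
#' with strong folding and bleb protrusions (elevated curvature).
#'
#' @return named list of \linkS4class{NucleusPhenotype} objects with entries
#'   \code{fresh}, \code{senescent} and \code{apoptotic}.
#' @examples
#' phenotypeTemplates()$senescent
#' @export
phenotypeTemplates <- function() {
    list(
        fresh = nucleusPhenotype(
            semiaxes = c(2000, 1700, 1400), wrinkleAmplitude = 0.01,
            wrinkleDegreeMax = 6L, nBlebs = 0L, hotspotFraction = 0,
            hotspotGain = 1, laminaToNucleoplasmRatio = 4.5,
            shellThickness = 250),
        senescent = nucleusPhenotype(
            semiaxes = c(1900, 1700, 1450), wrinkleAmplitude = 0.08,
            wrinkleDegreeMax = 8L, nBlebs = 0L, hotspotFraction = 0.2,
            hotspotGain = 2, laminaToNucleoplasmRatio = 2.5,
            shellThickness = 250),
        apoptotic = nucleusPhenotype(
            semiaxes = c(1800, 1650, 1500), wrinkleAmplitude = 0.16,
            wrinkleDegreeMax = 10L, nBlebs = 4L, hotspotFraction = 0.1,
            hotspotGain = 1.5, laminaToNucleoplasmRatio = 2.8,
            shellThickness = 250))
}

# Ellipsoid radius along unit directions (n x 3, axes z, y, x): the radial
# distance at which the ray hits the ellipsoid with semi-axes (a, b, c)
# along (x, y, z).
.ellipsoidRadius <- function(dirs, semiaxes) {
    1 / sqrt((dirs[, 3] / semiaxes[1])^2 + (dirs[, 2] / semiaxes[2])^2 +
             (dirs[, 1] / semiaxes[3])^2)
}

# Closed-form Gaussian curvature of an ellipsoid at surface points reached
# along unit directions.
.ellipsoidCurvature <- function(dirs, semiaxes) {
    a <- semiaxes[1]; b <- semiaxes[2]; c_ <- semiaxes[3]
    r <- .ellipsoidRadius(dirs, semiaxes)
    x <- r * dirs[, 3]; y <- r * dirs[, 2]; z <- r * dirs[, 1]
    1 / (a^2 * b^2 * c_^2 * (x^2 / a^4 + y^2 / b^4 + z^2 / c_^4)^2)
}

# Gaussian bleb constants: bump height relative to local radius and angular
# width (rad). Fixed characteristics; the per-cell count comes from the
# phenotype.
.BLEB_HEIGHT <- 0.15
.BLEB_WIDTH <- 0.3

#' Draw a ground-truth nuclear surface from a phenotype
#'
#' Builds the star-shaped radial surface r(u) = ellipsoid(u) * (1 + wrinkle
#' field + bleb bumps). The wrinkle field is a random real
#' spherical-harmonic field with equal expected power per degree over
#' degrees 2..\code{wrinkleDegreeMax}, normalized to unit RMS over the
#' sphere and scaled by \code{wrinkleAmplitude}. Blebs are Gaussian radial
#' bumps at random directions. The attached Gaussian-curvature field is the
#' ellipsoid closed form when the surface is unperturbed and a
#' finite-difference evaluation on the parametric surface otherwise.
#'
#' @param phenotype a \linkS4class{NucleusPhenotype}.
#' @param seed integer seed; the surface is deterministic given it.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' gt <- makeSurface(phenotypeTemplates()$fresh, seed = 1)
#' gt@enclosedVolume / 1e9  # um^3
#' @export
makeSurface <- function(phenotype, seed) {
    validObject(phenotype)
    amp <- phenotype@wrinkleAmplitude
    lmax <- phenotype@wrinkleDegreeMax
    semi <- phenotype@semiaxes
    nb <- phenotype@nBlebs
    coef <- NULL
    rmsNorm <- 1
    blebDirs <- NULL
    .withSeed(seed, {
        if (amp > 0) {
            nm_per_l <- 2L * (2:lmax) + 1L
            coef <- stats::rnorm(sum(nm_per_l)) *
                rep(1 / sqrt(nm_per_l), nm_per_l)
        }
        if (nb > 0L) blebDirs <- .randomDirections(nb)
    })
    perturb <- function(dirs) {
        w <- numeric(nrow(dirs))
        if (!is.null(coef))
            w <- w + amp * drop(
                .sphericalHarmonicsBasis(dirs, 2L, lmax) %*% coef) / rmsNorm
        if (!is.null(blebDirs)) {
            for (i in seq_len(nrow(blebDirs))) {
                cosang <- pmin(pmax(dirs %*% blebDirs[i, ], -1), 1)
                ang <- acos(drop(cosang))
                w <- w + .BLEB_HEIGHT * exp(-0.5 * (ang / .BLEB_WIDTH)^2)
            }
        }
        w
    }
    quad <- icosphere(3L)$vertices
    if (!is.null(coef)) {
        raw <- drop(.sphericalHarmonicsBasis(quad, 2L, lmax) %*% coef)
        rmsNorm <- sqrt(mean(raw^2))
    }
    radialFun <- function(dirs) {
        .ellipsoidRadius(dirs, semi) * (1 + perturb(dirs))
    }
    relief <- 1 + perturb(quad)
    if (min(relief) < 0.1)
        stop("phenotype rejected: perturbation amplitude produces a ",
             "self-intersecting surface", call. = FALSE)
    unperturbed <- amp == 0 && nb == 0L
    curvatureFun <- if (unperturbed) {
        function(dirs) .ellipsoidCurvature(dirs, semi)
    } else {
        function(dirs) .parametricCurvature(radialFun, dirs)
    }
    mesh <- icosphere(4L)
    vol <- meshVolume(mesh$vertices * radialFun(mesh$vertices), mesh$faces)
    new("GroundTruth", radialFun = radialFun, curvatureFun = curvatureFun,
        label = "", enclosedVolume = vol, phenotype = phenotype,
        seed = as.integer(seed))
}

# Finite-difference Gaussian curvature of a star-shaped surface p(u) =
# r(u) u. The surface is parameterized locally at each direction by the
# tangent plane (s, t) -> normalize(u + s e1 + t e2); first and second
# fundamental forms come from a 9-point central-difference stencil.
.parametricCurvature <- function(radialFun, dirs, h = 1e-3) {
    n <- nrow(dirs)
    tb <- .tangentBasis(dirs)
    pt <- function(s, t) {
        d <- dirs + s * tb$e1 + t * tb$e2
        d <- d / sqrt(rowSums(d^2))
        d * radialFun(d)
    }
    p00 <- pt(0, 0)
    pp0 <- pt(h, 0); pm0 <- pt(-h, 0)
    p0p <- pt(0, h); p0m <- pt(0, -h)
    ppp <- pt(h, h); ppm <- pt(h, -h)
    pmp <- pt(-h, h); pmm <- pt(-h, -h)
    ps <- (pp0 - pm0) / (2 * h)
    pt_ <- (p0p - p0m) / (2 * h)
    pss <- (pp0 - 2 * p00 + pm0) / h^2
    ptt <- (p0p - 2 * p00 + p0m) / h^2
    pst <- (ppp - ppm - pmp + pmm) / (4 * h^2)
    nrm <- cbind(ps[, 2] * pt_[, 3] - ps[, 3] * pt_[, 2],
                 ps[, 3] * pt_[, 1] - ps[, 1] * pt_[, 3],
                 ps[, 1] * pt_[, 2] - ps[, 2] * pt_[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    E <- rowSums(ps * ps); Fq <- rowSums(ps * pt_); G <- rowSums(pt_ * pt_)
    L <- rowSums(pss * nrm); M <- rowSums(pst * nrm); N <- rowSums(ptt * nrm)
    (L * N - M^2) / (E * G - Fq^2)
}

#' Mesh a ground-truth surface at a chosen resolution
#'
#' Evaluates the analytic radial surface on geodesic-sphere directions,
#' returning a closed oriented triangle mesh plus the analytic Gaussian
#' curvature at each vertex. Used to validate the mesh-based curvature
#' estimator against ground truth.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param subdiv icosphere subdivision level (4 gives 2562 vertices, 5 gives
#'   10242).
#' @return list with \code{vertices} (nm), \code{faces}, and
#'   \code{curvature} (analytic K per vertex, nm^-2).
#' @export
truthMesh <- function(truth, subdiv = 5L) {
    ico <- icosphere(subdiv)
    r <- truth@radialFun(ico$vertices)
    list(vertices = ico$vertices * r, faces = ico$faces,
         curvature = truth@curvatureFun(ico$vertices))
}

# Tabulate a radial function over a (theta, phi) grid. theta is the polar
# angle from the physical z axis, phi the azimuth in the (x, y) plane;
# directions are in the package's (z, y, x) component order.
.radialTable <- function(radialFun, nTheta = 257L, nPhi = 513L) {
    theta <- seq(0, pi, length.out = nTheta)
    phi <- seq(-pi, pi, length.out = nPhi)
    g <- expand.grid(theta = theta, phi = phi)
    dirs <- cbind(cos(g$theta), sin(g$theta) * sin(g$phi),
                  sin(g$theta) * cos(g$phi))
    r <- matrix(radialFun(dirs), nTheta, nPhi)
    list(theta = theta, phi = phi, r = r, dirs = dirs)
}

# Bilinear lookup of a tabulated radial function at unit directions.
.radialLookup <- function(rtab, dirs) {
    nTheta <- length(rtab$theta)
    nPhi <- length(rtab$phi)
    th <- acos(pmin(pmax(dirs[, 1], -1), 1))
    ph <- atan2(dirs[, 2], dirs[, 3])
    ft <- th / pi * (nTheta - 1)
    fp <- (ph + pi) / (2 * pi) * (nPhi - 1)
    i0 <- pmin(floor(ft), nTheta - 2); wt <- ft - i0
    j0 <- pmin(floor(fp), nPhi - 2); wp <- fp - j0
    at <- function(di, dj) rtab$r[cbind(i0 + di + 1, j0 + dj + 1)]
    (1 - wt) * ((1 - wp) * at(0, 0) + wp * at(0, 1)) +
        wt * ((1 - wp) * at(1, 0) + wp * at(1, 1))
}

# Spherical-cap hotspot centres and the common cap half-angle giving the
# requested total surface fraction split over `nCaps` caps. Centres are
# re-drawn (up to 60 tries) to keep caps disjoint when possible.
.hotspotCaps <- function(fraction, nCaps = 3L, seed = 0L) {
    if (fraction <= 0) return(NULL)
    capFrac <- fraction / nCaps
    alpha <- acos(1 - 2 * capFrac)
    centres <- .withSeed(seed, {
        ok <- FALSE
        cs <- NULL
        for (try in 1:60) {
            cs <- .randomDirections(nCaps)
            if (nCaps == 1L) { ok <- TRUE; break }
            dmin <- min(acos(pmin(pmax(
                tcrossprod(cs)[upper.tri(diag(nCaps))], -1), 1)))
            if (dmin > 2 * alpha) { ok <- TRUE; break }
        }
        cs
    })
    list(centres = centres, alpha = alpha)
}

#' Rasterize a ground-truth nucleus into a noiseless image stack
#'
#' Paints shell voxels (radial distance within \code{shellThickness} below
#' the surface) at the lamina intensity, applying the hotspot gain inside
#' spherical-cap patches, the interior at the nucleoplasm intensity and the
#' exterior at zero. The grid is sized to hold the surface plus a border
#' margin for later blurring.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param spacing per-axis voxel size in nm (scalar for isotropic; default
#'   50 nm isotropic).
#' @param interiorIntensity nucleoplasm intensity in counts; the shell gets
#'   \code{interiorIntensity * laminaToNucleoplasmRatio}.
#' @param marginVox border margin in voxels around the surface bound.
#' @return a noiseless \linkS4class{ImageStack}.
#' @export
rasterizeNucleus <- function(truth, spacing = 50,
                             interiorIntensity = 100, marginVox = 8L) {
    ph <- truth@phenotype
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    .stopIfNot(ph@shellThickness >= 2 * max(spacing),
               "shell thinner than sampling: need thickness >= 2 * spacing")
    # tabulate the radial surface on a fine (theta, phi) grid once; the
    # surface is band-limited (spherical-harmonic degrees <= ~10), so
    # bilinear interpolation of the table is accurate to ~1 nm and far
    # cheaper than evaluating the harmonic series at every voxel
    rtab <- .radialTable(truth@radialFun)
    relief <- range(rtab$r / .ellipsoidRadius(rtab$dirs, ph@semiaxes))
    reliefHi <- relief[2] + 0.02
    reliefLo <- relief[1] - 0.02
    rmax <- max(ph@semiaxes) * reliefHi
    dims <- as.integer(2 * ceiling(rmax / spacing) + 2L * marginVox + 1L)
    ctr <- (dims - 1) / 2 * spacing       # nm, (z, y, x)
    zc <- (seq_len(dims[1]) - 1) * spacing[1] - ctr[1]
    yc <- (seq_len(dims[2]) - 1) * spacing[2] - ctr[2]
    xc <- (seq_len(dims[3]) - 1) * spacing[3] - ctr[3]
    nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
    pz <- rep(zc, times = ny * nx)
    py <- rep(rep(yc, each = nz), times = nx)
    px <- rep(xc, each = nz * ny)
    rho <- sqrt(pz^2 + py^2 + px^2)
    rho[rho == 0] <- 1e-9
    dirs <- cbind(pz, py, px) / rho
    re <- .ellipsoidRadius(dirs, ph@semiaxes)
    t <- ph@shellThickness
    lo <- re * reliefLo - t
    hi <- re * reliefHi
    vox <- numeric(nz * ny * nx)
    vox[rho <= lo] <- interiorIntensity
    band <- which(rho > lo & rho <= hi)
    if (length(band)) {
        r <- .radialLookup(rtab, dirs[band, , drop = FALSE])
        shellI <- interiorIntensity * ph@laminaToNucleoplasmRatio
        val <- numeric(length(band))
        val[rho[band] <= r - t] <- interiorIntensity
        inShell <- rho[band] > r - t & rho[band] <= r
        val[inShell] <- shellI
        caps <- .hotspotCaps(ph@hotspotFraction,
                             seed = truth@seed + 7919L)
        if (!is.null(caps)) {
            hot <- rep(FALSE, length(band))
            for (i in seq_len(nrow(caps$centres))) {
                ca <- drop(dirs[band, , drop = FALSE] %*% caps$centres[i, ])
                hot <- hot | (ca > cos(caps$alpha))
            }
            val[inShell & hot] <- shellI * ph@hotspotGain
        }
        vox[band] <- val
    }
    imageStack(array(vox, dims), spacing,
               channelLabel = "synthetic lamina")
}

#' Apply a confocal-style imaging model to a noiseless stack
#'
#' Gaussian blur with per-axis sigma (larger axially mimics the elongated
#' confocal point-spread function), followed by a Poisson photon draw at
#' \code{photonScale} detected counts per intensity unit, Gaussian read
#' noise, and a constant background offset. Negative values are clipped at
#' zero. With \code{psfSigma = 0}, \code{photonScale = Inf},
#' \code{readNoiseSd = 0} and \code{background = 0} the stack is returned
#' unchanged.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param psfSigma per-axis Gaussian sigma in nm (z, y, x); scalar recycled.
#' @param photonScale detected photons per intensity unit; the Poisson draw
#'   is \code{rpois(v * photonScale) / photonScale} so the mean is preserved
#'   and the variance is v / photonScale. \code{Inf} disables shot noise.
#' @param readNoiseSd Gaussian read-noise standard deviation (counts).
#' @param background constant background offset (counts).
#' @param seed integer seed; output is deterministic given it.
#' @return an \linkS4class{ImageStack}.
#' @export
applyMicroscope <- function(stack, psfSigma = c(250, 120, 120),
                            photonScale = 1, readNoiseSd = 0,
                            background = 0, seed = 1) {
    .stopIfNot(all(psfSigma >= 0), "psfSigma must be >= 0")
    .stopIfNot(photonScale > 0, "photonScale must be positive")
    if (length(psfSigma) == 1L) psfSigma <- rep(psfSigma, 3L)
    v <- voxels(stack)
    if (any(psfSigma > 0))
        v <- .gaussianSmooth3(v, psfSigma / spacing(stack))
    .withSeed(seed, {
        if (is.finite(photonScale))
            v <- array(stats::rpois(length(v), pmax(v, 0) * photonScale) /
                       photonScale, dim(v))
        if (readNoiseSd > 0)
            v <- v + array(stats::rnorm(length(v), 0, readNoiseSd), dim(v))
    })
    v <- v + background
    v[v < 0] <- 0
    imageStack(v, spacing(stack), channelLabel = stack@channelLabel)
}

# Jitter one phenotype multiplicatively (lognormal with relative sd) while
# respecting slot constraints.
.jitterPhenotype <- function(ph, jitter) {
    if (jitter <= 0) return(ph)
    j <- function(x) x * exp(stats::rnorm(length(x), 0, jitter))
    nucleusPhenotype(
        semiaxes = j(ph@semiaxes),
        wrinkleAmplitude = min(j(ph@wrinkleAmplitude), 0.45),
        wrinkleDegreeMax = ph@wrinkleDegreeMax,
        nBlebs = ph@nBlebs,
        hotspotFraction = min(j(ph@hotspotFraction), 0.5),
        hotspotGain = 1 + j(ph@hotspotGain - 1),
        laminaToNucleoplasmRatio = max(1.05, j(ph@laminaToNucleoplasmRatio)),
        shellThickness = j(ph@shellThickness))
}

#' Analytic summary of a ground-truth surface
#'
#' Quadrature summary of the generating surface: enclosed volume, surface
#' area and mean absolute Gaussian curvature, plus the phenotype
#' parameters, label and seed. Suitable for writing as a JSON sidecar next
#' to a simulated stack.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param subdiv icosphere subdivision for the quadrature mesh.
#' @return a named list (JSON-ready).
#' @export
truthSummary <- function(truth, subdiv = 4L) {
    m <- truthMesh(truth, subdiv)
    a <- .vertexAreas(m$vertices, m$faces)
    ph <- truth@phenotype
    list(label = truth@label, seed = truth@seed,
         volume_nm3 = truth@enclosedVolume,
         area_nm2 = meshArea(m$vertices, m$faces),
         mean_abs_gaussian_curvature_nm_2 =
             sum(abs(m$curvature) * a) / sum(a),
         phenotype = list(
             semiaxes_nm = ph@semiaxes,
             wrinkle_amplitude = ph@wrinkleAmplitude,
             wrinkle_degree_max = ph@wrinkleDegreeMax,
             n_blebs = ph@nBlebs,
             hotspot_fraction = ph@hotspotFraction,
             hotspot_gain = ph@hotspotGain,
             lamina_to_nucleoplasm_ratio = ph@laminaToNucleoplasmRatio,
             shell_thickness_nm = ph@shellThickness))
}

#' Simulate a labeled population of nucleus image stacks
#'
#' For each label, draws \code{nPerLabel} cells around the template
#' phenotype (parameters jittered with relative standard deviation
#' \code{jitter}), builds the ground-truth surface, rasterizes it and
#' applies the imaging model. Fully reproducible for a fixed seed.
#'
#' @param phenotypes named list of \linkS4class{NucleusPhenotype} templates
#'   (the names are the population labels); defaults to
#'   \code{\link{phenotypeTemplates}()}.
#' @param nPerLabel cells per label.
#' @param jitter relative standard deviation of phenotype parameters across
#'   cells.
#' @param seed integer master seed.
#' @param spacing voxel size passed to \code{\link{rasterizeNucleus}}.
#' @param microscope named list of \code{\link{applyMicroscope}} arguments
#'   (psfSigma, photonScale, readNoiseSd, background), or NULL for
#'   noiseless stacks.
#' @return list of cells, each a list with elements \code{stack}
#'   (\linkS4class{ImageStack}), \code{truth} (\linkS4class{GroundTruth}
#'   with the label filled in), \code{label} and \code{cellId}.
#' @export
simulatePopulation <- function(phenotypes = phenotypeTemplates(),
                               nPerLabel = 10L, jitter = 0.05, seed = 1,
                               spacing = 50,
                               microscope = list(psfSigma = c(250, 120, 120),
                                                 photonScale = 1,
                                                 readNoiseSd = 2,
                                                 background = 5)) {
    .stopIfNot(nPerLabel >= 1L, "nPerLabel must be >= 1")
    .stopIfNot(length(names(phenotypes)) == length(phenotypes),
               "phenotypes must be a named list")
    out <- list()
    cellIdx <- 0L
    for (label in names(phenotypes)) {
        for (i in seq_len(nPerLabel)) {
            cellIdx <- cellIdx + 1L
            cellSeed <- as.integer(seed) * 1000L + cellIdx
            ph <- .withSeed(cellSeed,
                            .jitterPhenotype(phenotypes[[label]], jitter))
            truth <- makeSurface(ph, seed = cellSeed)
            truth@label <- label
            stack <- rasterizeNucleus(truth, spacing = spacing)
            if (!is.null(microscope))
                stack <- do.call(applyMicroscope,
                                 c(list(stack = stack,
                                        seed = cellSeed + 500000L),
                                   microscope))
            out[[cellIdx]] <- list(stack = stack, truth = truth,
                                   label = label,
                                   cellId = sprintf("%s_%03d", label, i))
        }
    }
    out
}
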
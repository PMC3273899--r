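# A hand-built LaminaSurface over a toy mask: half the nucleus voxels at
# intensity 4c (shell), half at c (interior), shell value sampled at every
# vertex. Lets the normalization arithmetic be checked exactly.
toySurface <- function(c0 = 10) {
    vox <- array(0, c(10, 10, 10))
    mask <- array(FALSE, c(10, 10, 10))
    mask[3:6, 3:6, 3:6] <- TRUE               # 64 nucleus voxels
    sel <- which(mask)
    shell <- sel[1:32]
    vox[shell] <- 4 * c0
    vox[setdiff(sel, shell)] <- c0
    ico <- icosphere(0L)
    surf <- new("LaminaSurface", vertices = ico$vertices * 100,
                faces = ico$faces,
                vertexIntensity = rep(4 * c0, nrow(ico$vertices)),
                nucleusMask = mask, spacing = rep(50, 3),
                success = TRUE, failureReason = "")
    list(surf = surf, stack = imageStack(vox, 50))
}

test_that("intensity normalization divides by the whole-nucleus mean", {
    ts <- toySurface()
    vals <- normalizedIntensityValues(ts$surf, ts$stack)
    expect_equal(vals, rep(4 / 2.5, 12))      # 4c / ((4c + c)/2) = 1.6
})

test_that("normalized intensities are invariant to global scaling", {
    ts <- toySurface()
    v1 <- normalizedIntensityValues(ts$surf, ts$stack)
    s10 <- imageStack(voxels(ts$stack) * 10, 50)
    surf10 <- ts$surf
    surf10@vertexIntensity <- surf10@vertexIntensity * 10
    expect_equal(normalizedIntensityValues(surf10, s10), v1)
})

test_that("uniform stacks normalize to 1 and zero means error", {
    ts <- toySurface()
    uni <- imageStack(array(5, c(10, 10, 10)), 50)
    su <- ts$surf
    su@vertexIntensity <- rep(5, 12)
    expect_equal(normalizedIntensityValues(su, uni), rep(1, 12))
    zero <- imageStack(array(0, c(10, 10, 10)), 50)
    expect_error(normalizedIntensityValues(su, zero), "zero mean")
})

test_that("featureIntensity is the arithmetic mean", {
    expect_equal(featureIntensity(rep(1.6, 40)), 1.6)
    expect_equal(featureIntensity(c(1, 2, 3)), 2)
    expect_error(featureIntensity(numeric(0)), "empty")
})

test_that("skewness matches the direct moment formula", {
    g1 <- function(x) {
        m <- mean(x)
        mean((x - m)^3) / mean((x - m)^2)^1.5
    }
    expect_equal(featureSkewness(c(1, 2, 3)), 0)
    x <- c(0, 0, 0, 1)
    expect_equal(featureSkewness(x), g1(x))
    expect_equal(featureSkewness(x), 2 / sqrt(3), tolerance = 1e-12)
    y <- rlnorm(200)
    expect_equal(featureSkewness(y), g1(y))
    # invariant under positive affine transforms
    expect_equal(featureSkewness(5 * y + 2), featureSkewness(y))
    expect_error(featureSkewness(rep(1, 10)), "degenerate")
    expect_error(featureSkewness(c(1, 2)), "at least 3")
})

test_that("quadric-fit curvature matches the sphere closed form", {
    m <- sphereMeshK()
    relErr <- abs(m$K * 2000^2 - 1)
    expect_lt(median(relErr), 0.05)
})

test_that("quadric-fit curvature matches the ellipsoid closed form", {
    m <- ellipsoidMeshK()
    expect_lt(median(abs(m$K / m$curvature - 1)), 0.10)
})

test_that("developable surfaces have near-zero Gaussian curvature", {
    # open cylinder patch, radius 1000 nm
    R <- 1000
    nth <- 48; nz <- 25
    th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
    zz <- seq(0, 2400, length.out = nz)
    vid <- function(i, k) (k - 1) * nth + i
    verts <- cbind(rep(zz, each = nth), R * sin(rep(th, nz)),
                   R * cos(rep(th, nz)))
    fc <- NULL
    for (k in 1:(nz - 1)) for (i in 1:nth) {
        i2 <- if (i == nth) 1L else i + 1L
        fc <- rbind(fc, c(vid(i, k), vid(i2, k), vid(i2, k + 1)),
                    c(vid(i, k), vid(i2, k + 1), vid(i, k + 1)))
    }
    K <- gaussianCurvature(list(vertices = verts, faces = fc))
    interior <- which(rep(seq_len(nz), each = nth) %in% 8:18)
    expect_lt(max(abs(K[interior])) * R^2, 0.05)
})

test_that("curvature estimator satisfies Gauss-Bonnet on closed meshes", {
    m <- sphereMeshK()
    expect_lt(abs(gaussBonnetTotal(m$vertices, m$faces, m$K) / (4 * pi) - 1),
              0.02)
    me <- ellipsoidMeshK()
    expect_lt(abs(gaussBonnetTotal(me$vertices, me$faces, me$K) /
                  (4 * pi) - 1), 0.02)
})

test_that("curvature feature is 1 for spheres and scale-invariant", {
    m <- sphereMeshK()
    feat <- featureCurvature(m, m$K)
    expect_lt(abs(feat - 1), 0.05)
    # uniform spatial rescaling: K scales by 1/s^2, R_eq^2 by s^2
    m2 <- list(vertices = m$vertices * 2, faces = m$faces)
    expect_equal(featureCurvature(m2, m$K / 4), feat, tolerance = 1e-12)
})

test_that("curvature feature grows monotonically with wrinkle amplitude", {
    feats <- vapply(c(0.02, 0.05, 0.08), function(a) {
        gt <- makeSurface(nucleusPhenotype(wrinkleAmplitude = a,
                                           wrinkleDegreeMax = 8L), seed = 21)
        m <- truthMesh(gt, subdiv = 4L)
        featureCurvature(m, gaussianCurvature(m))
    }, numeric(1))
    expect_gt(feats[1], 1)
    expect_true(all(diff(feats) > 0))
})

test_that("computeFeatures on a noiseless sphere shell hits the construction", {
    stk <- sphereStack()
    fe <- computeFeatures(stk, cellId = "sphere")
    surf <- sphereSurface()
    expectedIntensity <- 450 / mean(voxels(stk)[nucleusMask(surf)])
    expect_equal(fe@intensity, expectedIntensity, tolerance = 1e-6)
    expect_equal(fe@skewness, 0)
    expect_lt(abs(fe@curvature - 1), 0.1)
})

test_that("features are deterministic and unsegmentable input signals exclusion", {
    stk <- applyMicroscope(sphereStack(), seed = 8, readNoiseSd = 2,
                           background = 5)
    f1 <- computeFeatures(stk, cellId = "x")
    f2 <- computeFeatures(stk, cellId = "x")
    expect_identical(featureTable(list(f1)), featureTable(list(f2)))
    expect_error(computeFeatures(imageStack(array(0, c(16, 16, 16)), 50)),
                 class = "laminaSegmentationError")
})

test_that("intensity/skewness survive intensity scaling; curvature survives spatial scaling", {
    stk <- applyMicroscope(sphereStack(), seed = 15, readNoiseSd = 2,
                           background = 5)
    f1 <- computeFeatures(stk, cellId = "a")
    f2 <- computeFeatures(imageStack(voxels(stk) * 10, spacing(stk)),
                          cellId = "a")
    expect_equal(f2@intensity, f1@intensity, tolerance = 1e-9)
    expect_equal(f2@skewness, f1@skewness, tolerance = 1e-9)
    # spatial rescaling of the same image grid (x2 voxel size): curvature
    # descriptor unchanged within discretization error
    f3 <- computeFeatures(imageStack(voxels(stk), spacing(stk) * 2),
                          cellId = "a", minVolume = 1e10 * 8,
                          smoothingSigma = 200, intensityProbeDepth = 600)
    expect_equal(f3@curvature, f1@curvature, tolerance = 1e-6)
})
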
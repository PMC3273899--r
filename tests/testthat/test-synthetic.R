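test_that("icosphere meshes are closed, oriented, genus-0 spheres", {
    for (sub in c(2L, 4L)) {
        ico <- icosphere(sub)
        expect_equal(nrow(ico$vertices), 10 * 4^sub + 2)
        expect_equal(nrow(ico$faces), 20 * 4^sub)
        expect_equal(LaminaShape:::.eulerCharacteristic(nrow(ico$vertices),
                                                        ico$faces), 2)
        expect_true(LaminaShape:::.meshVolumeRaw(ico$vertices,
                                                 ico$faces) > 0)
    }
    # unit icosphere volume approaches 4 pi / 3
    ico <- icosphere(4L)
    expect_lt(abs(meshVolume(ico$vertices, ico$faces) / (4 * pi / 3) - 1),
              0.01)
})

test_that("sphere ground truth has constant curvature 1/R^2", {
    gt <- sphereTruth()
    dirs <- icosphere(2L)$vertices
    expect_equal(gt@radialFun(dirs), rep(2000, nrow(dirs)))
    expect_equal(gt@curvatureFun(dirs), rep(1 / 2000^2, nrow(dirs)))
    expect_lt(abs(gt@enclosedVolume / (4 / 3 * pi * 2000^3) - 1), 0.01)
})

test_that("ellipsoid curvature matches the closed form at the poles", {
    a <- 2000; b <- 1700; cc <- 1400
    gt <- ellipsoidTruth()
    # pole along physical z (direction (z,y,x) = (1,0,0)): K = c^2/(a^2 b^2)
    expect_equal(gt@curvatureFun(matrix(c(1, 0, 0), 1)),
                 cc^2 / (a^2 * b^2))
    # pole along x: K = a^2/(b^2 c^2)
    expect_equal(gt@curvatureFun(matrix(c(0, 0, 1), 1)),
                 a^2 / (b^2 * cc^2))
})

test_that("finite-difference parametric curvature reproduces the ellipsoid", {
    gt <- ellipsoidTruth()
    dirs <- icosphere(2L)$vertices
    kFD <- LaminaShape:::.parametricCurvature(gt@radialFun, dirs)
    kAn <- gt@curvatureFun(dirs)
    expect_lt(max(abs(kFD / kAn - 1)), 1e-4)
})

test_that("analytic curvature satisfies Gauss-Bonnet under quadrature", {
    for (gt in list(ellipsoidTruth(),
                    makeSurface(nucleusPhenotype(wrinkleAmplitude = 0.08,
                                                 wrinkleDegreeMax = 8L),
                                seed = 3))) {
        m <- truthMesh(gt, subdiv = 4L)
        total <- gaussBonnetTotal(m$vertices, m$faces, m$curvature)
        expect_lt(abs(total / (4 * pi) - 1), 0.01)
    }
})

test_that("surfaces are deterministic in the seed", {
    ph <- phenotypeTemplates()$senescent
    m1 <- truthMesh(makeSurface(ph, seed = 42), subdiv = 2L)
    m2 <- truthMesh(makeSurface(ph, seed = 42), subdiv = 2L)
    m3 <- truthMesh(makeSurface(ph, seed = 43), subdiv = 2L)
    expect_identical(m1$vertices, m2$vertices)
    expect_false(isTRUE(all.equal(m1$vertices, m3$vertices)))
})

test_that("self-intersecting perturbations are rejected", {
    ph <- nucleusPhenotype(wrinkleAmplitude = 0.49, wrinkleDegreeMax = 8L)
    fails <- vapply(1:12, function(s)
        inherits(tryCatch(makeSurface(ph, seed = s), error = identity),
                 "error"), logical(1))
    expect_true(any(fails))
})

test_that("rasterized shell volume matches the analytic shell volume", {
    gt <- sphereTruth()  # R = 2000, t = 250
    stk <- sphereStack()
    shellVox <- sum(voxels(stk) == 100 * 4.5)
    exact <- 4 * pi / 3 * (2000^3 - 1750^3)
    expect_lt(abs(shellVox * 50^3 / exact - 1), 0.05)
    # interior at nucleoplasm intensity
    intVox <- sum(voxels(stk) == 100)
    expect_lt(abs(intVox * 50^3 / (4 * pi / 3 * 1750^3) - 1), 0.01)
})

test_that("shell intensity structure follows the phenotype", {
    stk <- sphereStack()
    v <- voxels(stk)
    vals <- sort(unique(as.vector(v)))
    expect_equal(vals, c(0, 100, 450))  # hotspotFraction 0: one shell value
    expect_equal(mean(v[v == 450]) / mean(v[v == 100]), 4.5)
    # hotspots add exactly one more level at gain x shell
    gt2 <- makeSurface(nucleusPhenotype(semiaxes = c(1300, 1200, 1100),
                                        wrinkleAmplitude = 0,
                                        hotspotFraction = 0.2,
                                        hotspotGain = 2), seed = 7)
    v2 <- voxels(rasterizeNucleus(gt2))
    expect_setequal(sort(unique(as.vector(v2))), c(0, 100, 450, 900))
    hotFrac <- sum(v2 == 900) / sum(v2 >= 450)
    expect_gt(hotFrac, 0.1); expect_lt(hotFrac, 0.3)
})

test_that("too-thin shells are rejected at rasterization", {
    gt <- makeSurface(nucleusPhenotype(shellThickness = 80,
                                       wrinkleAmplitude = 0), seed = 1)
    expect_error(rasterizeNucleus(gt, spacing = 50), "thinner than sampling")
})

test_that("noiseless rasterized shell is one 6-connected component, no holes", {
    stk <- sphereStack()
    v <- voxels(stk)
    shell <- v == 450
    cc <- LaminaShape:::.cc_largest(shell, dim(v))
    expect_equal(cc$n_components, 1L)
    expect_false(cc$touches_border)
    # filling the shell's cavity reproduces shell + interior exactly
    filled <- LaminaShape:::.fill_holes(shell, dim(v))
    expect_identical(array(filled, dim(v)), v > 0)
})

test_that("microscope model: identity limit and constant preservation", {
    stk <- sphereStack()
    out <- applyMicroscope(stk, psfSigma = 0, photonScale = Inf,
                           readNoiseSd = 0, background = 0, seed = 1)
    expect_identical(voxels(out), voxels(stk))
    flat <- imageStack(array(42, c(16, 16, 16)), 50)
    blurred <- applyMicroscope(flat, psfSigma = c(200, 100, 100),
                               photonScale = Inf, seed = 1)
    expect_lt(max(abs(voxels(blurred) - 42)), 1e-9 * 42)
})

test_that("microscope shot noise has Poisson mean and variance", {
    flat <- imageStack(array(50, c(50, 50, 50)), 50)
    out <- applyMicroscope(flat, psfSigma = 0, photonScale = 2,
                           readNoiseSd = 0, background = 0, seed = 3)
    v <- as.vector(voxels(out))
    expect_lt(abs(mean(v) / 50 - 1), 0.05)
    expect_lt(abs(var(v) / 25 - 1), 0.05)   # var = c / photonScale
    # deterministic per seed
    out2 <- applyMicroscope(flat, psfSigma = 0, photonScale = 2,
                            readNoiseSd = 0, background = 0, seed = 3)
    expect_identical(voxels(out), voxels(out2))
})

test_that("population simulation is labeled, sized and reproducible", {
    tmpl <- list(a = nucleusPhenotype(semiaxes = c(1200, 1100, 1000),
                                      wrinkleAmplitude = 0.02),
                 b = nucleusPhenotype(semiaxes = c(1100, 1050, 950),
                                      wrinkleAmplitude = 0.05))
    cells <- simulatePopulation(tmpl, nPerLabel = 3, jitter = 0.05,
                                seed = 9, microscope = NULL)
    expect_length(cells, 6)
    expect_equal(vapply(cells, `[[`, "", "label"), rep(c("a", "b"), each = 3))
    cells2 <- simulatePopulation(tmpl, nPerLabel = 3, jitter = 0.05,
                                 seed = 9, microscope = NULL)
    expect_identical(voxels(cells[[4]]$stack), voxels(cells2[[4]]$stack))
    # jitter = 0 keeps same-label phenotype parameters identical
    cells0 <- simulatePopulation(tmpl, nPerLabel = 2, jitter = 0,
                                 seed = 9, microscope = NULL)
    expect_identical(cells0[[1]]$truth@phenotype@semiaxes,
                     cells0[[2]]$truth@phenotype@semiaxes)
    expect_false(identical(voxels(cells0[[1]]$stack),
                           voxels(cells0[[2]]$stack)))  # wrinkle phase differs
})
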
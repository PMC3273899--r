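# Shared fixtures, computed lazily and cached for the whole test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, force(expr), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

# Noiseless spherical shell: R = 2000 nm, thickness 250 nm, 50 nm voxels.
sphereTruth <- function() cachedFixture("sphereTruth", {
    makeSurface(nucleusPhenotype(semiaxes = c(2000, 2000, 2000),
                                 wrinkleAmplitude = 0), seed = 1)
})

sphereStack <- function() cachedFixture("sphereStack", {
    rasterizeNucleus(sphereTruth())
})

sphereSurface <- function() cachedFixture("sphereSurface", {
    segmentLamina(sphereStack())
})

# Unperturbed ellipsoid ground truth (closed-form curvature available).
ellipsoidTruth <- function() cachedFixture("ellipsoidTruth", {
    makeSurface(nucleusPhenotype(semiaxes = c(2000, 1700, 1400),
                                 wrinkleAmplitude = 0), seed = 1)
})

# High-resolution ground-truth meshes (10242 vertices) with estimated K.
sphereMeshK <- function() cachedFixture("sphereMeshK", {
    m <- truthMesh(sphereTruth(), subdiv = 5L)
    m$K <- gaussianCurvature(m)
    m
})

ellipsoidMeshK <- function() cachedFixture("ellipsoidMeshK", {
    m <- truthMesh(ellipsoidTruth(), subdiv = 5L)
    m$K <- gaussianCurvature(m)
    m
})

# The simulated study cohort used by the end-to-end acceptance checks:
# fresh / senescent / apoptotic, 25 cells each, plus 6 extra senescent and
# 2 apoptotic-template cells planted into the senescent cohort (33 cells
# labeled senescent, 2 of them truly apoptotic).
acceptanceCohort <- function(seed = 1) cachedFixture("acceptanceCohort", {
    tmpl <- phenotypeTemplates()
    base <- simulatePopulation(tmpl, nPerLabel = 25, seed = seed * 10 + 1)
    extraSen <- simulatePopulation(tmpl["senescent"], nPerLabel = 6,
                                   seed = seed * 10 + 2)
    planted <- simulatePopulation(tmpl["apoptotic"], nPerLabel = 2,
                                  seed = seed * 10 + 3)
    for (i in seq_along(planted)) {
        planted[[i]]$label <- "senescent"
        planted[[i]]$cellId <- sprintf("planted_%d", i)
    }
    cells <- c(base, extraSen, planted)
    feats <- list()
    for (cl in cells) {
        r <- tryCatch(computeFeatures(cl$stack, cellId = cl$cellId,
                                      label = cl$label),
                      laminaSegmentationError = function(e) NULL)
        if (!is.null(r)) feats[[length(feats) + 1L]] <- r
    }
    tab <- featureTable(feats)
    tab$planted <- grepl("^planted", tab$cell_id)
    tab
})
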
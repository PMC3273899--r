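#' @importFrom withr with_seed
NULL

# Run code under a local RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
    withr::with_seed(as.integer(seed), code)
}

#' Construct an ImageStack
#'
#' @param voxels numeric 3D array in (z, y, x) order, finite and >= 0.
#' @param spacing per-axis voxel size in nm, ordered (z, y, x); a scalar is
#'   recycled to all three axes.
#' @param channelLabel free-text channel description.
#' @return an \linkS4class{ImageStack}.
#' @examples
#' s <- imageStack(array(1, c(8, 8, 8)), spacing = 50)
#' isIsotropic(s)
#' @export
imageStack <- function(voxels, spacing, channelLabel = "") {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("ImageStack", voxels = voxels, spacing = as.numeric(spacing),
        channelLabel = channelLabel)
}

# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates (n x 3 matrix, axes ordered as the array dims). Points outside
# the grid are clamped to the border value.
.trilinear <- function(arr, pts) {
    d <- dim(arr)
    p1 <- pmin(pmax(pts[, 1], 0), d[1] - 1)
    p2 <- pmin(pmax(pts[, 2], 0), d[2] - 1)
    p3 <- pmin(pmax(pts[, 3], 0), d[3] - 1)
    i0 <- pmin(floor(p1), d[1] - 2); f1 <- p1 - i0
    j0 <- pmin(floor(p2), d[2] - 2); f2 <- p2 - j0
    k0 <- pmin(floor(p3), d[3] - 2); f3 <- p3 - k0
    if (d[1] == 1L) { i0 <- rep(0, length(p1)); f1 <- 0 }
    if (d[2] == 1L) { j0 <- rep(0, length(p2)); f2 <- 0 }
    if (d[3] == 1L) { k0 <- rep(0, length(p3)); f3 <- 0 }
    at <- function(di, dj, dk)
        arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
    (1 - f1) * ((1 - f2) * ((1 - f3) * at(0, 0, 0) + f3 * at(0, 0, 1)) +
                f2 * ((1 - f3) * at(0, 1, 0) + f3 * at(0, 1, 1))) +
        f1 * ((1 - f2) * ((1 - f3) * at(1, 0, 0) + f3 * at(1, 0, 1)) +
              f2 * ((1 - f3) * at(1, 1, 0) + f3 * at(1, 1, 1)))
}

# Separable Gaussian smoothing of a 3D array; sigma per axis in voxels.
# Kernel truncated at 3 sigma; borders use renormalized (reflected) weights
# via edge replication through shift-and-add.
.gaussianSmooth3 <- function(arr, sigmaVox) {
    d <- dim(arr)
    out <- arr
    for (ax in 1:3) {
        s <- sigmaVox[ax]
        if (s <= 0) next
        h <- max(1L, ceiling(3 * s))
        k <- exp(-0.5 * ((-h:h) / s)^2)
        k <- k / sum(k)
        n <- d[ax]
        # unfold: axis first, rest flattened
        perm <- c(ax, setdiff(1:3, ax))
        m <- matrix(aperm(out, perm), nrow = n)
        acc <- matrix(0, nrow = n, ncol = ncol(m))
        for (o in -h:h) {
            idx <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
            acc <- acc + k[o + h + 1] * m[idx, , drop = FALSE]
        }
        out <- aperm(array(acc, d[perm]), order(perm))
    }
    out
}

# Uniform random unit directions (n x 3).
.randomDirections <- function(n) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
}

# Two unit vectors orthogonal to each row of u (n x 3): a tangent basis.
.tangentBasis <- function(u) {
    a <- matrix(rep(c(1, 0, 0), each = nrow(u)), ncol = 3)
    flip <- abs(u[, 1]) > 0.9
    a[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
    e1 <- a - u * rowSums(a * u)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
                u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
                u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
    list(e1 = e1, e2 = e2)
}

.stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
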
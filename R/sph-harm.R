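# Real spherical harmonics evaluated at unit directions.
#
# Directions are n x 3 matrices in the package's (z, y, x) axis order; the
# polar angle is measured from the physical z axis (first column) and the
# azimuth in the (x, y) plane. Associated Legendre values come from
# pracma::legendre; rows are L2-orthonormalized over the sphere so a
# coefficient vector's power adds across modes.
#
# Returns an n x (sum over l of 2l+1) matrix for degrees lmin..lmax.
.sphericalHarmonicsBasis <- function(dirs, lmin = 2L, lmax = 8L) {
    uz <- dirs[, 1]
    uy <- dirs[, 2]
    ux <- dirs[, 3]
    ct <- pmin(pmax(uz, -1), 1)
    phi <- atan2(uy, ux)
    cols <- list()
    for (l in lmin:lmax) {
        P <- pracma::legendre(l, ct)       # (l+1) x n, orders m = 0..l
        if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
        block <- matrix(0, length(ct), 2L * l + 1L)
        nl0 <- sqrt((2 * l + 1) / (4 * pi))
        block[, 1] <- nl0 * P[1, ]
        for (m in seq_len(l)) {
            nlm <- sqrt((2 * l + 1) / (2 * pi) *
                        exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
            block[, 2 * m]     <- nlm * P[m + 1, ] * cos(m * phi)
            block[, 2 * m + 1] <- nlm * P[m + 1, ] * sin(m * phi)
        }
        cols[[length(cols) + 1L]] <- block
    }
    do.call(cbind, cols)
}
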
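#' Triangle-mesh helpers used by segmentation and curvature estimation
#'
#' The package represents closed surfaces as vertex/face matrices with
#' consistently outward-oriented triangles. Meshes produced here are
#' subdivided icosahedra (geodesic spheres), so they are guaranteed to be
#' closed 2-manifolds of genus 0.
#'
#' @name mesh-utils
NULL

#' Geodesic sphere (subdivided icosahedron)
#'
#' @param subdiv number of 4-to-1 subdivision rounds; the mesh has
#'   \code{10 * 4^subdiv + 2} vertices and \code{20 * 4^subdiv} faces.
#' @return list with \code{vertices} (unit-norm n x 3) and \code{faces}
#'   (m x 3, 1-based, oriented outwards).
#' @examples
#' ico <- icosphere(3)
#' nrow(ico$vertices)  # 642
#' @export
icosphere <- function(subdiv = 4L) {
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
        c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
        c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
        c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
    v <- v / sqrt(rowSums(v^2))
    f <- rbind(
        c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
        c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
        c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
        c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    for (it in seq_len(subdiv)) {
        nv <- nrow(v)
        ea <- pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
        eb <- pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
        key <- ea * (nv + 1) + eb
        uk <- unique(as.vector(key))
        mid_of <- match(as.vector(key), uk)
        ua <- as.vector(ea)[!duplicated(as.vector(key))]
        ub <- as.vector(eb)[!duplicated(as.vector(key))]
        mids <- (v[ua, , drop = FALSE] + v[ub, , drop = FALSE]) / 2
        mids <- mids / sqrt(rowSums(mids^2))
        m <- matrix(mid_of + nv, ncol = 3)   # midpoint index per face edge
        v <- rbind(v, mids)
        f <- rbind(cbind(f[, 1], m[, 1], m[, 3]),
                   cbind(f[, 2], m[, 2], m[, 1]),
                   cbind(f[, 3], m[, 3], m[, 2]),
                   m)
    }
    if (.meshVolumeRaw(v, f) < 0) f <- f[, c(1, 3, 2)]
    list(vertices = v, faces = f)
}

.meshVolumeRaw <- function(vertices, faces) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    c_ <- vertices[faces[, 3], , drop = FALSE]
    sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a closed oriented triangle mesh
#'
#' Divergence-theorem volume; positive for outward orientation.
#' @param vertices n x 3 matrix.
#' @param faces m x 3 index matrix.
#' @return volume in cubed vertex units.
#' @export
meshVolume <- function(vertices, faces) abs(.meshVolumeRaw(vertices, faces))

.faceCross <- function(vertices, faces) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    c_ <- vertices[faces[, 3], , drop = FALSE]
    u <- b - a; w <- c_ - a
    cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
          u[, 3] * w[, 1] - u[, 1] * w[, 3],
          u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Total surface area of a triangle mesh
#' @inheritParams meshVolume
#' @return area in squared vertex units.
#' @export
meshArea <- function(vertices, faces) {
    cr <- .faceCross(vertices, faces)
    sum(sqrt(rowSums(cr^2))) / 2
}

# Per-vertex barycentric area: one third of incident face areas.
.vertexAreas <- function(vertices, faces) {
    cr <- .faceCross(vertices, faces)
    fa <- sqrt(rowSums(cr^2)) / 2
    acc <- numeric(nrow(vertices))
    for (j in 1:3) {
        t <- rowsum(fa, faces[, j])
        acc[as.integer(rownames(t))] <- acc[as.integer(rownames(t))] + t
    }
    acc / 3
}

# Angle-unweighted, area-weighted vertex normals (outward for outward faces).
.vertexNormals <- function(vertices, faces) {
    cr <- .faceCross(vertices, faces)   # length = 2 * face area
    nrm <- matrix(0, nrow(vertices), 3)
    for (j in 1:3) {
        t <- rowsum(cr, faces[, j])
        rows <- as.integer(rownames(t))
        nrm[rows, ] <- nrm[rows, ] + t
    }
    len <- sqrt(rowSums(nrm^2))
    len[len == 0] <- 1
    nrm / len
}

# Sparse vertex adjacency from faces (symmetric logical pattern).
.meshAdjacency <- function(nVertices, faces) {
    i <- c(faces[, 1], faces[, 2], faces[, 3])
    j <- c(faces[, 2], faces[, 3], faces[, 1])
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                         dims = c(nVertices, nVertices), use.last.ij = FALSE)
}

# Euler characteristic V - E + F of a triangle mesh (E from unique edges).
.eulerCharacteristic <- function(nVertices, faces) {
    e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    nE <- nrow(unique(e))
    nVertices - nE + nrow(faces)
}

# Mean edge length of a mesh.
.meanEdgeLength <- function(vertices, faces) {
    e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    d <- vertices[e[, 1], , drop = FALSE] - vertices[e[, 2], , drop = FALSE]
    mean(sqrt(rowSums(d^2)))
}

#' Export a lamina mesh as an ASCII PLY file
#'
#' Writes vertices (with optional per-vertex scalar attributes such as
#' normalized intensity or curvature, stored as extra float properties) and
#' triangle faces, for rendering cross-section style maps externally.
#'
#' @param surface a successful \linkS4class{LaminaSurface}.
#' @param path output file path.
#' @param attributes named list of per-vertex numeric vectors.
#' @return invisibly, the path.
#' @export
writeSurfacePly <- function(surface, path, attributes = list()) {
    .stopIfNot(segmentationSuccess(surface),
               "cannot export a failed segmentation")
    v <- vertices(surface)
    f <- faces(surface)
    for (a in attributes)
        .stopIfNot(length(a) == nrow(v),
                   "attribute length must equal vertex count")
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("property float %s", names(attributes)),
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vmat <- cbind(v[, 3], v[, 2], v[, 1])  # PLY convention x, y, z
    for (a in attributes) vmat <- cbind(vmat, a)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(vmat, trim = TRUE, digits = 7), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}
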
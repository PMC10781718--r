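# Triangle meshes: container, topology checks, exact volume, primitives.

#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices per triangle.
#' @return Object of class `tmj_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  storage.mode(vertices) <- "double"
  structure(list(vertices = vertices, faces = faces), class = "tmj_mesh")
}

#' @export
print.tmj_mesh <- function(x, ...) {
  wt <- is_watertight(x)
  cat(sprintf("<mesh> %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (wt$watertight) "watertight" else
                sprintf("NOT watertight (%d open edges)", wt$open_edges)))
  invisible(x)
}

#' Watertightness report
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces; it is consistently oriented when each such edge is traversed once in
#' each direction.
#'
#' @param mesh A [triangle_mesh()].
#' @return List with `watertight`, `oriented`, `open_edges` (edges not shared
#'   by exactly 2 faces), `n_edges`.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "tmj_mesh"))
  f <- mesh$faces
  if (nrow(f) == 0L) {
    return(list(watertight = FALSE, oriented = FALSE,
                open_edges = 0L, n_edges = 0L))
  }
  nv <- nrow(mesh$vertices)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  # directed edge key a->b; undirected key with min/max
  lo <- pmin(a, b); hi <- pmax(a, b)
  ukey <- (as.double(lo) - 1) * nv + (hi - 1)
  cnt <- table(ukey)
  open_edges <- sum(cnt != 2L)
  dkey <- (as.double(a) - 1) * nv + (b - 1)
  oriented <- open_edges == 0L && !anyDuplicated(dkey)
  list(watertight = open_edges == 0L, oriented = oriented,
       open_edges = as.integer(open_edges), n_edges = length(cnt))
}

.require_watertight <- function(mesh, what = "mesh") {
  wt <- is_watertight(mesh)
  if (!wt$watertight) {
    stop(sprintf("topology error: %s is not watertight (%d open edges)",
                 what, wt$open_edges), call. = FALSE)
  }
  invisible(wt)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedra spanned by each
#' face against the origin. The result is returned positive regardless of the
#' mesh's global orientation.
#'
#' @param mesh A watertight [triangle_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  .require_watertight(mesh)
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  s <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
       p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
       p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(s)) / 6
}

#' Mesh axis-aligned bounds
#' @param mesh A [triangle_mesh()].
#' @return 2 x 3 matrix, rows `min` and `max`.
#' @export
mesh_bounds <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

#' Transform a mesh rigidly
#' @param mesh A [triangle_mesh()].
#' @param tf A [rigid_transform()].
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, tf) {
  triangle_mesh(apply_rigid(tf, mesh$vertices), mesh$faces)
}

#' Merge meshes into one (disjoint components)
#' @param ... [triangle_mesh()] objects.
#' @return A single [triangle_mesh()].
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  off <- 0L
  vs <- list(); fs <- list()
  for (m in ms) {
    stopifnot(inherits(m, "tmj_mesh"))
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Axis-aligned box mesh
#'
#' @param min,max Opposite corners (mm).
#' @return Watertight, outward-oriented [triangle_mesh()] with 12 faces.
#' @export
mesh_box <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  lo <- .as_point3(min, "min"); hi <- .as_point3(max, "max")
  stopifnot(all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order from expand.grid: index = 1 + dx + 2*dy + 4*dz
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),      # z = hi (+z)
    c(1, 2, 5), c(2, 6, 5),      # y = lo (-y)
    c(3, 7, 4), c(4, 7, 8),      # y = hi (+y)
    c(1, 5, 3), c(3, 5, 7),      # x = lo (-x)
    c(2, 4, 6), c(4, 8, 6))      # x = hi (+x)
  triangle_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with all vertices projected to the sphere; the
#' enclosed (inscribed) volume approaches `4/3 pi r^3` from below as the
#' subdivision level grows.
#'
#' @param radius Sphere radius (mm).
#' @param subdiv Number of 4-to-1 subdivision passes (0 = icosahedron).
#' @param center Sphere center (mm).
#' @return Watertight [triangle_mesh()] with `20 * 4^subdiv` faces.
#' @export
mesh_icosphere <- function(radius = 1, subdiv = 3, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdiv >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    a <- f[, 1]; b <- f[, 2]; cc <- f[, 3]
    ek <- function(i, j) (pmin(i, j) - 1) * nv + pmax(i, j)
    keys <- c(ek(a, b), ek(b, cc), ek(cc, a))
    uk <- unique(keys)
    mid_id <- match(keys, uk) + nv
    i1 <- (uk - 1) %/% nv + 1; i2 <- (uk - 1) %% nv + 1
    mids <- (v[i1, , drop = FALSE] + v[i2, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    mab <- mid_id[seq_len(nf)]
    mbc <- mid_id[nf + seq_len(nf)]
    mca <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(a, mab, mca), cbind(mab, b, mbc),
               cbind(mca, mbc, cc), cbind(mab, mbc, mca))
  }
  v <- v * radius
  v <- v + matrix(.as_point3(center, "center"), nrow(v), 3, byrow = TRUE)
  triangle_mesh(v, f)
}

#' Ellipsoid mesh
#'
#' An [mesh_icosphere()] scaled anisotropically to semi-axes `(a, b, c)` and
#' optionally rotated, then translated to `center`.
#'
#' @param semi_axes Numeric (a, b, c), mm, all positive.
#' @param center Ellipsoid center (mm).
#' @param subdiv Icosphere subdivision level.
#' @param rotation Optional 3x3 rotation applied about the center.
#' @return Watertight [triangle_mesh()].
#' @export
mesh_ellipsoid <- function(semi_axes, center = c(0, 0, 0), subdiv = 4,
                           rotation = NULL) {
  ax <- as.numeric(semi_axes)
  stopifnot(length(ax) == 3L, all(ax > 0))
  m <- mesh_icosphere(1, subdiv)
  v <- sweep(m$vertices, 2, ax, `*`)
  if (!is.null(rotation)) v <- v %*% t(rotation)
  v <- v + matrix(.as_point3(center, "center"), nrow(v), 3, byrow = TRUE)
  triangle_mesh(v, m$faces)
}
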
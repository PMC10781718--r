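# Voxel occupancy: point-in-mesh by ray-crossing parity and isotropic grids.
#
# Inside test: +x rays from the query points. To avoid edge/vertex grazing the
# ray origins' (y, z) are shifted by a fixed, deterministic sub-voxel offset
# (two incommensurate epsilons), which plays the role of a slightly tilted ray
# while keeping all rays of one (y, z) row co-linear so the parity fill stays
# fully vectorised.

#' Occupancy grid
#'
#' @param origin Grid corner (mm): the center of voxel (1,1,1) is at
#'   `origin + h/2` in each axis.
#' @param h Isotropic voxel pitch (mm).
#' @param dims Integer (nx, ny, nz).
#' @param occupancy Logical array `dims`, or vector of length `prod(dims)`.
#' @return Object of class `tmj_grid`.
#' @export
occupancy_grid <- function(origin, h, dims, occupancy) {
  stopifnot(h > 0, length(dims) == 3L, all(dims >= 1))
  dims <- as.integer(dims)
  occ <- array(as.logical(occupancy), dim = dims)
  if (anyNA(occ)) stop("occupancy must be TRUE/FALSE")
  structure(list(origin = .as_point3(origin, "origin"), h = h,
                 dims = dims, occupancy = occ), class = "tmj_grid")
}

#' @export
print.tmj_grid <- function(x, ...) {
  cat(sprintf("<occupancy grid> %d x %d x %d @ h = %g mm, %d occupied (%.2f mm^3)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, sum(x$occupancy),
              grid_volume(x)))
  invisible(x)
}

#' Occupied volume of a grid
#' @param grid A [occupancy_grid()].
#' @return `count(occupied) * h^3` in mm^3.
#' @export
grid_volume <- function(grid) {
  stopifnot(inherits(grid, "tmj_grid"))
  sum(grid$occupancy) * grid$h^3
}

#' Voxel-center coordinates of a grid
#'
#' @param grid A [occupancy_grid()].
#' @param which `"occupied"` (default), `"all"`, or a logical array/vector
#'   conformable with the grid.
#' @return n x 3 matrix of voxel-center coordinates (mm).
#' @export
grid_centers <- function(grid, which = "occupied") {
  stopifnot(inherits(grid, "tmj_grid"))
  d <- grid$dims
  sel <- if (identical(which, "all")) rep(TRUE, prod(d))
         else if (identical(which, "occupied")) as.vector(grid$occupancy)
         else as.vector(which)
  idx <- which(sel)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  cbind(grid$origin[1] + (i + 0.5) * grid$h,
        grid$origin[2] + (j + 0.5) * grid$h,
        grid$origin[3] + (k + 0.5) * grid$h)
}

# Core parity engine. points: n x 3. Returns logical inside flags.
# Queries sharing a (y, z) row share one ray; eps shifts are fixed fractions
# of the mesh extent so the test is deterministic.
.ray_parity_inside <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(points)
  if (n == 0L) return(logical(0))
  ext <- max(apply(v, 2, function(x) diff(range(x))), 1e-6)
  eps_y <- 1.0e-6 * ext
  eps_z <- 2.3e-6 * ext
  yq <- points[, 2] + eps_y
  zq <- points[, 3] + eps_z

  # group queries into rays by exact (yq, zq)
  rk <- paste(yq, zq)
  ur <- !duplicated(rk)
  ray_id <- match(rk, rk[ur])
  ry <- yq[ur]; rz <- zq[ur]
  nray <- length(ry)

  # quick reject: points outside mesh bbox are outside
  bb <- mesh_bounds(mesh)

  ord <- order(ry)
  ry_s <- ry[ord]

  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrmx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  nrmy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nrmz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nrmx^2 + nrmy^2 + nrmz^2)
  keep <- which(abs(nrmx) > 1e-12 * pmax(nn, 1e-300))

  cross_ray <- vector("list", length(keep))
  cross_x <- vector("list", length(keep))
  ti <- 0L
  for (t in keep) {
    ay <- p1[t, 2]; az <- p1[t, 3]
    by <- p2[t, 2]; bz <- p2[t, 3]
    cy <- p3[t, 2]; cz <- p3[t, 3]
    ylo <- min(ay, by, cy); yhi <- max(ay, by, cy)
    i0 <- findInterval(ylo, ry_s, left.open = TRUE) + 1L
    i1 <- findInterval(yhi, ry_s)
    if (i1 < i0) next
    cand <- ord[i0:i1]
    zlo <- min(az, bz, cz); zhi <- max(az, bz, cz)
    cand <- cand[rz[cand] >= zlo & rz[cand] <= zhi]
    if (!length(cand)) next
    py <- ry[cand]; pz <- rz[cand]
    # 2D edge-function inside test in the (y, z) projection
    d1 <- (by - ay) * (pz - az) - (bz - az) * (py - ay)
    d2 <- (cy - by) * (pz - bz) - (cz - bz) * (py - by)
    d3 <- (ay - cy) * (pz - cz) - (az - cz) * (py - cy)
    inside <- (d1 > 0 & d2 > 0 & d3 > 0) | (d1 < 0 & d2 < 0 & d3 < 0)
    if (!any(inside)) next
    cand <- cand[inside]
    # x where the ray (y, z) pierces the triangle's plane
    xs <- p1[t, 1] - (nrmy[t] * (ry[cand] - p1[t, 2]) +
                      nrmz[t] * (rz[cand] - p1[t, 3])) / nrmx[t]
    ti <- ti + 1L
    cross_ray[[ti]] <- cand
    cross_x[[ti]] <- xs
  }
  inside_pt <- logical(n)
  if (ti == 0L) return(inside_pt)
  cr <- unlist(cross_ray[seq_len(ti)], use.names = FALSE)
  cx <- unlist(cross_x[seq_len(ti)], use.names = FALSE)
  o2 <- order(cr, cx)
  cr <- cr[o2]; cx <- cx[o2]
  starts <- c(1L, which(diff(cr) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(cr))
  px <- points[, 1]
  # group query points by ray once (ray r -> o3[pstart[r]:pend[r]])
  o3 <- order(ray_id)
  pcnt <- tabulate(ray_id, nbins = nray)
  pend <- cumsum(pcnt)
  pstart <- pend - pcnt + 1L
  for (s in seq_along(starts)) {
    r <- cr[starts[s]]
    xs <- cx[starts[s]:ends[s]]
    qi <- o3[pstart[r]:pend[r]]
    # a point is inside iff an odd number of crossings lie at larger x
    inside_pt[qi] <- (length(xs) - findInterval(px[qi], xs)) %% 2L == 1L
  }
  # bbox guard (numerical safety; parity already handles it)
  inside_pt & points[, 1] >= bb[1, 1] & points[, 1] <= bb[2, 1] &
    points[, 2] >= bb[1, 2] - abs(eps_y) & points[, 2] <= bb[2, 2] + abs(eps_y) &
    points[, 3] >= bb[1, 3] - abs(eps_z) & points[, 3] <= bb[2, 3] + abs(eps_z)
}

#' Point-in-mesh test
#'
#' Ray-crossing parity along +x with deterministic grazing avoidance; the mesh
#' must be watertight for the parity to be meaningful.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh A watertight [triangle_mesh()].
#' @return Logical vector: `TRUE` where the point is inside.
#' @export
points_in_mesh <- function(points, mesh) {
  stopifnot(inherits(mesh, "tmj_mesh"))
  .require_watertight(mesh)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  .ray_parity_inside(points, mesh)
}

#' Voxelize a watertight mesh
#'
#' A voxel is occupied iff its center lies inside the mesh. The grid covers
#' the mesh bounds (or the given bounds) padded by at least one voxel.
#'
#' @param mesh A watertight [triangle_mesh()].
#' @param h Voxel pitch (mm), default 0.3 (a common CBCT slice thickness).
#' @param bounds Optional 2 x 3 matrix (rows min, max) of the region to grid;
#'   defaults to the mesh bounds.
#' @return An [occupancy_grid()].
#' @export
voxelize <- function(mesh, h = 0.3, bounds = NULL) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("voxel pitch h must be a positive number", call. = FALSE)
  }
  stopifnot(inherits(mesh, "tmj_mesh"))
  .require_watertight(mesh)
  bb <- if (is.null(bounds)) mesh_bounds(mesh) else {
    bounds <- as.matrix(bounds)
    stopifnot(all(dim(bounds) == c(2L, 3L)))
    bounds
  }
  origin <- bb[1, ] - h
  dims <- pmax(1L, as.integer(ceiling((bb[2, ] - origin) / h)) + 1L)
  d <- dims
  xs <- origin[1] + (seq_len(d[1]) - 0.5) * h
  ys <- origin[2] + (seq_len(d[2]) - 0.5) * h
  zs <- origin[3] + (seq_len(d[3]) - 0.5) * h
  centers <- cbind(rep(xs, times = d[2] * d[3]),
                   rep(rep(ys, each = d[1]), times = d[3]),
                   rep(zs, each = d[1] * d[2]))
  occ <- .ray_parity_inside(centers, mesh)
  occupancy_grid(origin, h, dims, occ)
}

#' Keep a subset of a grid's occupied voxels
#'
#' @param grid A [occupancy_grid()].
#' @param keep Logical vector over the currently occupied voxels, in the order
#'   of [grid_centers()] with `which = "occupied"`.
#' @return The filtered [occupancy_grid()].
#' @export
grid_subset <- function(grid, keep) {
  stopifnot(inherits(grid, "tmj_grid"))
  idx <- which(as.vector(grid$occupancy))
  stopifnot(length(keep) == length(idx))
  occ <- rep(FALSE, prod(grid$dims))
  occ[idx[keep]] <- TRUE
  occupancy_grid(grid$origin, grid$h, grid$dims, occ)
}

#' Export occupied voxel indices as CSV
#'
#' Writes columns `i, j, k` (1-based voxel indices) for debugging/visualising
#' occupancy grids.
#'
#' @param grid A [occupancy_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxels_csv <- function(grid, path) {
  stopifnot(inherits(grid, "tmj_grid"))
  d <- grid$dims
  idx <- which(as.vector(grid$occupancy))
  df <- data.frame(i = (idx - 1L) %% d[1] + 1L,
                   j = ((idx - 1L) %/% d[1]) %% d[2] + 1L,
                   k = (idx - 1L) %/% (d[1] * d[2]) + 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
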
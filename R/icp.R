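# Point-to-point ICP refinement, restricted to a half-space region.

# nearest-neighbour indices from query (n x 3) into ref (m x 3), brute force
# in blocks to bound memory; fine for the mesh sizes used here.
.nn_index <- function(query, ref, block = 512L) {
  n <- nrow(query)
  out <- integer(n)
  r2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), r2, `+`) - 2 * q %*% t(ref)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Iterative-closest-point refinement of a rigid alignment
#'
#' Point-to-point ICP between the vertices of `moving` and the vertices of
#' `fixed`, restricted to moving vertices on the positive side of `region`
#' (evaluated at the initial alignment) — the surgically unchanged cranial
#' region when refining serial-scan superimpositions. Correspondences farther
#' than 2x the median pair distance are rejected each iteration. The result
#' never has a larger restricted-region RMS than the initialisation.
#'
#' @param moving,fixed [triangle_mesh()] objects (vertex clouds are used).
#' @param init Initial [rigid_transform()] mapping `moving` into `fixed`'s
#'   frame.
#' @param region A [plane()]; only moving vertices with positive signed
#'   distance (after `init`) participate. `NULL` uses all vertices.
#' @param max_iter Maximum iterations.
#' @param tol Stop when the RMS residual changes by less than this (mm).
#' @return A [rigid_transform()] with attributes `rms` (final RMS, mm) and
#'   `iterations`.
#' @export
icp_refine <- function(moving, fixed, init = rigid_transform(),
                       region = NULL, max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(moving, "tmj_mesh"), inherits(fixed, "tmj_mesh"))
  if (nrow(moving$vertices) == 0L || nrow(fixed$vertices) == 0L) {
    stop("empty mesh", call. = FALSE)
  }
  src0 <- moving$vertices
  cur0 <- apply_rigid(init, src0)
  if (!is.null(region)) {
    stopifnot(inherits(region, "tmj_plane"))
    sel <- signed_distance(region, cur0) > 0
    if (!any(sel)) {
      stop("empty-region error: no moving vertices on the positive side of the region plane",
           call. = FALSE)
    }
    src0 <- src0[sel, , drop = FALSE]
  }
  ref <- fixed$vertices
  rms_of <- function(tf) {
    cur <- apply_rigid(tf, src0)
    nn <- .nn_index(cur, ref)
    sqrt(mean(rowSums((cur - ref[nn, , drop = FALSE])^2)))
  }
  tf <- init
  best <- init
  best_rms <- rms_of(init)
  prev_rms <- best_rms
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cur <- apply_rigid(tf, src0)
    nn <- .nn_index(cur, ref)
    tgt <- ref[nn, , drop = FALSE]
    d <- sqrt(rowSums((cur - tgt)^2))
    thr <- 2 * stats::median(d)
    keep <- d <= pmax(thr, 1e-12)
    if (sum(keep) < 3L) break
    step <- .kabsch(cur[keep, , drop = FALSE], tgt[keep, , drop = FALSE])
    tf <- compose_rigid(step, tf)
    rms <- rms_of(tf)
    if (rms < best_rms) { best <- tf; best_rms <- rms }
    if (abs(prev_rms - rms) < tol) break
    prev_rms <- rms
  }
  structure(best, rms = best_rms, iterations = it)
}
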
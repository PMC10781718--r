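# Joint-space volumetry: glenoid fossa volume, condyle removal, and the
# anterior/posterior and medial/lateral compartment partition.

#' Joint-space volume set
#'
#' @param Vgf,Vjs,Vajs,Vpjs,Vmjs,Vljs Volumes, mm^3.
#' @param side `"R"` or `"L"`.
#' @param timepoint One of `"T0"`, `"T1"`, `"T2"`, `"T3"`.
#' @param h Voxel pitch used (mm).
#' @return Object of class `tmj_volumes`.
#' @export
joint_space_volumes <- function(Vgf, Vjs, Vajs, Vpjs, Vmjs, Vljs,
                                side, timepoint, h) {
  stopifnot(Vgf >= 0, Vjs >= 0, Vajs >= 0, Vpjs >= 0, Vmjs >= 0, Vljs >= 0)
  if (Vjs > Vgf + 1e-9) stop("Vjs exceeds Vgf", call. = FALSE)
  if (abs(Vajs + Vpjs - Vjs) > 1e-9 * max(1, Vjs) ||
      abs(Vmjs + Vljs - Vjs) > 1e-9 * max(1, Vjs)) {
    stop("compartment volumes do not sum to Vjs", call. = FALSE)
  }
  structure(list(Vgf = Vgf, Vjs = Vjs, Vajs = Vajs, Vpjs = Vpjs,
                 Vmjs = Vmjs, Vljs = Vljs,
                 side = match.arg(side, c("R", "L")),
                 timepoint = match.arg(timepoint, c("T0", "T1", "T2", "T3")),
                 h = h),
            class = "tmj_volumes")
}

#' @export
print.tmj_volumes <- function(x, ...) {
  cat(sprintf("<joint space volumes> side %s, %s, h = %g mm\n",
              x$side, x$timepoint, x$h))
  v <- unlist(x[c("Vgf", "Vjs", "Vajs", "Vpjs", "Vmjs", "Vljs")])
  print(round(v, 2))
  invisible(x)
}

#' @export
as.data.frame.tmj_volumes <- function(x, ...) {
  data.frame(side = x$side, timepoint = x$timepoint, h_mm = x$h,
             Vgf = x$Vgf, Vjs = x$Vjs, Vajs = x$Vajs, Vpjs = x$Vpjs,
             Vmjs = x$Vmjs, Vljs = x$Vljs)
}

#' Glenoid fossa volume from a fossa ROI mesh
#'
#' Voxelizes the closed fossa capture-region mesh and keeps the voxels whose
#' centers lie on the superior side of the side's eminence plane (EmP); the
#' kept volume is Vgf and the kept grid is returned for reuse by the
#' joint-space measurements at every timepoint.
#'
#' @param roi Watertight [triangle_mesh()] bounding the fossa capture region.
#' @param frame A [build_reference_frame()] result.
#' @param side `"R"` or `"L"`.
#' @param h Voxel pitch (mm), default 0.3.
#' @return List with `Vgf` (mm^3) and `fossa_grid` (an [occupancy_grid()]
#'   holding only the above-EmP voxels).
#' @export
compute_vgf <- function(roi, frame, side = "R", h = 0.3) {
  stopifnot(inherits(frame, "tmj_frame"))
  sp <- .frame_side(frame, side)
  g <- voxelize(roi, h)
  centers <- grid_centers(g)
  keep <- signed_distance(sp$EmP, centers) > 0
  if (!any(keep)) {
    stop("empty-fossa error: no ROI voxel lies above the eminence plane",
         call. = FALSE)
  }
  fossa <- grid_subset(g, keep)
  list(Vgf = grid_volume(fossa), fossa_grid = fossa)
}

#' Joint-space volumes given the fossa grid and a mandible position
#'
#' Removes the mandible (condyle) from the fossa occupancy: joint-space
#' voxels are fossa voxels whose centers are not inside the mandible mesh.
#' The remaining voxels are partitioned by the side's GfCP into anterior /
#' posterior and, independently, by the side's GfSP into medial / lateral
#' compartments. Voxel centers exactly on a partition plane go to the
#' anterior (respectively medial) bin, a deterministic measure-zero
#' tie-break. The two partitions each cover the joint space exactly, so
#' `Vajs + Vpjs == Vjs` and `Vmjs + Vljs == Vjs` hold to the last bit.
#'
#' @param fossa_grid Fossa occupancy from [compute_vgf()].
#' @param mandible Watertight [triangle_mesh()] of the mandible (or condyle),
#'   already expressed in the fossa grid's coordinate frame.
#' @param frame The T0 [build_reference_frame()] result.
#' @param side `"R"` or `"L"`.
#' @param timepoint Label stored in the result.
#' @return A [joint_space_volumes()] object.
#' @export
compute_joint_space <- function(fossa_grid, mandible, frame, side = "R",
                                timepoint = "T0") {
  stopifnot(inherits(fossa_grid, "tmj_grid"), inherits(frame, "tmj_frame"))
  sp <- .frame_side(frame, side)
  h <- fossa_grid$h
  centers <- grid_centers(fossa_grid)
  Vgf <- nrow(centers) * h^3
  inside_cond <- points_in_mesh(centers, mandible)
  js <- centers[!inside_cond, , drop = FALSE]
  n_js <- nrow(js)
  d_cor <- signed_distance(sp$GfCP, js)   # positive = anterior
  d_sag <- signed_distance(sp$GfSP, js)   # positive = lateral
  n_a <- sum(d_cor >= 0)                  # ties -> anterior
  n_l <- sum(d_sag > 0)                   # ties -> medial
  joint_space_volumes(
    Vgf = Vgf, Vjs = n_js * h^3,
    Vajs = n_a * h^3, Vpjs = (n_js - n_a) * h^3,
    Vmjs = (n_js - n_l) * h^3, Vljs = n_l * h^3,
    side = side, timepoint = timepoint, h = h)
}

#' Timepoint case
#'
#' Bundles one scan's meshes and landmarks. The fossa ROI is only required on
#' the baseline (T0) case; follow-up cases are superimposed onto T0 and
#' measured against the T0 fossa.
#'
#' @param patient_id Identifier.
#' @param timepoint One of `"T0"`..`"T3"`.
#' @param cranial Cranial-base [triangle_mesh()] (used for ICP refinement).
#' @param mandible Mandible/condyle [triangle_mesh()].
#' @param landmarks A [landmark_set()] in the same coordinates.
#' @param fossa_roi Optional fossa ROI [triangle_mesh()] (T0).
#' @return Object of class `tmj_case`.
#' @export
timepoint_case <- function(patient_id, timepoint, cranial, mandible,
                           landmarks, fossa_roi = NULL) {
  structure(list(patient_id = patient_id,
                 timepoint = match.arg(timepoint, c("T0", "T1", "T2", "T3")),
                 cranial = cranial, mandible = mandible,
                 landmarks = landmarks, fossa_roi = fossa_roi),
            class = "tmj_case")
}

#' Superimpose a follow-up case onto baseline and measure its joint space
#'
#' Computes the rigid transform mapping the case's cranial frame onto the T0
#' frame from the (N, PoR, Ba) landmark correspondences (least-squares,
#' no scaling), optionally refines it with ICP restricted to the cranial
#' region above the T0 mid-axial plane, applies it to the case's mandible,
#' and measures the joint space against the T0 fossa grid and reference
#' frame. Vgf in the result is the T0 Vgf (the fossa does not change).
#'
#' @param t0 The baseline [timepoint_case()] (with `fossa_roi`).
#' @param case The follow-up [timepoint_case()] (may be `t0` itself).
#' @param frame_t0 The T0 [build_reference_frame()] result.
#' @param side `"R"` or `"L"`.
#' @param h Voxel pitch (mm).
#' @param refine Run [icp_refine()] on the cranial meshes after the landmark
#'   fit.
#' @param fossa_grid Optional precomputed fossa grid from [compute_vgf()]
#'   (computed from `t0$fossa_roi` when absent).
#' @return A [joint_space_volumes()] object; the applied transform is
#'   attached as attribute `transform`.
#' @export
measure_timepoint <- function(t0, case, frame_t0, side = "R", h = 0.3,
                              refine = FALSE, fossa_grid = NULL) {
  stopifnot(inherits(t0, "tmj_case"), inherits(case, "tmj_case"),
            inherits(frame_t0, "tmj_frame"))
  if (is.null(fossa_grid)) {
    if (is.null(t0$fossa_roi)) stop("t0 case carries no fossa ROI")
    fossa_grid <- compute_vgf(t0$fossa_roi, frame_t0, side, h)$fossa_grid
  }
  anchor <- c("N", "PoR", "Ba")
  tf <- rigid_from_three_correspondences(
    landmark_matrix(case$landmarks, anchor),
    landmark_matrix(t0$landmarks, anchor))
  if (refine) {
    tf <- icp_refine(case$cranial, t0$cranial, init = tf,
                     region = frame_t0$MAP)
  }
  mand <- transform_mesh(case$mandible, tf)
  out <- compute_joint_space(fossa_grid, mand, frame_t0, side,
                             timepoint = case$timepoint)
  attr(out, "transform") <- tf
  out
}

#' Percent change relative to a baseline volume
#'
#' @param diff Difference (mm^3 or any consistent unit).
#' @param baseline Baseline value (> 0).
#' @return `100 * diff / baseline` (unrounded; tables round to 2 decimals).
#' @export
percent_change <- function(diff, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline must be positive", call. = FALSE)
  }
  100 * diff / baseline
}

#' Write joint-space volumes to CSV
#'
#' One row per measurement, columns `patient_id, side, timepoint, h_mm, Vgf,
#' Vjs, Vajs, Vpjs, Vmjs, Vljs`, volumes rounded to 2 decimals.
#'
#' @param volumes A [joint_space_volumes()] or list of them.
#' @param path Output CSV path.
#' @param patient_id Identifier column value(s).
#' @return `path`, invisibly.
#' @export
write_volumes_csv <- function(volumes, path, patient_id = "case") {
  if (inherits(volumes, "tmj_volumes")) volumes <- list(volumes)
  rows <- lapply(volumes, as.data.frame)
  df <- do.call(rbind, rows)
  df <- cbind(patient_id = rep(patient_id, length.out = nrow(df)), df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
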
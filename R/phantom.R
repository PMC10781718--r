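# Geometric phantom: half-ellipsoidal fossa capture region, ellipsoidal
# condylar head, analytically placed landmarks, per-visit scanner pose and a
# condylar sagging-then-partial-recovery displacement across T0-T3, plus an
# independent fine-grid analytic oracle for all six volumes.

# canonical landmark layout (mm): x = right(lateral), y = anterior,
# z = superior; mid-axial plane z = 0, mid-sagittal x = 0, coronal y = -22.
.phantom_layout <- function() {
  list(
    N = c(0, 80, 15), OrR = c(32, 62, 0), OrL = c(-32, 62, 0),
    PoR = c(55, -18, 0), PoL = c(-55, -18, 0),
    Ba = c(0, -22, -18), Cg = c(0, 55, 38),
    EmR = c(52, -8, 6), EmL = c(-52, -8, 6),
    fossa_center_R = c(47, -15, 6), fossa_center_L = c(-47, -15, 6),
    cranial_center = c(0, 15, 10), cranial_semi_axes = c(65, 80, 55),
    contact_offset = c(0, 0, -20))   # osteotomy contact point vs condyle center
}

#' Phantom specification
#'
#' The stated synthetic world: a half-ellipsoidal fossa capture region whose
#' equator sits on the eminence plane, an ellipsoidal condylar head inside
#' it, the eleven reference landmarks placed analytically on a canonical
#' skull layout, a condylar sag (anterior/medial/inferior translation plus an
#' optional rotation about the osteotomy contact point) at the day-3 visit
#' that partially recovers at 6 and 12 months, and a random rigid "scanner
#' pose" per visit so the superimposition chain is exercised.
#'
#' @param fossa_semi_axes Fossa ellipsoid semi-axes (a, b, c), mm; the
#'   above-eminence-plane half has closed-form volume `2/3 pi a b c`.
#' @param condyle_semi_axes Condylar head semi-axes (p, q, r), mm.
#' @param condyle_offset Condyle-center offset from the fossa center, mm, in
#'   the canonical (right-side) frame; mirrored across the mid-sagittal plane
#'   for the left side.
#' @param sag Named numeric: `anterior`, `medial`, `inferior` translation
#'   components (mm) of the condylar sag at T1.
#' @param sag_rotation_deg Rotation (degrees) about the anterior axis through
#'   the osteotomy contact point at T1 (0 = pure translation).
#' @param recovery Named numeric `c(T2 = rho2, T3 = rho3)`: fractions of the
#'   T1 displacement recovered at T2 and T3; `0 <= rho2 <= rho3 <= 1`.
#' @param pose_rot_deg,pose_trans_mm Maximum scanner-pose rotation/translation
#'   per visit.
#' @param landmark_jitter Standard deviation (mm) of optional landmark noise.
#' @param subdiv Icosphere subdivision for the generated meshes.
#' @param seed Integer seed fixing poses and jitter.
#' @return Object of class `tmj_phantom_spec`.
#' @export
phantom_spec <- function(fossa_semi_axes = c(10, 8, 6),
                         condyle_semi_axes = c(7, 5.5, 4.5),
                         condyle_offset = c(0, 0, 1),
                         sag = c(anterior = 1.5, medial = 1.0,
                                 inferior = 1.5),
                         sag_rotation_deg = 0,
                         recovery = c(T2 = 0.6, T3 = 0.6),
                         pose_rot_deg = 8, pose_trans_mm = 6,
                         landmark_jitter = 0,
                         subdiv = 4L, seed = 1L) {
  stopifnot(all(fossa_semi_axes > 0), all(condyle_semi_axes > 0))
  sag <- sag[c("anterior", "medial", "inferior")]
  if (anyNA(sag)) stop("sag needs anterior, medial and inferior components")
  r2 <- recovery[["T2"]]; r3 <- recovery[["T3"]]
  if (is.na(r2) || is.na(r3) || r2 < 0 || r3 < r2 || r3 > 1) {
    stop("recovery fractions must satisfy 0 <= T2 <= T3 <= 1", call. = FALSE)
  }
  spec <- structure(list(fossa_semi_axes = as.numeric(fossa_semi_axes),
                         condyle_semi_axes = as.numeric(condyle_semi_axes),
                         condyle_offset = .as_point3(condyle_offset),
                         sag = sag, sag_rotation_deg = sag_rotation_deg,
                         recovery = c(T2 = r2, T3 = r3),
                         pose_rot_deg = pose_rot_deg,
                         pose_trans_mm = pose_trans_mm,
                         landmark_jitter = landmark_jitter,
                         subdiv = as.integer(subdiv),
                         seed = as.integer(seed),
                         layout = .phantom_layout()),
                    class = "tmj_phantom_spec")
  # the condyle must engage the fossa capture region at baseline
  lay <- spec$layout
  cc <- lay$fossa_center_R + spec$condyle_offset
  fa <- spec$fossa_semi_axes
  if (sum(((cc - lay$fossa_center_R) / fa)^2) >= 1 ||
      cc[3] + spec$condyle_semi_axes[3] <= lay$EmR[3]) {
    stop("phantom spec error: condyle does not intersect the fossa capture region at T0",
         call. = FALSE)
  }
  spec
}

# displacement scale per timepoint: T1 full, T2/T3 partially recovered
.sag_fraction <- function(spec, timepoint) {
  switch(timepoint,
         T0 = 0, T1 = 1,
         T2 = 1 - spec$recovery[["T2"]],
         T3 = 1 - spec$recovery[["T3"]])
}

# rigid condylar displacement for one side at one timepoint, in canonical
# coordinates. medial = toward the mid-sagittal plane.
.condyle_displacement <- function(spec, timepoint, side) {
  f <- .sag_fraction(spec, timepoint)
  sgn <- if (side == "R") 1 else -1
  lay <- spec$layout
  tr <- f * c(-sgn * spec$sag[["medial"]], spec$sag[["anterior"]],
              -spec$sag[["inferior"]])
  cc <- lay[[paste0("fossa_center_", side)]]
  cc[1] <- cc[1]  # condyle center
  center <- cc + spec$condyle_offset * c(sgn, 1, 1)
  contact <- center + lay$contact_offset
  R <- rotation_about_axis(c(0, 1, 0), sgn * f * spec$sag_rotation_deg)
  rigid_transform(R, contact - drop(R %*% contact) + tr)
}

# random scanner pose from the current RNG stream
.random_pose <- function(rot_deg, trans_mm) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, -rot_deg, rot_deg)
  tr <- stats::runif(3, -trans_mm, trans_mm)
  rigid_transform(rotation_about_axis(ax, ang), tr)
}

#' Generate the four-timepoint phantom series
#'
#' Emits one [timepoint_case()] per visit: cranial shell, mandible (both
#' condylar heads, displaced per the sag/recovery schedule), the eleven
#' landmarks, and (on T0) the fossa ROI meshes per side — all moved by that
#' visit's random scanner pose. Ground truth is returned alongside: the
#' scanner poses, the true case-to-T0 superimposition transforms, and the
#' true condyle-to-T0 displacement per side expressed in T0 coordinates.
#'
#' @param spec A [phantom_spec()].
#' @return List with `cases` (named list T0..T3 of [timepoint_case()]),
#'   `fossa_roi` (list `R`, `L` of meshes in T0 coordinates),
#'   `poses`, `true_superimposition` (case to T0), and
#'   `true_condyle_transform` (per timepoint, list per side).
#' @export
make_phantom_series <- function(spec) {
  stopifnot(inherits(spec, "tmj_phantom_spec"))
  lay <- spec$layout
  set.seed(spec$seed)
  poses <- lapply(.tmj_timepoints, function(t)
    .random_pose(spec$pose_rot_deg, spec$pose_trans_mm))
  names(poses) <- .tmj_timepoints

  cranial0 <- mesh_ellipsoid(lay$cranial_semi_axes, lay$cranial_center,
                             subdiv = 2L)
  lm_names <- c("N", "OrR", "OrL", "PoR", "PoL", "Ba", "Cg",
                "EmR", "EmL")
  lm0 <- lay[lm_names]
  lm0$GfR <- lay$fossa_center_R + c(0, 0, spec$fossa_semi_axes[3])
  lm0$GfL <- lay$fossa_center_L + c(0, 0, spec$fossa_semi_axes[3])

  condyle0 <- function(side) {
    sgn <- if (side == "R") 1 else -1
    mesh_ellipsoid(spec$condyle_semi_axes,
                   lay[[paste0("fossa_center_", side)]] +
                     spec$condyle_offset * c(sgn, 1, 1),
                   subdiv = spec$subdiv)
  }
  cR0 <- condyle0("R"); cL0 <- condyle0("L")
  roi0 <- list(
    R = mesh_ellipsoid(spec$fossa_semi_axes, lay$fossa_center_R,
                       subdiv = spec$subdiv),
    L = mesh_ellipsoid(spec$fossa_semi_axes, lay$fossa_center_L,
                       subdiv = spec$subdiv))

  cases <- list()
  true_cond <- list()
  for (t in .tmj_timepoints) {
    P <- poses[[t]]
    dR <- .condyle_displacement(spec, t, "R")
    dL <- .condyle_displacement(spec, t, "L")
    mand <- merge_meshes(transform_mesh(cR0, dR), transform_mesh(cL0, dL))
    lm_t <- lm0
    if (spec$landmark_jitter > 0) {
      lm_t <- lapply(lm_t, function(p)
        p + stats::rnorm(3, 0, spec$landmark_jitter))
    }
    lm_case <- transform_landmarks(landmark_set(lm_t), P)
    cases[[t]] <- timepoint_case(
      patient_id = "phantom", timepoint = t,
      cranial = transform_mesh(cranial0, P),
      mandible = transform_mesh(mand, P),
      landmarks = lm_case,
      fossa_roi = if (t == "T0") transform_mesh(roi0$R, P) else NULL)
    P0 <- poses[["T0"]]
    true_cond[[t]] <- list(
      R = compose_rigid(P0, compose_rigid(dR, invert_rigid(P0))),
      L = compose_rigid(P0, compose_rigid(dL, invert_rigid(P0))))
  }
  true_sup <- lapply(poses, function(P)
    compose_rigid(poses[["T0"]], invert_rigid(P)))
  list(cases = cases,
       fossa_roi = list(R = transform_mesh(roi0$R, poses[["T0"]]),
                        L = transform_mesh(roi0$L, poses[["T0"]])),
       poses = poses,
       true_superimposition = true_sup,
       true_condyle_transform = true_cond,
       spec = spec)
}

#' Independent fine-grid oracle for the phantom volumes
#'
#' Recomputes all six volumes for one phantom timepoint by brute force on a
#' fine lattice, using the analytic implicit surfaces (ellipsoid membership
#' inequalities and exact plane coordinates of the canonical layout) instead
#' of the pipeline's meshes, voxel grids and ray-parity test. Traversal is
#' slab-by-slab in z. Serves as the derived-value generator for volumetry
#' tests.
#'
#' @param spec A [phantom_spec()].
#' @param timepoint `"T0"`..`"T3"`.
#' @param h_fine Lattice pitch (mm); should be at most half the pipeline's
#'   voxel pitch.
#' @param side `"R"` or `"L"`.
#' @return A [joint_space_volumes()] object.
#' @export
oracle_volumes <- function(spec, timepoint = "T0", h_fine = 0.1,
                           side = "R") {
  stopifnot(inherits(spec, "tmj_phantom_spec"))
  side <- match.arg(side, c("R", "L"))
  lay <- spec$layout
  fc <- lay[[paste0("fossa_center_", side)]]
  fa <- spec$fossa_semi_axes
  ca <- spec$condyle_semi_axes
  z_em <- lay[[paste0("Em", side)]][3]
  D <- .condyle_displacement(spec, timepoint, side)
  Dinv <- invert_rigid(D)
  sgn <- if (side == "R") 1 else -1
  cc <- fc + spec$condyle_offset * c(sgn, 1, 1)

  xs <- seq(fc[1] - fa[1] + h_fine / 2, fc[1] + fa[1], by = h_fine)
  ys <- seq(fc[2] - fa[2] + h_fine / 2, fc[2] + fa[2], by = h_fine)
  zs <- seq(z_em + h_fine / 2, fc[3] + fa[3], by = h_fine)
  xg <- rep(xs, times = length(ys))
  yg <- rep(ys, each = length(xs))
  n_gf <- 0; n_js <- 0; n_a <- 0; n_l <- 0
  for (z in zs) {
    in_fossa <- ((xg - fc[1]) / fa[1])^2 + ((yg - fc[2]) / fa[2])^2 +
      ((z - fc[3]) / fa[3])^2 < 1
    if (!any(in_fossa)) next
    fx <- xg[in_fossa]; fy <- yg[in_fossa]
    n_gf <- n_gf + length(fx)
    q <- apply_rigid(Dinv, cbind(fx, fy, z))
    in_cond <- ((q[, 1] - cc[1]) / ca[1])^2 + ((q[, 2] - cc[2]) / ca[2])^2 +
      ((q[, 3] - cc[3]) / ca[3])^2 < 1
    jx <- fx[!in_cond]; jy <- fy[!in_cond]
    n_js <- n_js + length(jx)
    n_a <- n_a + sum(jy >= fc[2])           # anterior of GfCP (ties anterior)
    n_l <- n_l + sum(sgn * (jx - fc[1]) > 0)  # lateral of GfSP (ties medial)
  }
  if (n_gf == 0) stop("empty-fossa error: oracle found no volume above EmP")
  h3 <- h_fine^3
  joint_space_volumes(Vgf = n_gf * h3, Vjs = n_js * h3,
                      Vajs = n_a * h3, Vpjs = (n_js - n_a) * h3,
                      Vmjs = (n_js - n_l) * h3, Vljs = n_l * h3,
                      side = side, timepoint = timepoint, h = h_fine)
}
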
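test_that("phantom generation is seed-deterministic", {
  a <- make_phantom_series(phantom_spec(seed = 12))
  b <- make_phantom_series(phantom_spec(seed = 12))
  expect_identical(a$cases$T2$mandible$vertices, b$cases$T2$mandible$vertices)
  expect_identical(unclass(a$cases$T1$landmarks),
                   unclass(b$cases$T1$landmarks))
  c2 <- make_phantom_series(phantom_spec(seed = 13))
  expect_false(identical(a$cases$T0$cranial$vertices,
                         c2$cases$T0$cranial$vertices))
})

test_that("phantom spec validation", {
  expect_error(phantom_spec(fossa_semi_axes = c(-1, 8, 6)))
  expect_error(phantom_spec(recovery = c(T2 = 0.8, T3 = 0.4)),
               "recovery fractions")
  expect_error(phantom_spec(recovery = c(T2 = 0.2, T3 = 1.4)),
               "recovery fractions")
  # condyle pushed far out of the fossa: spec error
  expect_error(phantom_spec(condyle_offset = c(0, 0, -30)),
               "does not intersect")
})

test_that("superimposition chain recovers the ground-truth poses", {
  fx <- phantom_fixture()
  for (t in c("T1", "T2", "T3")) {
    est <- attr(fx$vols[[t]], "transform")
    truth <- fx$series$true_superimposition[[t]]
    # compare action on the landmark anchors: within 0.05 mm
    pts <- landmark_matrix(fx$series$cases[[t]]$landmarks,
                           c("N", "PoR", "Ba"))
    expect_lt(max(abs(apply_rigid(est, pts) - apply_rigid(truth, pts))),
              0.05)
    ang <- rotation_angle_deg(t(truth$rotation) %*% est$rotation)
    expect_lt(ang, 0.1)
  }
})

test_that("default phantom reproduces the sagging time-course signature", {
  fx <- phantom_fixture()
  v <- fx$vols
  # day-3 peak in every compartment
  for (nm in c("Vjs", "Vajs", "Vpjs", "Vmjs", "Vljs")) {
    expect_gt(v$T1[[nm]], v$T0[[nm]])
    expect_gt(v$T1[[nm]], v$T2[[nm]])
  }
  # plateau: equal recovery fractions at T2 and T3
  expect_lt(abs(v$T2$Vjs - v$T3$Vjs), 0.01 * v$T2$Vjs)
  # posterior and lateral stay elevated at 12 months
  expect_gt(v$T3$Vpjs, v$T0$Vpjs + 0.05 * v$T0$Vpjs)
  expect_gt(v$T3$Vljs, v$T0$Vljs + 0.05 * v$T0$Vljs)
  # anterior returns near baseline: residual change is small vs posterior's
  expect_lt(abs(v$T3$Vajs - v$T0$Vajs), 0.3 * (v$T3$Vpjs - v$T0$Vpjs))
  expect_lt(abs(v$T3$Vmjs - v$T0$Vmjs), 0.5 * (v$T3$Vljs - v$T0$Vljs))
  # and overall Vjs remains above baseline
  expect_gt(v$T3$Vjs, v$T0$Vjs)
})

test_that("zero-sag phantom measures flat across all four visits", {
  spec0 <- phantom_spec(sag = c(anterior = 0, medial = 0, inferior = 0),
                        recovery = c(T2 = 1, T3 = 1), seed = 6)
  ser0 <- make_phantom_series(spec0)
  fr <- build_reference_frame(ser0$cases$T0$landmarks)
  g <- compute_vgf(ser0$cases$T0$fossa_roi, fr, "R", h = 0.3)
  vols <- lapply(ser0$cases, function(cs)
    measure_timepoint(ser0$cases$T0, cs, fr, side = "R", h = 0.3,
                      fossa_grid = g$fossa_grid))
  ref <- vol6(vols$T0)
  for (t in c("T1", "T2", "T3")) {
    expect_lt(max(abs(vol6(vols[[t]]) - ref)), 0.005 * ref[["Vjs"]])
  }
})

test_that("oracle agrees with the pipeline and with closed forms", {
  fx <- phantom_fixture()
  for (t in c("T0", "T1")) {
    o <- oracle_volumes(fx$spec, t, h_fine = 0.1)
    p <- fx$vols[[t]]
    for (nm in c("Vgf", "Vjs", "Vajs", "Vpjs", "Vmjs", "Vljs")) {
      expect_lt(abs(o[[nm]] - p[[nm]]) / max(o[[nm]], 1), 0.01)
    }
    # additivity holds exactly in the oracle too
    expect_equal(o$Vajs + o$Vpjs, o$Vjs, tolerance = 1e-12)
    expect_equal(o$Vmjs + o$Vljs, o$Vjs, tolerance = 1e-12)
  }
  # the capture region itself matches the half-ellipsoid closed form
  exact <- 2 / 3 * pi * prod(fx$spec$fossa_semi_axes)
  o0 <- oracle_volumes(fx$spec, "T0", h_fine = 0.1)
  expect_lt(abs(o0$Vgf - exact) / exact, 0.01)

  # directional oracle: pure anterior sag raises Vpjs, lowers Vajs
  spA <- phantom_spec(sag = c(anterior = 1.5, medial = 0, inferior = 0))
  oA0 <- oracle_volumes(spA, "T0", h_fine = 0.15)
  oA1 <- oracle_volumes(spA, "T1", h_fine = 0.15)
  expect_gt(oA1$Vpjs, oA0$Vpjs)
  expect_lt(oA1$Vajs, oA0$Vajs)
})

test_that("left side and sag rotation are handled", {
  sp <- phantom_spec(sag_rotation_deg = 3, seed = 17)
  sr <- make_phantom_series(sp)
  fr <- build_reference_frame(sr$cases$T0$landmarks)
  gL <- compute_vgf(sr$fossa_roi$L, fr, "L", h = 0.4)
  jsL0 <- compute_joint_space(gL$fossa_grid,
                              transform_mesh(sr$cases$T0$mandible,
                                             sr$true_superimposition$T0),
                              fr, "L", "T0")
  oL0 <- oracle_volumes(sp, "T0", h_fine = 0.2, side = "L")
  expect_lt(abs(jsL0$Vjs - oL0$Vjs) / oL0$Vjs, 0.02)
  # rotation is part of the ground-truth transform
  tt <- sr$true_condyle_transform$T1$R
  expect_gt(rotation_angle_deg(tt$rotation), 2.5)
})
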
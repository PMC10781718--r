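test_that("compute_vgf matches the half-ellipsoid closed form", {
  fx <- phantom_fixture()
  # default phantom fossa: semi-axes (10, 8, 6) centered on EmP
  exact <- 2 / 3 * pi * prod(fx$spec$fossa_semi_axes)
  vg <- compute_vgf(fx$series$cases$T0$fossa_roi, fx$frame, "R", h = 0.25)
  expect_lt(abs(vg$Vgf - exact) / exact, 0.01)

  # halving h changes Vgf by < 1 %
  vg6 <- compute_vgf(fx$series$cases$T0$fossa_roi, fx$frame, "R", h = 0.6)
  expect_lt(abs(vg6$Vgf - fx$vgf$Vgf) / fx$vgf$Vgf, 0.01)

  # ROI entirely below the eminence plane: empty-fossa error
  low <- mesh_ellipsoid(c(5, 5, 3), center = c(47, -15, -40), subdiv = 2)
  low <- transform_mesh(low, fx$series$poses$T0)
  expect_error(compute_vgf(low, fx$frame, "R", h = 0.5), "empty-fossa")
})

test_that("compute_joint_space: condyle removal, partition, additivity", {
  fx <- phantom_fixture()
  grid <- fx$vgf$fossa_grid
  h <- grid$h

  # mandible far from the fossa: Vjs = Vgf and partitions cover it
  far <- mesh_icosphere(4, subdiv = 2, center = c(0, 0, -300))
  js_far <- compute_joint_space(grid, far, fx$frame, "R")
  expect_equal(js_far$Vjs, js_far$Vgf)
  # exact voxel partition (equality up to one ulp of the float sum)
  expect_equal(js_far$Vajs + js_far$Vpjs, js_far$Vjs, tolerance = 1e-12)
  expect_equal(js_far$Vmjs + js_far$Vljs, js_far$Vjs, tolerance = 1e-12)

  # symmetric fossa with no condyle: GfCP and GfSP split it near-evenly
  expect_lt(abs(js_far$Vajs - js_far$Vpjs) / js_far$Vjs, 0.01)
  expect_lt(abs(js_far$Vmjs - js_far$Vljs) / js_far$Vjs, 0.01)

  # sphere of radius 4 fully inside the above-EmP fossa: closed-form removal
  # (needs a fossa taller than the ball, so use a 12 x 10 x 9 capture region)
  sp2 <- phantom_spec(fossa_semi_axes = c(12, 10, 9), seed = 8)
  sr2 <- make_phantom_series(sp2)
  fr2 <- build_reference_frame(sr2$cases$T0$landmarks)
  ball <- mesh_icosphere(4, subdiv = 4,
                         center = apply_rigid(sr2$poses$T0, c(47, -15, 10.5)))
  vg25 <- compute_vgf(sr2$fossa_roi$R, fr2, "R", h = 0.25)
  js_ball <- compute_joint_space(vg25$fossa_grid, ball, fr2, "R")
  expected <- vg25$Vgf - 4 / 3 * pi * 64
  expect_lt(abs(js_ball$Vjs - expected) / expected, 0.015)

  # nestedness at the fixture resolution too
  for (v in fx$vols) {
    expect_lte(v$Vjs, v$Vgf)
    expect_equal(v$Vajs + v$Vpjs, v$Vjs, tolerance = 1e-12)
    expect_equal(v$Vmjs + v$Vljs, v$Vjs, tolerance = 1e-12)
  }
})

test_that("measure_timepoint: identity, equivariance, condylar sag response", {
  fx <- phantom_fixture()
  t0case <- fx$series$cases$T0

  # identity superimposition reproduces the T0 measurement bitwise
  again <- measure_timepoint(t0case, t0case, fx$frame, side = "R", h = 0.3,
                             fossa_grid = fx$vgf$fossa_grid)
  expect_identical(vol6(again), vol6(fx$vols$T0))

  # whole-head rigid motion (zero sag, full recovery irrelevant): volumes are
  # unchanged within a sliver of one voxel layer
  spec0 <- phantom_spec(sag = c(anterior = 0, medial = 0, inferior = 0),
                        seed = 4)
  ser0 <- make_phantom_series(spec0)
  fr0 <- build_reference_frame(ser0$cases$T0$landmarks)
  g0 <- compute_vgf(ser0$cases$T0$fossa_roi, fr0, "R", h = 0.3)
  v0 <- vapply(ser0$cases, function(cs)
    measure_timepoint(ser0$cases$T0, cs, fr0, side = "R", h = 0.3,
                      fossa_grid = g0$fossa_grid)$Vjs, numeric(1))
  expect_lt(max(v0) - min(v0), 0.005 * v0[["T0"]])

  # pure inferior condylar translation monotonically opens the joint space
  vjs <- numeric(0)
  for (delta in c(0, 1, 2)) {
    sp <- phantom_spec(sag = c(anterior = 0, medial = 0, inferior = delta),
                       seed = 4)
    sr <- make_phantom_series(sp)
    fr <- build_reference_frame(sr$cases$T0$landmarks)
    gg <- compute_vgf(sr$cases$T0$fossa_roi, fr, "R", h = 0.3)
    vjs <- c(vjs, measure_timepoint(sr$cases$T0, sr$cases$T1, fr, side = "R",
                                    h = 0.3, fossa_grid = gg$fossa_grid)$Vjs)
  }
  expect_true(all(diff(vjs) > 0))

  # anterior translation: condyle vacates the posterior compartment
  spA <- phantom_spec(sag = c(anterior = 1.5, medial = 0, inferior = 0),
                      seed = 4)
  srA <- make_phantom_series(spA)
  frA <- build_reference_frame(srA$cases$T0$landmarks)
  gA <- compute_vgf(srA$cases$T0$fossa_roi, frA, "R", h = 0.3)
  m <- function(cs) measure_timepoint(srA$cases$T0, cs, frA, side = "R",
                                      h = 0.3, fossa_grid = gA$fossa_grid)
  a0 <- m(srA$cases$T0); a1 <- m(srA$cases$T1)
  expect_gt(a1$Vpjs, a0$Vpjs)
  expect_lt(a1$Vajs, a0$Vajs)
})

test_that("percent_change matches the published worked examples", {
  expect_equal(round(percent_change(134.54, 1110.99), 2), 12.11)
  expect_equal(round(percent_change(283.12, 544.10), 2), 52.03)
  expect_equal(percent_change(0, 500), 0)
  expect_error(percent_change(10, 0), "positive")
  expect_error(percent_change(10, -5), "positive")
})

test_that("volumes CSV output has the documented columns and rounding", {
  fx <- phantom_fixture()
  f <- tempfile(fileext = ".csv")
  write_volumes_csv(fx$vols, f, patient_id = "phantom")
  df <- read.csv(f)
  expect_equal(names(df), c("patient_id", "side", "timepoint", "h_mm",
                            "Vgf", "Vjs", "Vajs", "Vpjs", "Vmjs", "Vljs"))
  expect_equal(nrow(df), 4)
  expect_equal(df$Vjs, round(vapply(fx$vols, `[[`, 0, "Vjs"), 2),
               ignore_attr = TRUE)
})
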
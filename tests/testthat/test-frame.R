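test_that("canonical layout produces the axis-aligned frame", {
  fr <- build_reference_frame(canonical_landmarks())
  expect_equal(fr$MAP$normal, c(0, 0, 1), tolerance = 1e-12)   # superior to Cg
  expect_equal(abs(fr$MSP$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$COP$normal, c(0, 1, 0), tolerance = 1e-12)   # anterior to N
  expect_equal(abs(signed_distance(fr$COP, c(0, -50, 3))), 0, tolerance = 1e-12)
  expect_equal(fr$superior, c(0, 0, 1))
  expect_equal(fr$anterior, c(0, 1, 0))
  expect_equal(fr$lateral_R, c(1, 0, 0))
  expect_equal(fr$lateral_L, c(-1, 0, 0))
  # side planes pass through their anchors
  lm <- canonical_landmarks()
  expect_equal(signed_distance(fr$EmP_R, lm$EmR), 0, tolerance = 1e-12)
  expect_equal(signed_distance(fr$GfSP_R, lm$GfR), 0, tolerance = 1e-12)
  expect_equal(signed_distance(fr$GfCP_R, lm$GfR), 0, tolerance = 1e-12)
  expect_equal(signed_distance(fr$GfSP_L, lm$GfL), 0, tolerance = 1e-12)
})

test_that("frame invariants: orthogonality, parallelism, unit vectors", {
  set.seed(21)
  for (i in 1:10) {
    tf <- random_rigid()
    lm <- transform_landmarks(canonical_landmarks(), tf)
    fr <- build_reference_frame(lm)
    dot <- function(a, b) abs(sum(a$normal * b$normal))
    expect_lt(dot(fr$MAP, fr$MSP), 1e-9)
    expect_lt(dot(fr$MAP, fr$COP), 1e-9)
    expect_lt(dot(fr$MSP, fr$COP), 1e-9)
    expect_equal(fr$EmP_R$normal, fr$MAP$normal, tolerance = 1e-12)
    expect_equal(fr$GfCP_R$normal, fr$COP$normal, tolerance = 1e-12)
    expect_equal(abs(sum(fr$GfSP_R$normal * fr$MSP$normal)), 1,
                 tolerance = 1e-9)
    for (v in list(fr$superior, fr$anterior, fr$lateral_R, fr$lateral_L)) {
      expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
    }
  }
})

test_that("frame construction is equivariant under rigid motion", {
  set.seed(5)
  lm0 <- canonical_landmarks()
  fr0 <- build_reference_frame(lm0)
  for (i in 1:5) {
    tf <- random_rigid()
    fr1 <- build_reference_frame(transform_landmarks(lm0, tf))
    for (nm in c("MAP", "MSP", "COP", "EmP_R", "EmP_L",
                 "GfSP_R", "GfSP_L", "GfCP_R", "GfCP_L")) {
      ex <- tmjvol:::transform_plane(tf, fr0[[nm]])
      got <- fr1[[nm]]
      expect_lt(max(abs(got$normal - ex$normal)), 1e-8)
      expect_lt(abs(signed_distance(got, ex$point)), 1e-8)
    }
    expect_lt(max(abs(fr1$superior - drop(tf$rotation %*% fr0$superior))),
              1e-8)
  }
})

test_that("degenerate landmark configurations raise named errors", {
  lm <- unclass(canonical_landmarks())
  lm$OrL <- lm$OrR
  expect_error(landmark_set(lm), "OrR/OrL")
  lm2 <- unclass(canonical_landmarks())
  lm2$PoR <- c(0, 40, 0)   # collinear-ish with OrR/OrL? make truly collinear
  lm2$OrR <- c(30, 40, 0); lm2$OrL <- c(-30, 40, 0); lm2$PoR <- c(60, 40, 0)
  expect_error(build_reference_frame(landmark_set(lm2)), "OrR/OrL/PoR")
  expect_error(landmark_set(N = c(0, 0, 0)), "missing landmarks")
})

test_that("landmark JSON I/O is strict and round-trips", {
  lm <- canonical_landmarks()
  f <- tempfile(fileext = ".json")
  write_landmarks_json(lm, f)
  back <- read_landmarks_json(f)
  expect_equal(unclass(back), unclass(lm))
  # unknown keys rejected
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$Bogus <- c(1, 2, 3)
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2)
  expect_error(read_landmarks_json(f2), "unknown landmarks")
  # frame export runs and contains all planes
  fr <- build_reference_frame(lm)
  f3 <- tempfile(fileext = ".json")
  write_frame_json(fr, f3)
  out <- jsonlite::read_json(f3, simplifyVector = TRUE)
  expect_true(all(c("MAP", "MSP", "COP", "GfCP_L", "superior") %in%
                    names(out)))
})

test_that("prognathism rule: signed anterior distance with strict 1 mm cut", {
  ceph <- ceph_landmarks(porion = c(0, 0), orbitale = c(80, 0),
                         nasion = c(70, 40), pogonion = c(72, -60))
  d <- diagnose_prognathism(ceph)
  expect_equal(d$distance_mm, 2.0)
  expect_true(d$prognathism)

  on_line <- diagnose_prognathism(ceph_landmarks(
    c(0, 0), c(80, 0), c(70, 40), c(70, -55)))
  expect_equal(on_line$distance_mm, 0)
  expect_false(on_line$prognathism)

  # exactly 1 mm anterior: NOT prognathism (strict inequality)
  at1 <- diagnose_prognathism(ceph_landmarks(
    c(0, 0), c(80, 0), c(70, 40), c(71, -55)))
  expect_equal(at1$distance_mm, 1.0)
  expect_false(at1$prognathism)

  # tilted FH line: distance is measured along FH, not along x
  tilt <- diagnose_prognathism(ceph_landmarks(
    c(0, 0), c(80, 80), c(0, 40), sqrt(2) * c(20, 20) + c(20, -20)))
  expect_equal(tilt$distance_mm,
               sum((sqrt(2) * c(20, 20) + c(20, -20) - c(0, 40)) *
                     c(1, 1) / sqrt(2)))

  expect_error(ceph_landmarks(c(0, 0), c(0, 0), c(1, 1), c(2, 2)),
               "degenerate")
})
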
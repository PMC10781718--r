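# Shared fixtures, built in code. Expensive phantom/grid objects are computed
# once per test run and reused read-only across files.

# canonical axis-aligned landmark layout used by the frame tests
canonical_landmarks <- function() {
  landmark_set(
    N = c(0, 60, 10),
    OrR = c(30, 40, 0), OrL = c(-30, 40, 0),
    PoR = c(40, -40, 0), PoL = c(-40, -40, 0),
    Ba = c(0, -50, -10), Cg = c(0, 50, 20),
    EmR = c(35, -20, 5), EmL = c(-35, -20, 5),
    GfR = c(40, -30, 8), GfL = c(-40, -30, 8))
}

random_rigid <- function() {
  rigid_transform(rotation_about_axis(stats::rnorm(3),
                                      stats::runif(1, -180, 180)),
                  stats::rnorm(3, 0, 20))
}

# default phantom pipeline objects at h = 0.3, shared across tests
.fix <- new.env()
phantom_fixture <- function() {
  if (is.null(.fix$series)) {
    spec <- phantom_spec()
    series <- make_phantom_series(spec)
    frame <- build_reference_frame(series$cases$T0$landmarks)
    vgf <- compute_vgf(series$cases$T0$fossa_roi, frame, "R", h = 0.3)
    vols <- lapply(series$cases, function(cs)
      measure_timepoint(series$cases$T0, cs, frame, side = "R", h = 0.3,
                        fossa_grid = vgf$fossa_grid))
    .fix$series <- list(spec = spec, series = series, frame = frame,
                        vgf = vgf, vols = vols)
  }
  .fix$series
}

# independent long-format null/complete record builder used by stats tests
make_records <- function(n, mu, S, seed, outcome = "Vjs") {
  set.seed(seed)
  Y <- tmjvol:::.rmvn(n, mu, S)
  data.frame(patient_id = rep(sprintf("P%03d", seq_len(n)), 4),
             joint_id = rep(sprintf("J%03d", seq_len(n)), 4),
             timepoint = rep(c("T0", "T1", "T2", "T3"), each = n),
             outcome = outcome, value_mm3 = as.vector(Y))
}

vol6 <- function(v) unlist(v[c("Vgf", "Vjs", "Vajs", "Vpjs", "Vmjs", "Vljs")])
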
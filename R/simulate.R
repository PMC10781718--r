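# Longitudinal record simulator: per-joint 4-visit multivariate-normal
# outcomes with a shared patient-level component and the cohort's T1
# missingness structure (a subset of patients scanned at day 3).

#' Simulation specification for longitudinal volume records
#'
#' Defaults emulate the reference cohort: 35 patients x 2 joints, the five
#' joint-space outcomes with the published per-visit means, and T1 observed
#' for 19 of 35 patients. Per-visit standard deviations default to
#' `se * sqrt(70)` (the SE of a mean of 70 joints under independence — an
#' approximation, since the published SEs are model-based), with an
#' exchangeable between-visit correlation.
#'
#' @param outcomes Named list; each element has `means` (length-4) and
#'   `cov` (4x4 PSD). Defaults built from [tovro_reference_volumes()].
#' @param n_patients Number of patients (default 35).
#' @param joints_per_patient Joints per patient (default 2).
#' @param t1_observed Number of patients with an observed T1 visit
#'   (default 19).
#' @param between_side_correlation Correlation of a patient's two joints at
#'   each visit, realised as a shared patient-level component (default 0.5).
#' @param visit_correlation Exchangeable between-visit correlation used for
#'   the default covariances (default 0.6).
#' @param missing_mechanism `"mcar"` (drop T1 for a random patient subset) or
#'   `"baseline"` (drop T1 for the patients with the highest T0 values of the
#'   first outcome — a missing-at-random mechanism for MAR tests).
#' @param seed Integer seed; fixes everything.
#' @return Object of class `tmj_sim_spec`.
#' @export
sim_spec <- function(outcomes = NULL, n_patients = 35L,
                     joints_per_patient = 2L, t1_observed = 19L,
                     between_side_correlation = 0.5,
                     visit_correlation = 0.6,
                     missing_mechanism = c("mcar", "baseline"),
                     seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (is.null(outcomes)) {
    ref <- tovro_reference_volumes()
    n_joints <- n_patients * joints_per_patient
    outcomes <- lapply(split(ref, ref$outcome), function(d) {
      d <- d[match(.tmj_timepoints, d$time), ]
      sd <- d$se * sqrt(70)
      R <- (1 - visit_correlation) * diag(4) + visit_correlation
      list(means = stats::setNames(d$mean, .tmj_timepoints),
           cov = outer(sd, sd) * R)
    })
    outcomes <- outcomes[intersect(.tmj_outcomes, names(outcomes))]
  }
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (length(o$means) != 4L) stop("means must have length 4")
    ev <- eigen((o$cov + t(o$cov)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("covariance for ", nm, " is not positive semi-definite",
           call. = FALSE)
    }
  }
  if (t1_observed < 0 || t1_observed > n_patients) {
    stop("t1_observed must be between 0 and n_patients", call. = FALSE)
  }
  if (between_side_correlation < 0 || between_side_correlation > 1) {
    stop("between_side_correlation must be in [0, 1]", call. = FALSE)
  }
  structure(list(outcomes = outcomes, n_patients = as.integer(n_patients),
                 joints_per_patient = as.integer(joints_per_patient),
                 t1_observed = as.integer(t1_observed),
                 between_side_correlation = between_side_correlation,
                 missing_mechanism = missing_mechanism,
                 seed = as.integer(seed)),
            class = "tmj_sim_spec")
}

# PSD-tolerant multivariate normal draws (n x d)
.rmvn <- function(n, mu, S) {
  d <- length(mu)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(stats::rnorm(n * d), n, d) %*% rt +
    matrix(mu, n, d, byrow = TRUE)
}

#' Simulate longitudinal volume records
#'
#' Draws per-joint 4-visit outcome vectors from a multivariate normal with
#' the spec's means and covariance, decomposed into a patient-level shared
#' component (fraction `between_side_correlation` of the covariance) plus an
#' independent joint-level component, then deletes the T1 rows of the
#' unobserved patients. Fully reproducible from `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return Long-format records data.frame (see [longitudinal_records()]).
#' @export
simulate_longitudinal_records <- function(spec) {
  stopifnot(inherits(spec, "tmj_sim_spec"))
  set.seed(spec$seed)
  np <- spec$n_patients; jp <- spec$joints_per_patient
  nj <- np * jp
  rho <- spec$between_side_correlation
  pid <- sprintf("P%02d", seq_len(np))
  side_lab <- if (jp == 2L) c("R", "L") else sprintf("J%d", seq_len(jp))
  jid <- as.vector(t(outer(pid, side_lab, paste, sep = "_")))
  jpat <- rep(pid, each = jp)
  out <- list()
  first_t0 <- NULL
  for (nm in names(spec$outcomes)) {
    o <- spec$outcomes[[nm]]
    shared <- .rmvn(np, rep(0, 4), rho * o$cov)[rep(seq_len(np), each = jp), ,
                                                drop = FALSE]
    own <- .rmvn(nj, rep(0, 4), (1 - rho) * o$cov)
    Y <- shared + own + matrix(o$means, nj, 4, byrow = TRUE)
    colnames(Y) <- .tmj_timepoints
    if (is.null(first_t0)) first_t0 <- tapply(Y[, "T0"], jpat, mean)
    out[[nm]] <- data.frame(
      patient_id = rep(jpat, times = 4L),
      joint_id = rep(jid, times = 4L),
      timepoint = rep(.tmj_timepoints, each = nj),
      outcome = nm,
      value_mm3 = as.vector(Y))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  n_missing <- np - spec$t1_observed
  if (n_missing > 0L) {
    drop_pat <- if (spec$missing_mechanism == "mcar") {
      sample(pid, n_missing)
    } else {
      names(sort(first_t0, decreasing = TRUE))[seq_len(n_missing)]
    }
    df <- df[!(df$timepoint == "T1" & df$patient_id %in% drop_pat), ,
             drop = FALSE]
  }
  longitudinal_records(df)
}
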
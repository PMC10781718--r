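# Repeated-measures time-course model: cell means per visit, unstructured
# within-joint covariance over the four visits, REML estimation with all
# available observations (missing-at-random likelihood), pairwise contrasts
# with Bonferroni adjustment, and table rendering.

.tmj_timepoints <- c("T0", "T1", "T2", "T3")
.tmj_outcomes <- c("Vjs", "Vajs", "Vpjs", "Vmjs", "Vljs")

#' Validate long-format longitudinal volume records
#'
#' Expected columns: `patient_id`, `joint_id`, `timepoint` (T0..T3),
#' `outcome`, `value_mm3`. Rows for unobserved visits are simply absent.
#'
#' @param records A data.frame of records.
#' @return The validated data.frame (invisibly classed `tmj_records`).
#' @export
longitudinal_records <- function(records) {
  req <- c("patient_id", "joint_id", "timepoint", "outcome", "value_mm3")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$timepoint %in% .tmj_timepoints)) {
    stop("timepoint must be one of ", paste(.tmj_timepoints, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(records$joint_id, records$timepoint, records$outcome)
  if (anyDuplicated(key)) {
    stop("duplicate (joint, timepoint, outcome) record", call. = FALSE)
  }
  class(records) <- unique(c("tmj_records", "data.frame", class(records)))
  invisible(records)
}

#' Read/write long-format volume records
#'
#' @param path CSV path with columns `patient_id, joint_id, timepoint,
#'   outcome, value_mm3`.
#' @return A validated records data.frame.
#' @export
read_records_csv <- function(path) {
  longitudinal_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_records_csv
#' @param records Records data.frame.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(unclass(records))[
    , c("patient_id", "joint_id", "timepoint", "outcome", "value_mm3")],
    path, row.names = FALSE)
  invisible(path)
}

# records -> list(Y = joints x 4 matrix with NA, patient = patient per joint)
.records_wide <- function(records, outcome) {
  r <- records[records$outcome == outcome, , drop = FALSE]
  if (nrow(r) == 0L) stop("no records for outcome ", outcome, call. = FALSE)
  joints <- sort(unique(r$joint_id))
  Y <- matrix(NA_real_, length(joints), 4L,
              dimnames = list(joints, .tmj_timepoints))
  Y[cbind(match(r$joint_id, joints), match(r$timepoint, .tmj_timepoints))] <-
    r$value_mm3
  pat <- r$patient_id[match(joints, r$joint_id)]
  list(Y = Y, patient = pat)
}

# lower-triangular log-Cholesky <-> covariance
.theta_to_sigma <- function(theta, d = 4L) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- 0
  diag(L) <- exp(theta[seq_len(d)])
  L[lower.tri(L)] <- theta[-seq_len(d)]
  tcrossprod(L)
}

.sigma_to_theta <- function(S) {
  L <- t(chol(S))
  c(log(diag(L)), L[lower.tri(L)])
}

# pairwise-complete covariance, floored to positive definite
.start_sigma <- function(Y) {
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  mu <- colMeans(Y, na.rm = TRUE)
  S[is.na(S)] <- 0
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  floorv <- max(mean(diag(S)), 1e-6) * 1e-4
  e$values <- pmax(e$values, floorv)
  e$vectors %*% (e$values * t(e$vectors))
}

# Negative REML criterion and GLS pieces for the marginal model.
# units: list of list(obs = integer idx into 1:4 per joint (possibly stacked
# over a patient's joints), y = observed values, key = pattern key).
# Returns -2 * restricted log-likelihood (up to constant) or the GLS fit.
.reml_pieces <- function(theta, units, d = 4L, patient_effect = FALSE,
                         fit = FALSE) {
  Sig <- .theta_to_sigma(theta[seq_len(d * (d + 1) / 2)], d)
  sp2 <- if (patient_effect) exp(theta[length(theta)])^2 else 0
  keys <- vapply(units, `[[`, "", "key")
  uk <- unique(keys)
  A <- matrix(0, d, d)
  b <- numeric(d)
  quad <- 0
  logdet <- 0
  for (k in uk) {
    idx <- which(keys == k)
    u1 <- units[[idx[1]]]
    obs <- u1$obs            # vector of timepoint indices, stacked
    m <- length(obs)
    V <- Sig[obs, obs, drop = FALSE]
    if (patient_effect) V <- V * u1$same + sp2
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(if (fit) NULL else 1e10)
    W <- chol2inv(ch)
    X <- matrix(0, m, d)
    X[cbind(seq_len(m), obs)] <- 1
    XtW <- crossprod(X, W)
    A <- A + length(idx) * (XtW %*% X)
    ys <- vapply(units[idx], `[[`, numeric(m), "y")  # m x n_idx
    ys <- matrix(ys, nrow = m)
    b <- b + XtW %*% rowSums(ys)
    quad <- quad + sum(ys * (W %*% ys))
    logdet <- logdet + 2 * length(idx) * sum(log(diag(ch)))
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(if (fit) NULL else 1e10)
  Ainv <- chol2inv(chA)
  mu <- drop(Ainv %*% b)
  if (fit) {
    return(list(mu = mu, vcov_mu = Ainv, sigma = Sig, sigma_p2 = sp2))
  }
  rss <- quad - sum(b * mu)
  # -2 restricted log-likelihood (constant dropped)
  logdet + rss + 2 * sum(log(diag(chA)))
}

.make_units <- function(Y, patient, patient_effect = FALSE) {
  n <- nrow(Y)
  if (!patient_effect) {
    lapply(seq_len(n), function(i) {
      obs <- which(!is.na(Y[i, ]))
      list(obs = obs, y = Y[i, obs], key = paste(obs, collapse = ","),
           same = NULL)
    })
  } else {
    lapply(split(seq_len(n), patient), function(rows) {
      obs <- integer(0); y <- numeric(0); grp <- integer(0)
      for (j in seq_along(rows)) {
        o <- which(!is.na(Y[rows[j], ]))
        obs <- c(obs, o); y <- c(y, Y[rows[j], o])
        grp <- c(grp, rep(j, length(o)))
      }
      same <- outer(grp, grp, `==`) * 1
      list(obs = obs, y = y,
           key = paste(paste(obs, collapse = ","),
                       paste(grp, collapse = ","), sep = "|"),
           same = same)
    })
  }
}

#' Fit the repeated-measures time-course model for one outcome
#'
#' Marginal linear model with one fixed mean per visit (cell-means coding)
#' and an unstructured 4x4 covariance across the visits of a joint, estimated
#' by REML over all available observations. A joint missing its T1 visit
#' contributes its observed visits through the multivariate-normal likelihood,
#' so the T1 mean is a model-based estimate, valid under missing-at-random.
#'
#' @param records Long-format records (see [longitudinal_records()]).
#' @param outcome Outcome name, e.g. `"Vjs"`.
#' @param include_patient_effect Add a patient-level random intercept shared
#'   by a patient's two joints (off by default; the repeated-measures unit is
#'   the joint).
#' @param complete_case Drop joints with any missing visit before fitting
#'   (for comparison with the likelihood-based analysis).
#' @param df_method `"normal"` (Wald z for contrasts) or `"satterthwaite"`.
#' @param max_iter Maximum optimizer iterations.
#' @return Object of class `tmj_fit`: `means`, `se` (per visit), `vcov_mu`,
#'   `sigma` (estimated 4x4 covariance), `overall` (F statistic, df, p),
#'   `n_joints`, `n_obs`, `reml_trace`, plus fit metadata.
#' @export
fit_time_course <- function(records, outcome = "Vjs",
                            include_patient_effect = FALSE,
                            complete_case = FALSE,
                            df_method = c("normal", "satterthwaite"),
                            max_iter = 500L) {
  df_method <- match.arg(df_method)
  wide <- .records_wide(records, outcome)
  Y <- wide$Y; patient <- wide$patient
  if (complete_case) {
    keep <- stats::complete.cases(Y)
    Y <- Y[keep, , drop = FALSE]; patient <- patient[keep]
  }
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 joints", call. = FALSE)
  if (any(rowSums(!is.na(Y)) < 2L)) {
    stop("every joint needs at least 2 observed timepoints", call. = FALSE)
  }
  if (any(colSums(!is.na(Y)) == 0L)) {
    stop("a timepoint has no observations at all", call. = FALSE)
  }
  units <- .make_units(Y, patient, include_patient_effect)
  theta0 <- .sigma_to_theta(.start_sigma(Y))
  if (include_patient_effect) {
    theta0 <- c(theta0, log(stats::sd(Y, na.rm = TRUE) * 0.3 + 1e-6))
  }
  evals <- new.env(); evals$hist <- numeric(0)
  obj <- function(th) {
    v <- .reml_pieces(th, units, patient_effect = include_patient_effect)
    evals$hist <- c(evals$hist, v)
    v
  }
  opt <- tryCatch(
    stats::optim(theta0, obj, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12)),
    error = function(e) NULL)
  structure_used <- "unstructured"
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    # fall back to diagonal-plus-common-correlation (compound symmetry)
    warning("unstructured covariance fit failed; falling back to a ",
            "diagonal-plus-common-correlation structure")
    structure_used <- "compound_symmetry"
    cs_theta <- function(p) {
      s2 <- exp(p[1])^2; rho <- tanh(p[2])
      S <- s2 * ((1 - rho) * diag(4) + rho)
      .sigma_to_theta(S)
    }
    obj_cs <- function(p) obj(if (include_patient_effect)
      c(cs_theta(p[1:2]), p[3]) else cs_theta(p[1:2]))
    p0 <- c(log(stats::sd(Y, na.rm = TRUE)), atanh(0.5))
    if (include_patient_effect) p0 <- c(p0, theta0[length(theta0)])
    opt <- stats::optim(p0, obj_cs, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-12))
    th_hat <- if (include_patient_effect)
      c(cs_theta(opt$par[1:2]), opt$par[3]) else cs_theta(opt$par[1:2])
  } else {
    th_hat <- opt$par
  }
  if (opt$convergence != 0L && opt$convergence != 1L) {
    stop(sprintf("convergence error after %d iterations (last -2 REML = %.6f)",
                 max_iter, opt$value), call. = FALSE)
  }
  if (opt$convergence == 1L) {
    warning("REML optimizer hit the iteration limit; estimates may be rough")
  }
  pieces <- .reml_pieces(th_hat, units, patient_effect = include_patient_effect,
                         fit = TRUE)
  mu <- pieces$mu
  V <- pieces$vcov_mu
  names(mu) <- .tmj_timepoints
  n_joints <- nrow(Y)
  # overall time effect: 3-df Wald statistic referred to F(3, n_joints - 3);
  # exact for complete balanced data, an approximation otherwise
  C <- cbind(-1, diag(3))
  cm <- drop(C %*% mu)
  Wstat <- drop(crossprod(cm, solve(C %*% V %*% t(C), cm)))
  df2 <- max(1L, n_joints - 3L)
  Fstat <- Wstat / 3
  overall <- list(F = Fstat, df1 = 3, df2 = df2,
                  p = stats::pf(Fstat, 3, df2, lower.tail = FALSE))
  structure(list(outcome = outcome, means = mu,
                 se = sqrt(pmax(diag(V), 0)), vcov_mu = V,
                 sigma = pieces$sigma, sigma_p2 = pieces$sigma_p2,
                 overall = overall, n_joints = n_joints,
                 n_obs = sum(!is.na(Y)),
                 df_method = df_method, structure = structure_used,
                 include_patient_effect = include_patient_effect,
                 theta = th_hat, units = units,
                 reml_trace = evals$hist,
                 minus2reml = opt$value),
            class = "tmj_fit")
}

#' @export
print.tmj_fit <- function(x, ...) {
  cat(sprintf("<time-course fit> %s, %d joints (%d observations), %s covariance\n",
              x$outcome, x$n_joints, x$n_obs, x$structure))
  est <- data.frame(time = .tmj_timepoints,
                    mean = round(x$means, 2), SE = round(x$se, 2))
  print(est, row.names = FALSE)
  cat(sprintf("overall time effect: F(%d, %d) = %.3f, p %s\n",
              x$overall$df1, x$overall$df2, x$overall$F,
              format_p(x$overall$p)))
  invisible(x)
}

# Satterthwaite df for contrast c'mu: 2 (c'Vc)^2 / (g' W g) with g the
# finite-difference gradient of c'V(theta)c and W the inverse curvature of
# the -2 REML criterion at the optimum.
.satterthwaite_df <- function(fit, cvec) {
  th <- fit$theta
  pe <- fit$include_patient_effect
  vfun <- function(t) {
    p <- .reml_pieces(t, fit$units, patient_effect = pe, fit = TRUE)
    if (is.null(p)) return(NA_real_)
    drop(crossprod(cvec, p$vcov_mu %*% cvec))
  }
  hstep <- 1e-4
  g <- vapply(seq_along(th), function(k) {
    tp <- th; tm <- th
    tp[k] <- tp[k] + hstep; tm[k] <- tm[k] - hstep
    (vfun(tp) - vfun(tm)) / (2 * hstep)
  }, numeric(1))
  H <- stats::optimHess(th, function(t)
    .reml_pieces(t, fit$units, patient_effect = pe))
  Wc <- tryCatch(solve(H / 2), error = function(e) NULL)  # var(theta-hat)
  if (is.null(Wc) || anyNA(g)) return(Inf)
  denom <- drop(crossprod(g, Wc %*% g))
  v <- vfun(th)
  if (!is.finite(denom) || denom <= 0) return(Inf)
  max(1, 2 * v^2 / denom)
}

#' Pairwise visit contrasts with Bonferroni adjustment
#'
#' The six ordered visit pairs (T0vT1, T0vT2, T0vT3, T1vT2, T1vT3, T2vT3).
#' Each difference is the mean of the second-listed visit minus the mean of
#' the first-listed one, matching the reporting convention in which the
#' T0-versus-T1 row is positive when T1 exceeds T0 and T1-versus-T2 is
#' negative when the volume falls back. Adjusted p-values are
#' `min(1, m * raw)` with `m = 6` by default.
#'
#' @param fit A [fit_time_course()] result.
#' @param bonferroni_m Multiplicity factor (default 6, the number of pairs).
#' @return data.frame: `pair`, `difference`, `se`, `p_raw`, `p_bonferroni`,
#'   `df` (Inf for the normal approximation), and display strings
#'   `p_display`, `significant` (starred at the 1e-4 threshold).
#' @export
pairwise_contrasts <- function(fit, bonferroni_m = 6) {
  stopifnot(inherits(fit, "tmj_fit"))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                c(2L, 3L), c(2L, 4L), c(3L, 4L))
  out <- lapply(pairs, function(pr) {
    cvec <- numeric(4); cvec[pr[1]] <- -1; cvec[pr[2]] <- 1
    diff <- sum(cvec * fit$means)
    se <- sqrt(drop(crossprod(cvec, fit$vcov_mu %*% cvec)))
    if (fit$df_method == "satterthwaite") {
      df <- .satterthwaite_df(fit, cvec)
      p <- 2 * stats::pt(-abs(diff / se), df = df)
    } else {
      df <- Inf
      p <- 2 * stats::pnorm(-abs(diff / se))
    }
    data.frame(pair = sprintf("%s versus %s", .tmj_timepoints[pr[1]],
                              .tmj_timepoints[pr[2]]),
               difference = diff, se = se, p_raw = p,
               p_bonferroni = min(1, bonferroni_m * p), df = df)
  })
  out <- do.call(rbind, out)
  out$p_display <- vapply(out$p_bonferroni, format_p, character(1))
  out$significant <- out$p_bonferroni <= 1e-4
  out
}

#' Format a p-value for the results tables
#'
#' 4 decimals, capped as `"< .0001"` below 1e-4 and `"> .9999"` at or above
#' 0.9999.
#'
#' @param p Numeric p-value.
#' @return Display string.
#' @export
format_p <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.0001) "< .0001"
  else if (p >= 0.9999) "> .9999"
  else sub("^0\\.", "0.", sprintf("%.4f", p))
}

#' Results table for one outcome
#'
#' Lays out the fit and its post-hoc contrasts in the standard longitudinal
#' reporting format: one row per visit with the estimated mean (SE), the
#' overall time-effect p-value on the first row, and the six pairwise
#' contrasts with Bonferroni-adjusted p-values alongside. Means, SEs and
#' differences are rounded to 2 decimals; p-values display with 4 decimals
#' and the `< .0001` / `> .9999` caps, starred at the 1e-4 significance
#' threshold.
#'
#' @param fit A [fit_time_course()] result.
#' @param contrasts Optional precomputed [pairwise_contrasts()] result.
#' @return data.frame with columns `outcome`, `time`, `estimated_mean`, `se`,
#'   `mean_se`, `overall_p`, `posthoc`, `difference`, `diff_se`,
#'   `difference_se`, `p_bonferroni`; class `tmj_results_table`.
#' @export
make_results_table <- function(fit, contrasts = NULL) {
  stopifnot(inherits(fit, "tmj_fit"))
  if (is.null(contrasts)) contrasts <- pairwise_contrasts(fit)
  n <- max(4L, nrow(contrasts))
  pad <- function(x, with = NA) c(x, rep(with, n - length(x)))
  star <- ifelse(contrasts$significant, "*", "")
  df <- data.frame(
    outcome = c(fit$outcome, rep("", n - 1L)),
    time = pad(.tmj_timepoints, ""),
    estimated_mean = pad(round(fit$means, 2)),
    se = pad(round(fit$se, 2)),
    mean_se = pad(sprintf("%.2f (%.2f)", fit$means, fit$se), ""),
    overall_p = c(format_p(fit$overall$p), rep("", n - 1L)),
    posthoc = contrasts$pair,
    difference = round(contrasts$difference, 2),
    diff_se = round(contrasts$se, 2),
    difference_se = sprintf("%.2f (%.2f)", contrasts$difference,
                            contrasts$se),
    p_bonferroni = paste0(contrasts$p_display, star))
  class(df) <- c("tmj_results_table", "data.frame")
  df
}

#' @export
print.tmj_results_table <- function(x, ...) {
  cat(format_results_text(x), sep = "\n")
  invisible(x)
}

#' Aligned-text rendition of a results table
#' @param table A [make_results_table()] result.
#' @return Character vector of aligned lines.
#' @export
format_results_text <- function(table) {
  cols <- c("outcome", "time", "mean_se", "overall_p", "posthoc",
            "difference_se", "p_bonferroni")
  hdr <- c("Outcome", "Time", "Estimated mean (SE)", "Overall p-value",
           "Post-hoc", "Differences (SE)", "p-value (bonferroni)")
  m <- rbind(hdr, as.matrix(as.data.frame(table)[, cols]))
  m[is.na(m)] <- ""
  widths <- apply(nchar(m), 2, max)
  apply(m, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
}

#' Write a results table to CSV
#' @param table A [make_results_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
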
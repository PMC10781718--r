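S_test <- outer(c(400, 520, 410, 405), c(400, 520, 410, 405)) *
  (0.4 * diag(4) + 0.6)

test_that("saturated-means identity on complete balanced data", {
  mu <- c(1110.99, 1459.21, 1253.05, 1245.53)
  rec <- make_records(60, mu, S_test, seed = 101)
  fit <- fit_time_course(rec, "Vjs")
  sm <- tapply(rec$value_mm3, rec$timepoint, mean)
  expect_lt(max(abs(fit$means - sm[c("T0", "T1", "T2", "T3")])), 1e-6)
  # REML covariance equals the sample covariance (n - 1 denominator)
  Y <- matrix(rec$value_mm3, ncol = 4)
  expect_equal(fit$sigma, unname(cov(Y)), tolerance = 1e-4)
  # -2 REML criterion never ends above its starting value
  expect_lte(fit$minus2reml, fit$reml_trace[1] + 1e-8)
})

test_that("likelihood-based T1 estimation beats complete-case under MAR", {
  mu <- c(1110.99, 1459.21, 1253.05, 1245.53)
  sp <- sim_spec(outcomes = list(Vjs = list(means = mu, cov = S_test)),
                 n_patients = 100, t1_observed = 50,
                 between_side_correlation = 0,
                 missing_mechanism = "baseline", seed = 77)
  rec <- simulate_longitudinal_records(sp)
  fit <- fit_time_course(rec, "Vjs")
  cc_mean <- mean(rec$value_mm3[rec$timepoint == "T1"])
  # T1 deleted for high-baseline patients: the complete-case average is
  # biased low; the model-based mean must land closer to the truth
  expect_lt(abs(fit$means["T1"] - mu[2]), abs(cc_mean - mu[2]))
})

test_that("parameter recovery at 200 joints within 2 SE", {
  mu <- c(1110.99, 1459.21, 1253.05, 1245.53)
  sp <- sim_spec(outcomes = list(Vjs = list(means = mu, cov = S_test)),
                 n_patients = 100, t1_observed = 54,
                 between_side_correlation = 0, seed = 31)
  fit <- fit_time_course(simulate_longitudinal_records(sp), "Vjs")
  expect_true(all(abs(fit$means - mu) < 2 * fit$se))
})

test_that("pairwise contrasts: signs, Bonferroni arithmetic, display caps", {
  # synthetic fit with identical means and nonzero covariance
  fit0 <- structure(list(outcome = "Vjs",
                         means = stats::setNames(rep(100, 4),
                                                 c("T0", "T1", "T2", "T3")),
                         se = rep(2, 4), vcov_mu = diag(4) * 4,
                         df_method = "normal"),
                    class = "tmj_fit")
  ct0 <- pairwise_contrasts(fit0)
  expect_true(all(ct0$p_display == "> .9999"))
  expect_true(all(ct0$difference == 0))

  # adjusted p = min(1, 6 x raw)
  mu <- c(1110.99, 1459.21, 1253.05, 1245.53)
  rec <- make_records(70, mu, S_test, seed = 5)
  fit <- fit_time_course(rec, "Vjs")
  ct <- pairwise_contrasts(fit)
  expect_equal(ct$p_bonferroni, pmin(1, 6 * ct$p_raw))
  expect_true(all(ct$p_bonferroni >= ct$p_raw))

  # reporting orientation: T0 versus T1 positive (T1 peak), T1 versus T2
  # negative (fall-back), like the published tables
  expect_gt(ct$difference[ct$pair == "T0 versus T1"], 0)
  expect_lt(ct$difference[ct$pair == "T1 versus T2"], 0)

  # raw 0.01 -> 0.06 arithmetic
  expect_equal(min(1, 6 * 0.01), 0.06)
  expect_equal(format_p(2e-6), "< .0001")
  expect_equal(format_p(0.99999), "> .9999")
  expect_equal(format_p(0.0298), "0.0298")
})

test_that("results table renders and round-trips through CSV", {
  mu <- c(1110.99, 1459.21, 1253.05, 1245.53)
  rec <- make_records(70, mu, S_test, seed = 5)
  fit <- fit_time_course(rec, "Vjs")
  tab <- make_results_table(fit)
  expect_s3_class(tab, "tmj_results_table")
  expect_equal(tab$time[1:4], c("T0", "T1", "T2", "T3"))
  expect_equal(nrow(tab), 6)   # six post-hoc rows
  expect_match(tab$mean_se[1], "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}\\)$")

  f <- tempfile(fileext = ".csv")
  write_results_csv(tab, f)
  back <- read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
  for (cl in c("estimated_mean", "difference", "p_bonferroni")) {
    expect_equal(back[[cl]], as.character(as.data.frame(tab)[[cl]]))
  }
  # aligned text rendition includes the table header
  txt <- format_results_text(tab)
  expect_match(txt[1], "Estimated mean \\(SE\\)")
  expect_length(txt, 7)
})

test_that("model options: Satterthwaite df, complete case, patient effect", {
  mu <- c(1000, 1100, 1050, 1040)
  sp <- sim_spec(outcomes = list(Vjs = list(means = mu, cov = S_test)),
                 n_patients = 40, t1_observed = 25,
                 between_side_correlation = 0.5, seed = 13)
  rec <- simulate_longitudinal_records(sp)

  fit_s <- fit_time_course(rec, "Vjs", df_method = "satterthwaite")
  ct_s <- pairwise_contrasts(fit_s)
  expect_true(all(ct_s$df > 1))
  expect_true(all(ct_s$p_raw > 0 & ct_s$p_raw <= 1))
  # t-based p-values are no smaller than the normal approximation
  fit_n <- fit_time_course(rec, "Vjs", df_method = "normal")
  ct_n <- pairwise_contrasts(fit_n)
  expect_true(all(ct_s$p_raw >= ct_n$p_raw - 1e-12))

  fit_cc <- fit_time_course(rec, "Vjs", complete_case = TRUE)
  expect_equal(fit_cc$n_joints, 2 * 25)
  expect_lt(max(abs(fit_cc$means -
                      tapply(rec$value_mm3[rec$joint_id %in%
                               rec$joint_id[rec$timepoint == "T1"]],
                             rec$timepoint[rec$joint_id %in%
                               rec$joint_id[rec$timepoint == "T1"]],
                             mean)[c("T0", "T1", "T2", "T3")])), 1e-6)

  fit_p <- fit_time_course(rec, "Vjs", include_patient_effect = TRUE)
  expect_true(is.finite(fit_p$overall$p))
  expect_gt(fit_p$sigma_p2, 0)
})

test_that("record validation and I/O", {
  rec <- simulate_longitudinal_records(sim_spec(seed = 2))
  f <- tempfile(fileext = ".csv")
  write_records_csv(rec, f)
  back <- read_records_csv(f)
  expect_equal(nrow(back), nrow(rec))
  expect_error(longitudinal_records(data.frame(a = 1)), "missing columns")
  dup <- rbind(as.data.frame(rec), as.data.frame(rec)[1, ])
  expect_error(longitudinal_records(dup), "duplicate")
  expect_error(fit_time_course(rec, "NotAnOutcome"), "no records")
  one <- as.data.frame(rec)[rec$joint_id == rec$joint_id[1], ]
  expect_error(fit_time_course(longitudinal_records(one), "Vjs"),
               "at least 2 joints")
})
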
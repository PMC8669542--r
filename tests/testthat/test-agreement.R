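make_pairs <- function(log_p_cam, log_p_3dcam,
                       ids = sprintf("P%02d", seq_along(log_p_cam))) {
  out <- data.frame(patient_id = ids,
                    eta_cam = qlogis(exp(log_p_cam)),
                    eta_3dcam = qlogis(exp(log_p_3dcam)),
                    p_cam = exp(log_p_cam), p_3dcam = exp(log_p_3dcam),
                    log_p_cam = log_p_cam, log_p_3dcam = log_p_3dcam,
                    stringsAsFactors = FALSE)
  class(out) <- c("latent_pairs", "data.frame")
  out
}

test_that("latent pairs are the closed-form fixed-effect predictions when EB modes are 0", {
  f <- fake_fit(c(intercept = -1, method = 0.5), patients = c("A", "B", "C"))
  pairs <- extract_latent_pairs(f)
  expect_equal(nrow(pairs), 3L)
  expect_true(all(pairs$p_cam == plogis(-1)))
  expect_true(all(pairs$p_3dcam == plogis(-0.5)))
  expect_equal(pairs$log_p_cam, log(pairs$p_cam))
  f_nomethod <- fake_fit(c(intercept = -1))
  expect_error(extract_latent_pairs(f_nomethod), "method fixed effect")
})

test_that("latent pairs are invariant to patient relabeling", {
  tab <- small_cohort(n_patients = 15, n_raters = 4, seed = 8)
  f1 <- fit_glmm(tab, glmm_spec("delirium"))
  tab2 <- tab
  tab2$patient_id <- relabel_ids(tab$patient_id, "XX")
  f2 <- fit_glmm(tab2, glmm_spec("delirium"))
  p1 <- extract_latent_pairs(f1)
  p2 <- extract_latent_pairs(f2)
  expect_equal(sort(p1$p_cam), sort(p2$p_cam), tolerance = 1e-5)
  expect_equal(sort(p1$p_3dcam), sort(p2$p_3dcam), tolerance = 1e-5)
})

test_that("Bland-Altman statistics follow the mean/SD definitions", {
  # identical methods: zero mean difference and collapsed limits
  same <- make_pairs(c(-1, -2, -0.5), c(-1, -2, -0.5))
  ba0 <- bland_altman(same, "log_probability")
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, c(0, 0))

  # arithmetic-mean oracle on fixed log differences {-1, -1, -1.09}
  pr <- make_pairs(c(-2, -2, -2.09), c(-1, -1, -1))
  ba <- bland_altman(pr, "log_probability")
  expect_equal(ba$mean_diff, mean(c(-1, -1, -1.09)))
  expect_equal(round(ba$mean_diff, 2), -1.03)
  expect_equal(ba$sd_diff, sd(c(-1, -1, -1.09)))
  expect_equal(ba$loa, ba$mean_diff + c(-1.96, 1.96) * ba$sd_diff)
  expect_equal(ba$mean_diff_ci,
               ba$mean_diff + c(-1, 1) * qnorm(0.975) * ba$sd_diff / sqrt(3))
  expect_equal(nrow(ba$points), 3L)
  expect_equal(ba$points$average,
               (pr$log_p_cam + pr$log_p_3dcam) / 2)

  expect_error(bland_altman(pr[1, , drop = FALSE]), "at least 2 pairs")
})

test_that("swapping the instruments negates differences and inverts ratios", {
  pr <- make_pairs(c(-2, -1.2, -0.4), c(-1, -0.8, -0.9))
  swapped <- pr
  swapped[, c("p_cam", "p_3dcam")] <- pr[, c("p_3dcam", "p_cam")]
  swapped[, c("log_p_cam", "log_p_3dcam")] <- pr[, c("log_p_3dcam", "log_p_cam")]
  ba <- bland_altman(pr, "log_probability")
  ba_sw <- bland_altman(swapped, "log_probability")
  expect_equal(ba_sw$points$difference, -ba$points$difference)
  expect_equal(ba_sw$mean_diff, -ba$mean_diff)
  r <- probability_ratio(ba)
  r_sw <- probability_ratio(ba_sw)
  expect_equal(r_sw$ratio, 1 / r$ratio, tolerance = 1e-12)
})

test_that("the ratio transform exponentiates the mean difference and its CI", {
  ba <- ba_summary(0, -0.1, 0.1)
  expect_equal(probability_ratio(ba)$ratio, 1.0)
  ba2 <- ba_summary(-0.5, -0.8, -0.2)
  r <- probability_ratio(ba2)
  expect_equal(r$ratio, exp(-0.5))
  expect_equal(r$ratio_ci, exp(c(-0.8, -0.2)))
  expect_true(r$ratio_ci[1] < r$ratio && r$ratio < r$ratio_ci[2])
  # inverse is the reciprocal of the rounded forward values
  expect_equal(r$inverse_ratio, round(1 / round(exp(-0.5), 2), 2))
  ba_prob <- ba_summary(0.2, 0.1, 0.3, scale = "probability")
  expect_error(probability_ratio(ba_prob), "log_probability")
})

test_that("feature agreement uses the scale policy and reports ratios only on the log scale", {
  cfg <- simulation_config(n_patients = 40, n_raters = 5, sigma_patient = 1.5,
                           sigma_rater = 0.2, sigma_interaction = 0.3,
                           beta0 = -0.8, beta_method = 0.6,
                           occasions = list(type = "probs", probs = c("3" = 1)),
                           duration_params = NULL, seed = 55)
  tab <- simulate_cohort(cfg)
  res_prob <- suppressMessages(feature_agreement(tab, "inattention"))
  expect_equal(res_prob$scale, "probability")
  expect_null(res_prob$ratio)
  res_log <- suppressMessages(feature_agreement(tab, "aloc"))
  expect_equal(res_log$scale, "log_probability")
  expect_s3_class(res_log$ratio, "ratio_result")
  expect_equal(res_log$ratio$ratio, exp(res_log$ba$mean_diff))
})

test_that("a null method effect yields a near-zero mean difference", {
  cfg <- simulation_config(n_patients = 120, n_raters = 8, sigma_patient = 1.5,
                           sigma_rater = 0.2, sigma_interaction = 0,
                           beta0 = -0.5, beta_method = 0,
                           occasions = list(type = "probs", probs = c("2" = 1)),
                           duration_params = NULL, seed = 61)
  tab <- simulate_cohort(cfg)
  fit <- fit_glmm(tab, glmm_spec(
    "delirium", random = c("patient_intercept", "rater_intercept")))
  pairs <- extract_latent_pairs(fit)
  w <- wald_test_fixed(fit, "method")
  # the latent differences move together with the estimated method effect,
  # so the Monte-Carlo SE of the mean difference is the Wald SE propagated
  # through the scale transform (delta method), not sd_diff / sqrt(n)
  se_md <- list(
    log_probability = w$std_error * mean(1 - pairs$p_3dcam),
    probability = w$std_error * mean(pairs$p_3dcam * (1 - pairs$p_3dcam)))
  for (scale in c("probability", "log_probability")) {
    ba <- bland_altman(pairs, scale)
    expect_lt(abs(ba$mean_diff), 2 * se_md[[scale]])
  }
})

test_that("Bland-Altman points export as TSV", {
  pr <- make_pairs(c(-2, -1.2, -0.4), c(-1, -0.8, -0.9))
  ba <- bland_altman(pr, "log_probability")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ba_points(ba, path)
  back <- read.delim(path)
  expect_equal(names(back), c("patient_id", "average", "difference"))
  expect_equal(back$difference, ba$points$difference)
})
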
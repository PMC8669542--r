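test_that("a spec without random terms reduces to ordinary logistic regression", {
  tab <- small_cohort(n_patients = 25, seed = 4)
  spec <- glmm_spec("delirium", random = character(0))
  f <- fit_glmm(tab, spec)
  g <- stats::glm(delirium ~ I(instrument == "3DCAM"),
                  family = binomial(), data = as.data.frame(tab))
  expect_lt(max(abs(unname(f$beta) - unname(coef(g)))), 1e-6)
  expect_true(f$converged)
  expect_equal(f$method, "ml")
})

test_that("brute-force oracle: point-mass prior equals the Bernoulli log-likelihood", {
  tab <- validate_assessments(tiny_table())
  spec <- glmm_spec("delirium", random = "patient_intercept")
  beta <- c(-0.4, 0.9)
  bf <- marginal_loglik_bruteforce(tab, spec,
    params = list(beta0 = beta[1], beta_method = beta[2], sigma_patient = 0))
  eta <- beta[1] + beta[2] * (tab$instrument == "3DCAM")
  plain <- sum(tab$delirium * eta - log1p(exp(eta)))
  expect_equal(bf, plain, tolerance = 1e-12)
})

test_that("brute-force oracle matches a hand-coded 1-D quadrature", {
  # 1 patient, 2 records, sigma_patient = 1
  tab <- validate_assessments(tiny_table())[1:2, ]
  spec <- glmm_spec("delirium", random = "patient_intercept")
  params <- list(beta0 = -0.3, beta_method = 0.6, sigma_patient = 1)
  bf <- marginal_loglik_bruteforce(tab, spec, params)
  lik <- function(b) {
    eta <- params$beta0 + params$beta_method * (tab$instrument == "3DCAM") + b
    exp(sum(tab$delirium * eta - log1p(exp(eta)))) * dnorm(b, 0, 1)
  }
  ref <- log(stats::integrate(Vectorize(lik), -Inf, Inf,
                              rel.tol = 1e-12)$value)
  expect_equal(bf, ref, tolerance = 1e-8)
})

test_that("brute-force oracle is symmetric under label flip", {
  tab <- validate_assessments(tiny_table())
  spec <- glmm_spec("delirium", random = "patient_intercept")
  params <- list(beta0 = 0.7, beta_method = 0, sigma_patient = 1.3)
  a <- marginal_loglik_bruteforce(tab, spec, params)
  flip <- tab
  flip$delirium <- 1L - flip$delirium
  params$beta0 <- -params$beta0
  b <- marginal_loglik_bruteforce(flip, spec, params)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("brute-force oracle refuses non-factorizable designs", {
  tab <- small_cohort(n_patients = 8, seed = 3)
  expect_error(
    marginal_loglik_bruteforce(tab, glmm_spec("delirium"),
                               params = list(beta0 = 0, sigma_patient = 1)),
    "too many random-effect dimensions")
  expect_error(
    marginal_loglik_bruteforce(tab, glmm_spec("delirium",
                                              random = "patient_intercept"),
                               params = list(beta0 = 0, sigma_patient = 1)),
    "5 patients")
})

test_that("AGQ fit agrees with lme4 glmer at matched quadrature order", {
  skip_if_not_installed("lme4")
  cfg <- simulation_config(n_patients = 40, n_raters = 4, sigma_patient = 1.5,
                           sigma_rater = 0, sigma_interaction = 0,
                           beta0 = -1, beta_method = 0.8,
                           occasions = list(type = "probs",
                                            probs = c("2" = 0.5, "3" = 0.5)),
                           duration_params = NULL, seed = 11)
  tab <- simulate_cohort(cfg)
  f <- fit_glmm(tab, glmm_spec("delirium", random = "patient_intercept"))
  expect_equal(f$method, "agq")
  expect_true(f$converged)
  d <- as.data.frame(tab)
  d$m <- as.integer(d$instrument == "3DCAM")
  g <- lme4::glmer(delirium ~ m + (1 | patient_id), data = d,
                   family = binomial(), nAGQ = 15)
  expect_lt(max(abs(unname(f$beta) - unname(lme4::fixef(g)))), 1e-3)
  expect_lt(abs(sqrt(f$variance_components$sigma2_patient) -
                  sqrt(unlist(lme4::VarCorr(g)))), 1e-3)
  expect_lt(abs(f$loglik - as.numeric(logLik(g))), 1e-4)
})

test_that("Laplace fit of the crossed patient+rater design agrees with lme4", {
  skip_if_not_installed("lme4")
  cfg <- simulation_config(n_patients = 80, n_raters = 8, sigma_patient = 2,
                           sigma_rater = 0.5, sigma_interaction = 0,
                           beta0 = -1.5, beta_method = 0.7,
                           occasions = list(type = "probs",
                                            probs = c("1" = 0.4, "2" = 0.6)),
                           duration_params = NULL, seed = 23)
  tab <- simulate_cohort(cfg)
  spec <- glmm_spec("delirium",
                    random = c("patient_intercept", "rater_intercept"))
  f <- fit_glmm(tab, spec)
  expect_equal(f$method, "laplace")
  d <- as.data.frame(tab)
  d$m <- as.integer(d$instrument == "3DCAM")
  g <- suppressMessages(
    lme4::glmer(delirium ~ m + (1 | patient_id) + (1 | rater_id),
                data = d, family = binomial()))
  expect_lt(max(abs(unname(f$beta) - unname(lme4::fixef(g)))), 5e-3)
  expect_lt(abs(f$loglik - as.numeric(logLik(g))), 1e-3)
  expect_lt(max(abs(sqrt(diag(f$beta_cov)) - sqrt(diag(as.matrix(vcov(g)))))),
            5e-3)
})

test_that("method effect is recovered within 3 SE on study-sized data", {
  cfg <- simulation_config(n_patients = 300, n_raters = 16,
                           beta0 = -2, beta_method = 0.7,
                           sigma_patient = 2, sigma_rater = 0.3,
                           sigma_interaction = 0,
                           occasions = list(type = "probs", probs = c("2" = 1)),
                           duration_params = NULL, seed = 41)
  tab <- simulate_cohort(cfg)
  f <- fit_glmm(tab, glmm_spec("delirium",
                               random = c("patient_intercept",
                                          "rater_intercept")))
  w <- wald_test_fixed(f, "method")
  expect_lt(abs(w$estimate - 0.7), 3 * w$std_error)
})

test_that("accepted log-likelihoods never decrease and fits are label-invariant", {
  tab <- small_cohort(n_patients = 25, n_raters = 5, seed = 13)
  spec <- glmm_spec("delirium")
  f1 <- fit_glmm(tab, spec)
  expect_true(all(diff(f1$trace) >= 0))
  tab2 <- tab
  tab2$patient_id <- relabel_ids(tab$patient_id, "ZZ", seed = 99)
  tab2$rater_id <- relabel_ids(tab$rater_id, "QQ", seed = 98)
  f2 <- fit_glmm(tab2, spec)
  expect_lt(max(abs(unname(f1$beta) - unname(f2$beta))), 1e-6)
  expect_lt(max(abs(unlist(f1$variance_components) -
                      unlist(f2$variance_components))), 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("degenerate inputs raise the documented errors", {
  tab <- small_cohort(n_patients = 10, seed = 6)
  allpos <- tab
  allpos$delirium <- 1L
  expect_error(fit_glmm(allpos, glmm_spec("delirium")), "constant")
  sep <- tab
  sep$delirium[sep$instrument == "CAM"] <- 1L
  expect_error(fit_glmm(sep, glmm_spec("delirium")), "separation")
  one <- tab[tab$patient_id == tab$patient_id[1], ]
  expect_error(fit_glmm(one, glmm_spec("delirium")), "2 patients")
})

test_that("Wald arithmetic follows the normal distribution exactly", {
  w0 <- wald_from_estimate(0, 1, 0.95)
  expect_equal(w0$ci_low, -qnorm(0.975))
  expect_equal(w0$ci_high, qnorm(0.975))
  expect_equal(w0$p_value, 1.0)

  # SE back-solved from a symmetric CI half-width of 0.635
  w <- wald_from_estimate(-0.68, 0.3237)
  expect_equal(round(w$ci_low, 2), -1.31)
  expect_equal(round(w$ci_high, 2), -0.05)
  expect_equal(w$p_value, 2 * pnorm(-abs(-0.68 / 0.3237)), tolerance = 1e-12)
  expect_equal(round(w$p_value, 2), 0.04)

  # CI (0.71, 1.74) around 1.23 implies a highly significant effect
  se <- (1.74 - 0.71) / (2 * qnorm(0.975))
  w2 <- wald_from_estimate(1.23, se)
  expect_lt(w2$p_value, 0.001)

  f <- fake_fit(c(intercept = -1, method = 0.5))
  expect_error(wald_test_fixed(f, "nonexistent"), "unknown coefficient")
})

test_that("latent prediction composes fixed effects and EB modes", {
  f0 <- fake_fit(c(intercept = 0, method = 0))
  expect_equal(predict_latent(f0, "A", "CAM"), list(eta = 0, p = 0.5))

  eb <- list(patient = c(A = 0.5, B = -1),
             patient_by_method = matrix(0, 2, 2,
                                        dimnames = list(c("A", "B"),
                                                        c("CAM", "3DCAM"))))
  f <- fake_fit(c(intercept = -2, method = 1), eb = eb)
  pr <- predict_latent(f, "A", "3DCAM")
  expect_equal(pr$eta, -0.5)
  expect_equal(pr$p, plogis(-0.5), tolerance = 1e-12)
  expect_equal(round(pr$p, 4), 0.3775)
  expect_error(predict_latent(f, "nobody", "CAM"), "unknown patient")
})

test_that("patients with large positive effects sit above the cohort rate", {
  cfg <- simulation_config(n_patients = 60, n_raters = 6, sigma_patient = 2,
                           sigma_rater = 0.2, sigma_interaction = 0.3,
                           beta0 = -1.5, beta_method = 0.7,
                           occasions = list(type = "probs", probs = c("3" = 1)),
                           duration_params = NULL, seed = 77)
  tab <- simulate_cohort(cfg)
  f <- fit_glmm(tab, glmm_spec("delirium"))
  pairs <- extract_latent_pairs(f)
  top <- pairs[which.max(f$eb_modes$patient[pairs$patient_id]), ]
  rate <- setNames(
    vapply(c("CAM", "3DCAM"), function(ins)
      mean(tab$delirium[tab$instrument == ins]), numeric(1)),
    c("CAM", "3DCAM"))
  expect_gt(top$p_cam, rate[["CAM"]])
  expect_gt(top$p_3dcam, rate[["3DCAM"]])
})
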
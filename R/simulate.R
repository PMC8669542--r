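#' Default per-feature generative parameters
#'
#' Intercepts and method effects (logit scale, 3D-CAM vs CAM) for the four
#' cardinal delirium features.  Signs follow the discordance pattern of the
#' two scoring algorithms: the long-form CAM scores acute change and altered
#' level of consciousness more often (negative 3D-CAM effect), while the
#' 3D-CAM scores inattention and disorganized thinking more often.  The
#' magnitudes are illustrative, not estimates.
#'
#' @return Named list of `(beta0, beta_method)` pairs, one per feature.
#' @export
default_feature_params <- function() {
  list(acute_change          = list(beta0 = -1.2, beta_method = -1.23),
       inattention           = list(beta0 = -1.6, beta_method =  0.84),
       disorganized_thinking = list(beta0 = -2.2, beta_method =  1.48),
       aloc                  = list(beta0 = -3.0, beta_method = -0.66))
}

#' Default per-instrument administration-duration parameters
#'
#' Log-normal draws (rounded to whole minutes, floored at 1) targeting a
#' median of 3 minutes (IQR about 2-4) for the 3D-CAM and 8 minutes (IQR
#' about 6-10) for the long-form CAM.
#'
#' @return Named list of `(meanlog, sdlog)` per instrument.
#' @export
default_duration_params <- function() {
  list(CAM     = list(meanlog = log(8), sdlog = 0.30),
       `3DCAM` = list(meanlog = log(3), sdlog = 0.45))
}

#' Build a simulation configuration
#'
#' Describes a synthetic cohort with the generative structure the agreement
#' analysis assumes: patient random intercepts `b_i ~ N(0, sigma_patient^2)`,
#' rater random intercepts `c_r ~ N(0, sigma_rater^2)` shared across
#' instruments, patient-by-method effects `d_im ~ N(0, sigma_interaction^2)`
#' (one draw per patient per instrument), and Bernoulli outcomes with
#' success probability `plogis(beta0 + beta_method * [m = 3DCAM] + b_i +
#' d_im + c_r)`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param occasions Occasions-per-patient spec: either
#'   `list(type = "probs", probs = c("1" = ..., ...))` (sampled per patient,
#'   support 1..6) or `list(type = "counts", counts = c("1" = n1, ...))`
#'   (an exact multiset of occasion counts, shuffled across patients).
#' @param n_raters Number of raters (>= 2; each occasion needs two distinct
#'   assessors).
#' @param beta0 Intercept on the logit scale (CAM reference arm).
#' @param beta_method 3D-CAM-vs-CAM fixed effect on the logit scale.
#' @param sigma_patient,sigma_rater,sigma_interaction Random-effect SDs
#'   (>= 0).
#' @param feature_params Per-feature `(beta0, beta_method)` overrides; see
#'   [default_feature_params()].  Features share `b_i` and `c_r` with the
#'   overall outcome and draw their own patient-by-method effects.
#' @param duration_params Per-instrument log-normal duration parameters or
#'   `NULL` to omit durations; see [default_duration_params()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list classed `"simulation_config"`.
#' @export
simulation_config <- function(n_patients = 299,
                              occasions = list(type = "probs",
                                               probs = c("1" = 0.62, "2" = 0.24,
                                                         "3" = 0.08, "4" = 0.03,
                                                         "5" = 0.02, "6" = 0.01)),
                              n_raters = 16,
                              beta0 = -2.0,
                              beta_method = 0.7,
                              sigma_patient = 2.0,
                              sigma_rater = 0.3,
                              sigma_interaction = 0.5,
                              feature_params = default_feature_params(),
                              duration_params = default_duration_params(),
                              seed = NULL) {
  stopifnot(n_patients >= 1, n_raters >= 1,
            sigma_patient >= 0, sigma_rater >= 0, sigma_interaction >= 0)
  if (!is.list(occasions) || !occasions$type %in% c("probs", "counts"))
    stop("occasions must be a list with type 'probs' or 'counts'")
  cfg <- list(n_patients = n_patients, occasions = occasions,
              n_raters = n_raters, beta0 = beta0, beta_method = beta_method,
              sigma_patient = sigma_patient, sigma_rater = sigma_rater,
              sigma_interaction = sigma_interaction,
              feature_params = feature_params,
              duration_params = duration_params, seed = seed)
  class(cfg) <- "simulation_config"
  cfg
}

#' Study-emulating simulation configuration
#'
#' Returns a configuration whose realized table has exactly 299 patients,
#' 471 concurrent assessment pairs, and 16 raters for every seed (the
#' occasion multiset is fixed: 191 patients with 1 occasion, 68 with 2, 24
#' with 3, 10 with 4, 4 with 5, and 2 with 6), with a positive 3D-CAM
#' method effect and patient variation much larger than rater variation.
#' The logit-scale parameter values are illustrative choices that
#' qualitatively reproduce the study regime (high per-instrument ICC,
#' 3D-CAM more often positive, substantial overall latent-pair agreement);
#' they are not estimates from patient data.
#'
#' @param seed Integer seed stored in the config.
#' @return A `"simulation_config"`.
#' @export
study_emulating_config <- function(seed = 1) {
  simulation_config(
    n_patients = 299,
    occasions = list(type = "counts",
                     counts = c("1" = 191, "2" = 68, "3" = 24,
                                "4" = 10, "5" = 4, "6" = 2)),
    n_raters = 16, seed = seed)
}

occasion_counts <- function(cfg) {
  occ <- cfg$occasions
  if (occ$type == "counts") {
    k <- as.integer(names(occ$counts))
    counts <- rep(k, occ$counts)
    if (length(counts) != cfg$n_patients)
      stop("occasion counts must sum to n_patients")
    sample(counts)
  } else {
    k <- as.integer(names(occ$probs))
    if (length(k) == 1L) rep(k, cfg$n_patients)
    else sample(k, cfg$n_patients, replace = TRUE, prob = occ$probs)
  }
}

#' Simulate a synthetic assessment cohort
#'
#' Draws a long-format assessment table from the generative model described
#' in [simulation_config()].  Each occasion is scored by an ordered pair of
#' distinct raters drawn uniformly (first administers the CAM, second the
#' 3D-CAM).  An identical seed yields an identical table.
#'
#' @param cfg A [simulation_config()].
#' @return A validated assessment table (long format, one row per
#'   instrument administration).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_raters < 2)
    stop("n_raters must be >= 2: each occasion needs two distinct raters")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  np <- cfg$n_patients
  pid <- sprintf("P%04d", seq_len(np))
  rid <- sprintf("R%02d", seq_len(cfg$n_raters))
  n_occ <- occasion_counts(cfg)
  b <- rnorm(np, 0, cfg$sigma_patient)
  c_r <- rnorm(cfg$n_raters, 0, cfg$sigma_rater)
  d <- matrix(rnorm(2 * np, 0, cfg$sigma_interaction), np, 2,
              dimnames = list(NULL, INSTRUMENTS))
  feat_d <- lapply(FEATURES, function(f)
    matrix(rnorm(2 * np, 0, cfg$sigma_interaction), np, 2,
           dimnames = list(NULL, INSTRUMENTS)))
  names(feat_d) <- FEATURES

  rows <- vector("list", sum(n_occ))
  idx <- 0L
  for (i in seq_len(np)) {
    for (j in seq_len(n_occ[i])) {
      raters <- sample(cfg$n_raters, 2L)
      idx <- idx + 1L
      rec <- data.frame(patient_id = pid[i],
                        occasion_id = sprintf("O%d", j),
                        instrument = INSTRUMENTS,
                        rater_id = rid[raters],
                        stringsAsFactors = FALSE)
      meth <- c(0, 1)  # CAM, 3DCAM
      eta <- cfg$beta0 + cfg$beta_method * meth + b[i] + d[i, ] + c_r[raters]
      rec$delirium <- rbinom(2L, 1L, plogis(eta))
      for (f in FEATURES) {
        fp <- cfg$feature_params[[f]]
        eta_f <- fp$beta0 + fp$beta_method * meth + b[i] + feat_d[[f]][i, ] +
          c_r[raters]
        rec[[f]] <- rbinom(2L, 1L, plogis(eta_f))
      }
      if (!is.null(cfg$duration_params)) {
        rec$duration_minutes <- vapply(INSTRUMENTS, function(ins) {
          dp <- cfg$duration_params[[ins]]
          max(1, round(rlnorm(1L, dp$meanlog, dp$sdlog)))
        }, numeric(1))
      }
      rows[[idx]] <- rec
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_assessments(tab)
}

#' Model-implied marginal positive rate
#'
#' Numerically integrates the Bernoulli-logit model over the random effects
#' to obtain the marginal probability of a positive outcome for one
#' instrument: `E[plogis(beta0 + beta_method * [m = 3DCAM] + s Z)]` with
#' `s^2 = sigma_patient^2 + sigma_interaction^2 + sigma_rater^2` and
#' `Z ~ N(0, 1)`.  Used to check that empirical rates converge to the
#' model-implied rates (marginalization attenuates logit-scale effects, so
#' the marginal log-rate ratio is smaller than `beta_method`).
#'
#' @param cfg A [simulation_config()].
#' @param instrument `"CAM"` or `"3DCAM"`.
#' @return Marginal positive probability.
#' @export
marginal_rate <- function(cfg, instrument = c("CAM", "3DCAM")) {
  instrument <- match.arg(instrument)
  mu <- cfg$beta0 + cfg$beta_method * (instrument == "3DCAM")
  s <- sqrt(cfg$sigma_patient^2 + cfg$sigma_interaction^2 + cfg$sigma_rater^2)
  if (s == 0) return(plogis(mu))
  stats::integrate(function(z) plogis(mu + s * z) * dnorm(z),
                   -Inf, Inf, rel.tol = 1e-10)$value
}
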
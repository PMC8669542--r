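# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# Hand-written 6-row table: 3 patients x 1 occasion x 2 instruments.
tiny_table <- function() {
  data.frame(
    patient_id = rep(c("p1", "p2", "p3"), each = 2),
    occasion_id = "d1",
    instrument = rep(c("CAM", "3DCAM"), 3),
    rater_id = c("r1", "r2", "r2", "r1", "r1", "r3"),
    delirium = c(1L, 1L, 0L, 1L, 0L, 0L),
    acute_change = c(1L, 0L, 0L, 0L, 0L, 0L),
    inattention = c(1L, 1L, 0L, 1L, 0L, 0L),
    disorganized_thinking = c(0L, 1L, 0L, 0L, 0L, 0L),
    aloc = c(0L, 0L, 0L, 0L, 0L, 0L),
    duration_minutes = c(8, 3, 9, 2, 7, 4),
    stringsAsFactors = FALSE)
}

# Small simulated cohort with every occasion count fixed.
small_cohort <- function(n_patients = 20, n_occ = 2, n_raters = 4, seed = 1,
                         ...) {
  cfg <- simulation_config(
    n_patients = n_patients, n_raters = n_raters,
    occasions = list(type = "probs", probs = setNames(1, n_occ)),
    seed = seed, ...)
  simulate_cohort(cfg)
}

# Deterministic permutation relabeling of an identifier column.
relabel_ids <- function(ids, prefix, seed = 99) {
  set.seed(seed)
  lev <- unique(ids)
  new <- setNames(paste0(prefix, sample(length(lev))), lev)
  unname(new[ids])
}

# Construct a minimal glmm_fit-like object for closed-form checks.
fake_fit <- function(beta, patients = c("A", "B"), eb = list(),
                     vc = list(), converged = TRUE) {
  structure(list(beta = beta,
                 beta_cov = diag(length(beta)),
                 variance_components = vc, eb_modes = eb,
                 loglik = NA_real_, converged = converged,
                 boundary = FALSE, patients = patients,
                 spec = glmm_spec()),
            class = "glmm_fit")
}
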
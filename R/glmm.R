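#' Specify a Bernoulli-logit mixed model
#'
#' The agreement analysis uses models of the form
#' `logit P(y = 1) = beta0 + beta_method * [m = 3DCAM] + b_i + d_im + c_r`
#' with patient random intercepts `b_i`, patient-by-method effects `d_im`
#' (one level per patient per instrument, shared SD), and rater random
#' intercepts `c_r`.
#'
#' @param response Response column: `"delirium"` or one of the four cardinal
#'   features.
#' @param fixed Fixed-effect terms: `"intercept"` (always included) and
#'   optionally `"method"` (the 3D-CAM-vs-CAM indicator).
#' @param random Subset of `c("patient_intercept", "rater_intercept",
#'   "patient_by_method")`; `patient_by_method` requires
#'   `patient_intercept`.
#' @return A list classed `"glmm_spec"`.
#' @export
glmm_spec <- function(response = "delirium",
                      fixed = c("intercept", "method"),
                      random = c("patient_intercept", "rater_intercept",
                                 "patient_by_method")) {
  stopifnot(length(response) == 1L)
  fixed <- union("intercept", match.arg(fixed, several.ok = TRUE))
  if (length(random))
    random <- match.arg(random, several.ok = TRUE)
  if ("patient_by_method" %in% random &&
      !"patient_intercept" %in% random)
    stop("patient_by_method requires patient_intercept")
  if ("patient_by_method" %in% random && !"method" %in% fixed)
    stop("patient_by_method requires the method fixed effect")
  out <- list(response = response, fixed = fixed, random = random)
  class(out) <- "glmm_spec"
  out
}

#' Fitting control parameters
#'
#' @param max_iter Maximum outer likelihood evaluations before giving up.
#' @param rel_tol Relative log-likelihood change declaring outer convergence.
#' @param grad_tol Infinity-norm tolerance on the outer gradient (free,
#'   non-boundary coordinates) required for `converged = TRUE`.
#' @param inner_tol Gradient tolerance of the penalized Newton solve for
#'   the random-effect modes.
#' @param inner_max Maximum inner Newton iterations.
#' @param agq_order Number of adaptive Gauss-Hermite nodes (used when the
#'   only random term is the patient intercept).
#' @param method `"auto"` picks adaptive Gauss-Hermite for patient-only
#'   models, the Laplace approximation otherwise; `"laplace"` or `"agq"`
#'   force a method; `"ml"` is plain maximum likelihood (no random terms).
#' @param sigma_floor Lower bound for random-effect SDs during
#'   optimization; a component ending at the floor is reported as 0 with a
#'   boundary flag.
#' @param sigma_ceiling Upper bound for random-effect SDs.  Binary
#'   responses can be patient-level quasi-separated (every replicate within
#'   a random-effect level concordant), in which case the likelihood is
#'   monotone in the SD and the estimate diverges; the fit then stops at
#'   the ceiling and is flagged as a boundary fit.
#' @return A list classed `"glmm_control"`.
#' @export
glmm_control <- function(max_iter = 500L, rel_tol = 1e-8, grad_tol = 1e-5,
                         inner_tol = 1e-10, inner_max = 50L,
                         agq_order = 15L,
                         method = c("auto", "laplace", "agq", "agq2", "ml"),
                         sigma_floor = 1e-6, sigma_ceiling = 10) {
  method <- match.arg(method)
  out <- list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
              grad_tol = grad_tol, inner_tol = inner_tol,
              inner_max = as.integer(inner_max),
              agq_order = as.integer(agq_order), method = method,
              sigma_floor = sigma_floor, sigma_ceiling = sigma_ceiling)
  class(out) <- "glmm_control"
  out
}

log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

# Model matrices and random-effect index layout for one spec.
build_design <- function(tab, spec) {
  tab <- as.data.frame(tab)
  y <- tab[[spec$response]]
  keep <- !is.na(y)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing '", spec$response,
            "' excluded from this fit")
    tab <- tab[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  meth <- as.integer(tab$instrument == "3DCAM")
  has_method <- "method" %in% spec$fixed
  X <- if (has_method) cbind(intercept = 1, method = meth)
       else cbind(intercept = rep(1, n))
  patients <- sort(unique(tab$patient_id))
  raters <- sort(unique(tab$rater_id))
  np <- length(patients)
  nr <- length(raters)
  ip <- match(tab$patient_id, patients)
  ir <- match(tab$rater_id, raters)

  has_p <- "patient_intercept" %in% spec$random
  has_d <- "patient_by_method" %in% spec$random
  has_r <- "rater_intercept" %in% spec$random
  blocks <- list()
  offset <- 0L
  cols <- list()
  if (has_p) {
    cols$patient <- ip
    blocks$patient <- list(start = offset, len = np)
    offset <- offset + np
  }
  if (has_d) {
    cols$patient_by_method <- offset + (meth * np) + ip
    blocks$patient_by_method <- list(start = offset, len = 2L * np)
    offset <- offset + 2L * np
  }
  if (has_r) {
    cols$rater <- offset + ir
    blocks$rater <- list(start = offset, len = nr)
    offset <- offset + nr
  }
  q <- offset
  Z <- NULL
  if (q > 0) {
    ii <- rep(seq_len(n), times = length(cols))
    jj <- unlist(cols, use.names = FALSE)
    Z <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, q))
  }
  list(y = y, X = X, Z = Z, Zt = if (!is.null(Z)) Matrix::t(Z),
       n = n, q = q, np = np, nr = nr, ip = ip, ir = ir, meth = meth,
       patients = patients, raters = raters, blocks = blocks,
       has_p = has_p, has_d = has_d, has_r = has_r,
       has_method = has_method, tab = tab)
}

# Expand the per-term SD vector to the per-coefficient prior precision.
prior_precision <- function(des, sigmas) {
  dinv <- numeric(des$q)
  for (term in names(des$blocks)) {
    blk <- des$blocks[[term]]
    dinv[blk$start + seq_len(blk$len)] <- 1 / sigmas[[term]]^2
  }
  dinv
}

# Penalized Newton solve for the random-effect modes given (beta, sigmas).
# Step-halving keeps the penalized log-likelihood monotone.
inner_modes <- function(des, beta, dinv, u0, control) {
  xb <- drop(des$X %*% beta)
  u <- u0
  pen <- function(u, eta) sum(des$y * eta - log1pexp(eta)) -
    0.5 * sum(dinv * u^2)
  eta <- xb + as.numeric(des$Z %*% u)
  f <- pen(u, eta)
  H <- NULL
  for (it in seq_len(control$inner_max)) {
    mu <- plogis(eta)
    g <- as.numeric(des$Zt %*% (des$y - mu)) - dinv * u
    if (max(abs(g)) < control$inner_tol) break
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- Matrix::forceSymmetric(
      des$Zt %*% (w * des$Z) + Matrix::Diagonal(x = dinv))
    delta <- as.numeric(Matrix::solve(H, g))
    step <- 1
    repeat {
      u_new <- u + step * delta
      eta_new <- xb + as.numeric(des$Z %*% u_new)
      f_new <- pen(u_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { u_new <- u; eta_new <- eta; f_new <- f; break }
    }
    if (abs(f_new - f) < 1e-13 * (abs(f) + 1)) {
      u <- u_new; eta <- eta_new; f <- f_new; break
    }
    u <- u_new; eta <- eta_new; f <- f_new
  }
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- Matrix::forceSymmetric(
    des$Zt %*% (w * des$Z) + Matrix::Diagonal(x = dinv))
  list(u = u, f = f, H = H)
}

# Laplace-approximate marginal log-likelihood.
laplace_loglik <- function(des, beta, sigmas, state, control) {
  dinv <- prior_precision(des, sigmas)
  sol <- inner_modes(des, beta, dinv, state$u, control)
  state$u <- sol$u
  ld <- as.numeric(Matrix::determinant(sol$H, logarithm = TRUE)$modulus)
  sol$f + 0.5 * sum(log(dinv)) - 0.5 * ld
}

gh_nodes <- function(order) pracma::gaussHermite(order)

# Adaptive Gauss-Hermite marginal log-likelihood; patient intercept only.
agq_loglik <- function(des, beta, sigma_p, state, control) {
  gh <- state$gh
  xb <- drop(des$X %*% beta)
  total <- 0
  modes <- numeric(des$np)
  for (i in seq_len(des$np)) {
    rows <- which(des$ip == i)
    yi <- des$y[rows]; oi <- xb[rows]
    gfun <- function(b) {
      eta <- oi + b
      sum(yi * eta - log1pexp(eta)) + dnorm(b, 0, sigma_p, log = TRUE)
    }
    b <- state$modes[i]
    for (it in 1:50) {
      mu <- plogis(oi + b)
      g1 <- sum(yi - mu) - b / sigma_p^2
      g2 <- -sum(pmax(mu * (1 - mu), 1e-12)) - 1 / sigma_p^2
      step <- -g1 / g2
      # damped Newton: the 1-D objective is concave, full steps are safe
      # once near the mode; cap very large moves
      step <- sign(step) * min(abs(step), 5 * sigma_p + 1)
      b <- b + step
      if (abs(g1) < control$inner_tol) break
    }
    modes[i] <- b
    tau <- 1 / sqrt(sum(pmax(plogis(oi + b) * (1 - plogis(oi + b)), 1e-12)) +
                      1 / sigma_p^2)
    z <- b + sqrt(2) * tau * gh$x
    lg <- vapply(z, gfun, numeric(1)) + gh$x^2 + log(gh$w)
    m <- max(lg)
    total <- total + m + log(sum(exp(lg - m))) + 0.5 * log(2) + log(tau)
  }
  state$modes <- modes
  total
}

# Adaptive Gauss-Hermite for patient intercept + patient-by-method (no
# rater).  Per patient the two method-level effects a_m = b_i + d_im form
# a bivariate normal with variance sp^2 + sd^2 and covariance sp^2; the
# marginal likelihood factorizes over patients and each factor is
# integrated on an adaptive tensor grid centered at the 2-D conditional
# mode.  Near-singular corners (one SD at the floor) reduce to the exact
# 1-D limits.
agq2_loglik <- function(des, beta, sp, sd_i, state, control) {
  gh <- state$gh
  xb <- drop(des$X %*% beta)
  if (sd_i < 1e-5) return(agq_loglik_collapsed(des, beta, sqrt(sp^2 + sd_i^2),
                                               state, control))
  if (sp < 1e-5) return(agq_indep_loglik(des, beta, sqrt(sp^2 + sd_i^2),
                                         state, control))
  Sig <- matrix(c(sp^2 + sd_i^2, sp^2, sp^2, sp^2 + sd_i^2), 2, 2)
  Siginv <- solve(Sig)
  ld_Sig <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
  k <- length(gh$x)
  zz <- cbind(rep(gh$x, each = k), rep(gh$x, times = k))
  lw2 <- rep(log(gh$w), each = k) + rep(log(gh$w), times = k) +
    zz[, 1]^2 + zz[, 2]^2
  total <- 0
  modes <- state$modes2
  for (i in seq_len(des$np)) {
    rows <- which(des$ip == i)
    yi <- des$y[rows]; oi <- xb[rows]; mi <- des$meth[rows] + 1L
    a <- modes[i, ]
    # 2-D Newton for the conditional mode
    for (it in 1:60) {
      eta <- oi + a[mi]
      mu <- plogis(eta)
      r <- yi - mu
      g <- c(sum(r[mi == 1L]), sum(r[mi == 2L])) - as.numeric(Siginv %*% a)
      w <- pmax(mu * (1 - mu), 1e-12)
      Hc <- diag(c(sum(w[mi == 1L]), sum(w[mi == 2L])), 2) + Siginv
      a <- a + solve(Hc, g)
      if (max(abs(g)) < control$inner_tol) break
    }
    modes[i, ] <- a
    eta <- oi + a[mi]
    w <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-12)
    Hc <- diag(c(sum(w[mi == 1L]), sum(w[mi == 2L])), 2) + Siginv
    C <- t(chol(solve(Hc)))
    A <- a + sqrt(2) * C %*% t(zz)          # 2 x k^2 effect nodes
    eta_n <- matrix(oi, length(rows), k * k) + A[mi, , drop = FALSE]
    cll <- colSums(yi * eta_n - log1pexp(eta_n))
    qf <- colSums((Siginv %*% A) * A)
    lg <- lw2 + cll - 0.5 * qf - log(2 * pi) - 0.5 * ld_Sig
    m <- max(lg)
    total <- total + m + log(sum(exp(lg - m))) + log(2) +
      sum(log(diag(C)))
  }
  state$modes2 <- modes
  total
}

# 1-D AGQ over the collapsed patient effect (sigma_interaction at 0): both
# methods share a single N(0, s^2) effect.
agq_loglik_collapsed <- function(des, beta, s, state, control) {
  des1 <- des
  agq_loglik(des1, beta, s, state, control)
}

# Independent per-(patient, method) 1-D AGQ (sigma_patient at 0).
agq_indep_loglik <- function(des, beta, s, state, control) {
  gh <- state$gh
  xb <- drop(des$X %*% beta)
  total <- 0
  for (i in seq_len(des$np)) {
    for (m in 0:1) {
      rows <- which(des$ip == i & des$meth == m)
      if (!length(rows)) next
      yi <- des$y[rows]; oi <- xb[rows]
      b <- 0
      for (it in 1:50) {
        mu <- plogis(oi + b)
        g1 <- sum(yi - mu) - b / s^2
        g2 <- -sum(pmax(mu * (1 - mu), 1e-12)) - 1 / s^2
        b <- b - g1 / g2
        if (abs(g1) < control$inner_tol) break
      }
      tau <- 1 / sqrt(sum(pmax(plogis(oi + b) * (1 - plogis(oi + b)),
                               1e-12)) + 1 / s^2)
      z <- b + sqrt(2) * tau * gh$x
      lg <- vapply(z, function(bb) {
        eta <- oi + bb
        sum(yi * eta - log1pexp(eta)) + dnorm(bb, 0, s, log = TRUE)
      }, numeric(1)) + gh$x^2 + log(gh$w)
      mx <- max(lg)
      total <- total + mx + log(sum(exp(lg - mx))) + 0.5 * log(2) + log(tau)
    }
  }
  total
}

bernoulli_loglik <- function(des, beta) {
  eta <- drop(des$X %*% beta)
  sum(des$y * eta - log1pexp(eta))
}

# Small pseudo-inverse used when the outer Hessian is numerically singular.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit a Bernoulli-logit mixed model
#'
#' Maximizes the approximate marginal likelihood over fixed effects and
#' random-effect SDs (the SDs on the log scale).  Patient-only models use
#' adaptive Gauss-Hermite quadrature (default order 15); models with
#' crossed rater effects or patient-by-method effects use the Laplace
#' approximation; a spec without random terms reduces to ordinary logistic
#' regression fitted by the same optimizer.
#'
#' @param tab A validated assessment table.
#' @param spec A [glmm_spec()].
#' @param control A [glmm_control()].
#' @return A list classed `"glmm_fit"`: `beta` (named fixed effects),
#'   `beta_cov`, `variance_components` (named `sigma2_*`, natural scale, 0
#'   at the boundary), `sigmas`, `eb_modes` (per-term empirical-Bayes
#'   posterior modes), `loglik`, `converged`, `boundary`, `n_iter`,
#'   `gradient_norm`, `method`, `trace` (accepted log-likelihood values),
#'   plus the spec and level tables.
#' @export
fit_glmm <- function(tab, spec, control = glmm_control()) {
  stopifnot(inherits(spec, "glmm_spec"))
  des <- build_design(tab, spec)
  if ((des$has_p || des$has_d) && des$np < 2)
    stop("need at least 2 patients to estimate patient variance components")
  if (des$has_method && length(unique(des$meth)) < 2)
    stop("method fixed effect requires both instruments in the data")
  if (length(unique(des$y)) < 2)
    stop("response is constant; model not estimable")
  if (des$has_method) {
    for (m in 0:1)
      if (length(unique(des$y[des$meth == m])) < 2)
        stop("complete separation: response is constant within the ",
             c("CAM", "3DCAM")[m + 1],
             " arm; the method effect diverges and the fit cannot converge")
  }

  terms <- names(des$blocks)
  k <- length(terms)
  method <- control$method
  if (method == "auto")
    method <- if (k == 0) "ml"
              else if (identical(terms, "patient")) "agq"
              else if (identical(terms, c("patient", "patient_by_method")))
                "agq2"
              else "laplace"
  if (method == "agq" && !identical(terms, "patient"))
    stop("adaptive Gauss-Hermite supports the patient-intercept-only model")
  if (method == "agq2" &&
      !identical(terms, c("patient", "patient_by_method")))
    stop("2-D adaptive Gauss-Hermite requires patient_intercept + ",
         "patient_by_method and no rater term")
  if (method == "ml" && k > 0)
    stop("method 'ml' requires a spec without random terms")

  # starting values: plain logistic regression for beta, unit SDs
  beta0 <- tryCatch(
    stats::glm.fit(des$X, des$y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, ncol(des$X)))
  beta0[!is.finite(beta0)] <- 0
  p <- ncol(des$X)
  par0 <- c(beta0, rep(0, k))
  lower <- c(rep(-Inf, p), rep(log(control$sigma_floor), k))
  upper <- c(rep(Inf, p), rep(log(control$sigma_ceiling), k))

  state <- new.env(parent = emptyenv())
  state$u <- if (des$q > 0) numeric(des$q) else NULL
  state$modes <- numeric(des$np)
  state$modes2 <- matrix(0, des$np, 2)
  if (method %in% c("agq", "agq2")) state$gh <- gh_nodes(control$agq_order)

  evals <- 0L
  best <- -Inf
  trace <- numeric(0)
  loglik_at <- function(par) {
    evals <<- evals + 1L
    beta <- par[seq_len(p)]
    sig <- setNames(as.list(exp(par[p + seq_len(k)])), terms)
    ll <- switch(method,
      ml = bernoulli_loglik(des, beta),
      agq = agq_loglik(des, beta, sig$patient, state, control),
      agq2 = agq2_loglik(des, beta, sig$patient, sig$patient_by_method,
                         state, control),
      laplace = laplace_loglik(des, beta, sig, state, control))
    if (!is.finite(ll)) ll <- -1e10
    if (ll > best) { best <<- ll; trace <<- c(trace, ll) }
    ll
  }
  negll <- function(par) -loglik_at(par)
  num_grad <- function(par, free = rep(TRUE, length(par))) {
    g <- numeric(length(par))
    for (j in which(free)) {
      h <- 1e-5 * (1 + abs(par[j]))
      up <- dn <- par
      up[j] <- par[j] + h; dn[j] <- par[j] - h
      g[j] <- (negll(up) - negll(dn)) / (2 * h)
    }
    g
  }

  par <- par0
  if (length(par) >= 2) {
    nm <- optim(par, negll, method = "Nelder-Mead",
                control = list(maxit = min(300L, control$max_iter),
                               reltol = 1e-10))
    par <- nm$par
  }
  opt <- nlminb(par, negll, gradient = num_grad, lower = lower,
                upper = upper,
                control = list(rel.tol = control$rel_tol,
                               iter.max = control$max_iter,
                               eval.max = 4L * control$max_iter))
  par <- pmin(pmax(opt$par, lower), upper)

  # damped Newton polish on the outer parameters: numeric gradient and
  # Hessian, halving the step until the objective does not worsen; drives
  # the gradient below the convergence tolerance and yields the Hessian
  # used for Wald covariance
  floor_tol <- log(control$sigma_floor) + 1e-6
  ceil_tol <- log(control$sigma_ceiling) - 1e-6
  interior <- function(par)
    c(rep(TRUE, p),
      par[p + seq_len(k)] > floor_tol & par[p + seq_len(k)] < ceil_tol)
  hess_free <- NULL
  free <- rep(TRUE, length(par))
  grad <- NULL
  for (pol in seq_len(20L)) {
    free <- interior(par)
    grad <- num_grad(par, free)
    if (max(abs(grad[free])) < 0.5 * control$grad_tol) break
    hess_free <- tryCatch(
      optimHess(par[free], function(pf) {
        full <- par; full[free] <- pf; negll(full)
      }),
      error = function(e) NULL)
    if (is.null(hess_free)) break
    step <- tryCatch(-solve(hess_free, grad[free]),
                     error = function(e) -pinv(hess_free) %*% grad[free])
    f_cur <- negll(par)
    moved <- FALSE
    lam <- 1
    for (h in 1:12) {
      cand <- par
      cand[free] <- par[free] + lam * step
      cand <- pmin(pmax(cand, lower), upper)
      if (negll(cand) <= f_cur + 1e-10) { par <- cand; moved <- TRUE; break }
      lam <- lam / 2
    }
    if (!moved) break
  }

  beta <- setNames(par[seq_len(p)], colnames(des$X))
  log_sig <- par[p + seq_len(k)]
  at_floor <- log_sig <= floor_tol
  at_ceiling <- log_sig >= ceil_tol
  sigmas <- setNames(as.list(exp(log_sig)), terms)
  free <- c(rep(TRUE, p), !at_floor & !at_ceiling)

  loglik <- loglik_at(par)
  grad <- num_grad(par, free)
  grad_norm <- if (any(free)) max(abs(grad[free])) else 0
  if (is.null(hess_free) || length(grad[free]) != nrow(hess_free))
    hess_free <- tryCatch(
      optimHess(par[free], function(pf) {
        full <- par; full[free] <- pf; negll(full)
      }),
      error = function(e) NULL)
  cov_full <- matrix(NA_real_, length(par), length(par))
  if (!is.null(hess_free)) {
    cov_free <- tryCatch(solve(hess_free), error = function(e) pinv(hess_free))
    cov_full[free, free] <- cov_free
  }
  beta_cov <- cov_full[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(beta_cov) <- list(names(beta), names(beta))

  # empirical-Bayes modes at the optimum
  eb <- list()
  if (method == "laplace") {
    dinv <- prior_precision(des, sigmas)
    sol <- inner_modes(des, beta, dinv, state$u, control)
    u <- sol$u
    for (term in terms) {
      blk <- des$blocks[[term]]
      v <- u[blk$start + seq_len(blk$len)]
      eb[[term]] <- switch(term,
        patient = setNames(v, des$patients),
        rater = setNames(v, des$raters),
        patient_by_method = matrix(v, des$np, 2,
                                   dimnames = list(des$patients, INSTRUMENTS)))
    }
  } else if (method == "agq") {
    loglik <- loglik_at(par)  # refresh state$modes at the optimum
    eb$patient <- setNames(state$modes, des$patients)
  } else if (method == "agq2") {
    loglik <- loglik_at(par)  # refresh state$modes2 at the optimum
    # decompose the per-method mode a_m = b + d_m into the prior-optimal
    # (b, d_CAM, d_3DCAM): b = sp^2 (a1 + a2) / (sd^2 + 2 sp^2)
    sp2 <- sigmas$patient^2
    sd2 <- sigmas$patient_by_method^2
    a <- state$modes2
    bvec <- if (sd2 + 2 * sp2 > 0) sp2 * (a[, 1] + a[, 2]) / (sd2 + 2 * sp2)
            else numeric(des$np)
    eb$patient <- setNames(bvec, des$patients)
    eb$patient_by_method <- matrix(c(a[, 1] - bvec, a[, 2] - bvec),
                                   des$np, 2,
                                   dimnames = list(des$patients, INSTRUMENTS))
  }

  vc <- list()
  for (j in seq_along(terms)) {
    nm_out <- c(patient = "sigma2_patient", rater = "sigma2_rater",
                patient_by_method = "sigma2_interaction")[[terms[j]]]
    vc[[nm_out]] <- if (at_floor[j]) 0 else exp(log_sig[j])^2
  }
  if (any(at_ceiling))
    warning("variance component(s) ",
            paste(terms[at_ceiling], collapse = ", "),
            " reached the upper boundary (sigma = ", control$sigma_ceiling,
            "): the response is quasi-separated at that level and the ",
            "component is not identified")

  fit <- list(beta = beta, beta_cov = beta_cov,
              variance_components = vc,
              sigmas = sigmas,
              eb_modes = eb,
              loglik = loglik,
              converged = is.finite(loglik) && grad_norm < control$grad_tol,
              boundary = any(at_floor) || any(at_ceiling),
              boundary_upper = any(at_ceiling),
              n_iter = evals,
              gradient_norm = grad_norm,
              method = method,
              trace = trace,
              spec = spec,
              control = control,
              patients = des$patients,
              raters = des$raters,
              n_obs = des$n)
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Bernoulli-logit mixed model (", x$method, "), response '",
      x$spec$response, "'\n", sep = "")
  cat("  fixed effects:\n")
  se <- sqrt(diag(x$beta_cov))
  for (nm in names(x$beta))
    cat(sprintf("    %-10s %8.4f (SE %.4f)\n", nm, x$beta[[nm]], se[[nm]]))
  if (length(x$variance_components)) {
    cat("  variance components:\n")
    for (nm in names(x$variance_components))
      cat(sprintf("    %-18s %.4f\n", nm, x$variance_components[[nm]]))
  }
  cat(sprintf("  loglik %.4f, converged %s%s, %d evaluations\n",
              x$loglik, x$converged, if (x$boundary) " (boundary)" else "",
              x$n_iter))
  invisible(x)
}

#' Brute-force marginal log-likelihood by dense grid integration
#'
#' Testing oracle: integrates the random effects out of the Bernoulli-logit
#' likelihood on a dense tensor grid, independently of the Laplace/AGQ
#' machinery.  Supports patient-level effects only (patient intercept, and
#' optionally the patient-by-method effect, which together give a bivariate
#' correlated patient-method effect that is integrated on a 2-D grid);
#' crossed rater effects do not factorize by patient and are refused.  The
#' cost is exponential in the grid dimension by design; at the default grid
#' a refinement changes the result by less than 1e-6.
#'
#' @param tab A validated assessment table (at most 5 patients).
#' @param spec A [glmm_spec()] without `rater_intercept`.
#' @param params List with `beta0`, optionally `beta_method`,
#'   `sigma_patient`, and optionally `sigma_interaction`.
#' @param grid List with `points` (nodes per dimension, default 401 in 1-D
#'   and 161 in 2-D) and `half_width` (integration range in prior SDs,
#'   default 10).
#' @return The marginal log-likelihood (a number).
#' @export
marginal_loglik_bruteforce <- function(tab, spec, params,
                                       grid = list(points = NULL,
                                                   half_width = 10)) {
  stopifnot(inherits(spec, "glmm_spec"))
  if ("rater_intercept" %in% spec$random)
    stop("too many random-effect dimensions: the brute-force oracle ",
         "supports patient-level effects only")
  des <- build_design(tab, spec)
  if (des$np > 5)
    stop("brute-force oracle limited to 5 patients (cost is exponential)")
  has_d <- des$has_d
  sp <- params$sigma_patient %||% 0
  sd_i <- if (has_d) params$sigma_interaction %||% 0 else 0
  beta <- c(params$beta0,
            if (des$has_method) params$beta_method %||% 0)
  xb <- drop(des$X %*% beta)
  hw <- grid$half_width %||% 10
  npts <- grid$points %||% (if (has_d && sd_i > 0 && sp > 0) 161 else 401)

  cond_ll <- function(rows, eff) {
    eta <- xb[rows] + eff
    sum(des$y[rows] * eta - log1pexp(eta))
  }
  log_trapz <- function(lg, dx) {
    m <- max(lg)
    wts <- rep(1, length(lg)); wts[c(1, length(lg))] <- 0.5
    m + log(sum(wts * exp(lg - m)) * dx)
  }

  total <- 0
  for (i in seq_len(des$np)) {
    rows <- which(des$ip == i)
    m_i <- des$meth[rows]
    if (!des$has_p || (sp == 0 && sd_i == 0)) {
      total <- total + cond_ll(rows, 0)
    } else if (!has_d || sd_i == 0) {
      z <- seq(-hw, hw, length.out = npts)
      b <- sp * z
      lg <- vapply(seq_along(b), function(j)
        cond_ll(rows, b[j]) + dnorm(z[j], log = TRUE), numeric(1))
      total <- total + log_trapz(lg, z[2] - z[1])
    } else if (sp == 0) {
      # independent per-method effects: product of two 1-D integrals
      for (m in 0:1) {
        rs <- rows[m_i == m]
        if (!length(rs)) next
        z <- seq(-hw, hw, length.out = npts)
        dd <- sd_i * z
        lg <- vapply(seq_along(dd), function(j)
          cond_ll(rs, dd[j]) + dnorm(z[j], log = TRUE), numeric(1))
        total <- total + log_trapz(lg, z[2] - z[1])
      }
    } else {
      # a_im = b_i + d_im: bivariate normal, integrate on a 2-D grid of
      # independent standard coordinates through the Cholesky factor
      Sig <- matrix(c(sp^2 + sd_i^2, sp^2, sp^2, sp^2 + sd_i^2), 2, 2)
      L <- t(chol(Sig))
      z <- seq(-hw, hw, length.out = npts)
      dx <- z[2] - z[1]
      lw <- dnorm(z, log = TRUE)
      lmat <- matrix(0, npts, npts)
      for (j1 in seq_len(npts)) {
        a <- L %*% rbind(z[j1], z)   # 2 x npts: effects (CAM, 3DCAM)
        for (j2 in seq_len(npts)) {
          eff <- a[m_i + 1L, j2]
          lmat[j1, j2] <- cond_ll(rows, eff) + lw[j1] + lw[j2]
        }
      }
      m <- max(lmat)
      wts <- rep(1, npts); wts[c(1, npts)] <- 0.5
      W2 <- outer(wts, wts)
      total <- total + m + log(sum(W2 * exp(lmat - m)) * dx * dx)
    }
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald test and confidence interval for a fixed effect
#'
#' `estimate +/- z_{1-alpha/2} * SE` with a two-sided normal p-value, on
#' the logit (natural model) scale.
#'
#' @param fit A converged [fit_glmm()] result.
#' @param coefficient Name of the fixed effect (`"intercept"` or
#'   `"method"`).
#' @param level Confidence level (default 0.95).
#' @return A list classed `"fixed_effect_test"` with `estimate`,
#'   `std_error`, `ci_low`, `ci_high`, `p_value`.
#' @export
wald_test_fixed <- function(fit, coefficient = "method", level = 0.95) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!coefficient %in% names(fit$beta))
    stop("unknown coefficient: ", coefficient)
  if (!isTRUE(fit$converged))
    warning("fit did not satisfy the convergence criteria; ",
            "Wald inference may be unreliable")
  est <- fit$beta[[coefficient]]
  se <- sqrt(fit$beta_cov[coefficient, coefficient])
  wald_from_estimate(est, se, level, coefficient)
}

#' Wald interval from an estimate and standard error
#'
#' @param estimate Point estimate.
#' @param std_error Standard error.
#' @param level Confidence level.
#' @param coefficient Optional label.
#' @return A `"fixed_effect_test"` list.
#' @export
wald_from_estimate <- function(estimate, std_error, level = 0.95,
                               coefficient = NA_character_) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- list(coefficient = coefficient,
              estimate = estimate, std_error = std_error,
              ci_low = estimate - z * std_error,
              ci_high = estimate + z * std_error,
              p_value = 2 * pnorm(-abs(estimate / std_error)),
              level = level)
  class(out) <- "fixed_effect_test"
  out
}

#' @export
print.fixed_effect_test <- function(x, ...) {
  cat(sprintf("%s: %.3f (%.0f%% CI %.3f to %.3f), P = %.3g\n",
              if (is.na(x$coefficient)) "estimate" else x$coefficient,
              x$estimate, 100 * x$level, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Latent linear predictor and probability for one patient and instrument
#'
#' `eta = beta0 + beta_method * [m = 3DCAM] + b_i + d_im` using the
#' empirical-Bayes posterior modes; rater effects are set to their
#' population mean of 0, so the prediction describes the patient-by-method
#' propensity free of the particular assessor.
#'
#' @param fit A [fit_glmm()] result.
#' @param patient_id Patient identifier present in the fitted data.
#' @param instrument `"CAM"` or `"3DCAM"`.
#' @return List with `eta` and `p = plogis(eta)`.
#' @export
predict_latent <- function(fit, patient_id, instrument = c("CAM", "3DCAM")) {
  stopifnot(inherits(fit, "glmm_fit"))
  instrument <- match.arg(instrument)
  if (!patient_id %in% fit$patients)
    stop("unknown patient: ", patient_id)
  eta <- fit$beta[["intercept"]]
  if ("method" %in% names(fit$beta) && instrument == "3DCAM")
    eta <- eta + fit$beta[["method"]]
  if (!is.null(fit$eb_modes$patient))
    eta <- eta + fit$eb_modes$patient[[patient_id]]
  if (!is.null(fit$eb_modes$patient_by_method))
    eta <- eta + fit$eb_modes$patient_by_method[patient_id, instrument]
  list(eta = unname(eta), p = unname(plogis(eta)))
}
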
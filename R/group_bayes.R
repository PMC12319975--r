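#' Fixed-effects Bayesian model selection
#'
#' Posterior model probabilities proportional to `exp(colSums(F))`, computed
#' with max subtraction for numerical stability. Treats every subject as
#' sharing one model.
#'
#' @param F Subjects x models matrix of free energies (nats); >= 2 models.
#' @return A `bms_result`: `alpha` (NA for FFX), `expected_prob`,
#'   `exceedance_prob` (equal to the posterior probabilities for FFX),
#'   `method`.
#' @export
ffx_bms <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(is.finite(F)), ncol(F) >= 2)
  s <- colSums(F)
  p <- exp(s - max(s))
  p <- p / sum(p)
  structure(list(alpha = rep(NA_real_, length(p)), expected_prob = p,
                 exceedance_prob = p, method = "FFX",
                 models = colnames(F)), class = "bms_result")
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over per-subject model frequencies: iterate
#' `u_nk = exp(F_nk + psi(alpha_k) - psi(sum alpha))`, normalize to subject
#' responsibilities `g_nk`, and set `alpha = alpha0 + colSums(g)` until the
#' concentration parameters change by less than 1e-4. Exceedance
#' probabilities (probability that a model's population frequency exceeds
#' all others) use the analytic Beta marginal when there are two models, and
#' seeded Dirichlet Monte Carlo otherwise.
#'
#' @param F Subjects x models matrix of free energies (nats).
#' @param alpha0 Dirichlet prior concentration (default 1).
#' @param n_samples Monte Carlo draws for exceedance when K > 2.
#' @param seed Seed for the Monte Carlo draws.
#' @return A `bms_result` with `alpha`, `expected_prob`, `exceedance_prob`,
#'   `method = "RFX"`.
#' @export
rfx_bms <- function(F, alpha0 = 1, n_samples = 1e5, seed = 1) {
  F <- as.matrix(F)
  stopifnot(all(is.finite(F)), ncol(F) >= 2, nrow(F) >= 1, alpha0 > 0)
  N <- nrow(F); K <- ncol(F)
  alpha <- rep(alpha0, K)
  for (sweep in 1:500) {
    lu <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-4) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (sweep == 500)
      stop("RFX BMS did not converge in 500 sweeps; last alpha: ",
           paste(signif(alpha, 6), collapse = ", "))
  }
  expected <- alpha / sum(alpha)
  if (K == 2) {
    # p1 ~ Beta(a1, a2); P(p1 > p2) = P(p1 > 1/2)
    xp <- c(stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE),
            stats::pbeta(0.5, alpha[2], alpha[1], lower.tail = FALSE))
  } else {
    rng <- local_rng(seed)
    draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                    n_samples, K)
    rng()
    win <- max.col(draws, ties.method = "first")
    xp <- tabulate(win, K) / n_samples
  }
  structure(list(alpha = alpha, expected_prob = expected,
                 exceedance_prob = xp, method = "RFX",
                 models = colnames(F)), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(x$method, "BMS over", length(x$expected_prob), "models\n")
  m <- rbind(expected = x$expected_prob, exceedance = x$exceedance_prob)
  colnames(m) <- x$models %||% paste0("m", seq_len(ncol(m)))
  print(round(m, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian model averaging of Gaussian posteriors
#'
#' Moment-matched Gaussian of the mixture of model-specific posteriors:
#' `mean = sum w mu`, `cov = sum w (Sigma_i + mu_i mu_i') - mu mu'`.
#' All posteriors must live on the same (named) parameter space; parameters
#' absent from a model should be entered at their prior.
#'
#' @param posteriors List of `list(mean, cov)` with identical parameter
#'   names/order.
#' @param weights Model probabilities summing to 1 (within 1e-8).
#' @return `list(mean, cov)` of the moment-matched Gaussian.
#' @export
bma <- function(posteriors, weights) {
  stopifnot(length(posteriors) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  nm <- names(posteriors[[1]]$mean)
  p <- length(posteriors[[1]]$mean)
  for (po in posteriors) stopifnot(length(po$mean) == p,
                                   identical(names(po$mean), nm))
  mu <- rep(0, p)
  for (i in seq_along(posteriors)) mu <- mu + weights[i] * posteriors[[i]]$mean
  S <- matrix(0, p, p)
  for (i in seq_along(posteriors)) {
    m <- as.numeric(posteriors[[i]]$mean)
    S <- S + weights[i] * (as.matrix(posteriors[[i]]$cov) + tcrossprod(m))
  }
  S <- S - tcrossprod(as.numeric(mu))
  dimnames(S) <- list(nm, nm)
  list(mean = mu, cov = S)
}

# Gaussians as list(mean, cov); precision of a possibly-degenerate prior:
# variance 0 (parameter removed) is mapped to a large finite precision, which
# cancels in the evidence ratio.
prec_of <- function(g, vmin = 1e-8) {
  S <- as.matrix(g$cov)
  if (all(S[row(S) != col(S)] == 0)) {
    v <- diag(S)
    diag(pmax(1 / pmax(v, vmin), 0), length(v))
  } else solve(S)
}

#' Bayesian model reduction
#'
#' Closed-form evidence change and posterior under a reduced (more
#' constrained) Gaussian prior, given the full prior and full posterior.
#' Setting a reduced prior variance to 0 removes that parameter (it is
#' clamped at the reduced prior mean). `delta_F` is the log evidence of the
#' reduced model minus that of the full model; it is exactly 0 when the
#' reduced prior equals the prior, and reductions compose additively.
#'
#' @param prior,posterior,reduced_prior `list(mean, cov)` Gaussians on the
#'   same parameter space.
#' @return `list(delta_F, mean, cov)`: the evidence change (nats) and the
#'   reduced posterior.
#' @export
bayesian_model_reduction <- function(prior, posterior, reduced_prior) {
  p <- length(prior$mean)
  stopifnot(length(posterior$mean) == p, length(reduced_prior$mean) == p)
  P0 <- prec_of(prior)
  Pq <- solve(as.matrix(posterior$cov))
  Pr <- prec_of(reduced_prior)
  Pqr <- Pq + Pr - P0
  ev <- eigen(Pqr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("reduced posterior precision is not positive definite")
  m0 <- as.numeric(prior$mean); mq <- as.numeric(posterior$mean)
  mr0 <- as.numeric(reduced_prior$mean)
  b <- Pq %*% mq + Pr %*% mr0 - P0 %*% m0
  mqr <- solve(Pqr, b)
  delta_F <- 0.5 * (logdet(Pq) + logdet(Pr) - logdet(P0) - logdet(Pqr)) +
    0.5 * (sum(b * mqr) - sum(mq * (Pq %*% mq)) - sum(mr0 * (Pr %*% mr0)) +
             sum(m0 * (P0 %*% m0)))
  Sqr <- solve(Pqr)
  nm <- names(prior$mean)
  dimnames(Sqr) <- list(nm, nm)
  list(delta_F = as.numeric(delta_F),
       mean = stats::setNames(as.numeric(mqr), nm), cov = Sqr)
}

#' Parametric empirical Bayes over subject posteriors
#'
#' Two-level Gaussian model: subject parameters are design-matrix
#' combinations of group effects plus an iid random effect whose scalar
#' precision is optimized on a log grid by maximizing the two-level model
#' evidence. Subject posterior means are treated as observations with their
#' posterior covariances; the group effect posterior is the precision
#' weighted combination. Per-parameter posterior probabilities (probability
#' the effect is nonzero, the "probability of occurrence") come from
#' Bayesian model reduction, comparing the full group prior against a prior
#' with that effect's variance shrunk to zero.
#'
#' @param subject_posteriors List (one per subject) of `list(mean, cov)` on
#'   a shared named parameter space.
#' @param design_matrix Subjects x covariates matrix; first column must be
#'   the constant 1 (group mean). Default: intercept only.
#' @param group_priors Optional `list(mean, var)` scalars or vectors for the
#'   group effects; default N(0, 1/16) per effect.
#' @param gamma Optional fixed random-effect precision (skips the grid
#'   search).
#' @return A `peb_result`: `mean`, `cov` (group effects, named
#'   `param:covariate`), `Pp`, `gamma`, `logev`.
#' @export
peb <- function(subject_posteriors, design_matrix = NULL, group_priors = NULL,
                gamma = NULL) {
  N <- length(subject_posteriors)
  stopifnot(N >= 2)
  nm <- names(subject_posteriors[[1]]$mean)
  p <- length(nm)
  X <- if (is.null(design_matrix)) matrix(1, N, 1,
                                          dimnames = list(NULL, "mean"))
  else as.matrix(design_matrix)
  stopifnot(nrow(X) == N, all(X[, 1] == 1))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  K <- ncol(X)
  cn <- colnames(X) %||% paste0("x", seq_len(K))
  bn <- as.vector(outer(nm, cn, function(a, b) paste(a, b, sep = ":")))
  # beta ordering: covariate-major (all parameters for covariate 1 first)
  mu <- lapply(subject_posteriors, function(s) as.numeric(s$mean))
  Sg <- lapply(subject_posteriors, function(s) as.matrix(s$cov))
  prior_var <- if (is.null(group_priors)) rep(1 / 16, p * K)
  else rep(as.numeric(group_priors$var), length.out = p * K)
  prior_mean <- if (is.null(group_priors)) rep(0, p * K)
  else rep(as.numeric(group_priors$mean), length.out = p * K)

  Amat <- function(i) {
    out <- matrix(0, p, p * K)
    for (k in seq_len(K)) out[, ((k - 1) * p + 1):(k * p)] <- X[i, k] * diag(p)
    out
  }
  fit_at <- function(g) {
    Q <- diag(1 / g, p)
    Pb <- diag(1 / prior_var, p * K)
    rhs <- Pb %*% prior_mean
    logev <- 0
    # accumulate precision-weighted contributions and exact marginal evidence
    bigV <- matrix(0, N * p, N * p)
    bigM <- matrix(0, N * p, p * K)
    bigy <- numeric(N * p)
    for (i in seq_len(N)) {
      Vi <- Sg[[i]] + Q
      Wi <- solve(Vi)
      Ai <- Amat(i)
      Pb <- Pb + t(Ai) %*% Wi %*% Ai
      rhs <- rhs + t(Ai) %*% Wi %*% mu[[i]]
      idx <- ((i - 1) * p + 1):(i * p)
      bigV[idx, idx] <- Vi
      bigM[idx, ] <- Ai
      bigy[idx] <- mu[[i]]
    }
    Sb <- solve(Pb)
    mb <- Sb %*% rhs
    C <- bigV + bigM %*% diag(prior_var, p * K) %*% t(bigM)
    r <- bigy - bigM %*% prior_mean
    logev <- -0.5 * (N * p * log(2 * pi) + logdet(C) +
                       sum(r * solve(C, r)))
    list(mean = stats::setNames(as.numeric(mb), bn), cov = Sb,
         logev = as.numeric(logev))
  }

  if (is.null(gamma)) {
    prec_mean <- mean(vapply(Sg, function(S) mean(1 / diag(S)), numeric(1)))
    grid <- prec_mean * 10^seq(-2, 2, length.out = 16)
    fits <- lapply(grid, fit_at)
    best <- which.max(vapply(fits, `[[`, numeric(1), "logev"))
    gamma <- grid[best]
    ft <- fits[[best]]
  } else ft <- fit_at(gamma)

  Sb <- ft$cov
  dimnames(Sb) <- list(bn, bn)
  prior_g <- list(mean = stats::setNames(prior_mean, bn),
                  cov = diag(prior_var, p * K))
  Pp <- stats::setNames(numeric(p * K), bn)
  for (j in seq_len(p * K)) {
    rv <- prior_var
    rv[j] <- 0
    red <- list(mean = prior_g$mean, cov = diag(rv, p * K))
    dF <- bayesian_model_reduction(prior_g, list(mean = ft$mean, cov = Sb),
                                   red)$delta_F
    Pp[j] <- 1 / (1 + exp(dF))
  }
  structure(list(mean = ft$mean, cov = Sb, Pp = Pp, gamma = gamma,
                 logev = ft$logev, design = X), class = "peb_result")
}

#' Retain parameters exceeding a posterior occurrence probability
#'
#' @param peb A `peb_result` (or any object with a named `Pp` vector).
#' @param threshold Probability threshold in (0, 1); strictly exceeded
#'   (default 0.75, i.e. "more than 75%").
#' @return Character vector of retained parameter names.
#' @export
occurrence_filter <- function(peb, threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  names(peb$Pp)[peb$Pp > threshold]
}
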
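#' Prior specification for model inversion
#'
#' Gaussian priors over an ordered, named parameter vector plus a Gaussian
#' prior over the observation-noise log precision. A prior variance of 0
#' fixes that parameter at its prior mean.
#'
#' @param mean Named numeric vector of prior means.
#' @param var Named numeric vector (same names) of prior variances, >= 0.
#' @param lambda_mean,lambda_var Prior mean and variance of the noise log
#'   precision (defaults N(4, 1)).
#' @return An object of class `dcm_priors`.
#' @export
dcm_priors <- function(mean, var, lambda_mean = 4, lambda_var = 1) {
  stopifnot(length(mean) == length(var), !is.null(names(mean)),
            identical(names(mean), names(var)), all(is.finite(mean)),
            all(is.finite(var)), all(var >= 0), lambda_var > 0)
  structure(list(mean = mean, var = var, lambda_mean = lambda_mean,
                 lambda_var = lambda_var), class = "dcm_priors")
}

#' Default shrinkage priors for a CMC network's free parameters
#'
#' Every extrinsic log gain (forward, backward) and input log gain gets a
#' N(0, 1/16) prior -- conventional shrinkage for log-scaling parameters --
#' and the noise log precision gets N(4, 1). Parameter names are
#' `Af:<src>-><tgt>`, `Ab:<src>-><tgt>`, `C:<region>`.
#'
#' @param spec A [network_spec()].
#' @param sd Prior standard deviation of the log-scaling parameters.
#' @return A [dcm_priors()] covering all extrinsic and input gains.
#' @export
cmc_priors <- function(spec, sd = 1 / 4) {
  nm <- c(if (nrow(spec$forward_edges)) paste0("Af:", names(spec$logA_f)),
          if (nrow(spec$backward_edges)) paste0("Ab:", names(spec$logA_b)),
          if (length(spec$input_regions)) paste0("C:", names(spec$logC)))
  m <- stats::setNames(rep(0, length(nm)), nm)
  dcm_priors(m, stats::setNames(rep(sd^2, length(nm)), nm))
}

#' Apply named parameter values to a network specification
#'
#' Writes a named parameter vector (`Af:<src>-><tgt>`, `Ab:<src>-><tgt>`,
#' `C:<region>`) onto the corresponding log-gain slots of a
#' [network_spec()], e.g. to simulate at a fitted posterior mean.
#'
#' @param spec A [network_spec()].
#' @param theta Named numeric vector of parameter values.
#' @return The updated [network_spec()].
#' @export
apply_theta <- function(spec, theta) {
  for (nm in names(theta)) {
    key <- sub("^[^:]+:", "", nm)
    if (startsWith(nm, "Af:")) spec$logA_f[key] <- theta[nm]
    else if (startsWith(nm, "Ab:")) spec$logA_b[key] <- theta[nm]
    else if (startsWith(nm, "C:")) spec$logC[key] <- theta[nm]
    else stop("unknown parameter name: ", nm)
  }
  spec
}

#' Settings for variational Laplace inversion
#'
#' @param max_iter Maximum Gauss-Newton iterations (default 64).
#' @param tol Free-energy convergence tolerance in nats (default 0.01); the
#'   scheme stops after `tol_count` consecutive proposals changing F by less
#'   than `tol`.
#' @param tol_count Consecutive small-change proposals required (default 3).
#' @param fd_step Forward finite-difference step on the (log) parameter scale.
#' @param lm_init,lm_up,lm_down Initial Levenberg-Marquardt damping and its
#'   multiplicative update on rejection / acceptance.
#' @param window Fit window (s) for ERP fits, default c(-0.05, 0.8).
#' @param fit_step Target step (s) of the fit grid; the data grid is
#'   decimated down to it (default 0.004, i.e. a 4 ms grid for 1000 Hz
#'   data; data already on a coarser grid are used as-is).
#' @return List of settings.
#' @export
invert_settings <- function(max_iter = 64, tol = 0.01, tol_count = 3,
                            fd_step = 1e-3, lm_init = 1, lm_up = 8,
                            lm_down = 2, window = c(-0.05, 0.8),
                            fit_step = 0.004) {
  list(max_iter = max_iter, tol = tol, tol_count = tol_count,
       fd_step = fd_step, lm_init = lm_init, lm_up = lm_up,
       lm_down = lm_down, window = window, fit_step = fit_step)
}

#' Log joint density of data, parameters, and noise log precision
#'
#' Gaussian log likelihood of the residuals `y - forward(theta)` at precision
#' `exp(lambda)`, plus the Gaussian log prior of the free parameters, plus
#' the Gaussian log prior of `lambda`.
#'
#' @param theta Named parameter vector (full, fixed entries included).
#' @param lambda Noise log precision.
#' @param y Numeric data vector (or matrix, flattened).
#' @param forward Function mapping `theta` to a prediction of the same shape.
#' @param priors A [dcm_priors()].
#' @return Scalar log joint; `-Inf` (with a warning) if the forward
#'   simulation is non-finite.
#' @export
log_joint <- function(theta, lambda, y, forward, priors) {
  y <- as.numeric(y)
  f <- tryCatch(as.numeric(forward(theta)), error = function(e) NA_real_)
  if (length(f) != length(y) || !all(is.finite(f))) {
    warning("non-finite forward simulation; log joint is -Inf")
    return(-Inf)
  }
  r <- y - f
  n <- length(y)
  ll <- -n / 2 * log(2 * pi) + n / 2 * lambda - exp(lambda) / 2 * sum(r^2)
  free <- priors$var > 0
  lp <- 0
  if (any(free)) {
    d <- theta[names(priors$mean)[free]] - priors$mean[free]
    v <- priors$var[free]
    lp <- sum(-0.5 * log(2 * pi * v) - d^2 / (2 * v))
  }
  lpl <- -0.5 * log(2 * pi * priors$lambda_var) -
    (lambda - priors$lambda_mean)^2 / (2 * priors$lambda_var)
  ll + lp + lpl
}

# Optimize lambda (noise log precision) given residuals and the GN curvature;
# returns lambda, its posterior variance, posterior covariance of theta, and
# the variational free energy F = accuracy - complexity.
vl_objective <- function(r, J, priors, free) {
  n <- length(r)
  rr <- sum(r^2)
  p <- sum(free)
  m0 <- priors$mean[free]
  S0 <- diag(priors$var[free], p)
  P0 <- diag(1 / priors$var[free], p)
  if (!is.finite(rr) || rr > 1e200) return(NULL)
  JtJ <- if (p) crossprod(J) else matrix(0, 0, 0)
  if (p && !all(is.finite(JtJ))) return(NULL)
  l <- priors$lambda_mean
  Sigma <- NULL
  # dF/dl = n/2 - e^l/2 (r'r + tr) - (l - l0)/v is monotone decreasing in l,
  # so the stationary point is a unique root; bracketed solve avoids the
  # overflow that plain Newton hits when residuals are small.
  for (k in 1:8) {
    Sigma <- if (p) tryCatch(solve(exp(l) * JtJ + P0), error = function(e) NULL)
    else matrix(0, 0, 0)
    if (is.null(Sigma)) return(NULL)
    tr <- if (p) sum(JtJ * Sigma) else 0
    if (!is.finite(tr)) return(NULL)
    gfun <- function(lam)
      n / 2 - exp(lam) / 2 * (rr + tr) -
        (lam - priors$lambda_mean) / priors$lambda_var
    hi <- max(60, priors$lambda_mean + priors$lambda_var * n / 2 + 10)
    l_new <- tryCatch(stats::uniroot(gfun, c(-60, hi), tol = 1e-10)$root,
                      error = function(e) NULL)
    if (is.null(l_new)) return(NULL)
    if (abs(l_new - l) < 1e-8) { l <- l_new; break }
    l <- l_new
  }
  Sigma <- if (p) solve(exp(l) * JtJ + P0) else matrix(0, 0, 0)
  tr <- if (p) sum(JtJ * Sigma) else 0
  lambda_var <- 1 / (exp(l) / 2 * (rr + tr) + 1 / priors$lambda_var)
  accuracy <- -n / 2 * log(2 * pi) + n / 2 * l - exp(l) / 2 * (rr + tr)
  list(lambda = l, lambda_var = lambda_var, Sigma = Sigma, accuracy = accuracy,
       tr = tr, P0 = P0, S0 = S0)
}

#' Invert a generic forward model by variational Laplace
#'
#' Gauss-Newton / Levenberg-Marquardt ascent on the free parameters with
#' interleaved EM updates of the noise log precision; the posterior is the
#' Laplace (Gaussian) approximation and the returned free energy
#' `F = accuracy - complexity` is the variational bound on log model
#' evidence. Accepted-step F is nondecreasing by construction. The scheme is
#' deterministic: identical inputs give identical results.
#'
#' @param y Numeric data vector (or matrix, flattened internally).
#' @param forward Function from a full named parameter vector to a prediction.
#' @param priors A [dcm_priors()].
#' @param settings [invert_settings()].
#' @return An object of class `dcm_fit`: posterior `mean` (full vector),
#'   `cov` (free parameters), `lambda`, `lambda_var`, `F`, `F_trace`
#'   (accepted values), `accuracy`, `complexity`, `predicted`, `mse`,
#'   `iterations`, `converged`.
#' @export
invert_model <- function(y, forward, priors, settings = invert_settings()) {
  y <- as.numeric(y)
  theta <- priors$mean
  free <- priors$var > 0
  p <- sum(free)
  fnames <- names(priors$mean)[free]

  eval_state <- function(theta) {
    f0 <- tryCatch(as.numeric(forward(theta)), error = function(e) NULL)
    if (is.null(f0) || length(f0) != length(y) || !all(is.finite(f0))) return(NULL)
    r <- y - f0
    J <- matrix(0, length(y), p)
    for (j in seq_len(p)) {
      th <- theta
      th[fnames[j]] <- th[fnames[j]] + settings$fd_step
      fj <- tryCatch(as.numeric(forward(th)), error = function(e) NULL)
      if (is.null(fj) || !all(is.finite(fj))) return(NULL)
      J[, j] <- (fj - f0) / settings$fd_step
    }
    ob <- vl_objective(r, J, priors, free)
    if (is.null(ob)) return(NULL)
    kl_t <- if (p) {
      d <- theta[fnames] - priors$mean[free]
      0.5 * (sum(diag(ob$P0 %*% ob$Sigma)) + sum(d * (ob$P0 %*% d)) - p +
               logdet(ob$S0) - logdet(ob$Sigma))
    } else 0
    kl_l <- 0.5 * (ob$lambda_var / priors$lambda_var +
                     (ob$lambda - priors$lambda_mean)^2 / priors$lambda_var -
                     1 + log(priors$lambda_var / ob$lambda_var))
    complexity <- kl_t + kl_l
    list(theta = theta, f0 = f0, r = r, J = J, lambda = ob$lambda,
         lambda_var = ob$lambda_var, Sigma = ob$Sigma, P0 = ob$P0,
         accuracy = ob$accuracy, complexity = complexity,
         F = ob$accuracy - complexity)
  }

  cur <- eval_state(theta)
  if (is.null(cur)) stop("forward simulation failed at the prior mean")
  F_trace <- cur$F
  iterations <- 1L
  converged <- FALSE

  if (p > 0) {
    rho <- settings$lm_init
    small <- 0L
    n_accept <- 0L
    n_finite_prop <- 0L
    for (iter in seq_len(settings$max_iter)) {
      iterations <- iter
      gr <- exp(cur$lambda) * crossprod(cur$J, cur$r) +
        cur$P0 %*% (priors$mean[free] - cur$theta[fnames])
      H <- exp(cur$lambda) * crossprod(cur$J) + cur$P0
      Hd <- H + rho * diag(diag(H), p)
      step <- tryCatch(solve(Hd, gr), error = function(e) NULL)
      if (is.null(step)) { rho <- rho * settings$lm_up; next }
      th_new <- cur$theta
      th_new[fnames] <- th_new[fnames] + as.numeric(step)
      prop <- eval_state(th_new)
      if (is.null(prop)) { rho <- rho * settings$lm_up
        if (rho > 1e12) break
        next }
      n_finite_prop <- n_finite_prop + 1L
      dF <- prop$F - cur$F
      if (dF > 0) {
        cur <- prop
        F_trace <- c(F_trace, cur$F)
        rho <- max(rho / settings$lm_down, 1e-8)
        n_accept <- n_accept + 1L
      } else {
        rho <- rho * settings$lm_up
      }
      small <- if (abs(dF) < settings$tol) small + 1L else 0L
      if (small >= settings$tol_count) { converged <- TRUE; break }
      if (rho > 1e12) break
    }
    if (n_finite_prop == 0L)
      stop("no finite step could be evaluated; F trace: ",
           paste(signif(F_trace, 6), collapse = ", "))
  } else {
    converged <- TRUE
  }

  cov <- matrix(0, p, p, dimnames = list(fnames, fnames))
  if (p) cov[] <- cur$Sigma
  structure(list(mean = cur$theta, cov = cov, free = fnames,
                 lambda = cur$lambda, lambda_var = cur$lambda_var,
                 F = cur$F, F_trace = F_trace, accuracy = cur$accuracy,
                 complexity = cur$complexity, predicted = cur$f0,
                 mse = mean(cur$r^2), iterations = iterations,
                 converged = converged,
                 priors = priors, settings = settings),
            class = "dcm_fit")
}

#' Decompose a fit's free energy into accuracy and complexity
#'
#' Accuracy is the (Gauss-Newton approximate) expected log likelihood under
#' the posterior; complexity is the KL divergence of the Gaussian posterior
#' (parameters and noise log precision) from the prior. The identity
#' `accuracy - complexity = F` holds exactly, and complexity is 0 when the
#' posterior equals the prior.
#'
#' @param fit A `dcm_fit`.
#' @return Named numeric: `accuracy`, `complexity`.
#' @export
free_energy_decomposition <- function(fit) {
  c(accuracy = fit$accuracy, complexity = fit$complexity)
}

#' Fit a CMC network to an observed ERP
#'
#' Builds the deterministic forward map (network integration, scalp
#' projection, temporal decimation, amplitude scaling) and inverts it with
#' [invert_model()]. The observed ERP is rescaled to unit median absolute
#' amplitude before fitting; the scale is stored and the predicted response
#' is returned on the original scale.
#'
#' @param erp Channels x time matrix of the observed (averaged or single
#'   trial) ERP.
#' @param time Time grid (s) of the columns, uniform step.
#' @param spec A [network_spec()].
#' @param leadfield A [lead_field()].
#' @param priors A [dcm_priors()]; defaults to [cmc_priors()] on the spec.
#' @param stim A [stimulus_spec()].
#' @param settings [invert_settings()]; `window` and `fit_step` control the
#'   fit grid.
#' @return A `dcm_fit` with `predicted` (channels x fit-grid matrix on the
#'   data scale), `fit_time`, `scale`, and `mse` (on the scaled data).
#' @export
invert_erp <- function(erp, time, spec, leadfield, priors = cmc_priors(spec),
                       stim = stimulus_spec(), settings = invert_settings()) {
  erp <- as.matrix(erp)
  stopifnot(ncol(erp) == length(time))
  dts <- diff(time)
  if (max(dts) - min(dts) > 1e-9) stop("time grid must be uniform")
  sel <- which(time >= settings$window[1] - 1e-9 &
                 time <= settings$window[2] + 1e-9)
  by <- max(1L, as.integer(round(settings$fit_step / dts[1])))
  sel <- sel[seq(1, length(sel), by = by)]
  if (length(sel) < 4) stop("fit window contains too few samples")
  tfit <- time[sel]
  dt_fit <- tfit[2] - tfit[1]
  yobs <- erp[, sel, drop = FALSE]
  scale <- stats::median(abs(yobs))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  ys <- yobs / scale

  nch <- nrow(erp)
  forward <- function(theta) {
    sp <- apply_theta(spec, theta)
    tr <- integrate_cmc(sp, stim, t_start = tfit[1], t_end = tfit[length(tfit)],
                        dt = dt_fit)
    project_to_scalp(tr, leadfield) / scale
  }
  fit <- invert_model(as.numeric(ys), forward, priors, settings)
  fit$predicted <- matrix(fit$predicted * scale, nch,
                          dimnames = list(rownames(erp), NULL))
  fit$fit_time <- tfit
  fit$scale <- scale
  fit$spec <- apply_theta(spec, fit$mean)
  fit$leadfield <- leadfield
  fit$stim <- stim
  fit
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("Variational Laplace fit: F =", format(x$F, digits = 6),
      "| mse =", format(x$mse, digits = 4),
      "| iterations =", x$iterations,
      if (x$converged) "(converged)" else "(iteration limit)", "\n")
  invisible(x)
}
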
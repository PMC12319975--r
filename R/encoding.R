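#' Container for per-trial latent trajectories
#'
#' @param trajectories List of `latent_trajectory` objects, one per fitted
#'   trial.
#' @param diagnostics data.frame with one row per trial: `trial`, `F`,
#'   `mse`, `converged`.
#' @param info Optional per-trial metadata (behavior rows).
#' @return An object of class `trial_latents`.
#' @export
trial_latents <- function(trajectories, diagnostics, info = NULL) {
  stopifnot(is.list(trajectories), nrow(diagnostics) == length(trajectories))
  structure(list(trajectories = trajectories, diagnostics = diagnostics,
                 info = info), class = "trial_latents")
}

#' @export
print.trial_latents <- function(x, ...) {
  cat("Trial latents:", length(x$trajectories), "trials,",
      sum(x$diagnostics$converged), "converged\n")
  invisible(x)
}

#' Reported signal of a population
#'
#' The canonical microcircuit reports scaled voltages for the excitatory
#' populations (SS, SP, DP) but scaled *current* for the inhibitory
#' interneurons.
#'
#' @param traj A `latent_trajectory`.
#' @param region Region label.
#' @param population One of "SS", "SP", "II", "DP".
#' @return Numeric vector over the trajectory's time grid.
#' @export
reported_signal <- function(traj, region, population) {
  stopifnot(population %in% CMC_POPULATIONS,
            region %in% dimnames(traj$voltage)[[1]])
  if (population == "II") traj$current[region, "II", ]
  else traj$voltage[region, population, ]
}

#' Fit single-trial DCMs initialized from a winning averaged fit
#'
#' Every trial is inverted independently with priors centred on the winning
#' model's posterior means; the trial prior variances default to a quarter
#' of the averaged-fit prior variances (the initialization is informed).
#' Latent trajectories are integrated at each trial's posterior mean.
#' Trials whose inversion fails are flagged (`converged = FALSE`) and their
#' trajectory left NULL; results do not depend on trial order.
#'
#' @param epochs An [erp_epochs()] covering the trial window.
#' @param winning A `dcm_fit` from [invert_erp()] on the averaged ERP.
#' @param spec The [network_spec()] of the winning model.
#' @param prior_shrink Factor dividing the averaged-fit prior variances
#'   (default 4).
#' @param settings [invert_settings()] for the trial fits; default uses the
#'   full -50..1200 ms window.
#' @return A [trial_latents()] with per-trial fit diagnostics.
#' @export
fit_trial_dcms <- function(epochs, winning, spec, prior_shrink = 4,
                           settings = invert_settings(window = c(-0.05, 1.2))) {
  stopifnot(inherits(epochs, "erp_epochs"), inherits(winning, "dcm_fit"))
  pr0 <- winning$priors
  priors <- dcm_priors(winning$mean[names(pr0$mean)], pr0$var / prior_shrink,
                       lambda_mean = pr0$lambda_mean,
                       lambda_var = pr0$lambda_var)
  n <- dim(epochs$data)[1]
  trajs <- vector("list", n)
  diag_rows <- vector("list", n)
  for (tr in seq_len(n)) {
    y <- epochs$data[tr, , ]
    fit <- tryCatch({
      if (!all(is.finite(y))) stop("non-finite trial data")
      invert_erp(y, epochs$time, spec, winning$leadfield, priors = priors,
                 stim = winning$stim, settings = settings)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      diag_rows[[tr]] <- data.frame(trial = tr, F = NA_real_, mse = NA_real_,
                                    converged = FALSE)
    } else {
      sel_dt <- fit$fit_time[2] - fit$fit_time[1]
      trajs[[tr]] <- integrate_cmc(apply_theta(spec, fit$mean), winning$stim,
                                   t_start = fit$fit_time[1],
                                   t_end = fit$fit_time[length(fit$fit_time)],
                                   dt = sel_dt)
      diag_rows[[tr]] <- data.frame(trial = tr, F = fit$F, mse = fit$mse,
                                    converged = TRUE)
    }
  }
  dg <- do.call(rbind, diag_rows)
  n_failed <- sum(!dg$converged)
  if (n_failed > 0)
    message(n_failed, " of ", n, " trial fits failed and were flagged")
  trial_latents(trajs, dg, info = epochs$trial_info)
}

#' Build a trials x timepoints feature matrix from trial latents
#'
#' Samples each fitted trial's reported population signal (voltage, or
#' current for II) on a uniform grid and z-scores every column across
#' trials. Column means/sds are stored as attributes; zero-variance columns
#' are retained unscaled and flagged.
#'
#' @param latents A [trial_latents()].
#' @param region,population Which latent signal to extract.
#' @param window Analysis window (s), default 0-800 ms.
#' @param step Grid step (s), default 4 ms.
#' @return Matrix trials x timepoints with attributes `time`, `center`,
#'   `scale`, `zero_variance`, `trials` (indices of usable trials).
#' @export
build_feature_matrix <- function(latents, region, population,
                                 window = c(0, 0.8), step = 0.004) {
  stopifnot(inherits(latents, "trial_latents"))
  grid <- seq(window[1], window[2], by = step)
  if (!length(grid)) stop("empty analysis window")
  ok <- which(latents$diagnostics$converged)
  X <- matrix(NA_real_, length(ok), length(grid))
  for (i in seq_along(ok)) {
    tj <- latents$trajectories[[ok[i]]]
    sig <- reported_signal(tj, region, population)
    X[i, ] <- stats::approx(tj$time, sig, xout = grid, rule = 2)$y
  }
  ctr <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- !is.finite(sdv) | sdv < 1e-12
  sc <- ifelse(zero, 1, sdv)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, sc, "/")
  attr(Xs, "time") <- grid
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- sc
  attr(Xs, "zero_variance") <- zero
  attr(Xs, "trials") <- ok
  Xs
}

#' Settings for the encoding analysis
#'
#' @param n_folds Cross-validation folds (default 5).
#' @param n_permutations Permutations per timepoint for the importance
#'   estimate (default 50).
#' @param n_bootstrap Bootstrap resamples of trials (default 500).
#' @param null_quantile Quantile of the within-resample permutation null an
#'   importance must exceed (default 0.95).
#' @param pass_threshold Bootstrap pass-fraction threshold applied before
#'   group inference (default 0.7).
#' @param cost,epsilon SVR regularization and tube width (libsvm defaults
#'   C = 1, epsilon = 0.1).
#' @param gamma Gaussian kernel bandwidth; NULL means `1 / (p * mean
#'   feature variance)`.
#' @return List of settings.
#' @export
encode_settings <- function(n_folds = 5, n_permutations = 50,
                            n_bootstrap = 500, null_quantile = 0.95,
                            pass_threshold = 0.7, cost = 1, epsilon = 0.1,
                            gamma = NULL) {
  list(n_folds = n_folds, n_permutations = n_permutations,
       n_bootstrap = n_bootstrap, null_quantile = null_quantile,
       pass_threshold = pass_threshold, cost = cost, epsilon = epsilon,
       gamma = gamma)
}

# Batched prediction from a fitted e1071 SVR model (the per-timepoint
# permutation loops need thousands of predictions; one BLAS kernel-matrix
# product replaces them).
svr_predict_fast <- function(model, X) {
  SV <- model$SV
  co <- as.numeric(model$coefs)
  if (model$kernel == 0) {             # linear
    w <- crossprod(SV, co)
    as.numeric(X %*% w) - model$rho
  } else {                             # radial
    d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * tcrossprod(X, SV)
    as.numeric(exp(-model$gamma * pmax(d2, 0)) %*% co) - model$rho
  }
}

svr_fit <- function(X, y, kernel, settings) {
  gam <- settings$gamma
  if (is.null(gam))
    gam <- 1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12))
  e1071::svm(x = X, y = y, type = "eps-regression",
             kernel = if (kernel == "linear") "linear" else "radial",
             cost = settings$cost, epsilon = settings$epsilon, gamma = gam,
             scale = FALSE, fitted = FALSE)
}

# R^2 against the mean predictor computed on held-out data.
r2_score <- function(y, pred, baseline) {
  ss0 <- sum((y - baseline)^2)
  if (ss0 <= 0) return(NA_real_)
  1 - sum((y - pred)^2) / ss0
}

#' Nonlinear encoding analysis of latent activity
#'
#' Trains support vector regression (linear or Gaussian kernel) from the
#' trials x timepoints feature matrix to a behavioral target and assesses
#' each timepoint by (i) k-fold cross-validated performance (R-squared
#' against the mean predictor), (ii) permutation importance (mean
#' performance drop over column permutations on held-out folds),
#' (iii) a sensitivity sign (direction of the prediction change under a
#' +0.1 SD perturbation of that column), and (iv) a bootstrap pass
#' fraction: over B resamples of trials, the fraction in which the
#' timepoint's out-of-bag mean performance drop exceeds the 95th percentile
#' of its resample-specific permutation null (the single-permutation drops
#' are centred on zero under irrelevance; the mean drop is compared with the
#' null quantile of its standard error) with a sensitivity sign matching the
#' full-data sign. Resamples whose out-of-bag R-squared is not positive never
#' pass: performance drops of a model with no held-out skill do not measure
#' encoding.
#'
#' @param features Trials x timepoints matrix from [build_feature_matrix()].
#' @param targets Numeric per-trial target (RT in s, or confidence 1-9).
#' @param kernel "linear" or "gaussian".
#' @param settings [encode_settings()].
#' @param seed Integer seed (folds, permutations, resamples).
#' @return An `encoding_report`: `time`, `importance`, `sign`,
#'   `pass_fraction` per timepoint, plus `cv_r2`, `kernel`, `n_trials`,
#'   `settings`.
#' @export
encode <- function(features, targets, kernel = c("gaussian", "linear"),
                   settings = encode_settings(), seed = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(features)
  y <- as.numeric(targets)
  stopifnot(length(y) == nrow(X), all(is.finite(y)))
  n <- nrow(X); p <- ncol(X)
  if (n < 20) stop("need at least 20 trials")
  if (n < settings$n_folds) stop("fewer trials than folds")
  R <- settings$n_permutations
  B <- settings$n_bootstrap

  rng <- local_rng(derive_seed(seed, "encode"))
  on.exit(rng(), add = TRUE)

  ## (i)+(ii) cross-validated performance and permutation importance
  folds <- sample(rep(seq_len(settings$n_folds), length.out = n))
  drops <- matrix(0, settings$n_folds, p)
  press <- 0; sst <- 0
  for (f in seq_len(settings$n_folds)) {
    te <- which(folds == f); trn <- which(folds != f)
    m <- svr_fit(X[trn, , drop = FALSE], y[trn], kernel, settings)
    base_mean <- mean(y[trn])
    pred <- svr_predict_fast(m, X[te, , drop = FALSE])
    press <- press + sum((y[te] - pred)^2)
    sst <- sst + sum((y[te] - base_mean)^2)
    r2_f <- r2_score(y[te], pred, base_mean)
    # stack R permuted copies of the fold per timepoint, predict in one go
    nt <- length(te)
    perm_idx <- replicate(R, sample(nt))
    for (j in seq_len(p)) {
      Xp <- X[rep(te, R), , drop = FALSE]
      col <- X[te, j]
      Xp[, j] <- as.numeric(col[perm_idx])
      pp <- svr_predict_fast(m, Xp)
      r2p <- vapply(seq_len(R), function(r)
        r2_score(y[te], pp[((r - 1) * nt + 1):(r * nt)], base_mean),
        numeric(1))
      drops[f, j] <- mean(r2_f - r2p)
    }
  }
  cv_r2 <- 1 - press / sst
  importance <- colMeans(drops)

  ## (iii) sensitivity sign from a full-data fit
  m_full <- svr_fit(X, y, kernel, settings)
  pred0 <- svr_predict_fast(m_full, X)
  sens <- numeric(p)
  for (j in seq_len(p)) {
    Xp <- X
    Xp[, j] <- Xp[, j] + 0.1
    sens[j] <- mean(svr_predict_fast(m_full, Xp) - pred0)
  }
  sgn <- ifelse(abs(sens) < 1e-12, 0, sign(sens))

  ## (iv) bootstrap pass fraction
  pass <- matrix(FALSE, B, p)
  for (b in seq_len(B)) {
    idx <- sample(n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) < 5) next
    mb <- svr_fit(X[idx, , drop = FALSE], y[idx], kernel, settings)
    base_mean <- mean(y[idx])
    Xo <- X[oob, , drop = FALSE]
    predo <- svr_predict_fast(mb, Xo)
    r2o <- r2_score(y[oob], predo, base_mean)
    # a resample only counts toward passing if the model shows out-of-bag
    # skill: performance drops of a model with no predictive skill do not
    # measure encoding
    if (!is.finite(r2o) || r2o <= 0) next
    no <- length(oob)
    perm_idx <- replicate(R, sample(no))
    dmat <- matrix(0, R, p)
    Xrep <- Xo[rep(seq_len(no), R), , drop = FALSE]
    for (j in seq_len(p)) {
      Xp <- Xrep
      col <- Xo[, j]
      Xp[, j] <- as.numeric(col[perm_idx])
      pp <- svr_predict_fast(mb, Xp)
      dmat[, j] <- vapply(seq_len(R), function(r)
        r2o - r2_score(y[oob], pp[((r - 1) * no + 1):(r * no)], base_mean),
        numeric(1))
    }
    imp_b <- colMeans(dmat)
    # Per-timepoint permutation null for the mean drop: single-permutation
    # drops are centred under irrelevance, up to a resample-wide positive
    # bias (permuting any column an overfit model uses degrades held-out
    # predictions); the median drop across timepoints estimates that bias,
    # and the recentred mean drop is compared with the null quantile of its
    # own standard error.
    bias_b <- stats::median(imp_b)
    se_b <- pmax(apply(dmat, 2, stats::sd), 1e-12) / sqrt(R)
    thr <- bias_b + stats::qnorm(settings$null_quantile) * se_b
    # sensitivity sign within the resample
    predb <- svr_predict_fast(mb, Xo)
    sens_b <- numeric(p)
    Xp <- Xrep[seq_len(no), , drop = FALSE]
    for (j in seq_len(p)) {
      Xj <- Xo
      Xj[, j] <- Xj[, j] + 0.1
      sens_b[j] <- mean(svr_predict_fast(mb, Xj) - predb)
    }
    pass[b, ] <- imp_b > thr & sign(sens_b) == sgn & sgn != 0
  }
  pass_fraction <- colMeans(pass)

  tgrid <- attr(features, "time")
  if (is.null(tgrid)) tgrid <- seq_len(p) - 1

  structure(list(time = tgrid, importance = importance,
                 sign = sgn, pass_fraction = pass_fraction, cv_r2 = cv_r2,
                 kernel = kernel, n_trials = n, settings = settings,
                 seed = seed),
            class = "encoding_report")
}

#' @export
print.encoding_report <- function(x, ...) {
  cat("Encoding report (", x$kernel, " kernel): ", x$n_trials, " trials, ",
      length(x$importance), " timepoints, cv R2 = ",
      round(x$cv_r2, 3), "\n", sep = "")
  invisible(x)
}

#' Across-participant significance of encoding importance
#'
#' At every timepoint, participants whose bootstrap pass fraction exceeds
#' the threshold contribute their signed importance (sensitivity sign times
#' importance); the others contribute 0. A Wilcoxon signed-rank test against
#' 0 across participants yields the group mask at `p < alpha`; the mask
#' carries the majority sensitivity sign.
#'
#' @param reports List of `encoding_report`s (>= 5 participants) on the same
#'   timepoint grid.
#' @param alpha Significance level (default 0.05).
#' @param pass_threshold Per-participant pass-fraction gate (default: taken
#'   from the first report's settings).
#' @return List: `time`, `mask` (logical), `sign` (majority sign), `p`
#'   (per-timepoint p-values).
#' @export
group_significance <- function(reports, alpha = 0.05, pass_threshold = NULL) {
  if (length(reports) < 5)
    stop("need at least 5 participants for the across-participant test")
  if (is.null(pass_threshold))
    pass_threshold <- reports[[1]]$settings$pass_threshold
  p_tp <- length(reports[[1]]$importance)
  for (r in reports) stopifnot(length(r$importance) == p_tp)
  S <- vapply(reports, function(r) {
    s <- r$sign * r$importance
    s[r$pass_fraction <= pass_threshold] <- 0
    s
  }, numeric(p_tp))
  S <- matrix(S, nrow = p_tp)
  pv <- apply(S, 1, function(row) {
    if (all(row == 0)) return(1)
    suppressWarnings(stats::wilcox.test(row, mu = 0)$p.value)
  })
  sgn <- apply(S, 1, function(row) {
    s <- sign(sum(sign(row)))
    if (s == 0 && any(row != 0)) s <- sign(sum(row))
    s
  })
  mask <- !is.na(pv) & pv < alpha
  list(time = reports[[1]]$time, mask = mask, sign = sgn, p = pv)
}

#' Detect sustained significant windows
#'
#' Maximal runs of consecutive TRUE mask samples whose duration (computed as
#' `(run_length - 1) * dt`) strictly exceeds the minimum duration.
#'
#' @param mask Logical vector on a uniform grid.
#' @param dt Grid step (s).
#' @param min_duration Minimum duration (s), strict; default 0.025.
#' @param time Optional time grid (for reported onsets); defaults to
#'   `(0:(n-1)) * dt`.
#' @param sign Optional per-sample sign vector; each window carries its
#'   majority sign.
#' @return data.frame with columns `start`, `end` (s), `n_samples`, `sign`;
#'   zero rows if no window qualifies.
#' @export
detect_sustained_windows <- function(mask, dt, min_duration = 0.025,
                                     time = NULL, sign = NULL) {
  mask <- as.logical(mask)
  mask[is.na(mask)] <- FALSE
  if (is.null(time)) time <- (seq_along(mask) - 1) * dt
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    dur <- (r$lengths[k] - 1) * dt
    if (dur > min_duration) {
      idx <- starts[k]:ends[k]
      s <- if (is.null(sign)) NA_real_ else {
        tt <- sum(base::sign(sign[idx]))
        if (tt == 0) 0 else base::sign(tt)
      }
      out[[length(out) + 1]] <- data.frame(start = time[starts[k]],
                                           end = time[ends[k]],
                                           n_samples = r$lengths[k],
                                           sign = s)
    }
  }
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_samples = integer(0), sign = numeric(0)))
  do.call(rbind, out)
}

#' Linear-kernel screen across conditions
#'
#' Tabulates, per condition, whether any sustained window survives the
#' group-level test with the linear kernel; Gaussian-kernel results are
#' reported as nonlinear only for conditions whose linear screen is
#' negative.
#'
#' @param reports_by_condition Named list; each element is a list of
#'   linear-kernel `encoding_report`s (one per participant).
#' @param alpha Group-test significance level.
#' @param min_duration Sustained-window rule (s).
#' @return data.frame with columns `condition`, `any_window`, `n_windows`.
#' @export
linear_screen <- function(reports_by_condition, alpha = 0.05,
                          min_duration = 0.025) {
  rows <- lapply(names(reports_by_condition), function(cond) {
    reports <- reports_by_condition[[cond]]
    gs <- group_significance(reports, alpha = alpha)
    dt <- diff(gs$time[1:2])
    w <- detect_sustained_windows(gs$mask, dt, min_duration, time = gs$time,
                                  sign = gs$sign)
    data.frame(condition = cond, any_window = nrow(w) > 0,
               n_windows = nrow(w))
  })
  do.call(rbind, rows)
}
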
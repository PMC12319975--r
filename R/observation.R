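#' Lead field mapping regions to scalp channels
#'
#' The latent-to-scalp map is linear: channel `c` at time `t` is
#' `sum_regions L[c, region] * sum_pop J[pop] * v[region, pop, t]`.
#' The default population contribution weights make the superficial pyramidal
#' population dominate (its apical dendrites generate most of the scalp
#' signal), inhibitory interneurons contribute nothing, and spiny stellate and
#' deep pyramidal populations contribute weakly.
#'
#' @param matrix Numeric channels x regions gain matrix (finite, >= 1
#'   channel). Column names, if present, must match the region labels used.
#' @param J Numeric(4) nonnegative population contribution weights in the
#'   order SS, SP, II, DP.
#' @return An object of class `lead_field`.
#' @export
lead_field <- function(matrix, J = c(SS = 0.2, SP = 0.8, II = 0, DP = 0.2)) {
  matrix <- as.matrix(matrix)
  J <- as.numeric(J)
  stopifnot(nrow(matrix) >= 1, all(is.finite(matrix)), length(J) == 4,
            all(is.finite(J)), all(J >= 0))
  names(J) <- CMC_POPULATIONS
  structure(list(matrix = matrix, J = J), class = "lead_field")
}

#' Random unit-norm lead field for synthetic cohorts
#'
#' Columns are drawn from a seeded standard normal generator and normalized
#' to unit Euclidean norm; no head modelling is implied.
#'
#' @param n_channels Number of scalp channels.
#' @param regions Character vector of region labels (one column each).
#' @param seed Integer seed.
#' @inheritParams lead_field
#' @return A [lead_field()].
#' @export
random_lead_field <- function(n_channels, regions, seed = 1,
                              J = c(SS = 0.2, SP = 0.8, II = 0, DP = 0.2)) {
  rng <- local_rng(seed)
  m <- matrix(stats::rnorm(n_channels * length(regions)), n_channels,
              dimnames = list(NULL, regions))
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  rng()
  lead_field(m, J)
}

#' Project a latent trajectory to scalp channels
#'
#' @param traj A `latent_trajectory` from [integrate_cmc()].
#' @param lf A [lead_field()] whose region count matches the trajectory.
#' @return Numeric channels x time matrix; linear in the trajectory.
#' @export
project_to_scalp <- function(traj, lf) {
  R <- dim(traj$voltage)[1]
  if (ncol(lf$matrix) != R)
    stop("lead field has ", ncol(lf$matrix), " regions but trajectory has ", R)
  nt <- dim(traj$voltage)[3]
  # region x time signal: population-weighted voltage sum
  s <- matrix(0, R, nt)
  for (p in 1:4) s <- s + lf$J[p] * traj$voltage[, p, , drop = FALSE][, 1, ]
  if (R == 1) s <- matrix(s, 1, nt)
  lf$matrix %*% s
}

#' ERP epoch container
#'
#' Holds trials x channels x time data (microvolts) on a uniform grid, with
#' the stimulus at time 0, plus a per-trial metadata table linking epochs to
#' behavior rows.
#'
#' @param data Numeric array trials x channels x time. NaN/NA samples are
#'   allowed (unusable trials are flagged by downstream fitting); infinite
#'   values are rejected.
#' @param srate Sampling rate (Hz), > 0. Default 1000.
#' @param window Numeric(2) epoch window (s) with `window[1] < 0 < window[2]`.
#'   Default c(-0.05, 1.2).
#' @param channels Optional channel labels.
#' @param trial_info Optional data.frame of per-trial metadata (one row per
#'   trial).
#' @return An object of class `erp_epochs` with a `time` grid of length
#'   `dim(data)[3]`.
#' @export
erp_epochs <- function(data, srate = 1000, window = c(-0.05, 1.2),
                       channels = NULL, trial_info = NULL) {
  stopifnot(length(dim(data)) == 3, !any(is.infinite(data)), srate > 0,
            window[1] < 0, window[2] > 0)
  nt <- dim(data)[3]
  time <- window[1] + (seq_len(nt) - 1) / srate
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (!is.null(trial_info)) stopifnot(nrow(trial_info) == dim(data)[1])
  structure(list(data = data, srate = srate, window = window, time = time,
                 channels = channels, trial_info = trial_info,
                 baseline_corrected = FALSE),
            class = "erp_epochs")
}

#' Baseline-correct ERP epochs
#'
#' Subtracts, per trial and channel, the mean signal over the 100 ms
#' pre-stimulus interval (or the available shorter pre-stimulus window, with
#' a warning). Idempotent.
#'
#' @param epochs An [erp_epochs()].
#' @return The epochs with corrected data and `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(epochs) {
  pre <- epochs$time >= -0.1 & epochs$time < 0
  if (!any(epochs$time < 0)) stop("no pre-stimulus samples to baseline on")
  if (epochs$time[1] > -0.1 + 1e-9)
    warning("pre-stimulus window shorter than 100 ms; using available samples")
  base <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- sweep(epochs$data, c(1, 2), base, "-")
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Average baseline-corrected epochs over selected trials
#'
#' @param epochs An [erp_epochs()].
#' @param trial_mask Logical or integer selection of trials (>= 1 trial).
#' @return Channels x time matrix: the arithmetic mean over selected trials
#'   after baseline correction.
#' @export
average_erp <- function(epochs, trial_mask = TRUE) {
  idx <- seq_len(dim(epochs$data)[1])[trial_mask]
  if (length(idx) < 1) stop("trial mask selects no trials")
  if (!isTRUE(epochs$baseline_corrected)) epochs <- baseline_correct(epochs)
  m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  rownames(m) <- epochs$channels
  m
}

#' Mean squared error between predicted and observed scalp activity
#'
#' @param predicted,observed Channels x time matrices of equal shape.
#' @return Mean over all channel-time samples of the squared difference.
#' @export
mse_fit <- function(predicted, observed) {
  if (!identical(dim(as.matrix(predicted)), dim(as.matrix(observed))))
    stop("shape mismatch between predicted and observed")
  mean((predicted - observed)^2)
}

#' Export an averaged ERP as a long-format data frame
#'
#' @param erp Channels x time matrix (e.g. from [average_erp()]).
#' @param time Time grid (s) matching the columns.
#' @return data.frame with columns `channel`, `time`, `value`.
#' @export
erp_long <- function(erp, time) {
  erp <- as.matrix(erp)
  stopifnot(ncol(erp) == length(time))
  ch <- rownames(erp)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(erp)))
  data.frame(channel = rep(ch, times = ncol(erp)),
             time = rep(time, each = nrow(erp)),
             value = as.vector(erp))
}
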
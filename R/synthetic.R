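#' Experimental protocol specification for the synthetic cohort
#'
#' Defaults mirror the study protocol being emulated: 24 participants, 2
#' blocks of 160 trials, responses capped at 1.2 s, inter-phase delay
#' uniform on 1.5-4 s, confidence reported on a 1-9 scale, and task
#' difficulty targeting about 75% correct.
#'
#' @param n_participants Number of participants (default 24).
#' @param n_blocks Blocks per participant (default 2).
#' @param trials_per_block Trials per block (default 160).
#' @param rt_cap Response window (s, default 1.2).
#' @param delay_range Delay-period range (s, default c(1.5, 4)).
#' @param conf_scale Maximum confidence rating (default 9).
#' @param target_accuracy Overall proportion correct the difficulty
#'   calibration aims for (default 0.75); must lie in (0.55, 0.95).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_participants = 24, n_blocks = 2,
                          trials_per_block = 160, rt_cap = 1.2,
                          delay_range = c(1.5, 4), conf_scale = 9,
                          target_accuracy = 0.75) {
  stopifnot(n_participants >= 1, n_blocks >= 1, trials_per_block >= 1,
            rt_cap > 0, delay_range[1] < delay_range[2], conf_scale == 9)
  if (target_accuracy <= 0.55 || target_accuracy >= 0.95)
    stop("infeasible accuracy target: must be in (0.55, 0.95)")
  structure(list(n_participants = n_participants, n_blocks = n_blocks,
                 trials_per_block = trials_per_block, rt_cap = rt_cap,
                 delay_range = delay_range, conf_scale = conf_scale,
                 target_accuracy = target_accuracy),
            class = "protocol_spec")
}

# Symmetric collapsing bound (unit diffusion): linear decay from `bound` to
# `floor_frac * bound` over `collapse_time`, constant afterwards.
bound_profile <- function(bound, floor_frac, collapse_time, t) {
  bound * pmax(floor_frac, 1 - (1 - floor_frac) * t / collapse_time)
}

# First passage of pre-computed diffusion paths across the symmetric bound
# profile: returns the crossing step (NA if none) and the sign of the state
# at crossing.
first_passage <- function(paths, b_t) {
  n <- nrow(paths)
  idx <- rep(NA_integer_, n)
  sgn <- rep(NA, n)
  for (i in seq_len(n)) {
    hit <- which(abs(paths[i, ]) >= b_t)
    if (length(hit)) {
      idx[i] <- hit[1]
      sgn[i] <- paths[i, hit[1]] > 0
    }
  }
  list(idx = idx, correct = sgn)
}

# Empirical accuracy calibration of the median drift: a fixed-seed pilot
# cohort (common random numbers, so accuracy is monotone in the drift scale)
# is re-scored inside a root solve. Cached per parameter set.
.cal_cache <- new.env(parent = emptyenv())
calibrate_drift <- function(target, sdlog, ratio, w_hard, bound, floor_frac,
                            collapse_time, t0, rt_cap) {
  key <- paste(target, sdlog, ratio, w_hard, bound, floor_frac,
               collapse_time, t0, rt_cap, sep = "|")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  dt <- 0.002
  n_steps <- max(1, round((rt_cap - t0) / dt))
  n_pilot <- 4000
  rng <- local_rng(20240915L)
  z <- matrix(stats::rnorm(n_pilot * n_steps, sd = sqrt(dt)), n_pilot, n_steps)
  hard <- stats::runif(n_pilot) < w_hard
  vbase <- stats::rlnorm(n_pilot, log(ratio) * !hard, sdlog)
  rng()
  W <- t(apply(z, 1, cumsum))
  tgrid <- (seq_len(n_steps)) * dt
  b_t <- bound_profile(bound, floor_frac, collapse_time, tgrid)
  drift_part <- tcrossprod(vbase, tgrid)
  acc_at <- function(m) {
    fp <- first_passage(W + m * drift_part, b_t)
    mean(fp$correct, na.rm = TRUE)
  }
  m <- stats::uniroot(function(m) acc_at(m) - target, c(0.01, 30),
                      tol = 1e-3, extendInt = "upX")$root
  .cal_cache[[key]] <- m
  m
}

#' Simulate cohort behavior with the study's statistical structure
#'
#' Each trial is a symmetric two-boundary diffusion (Euler-Maruyama, 1 ms
#' steps) with a linearly collapsing bound. The drift magnitude is drawn per
#' trial from a two-level lognormal mixture -- emulating the hard/easy trial
#' mix a coherence-titrated motion task produces -- whose hard-level median
#' is calibrated on a fixed-seed pilot cohort so the cohort accuracy matches
#' the protocol target. Across-trial drift variability plus the collapsing
#' bound make fast trials substantially more accurate than slow ones (strong
#' evidence terminates quickly at a high bound; weak evidence terminates
#' late at a collapsed, less reliable bound). Confidence is a noisy
#' decreasing function of RT
#' discretized to 1-9 (negative Spearman correlation, significant for the
#' large majority of participants at the default noise); the delay period is
#' uniform on its range and independent of confidence. Trials that do not
#' reach a bound before the response cap are recorded as missing.
#'
#' @param protocol A [protocol_spec()].
#' @param seed Integer cohort seed; all randomness derives from it.
#' @param drift_sdlog Within-level lognormal spread of the drift magnitude
#'   (log scale).
#' @param drift_ratio Easy-to-hard median drift ratio of the difficulty
#'   mixture.
#' @param w_hard Proportion of hard trials.
#' @param drift_participant_sd Participant-level jitter of the median drift
#'   (log scale).
#' @param bound Initial decision bound (unit diffusion).
#' @param collapse_floor Fraction of the initial bound the collapse levels
#'   off at.
#' @param collapse_time Time (s of decision time) over which the bound
#'   collapses linearly to its floor.
#' @param t0 Non-decision time (s).
#' @param conf_slope Confidence-on-RT slope (rating units per s, negative
#'   relation; default 7).
#' @param conf_noise_sd Trial-level confidence noise (rating units); 0 makes
#'   the confidence-RT link deterministic.
#' @return data.frame with one row per trial: `participant`, `block`,
#'   `trial`, `rt` (s, NA for misses), `confidence` (1-9, NA for misses),
#'   `correct` (logical, NA for misses), `choice` ("L"/"R"), `delay` (s).
#' @export
simulate_behavior <- function(protocol = protocol_spec(), seed = 1,
                              drift_sdlog = 0.15, drift_ratio = 20,
                              w_hard = 0.85, drift_participant_sd = 0.1,
                              bound = 1.1, collapse_floor = 0.55,
                              collapse_time = 1.0, t0 = 0.15, conf_slope = 7,
                              conf_noise_sd = 1.0) {
  stopifnot(inherits(protocol, "protocol_spec"))
  m_drift <- calibrate_drift(protocol$target_accuracy, drift_sdlog,
                             drift_ratio, w_hard, bound, collapse_floor,
                             collapse_time, t0, protocol$rt_cap)
  dt <- 0.001
  n_steps <- max(1, round((protocol$rt_cap - t0) / dt))
  b_t <- bound_profile(bound, collapse_floor, collapse_time,
                       seq_len(n_steps) * dt)
  n_trials <- protocol$n_blocks * protocol$trials_per_block
  rows <- vector("list", protocol$n_participants)
  for (i in seq_len(protocol$n_participants)) {
    rng <- local_rng(derive_seed(seed, "behavior", i))
    mi <- m_drift * exp(stats::rnorm(1, 0, drift_participant_sd))
    conf_icpt <- 9.5 + stats::rnorm(1, 0, 0.4)
    hard <- stats::runif(n_trials) < w_hard
    v <- stats::rlnorm(n_trials, log(mi) + log(drift_ratio) * !hard,
                       drift_sdlog)
    dirs <- sample(c("L", "R"), n_trials, replace = TRUE)
    incr <- matrix(stats::rnorm(n_trials * n_steps, sd = sqrt(dt)),
                   n_trials, n_steps)
    incr <- incr + v * dt
    path <- t(apply(incr, 1, cumsum))
    fp <- first_passage(path, b_t)
    rt <- t0 + fp$idx * dt
    correct <- fp$correct
    conf_raw <- conf_icpt - conf_slope * rt +
      stats::rnorm(n_trials, 0, conf_noise_sd)
    confidence <- pmin(protocol$conf_scale, pmax(1, round(conf_raw)))
    choice <- ifelse(is.na(correct), NA_character_,
                     ifelse(correct, dirs, ifelse(dirs == "L", "R", "L")))
    rows[[i]] <- data.frame(
      participant = sprintf("P%02d", i),
      block = rep(seq_len(protocol$n_blocks), each = protocol$trials_per_block),
      trial = seq_len(n_trials),
      rt = rt,
      confidence = ifelse(is.na(rt), NA_integer_, confidence),
      correct = correct,
      choice = choice,
      delay = stats::runif(n_trials, protocol$delay_range[1],
                           protocol$delay_range[2]))
    rng()
  }
  do.call(rbind, rows)
}

#' Ground truth for a synthetic ERP cohort
#'
#' Bundles the generating network(s), optional per-trial connectivity
#' modulation, optional planted time-localized encoding effects, the lead
#' field, and the signal-to-noise ratio.
#'
#' @param network A [network_spec()] (the generating model).
#' @param lead_field A [lead_field()] over the network's regions.
#' @param snr Signal-to-noise ratio (signal power over noise power), > 0.
#' @param modulation Optional list of
#'   `list(param, variable, link)` entries: `param` names a fitted parameter
#'   (e.g. `"Af:A->B"`), `variable` a behavior column, and `link` a bounded
#'   function mapping the (z-scored within cohort) variable to an additive
#'   shift of that parameter.
#' @param planted Optional list of
#'   `list(region, population, window, sign, amplitude, variable, link)`
#'   entries describing a time-localized additive modulation of a
#'   population's reported signal (voltage, or current for II), with a raised
#'   cosine profile over `window` (s) and magnitude
#'   `amplitude * link(variable)`.
#' @param stim A [stimulus_spec()].
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(network, lead_field, snr = 10, modulation = list(),
                         planted = list(), stim = stimulus_spec()) {
  stopifnot(inherits(network, "network_spec"), snr > 0)
  structure(list(network = network, lead_field = lead_field, snr = snr,
                 modulation = modulation, planted = planted, stim = stim),
            class = "ground_truth")
}

# z-score a behavioral variable within the cohort (NA-safe).
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x, na.rm = TRUE)) / s
}

#' Simulate scalp epochs (and ground-truth latents) for behavior trials
#'
#' For every behavior row, the generating network's modulated parameters are
#' set from that trial's behavioral variables, the latent trajectories are
#' integrated, planted time-localized effects are added to the reported
#' population signals, the result is projected through the lead field, and
#' iid Gaussian noise is added so that (mean) signal power over noise power
#' equals the requested SNR.
#'
#' @param truth A [ground_truth()].
#' @param behavior Behavior data.frame (rows define the trials; missing-RT
#'   trials are skipped).
#' @param seed Integer seed for the observation noise.
#' @param window Epoch window (s), default c(-0.05, 1.2).
#' @param dt Integration/sampling step (s), default 0.004.
#' @return List: `epochs` (an [erp_epochs()] with `trial_info` = the used
#'   behavior rows), `latents` (a `trial_latents` object of ground-truth
#'   trajectories), `noise_sd`.
#' @export
simulate_cohort_erps <- function(truth, behavior, seed = 1,
                                 window = c(-0.05, 1.2), dt = 0.004) {
  stopifnot(inherits(truth, "ground_truth"))
  used <- behavior[!is.na(behavior$rt), , drop = FALSE]
  n <- nrow(used)
  if (n < 1) stop("no usable trials")
  zvars <- list(rt = zscore(used$rt), confidence = zscore(used$confidence),
                delay = zscore(used$delay))
  trajs <- vector("list", n)
  sigs <- NULL
  for (tr in seq_len(n)) {
    th <- numeric(0)
    for (mo in truth$modulation) {
      x <- zvars[[mo$variable]][tr]
      th <- c(th, stats::setNames(mo$link(x), mo$param))
    }
    sp <- if (length(th)) apply_theta(truth$network, th) else truth$network
    tj <- integrate_cmc(sp, truth$stim, window[1], window[2], dt)
    for (pl in truth$planted) {
      idx <- which(tj$time >= pl$window[1] & tj$time <= pl$window[2])
      if (!length(idx)) next
      prof <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / (length(idx) + 1))
      x <- zvars[[pl$variable]][tr]
      bump <- pl$sign * pl$amplitude * pl$link(x) * prof
      slot <- if (pl$population == "II") "current" else "voltage"
      tj[[slot]][pl$region, pl$population, idx] <-
        tj[[slot]][pl$region, pl$population, idx] + bump
    }
    trajs[[tr]] <- tj
    y <- project_to_scalp(tj, truth$lead_field)
    if (is.null(sigs)) sigs <- array(0, c(n, nrow(y), ncol(y)))
    sigs[tr, , ] <- y
  }
  p_signal <- mean(sigs^2)
  noise_sd <- sqrt(p_signal / truth$snr)
  rng <- local_rng(derive_seed(seed, "erps"))
  noisy <- sigs + array(stats::rnorm(length(sigs), sd = noise_sd), dim(sigs))
  rng()
  srate <- 1 / dt
  epochs <- erp_epochs(noisy, srate = srate, window = window,
                       trial_info = used)
  latents <- trial_latents(trajs,
                           diagnostics = data.frame(trial = seq_len(n),
                                                    F = NA_real_,
                                                    mse = NA_real_,
                                                    converged = TRUE),
                           info = used)
  list(epochs = epochs, latents = latents, noise_sd = noise_sd)
}

#' Condition-specific model spaces used as structural fixtures
#'
#' Returns, per condition, a two-model space over the condition's active
#' regions: for the confidence contrast, three left parietal regions
#' (lPreCUN, lIPL, lSPL) and four frontal regions (l/rMFG, l/rSFG); for the
#' RT contrast, three parietal (rSPL, lPreCUN, rSMG) and two frontal
#' (lPreCG, lMeFG) regions, with only the left precuneus shared between the
#' two. Model 1 routes parietal-to-frontal flow through the lPreCUN hub;
#' model 2 extends model 1 with direct parietal-to-frontal forward edges
#' (lIPL and lSPL to lSFG for confidence; rSPL to lPreCG and lMeFG for RT).
#'
#' @return Named list with elements `confidence` and `rt`, each a list of
#'   two [network_spec()]s.
#' @export
condition_model_spaces <- function() {
  conf_regions <- c("lPreCUN", "lIPL", "lSPL", "lMFG", "rMFG", "lSFG", "rSFG")
  conf_f1 <- rbind(c("lIPL", "lPreCUN"), c("lSPL", "lPreCUN"),
                   c("lPreCUN", "lMFG"), c("lPreCUN", "rMFG"),
                   c("lPreCUN", "lSFG"), c("lPreCUN", "rSFG"))
  conf_b1 <- rbind(c("lPreCUN", "lIPL"), c("lPreCUN", "lSPL"),
                   c("lMFG", "lPreCUN"), c("rMFG", "lPreCUN"),
                   c("lSFG", "lPreCUN"), c("rSFG", "lPreCUN"))
  conf_m1 <- network_spec(conf_regions, conf_f1, conf_b1,
                          input_regions = c("lIPL", "lSPL"))
  conf_m2 <- network_spec(conf_regions,
                          rbind(conf_f1, c("lIPL", "lSFG"), c("lSPL", "lSFG")),
                          conf_b1, input_regions = c("lIPL", "lSPL"))
  rt_regions <- c("rSPL", "lPreCUN", "rSMG", "lPreCG", "lMeFG")
  rt_f1 <- rbind(c("rSPL", "lPreCUN"), c("rSMG", "lPreCUN"),
                 c("lPreCUN", "lPreCG"), c("lPreCUN", "lMeFG"))
  rt_b1 <- rbind(c("lPreCUN", "rSPL"), c("lPreCUN", "rSMG"),
                 c("lPreCG", "lPreCUN"), c("lMeFG", "lPreCUN"))
  rt_m1 <- network_spec(rt_regions, rt_f1, rt_b1,
                        input_regions = c("rSPL", "rSMG"))
  rt_m2 <- network_spec(rt_regions,
                        rbind(rt_f1, c("rSPL", "lPreCG"), c("rSPL", "lMeFG")),
                        rt_b1, input_regions = c("rSPL", "rSMG"))
  list(confidence = list(conf_m1, conf_m2), rt = list(rt_m1, rt_m2))
}
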
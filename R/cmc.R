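#' @useDynLib confdcm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Population order used throughout the package.
CMC_POPULATIONS <- c("SS", "SP", "II", "DP")

# Intrinsic connection labels, in the fixed gain order (sign is fixed by the
# canonical wiring, not by the gain):
CMC_INTRINSIC <- c("ss_ss", "sp_ss", "ii_ss", "ii_ii", "ss_ii",
                   "dp_ii", "sp_sp", "ss_sp", "ii_dp", "dp_dp")
CMC_INTRINSIC_SIGN <- c(-1, -1, -1, -1, +1, +1, -1, +1, -1, -1)

# Canonical base gains that the log-scaling parameters multiply.
CMC_SCALE_FORWARD  <- 800
CMC_SCALE_BACKWARD <- 200
CMC_SCALE_INPUT    <- 256
CMC_SCALE_INTRINSIC <- 200

#' Per-region canonical microcircuit parameters
#'
#' Rate constants, intrinsic gains, and the sigmoid slope of one cortical
#' column. Defaults are the conventional CMC values used for ERP modelling:
#' population rate constants `kappa` in 1/s (SS, SP, II, DP), dimensionless
#' intrinsic gain magnitudes `g` of order 1-8 (multiplied internally by a
#' common canonical scale so that unit-amplitude input yields damped
#' oscillatory millivolt-scale responses), and sigmoid slope `r` in 1/mV.
#'
#' @param kappa Named or unnamed numeric(4), rate constants (1/s), order
#'   SS, SP, II, DP. All must be > 0.
#' @param g Numeric(10), intrinsic gain magnitudes (>= 0) in the order
#'   `ss_ss, sp_ss, ii_ss, ii_ii, ss_ii, dp_ii, sp_sp, ss_sp, ii_dp, dp_dp`.
#'   Signs are fixed by the canonical wiring.
#' @param r Sigmoid slope (1/mV), > 0.
#' @return An object of class `cmc_region_params`.
#' @export
cmc_region_params <- function(kappa = c(SS = 256, SP = 128, II = 16, DP = 32),
                              g = c(ss_ss = 4, sp_ss = 4, ii_ss = 8, ii_ii = 4,
                                    ss_ii = 4, dp_ii = 2, sp_sp = 4, ss_sp = 4,
                                    ii_dp = 2, dp_dp = 1),
                              r = 2 / 3) {
  kappa <- as.numeric(kappa)
  g <- as.numeric(g)
  stopifnot(length(kappa) == 4, length(g) == 10, length(r) == 1)
  if (!all(is.finite(kappa)) || any(kappa <= 0)) stop("all kappa must be finite and > 0")
  if (!all(is.finite(g)) || any(g < 0)) stop("intrinsic gains g must be finite and >= 0")
  if (!is.finite(r) || r <= 0) stop("sigmoid slope r must be > 0")
  names(kappa) <- CMC_POPULATIONS
  names(g) <- CMC_INTRINSIC
  structure(list(kappa = kappa, g = g, r = r), class = "cmc_region_params")
}

#' Cumulative-Gaussian stimulus specification
#'
#' The exogenous drive is `amplitude * pnorm((t - mu)/sigma)` with
#' `mu = onset + 2.326 * sigma`, so the ramp carries about 1% of its final
#' amplitude at the nominal onset time: "onset" means the input begins there,
#' not that it half-peaks there.
#'
#' @param onset Nominal input onset (s), >= 0. Default 0.200 s, accounting for
#'   sensory transduction delay.
#' @param sigma Spread of the cumulative Gaussian (s), > 0.
#' @param amplitude Input amplitude (arbitrary units).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(onset = 0.200, sigma = 0.050, amplitude = 1) {
  stopifnot(is.finite(onset), onset >= 0, is.finite(sigma), sigma > 0,
            is.finite(amplitude))
  structure(list(onset = onset, sigma = sigma, amplitude = amplitude,
                 mu = onset + 2.326 * sigma),
            class = "stimulus_spec")
}

#' Evaluate the stimulus input at given times
#'
#' @param t Numeric vector of times (s); must be finite.
#' @param spec A [stimulus_spec()].
#' @return Input amplitude at each `t`; monotone nondecreasing, tending to
#'   `amplitude` as `t` grows.
#' @export
stimulus_value <- function(t, spec = stimulus_spec()) {
  if (!all(is.finite(t))) stop("non-finite stimulus time")
  spec$amplitude * stats::pnorm((t - spec$mu) / spec$sigma)
}

#' Network specification for a CMC dynamic causal model
#'
#' A directed region graph with laminar-specific extrinsic connections:
#' forward edges project from SP of the source onto SS and DP of the target,
#' backward edges from DP of the source onto SP and II of the target, and the
#' exogenous input drives SS of the input regions. Extrinsic and input gains
#' are parameterized on the log scale, multiplying canonical unit values, so
#' gains stay positive and `logA = 0` is the canonical strength.
#'
#' @param regions Character vector of region labels (unique, non-empty).
#' @param forward_edges,backward_edges Two-column matrices or data frames
#'   (source, target) of region labels; self-edges are rejected.
#' @param input_regions Character vector, subset of `regions`; must be
#'   non-empty for any driven simulation.
#' @param logA_f,logA_b Per-edge log scaling parameters (default 0).
#' @param logC Per-input-region log input gains (default 0).
#' @param region_params A single [cmc_region_params()] shared by all regions,
#'   or a named list with one entry per region.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(regions, forward_edges = NULL, backward_edges = NULL,
                         input_regions = character(),
                         logA_f = NULL, logA_b = NULL, logC = NULL,
                         region_params = cmc_region_params()) {
  regions <- as.character(regions)
  stopifnot(length(regions) >= 1, !anyDuplicated(regions))
  as_edges <- function(e) {
    if (is.null(e) || (is.matrix(e) && nrow(e) == 0) || length(e) == 0)
      return(matrix(character(), 0, 2, dimnames = list(NULL, c("from", "to"))))
    e <- as.matrix(e)
    stopifnot(ncol(e) == 2)
    e <- matrix(as.character(e), ncol = 2, dimnames = list(NULL, c("from", "to")))
    if (!all(e %in% regions)) stop("edge endpoint not a listed region")
    if (any(e[, 1] == e[, 2])) stop("self-edges are not allowed")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) stop("duplicate edge")
    e
  }
  fe <- as_edges(forward_edges)
  be <- as_edges(backward_edges)
  input_regions <- as.character(input_regions)
  if (!all(input_regions %in% regions)) stop("input region not a listed region")
  fill <- function(x, n, what) {
    if (is.null(x)) return(rep(0, n))
    if (length(x) != n) stop("wrong length for ", what)
    stopifnot(all(is.finite(x)))
    as.numeric(x)
  }
  logA_f <- fill(logA_f, nrow(fe), "logA_f")
  logA_b <- fill(logA_b, nrow(be), "logA_b")
  logC <- fill(logC, length(input_regions), "logC")
  if (nrow(fe)) names(logA_f) <- paste0(fe[, 1], "->", fe[, 2])
  if (nrow(be)) names(logA_b) <- paste0(be[, 1], "->", be[, 2])
  names(logC) <- input_regions
  if (inherits(region_params, "cmc_region_params")) {
    region_params <- stats::setNames(rep(list(region_params), length(regions)), regions)
  } else {
    stopifnot(is.list(region_params), setequal(names(region_params), regions))
    region_params <- region_params[regions]
  }
  structure(list(regions = regions, forward_edges = fe, backward_edges = be,
                 input_regions = input_regions, logA_f = logA_f,
                 logA_b = logA_b, logC = logC, region_params = region_params),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("CMC network:", length(x$regions), "regions,",
      nrow(x$forward_edges), "forward /", nrow(x$backward_edges),
      "backward edges, input ->", paste(x$input_regions, collapse = ", "), "\n")
  invisible(x)
}

# Pack a network_spec into the flat numeric blocks the C++ core expects.
spec_to_blocks <- function(spec) {
  R <- length(spec$regions)
  kappa <- vapply(spec$region_params, function(p) p$kappa, numeric(4))
  g <- vapply(spec$region_params, function(p) p$g, numeric(10)) * CMC_SCALE_INTRINSIC
  r <- vapply(spec$region_params, function(p) p$r, numeric(1))
  idx <- function(lab) match(lab, spec$regions) - 1L
  list(kappa = matrix(kappa, 4, R), g = matrix(g, 10, R), r = as.numeric(r),
       ef_src = as.integer(idx(spec$forward_edges[, 1])),
       ef_tgt = as.integer(idx(spec$forward_edges[, 2])),
       af = exp(spec$logA_f) * CMC_SCALE_FORWARD,
       eb_src = as.integer(idx(spec$backward_edges[, 1])),
       eb_tgt = as.integer(idx(spec$backward_edges[, 2])),
       ab = exp(spec$logA_b) * CMC_SCALE_BACKWARD,
       inp = as.integer(idx(spec$input_regions)),
       cin = exp(spec$logC) * CMC_SCALE_INPUT)
}

#' Time derivative of the CMC network state
#'
#' Evaluates the right-hand side of the second-order neural mass equations:
#' for every population `dv/dt = i` and
#' `di/dt = kappa*u - 2*kappa*i - kappa^2*v`, where `u` is the signed,
#' gain-weighted sum of presynaptic firing `S(v) = 1/(1+exp(-r*v)) - 1/2`
#' over the canonical intrinsic wiring, the laminar extrinsic connections,
#' and the exogenous input onto SS of input regions.
#'
#' @param v,i Numeric 4 x R matrices (populations x regions) of voltages (mV)
#'   and currents (mV/s).
#' @param spec A [network_spec()].
#' @param u Scalar exogenous input amplitude.
#' @return List with matrices `dv` and `di` (4 x R).
#' @export
cmc_derivatives <- function(v, i, spec, u = 0) {
  R <- length(spec$regions)
  v <- as.matrix(v); i <- as.matrix(i)
  if (!identical(dim(v), c(4L, R)) || !identical(dim(i), c(4L, R)))
    stop("state dimensions must be 4 populations x ", R, " regions")
  if (!all(is.finite(v)) || !all(is.finite(i)) || !is.finite(u))
    stop("non-finite state or input")
  b <- spec_to_blocks(spec)
  cmc_deriv_cpp(v, i, b$kappa, b$g, b$r, b$ef_src, b$ef_tgt, b$af,
                b$eb_src, b$eb_tgt, b$ab, b$inp, b$cin, u)
}

#' Integrate a CMC network to a latent trajectory
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration from the zero
#' initial state on a uniform grid; the default grid matches the 1000 Hz data
#' grid from -50 ms.
#'
#' @param spec A [network_spec()].
#' @param stim A [stimulus_spec()].
#' @param t_start,t_end Window (s), `t_start < t_end`.
#' @param dt Step (s), > 0.
#' @return A `latent_trajectory`: list with `time` (s), `voltage` and
#'   `current` arrays of dimension regions x populations x time (mV, mV/s),
#'   and the step `dt`.
#' @export
integrate_cmc <- function(spec, stim = stimulus_spec(), t_start = -0.05,
                          t_end = 1.2, dt = 0.001) {
  stopifnot(t_start < t_end, dt > 0)
  b <- spec_to_blocks(spec)
  out <- cmc_integrate_cpp(b$kappa, b$g, b$r, b$ef_src, b$ef_tgt, b$af,
                           b$eb_src, b$eb_tgt, b$ab, b$inp, b$cin,
                           stim$amplitude, stim$mu, stim$sigma,
                           t_start, t_end, dt)
  if (!isTRUE(out$ok))
    stop(sprintf("non-finite trajectory at t = %.4f s (parameter blow-up)",
                 out$bad_time))
  R <- length(spec$regions)
  n <- length(out$time)
  shape <- function(m) {
    a <- aperm(array(m, dim = c(4, R, n)), c(2, 1, 3))
    dimnames(a) <- list(spec$regions, CMC_POPULATIONS, NULL)
    a
  }
  structure(list(time = as.numeric(out$time), voltage = shape(out$v),
                 current = shape(out$i), dt = dt),
            class = "latent_trajectory")
}
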
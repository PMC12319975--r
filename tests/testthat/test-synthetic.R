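test_that("simulated behavior matches the protocol's calibration targets", {
  b <- simulate_behavior(protocol_spec(), seed = 1)
  expect_equal(nrow(b), 24 * 2 * 160)
  expect_equal(max(b$block), 2)
  expect_equal(sum(b$block == 1 & b$participant == "P01"), 160)
  resp <- b[!is.na(b$rt), ]
  expect_true(all(resp$rt > 0 & resp$rt <= 1.2))
  expect_true(all(resp$confidence %in% 1:9))
  expect_true(all(b$delay >= 1.5 & b$delay <= 4))
  expect_lt(abs(mean(resp$correct) - 0.75), 0.03)
  expect_true(all(is.na(b$correct[is.na(b$rt)])))
})

test_that("fast trials are substantially more accurate than slow trials", {
  b <- simulate_behavior(protocol_spec(), seed = 2)
  resp <- b[!is.na(b$rt), ]
  fast <- slow <- c()
  for (p in unique(resp$participant)) {
    d <- resp[resp$participant == p, ]
    cl <- cluster_rts(d$rt)
    fast <- c(fast, mean(d$correct[cl$labels == "fast"]))
    slow <- c(slow, mean(d$correct[cl$labels == "slow"]))
  }
  expect_gt(mean(fast) - mean(slow), 0.1)
  ac <- accuracy_contrast(resp)
  expect_lt(ac$p_one_sided, 0.01)
})

test_that("confidence is anticorrelated with RT for (nearly) all participants", {
  b <- simulate_behavior(protocol_spec(n_participants = 12), seed = 3)
  scr <- screen_participants(b)
  expect_gte(mean(scr$included), 0.9)
  expect_true(all(scr$rho[scr$included] < 0))
  # with zero confidence noise the rank relation is deterministic
  b0 <- simulate_behavior(protocol_spec(n_participants = 3), seed = 4,
                          conf_noise_sd = 0)
  scr0 <- screen_participants(b0)
  expect_true(all(scr0$included))
  expect_true(all(scr0$rho < -0.9))
})

test_that("the delay period is independent of confidence", {
  rhos <- vapply(1:5, function(s) {
    b <- simulate_behavior(protocol_spec(), seed = 100 + s)
    delay_confidence_check(b[!is.na(b$rt), ])$rho
  }, numeric(1))
  expect_true(mean(abs(rhos) < 0.05) >= 0.8)
})

test_that("behavior generation is reproducible and seed-sensitive", {
  p <- protocol_spec(n_participants = 2)
  expect_identical(simulate_behavior(p, seed = 7), simulate_behavior(p, seed = 7))
  expect_false(identical(simulate_behavior(p, seed = 7),
                         simulate_behavior(p, seed = 8)))
  expect_error(protocol_spec(target_accuracy = 0.99), "infeasible")
})

test_that("the condition model spaces have the study's structure", {
  fx <- condition_model_spaces()
  expect_named(fx, c("confidence", "rt"))
  conf <- fx$confidence; rt <- fx$rt
  expect_length(conf, 2); expect_length(rt, 2)
  expect_length(conf[[1]]$regions, 7)
  expect_length(rt[[1]]$regions, 5)
  # model 2 strictly extends model 1 in both spaces
  e <- function(m) paste(m$forward_edges[, 1], m$forward_edges[, 2])
  expect_true(all(e(conf[[1]]) %in% e(conf[[2]])))
  expect_gt(nrow(conf[[2]]$forward_edges), nrow(conf[[1]]$forward_edges))
  expect_true(all(e(rt[[1]]) %in% e(rt[[2]])))
  expect_gt(nrow(rt[[2]]$forward_edges), nrow(rt[[1]]$forward_edges))
  # the added edges are the direct parietal-to-frontal routes
  expect_true(all(c("lIPL lSFG", "lSPL lSFG") %in% setdiff(e(conf[[2]]), e(conf[[1]]))))
  expect_true(all(c("rSPL lPreCG", "rSPL lMeFG") %in% setdiff(e(rt[[2]]), e(rt[[1]]))))
  # only the left precuneus is shared between the two spaces
  expect_equal(intersect(conf[[1]]$regions, rt[[1]]$regions), "lPreCUN")
})

test_that("generated epochs carry the requested signal-to-noise ratio", {
  spec <- two_region_spec()
  lf <- random_lead_field(6, c("A", "B"), seed = 11)
  b <- simulate_behavior(protocol_spec(n_participants = 1), seed = 5)
  b <- b[!is.na(b$rt), ][1:40, ]
  gt <- ground_truth(spec, lf, snr = 10)
  sim <- simulate_cohort_erps(gt, b, seed = 6)
  expect_equal(dim(sim$epochs$data)[1], 40)
  # empirical SNR within 10% of requested
  sig <- array(0, dim(sim$epochs$data))
  for (i in 1:40) sig[i, , ] <- project_to_scalp(sim$latents$trajectories[[i]], lf)
  p_sig <- mean(sig^2)
  p_noise <- mean((sim$epochs$data - sig)^2)
  expect_lt(abs(p_sig / p_noise - 10) / 10, 0.1)
  # with an empty modulation map all trials share one trajectory
  expect_equal(sim$latents$trajectories[[1]]$voltage,
               sim$latents$trajectories[[40]]$voltage)
  expect_error(ground_truth(spec, lf, snr = -1))
})

test_that("per-trial connectivity modulation moves the latents", {
  spec <- two_region_spec()
  lf <- random_lead_field(6, c("A", "B"), seed = 12)
  b <- simulate_behavior(protocol_spec(n_participants = 1), seed = 8)
  b <- b[!is.na(b$rt), ][1:10, ]
  gt <- ground_truth(spec, lf, snr = 100,
                     modulation = list(list(param = "Af:A->B",
                                            variable = "confidence",
                                            link = function(z) 0.4 * tanh(z))))
  sim <- simulate_cohort_erps(gt, b, seed = 9)
  vB <- vapply(sim$latents$trajectories, function(tj)
    max(abs(tj$voltage["B", "SP", ])), numeric(1))
  # trials with different confidence get different region-B responses
  expect_gt(stats::sd(vB), 0)
})

test_that("full-loop model recovery: RFX BMS selects the generating model", {
  fx <- list(gen = two_region_spec(),
             alt = network_spec(c("A", "B"),
                                forward_edges = rbind(c("A", "B"), c("B", "A")),
                                backward_edges = rbind(c("B", "A"), c("A", "B")),
                                input_regions = "A"))
  lf <- random_lead_field(6, c("A", "B"), seed = 21)
  truth <- c("Af:A->B" = 0.35, "Ab:B->A" = -0.25, "C:A" = 0.2)
  Fm <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    set.seed(500 + s)
    jit <- truth + rnorm(3, 0, 0.08)
    sim <- simulate_erp(fx$gen, lf, theta = stats::setNames(jit, names(truth)))
    noisy <- sim$erp + rnorm(length(sim$erp), sd = sqrt(mean(sim$erp^2) / 10))
    f1 <- invert_erp(noisy, sim$time, fx$gen, lf,
                     settings = quick_settings(max_iter = 24))
    f2 <- invert_erp(noisy, sim$time, fx$alt, lf,
                     settings = quick_settings(max_iter = 24))
    Fm[s, ] <- c(f1$F, f2$F)
  }
  r <- rfx_bms(Fm, seed = 3)
  expect_gt(r$exceedance_prob[1], 0.9)
})

test_that("PEB recovers a planted group-level forward-gain effect", {
  spec <- two_region_spec()
  lf <- random_lead_field(6, c("A", "B"), seed = 31)
  hits_effect <- 0; clean_null <- 0
  n_cohort <- 10
  for (cohort in seq_len(n_cohort)) {
    set.seed(600 + cohort)
    posts <- lapply(1:6, function(s) {
      th <- c("Af:A->B" = 0.4 + rnorm(1, 0, 0.1),  # planted +0.4 group effect
              "Ab:B->A" = rnorm(1, 0, 0.1),        # no group effect
              "C:A" = rnorm(1, 0, 0.1))
      sim <- simulate_erp(spec, lf, theta = th)
      noisy <- sim$erp + rnorm(length(sim$erp), sd = sqrt(mean(sim$erp^2) / 10))
      fit <- invert_erp(noisy, sim$time, spec, lf,
                        settings = quick_settings(max_iter = 24))
      list(mean = fit$mean[fit$free], cov = fit$cov)
    })
    pb <- peb(posts)
    keep <- occurrence_filter(pb, 0.75)
    if ("Af:A->B:mean" %in% keep) hits_effect <- hits_effect + 1
    if (!("Ab:B->A:mean" %in% keep)) clean_null <- clean_null + 1
  }
  expect_gte(hits_effect, 8)
  expect_gte(clean_null, 8)
})

test_that("trial-wise fits recover per-trial gain variation", {
  spec <- two_region_spec()
  lf <- random_lead_field(6, c("A", "B"), seed = 41)
  # averaged "winning" fit at the central parameters
  base <- c("Af:A->B" = 0.3, "Ab:B->A" = -0.2, "C:A" = 0.1)
  sim0 <- simulate_erp(spec, lf, theta = base, window = c(-0.048, 0.6))
  win <- invert_erp(sim0$erp, sim0$time, spec, lf,
                    settings = quick_settings(max_iter = 24))
  # 20 trials with a varying forward gain at SNR 10
  set.seed(42)
  n_tr <- 20
  gains <- base["Af:A->B"] + seq(-0.35, 0.35, length.out = n_tr)
  dat <- array(0, c(n_tr, 6, length(sim0$time)))
  for (i in seq_len(n_tr)) {
    th <- base; th["Af:A->B"] <- gains[i]
    s <- simulate_erp(spec, lf, theta = th, window = c(-0.048, 0.6))
    dat[i, , ] <- s$erp + rnorm(length(s$erp), sd = sqrt(mean(s$erp^2) / 10))
  }
  ep <- erp_epochs(dat, srate = 250, window = c(-0.048, 0.6))
  tl <- fit_trial_dcms(ep, win, spec,
                       settings = quick_settings(max_iter = 20))
  expect_true(all(tl$diagnostics$converged))
  fitted_gain <- vapply(seq_len(n_tr), function(i) {
    tj <- tl$trajectories[[i]]
    max(abs(tj$voltage["B", "SP", ]))
  }, numeric(1))
  # recovered region-B drive must track the generating gain
  expect_gt(cor(gains, fitted_gain, method = "spearman"), 0.7)
})

test_that("trial fits flag unusable trials and are self-consistent at SNR infinity", {
  spec <- two_region_spec()
  lf <- random_lead_field(4, c("A", "B"), seed = 51)
  base <- c("Af:A->B" = 0.2, "Ab:B->A" = 0, "C:A" = 0)
  sim0 <- simulate_erp(spec, lf, theta = base, window = c(-0.048, 0.6))
  win <- invert_erp(sim0$erp, sim0$time, spec, lf,
                    settings = quick_settings(max_iter = 24))
  dat <- array(0, c(3, 4, length(sim0$time)))
  pred <- simulate_erp(spec, lf, theta = win$mean, window = c(-0.048, 0.6))$erp
  for (i in 1:3) dat[i, , ] <- pred
  dat[2, , ] <- NaN  # corrupt one trial
  ep <- erp_epochs(dat, srate = 250, window = c(-0.048, 0.6))
  expect_message(tl <- fit_trial_dcms(ep, win, spec,
                                      settings = quick_settings(max_iter = 16)),
                 "1 of 3")
  expect_false(tl$diagnostics$converged[2])
  expect_true(all(tl$diagnostics$converged[c(1, 3)]))
  # data generated at the initialization: posterior stays at the winning mean
  fitq <- invert_erp(pred, sim0$time, spec, lf,
                     priors = dcm_priors(win$mean[names(win$priors$mean)],
                                         win$priors$var / 4),
                     settings = quick_settings(max_iter = 16))
  expect_lt(max(abs(fitq$mean - win$mean[names(fitq$mean)])), 0.05)
})
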
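# Shared fixtures: small networks, fast inversion settings, and a
# generate-on-the-fit-grid helper so that noiseless self-inversion tests have
# exactly realizable data.

two_region_spec <- function(...) {
  network_spec(c("A", "B"),
               forward_edges = rbind(c("A", "B")),
               backward_edges = rbind(c("B", "A")),
               input_regions = "A", ...)
}

one_region_spec <- function() {
  network_spec("A", input_regions = "A")
}

quick_settings <- function(...) {
  invert_settings(window = c(-0.05, 0.6), ...)
}

# Simulate a scalp ERP on the same 4 ms grid the fit uses.
simulate_erp <- function(spec, lf, theta = NULL, window = c(-0.048, 0.6),
                         dt = 0.004, stim = stimulus_spec()) {
  sp <- if (is.null(theta)) spec else confdcm:::apply_theta(spec, theta)
  tr <- integrate_cmc(sp, stim, window[1], window[2], dt)
  list(erp = project_to_scalp(tr, lf), time = tr$time, traj = tr)
}

expect_monotone_F <- function(fit) {
  expect_true(all(diff(fit$F_trace) >= -1e-9))
}
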
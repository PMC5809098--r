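# shared fixtures: small, fast configurations used across test files

# minimal feedback model matching the worked example conditions
theory_params <- function(duration = 2000, dt = 0.01, w = -0.5, sigma = 1) {
  feedback_params(tau = 1.05, w = w, sigma = sigma, dt = dt,
                  duration = duration)
}

# single-cell strongly coupled session: the per-cell loop equals the
# population loop, so the closed-form power-ratio prediction is exact
single_cell_config <- function(...) {
  defaults <- list(n_cells = 1L, fraction_feedback = 1, afferent_net = -1,
                   efferent_net = 0.5, amp_spread = 0, env_drive_sd = 0,
                   env_baseline = 0, gain_levels = c(1, 1))
  do.call(session_config, utils::modifyList(defaults, list(...)))
}

# a small cached network so whisker tests do not rebuild one each block
cached_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(network_params(), seed = 42)
    net
  }
})

# numeric quadrature of the Chernoff integrand for Gaussians (independent
# oracle for the closed-form objective)
chernoff_quad_1d <- function(lambda, m0, s0, m1, s1) {
  f <- function(x) {
    stats::dnorm(x, m1, s1)^lambda * stats::dnorm(x, m0, s0)^(1 - lambda)
  }
  -log(stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
}
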
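# Shared fixtures: small synthetic ensembles built once per test session.

fig2_params <- function() abp_preset("fig2")

# moderate stationary ensemble at the fig2 parameter set
fig2_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(dt = 0.0066, n_steps = 4000, n_runs = 60,
                        seed = 101, init = "stationary",
                        dt_policy = "none")
      cache <<- simulate_ensemble(fig2_params(), cfg)
    }
    cache
  }
})

fig2_curves <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- abp_curves(
        fig2_ensemble(),
        lags_msd = sort(unique(round(exp(seq(0, log(2000),
                                             length.out = 25))))),
        lags_delay = c(0:5 * 2, seq(15, 240, by = 15)))
    }
    cache
  }
})

expect_rel <- function(got, want, tol, label = NULL) {
  expect_lt(abs(got / want - 1), tol, label = label)
}
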
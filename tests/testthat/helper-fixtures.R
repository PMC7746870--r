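# Shared fixtures, built in code.

# Small virtual subject + trials, cached across test files.
fixture_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_virtual_subject(seed = 7)
    cache
  }
})

fixture_trials <- local({
  cache <- list()
  function(key = "noiseless", n_per_speed = 2, noise = list(exc = 0, mom = 0),
           seed = 11) {
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_trials(fixture_subject(), n_per_speed, noise,
                                       seed = seed)
    cache[[key]]
  }
})

# Tiny hand-built single/multi-muscle models for forward-model tests.
toy_geometry <- function(l0 = 0.35, r0 = 0.05, kap = 0, dof = "KneeFE",
                         qlim = c(-1, 1)) {
  qs <- matrix(seq(qlim[1], qlim[2], length.out = 25), ncol = 1,
               dimnames = list(NULL, dof))
  fit_geometry_surrogate(qs, l0 - r0 * qs[, 1] - kap * qs[, 1]^2 / 2,
                         degree = 2)
}

toy_muscle <- function(channel = "ch1", dof = "KneeFE", F_o = 1000,
                       l_oM = 0.1, l0 = 0.35, r0 = 0.05,
                       alpha_o = 0, emg_scale = 1, tau_act = 0.015,
                       c3 = 0, d = 0) {
  geom <- toy_geometry(l0 = l0, r0 = r0, dof = dof)
  list(act = activation_params(tau_act = tau_act, c3 = c3, d = d),
       mt = muscle_params(F_o = F_o, l_oM = l_oM,
                          l_sT = l0 - l_oM * cos(alpha_o),
                          alpha_o = alpha_o, emg_scale = emg_scale,
                          channel = channel),
       geom = geom)
}

toy_model <- function(muscles, dofs = "KneeFE") {
  musculotendon_model(muscles, dofs)
}

# Synthetic raw trial: known envelope modulating nothing (direct envelope
# samples) for the processing chain.
toy_raw_trial <- function(signal_fun, fs = 1000, t_f = 1.0, pre = 0.3,
                          channels = c("ch1", "ch2")) {
  time <- seq(0, pre + t_f + 0.1, by = 1 / fs)
  samples <- sapply(seq_along(channels), function(j) signal_fun(time, j))
  colnames(samples) <- channels
  raw_emg_trial(samples, channels, fs, cycle_events = c(pre, pre + t_f),
                time = time)
}

expect_series_equal <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)), tol)
}
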
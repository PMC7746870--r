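# The core estimator: weight recovery by moment tracking.

test_that("extrapolate_excitation is the documented linear reconstruction", {
  W <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  expect_equal(extrapolate_excitation(W, c(0.2, 0.5), 0.1), c(0.3, 0.6, 0.8))
  expect_equal(extrapolate_excitation(W, c(0, 0), 0.3), rep(0.3, 3))
  expect_equal(extrapolate_excitation(W, c(0, 0)), rep(0, 3))
  expect_error(extrapolate_excitation(W, c(1, 2, 3)), "length")
})

test_that("PCA SynX recovers a held-out excitation exactly on noiseless data", {
  vs <- fixture_subject()
  trials <- fixture_trials("noiseless")
  meas <- setdiff(vs$channels, "iliopsoas")
  for (tr in trials[c(1, 3)]) { # one trial per speed
    syn <- synergy_decompose(tr$envelopes[, meas], 5, "pca")
    fit <- synx(vs$model, tr, syn, "iliopsoas", n_starts = 2, seed = 17)
    truth <- tr$truth$excitations[(tr$n_pad + 1):(tr$n_pad + 101), "iliopsoas"]
    expect_gte(pearson_r(fitted(fit), truth), 0.99)
    expect_lte(rmse(fitted(fit), truth), 0.01)
    # moments tracked essentially perfectly
    expect_lt(fit$J, 1e-4 * sum(tr$M_exp^2))
    expect_true(fit$diagnostics$feasible)
  }
})

test_that("solution invariants hold: J re-evaluation, start ordering, bounds", {
  vs <- fixture_subject()
  tr <- fixture_trials("noiseless")[[1]]
  meas <- setdiff(vs$channels, "adductor_longus")
  syn <- synergy_decompose(tr$envelopes[, meas], 5, "pca")
  fit <- synx(vs$model, tr, syn, "adductor_longus", n_starts = 3, seed = 23)
  # J equals the tracking objective re-evaluated at the solution
  J_re <- sum((fit$M_mod - fit$M_exp)^2)
  expect_equal(fit$J, J_re, tolerance = 1e-8)
  # the kept solution is the best logged start
  expect_equal(fit$J, min(fit$diagnostics$starts$J))
  # reconstruction is within [0,1] and consistent with the raw series
  expect_true(all(fit$e_x >= 0 & fit$e_x <= 1))
  inactive <- fit$e_x_raw > 1e-6 & fit$e_x_raw < 1 - 1e-6
  expect_lt(max(abs(fit$e_x[inactive] - fit$e_x_raw[inactive])), 1e-12)
  # coef/fitted/residuals interfaces
  expect_length(coef(fit), 6) # 5 weights + mu_x
  expect_length(fitted(fit), 101)
  expect_equal(dim(residuals(fit)), c(101, 5))
  expect_equal(predict(fit, type = "moments"), fit$M_mod)
  expect_equal(predict(fit, newW = syn$W), fit$e_x)
})

test_that("NMF SynX keeps weights non-negative and fits the moments", {
  vs <- fixture_subject()
  tr <- fixture_trials("noiseless")[[2]]
  meas <- setdiff(vs$channels, "iliopsoas")
  syn <- synergy_decompose(tr$envelopes[, meas], 5, "nmf", seed = 41)
  fit <- synx(vs$model, tr, syn, "iliopsoas", n_starts = 3, seed = 42)
  expect_true(all(fit$H_x >= -1e-12))
  expect_null(fit$mu_x)
  truth <- tr$truth$excitations[(tr$n_pad + 1):(tr$n_pad + 101), "iliopsoas"]
  expect_gte(pearson_r(fitted(fit), truth), 0.9)
  expect_true(all(fit$e_x >= 0 & fit$e_x <= 1))
})

test_that("two seeds agree on a well-posed noiseless problem", {
  vs <- fixture_subject()
  tr <- fixture_trials("noiseless")[[1]]
  meas <- setdiff(vs$channels, "iliopsoas")
  syn <- synergy_decompose(tr$envelopes[, meas], 5, "pca")
  f1 <- synx(vs$model, tr, syn, "iliopsoas", n_starts = 2, seed = 1)
  f2 <- synx(vs$model, tr, syn, "iliopsoas", n_starts = 2, seed = 999)
  expect_equal(f1$J, f2$J, tolerance = 1e-6)
  expect_gt(stats::cor(fitted(f1), fitted(f2)), 0.999)
})

test_that("a muscle with zero moment arms is flagged non-identifiable", {
  # single unmeasured muscle whose moment arm is identically zero
  muscles <- list(
    meas = toy_muscle("chm", "KneeFE", F_o = 900, r0 = 0.04),
    unm = toy_muscle("chx", "KneeFE", F_o = 900, r0 = 0))
  model <- toy_model(muscles, "KneeFE")
  s <- seq(0, 1, length.out = 101)
  q <- cbind(KneeFE = 0.3 * sin(2 * pi * s))
  qdot <- cbind(KneeFE = 0.3 * 2 * pi * cos(2 * pi * s))
  exc <- matrix(clamp01(0.5 + 0.3 * sin(2 * pi * seq(-0.1, 1, length.out = 111))),
                111, 2, dimnames = list(NULL, c("chm", "chx")))
  exc[, 2] <- 0.4
  trial <- list(envelopes = exc, q = q, qdot = qdot,
                M_exp = net_joint_moments(model, q, qdot, exc, 1.0), t_f = 1.0)
  syn <- synergy_decompose(exc[, "chm", drop = FALSE], 1, "pca")
  fit <- synx(model, trial, syn, "chx", n_starts = 2, seed = 3)
  expect_true(fit$diagnostics$non_identifiable)
  # the well-posed configuration is not flagged
  vs <- fixture_subject()
  tr <- fixture_trials("noiseless")[[1]]
  meas <- setdiff(vs$channels, "iliopsoas")
  syn2 <- synergy_decompose(tr$envelopes[, meas], 5, "pca")
  fit2 <- synx(vs$model, tr, syn2, "iliopsoas", n_starts = 1, seed = 5)
  expect_false(fit2$diagnostics$non_identifiable)
})

test_that("argument validation catches inconsistent problems", {
  vs <- fixture_subject()
  tr <- fixture_trials("noiseless")[[1]]
  syn_all <- synergy_decompose(tr$envelopes, 5, "pca") # includes unmeasured
  expect_error(synx(vs$model, tr, syn_all, "iliopsoas"), "measured")
  meas <- setdiff(vs$channels, "iliopsoas")
  syn <- synergy_decompose(tr$envelopes[, meas], 5, "pca")
  expect_error(synx(vs$model, tr, syn, "nonexistent"), "not present")
})

test_that("the methodological sweep covers the 80-combination grid", {
  vs <- fixture_subject()
  tr <- fixture_trials("noiseless")[1]
  # restrict to a slice to keep this test quick; the grid arithmetic is
  # what matters here (the full grid runs in the acceptance suite)
  res <- run_sweep(vs$model, tr, "iliopsoas", algorithms = "pca",
                   schemes = c("MaxOver", "MagPer"), p_range = c(4, 5),
                   seed = 6, n_starts = 1)
  expect_equal(nrow(res), 4)
  expect_equal(attr(res, "n_combinations"), 4)
  expect_true(all(!res$failed))
  expect_true(all(res$max_violation < 1e-3))
  expect_true(all(is.finite(res$r)))
  full_grid <- expand.grid(algorithm = c("pca", "nmf"),
                           scheme = NORMALIZATION_SCHEMES, p = 3:10)
  expect_equal(nrow(full_grid), 80)
  # a single-combination sweep reproduces a direct solve
  one <- run_sweep(vs$model, tr, "iliopsoas", algorithms = "pca",
                   schemes = "MaxOver", p_range = 5, seed = 6, n_starts = 1)
  meas <- setdiff(vs$channels, "iliopsoas")
  nrm <- normalize_emg(list(tr[[1]]$envelopes[, meas]), "MaxOver")$trials[[1]]
  syn <- synergy_decompose(nrm, 5, "pca",
                           seed = synx:::derive_seed(6, 1 * 1000 + 1))
  fit <- synx(vs$model, tr[[1]], syn, "iliopsoas", n_starts = 1,
              seed = synx:::derive_seed(6, 1 * 1000 + 500 + 1))
  expect_equal(one$J[1], fit$J, tolerance = 1e-12)
})
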
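# Activation dynamics, Hill curves, fiber kinematics, geometry surrogate,
# forward moments.

test_that("activation dynamics match the closed-form exponential solution", {
  # for constant excitation e the ODE has the analytic solution
  # u(t) = e + (u0 - e) exp(-(c1 e + c2) t)
  par <- activation_params(tau_act = 0.015, c3 = 0, d = 0)
  dt <- 0.001
  n <- 600
  for (e_const in c(0.25, 0.5, 1)) {
    e <- rep(e_const, n)
    a <- activation_from_excitation(e, par, dt, keep = "all")
    tg <- (seq_len(n) - 1) * dt
    u_exact <- e_const + (e[1] - e_const) * exp(-(par$c1 * e_const + par$c2) * tg)
    expect_lt(max(abs(a - u_exact)), 1e-4)
    # steady state u = e
    expect_equal(a[n], e_const, tolerance = 1e-6)
  }
  # step input: closed form from the first constant-input frame onward
  # (between frames the integrator sees a linear ramp, so the comparison
  # starts once the input is constant at 0.8)
  e <- c(rep(0, 200), rep(0.8, 400))
  a <- activation_from_excitation(e, par, dt, keep = "all")
  tg <- (0:399) * dt
  u_exact <- 0.8 + (a[201] - 0.8) * exp(-(par$c1 * 0.8 + par$c2) * tg)
  expect_lt(max(abs(a[201:600] - u_exact)), 1e-4)
  # zero excitation stays identically zero through the nonlinearity
  par_nl <- activation_params(tau_act = 0.02, c3 = 0.4)
  expect_true(all(activation_from_excitation(rep(0, 200), par_nl, dt,
                                             keep = "all") == 0))
})

test_that("the activation nonlinearity is a monotone [0,1] -> [0,1] map", {
  par <- activation_params(tau_act = 0.02, c3 = 1)
  u <- seq(0, 1, length.out = 101)
  a <- activation_nonlinearity(u, par)
  expect_equal(a[1], 0, tolerance = 1e-10)
  expect_equal(a[101], 1, tolerance = 1e-10)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= u - 1e-10)) # concave A-shape sits above identity
  # deactivation constant is four times the activation constant
  expect_equal(par$tau_dact, 4 * par$tau_act)
  expect_equal(par$c1, 1 / par$tau_act - 1 / par$tau_dact)
  # invalid shapes are rejected at construction
  expect_error(activation_params(g = c(-1, 1, 0.1, 0.5, 0)), "endpoint")
  expect_error(activation_params(d = 0.2), "0.1")
})

test_that("the electromechanical delay shifts excitation by d", {
  dt <- 0.0125 # 1% of a 1.25 s cycle
  n <- 160
  tg <- (seq_len(n) - 1) * dt
  e <- clamp01(0.5 + 0.4 * sin(2 * pi * tg))
  par_fast <- activation_params(tau_act = 0.011, d = 0.05)
  par_0 <- activation_params(tau_act = 0.011, d = 0)
  a_d <- activation_from_excitation(e, par_fast, dt, keep = "all")
  a_0 <- activation_from_excitation(e, par_0, dt, keep = "all")
  # with fast dynamics a tracks e; the delayed trace lags by ~4 frames
  lag <- which.max(sapply(0:8, function(k)
    stats::cor(a_d[(1 + k):n], a_0[1:(n - k)]))) - 1
  expect_equal(lag, 4)
  # delay larger than the padding is rejected on the cycle grid
  par_big <- activation_params(d = 0.1)
  expect_error(activation_from_excitation(e[1:104], par_big, dt), "exceeds")
})

test_that("Hill curves satisfy their shape constraints", {
  cv <- muscle_curves()
  expect_equal(fl_curve(1, cv), 1)
  lgrid <- seq(0.5, 1.6, by = 0.01)
  expect_equal(lgrid[which.max(fl_curve(lgrid, cv))], 1) # unimodal peak at 1
  expect_equal(fv_curve(0, cv), 1)
  expect_equal(fv_curve(-1, cv), 0)
  vgrid <- seq(-1.2, 1.5, by = 0.01)
  expect_true(all(diff(fv_curve(vgrid, cv)) >= 0)) # monotone non-decreasing
  expect_lt(max(fv_curve(vgrid, cv)), cv$plateau)
  expect_true(all(fp_curve(seq(0.5, 1, by = 0.01), cv) == 0))
  fpg <- fp_curve(seq(1, 1.6, by = 0.01), cv)
  expect_true(all(diff(fpg) >= 0) && all(diff(diff(fpg)) > -1e-12)) # convex
  expect_equal(fp_curve(1 + cv$e0, cv), 1)
})

test_that("fiber kinematics follow the rigid-tendon identities", {
  cv <- muscle_curves()
  mp <- muscle_params(1000, 0.1, 0.25, alpha_o = 0, channel = "c")
  fk <- fiber_kinematics(0.25 + 0.1, 0, mp, cv)
  expect_equal(fk$ltilde, 1)
  expect_equal(fk$vtilde, 0)
  expect_equal(fk$cos_alpha, 1)
  expect_equal(fiber_kinematics(0.25 + 0.12, 0, mp, cv)$ltilde, 1.2)
  # pennated: l_MT - l_sT = l_oM cos(alpha_o) gives ltilde = 1 exactly
  mp2 <- muscle_params(1000, 0.1, 0.25, alpha_o = 0.2, channel = "c")
  fk2 <- fiber_kinematics(0.25 + 0.1 * cos(0.2), 0, mp2, cv)
  expect_equal(fk2$ltilde, 1, tolerance = 1e-12)
  expect_equal(fk2$cos_alpha, cos(0.2), tolerance = 1e-12)
  # velocity normalization: v_mt = vmax * l_oM maps to vtilde = cos(alpha)
  fk3 <- fiber_kinematics(0.25 + 0.1, cv$vmax * 0.1, mp, cv)
  expect_equal(fk3$vtilde, 1)
  expect_error(fiber_kinematics(0.2, 0, mp, cv, muscle = "vasmed"), "vasmed")
})

test_that("muscle_moment reproduces hand-evaluated Hill forces", {
  cv <- muscle_curves()
  mp <- muscle_params(1000, 0.1, 0.25, alpha_o = 0, channel = "c")
  # all curve factors 1, passive 0: M = r F a
  expect_equal(muscle_moment(1, 1, 0, 0.05, mp, cv), 50)
  expect_equal(muscle_moment(0, 1, 0, 0.05, mp, cv), 0)
  # beyond optimal length the passive term engages; hand formula oracle
  a <- 0.5; lt <- 1.3
  hand <- 0.05 * 1000 * (a * exp(-(lt - 1)^2 / cv$gamma) * 1 +
                           expm1(cv$kp * (lt - 1) / cv$e0) / expm1(cv$kp))
  expect_equal(muscle_moment(a, lt, 0, 0.05, mp, cv), hand, tolerance = 1e-12)
  expect_gt(muscle_moment(0.5, 1.3, 0, 0.05, mp, cv),
            muscle_moment(0.5, 1.3, 0, 0.05, mp, cv) -
              muscle_moment(0, 1.3, 0, 0.05, mp, cv)) # passive > 0
})

test_that("geometry surrogate recovers polynomials and their moment arms", {
  q <- matrix(seq(-0.8, 0.8, length.out = 30), ncol = 1,
              dimnames = list(NULL, "HipFE"))
  # linear: r = -slope everywhere
  lin <- fit_geometry_surrogate(q, 0.3 - 0.04 * q[, 1], degree = 1)
  expect_lt(max(abs(lin$residuals)), 1e-12)
  expect_series_equal(moment_arms(lin, q)[, 1], rep(0.04, 30), tol = 1e-10)
  # quadratic: l = 0.3 - 0.04 q + 0.01 q^2 -> r(q) = 0.04 - 0.02 q
  quad <- fit_geometry_surrogate(q, 0.3 - 0.04 * q[, 1] + 0.01 * q[, 1]^2,
                                 degree = 2)
  expect_series_equal(moment_arms(quad, q)[, 1], 0.04 - 0.02 * q[, 1],
                      tol = 1e-10)
  expect_lt(quad$rmse, 1e-12)
  # degree-0 fit to varying data reports its residual, no silent success
  d0 <- fit_geometry_surrogate(q, 0.3 - 0.04 * q[, 1], degree = 0)
  expect_gt(d0$rmse, 1e-3)
  # rank deficiency: all samples at one point
  q_bad <- matrix(rep(0.1, 10), ncol = 1, dimnames = list(NULL, "HipFE"))
  expect_error(fit_geometry_surrogate(q_bad, rep(0.3, 10), degree = 2),
               "rank-deficient")
})

test_that("tendon-excursion consistency r = -dl/dq holds by finite differences", {
  set.seed(44)
  q <- cbind(HipFE = stats::runif(40, -0.6, 0.6),
             KneeFE = stats::runif(40, -0.9, 0.3))
  lmt <- 0.35 - 0.05 * q[, 1] - 0.03 * q[, 2] + 0.008 * q[, 1] * q[, 2] +
    0.004 * q[, 1]^2
  surr <- fit_geometry_surrogate(q, lmt, degree = 2)
  qs <- cbind(HipFE = stats::runif(100, -0.5, 0.5),
              KneeFE = stats::runif(100, -0.8, 0.2))
  R <- moment_arms(surr, qs)
  h <- 1e-6
  for (j in 1:2) {
    qp <- qs; qp[, j] <- qp[, j] + h
    qm <- qs; qm[, j] <- qm[, j] - h
    fd <- -(eval_lmt(surr, qp) - eval_lmt(surr, qm)) / (2 * h)
    expect_lt(max(abs(fd - R[, j])) / max(abs(R[, j])), 1e-6)
  }
})

test_that("net joint moments equal a brute-force per-muscle summation", {
  set.seed(45)
  dofs <- c("HipFE", "KneeFE")
  muscles <- list(
    m1 = toy_muscle("ch1", "HipFE", F_o = 800, r0 = 0.04),
    m2 = toy_muscle("ch1", "KneeFE", F_o = 1200, r0 = -0.03),
    m3 = toy_muscle("ch2", "KneeFE", F_o = 600, r0 = 0.05, alpha_o = 0.15),
    m4 = toy_muscle("ch2", "HipFE", F_o = 900, r0 = 0.02, c3 = 0.3, d = 0.02))
  model <- toy_model(muscles, dofs)
  t_f <- 1.0; n_pad <- 10
  s <- seq(0, 1, length.out = 101)
  q <- cbind(HipFE = 0.3 * sin(2 * pi * s), KneeFE = 0.4 * cos(2 * pi * s))
  qdot <- cbind(HipFE = 0.3 * 2 * pi / t_f * cos(2 * pi * s),
                KneeFE = -0.4 * 2 * pi / t_f * sin(2 * pi * s))
  exc <- matrix(stats::runif(2 * (101 + n_pad), 0, 0.9), 101 + n_pad, 2,
                dimnames = list(NULL, c("ch1", "ch2")))
  M <- net_joint_moments(model, q, qdot, exc, t_f)
  # independent brute-force loop over muscles, frames and DOFs
  M_oracle <- matrix(0, 101, 2, dimnames = list(NULL, dofs))
  for (nm in names(muscles)) {
    m <- muscles[[nm]]
    e <- pmin(pmax(m$mt$emg_scale * exc[, m$mt$channel], 0), 1)
    a <- activation_from_excitation(e, m$act, t_f / 100)
    dof <- m$geom$dof_names
    lmt <- eval_lmt(m$geom, q[, dof, drop = FALSE])
    r <- moment_arms(m$geom, q[, dof, drop = FALSE])[, 1]
    vmt <- -r * qdot[, dof]
    fk <- fiber_kinematics(lmt, vmt, m$mt, model$curves)
    for (i in 1:101)
      M_oracle[i, dof] <- M_oracle[i, dof] +
        muscle_moment(a[i], fk$ltilde[i], fk$vtilde[i], r[i], m$mt,
                      model$curves)[1]
  }
  expect_lt(max(abs(M - M_oracle)), 1e-10)
  # single-muscle model: net moment equals the single contribution
  one <- toy_model(muscles["m1"], "HipFE")
  M1 <- net_joint_moments(one, q[, "HipFE", drop = FALSE],
                          qdot[, "HipFE", drop = FALSE], exc, t_f)
  expect_equal(ncol(M1), 1)
  # zero excitation at passive-free lengths: zero moments
  M0 <- net_joint_moments(model, q, qdot, 0 * exc, t_f)
  passive_only <- max(abs(M0))
  expect_lt(passive_only, max(abs(M)) * 0.5) # passive share is minor here
  # missing channel errors
  exc_bad <- exc[, "ch1", drop = FALSE]
  expect_error(net_joint_moments(model, q, qdot, exc_bad, t_f), "ch2")
})

test_that("active moments superpose linearly in F_o when passive force is zero", {
  # keep fibers at/below optimal length so fp = 0
  mus <- list(m1 = toy_muscle("ch1", "KneeFE", F_o = 500, l0 = 0.35, r0 = 0.03))
  mus$m1$mt$l_sT <- 0.35 - 0.1 # ltilde <= 1 over q in [0, 1]
  mus2 <- mus
  mus2$m1$mt$F_o <- 1000
  model1 <- toy_model(mus, "KneeFE")
  model2 <- toy_model(mus2, "KneeFE")
  s <- seq(0, 1, length.out = 101)
  q <- cbind(KneeFE = 0.5 * s)           # shortening keeps lengths below slack+l_oM
  qdot <- cbind(KneeFE = rep(0.5, 101))
  exc <- matrix(0.6, 111, 1, dimnames = list(NULL, "ch1"))
  M1 <- net_joint_moments(model1, q, qdot, exc, 1.0)
  M2 <- net_joint_moments(model2, q, qdot, exc, 1.0)
  expect_series_equal(M2, 2 * M1, tol = 1e-9)
})
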
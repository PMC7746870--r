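#' Activation-dynamics parameters
#'
#' Parameters of the excitation-to-activation model: a first-order ODE
#' `du/dt = (c1 e(t-d) + c2)(e(t-d) - u)` with `c1 = 1/tau_act - 1/tau_dact`,
#' `c2 = 1/tau_dact`, `tau_dact = 4 tau_act`, followed by the nonlinearity
#' `a = (1 - c3) u + c3 [g1 g2 (u + g3)^g4 + g5 + 1]`.  The default `g1..g5`
#' make the bracketed term a concave map of `[0,1]` onto `[0,1]` with
#' endpoints `a(0) = 0`, `a(1) = 1`; endpoint and monotonicity checks run at
#' construction, so user-supplied `g` vectors that break the A-shape are
#' rejected.
#'
#' @param tau_act Activation time constant (s), > 0; deactivation constant is
#'   `4 * tau_act`.
#' @param c3 Activation nonlinearity constant in `[0, 1]`.
#' @param d Electromechanical delay (s), in `[0, 0.1]`.
#' @param g Optional length-5 numeric vector `g1..g5`.
#' @return Object of class `"activation_params"`.
#' @export
activation_params <- function(tau_act = 0.015, c3 = 0, d = 0, g = NULL) {
  if (!is_number(tau_act) || tau_act <= 0) stopf("tau_act must be > 0")
  if (!is_number(c3) || c3 < 0 || c3 > 1) stopf("c3 must lie in [0, 1]")
  if (!is_number(d) || d < 0 || d > 0.1) stopf("delay d must lie in [0, 0.1] s")
  tau_dact <- 4 * tau_act
  if (is.null(g)) g <- default_g_constants()
  if (length(g) != 5) stopf("g must have length 5")
  par <- structure(
    list(tau_act = tau_act, tau_dact = tau_dact,
         c1 = 1 / tau_act - 1 / tau_dact, c2 = 1 / tau_dact,
         c3 = c3, d = d, g = as.numeric(g)),
    class = "activation_params")
  ug <- seq(0, 1, length.out = 201)
  B <- bracket_term(ug, par$g)
  if (abs(B[1]) > 1e-8 || abs(B[201] - 1) > 1e-8)
    stopf("nonlinearity endpoints violated: need a(0) = 0 and a(1) = 1")
  if (any(diff(B) < -1e-10))
    stopf("nonlinearity must be monotone non-decreasing on [0, 1]")
  par
}

# Concave power-law bracket fitted so B(0) = 0, B(1) = 1.
default_g_constants <- function(g3 = 0.1, g4 = 0.5) {
  a <- 1 / ((1 + g3)^g4 - g3^g4)
  c(a, 1, g3, g4, -a * g3^g4 - 1)
}

bracket_term <- function(u, g) g[1] * g[2] * (u + g[3])^g[4] + g[5] + 1

#' Neural-activation to muscle-activation nonlinearity
#'
#' @param u Neural activation series in `[0, 1]`.
#' @param params An [activation_params()] object.
#' @return Muscle activation, same length as `u`.
#' @export
activation_nonlinearity <- function(u, params) {
  (1 - params$c3) * u + params$c3 * bracket_term(u, params$g)
}

#' Muscle activation from excitation
#'
#' Shifts the excitation by the electromechanical delay (cubic interpolation
#' for fractional-frame delays, constant extension before the grid start),
#' integrates the first-order activation ODE with an explicit midpoint scheme
#' (sub-stepped when `dt * (c1 + c2) > 0.5` for stability), applies the
#' activation nonlinearity and clamps to `[0, 1]`.
#'
#' @param e Excitation series in `[0, 1]` on the padded frame grid.
#' @param params An [activation_params()] object.
#' @param dt Frame spacing in seconds.
#' @param keep `"cycle"` (default) returns the final 101 frames (the gait
#'   cycle); `"all"` returns the full grid.
#' @return Activation series.
#' @export
activation_from_excitation <- function(e, params, dt,
                                       keep = c("cycle", "all")) {
  keep <- match.arg(keep)
  stopifnot(inherits(params, "activation_params"), is_number(dt), dt > 0)
  n <- length(e)
  if (any(!is.finite(e))) stopf("excitation contains non-finite values")
  if (any(e < -1e-8) || any(e > 1 + 1e-8))
    stopf("excitation must lie in [0, 1]")
  e <- clamp01(e)
  if (keep == "cycle") {
    if (n < 101) stopf("need >= 101 frames to extract the gait cycle")
    if (params$d > (n - 101) * dt + 1e-12)
      stopf("delay %.3f s exceeds the padded duration %.3f s",
            params$d, (n - 101) * dt)
  }
  ed <- e
  if (params$d > 0) {
    tg <- (seq_len(n) - 1) * dt
    sf <- stats::splinefun(tg, e, method = "fmm")
    ed <- clamp01(sf(pmax(tg - params$d, 0)))
  }
  u <- activation_ode_c(ed, dt, params$c1, params$c2, ed[1])
  a <- clamp01(activation_nonlinearity(clamp01(u), params))
  if (keep == "cycle") a[(n - 100):n] else a
}

#' Hill-model normalized force curves
#'
#' Parameter container for the three normalized curves of the rigid-tendon
#' Hill model:
#' \itemize{
#'   \item active force-length `fl(l) = exp(-(l - 1)^2 / gamma)` (unimodal,
#'     `fl(1) = 1`);
#'   \item active force-velocity: Hill hyperbola on the concentric side
#'     (`fv(-1) = 0`, `fv(0) = 1`, shape constant `af`) with a C1-continuous
#'     eccentric branch saturating at `plateau`; velocities in units of the
#'     maximum contraction velocity `vmax` (optimal fiber lengths per
#'     second), lengthening positive;
#'   \item passive force-length `fp`: zero at or below optimal length,
#'     exponential beyond, scaled so `fp(1 + e0) = 1` with stiffness `kp`.
#' }
#'
#' @param gamma,af,plateau,vmax,kp,e0 Curve constants (see above).
#' @return Object of class `"muscle_curves"`.
#' @export
muscle_curves <- function(gamma = 0.45, af = 0.25, plateau = 1.4, vmax = 10,
                          kp = 4, e0 = 0.6) {
  stopifnot(gamma > 0, af > 0, plateau > 1, vmax > 0, kp > 0, e0 > 0)
  structure(list(gamma = gamma, af = af, plateau = plateau, vmax = vmax,
                 kp = kp, e0 = e0), class = "muscle_curves")
}

#' @rdname muscle_curves
#' @param l Normalized fiber length.
#' @param curves A [muscle_curves()] object.
#' @export
fl_curve <- function(l, curves = muscle_curves()) {
  exp(-(l - 1)^2 / curves$gamma)
}

#' @rdname muscle_curves
#' @param v Normalized fiber velocity (lengthening positive, units of vmax).
#' @export
fv_curve <- function(v, curves = muscle_curves()) {
  af <- curves$af
  cc <- (curves$plateau - 1) * af / (af + 1) # matches concentric slope at 0
  vc <- pmax(v, -1)
  ifelse(v <= 0,
         (1 + vc) / (1 - vc / af),
         1 + (curves$plateau - 1) * v / (v + cc))
}

#' @rdname muscle_curves
#' @export
fp_curve <- function(l, curves = muscle_curves()) {
  pmax(0, expm1(curves$kp * (l - 1) / curves$e0) / expm1(curves$kp))
}

#' Musculotendon parameters for one muscle
#'
#' @param F_o Maximum isometric force (N), > 0.
#' @param l_oM Optimal fiber length (m), > 0.
#' @param l_sT Tendon slack length (m), > 0.
#' @param alpha_o Pennation angle at optimal fiber length (rad), in
#'   `[0, pi/2)`.
#' @param emg_scale Excitation scale factor in `[0.05, 1]`.
#' @param channel EMG channel identifier this muscle is driven by.
#' @return Object of class `"muscle_params"`.
#' @export
muscle_params <- function(F_o, l_oM, l_sT, alpha_o = 0, emg_scale = 1,
                          channel = NA_character_) {
  stopifnot(F_o > 0, l_oM > 0, l_sT > 0)
  if (alpha_o < 0 || alpha_o >= pi / 2) stopf("alpha_o must lie in [0, pi/2)")
  if (emg_scale < 0.05 || emg_scale > 1)
    stopf("emg_scale must lie in [0.05, 1]")
  structure(list(F_o = F_o, l_oM = l_oM, l_sT = l_sT, alpha_o = alpha_o,
                 emg_scale = emg_scale, channel = channel),
            class = "muscle_params")
}

#' Rigid-tendon fiber kinematics
#'
#' With a rigid tendon the fiber length along the tendon is
#' `l_MT - l_sT`; constant-thickness pennation gives
#' `l_M = sqrt((l_MT - l_sT)^2 + (l_oM sin(alpha_o))^2)` and
#' `cos(alpha) = (l_MT - l_sT) / l_M`.  Fiber velocity follows by the chain
#' rule, `v_M = cos(alpha) * v_MT`, and is normalized by the maximum
#' contraction velocity `vmax * l_oM`.
#'
#' @param l_mt Musculotendon length series (m).
#' @param v_mt Musculotendon lengthening velocity series (m/s).
#' @param params A [muscle_params()] object.
#' @param curves A [muscle_curves()] object (supplies `vmax`).
#' @param muscle Muscle name used in error messages.
#' @return List with `ltilde`, `vtilde`, `cos_alpha`.
#' @export
fiber_kinematics <- function(l_mt, v_mt, params, curves = muscle_curves(),
                             muscle = "muscle") {
  h <- l_mt - params$l_sT
  bad <- which(h <= 0)
  if (length(bad))
    stopf("fiber length <= 0 for %s at frame %d (l_MT = %.4f m <= l_sT = %.4f m)",
          muscle, bad[1], l_mt[bad[1]], params$l_sT)
  w <- params$l_oM * sin(params$alpha_o)
  l_m <- sqrt(h^2 + w^2)
  cos_alpha <- h / l_m
  list(ltilde = l_m / params$l_oM,
       vtilde = cos_alpha * v_mt / (curves$vmax * params$l_oM),
       cos_alpha = cos_alpha)
}

#' Joint moment contributed by one muscle
#'
#' `M = r * F_o * (a * fl * fv + fp) * cos(alpha)` with the normalized curves
#' of [muscle_curves()].  The pennation angle at the current length follows
#' the constant-thickness assumption `sin(alpha) = sin(alpha_o) / ltilde`.
#'
#' @param a Activation series in `[0, 1]`.
#' @param ltilde,vtilde Normalized fiber length and velocity series.
#' @param r Moment arm series (m) about the joint.
#' @param params A [muscle_params()] object.
#' @param curves A [muscle_curves()] object.
#' @return Moment series (N m).
#' @export
muscle_moment <- function(a, ltilde, vtilde, r, params,
                          curves = muscle_curves()) {
  if (any(a < -1e-9) || any(a > 1 + 1e-9)) stopf("activation must lie in [0, 1]")
  sin_a <- pmin(sin(params$alpha_o) / ltilde, 1)
  cos_a <- sqrt(1 - sin_a^2)
  r * params$F_o *
    (a * fl_curve(ltilde, curves) * fv_curve(vtilde, curves) +
       fp_curve(ltilde, curves)) * cos_a
}

# ---- polynomial geometry surrogate ------------------------------------------

# Exponent rows of all monomials in `nd` variables with total degree <= degree.
monomial_exponents <- function(nd, degree) {
  grids <- rep(list(0:degree), nd)
  ex <- as.matrix(expand.grid(grids))
  ex <- ex[rowSums(ex) <= degree, , drop = FALSE]
  ex[order(rowSums(ex), apply(ex, 1, paste, collapse = ",")), , drop = FALSE]
}

monomial_design <- function(q, exponents) {
  n <- nrow(q)
  X <- matrix(1, n, nrow(exponents))
  for (k in seq_len(nrow(exponents)))
    for (j in seq_len(ncol(exponents)))
      if (exponents[k, j] > 0) X[, k] <- X[, k] * q[, j]^exponents[k, j]
  X
}

#' Fit a polynomial musculotendon-geometry surrogate
#'
#' Least-squares fit of musculotendon length `l_MT(q)` as a multivariate
#' polynomial in the joint angles the muscle spans.  Moment arms are the
#' analytic negative partial derivatives of the fitted polynomial,
#' `r_j(q) = -d l_MT / d q_j`, so tendon-excursion consistency holds by
#' construction.
#'
#' @param q Numeric matrix of joint angles (rad), samples x DOFs, with DOF
#'   column names.
#' @param l_mt Musculotendon length at each sample (m).
#' @param degree Total polynomial degree.
#' @return Object of class `"geometry_surrogate"` with coefficients, the
#'   monomial exponent table, the evaluation domain (per-DOF sample range)
#'   and fit residuals.
#' @export
fit_geometry_surrogate <- function(q, l_mt, degree = 2) {
  q <- as.matrix(q)
  if (is.null(colnames(q))) colnames(q) <- paste0("q", seq_len(ncol(q)))
  exponents <- monomial_exponents(ncol(q), degree)
  if (nrow(q) < nrow(exponents))
    stopf("need >= %d samples for a degree-%d fit in %d DOFs (have %d)",
          nrow(exponents), degree, ncol(q), nrow(q))
  X <- monomial_design(q, exponents)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("rank-deficient geometry fit: sample a wider motion range or lower the degree")
  coef <- qr.coef(qrX, l_mt)
  res <- l_mt - drop(X %*% coef)
  structure(
    list(coef = as.numeric(coef), exponents = exponents,
         dof_names = colnames(q), degree = degree,
         domain = apply(q, 2, range), residuals = res,
         rmse = sqrt(mean(res^2))),
    class = "geometry_surrogate")
}

check_domain <- function(surr, q) {
  for (j in seq_len(ncol(q))) {
    rng <- surr$domain[, j]
    margin <- 0.25 * max(diff(rng), 1e-6)
    if (any(q[, j] < rng[1] - margin) || any(q[, j] > rng[2] + margin))
      stopf("joint angle for DOF '%s' outside the surrogate's fitted domain",
            surr$dof_names[j])
  }
}

#' Evaluate a geometry surrogate
#'
#' @param surr A [fit_geometry_surrogate()] result.
#' @param q Joint-angle matrix (frames x DOFs) in the surrogate's DOF order.
#' @return `eval_lmt`: musculotendon length series (m); `moment_arms`: frames
#'   x DOFs matrix of moment arms (m), `r_j = -d l_MT / d q_j`.
#' @export
eval_lmt <- function(surr, q) {
  q <- as.matrix(q)
  check_domain(surr, q)
  drop(monomial_design(q, surr$exponents) %*% surr$coef)
}

#' @rdname eval_lmt
#' @export
moment_arms <- function(surr, q) {
  q <- as.matrix(q)
  check_domain(surr, q)
  nd <- ncol(q)
  R <- matrix(0, nrow(q), nd, dimnames = list(NULL, surr$dof_names))
  for (j in seq_len(nd)) {
    ex <- surr$exponents
    active <- which(ex[, j] > 0)
    if (!length(active)) next
    dex <- ex[active, , drop = FALSE]
    dcoef <- surr$coef[active] * dex[, j]
    dex[, j] <- dex[, j] - 1
    R[, j] <- -drop(monomial_design(q, dex) %*% dcoef)
  }
  R
}

#' Assemble a musculotendon model
#'
#' @param muscles Named list; each element is a list with components
#'   `act` ([activation_params()]), `mt` ([muscle_params()], whose `channel`
#'   maps the muscle to an EMG channel; compartments may share a channel) and
#'   `geom` ([fit_geometry_surrogate()] over the DOFs the muscle spans).
#' @param dof_names Character vector of model DOF names; every muscle's
#'   geometry DOFs must be a subset.
#' @param curves A [muscle_curves()] object shared by all muscles.
#' @return Object of class `"musculotendon_model"`.
#' @export
musculotendon_model <- function(muscles, dof_names, curves = muscle_curves()) {
  stopifnot(length(muscles) >= 1, length(dof_names) >= 1)
  if (is.null(names(muscles))) stopf("muscles must be a named list")
  for (nm in names(muscles)) {
    m <- muscles[[nm]]
    stopifnot(inherits(m$act, "activation_params"),
              inherits(m$mt, "muscle_params"),
              inherits(m$geom, "geometry_surrogate"))
    if (is.na(m$mt$channel)) stopf("muscle '%s' has no EMG channel", nm)
    if (!all(m$geom$dof_names %in% dof_names))
      stopf("muscle '%s' spans unknown DOFs", nm)
  }
  structure(list(muscles = muscles, dof_names = dof_names, curves = curves,
                 channels = unique(vapply(muscles, function(m) m$mt$channel, ""))),
            class = "musculotendon_model")
}

#' @export
print.musculotendon_model <- function(x, ...) {
  cat(sprintf("Musculotendon model: %d muscles, %d EMG channels, DOFs: %s\n",
              length(x$muscles), length(x$channels),
              paste(x$dof_names, collapse = ", ")))
  invisible(x)
}

# Frame-wise moment-arm / force-scaling terms of one muscle along a trajectory:
# everything in the moment except the activation.  Used by the forward model
# and reused by the synergy-extrapolation solver, where only the activation of
# the unmeasured muscle changes between objective evaluations.
muscle_moment_terms <- function(model, name, q, qdot) {
  m <- model$muscles[[name]]
  dofs <- m$geom$dof_names
  qs <- q[, dofs, drop = FALSE]
  R <- moment_arms(m$geom, qs)
  v_mt <- if (is.null(qdot)) {
    l_mt <- eval_lmt(m$geom, qs)
    c(diff(l_mt)[1], (l_mt[-1:-2] - l_mt[1:(length(l_mt) - 2)]) / 2,
      diff(l_mt)[length(l_mt) - 1]) / attr(q, "dt")
  } else {
    -rowSums(R * qdot[, dofs, drop = FALSE])
  }
  l_mt <- eval_lmt(m$geom, qs)
  fk <- fiber_kinematics(l_mt, v_mt, m$mt, model$curves, muscle = name)
  list(dofs = dofs, R = R,
       active_gain = m$mt$F_o * fl_curve(fk$ltilde, model$curves) *
         fv_curve(fk$vtilde, model$curves) * fk$cos_alpha,
       passive = m$mt$F_o * fp_curve(fk$ltilde, model$curves) * fk$cos_alpha)
}

#' Net joint moments from an EMG-driven forward simulation
#'
#' For every muscle: scales its EMG channel by `emg_scale` (clamping the
#' product into `[0, 1]`), runs activation dynamics, evaluates rigid-tendon
#' fiber kinematics on the surrogate geometry, and accumulates
#' moment-arm-weighted Hill-model forces into net moments per DOF.
#'
#' @param model A [musculotendon_model()].
#' @param q,qdot Joint angle and angular-velocity matrices (101 frames x
#'   DOFs, columns named as `model$dof_names`; `qdot` may be `NULL` to use
#'   finite differences of musculotendon length).
#' @param excitations Padded excitation matrix ((101 + n_pad) frames x
#'   channels, named columns covering every channel in the model).
#' @param t_f Gait-cycle period (s); frame spacing is `t_f / 100`.
#' @param details If `TRUE`, also return per-muscle activations and moment
#'   contributions.
#' @return 101 x n_DOF moment matrix (N m), or a list when `details = TRUE`.
#' @export
net_joint_moments <- function(model, q, qdot, excitations, t_f,
                              details = FALSE) {
  stopifnot(inherits(model, "musculotendon_model"))
  q <- as.matrix(q)
  if (nrow(q) != 101) stopf("q must have 101 frames (the gait-cycle grid)")
  missing_ch <- setdiff(model$channels, colnames(excitations))
  if (length(missing_ch))
    stopf("no excitation for channel '%s'", missing_ch[1])
  dt <- t_f / 100
  attr(q, "dt") <- dt
  M <- matrix(0, 101, length(model$dof_names),
              dimnames = list(NULL, model$dof_names))
  acts <- matrix(NA_real_, 101, length(model$muscles),
                 dimnames = list(NULL, names(model$muscles)))
  for (nm in names(model$muscles)) {
    m <- model$muscles[[nm]]
    e <- clamp01(m$mt$emg_scale * clamp01(excitations[, m$mt$channel]))
    a <- activation_from_excitation(e, m$act, dt)
    terms <- muscle_moment_terms(model, nm, q, qdot)
    force <- a * terms$active_gain + terms$passive
    M[, terms$dofs] <- M[, terms$dofs] + terms$R * force
    acts[, nm] <- a
  }
  if (details) list(moments = M, activations = acts) else M
}
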
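#' Joint-moment tracking objective
#'
#' Sum of squared differences between model-predicted and experimental
#' (inverse-dynamics) joint moments, pooled over frames, DOFs and trials:
#' `J = sum_trials sum_frames sum_dofs (M_mod - M_exp)^2`.
#'
#' @param model A [musculotendon_model()].
#' @param trials List of trials; each needs `envelopes` (padded excitation
#'   matrix with channel columns), `q`, `qdot`, `M_exp` (101 x DOFs) and
#'   `t_f`.
#' @return Scalar objective (N^2 m^2).
#' @export
tracking_objective <- function(model, trials) {
  J <- 0
  for (tr in trials) {
    M <- net_joint_moments(model, tr$q, tr$qdot, tr$envelopes, tr$t_f)
    J <- J + sum((M - tr$M_exp[, colnames(M), drop = FALSE])^2)
  }
  J
}

CAL_PARAMS <- c("d", "tau_act", "c3", "emg_scale", "l_oM_adj", "l_sT_adj")

#' Default calibration bounds
#'
#' Per-parameter box bounds: delay `d` in `[0, 0.1]` s, `tau_act` in
#' `[0.01, 0.05]` s, nonlinearity `c3` in `[0, 1]`, `emg_scale` in
#' `[0.05, 1]`, and multiplicative optimal-fiber-length / tendon-slack-length
#' adjustments within +/-15% of nominal.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
calibration_bounds <- function() {
  list(d = c(0, 0.1), tau_act = c(0.01, 0.05), c3 = c(0, 1),
       emg_scale = c(0.05, 1), l_oM_adj = c(0.85, 1.15),
       l_sT_adj = c(0.85, 1.15))
}

#' Define a calibration problem
#'
#' Chooses which per-muscle parameters are free during joint-moment-tracking
#' calibration of an EMG-driven model, with box bounds per parameter.  The
#' length adjustments are multiplicative factors on the template's nominal
#' `l_oM` and `l_sT`.
#'
#' @param model Template [musculotendon_model()]; its current parameter
#'   values are the initial guesses.
#' @param trials Calibration trials (see [tracking_objective()]).
#' @param design Character subset of
#'   `c("d", "tau_act", "c3", "emg_scale", "l_oM_adj", "l_sT_adj")`.
#' @param muscles Muscle names to calibrate (default all).
#' @param bounds Named list of bounds as in [calibration_bounds()].
#' @param lambda Weight of the quadratic regularizer pulling parameters
#'   toward their initial values (on the bound-normalized scale); small by
#'   default.
#' @return Object of class `"calibration_problem"`.
#' @export
calibration_problem <- function(model, trials, design = c("emg_scale"),
                                muscles = names(model$muscles),
                                bounds = calibration_bounds(),
                                lambda = 1e-4) {
  stopifnot(inherits(model, "musculotendon_model"), length(trials) >= 1)
  design <- match.arg(design, CAL_PARAMS, several.ok = TRUE)
  stopifnot(all(muscles %in% names(model$muscles)))
  for (p in design) {
    b <- bounds[[p]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stopf("bounds for '%s' must be finite with lower < upper", p)
  }
  structure(list(model = model, trials = trials, design = design,
                 muscles = muscles, bounds = bounds, lambda = lambda),
            class = "calibration_problem")
}

# Current parameter value of one muscle on the design scale.
cal_get <- function(m, param) {
  switch(param,
         d = m$act$d, tau_act = m$act$tau_act, c3 = m$act$c3,
         emg_scale = m$mt$emg_scale, l_oM_adj = 1, l_sT_adj = 1)
}

# Apply a design vector (one value per muscle x parameter) to the template.
cal_apply <- function(problem, theta) {
  model <- problem$model
  k <- 0L
  for (nm in problem$muscles) {
    m <- model$muscles[[nm]]
    for (p in problem$design) {
      k <- k + 1L
      v <- theta[k]
      if (p %in% c("d", "tau_act", "c3")) {
        args <- list(tau_act = m$act$tau_act, c3 = m$act$c3, d = m$act$d,
                     g = m$act$g)
        args[[if (p == "tau_act") "tau_act" else p]] <- v
        m$act <- do.call(activation_params, args)
      } else if (p == "emg_scale") {
        m$mt$emg_scale <- v
      } else if (p == "l_oM_adj") {
        m$mt$l_oM <- problem$model$muscles[[nm]]$mt$l_oM * v
      } else if (p == "l_sT_adj") {
        m$mt$l_sT <- problem$model$muscles[[nm]]$mt$l_sT * v
      }
    }
    model$muscles[[nm]] <- m
  }
  model
}

# Build a fast tracking objective for designs that leave the geometry fixed
# (no l_oM / l_sT adjustments): moment-arm and Hill-curve terms per
# (trial, muscle) and the moment contribution of non-calibrated muscles are
# precomputed once, so each evaluation only reruns activation dynamics for
# the calibrated muscles.
cal_fast_objective <- function(problem) {
  model <- problem$model
  cal_set <- problem$muscles
  has_delay <- "d" %in% problem$design
  cache <- lapply(problem$trials, function(tr) {
    q <- as.matrix(tr$q); dt <- tr$t_f / 100; attr(q, "dt") <- dt
    M_fixed <- matrix(0, 101, length(model$dof_names),
                      dimnames = list(NULL, model$dof_names))
    mus <- list()
    for (nm in names(model$muscles)) {
      m <- model$muscles[[nm]]
      terms <- muscle_moment_terms(model, nm, q, tr$qdot)
      e_ch <- clamp01(tr$envelopes[, m$mt$channel])
      if (nm %in% cal_set) {
        n <- length(e_ch); tg <- (seq_len(n) - 1) * dt
        sf <- stats::splinefun(tg, e_ch, method = "fmm")
        # emg_scale <= 1 and e in [0,1], so scaling commutes with the
        # delay shift and no clamp is active in between
        mus[[nm]] <- list(terms = terms, dt = dt, n = n, tg = tg,
                          e_fun = if (has_delay) sf else NULL,
                          e_base = if (has_delay) NULL else
                            sf(pmax(tg - m$act$d, 0)))
      } else {
        e <- clamp01(m$mt$emg_scale * e_ch)
        a <- activation_from_excitation(e, m$act, dt)
        force <- a * terms$active_gain + terms$passive
        M_fixed[, terms$dofs] <- M_fixed[, terms$dofs] + terms$R * force
      }
    }
    list(M_fixed = M_fixed, mus = mus, dt = dt,
         M_exp = tr$M_exp[, model$dof_names, drop = FALSE])
  })
  function(cal_model) {
    J <- 0
    for (tc in cache) {
      M <- tc$M_fixed
      for (nm in names(tc$mus)) {
        mc <- tc$mus[[nm]]
        m <- cal_model$muscles[[nm]]
        e <- if (is.null(mc$e_base))
          clamp01(mc$e_fun(pmax(mc$tg - m$act$d, 0))) else mc$e_base
        e <- clamp01(m$mt$emg_scale * e)
        u <- activation_ode_c(e, mc$dt, m$act$c1, m$act$c2, e[1])
        a <- clamp01(activation_nonlinearity(clamp01(u), m$act))
        a <- a[(mc$n - 100):mc$n]
        force <- a * mc$terms$active_gain + mc$terms$passive
        M[, mc$terms$dofs] <- M[, mc$terms$dofs] + mc$terms$R * force
      }
      J <- J + sum((M - tc$M_exp)^2)
    }
    J
  }
}

#' Calibrate an EMG-driven model by joint-moment tracking
#'
#' Bound-constrained quasi-Newton (L-BFGS-B) minimization of
#' [tracking_objective()] over the chosen design parameters, on a
#' bound-normalized scale, starting from the template's current values.  A
#' small quadratic regularizer (weight `lambda` in the problem) pulls
#' parameters toward their initial values.  Optionally staged: `stages` is a
#' list of design-parameter subsets optimized in sequence (each stage holds
#' the others fixed), mimicking sequential calibration protocols.
#'
#' @param problem A [calibration_problem()].
#' @param seed Unused placeholder for interface symmetry (the optimizer is
#'   deterministic from the template start).
#' @param max_iter Maximum optimizer iterations per stage.
#' @param stages Optional list of character vectors (subsets of the
#'   problem's design) to optimize sequentially; default one stage with all.
#' @return Object of class `"synx_calibration"`: calibrated `model`, final
#'   `J`, initial `J_init`, per-trial per-DOF `mae`, parameter table
#'   `parameters` (with bound flags), and the objective `log` across
#'   accepted evaluations.
#' @export
calibrate <- function(problem, seed = NULL, max_iter = 100, stages = NULL) {
  stopifnot(inherits(problem, "calibration_problem"))
  design_all <- problem$design
  lb_of <- function(p) problem$bounds[[p]][1]
  ub_of <- function(p) problem$bounds[[p]][2]
  grid <- expand.grid(param = design_all, muscle = problem$muscles,
                      stringsAsFactors = FALSE)
  # vector layout must match cal_apply: muscles outer, params inner
  grid <- grid[order(match(grid$muscle, problem$muscles)), , drop = FALSE]
  theta0 <- mapply(function(p, nm) cal_get(problem$model$muscles[[nm]], p),
                   grid$param, grid$muscle)
  lb <- vapply(grid$param, lb_of, 0); ub <- vapply(grid$param, ub_of, 0)
  theta0 <- pmin(pmax(theta0, lb), ub)
  J0 <- tracking_objective(problem$model, problem$trials)
  if (!is.finite(J0)) stopf("objective non-finite at the initial point")
  if (nrow(grid) == 0)
    return(finish_calibration(problem, theta0, grid, J0, J0,
                              data.frame(eval = integer(), J = numeric())))
  log_env <- new.env(); log_env$J <- numeric(); log_env$n <- 0L
  geometry_static <- !any(c("l_oM_adj", "l_sT_adj") %in% design_all)
  obj <- if (geometry_static) cal_fast_objective(problem)
         else function(m) tracking_objective(m, problem$trials)
  z0_all <- (theta0 - lb) / (ub - lb)
  z <- z0_all
  if (is.null(stages)) stages <- list(design_all)
  for (stage in stages) {
    idx <- which(grid$param %in% stage)
    if (!length(idx)) next
    fn <- function(zi) {
      zz <- z; zz[idx] <- zi
      th <- lb + zz * (ub - lb)
      J <- obj(cal_apply(problem, th)) +
        problem$lambda * sum((zz - z0_all)^2)
      log_env$n <- log_env$n + 1L
      log_env$J <- c(log_env$J, J)
      J
    }
    res <- stats::optim(z[idx], fn, method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(maxit = max_iter, factr = 1e7))
    z[idx] <- res$par
  }
  theta <- lb + z * (ub - lb)
  Jfin <- tracking_objective(cal_apply(problem, theta), problem$trials)
  if (Jfin > J0) { theta <- theta0; Jfin <- J0 } # never worse than the start
  finish_calibration(problem, theta, grid, Jfin, J0,
                     data.frame(eval = seq_along(log_env$J), J = log_env$J))
}

finish_calibration <- function(problem, theta, grid, J, J0, log) {
  model <- if (nrow(grid)) cal_apply(problem, theta) else problem$model
  mae <- t(vapply(problem$trials, function(tr) {
    M <- net_joint_moments(model, tr$q, tr$qdot, tr$envelopes, tr$t_f)
    colMeans(abs(M - tr$M_exp[, colnames(M), drop = FALSE]))
  }, numeric(length(problem$model$dof_names))))
  params <- if (nrow(grid)) {
    lo <- vapply(grid$param, function(p) problem$bounds[[p]][1], 0)
    hi <- vapply(grid$param, function(p) problem$bounds[[p]][2], 0)
    data.frame(muscle = grid$muscle, param = grid$param, value = theta,
               lower = lo, upper = hi,
               at_bound = theta <= lo + 1e-6 * (hi - lo) |
                 theta >= hi - 1e-6 * (hi - lo),
               row.names = NULL)
  } else {
    data.frame(muscle = character(), param = character(), value = numeric(),
               lower = numeric(), upper = numeric(), at_bound = logical())
  }
  structure(list(model = model, J = J, J_init = J0, mae = mae,
                 parameters = params, log = log),
            class = "synx_calibration")
}

#' @export
print.synx_calibration <- function(x, ...) {
  cat(sprintf("EMG-driven model calibration: J %.4g -> %.4g (%d objective evaluations)\n",
              x$J_init, x$J, nrow(x$log)))
  if (any(x$parameters$at_bound))
    cat(sprintf("  %d parameter(s) at a bound\n", sum(x$parameters$at_bound)))
  invisible(x)
}
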
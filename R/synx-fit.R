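#' Reconstruct an unmeasured excitation from synergies
#'
#' `e_x = W %*% H_x` (NMF) or `e_x = W %*% H_x + mu_x` (PCA): the unmeasured
#' muscle's excitation as a weighted combination of the measured synergy
#' excitations.  Returned unclamped; callers clamp into `[0, 1]` where the
#' muscle model requires it.
#'
#' @param W Synergy-excitation matrix (frames x p).
#' @param H_x Length-`p` weight vector.
#' @param mu_x Scalar offset (PCA), or `NULL`.
#' @return Excitation series (length `nrow(W)`).
#' @export
extrapolate_excitation <- function(W, H_x, mu_x = NULL) {
  W <- as.matrix(W)
  if (length(H_x) != ncol(W))
    stopf("H_x has length %d but W has %d columns", length(H_x), ncol(W))
  e <- drop(W %*% H_x)
  if (!is.null(mu_x)) e <- e + mu_x
  e
}

#' Synergy extrapolation: fit unmeasured synergy weights by moment tracking
#'
#' The core estimator.  Holding all musculotendon model parameters fixed at
#' their calibrated values, finds the unmeasured muscle's synergy weights
#' `H_x` (plus offset `mu_x` for PCA) such that the EMG-driven model — driven
#' by the measured excitations plus the reconstructed unmeasured excitation
#' `e_x = W H_x (+ mu_x)` — tracks the experimental inverse-dynamics joint
#' moments in the least-squares sense ([tracking_objective()]).
#'
#' The constraint `e_x(t) in [0, 1]` at every frame is linear in
#' `(H_x, mu_x)` and is enforced by an exterior quadratic-penalty loop around
#' a bound-constrained quasi-Newton solve (L-BFGS-B): the penalty weight
#' grows until the unclamped reconstruction violates the box by less than
#' `control$penalty_tol`.  `H_x` is bounded below by zero for NMF and left
#' effectively unbounded for PCA (a wide stabilizing box of
#' `+/- 10 max|H_m|`, reported if it ever binds).  `n_starts` random
#' initializations of `H_x` in `[0, 1]^p` guard against local minima; the
#' best final objective wins and every start is logged.
#'
#' @param model Calibrated [musculotendon_model()] containing the unmeasured
#'   muscle's channel.
#' @param trial Trial data: list with `envelopes` (padded excitation matrix
#'   including all measured channels), `q`, `qdot`, `M_exp`, `t_f`.
#' @param synergy A [synergy_decompose()] fit of the measured channels on
#'   this trial's padded grid.
#' @param unmeasured Name of the unmeasured EMG channel (absent from the
#'   synergy model, present in the musculotendon model's channel map).
#' @param n_starts Number of seeded random starts (default 5).
#' @param seed Integer seed for the start values.
#' @param control List of solver settings: `penalty_tol` (default 1e-5),
#'   `feas_tol` (1e-3), `maxit` (200), `max_penalty_rounds` (6),
#'   `bounds_mult` (10).
#' @return Object of class `"synx"`; see [coef.synx()], [fitted.synx()],
#'   [residuals.synx()], [predict.synx()], [plot.synx()].
#' @export
synx <- function(model, trial, synergy, unmeasured, n_starts = 5,
                 seed = NULL, control = list()) {
  stopifnot(inherits(model, "musculotendon_model"),
            inherits(synergy, "synergy_model"))
  ctl <- utils::modifyList(
    list(penalty_tol = 1e-5, feas_tol = 1e-3, maxit = 200,
         max_penalty_rounds = 6, bounds_mult = 10), control)
  if (synergy$p < 1) stopf("synergy model has p = 0")
  if (unmeasured %in% synergy$channel_names)
    stopf("channel '%s' is part of the measured synergy model", unmeasured)
  if (!unmeasured %in% model$channels)
    stopf("channel '%s' not present in the musculotendon model", unmeasured)
  W <- synergy$W
  p <- synergy$p
  is_pca <- synergy$algorithm == "pca"
  n_frames <- nrow(trial$envelopes)
  if (nrow(W) != n_frames)
    stopf("synergy excitations (%d frames) do not match the trial grid (%d frames)",
          nrow(W), n_frames)
  dt <- trial$t_f / 100

  x_names <- names(model$muscles)[vapply(model$muscles,
    function(m) m$mt$channel == unmeasured, TRUE)]
  meas_model <- musculotendon_model(
    model$muscles[setdiff(names(model$muscles), x_names)],
    model$dof_names, model$curves)
  missing_ch <- setdiff(meas_model$channels, colnames(trial$envelopes))
  if (length(missing_ch)) stopf("trial lacks measured channel '%s'", missing_ch[1])
  M_meas <- net_joint_moments(meas_model, trial$q, trial$qdot,
                              trial$envelopes, trial$t_f)
  M_exp <- trial$M_exp[, colnames(M_meas), drop = FALSE]
  q <- as.matrix(trial$q); attr(q, "dt") <- dt
  x_terms <- lapply(x_names, function(nm) {
    tm <- muscle_moment_terms(model, nm, q, trial$qdot)
    tm$act <- model$muscles[[nm]]$act
    tm$scale <- model$muscles[[nm]]$mt$emg_scale
    tm
  })

  moments_x <- function(e_clamped) {
    Mx <- matrix(0, 101, ncol(M_meas), dimnames = dimnames(M_meas))
    for (tm in x_terms) {
      a <- activation_from_excitation(clamp01(tm$scale * e_clamped), tm$act, dt)
      force <- a * tm$active_gain + tm$passive
      Mx[, tm$dofs] <- Mx[, tm$dofs] + tm$R * force
    }
    Mx
  }
  track_J <- function(e_clamped) {
    sum((M_meas + moments_x(e_clamped) - M_exp)^2)
  }
  e_raw_of <- function(theta)
    extrapolate_excitation(W, theta[seq_len(p)],
                           if (is_pca) theta[p + 1] else NULL)
  violation <- function(e_raw) max(0, max(-e_raw), max(e_raw - 1))

  Hm_max <- max(abs(synergy$H), if (is_pca) abs(synergy$mu), 1)
  B <- ctl$bounds_mult * Hm_max
  lower <- if (is_pca) rep(-B, p + 1) else rep(0, p)
  upper <- if (is_pca) rep(B, p + 1) else rep(Inf, p)
  mu_init <- if (is_pca) mean(synergy$mu) else NULL

  rho_scale <- max(sum(M_exp^2), 1)
  starts <- list()
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      theta <- c(stats::runif(p), mu_init)
      rho <- rho_scale
      conv <- NA_integer_
      for (round in seq_len(ctl$max_penalty_rounds)) {
        fn <- function(th) {
          e_raw <- e_raw_of(th)
          track_J(clamp01(e_raw)) +
            rho * sum(pmax(-e_raw, 0)^2 + pmax(e_raw - 1, 0)^2)
        }
        res <- stats::optim(theta, fn, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = ctl$maxit, factr = 1e7))
        theta <- res$par
        conv <- res$convergence
        if (violation(e_raw_of(theta)) < ctl$penalty_tol) break
        rho <- rho * 10
      }
      viol <- violation(e_raw_of(theta))
      Jfin <- track_J(clamp01(e_raw_of(theta)))
      starts[[s]] <- data.frame(start = s, J = Jfin, violation = viol,
                                convergence = conv,
                                penalty_rounds = round)
      if (is.null(best) || Jfin < best$J)
        best <- list(theta = theta, J = Jfin, viol = viol, conv = conv)
    }
  })
  starts <- do.call(rbind, starts)

  theta <- best$theta
  H_x <- theta[seq_len(p)]
  mu_x <- if (is_pca) theta[p + 1] else NULL
  e_raw <- e_raw_of(theta)
  e_x <- clamp01(e_raw)
  Mx <- moments_x(e_x)
  M_mod <- M_meas + Mx
  resid <- M_mod - M_exp
  J <- sum(resid^2)

  # identifiability probe: does perturbing the weights move the moments?
  dM <- vapply(seq_along(theta), function(k) {
    th2 <- theta; th2[k] <- th2[k] + 0.1
    max(abs(moments_x(clamp01(e_raw_of(th2))) - Mx))
  }, 0)
  non_identifiable <- max(dM) < 1e-8 * max(1, max(abs(M_exp)))

  structure(
    list(H_x = stats::setNames(H_x, colnames(W)), mu_x = mu_x,
         e_x = e_x, e_x_raw = e_raw,
         e_x_cycle = e_x[(n_frames - 100):n_frames],
         J = J, M_mod = M_mod, M_meas = M_meas, M_exp = M_exp,
         residuals = resid,
         mae = colMeans(abs(resid)),
         algorithm = synergy$algorithm, p = p, unmeasured = unmeasured,
         muscles = x_names, n_pad = n_frames - 101, t_f = trial$t_f,
         diagnostics = list(
           starts = starts, feasible = best$viol < ctl$feas_tol,
           violation = best$viol, convergence = best$conv,
           bounds_active = any(abs(theta - lower) < 1e-8 & is.finite(lower)) ||
             any(abs(theta - upper) < 1e-8 & is.finite(upper)),
           non_identifiable = non_identifiable),
         synergy = synergy),
    class = "synx")
}

#' @export
print.synx <- function(x, ...) {
  cat(sprintf("SynX fit (%s, p = %d): unmeasured channel '%s'\n",
              toupper(x$algorithm), x$p, x$unmeasured))
  cat(sprintf("  J = %.4g;  moment MAE (N m): %s\n", x$J,
              paste(sprintf("%s %.3f", names(x$mae), x$mae), collapse = ", ")))
  if (x$diagnostics$non_identifiable)
    cat("  WARNING: weights not identifiable (moments insensitive to H_x)\n")
  invisible(x)
}

#' @export
summary.synx <- function(object, ...) {
  structure(list(fit = object), class = "summary.synx")
}

#' @export
print.summary.synx <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  H_x:\n")
  print(round(f$H_x, 4))
  if (!is.null(f$mu_x)) cat(sprintf("  mu_x = %.4f\n", f$mu_x))
  d <- f$diagnostics
  cat(sprintf("  starts: %d, best J span [%.4g, %.4g], max e_x violation %.2g\n",
              nrow(d$starts), min(d$starts$J), max(d$starts$J), d$violation))
  invisible(x)
}

#' Methods for SynX fits
#'
#' `coef()` returns the fitted synergy weights (with `mu_x` appended for
#' PCA); `fitted()` the reconstructed unmeasured excitation on the 101-frame
#' gait-cycle grid; `residuals()` the joint-moment residual matrix
#' (model minus experimental, 101 x DOFs); `predict()` evaluates the fitted
#' weights on a (possibly new) synergy-excitation matrix or returns the
#' model-predicted moments.
#'
#' @param object A [synx()] fit.
#' @param ... Unused.
#' @return See the description.
#' @export
coef.synx <- function(object, ...) {
  cf <- object$H_x
  if (!is.null(object$mu_x)) cf <- c(cf, mu_x = object$mu_x)
  cf
}

#' @rdname coef.synx
#' @export
fitted.synx <- function(object, ...) object$e_x_cycle

#' @rdname coef.synx
#' @export
residuals.synx <- function(object, ...) object$residuals

#' @rdname coef.synx
#' @param newW Optional synergy-excitation matrix with `p` columns; defaults
#'   to the training synergies.
#' @param type `"excitation"` (default) or `"moments"`.
#' @export
predict.synx <- function(object, newW = NULL, type = c("excitation", "moments"),
                         ...) {
  type <- match.arg(type)
  if (type == "moments") return(object$M_mod)
  if (is.null(newW)) return(object$e_x)
  clamp01(extrapolate_excitation(newW, object$H_x, object$mu_x))
}

#' @rdname coef.synx
#' @param x A [synx()] fit.
#' @param truth Optional true excitation series (cycle grid) to overlay.
#' @export
plot.synx <- function(x, truth = NULL, ...) {
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  pct <- seq(0, 100, length.out = 101)
  graphics::plot(pct, x$e_x_cycle, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "% gait cycle", ylab = "excitation",
                 main = sprintf("SynX %s: '%s'", toupper(x$algorithm),
                                x$unmeasured))
  if (!is.null(truth)) {
    graphics::lines(pct, truth, lty = 2)
    graphics::legend("topright", c("SynX", "truth"), lty = 1:2, bty = "n")
  }
  graphics::matplot(pct, x$M_exp, type = "l", lty = 2,
                    xlab = "% gait cycle", ylab = "moment (N m)",
                    main = "moment tracking (dashed = experimental)")
  graphics::matlines(pct, x$M_mod, lty = 1)
  invisible(x)
}
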
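# Seeded ground-truth generator: a synthetic lower-limb system with
# synergy-structured excitations, used to exercise and validate every
# pipeline stage without experimental data.

VS_DOFS <- c("HipFE", "HipAA", "KneeFE", "AnklePD", "AnkleIE")

# 16 leg muscles with anatomically flavoured DOF spans and channel names.
vs_muscle_table <- function() {
  list(
    iliopsoas       = c("HipFE"),
    adductor_longus = c("HipFE", "HipAA"),
    glut_max        = c("HipFE"),
    glut_med        = c("HipAA"),
    rect_fem        = c("HipFE", "KneeFE"),
    vas_lat         = c("KneeFE"),
    vas_med         = c("KneeFE"),
    ham_med         = c("HipFE", "KneeFE"),
    ham_lat         = c("HipFE", "KneeFE"),
    tib_ant         = c("AnklePD", "AnkleIE"),
    per_long        = c("AnklePD", "AnkleIE"),
    soleus          = c("AnklePD"),
    gas_med         = c("KneeFE", "AnklePD"),
    gas_lat         = c("KneeFE", "AnklePD"),
    tfl             = c("HipAA"),
    sart            = c("HipFE", "KneeFE"))
}

# Per-DOF gait-angle scales (rad): offset and fundamental amplitude.
vs_angle_scales <- function() {
  rbind(HipFE = c(0.10, 0.30), HipAA = c(0.00, 0.08),
        KneeFE = c(0.60, 0.45), AnklePD = c(0.00, 0.20),
        AnkleIE = c(0.00, 0.08))
}

#' Default virtual-subject configuration
#'
#' Study-shaped defaults: 16 EMG channels driving 16 muscles over the 5
#' lower-limb DOFs, `p_true = 5` underlying synergies, two walking speeds
#' with gait-cycle periods of 1.25 s (slow) and 1.0 s (fast).
#'
#' @param n_muscles Number of muscles (recycled over the 16-muscle template;
#'   muscles beyond the channel count share channels).
#' @param n_channels Number of EMG channels (<= n_muscles).
#' @param p_true Number of ground-truth synergies.
#' @param t_f Named numeric vector of gait-cycle periods per speed (s).
#' @param degree Geometry-surrogate polynomial degree.
#' @return Configuration list.
#' @export
virtual_subject_config <- function(n_muscles = 16, n_channels = 16,
                                   p_true = 5,
                                   t_f = c(slow = 1.25, fast = 1.0),
                                   degree = 2) {
  list(n_muscles = n_muscles, n_channels = n_channels, p_true = p_true,
       t_f = t_f, degree = degree, dofs = VS_DOFS)
}

#' Generate a ground-truth virtual subject
#'
#' Samples, deterministically for a given seed: smooth per-DOF gait-angle
#' profiles (truncated Fourier series over the cycle), quadratic polynomial
#' musculotendon geometry satisfying the tendon-excursion identity
#' `r = -d l_MT / d q` by construction, Hill/activation parameters inside the
#' usual calibration bounds, and `p_true` Gaussian-bump synergy excitations
#' with non-negative channel weights whose mixtures form every channel's true
#' excitation.
#'
#' @param config A [virtual_subject_config()] list (entries can be
#'   overridden).
#' @param seed Integer seed; the subject is fully deterministic given it.
#' @return Object of class `"virtual_subject"` containing the ground-truth
#'   [musculotendon_model()], synergy bump parameters, weights `H_true`
#'   (p x channels), channel names, angle-profile coefficients and the
#'   configuration.
#' @export
make_virtual_subject <- function(config = virtual_subject_config(), seed = 1) {
  cfg <- utils::modifyList(virtual_subject_config(), config)
  if (cfg$p_true < 1 || cfg$p_true > cfg$n_channels)
    stopf("infeasible config: need 1 <= p_true <= n_channels")
  if (cfg$n_muscles < 2 || cfg$n_channels > cfg$n_muscles)
    stopf("infeasible config: need >= 2 muscles and n_channels <= n_muscles")
  with_seed(seed, {
    tmpl <- vs_muscle_table()
    base_names <- names(tmpl)
    muscle_names <- vapply(seq_len(cfg$n_muscles), function(i) {
      k <- (i - 1) %% length(tmpl) + 1
      if (i <= length(tmpl)) base_names[k] else paste0(base_names[k], "_", i)
    }, "")
    channels <- muscle_names[seq_len(cfg$n_channels)]
    # angle profiles: q_j(s) = m + a1 cos(2 pi s + ph1) + a2 cos(4 pi s + ph2)
    sc <- vs_angle_scales()[cfg$dofs, , drop = FALSE]
    gains <- stats::setNames(seq(0.85, 1.0, length.out = length(cfg$t_f)),
                             names(cfg$t_f))
    angles <- lapply(cfg$dofs, function(d) {
      list(mean = sc[d, 1],
           a = c(sc[d, 2] * stats::runif(1, 0.7, 1.0),
                 sc[d, 2] * stats::runif(1, 0.15, 0.30)),
           phase = stats::runif(2, 0, 2 * pi),
           speed_gain = gains)
    })
    names(angles) <- cfg$dofs
    # gait angle ranges (over all speeds, widened) bound the geometry domain
    qr_lim <- vapply(cfg$dofs, function(d) {
      a <- angles[[d]]
      half <- sum(abs(a$a)) * max(gains) * 1.3 + 0.05
      c(a$mean - half, a$mean + half)
    }, numeric(2))
    muscles <- list()
    for (i in seq_len(cfg$n_muscles)) {
      nm <- muscle_names[i]
      dofs_i <- tmpl[[(i - 1) %% length(tmpl) + 1]]
      nd <- length(dofs_i)
      r0 <- stats::runif(nd, 0.025, 0.055) *
        sample(c(-1, 1), nd, replace = TRUE)
      kap <- stats::runif(nd, -0.008, 0.008)
      l0 <- stats::runif(1, 0.25, 0.40)
      # exact quadratic l_MT = l0 - sum(r0 q + kap q^2 / 2); fit recovers it
      nsamp <- 60
      qs <- sapply(seq_len(nd), function(j)
        stats::runif(nsamp, qr_lim[1, dofs_i[j]], qr_lim[2, dofs_i[j]]))
      qs <- matrix(qs, nsamp, nd, dimnames = list(NULL, dofs_i))
      lmt <- l0 - qs %*% r0 - (qs^2 %*% kap) / 2
      geom <- fit_geometry_surrogate(qs, drop(lmt), degree = cfg$degree)
      l_oM <- stats::runif(1, 0.07, 0.12)
      alpha_o <- stats::runif(1, 0, 0.25)
      # place the operating range around optimal fiber length
      lmt_mid <- mean(range(lmt))
      l_sT <- max(lmt_mid - l_oM * cos(alpha_o), 1e-3)
      muscles[[nm]] <- list(
        act = activation_params(tau_act = stats::runif(1, 0.012, 0.035),
                                c3 = stats::runif(1, 0, 0.3),
                                d = stats::runif(1, 0.01, 0.05)),
        mt = muscle_params(F_o = stats::runif(1, 400, 1500), l_oM = l_oM,
                           l_sT = l_sT, alpha_o = alpha_o,
                           emg_scale = stats::runif(1, 0.35, 0.9),
                           channel = channels[(i - 1) %% cfg$n_channels + 1]),
        geom = geom)
    }
    model <- musculotendon_model(muscles, cfg$dofs)
    # synergy bumps in % gait cycle, periodic
    centers <- (seq_len(cfg$p_true) - 0.5) / cfg$p_true * 100 +
      stats::runif(cfg$p_true, -5, 5)
    widths <- stats::runif(cfg$p_true, 7, 13)
    H <- matrix(0, cfg$p_true, cfg$n_channels,
                dimnames = list(paste0("syn", seq_len(cfg$p_true)), channels))
    for (j in seq_len(cfg$n_channels)) {
      primary <- (j - 1) %% cfg$p_true + 1
      h <- stats::runif(cfg$p_true, 0, 0.2) *
        stats::rbinom(cfg$p_true, 1, 0.5)
      h[primary] <- stats::runif(1, 0.7, 1.0)
      # scale so the channel's peak excitation hits a target amplitude
      pct <- seq(0, 100, by = 0.5)
      Wd <- synergy_bumps(pct, centers, widths)
      amp <- stats::runif(1, 0.30, 0.80)
      H[, j] <- h * amp / max(Wd %*% h)
    }
    structure(
      list(model = model, channels = channels,
           synergies = list(centers = centers, widths = widths, H = H),
           angles = angles, config = cfg, seed = seed),
      class = "virtual_subject")
  })
}

# Periodic Gaussian bumps evaluated at % gait cycle positions.
synergy_bumps <- function(pct, centers, widths, center_shift = 0,
                          amp_mult = 1) {
  p <- length(centers)
  W <- matrix(0, length(pct), p)
  for (k in seq_len(p)) {
    ck <- centers[k] + if (length(center_shift) > 1) center_shift[k] else center_shift
    for (m in -1:1)
      W[, k] <- W[, k] + exp(-0.5 * ((pct - ck + 100 * m) / widths[k])^2)
    W[, k] <- W[, k] * (if (length(amp_mult) > 1) amp_mult[k] else amp_mult)
  }
  colnames(W) <- paste0("syn", seq_len(p))
  W
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf(
    "Virtual subject: %d muscles / %d channels, p_true = %d, DOFs: %s (seed %d)\n",
    length(x$model$muscles), length(x$channels), x$config$p_true,
    paste(x$config$dofs, collapse = ", "), x$seed))
  invisible(x)
}

# Joint angles and velocities on the 101-frame cycle grid for one speed.
vs_kinematics <- function(subject, speed) {
  s <- seq(0, 1, length.out = 101)
  t_f <- subject$config$t_f[[speed]]
  q <- qd <- matrix(0, 101, length(subject$config$dofs),
                    dimnames = list(NULL, subject$config$dofs))
  for (d in subject$config$dofs) {
    a <- subject$angles[[d]]
    g <- a$speed_gain[[speed]]
    q[, d] <- a$mean +
      g * a$a[1] * cos(2 * pi * s + a$phase[1]) +
      g * a$a[2] * cos(4 * pi * s + a$phase[2])
    qd[, d] <- -g * a$a[1] * 2 * pi / t_f * sin(2 * pi * s + a$phase[1]) -
      g * a$a[2] * 4 * pi / t_f * sin(4 * pi * s + a$phase[2])
  }
  list(q = q, qdot = qd, t_f = t_f)
}

#' Generate synthetic gait trials from a virtual subject
#'
#' Per trial: jitters the synergy bump timings and amplitudes (trial-to-trial
#' variability), forms true channel excitations `e = W H_true` clamped to
#' `[0, 1]` on the padded gait-cycle grid, runs the ground-truth forward
#' model for inverse-dynamics-style moments, and adds the configured noise
#' (multiplicative Gaussian on envelopes, additive Gaussian on moments scaled
#' by each DOF's moment SD).  Optionally also synthesizes raw EMG as a
#' 40-450 Hz band-limited carrier amplitude-modulated by the true envelope so
#' the full filtering chain can be exercised.
#'
#' @param subject A [make_virtual_subject()] result.
#' @param n_per_speed Trials per speed (default 5, giving 10 trials over the
#'   two speeds).
#' @param noise List with `exc` (multiplicative envelope noise SD, e.g. 0.10)
#'   and `mom` (additive moment noise SD as a fraction of each DOF's moment
#'   SD, e.g. 0.05).
#' @param seed Integer seed.
#' @param raw_emg If `TRUE`, attach a carrier-synthesized [raw_emg_trial()]
#'   to each trial.
#' @return List of `"synthetic_trial"` objects with fields `envelopes`
#'   (padded frames x channels, noisy), `q`, `qdot`, `M_exp`, `t_f`, `n_pad`,
#'   `speed`, and `truth` (noise-free excitations, activations, moments).
#' @export
generate_trials <- function(subject, n_per_speed = 5,
                            noise = list(exc = 0, mom = 0), seed = 1,
                            raw_emg = FALSE) {
  stopifnot(inherits(subject, "virtual_subject"))
  noise <- utils::modifyList(list(exc = 0, mom = 0), noise)
  syn <- subject$synergies
  trials <- list()
  with_seed(seed, {
    for (speed in names(subject$config$t_f)) {
      kin <- vs_kinematics(subject, speed)
      n_pad <- n_pad_frames(kin$t_f)
      pct <- seq(-n_pad, 100)
      for (tr in seq_len(n_per_speed)) {
        shift <- stats::runif(length(syn$centers), -2, 2)
        amp <- 1 + stats::runif(length(syn$centers), -0.15, 0.15)
        W <- synergy_bumps(pct, syn$centers, syn$widths,
                           center_shift = shift, amp_mult = amp)
        E_true <- clamp01(W %*% syn$H)
        colnames(E_true) <- subject$channels
        fwd <- net_joint_moments(subject$model, kin$q, kin$qdot, E_true,
                                 kin$t_f, details = TRUE)
        M_exp <- fwd$moments
        if (noise$mom > 0) {
          sds <- apply(fwd$moments, 2, stats::sd)
          M_exp <- M_exp + matrix(stats::rnorm(length(M_exp)), nrow(M_exp)) *
            rep(noise$mom * sds, each = nrow(M_exp))
        }
        env <- E_true
        if (noise$exc > 0)
          env <- clamp01(E_true * (1 + noise$exc *
                                     matrix(stats::rnorm(length(E_true)),
                                            nrow(E_true))))
        trial <- structure(
          list(envelopes = env, q = kin$q, qdot = kin$qdot, M_exp = M_exp,
               t_f = kin$t_f, n_pad = n_pad, speed = speed,
               truth = list(excitations = E_true,
                            activations = fwd$activations,
                            moments = fwd$moments,
                            W = W, shift = shift, amp = amp)),
          class = "synthetic_trial")
        if (raw_emg)
          trial$raw <- synth_raw_emg(subject, syn, shift, amp, kin$t_f)
        trials[[length(trials) + 1L]] <- trial
      }
    }
  })
  trials
}

# Carrier-mode raw EMG: band-passed white noise amplitude-modulated by the
# true envelope (plumbing to exercise the filtering chain, not physiology).
synth_raw_emg <- function(subject, syn, shift, amp, t_f, fs = 1000) {
  pre <- 0.35
  time <- seq(0, pre + t_f + 0.05, by = 1 / fs)
  pct <- (time - pre) / t_f * 100
  W <- synergy_bumps(pct %% 100, syn$centers, syn$widths,
                     center_shift = shift, amp_mult = amp)
  env <- clamp01(W %*% syn$H)
  bp <- signal::butter(2, c(40, 450) / (fs / 2), type = "pass")
  samples <- matrix(0, length(time), length(subject$channels))
  for (j in seq_len(ncol(samples))) {
    carrier <- signal::filtfilt(bp, stats::rnorm(length(time)))
    carrier <- carrier / stats::sd(carrier)
    samples[, j] <- carrier * env[, j]
  }
  colnames(samples) <- subject$channels
  raw_emg_trial(samples, subject$channels, fs,
                cycle_events = c(pre, pre + t_f), time = time)
}
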
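#' Methodological sweep over algorithms, normalizations and synergy numbers
#'
#' Runs synergy extrapolation for every combination of factorization
#' algorithm (PCA, NMF), EMG normalization scheme (MaxOver, MaxPer, VarOver,
#' VarPer, MagPer) and synergy count (default 3-10) on every trial: the
#' default grid is the 2 x 5 x 8 = 80-combination design.  For each
#' combination the measured channels are re-normalized across the trial set
#' under the scheme, decomposed per trial, and [synx()] solves for the
#' unmeasured weights.  When trials carry ground truth (synthetic trials),
#' the reconstruction is scored against it on the 101-frame cycle grid.
#'
#' @param model Calibrated [musculotendon_model()].
#' @param trials List of trials (e.g. from [generate_trials()]); each needs
#'   `envelopes`, `q`, `qdot`, `M_exp`, `t_f`, and optionally
#'   `truth$excitations`.
#' @param unmeasured Unmeasured channel name.
#' @param algorithms,schemes,p_range Grid factors.
#' @param seed Integer seed; every decomposition and solve draws a derived
#'   child seed, so the whole sweep is reproducible.
#' @param n_starts Random starts per solve (default 2 to keep sweeps fast).
#' @param replicates NMF replicates (default 10).
#' @return Long-format `data.frame`, one row per combination x trial, with
#'   columns `trial`, `speed`, `algorithm`, `scheme`, `p`, `vaf`, `J`,
#'   `mae` (mean over DOFs), per-DOF `mae_*`, `r`/`rmse` versus truth (NA
#'   without truth), constraint diagnostics (`min_Hx`, `max_violation`,
#'   `feasible`), and `failed`/`message` for combinations that errored
#'   (the sweep continues past failures).  The attribute `"n_combinations"`
#'   records the grid size.
#' @export
run_sweep <- function(model, trials, unmeasured,
                      algorithms = c("pca", "nmf"),
                      schemes = NORMALIZATION_SCHEMES,
                      p_range = 3:10, seed = 1, n_starts = 2,
                      replicates = 10) {
  stopifnot(length(trials) >= 1)
  measured <- setdiff(colnames(trials[[1]]$envelopes), unmeasured)
  if (length(measured) == ncol(trials[[1]]$envelopes))
    stopf("unmeasured channel '%s' not found in the trials", unmeasured)
  norm_sets <- lapply(schemes, function(sc)
    normalize_emg(lapply(trials, function(tr)
      tr$envelopes[, measured, drop = FALSE]), sc)$trials)
  names(norm_sets) <- schemes
  rows <- list()
  combo <- 0L
  for (alg in algorithms) for (sc in schemes) for (p in p_range) {
    combo <- combo + 1L
    for (i in seq_along(trials)) {
      tr <- trials[[i]]
      row <- data.frame(trial = i,
                        speed = if (is.null(tr$speed)) NA_character_ else tr$speed,
                        algorithm = alg, scheme = sc, p = p,
                        vaf = NA_real_, J = NA_real_, mae = NA_real_,
                        r = NA_real_, rmse = NA_real_,
                        min_Hx = NA_real_, max_violation = NA_real_,
                        feasible = NA, failed = FALSE, message = "")
      res <- tryCatch({
        syn <- synergy_decompose(norm_sets[[sc]][[i]], p, alg,
                                 replicates = replicates,
                                 seed = derive_seed(seed, combo * 1000L + i))
        fit <- synx(model, tr, syn, unmeasured, n_starts = n_starts,
                    seed = derive_seed(seed, combo * 1000L + 500L + i))
        row$vaf <- syn$vaf
        row$J <- fit$J
        row$mae <- mean(fit$mae)
        for (d in names(fit$mae)) row[[paste0("mae_", d)]] <- fit$mae[[d]]
        if (!is.null(tr$truth)) {
          truth <- tr$truth$excitations[(tr$n_pad + 1):(tr$n_pad + 101),
                                        unmeasured]
          row$r <- pearson_r(fit$e_x_cycle, truth)
          row$rmse <- rmse(fit$e_x_cycle, truth)
        }
        row$min_Hx <- min(fit$H_x)
        row$max_violation <- fit$diagnostics$violation
        row$feasible <- fit$diagnostics$feasible
        row
      }, error = function(e) {
        row$failed <- TRUE
        row$message <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # harmonize columns across failed / successful rows
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
  attr(out, "n_combinations") <- length(algorithms) * length(schemes) *
    length(p_range)
  out
}
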
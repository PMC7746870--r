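# Readers/writers: OpenSim Storage (.sto/.mot), EMG CSV, model configs,
# result manifests.  All writes go through a temp-then-rename so failures
# never leave partial output behind.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move temp file onto '%s'", path)
  invisible(path)
}

#' Read and write OpenSim Storage files
#'
#' Minimal `.sto`/`.mot` support: a key-value header terminated by
#' `endheader`, then a tab-delimited table whose first column is `time`.
#' Round-trips are lossless within float formatting and preserve column
#' order.
#'
#' @param path File path.
#' @return `read_sto`: a `data.frame` whose first column is `time`.
#' @export
read_sto <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0)
    stopf("malformed .sto '%s': no 'endheader' line found (searched %d lines)",
          path, length(lines))
  end <- end[1]
  if (end + 1 > length(lines)) stopf("malformed .sto '%s': no column labels after line %d",
                                     path, end)
  labels <- strsplit(trimws(lines[end + 1]), "\t")[[1]]
  if (length(labels) < 1 || tolower(labels[1]) != "time")
    stopf("malformed .sto '%s': first column label must be 'time' (line %d)",
          path, end + 1)
  body <- lines[(end + 2):length(lines)]
  body <- body[nzchar(trimws(body))]
  dat <- if (length(body)) {
    do.call(rbind, lapply(seq_along(body), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[\t ]+")[[1]]))
      if (length(v) != length(labels) || any(is.na(v)))
        stopf("malformed .sto '%s': bad data row at line %d", path, end + 1 + i)
      v
    }))
  } else matrix(numeric(), 0, length(labels))
  df <- as.data.frame(dat)
  names(df) <- labels
  df
}

#' @rdname read_sto
#' @param table `data.frame` with a leading `time` column.
#' @param name Header name entry.
#' @export
write_sto <- function(table, path, name = "synx") {
  stopifnot(is.data.frame(table), tolower(names(table)[1]) == "time")
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(name, "version=1",
                 sprintf("nRows=%d", nrow(table)),
                 sprintf("nColumns=%d", ncol(table)),
                 "inDegrees=no", "endheader",
                 paste(names(table), collapse = "\t")), con)
    if (nrow(table))
      utils::write.table(format(table, digits = 15, trim = TRUE,
                                scientific = FALSE),
                         con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  })
}

#' Read an EMG CSV into a raw trial
#'
#' Expects a header row (first column `time` in seconds, remaining columns
#' channel names).  The sampling rate is inferred from the time column,
#' which must be uniform to 1e-6 relative.
#'
#' @param path CSV path.
#' @param cycle_events Heel-strike times (s) bounding the gait cycle.
#' @return A [raw_emg_trial()].
#' @export
read_emg_csv <- function(path, cycle_events) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stopf("EMG CSV needs a time column plus >= 1 channel")
  tm <- df[[1]]
  dts <- diff(tm)
  if (any(abs(dts - dts[1]) > 1e-6 * abs(dts[1])))
    stopf("non-uniform sampling in '%s' (relative jitter > 1e-6)", path)
  raw_emg_trial(as.matrix(df[, -1, drop = FALSE]), names(df)[-1],
                sampling_rate = 1 / dts[1], cycle_events = cycle_events,
                time = tm)
}

#' @rdname read_emg_csv
#' @param trial A [raw_emg_trial()] to serialize.
#' @export
write_emg_csv <- function(trial, path) {
  stopifnot(inherits(trial, "raw_emg_trial"))
  df <- data.frame(time = trial$time, trial$samples, check.names = FALSE)
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
}

#' Serialize a processed EMG trial
#'
#' Writes the padded frame matrix as CSV plus a JSON sidecar recording the
#' normalization scheme, constants, `t_f` and `n_pad`.
#'
#' @param pt A `processed_emg_trial`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @param constants Optional normalization constants for the sidecar.
#' @return `read_processed_trial`: the restored trial.
#' @export
write_processed_trial <- function(pt, path, constants = NULL) {
  stopifnot(inherits(pt, "processed_emg_trial"))
  frame_pct <- c(seq(-pt$n_pad, -1), pt$percent_grid)
  df <- data.frame(percent = frame_pct, pt$frames, check.names = FALSE)
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  meta <- list(normalization = pt$normalization, t_f = pt$t_f,
               n_pad = pt$n_pad, channels = pt$channel_names,
               constants = constants)
  atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_processed_trial
#' @export
read_processed_trial <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  frames <- as.matrix(df[, -1, drop = FALSE])
  structure(
    list(channel_names = colnames(frames), frames = frames,
         n_pad = meta$n_pad, normalization = meta$normalization,
         t_f = meta$t_f, percent_grid = seq(0, 100, length.out = 101)),
    class = "processed_emg_trial")
}

#' Serialize a musculotendon model
#'
#' Structured JSON config: per-muscle activation and musculotendon
#' parameters plus the geometry-surrogate coefficient tables.
#'
#' @param model A [musculotendon_model()].
#' @param path Destination path.
#' @return `read_model_config`: the restored model.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "musculotendon_model"))
  ser <- list(
    dof_names = model$dof_names,
    curves = unclass(model$curves),
    muscles = lapply(model$muscles, function(m) list(
      act = list(tau_act = m$act$tau_act, c3 = m$act$c3, d = m$act$d,
                 g = m$act$g),
      mt = unclass(m$mt),
      geom = list(coef = m$geom$coef,
                  exponents = unname(m$geom$exponents),
                  dof_names = m$geom$dof_names, degree = m$geom$degree,
                  domain = unname(m$geom$domain)))))
  atomic_write(path, function(tmp)
    jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA))
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  muscles <- lapply(ser$muscles, function(m) {
    ex <- matrix(as.numeric(m$geom$exponents), ncol = length(m$geom$dof_names),
                 dimnames = list(NULL, m$geom$dof_names))
    dom <- matrix(as.numeric(m$geom$domain), nrow = 2,
                  dimnames = list(NULL, m$geom$dof_names))
    geom <- structure(
      list(coef = as.numeric(m$geom$coef), exponents = ex,
           dof_names = m$geom$dof_names, degree = m$geom$degree,
           domain = dom, residuals = NULL, rmse = NA_real_),
      class = "geometry_surrogate")
    list(act = activation_params(m$act$tau_act, m$act$c3, m$act$d,
                                 as.numeric(m$act$g)),
         mt = muscle_params(m$mt$F_o, m$mt$l_oM, m$mt$l_sT, m$mt$alpha_o,
                            m$mt$emg_scale, m$mt$channel),
         geom = geom)
  })
  musculotendon_model(muscles, ser$dof_names, do.call(muscle_curves,
                                                     as.list(ser$curves)))
}

#' Write a results directory with manifest
#'
#' Writes a results table as CSV together with a JSON manifest recording the
#' configuration (with a fingerprint hash) and the seeds in use, so runs are
#' attributable and reproducible.
#'
#' @param results `data.frame` of results.
#' @param dir Output directory (created if needed).
#' @param config List describing the run configuration.
#' @param seeds Named list/vector of seeds used.
#' @return The directory, invisibly.
#' @export
write_results <- function(results, dir, config = list(), seeds = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atomic_write(file.path(dir, "results.csv"), function(tmp)
    utils::write.csv(results, tmp, row.names = FALSE))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = config, config_hash = config_hash(cfg_json),
                   seeds = seeds, n_rows = nrow(results),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  atomic_write(file.path(dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}
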
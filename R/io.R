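#' Write a session to disk
#'
#' Serialises a session as a JSON manifest plus two CSV files per trial: a
#' 40 Hz hand file (`t_ms, target_x_px, hand_x_px, cursor_x_px`; the target
#' column is the 1000 Hz target downsampled to the hand grid for convenience)
#' and a 1000 Hz gaze file (`t_ms, gaze_x_px, gaze_y_px, pupil_area_px,
#' valid`). The manifest records participant, group, screen geometry,
#' protocol constants, seed, and the per-trial file names. The full-rate
#' target is reconstructed from the stored sine components on read.
#'
#' @param session a `session` from [simulate_session()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- attr(session, "config")
  trials <- lapply(session, function(tr) {
    hand_file <- sprintf("trial%02d_hand.csv", tr$trial_order)
    gaze_file <- sprintf("trial%02d_gaze.csv", tr$trial_order)
    idx <- match(tr$hand_t_ms, tr$target_t_ms)
    utils::write.csv(
      data.frame(t_ms = tr$hand_t_ms, target_x_px = tr$target_x_px[idx],
                 hand_x_px = tr$hand_x_px, cursor_x_px = tr$cursor_x_px),
      file.path(dir, hand_file), row.names = FALSE)
    utils::write.csv(
      data.frame(t_ms = tr$gaze_t_ms, gaze_x_px = tr$gaze_x_px,
                 gaze_y_px = tr$gaze_y_px,
                 pupil_area_px = tr$pupil_area_px,
                 valid = as.integer(tr$valid)),
      file.path(dir, gaze_file), row.names = FALSE)
    list(trial_order = tr$trial_order, phase = tr$phase,
         delay_ms = tr$delay_ms, hand_file = hand_file,
         gaze_file = gaze_file,
         components = as.list(tr$components))
  })
  manifest <- list(
    participant_id = attr(session, "participant_id"),
    group = attr(session, "group"),
    seed = attr(session, "seed"),
    screen = unclass(config$screen),
    protocol = list(n_baseline = config$n_baseline, n_adapt = config$n_adapt,
                    n_post = config$n_post,
                    tracking_duration_ms = config$tracking_duration_ms,
                    trim_ms = config$trim_ms,
                    delay_ms_by_phase = as.list(config$delay_ms_by_phase),
                    hand_rate_hz = config$hand_rate_hz,
                    gaze_rate_hz = config$gaze_rate_hz,
                    max_shift_px = config$max_shift_px),
    trials = trials)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_uniform_grid <- function(t_ms, file, expected_dt = NULL) {
  if (length(t_ms) > 1) {
    dt <- diff(t_ms)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop("non-uniform time grid in ", file)
    if (!is.null(expected_dt) && abs(dt[1] - expected_dt) > 1e-6)
      stop("unexpected sampling interval in ", file, ": ", dt[1],
           " ms (expected ", expected_dt, " ms)")
  }
  invisible(TRUE)
}

read_trace_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  df
}

#' Read a session from disk
#'
#' Loads a manifest written by [write_session()] (or externally converted
#' data following the same schema), validating grids and labels. The 1000 Hz
#' target is reconstructed from each trial's stored sine components.
#'
#' @param dir session directory containing `manifest.json`.
#' @return a `session` list of `trial_trace` objects.
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  m <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  screen <- do.call(screen_geometry, lapply(m$screen, unlist))
  p <- m$protocol
  config <- protocol_config(
    n_baseline = p$n_baseline, n_adapt = p$n_adapt, n_post = p$n_post,
    tracking_duration_ms = p$tracking_duration_ms, trim_ms = p$trim_ms,
    delay_ms_by_phase = unlist(p$delay_ms_by_phase),
    hand_rate_hz = p$hand_rate_hz, gaze_rate_hz = p$gaze_rate_hz,
    max_shift_px = p$max_shift_px, screen = screen)
  trials_meta <- m$trials
  n_trials <- length(trials_meta)
  get_meta <- function(i, field) trials_meta[[i]][[field]]
  session <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    hand <- read_trace_csv(file.path(dir, get_meta(i, "hand_file")),
                           c("t_ms", "hand_x_px", "cursor_x_px"))
    gaze <- read_trace_csv(file.path(dir, get_meta(i, "gaze_file")),
                           c("t_ms", "gaze_x_px", "gaze_y_px",
                             "pupil_area_px", "valid"))
    check_uniform_grid(hand$t_ms, get_meta(i, "hand_file"),
                       1000 / config$hand_rate_hz)
    check_uniform_grid(gaze$t_ms, get_meta(i, "gaze_file"),
                       1000 / config$gaze_rate_hz)
    comps_l <- get_meta(i, "components")
    comps <- sine_components(freq_hz = unlist(comps_l$freq_hz),
                             amp_px = unlist(comps_l$amp_px))
    comps$phase_rad <- unlist(comps_l$phase_rad)
    target_x <- eval_sines(comps, gaze$t_ms / 1000)
    valid <- as.logical(gaze$valid)
    gx <- gaze$gaze_x_px; gy <- gaze$gaze_y_px; pp <- gaze$pupil_area_px
    gx[!valid] <- NA_real_; gy[!valid] <- NA_real_; pp[!valid] <- NA_real_
    session[[i]] <- structure(list(
      participant_id = m$participant_id, group = m$group,
      trial_order = as.integer(get_meta(i, "trial_order")),
      phase = get_meta(i, "phase"),
      delay_ms = get_meta(i, "delay_ms"),
      target_t_ms = gaze$t_ms, target_x_px = target_x, components = comps,
      hand_t_ms = hand$t_ms, hand_x_px = hand$hand_x_px,
      cursor_x_px = hand$cursor_x_px,
      gaze_t_ms = gaze$t_ms, gaze_x_px = gx, gaze_y_px = gy,
      pupil_area_px = pp, valid = valid,
      ground_truth = NULL), class = "trial_trace")
  }
  structure(session, class = "session", participant_id = m$participant_id,
            group = m$group, config = config, seed = m$seed)
}

#' Run the full analysis pipeline on one or more sessions
#'
#' Composes the stages in order — preprocess, event detection, per-trial
#' metrics, phase binning — over a list of sessions, and optionally fits the
#' group-level mixed-model comparison when the pooled table spans at least
#' two participants with the required variables.
#'
#' @param sessions a single `session` or a list of them.
#' @param config a [protocol_config()] (defaults to the one attached to the
#'   first session).
#' @param max_lag_ms cross-correlation search half-window (ms).
#' @param fit_models fit the mixed-model comparison on the pooled adaptation
#'   trials (requires >= 2 participants).
#' @return list with `metrics` (binned per-trial table), `summaries` (phase
#'   summaries of the main metrics), and `models` (comparison table and LRTs,
#'   or `NULL`).
#' @export
run_pipeline <- function(sessions, config = NULL, max_lag_ms = 1000,
                         fit_models = FALSE) {
  if (inherits(sessions, "session")) sessions <- list(sessions)
  if (is.null(config)) config <- attr(sessions[[1]], "config")
  metrics <- do.call(rbind, lapply(sessions, session_metrics,
                                   config = config,
                                   max_lag_ms = max_lag_ms))
  metrics <- assign_phase_bins(metrics)
  summaries <- lapply(
    c(rmse = "rmse_deg", tc_lag = "tc_lag_ms", gt_lag = "gt_lag_ms",
      random_error = "random_error_deg", saccade_rate = "saccade_rate_hz"),
    function(v) phase_summary(metrics, v))
  models <- NULL
  if (fit_models) {
    adapt <- metrics[metrics$phase == "adaptation", ]
    if (length(unique(adapt$participant_id)) >= 2) {
      if (!"age" %in% names(adapt))
        adapt$age <- ifelse(adapt$group == "older", 66, 23)
      models <- model_comparison_table(adapt)
    }
  }
  list(metrics = metrics, summaries = summaries, models = models)
}
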
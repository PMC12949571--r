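#' Default epoch boundaries of the ODR task
#'
#' Times are seconds relative to cue onset: fixation `[-1, 0)`, cue `[0, 0.5)`
#' (the cue is flashed for 0.5 s), delay `[0.5, 3.5)` (3 s memory delay),
#' response `[3.5, 4.1)` (saccade within 0.6 s of fixation offset).
#'
#' @return Named list of two-element numeric vectors.
#' @export
default_epochs <- function() {
  list(fixation = c(-1.0, 0.0),
       cue      = c(0.0, 0.5),
       delay    = c(0.5, 3.5),
       response = c(3.5, 4.1))
}

validate_epochs <- function(epochs) {
  need <- c("fixation", "cue", "delay", "response")
  if (!all(need %in% names(epochs)))
    stop("epochs must name fixation, cue, delay and response intervals")
  m <- do.call(rbind, epochs[need])
  if (any(m[, 2] <= m[, 1])) stop("epoch intervals must have end > start")
  if (any(diff(as.vector(t(m))) < -1e-12))
    stop("epoch intervals must be ordered and non-overlapping")
  lapply(epochs[need], as.numeric)
}

#' Assemble and validate a recording session
#'
#' A session bundles unit metadata, trial metadata and spike events, all in
#' plain data frames, together with the task epoch boundaries (seconds
#' relative to cue onset).
#'
#' @param units data.frame with columns `unit_id`, `area` ("PFC"/"PPC"),
#'   `depth_mm` (>= 0), `kind` ("single"/"multi").
#' @param trials data.frame with columns `trial_id`, `cue_location_deg`
#'   (multiple of 45 in `[0, 360)`), `correct` (0/1 or logical),
#'   `reaction_time_ms` (positive; `NA` allowed).
#' @param spikes data.frame with columns `unit_id`, `trial_id`, `time_s`
#'   (seconds relative to cue onset, within the recorded trial span).
#' @param session_id character scalar.
#' @param epochs named list of epoch intervals; see [default_epochs()].
#' @param provenance free-form note (e.g. "synthetic, seed 7").
#' @return An object of class `wm_session`.
#' @export
wm_session <- function(units, trials, spikes,
                       session_id = "session",
                       epochs = default_epochs(),
                       provenance = "unspecified") {
  epochs <- validate_epochs(epochs)
  units <- as.data.frame(units)
  trials <- as.data.frame(trials)
  spikes <- as.data.frame(spikes)

  need_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
  }
  need_cols(units, c("unit_id", "area", "depth_mm", "kind"), "units")
  need_cols(trials, c("trial_id", "cue_location_deg", "correct"), "trials")
  need_cols(spikes, c("unit_id", "trial_id", "time_s"), "spikes")
  if (!"reaction_time_ms" %in% names(trials)) trials$reaction_time_ms <- NA_real_

  units$unit_id <- as.character(units$unit_id)
  trials$trial_id <- as.character(trials$trial_id)
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$trial_id <- as.character(spikes$trial_id)
  trials$correct <- as.logical(trials$correct)
  trials$cue_location_deg <- as.numeric(trials$cue_location_deg)
  trials$reaction_time_ms <- as.numeric(trials$reaction_time_ms)
  spikes$time_s <- as.numeric(spikes$time_s)
  units$depth_mm <- as.numeric(units$depth_mm)

  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id in units table")
  if (anyDuplicated(trials$trial_id)) stop("duplicate trial_id in trials table")
  if (any(units$depth_mm < 0)) stop("unit depth_mm must be >= 0")
  if (!all(units$kind %in% c("single", "multi")))
    stop("unit kind must be 'single' or 'multi'")
  bad_cue <- which(trials$cue_location_deg %% 45 != 0 |
                   trials$cue_location_deg < 0 | trials$cue_location_deg >= 360)
  if (length(bad_cue))
    stop(sprintf("trial row %d: cue_location_deg %.1f is not a multiple of 45 in [0,360)",
                 bad_cue[1], trials$cue_location_deg[bad_cue[1]]))
  bad_rt <- which(!is.na(trials$reaction_time_ms) & trials$reaction_time_ms <= 0)
  if (length(bad_rt))
    stop(sprintf("trial row %d: reaction_time_ms must be positive", bad_rt[1]))

  span <- session_span(epochs)
  if (nrow(spikes)) {
    bad_u <- which(!(spikes$unit_id %in% units$unit_id))
    if (length(bad_u))
      stop(sprintf("spike row %d references unknown unit_id '%s'",
                   bad_u[1], spikes$unit_id[bad_u[1]]))
    bad_t <- which(!(spikes$trial_id %in% trials$trial_id))
    if (length(bad_t))
      stop(sprintf("spike row %d references unknown trial_id '%s'",
                   bad_t[1], spikes$trial_id[bad_t[1]]))
    bad_s <- which(spikes$time_s < span[1] - 1e-9 | spikes$time_s > span[2] + 1e-9)
    if (length(bad_s))
      stop(sprintf("spike row %d: time_s %.5f outside recorded span [%.2f, %.2f]",
                   bad_s[1], spikes$time_s[bad_s[1]], span[1], span[2]))
    ## per (unit, trial) ascending spike times
    o <- order(spikes$unit_id, spikes$trial_id, spikes$time_s)
    spikes <- spikes[o, , drop = FALSE]
    rownames(spikes) <- NULL
  }

  structure(list(session_id = as.character(session_id),
                 units = units, trials = trials, spikes = spikes,
                 epochs = epochs, provenance = provenance),
            class = "wm_session")
}

## Recorded span implied by the epoch table
session_span <- function(epochs) {
  c(min(vapply(epochs, `[`, numeric(1), 1)),
    max(vapply(epochs, `[`, numeric(1), 2)))
}

#' @export
print.wm_session <- function(x, ...) {
  cat(sprintf("<wm_session '%s'> %d units, %d trials, %d spikes\n",
              x$session_id, nrow(x$units), nrow(x$trials), nrow(x$spikes)))
  cat(sprintf("  epochs: fixation [%g,%g) cue [%g,%g) delay [%g,%g) response [%g,%g)\n",
              x$epochs$fixation[1], x$epochs$fixation[2],
              x$epochs$cue[1], x$epochs$cue[2],
              x$epochs$delay[1], x$epochs$delay[2],
              x$epochs$response[1], x$epochs$response[2]))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' Load a session from tabular files
#'
#' Reads the three CSV tables (spikes, trials, units) and validates referential
#' integrity. A YAML/JSON manifest naming the files (keys `spikes`, `trials`,
#' `units`, optional `session_id` and `epochs`) can be used instead via
#' [load_session_manifest()].
#'
#' @param spikes_path CSV with columns `unit_id`, `trial_id`, `time_s`.
#' @param trials_path CSV with columns `trial_id`, `cue_location_deg`,
#'   `correct`, `reaction_time_ms` (empty allowed).
#' @param units_path CSV with columns `unit_id`, `area`, `depth_mm`, `kind`.
#' @param session_id,epochs,provenance passed to [wm_session()].
#' @return A validated `wm_session`.
#' @export
load_session <- function(spikes_path, trials_path, units_path,
                         session_id = "session", epochs = default_epochs(),
                         provenance = NULL) {
  spikes <- read.csv(spikes_path, stringsAsFactors = FALSE)
  trials <- read.csv(trials_path, stringsAsFactors = FALSE)
  units <- read.csv(units_path, stringsAsFactors = FALSE)
  wm_session(units, trials, spikes, session_id = session_id, epochs = epochs,
             provenance = provenance %||% sprintf("loaded from %s", spikes_path))
}

#' @rdname load_session
#' @param manifest_path YAML or JSON manifest file.
#' @export
load_session_manifest <- function(manifest_path) {
  man <- if (grepl("\\.json$", manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  pth <- function(p) if (file.exists(p)) p else file.path(dir, p)
  epochs <- if (!is.null(man$epochs)) lapply(man$epochs, as.numeric) else default_epochs()
  load_session(pth(man$spikes), pth(man$trials), pth(man$units),
               session_id = man$session_id %||% "session", epochs = epochs)
}

#' Write a session to tabular files
#'
#' Spike times are written as decimal text with 5 fractional digits, so a
#' write/load round trip is lossless at 1e-5 s precision.
#'
#' @param session a `wm_session`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "wm_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- session$spikes
  sp$time_s <- sprintf("%.5f", sp$time_s)
  paths <- c(spikes = file.path(dir, "spikes.csv"),
             trials = file.path(dir, "trials.csv"),
             units = file.path(dir, "units.csv"),
             manifest = file.path(dir, "manifest.yaml"))
  write.csv(sp, paths["spikes"], row.names = FALSE)
  tr <- session$trials
  tr$correct <- as.integer(tr$correct)
  write.csv(tr, paths["trials"], row.names = FALSE)
  write.csv(session$units, paths["units"], row.names = FALSE)
  yaml::write_yaml(list(session_id = session$session_id,
                        spikes = "spikes.csv", trials = "trials.csv",
                        units = "units.csv",
                        epochs = lapply(session$epochs, as.numeric)),
                   paths["manifest"])
  invisible(paths)
}

## Spikes of one epoch (half-open interval), optionally for a unit/trial subset
epoch_spikes <- function(session, epoch = "delay", unit_ids = NULL, trial_ids = NULL) {
  iv <- session$epochs[[epoch]]
  if (is.null(iv)) stop(sprintf("unknown epoch '%s'", epoch))
  sp <- session$spikes
  keep <- in_interval(sp$time_s, iv[1], iv[2])
  if (!is.null(unit_ids)) keep <- keep & sp$unit_id %in% unit_ids
  if (!is.null(trial_ids)) keep <- keep & sp$trial_id %in% trial_ids
  sp[keep, , drop = FALSE]
}

## Per (unit, trial) spike counts in an epoch: trials x units matrix
epoch_count_matrix <- function(session, epoch = "delay") {
  iv <- session$epochs[[epoch]]
  sp <- epoch_spikes(session, epoch)
  tid <- factor(sp$trial_id, levels = session$trials$trial_id)
  uid <- factor(sp$unit_id, levels = session$units$unit_id)
  tab <- table(tid, uid)
  m <- matrix(as.integer(tab), nrow = nrow(session$trials),
              dimnames = list(session$trials$trial_id, session$units$unit_id))
  m
}
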
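# Trial-structured session container.
#
# A session is stored as a versioned directory of plain-text files mirroring
# a hierarchical layout:
#
#   <path>/
#     meta.json            schema version, session id, task, sampling rate
#     neurons.csv          one row per neuron (unique ids)
#     trials.csv           one row per trial: direction, target, event times,
#                          trace start/length, inclusion state
#     eye/trial_<k>.csv    columns x, y (degrees); time is t0 + 0:(n-1) * dt
#     spikes/trial_<k>.csv columns neuron_id, time (ms from trial start)
#
# Times are ms from trial start. Missing spike rows for a neuron mean an
# empty train, never a dropped neuron.

SESSION_SCHEMA_VERSION <- "1.0"

.known_tasks <- c("SCS_horizontal", "SCS_oblique", "MGS", "CCS")
.mandatory_events <- c("fixation_onset", "target_onset", "cue_on",
                       "cue_off", "fp_offset")

#' Construct a trial
#'
#' @param trial_id integer id, unique within the session.
#' @param direction "left" or "right".
#' @param target numeric `c(x, y)` target position, degrees.
#' @param events named numeric vector of event times (ms from trial start);
#'   must contain fixation_onset, target_onset, cue_on, cue_off, fp_offset in
#'   strictly increasing order.
#' @param eye an `eye_trace` (list with `t0`, `dt`, `x`, `y`).
#' @param spikes named list, one sorted numeric vector of spike times per
#'   neuron id (possibly empty).
#' @param included inclusion state: "untested", "pass" or "fail(<reason>)".
#' @return object of class `scs_trial`.
#' @export
new_trial <- function(trial_id, direction, target, events, eye, spikes,
                      included = "untested") {
  structure(list(trial_id = as.integer(trial_id), direction = direction,
                 target = as.numeric(target), events = events, eye = eye,
                 spikes = spikes, included = included),
            class = "scs_trial")
}

#' Construct a session
#'
#' @param session_id character id.
#' @param task one of "SCS_horizontal", "SCS_oblique", "MGS", "CCS".
#' @param sampling_rate eye-trace sampling rate, Hz.
#' @param trials list of [new_trial()] objects.
#' @param neurons data frame with (at least) a `neuron_id` column.
#' @param validate run [validate_session()] on the result.
#' @return object of class `scs_session`.
#' @export
new_session <- function(session_id, task = "SCS_horizontal",
                        sampling_rate = 1000, trials = list(),
                        neurons = data.frame(neuron_id = character(0)),
                        validate = TRUE) {
  s <- structure(list(session_id = session_id, task = task,
                      sampling_rate = sampling_rate, trials = trials,
                      neurons = neurons),
                 class = "scs_session")
  if (validate) validate_session(s)
  s
}

#' Validate a session's structural invariants
#'
#' Checks task label, unique neuron ids, per-trial event ordering, finite
#' eye traces spanning all events, and sorted in-bounds spike trains.
#' Violations raise an error naming the offending trial or neuron.
#'
#' @param session an `scs_session`.
#' @return the session, invisibly.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "scs_session"))
  if (!session$task %in% .known_tasks) {
    stop("unknown task label: ", session$task)
  }
  if (anyDuplicated(session$neurons$neuron_id)) {
    stop("duplicate neuron ids: ",
         paste(unique(session$neurons$neuron_id[
           duplicated(session$neurons$neuron_id)]), collapse = ", "))
  }
  for (tr in session$trials) {
    where <- paste0("trial ", tr$trial_id)
    missing_ev <- setdiff(.mandatory_events, names(tr$events))
    if (length(missing_ev) > 0) {
      stop(where, ": missing mandatory events: ",
           paste(missing_ev, collapse = ", "))
    }
    ev <- tr$events[.mandatory_events]
    if (any(diff(ev) <= 0)) {
      stop(where, ": event times are not strictly increasing")
    }
    n <- length(tr$eye$x)
    if (n == 0 || length(tr$eye$y) != n) {
      stop(where, ": eye trace empty or x/y length mismatch")
    }
    if (!all(is.finite(tr$eye$x)) || !all(is.finite(tr$eye$y))) {
      stop(where, ": non-finite eye-trace values")
    }
    t_max <- tr$eye$t0 + n * tr$eye$dt
    if (max(ev) >= t_max) {
      stop(where, ": eye trace does not span all events")
    }
    for (nid in names(tr$spikes)) {
      st <- tr$spikes[[nid]]
      if (is.unsorted(st)) {
        stop(where, ", neuron ", nid, ": spike times not sorted")
      }
      if (length(st) > 0 && (min(st) < tr$eye$t0 || max(st) >= t_max)) {
        stop(where, ", neuron ", nid, ": spike times outside trial bounds")
      }
    }
  }
  invisible(session)
}

# full-precision numeric formatting so a written session round-trips
.fmt_num <- function(x) formatC(x, digits = 15, format = "g")

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Write a session container
#'
#' @param session an `scs_session`.
#' @param path directory to create.
#' @param overwrite refuse to overwrite an existing container unless TRUE.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE) {
  validate_session(session)
  if (dir.exists(path) || file.exists(path)) {
    if (!overwrite) stop("refusing to overwrite existing path: ", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  dir.create(file.path(path, "eye"))
  dir.create(file.path(path, "spikes"))
  meta <- list(schema_version = SESSION_SCHEMA_VERSION,
               session_id = session$session_id, task = session$task,
               sampling_rate = session$sampling_rate)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .write_csv(session$neurons, file.path(path, "neurons.csv"))
  trows <- lapply(session$trials, function(tr) {
    ev <- as.list(tr$events[.mandatory_events])
    cbind(data.frame(trial_id = tr$trial_id, direction = tr$direction,
                     target_x = tr$target[1], target_y = tr$target[2],
                     t0 = tr$eye$t0, dt = tr$eye$dt,
                     n_samples = length(tr$eye$x),
                     included = tr$included, stringsAsFactors = FALSE),
          as.data.frame(ev))
  })
  .write_csv(do.call(rbind, trows), file.path(path, "trials.csv"))
  for (tr in session$trials) {
    eye_df <- data.frame(x = .fmt_num(tr$eye$x), y = .fmt_num(tr$eye$y))
    .write_csv(eye_df, file.path(path, "eye",
                                 sprintf("trial_%05d.csv", tr$trial_id)))
    nid <- rep(names(tr$spikes), vapply(tr$spikes, length, 1L))
    times <- unlist(tr$spikes, use.names = FALSE)
    spk_df <- data.frame(neuron_id = if (length(nid)) nid else character(0),
                         time = .fmt_num(if (length(nid)) times else numeric(0)),
                         stringsAsFactors = FALSE)
    .write_csv(spk_df, file.path(path, "spikes",
                                 sprintf("trial_%05d.csv", tr$trial_id)))
  }
  invisible(path)
}

#' Read a session container
#'
#' @param path directory written by [write_session()].
#' @return a validated `scs_session`.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("not a session container: ", path)
  meta <- jsonlite::read_json(meta_file)
  if (!identical(meta$schema_version, SESSION_SCHEMA_VERSION)) {
    stop("unsupported session schema version: ", meta$schema_version)
  }
  neurons <- utils::read.csv(file.path(path, "neurons.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  tdf <- utils::read.csv(file.path(path, "trials.csv"),
                         stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(tdf)), function(i) {
    row <- tdf[i, ]
    eye_df <- utils::read.csv(
      file.path(path, "eye", sprintf("trial_%05d.csv", row$trial_id)))
    spk_df <- utils::read.csv(
      file.path(path, "spikes", sprintf("trial_%05d.csv", row$trial_id)),
      stringsAsFactors = FALSE)
    spikes <- stats::setNames(
      lapply(neurons$neuron_id, function(nid) {
        as.numeric(spk_df$time[spk_df$neuron_id == nid])
      }), neurons$neuron_id)
    if (nrow(eye_df) != row$n_samples) {
      stop("trial ", row$trial_id, ": eye-trace length does not match header")
    }
    new_trial(trial_id = row$trial_id, direction = row$direction,
              target = c(row$target_x, row$target_y),
              events = unlist(row[.mandatory_events]),
              eye = structure(list(t0 = row$t0, dt = row$dt,
                                   x = as.numeric(eye_df$x),
                                   y = as.numeric(eye_df$y)),
                              class = "eye_trace"),
              spikes = spikes, included = row$included)
  })
  new_session(session_id = meta$session_id, task = meta$task,
              sampling_rate = meta$sampling_rate,
              trials = trials, neurons = neurons)
}

#' Write result tables as CSV files
#'
#' Each element of `tables` (a named list of data frames) is written to
#' `<dir>/<name>.csv`. Missing values become empty cells.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    .write_csv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Write generator ground truth as sidecar CSVs
#'
#' @param ground_truth the `ground_truth` element returned by
#'   [generate_session()].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  write_results(list(ground_truth_neurons = ground_truth$neurons,
                     ground_truth_trials = ground_truth$trials), dir)
}

#' @export
print.scs_session <- function(x, ...) {
  cat(sprintf("<scs_session> %s  task=%s  %d trials, %d neurons @ %g Hz\n",
              x$session_id, x$task, length(x$trials), nrow(x$neurons),
              x$sampling_rate))
  invisible(x)
}
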
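# Plain-text interchange formats: trial tables, kinematics, features, events.

#' Write / read a trial table CSV
#'
#' Header: `participant_id,trial_index,condition,actual,verbalized,valid,release_time_s,audio_ref`.
#'
#' @param trials trial data frame or `throw_cohort`.
#' @param path CSV path.
#' @return `path` invisibly (write); trial data frame (read).
#' @export
write_trials_csv <- function(trials, path) {
  if (inherits(trials, "throw_cohort")) trials <- trials$trials
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("participant_id", "trial_index", "condition", "actual",
            "verbalized", "valid")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trial CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr$valid <- as.logical(tr$valid)
  tr
}

#' Write / read a kinematic stream as long-format CSV
#'
#' Columns `frame,marker,x,y,z`; `frame` is 0-based, coordinates in metres,
#' `z` vertical.
#'
#' @param stream a `kinematic_stream`.
#' @param path CSV path.
#' @param fs_hz sampling rate (needed when reading; the CSV carries none).
#' @return `path` invisibly (write); a `kinematic_stream` (read).
#' @export
write_kinematics_csv <- function(stream, path) {
  stopifnot(inherits(stream, "kinematic_stream"))
  rows <- lapply(names(stream$markers), function(nm) {
    m <- stream$markers[[nm]]
    data.frame(frame = 0:(nrow(m) - 1), marker = nm,
               x = m[, 1], y = m[, 2], z = m[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @export
read_kinematics_csv <- function(path, fs_hz) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("kinematics CSV must have columns frame,marker,x,y,z", call. = FALSE)
  }
  frames <- sort(unique(d$frame))
  if (!identical(frames, seq(min(frames), max(frames)))) {
    stop("kinematics CSV has missing frames; flag such trials invalid upstream",
         call. = FALSE)
  }
  n <- length(frames)
  markers <- lapply(split(d, d$marker), function(s) {
    s <- s[order(s$frame), ]
    if (nrow(s) != n) stop("marker with missing frames in ", path, call. = FALSE)
    cbind(x = s$x, y = s$y, z = s$z)
  })
  structure(list(fs_hz = fs_hz, n_frames = n, markers = markers,
                 flags = rep(FALSE, n), ledger = NULL),
            class = "kinematic_stream")
}

#' Write per-participant metrics to CSV
#'
#' Header: `participant_id,HR,FA,d_prime,c,pC_chance,pC_pred,acc_pred`.
#'
#' @param fit a `prediction_fit`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_metrics_csv <- function(fit, path) {
  stopifnot(inherits(fit, "prediction_fit"))
  p <- fit$participants
  out <- data.frame(participant_id = p$participant_id, HR = p$HR, FA = p$FA,
                    d_prime = p$d_prime, c = p$c, pC_chance = p$pc_chance,
                    pC_pred = p$pc_pred, acc_pred = p$acc_pred)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write release events to CSV
#'
#' Header: `participant_id,trial_index,frame,time_s,method,confirmed`.
#'
#' @param events data frame of events (one row per trial).
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort ground-truth ledger as JSON
#'
#' @param cohort a `throw_cohort`.
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_ledger_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "throw_cohort"))
  jsonlite::write_json(cohort$ledger, path, dataframe = "columns",
                       digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}
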
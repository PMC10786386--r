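#' Clinical event logs
#'
#' An event log records one clinical interaction per row: the patient, the
#' care setting (`ED` or `MHOA`), the mode of presentation, a date and a
#' time at minute precision, the agents involved, any information systems
#' accessed, and an optional resulting action (for example a referral or a
#' discharge). Multi-valued fields (agents, information systems) are
#' semicolon-separated in the CSV representation.
#'
#' [as_event_log()] builds a validated log from an in-memory data frame with
#' columns `patient`, `setting`, `presentation`, `date` (`DD/MM/YYYY`),
#' `time` (`HH:MM`, 24 h), `agents`, `information_systems`, `action`.
#' Validation enforces that every name resolves in the catalog, that agents
#' are non-empty and contain no information system, that the information
#' system column contains only information systems, and that a patient's
#' presentation mode is constant along their trajectory. Records are sorted
#' by patient and timestamp.
#'
#' @param df A data frame in the event-log column layout.
#' @param catalog An [agent_catalog()].
#' @return An object of class `event_log`: a list with elements `records`
#'   (data frame with list columns `agents` and `info_systems` and a POSIXct
#'   `timestamp`) and `catalog`.
#' @seealso [read_event_log()], [exclude_mhoa_only_patients()],
#'   [trajectory_statistics()]
#' @export
as_event_log <- function(df, catalog) {
  catalog <- validate_catalog(as.data.frame(catalog))
  required <- c("patient", "setting", "presentation", "date", "time",
                "agents", "information_systems", "action")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("event log is missing columns: ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  rec <- data.frame(
    patient = as.character(df$patient),
    setting = as.character(df$setting),
    presentation = trimws(as.character(df$presentation)),
    date = as.character(df$date),
    time = as.character(df$time),
    action = trimws(as.character(df$action)),
    stringsAsFactors = FALSE
  )
  rec$agents <- split_multi(df$agents)
  rec$info_systems <- split_multi(df$information_systems)

  if (n > 0) {
    bad <- !rec$setting %in% c("ED", "MHOA")
    if (any(bad)) {
      stop("invalid setting in row(s) ", paste(which(bad), collapse = ", "),
           " (expected ED or MHOA)")
    }
    ts <- as.POSIXct(paste(rec$date, rec$time),
                     format = "%d/%m/%Y %H:%M", tz = "UTC")
    if (anyNA(ts)) {
      stop("unparseable timestamp in row(s) ",
           paste(which(is.na(ts)), collapse = ", "),
           " (expected DD/MM/YYYY and HH:MM)")
    }
    rec$timestamp <- ts

    for (i in seq_len(n)) {
      if (length(rec$agents[[i]]) == 0) {
        stop("row ", i, ": agents must be non-empty")
      }
    }
    all_names <- unique(c(unlist(rec$agents), unlist(rec$info_systems)))
    unknown <- setdiff(all_names, catalog$name)
    if (length(unknown) > 0) {
      rows <- which(vapply(seq_len(n), function(i) {
        any(c(rec$agents[[i]], rec$info_systems[[i]]) %in% unknown)
      }, logical(1)))
      stop("unknown agent name(s) ", paste(unknown, collapse = ", "),
           " in row(s) ", paste(rows, collapse = ", "))
    }
    systems <- catalog$name[catalog$category == "information_system"]
    for (i in seq_len(n)) {
      mis <- intersect(rec$agents[[i]], systems)
      if (length(mis) > 0) {
        stop("row ", i, ": information system(s) listed in agents column: ",
             paste(mis, collapse = ", "))
      }
      mis <- setdiff(rec$info_systems[[i]], systems)
      if (length(mis) > 0) {
        stop("row ", i, ": non-system name(s) in information_systems column: ",
             paste(mis, collapse = ", "))
      }
    }
    # stable sort: per-patient chronological order, file order breaks ties
    rec <- rec[order(rec$patient, rec$timestamp), , drop = FALSE]
    rownames(rec) <- NULL
    # presentation mode fixed per patient (taken from the first record)
    for (p in unique(rec$patient)) {
      pres <- rec$presentation[rec$patient == p]
      pres <- pres[pres != ""]
      if (length(unique(pres)) > 1) {
        stop("patient ", p, ": inconsistent presentation modes: ",
             paste(unique(pres), collapse = " vs "))
      }
    }
  } else {
    rec$timestamp <- as.POSIXct(character(0), tz = "UTC")
  }

  structure(list(records = rec, catalog = catalog), class = "event_log")
}

split_multi <- function(x) {
  x <- as.character(x)
  lapply(x, function(s) {
    if (is.na(s) || trimws(s) == "") return(character(0))
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts[parts != ""]
  })
}

#' Read a clinical event log from CSV
#'
#' Reads the study observation format: a UTF-8, comma-separated file with
#' header `patient,setting,presentation,date,time,agents,information_systems,action`
#' where `agents` and `information_systems` hold semicolon-separated lists.
#' All validation of [as_event_log()] is applied; records are returned sorted
#' per patient by timestamp.
#'
#' @param path Path to the CSV file.
#' @param catalog An [agent_catalog()] used to resolve every name.
#' @return An `event_log`.
#' @export
read_event_log <- function(path, catalog) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_event_log(df, catalog)
}

#' @rdname read_event_log
#' @param log An `event_log`.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  rec <- log$records
  out <- data.frame(
    patient = rec$patient,
    setting = rec$setting,
    presentation = rec$presentation,
    date = rec$date,
    time = rec$time,
    agents = vapply(rec$agents, paste, "", collapse = "; "),
    information_systems = vapply(rec$info_systems, paste, "", collapse = "; "),
    action = rec$action,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.event_log <- function(x, ...) {
  rec <- x$records
  cat("Clinical event log: ", nrow(rec), " interactions, ",
      length(unique(rec$patient)), " patients\n", sep = "")
  if (nrow(rec) > 0) {
    cat("  settings:", paste(sprintf("%s=%d", names(table(rec$setting)),
                                     table(rec$setting)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of records in an event log
#' @param log An `event_log`.
#' @return Integer count of interaction records.
#' @export
n_records <- function(log) nrow(log$records)

#' Drop patients observed only in the MHOA
#'
#' Patients whose every record was observed in the Mental Health Observational
#' Area serve a different model of care and are excluded before interaction
#' and trajectory statistics. Patients with at least one ED record keep all
#' of their records, including any MHOA ones; the operation is idempotent.
#'
#' @param log An `event_log`.
#' @return An `event_log` restricted to patients with at least one ED record.
#' @export
exclude_mhoa_only_patients <- function(log) {
  stopifnot(inherits(log, "event_log"))
  rec <- log$records
  keep_patients <- unique(rec$patient[rec$setting == "ED"])
  rec <- rec[rec$patient %in% keep_patients, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, catalog = log$catalog), class = "event_log")
}

#' Per-trajectory statistics
#'
#' Summarizes each patient's trajectory by its presentation mode, trajectory
#' time (hours between first and last observed interaction), number of
#' interactions, and number of distinct types of clinical staff involved
#' (distinct catalog names with category `clinical_staff`). Cohort medians
#' are reported with empirical 95\% intervals (the 2.5th to 97.5th percentile
#' of the per-patient values), together with a presentation-mode histogram.
#' MHOA-only patients should be excluded beforehand with
#' [exclude_mhoa_only_patients()] when ED statistics are wanted.
#'
#' @param log A non-empty `event_log`.
#' @return An object of class `trajectory_summary`: a list with
#'   `per_patient` (data frame), `cohort` (data frame of median/lower95/upper95
#'   for trajectory_hours, n_interactions and n_staff_types) and
#'   `presentation` (named table).
#' @export
trajectory_statistics <- function(log) {
  stopifnot(inherits(log, "event_log"))
  rec <- log$records
  if (nrow(rec) == 0) stop("event log is empty")
  staff <- log$catalog$name[log$catalog$category == "clinical_staff"]
  patients <- unique(rec$patient)
  per <- do.call(rbind, lapply(patients, function(p) {
    r <- rec[rec$patient == p, , drop = FALSE]
    pres <- r$presentation[r$presentation != ""]
    data.frame(
      patient = p,
      presentation = if (length(pres) > 0) pres[1] else "",
      trajectory_hours =
        as.numeric(difftime(max(r$timestamp), min(r$timestamp), units = "hours")),
      n_interactions = nrow(r),
      n_staff_types = length(intersect(unique(unlist(r$agents)), staff)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  summarize <- function(v) {
    q <- unname(quantile(v, c(0.025, 0.975)))
    c(median = median(v), lower95 = q[1], upper95 = q[2])
  }
  cohort <- as.data.frame(rbind(
    trajectory_hours = summarize(per$trajectory_hours),
    n_interactions = summarize(per$n_interactions),
    n_staff_types = summarize(per$n_staff_types)
  ))
  structure(list(per_patient = per, cohort = cohort,
                 presentation = table(per$presentation)),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("Trajectory summary for", nrow(x$per_patient), "patients\n")
  cohort <- x$cohort
  cat(sprintf("  trajectory time: median %.2f h [%.2f, %.2f]\n",
              cohort["trajectory_hours", "median"],
              cohort["trajectory_hours", "lower95"],
              cohort["trajectory_hours", "upper95"]))
  cat(sprintf("  interactions:    median %g [%g, %g]\n",
              cohort["n_interactions", "median"],
              cohort["n_interactions", "lower95"],
              cohort["n_interactions", "upper95"]))
  cat(sprintf("  staff types:     median %g [%g, %g]\n",
              cohort["n_staff_types", "median"],
              cohort["n_staff_types", "lower95"],
              cohort["n_staff_types", "upper95"]))
  cat("  presentation modes:\n")
  print(x$presentation)
  invisible(x)
}
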
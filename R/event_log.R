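# Event-log construction: parse treatment-line / response / patient tables,
# validate them, merge within-line modifications, and emit a per-patient
# ordered event log suitable for treatment-tree discovery.

#' Canonical treatment-setting values
#' @keywords internal
.settings <- c("advanced", "adjuvant")

#' Canonical treatment-type vocabulary
#' @keywords internal
.canonical_types <- c("PD1", "CTLA4", "CTLA4+PD1", "BRAFi", "MEKi",
                      "BRAFi+MEKi", "chemo", "other")

#' Response label vocabularies
#'
#' Advanced (non-adjuvant) lines are assessed with RECIST-like labels
#' CR/PR/SD/PD; adjuvant lines with recurrence labels RE/NR.
#' @keywords internal
.response_labels <- c("CR", "PR", "SD", "PD", "RE", "NR")

#' Parse dates in DD.MM.YYYY or ISO-8601 form
#'
#' The treatment tables print dates as `DD.MM.YYYY`; ISO `YYYY-MM-DD` is also
#' accepted. Empty strings and NA become `NA` (an ongoing treatment line has
#' no stop date).
#'
#' @param x character vector of date strings.
#' @return a `Date` vector; unparseable non-empty entries are `NA` and should
#'   be flagged by the caller.
#' @examples
#' parse_mixed_date(c("01.07.2016", "2016-07-01", ""))
#' @export
parse_mixed_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | x == ""
  dotted <- !blank & grepl("^\\d{1,2}\\.\\d{1,2}\\.\\d{4}$", x)
  iso <- !blank & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[dotted] <- as.Date(x[dotted], format = "%d.%m.%Y")
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out
}

.new_issues <- function() {
  data.frame(patient_id = character(), row = integer(),
             rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

.add_issue <- function(issues, patient_id, row, rule, message) {
  rbind(issues, data.frame(patient_id = as.character(patient_id),
                           row = as.integer(row), rule = rule,
                           message = message, stringsAsFactors = FALSE))
}

#' Read and validate the three input tables
#'
#' Reads the treatment-line, response and patient CSV tables, parses dates,
#' normalises the setting flag (blank = advanced) and collects every
#' invariant violation into a validation report instead of failing fast.
#' Rows violating hard invariants (unparseable date, inverted interval,
#' unknown response label, non-positive line/modification index, duplicate
#' (patient, line, modification) key) are dropped from the returned tables
#' and reported.
#'
#' Expected columns:
#' \describe{
#'   \item{treatments}{`patient_id,line,modification,treatment,type,start,stop,setting`}
#'   \item{responses}{`patient_id,line,date,label`}
#'   \item{patients}{`patient_id,sex,birth_date,death_date,last_followup_date`
#'     plus free extra columns kept as patient attributes}
#' }
#'
#' @param treatments_path,responses_path,patients_path paths to CSV files.
#' @return an object of class `treatment_tables`: a list with elements
#'   `treatments`, `responses`, `patients` (data frames with parsed `Date`
#'   columns) and `issues` (data frame `patient_id,row,rule,message`).
#' @seealso [merge_modifications()], [build_event_log()],
#'   [write_validation_report()]
#' @export
read_tables <- function(treatments_path, responses_path, patients_path) {
  for (p in c(treatments_path, responses_path, patients_path)) {
    if (!file.exists(p)) stop("cannot read input file: ", p)
  }
  issues <- .new_issues()

  tr <- utils::read.csv(treatments_path, colClasses = "character",
                        check.names = FALSE)
  need <- c("patient_id", "line", "modification", "treatment", "type",
            "start", "stop", "setting")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop("treatments table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tr) > 0) {
    tr$line <- suppressWarnings(as.integer(tr$line))
    tr$modification <- suppressWarnings(as.integer(tr$modification))
    tr$setting <- ifelse(trimws(tr$setting) == "" | is.na(tr$setting),
                         "advanced", trimws(tr$setting))
    start_raw <- tr$start; stop_raw <- tr$stop
    tr$start <- parse_mixed_date(start_raw)
    tr$stop <- parse_mixed_date(stop_raw)

    bad <- rep(FALSE, nrow(tr))
    for (i in seq_len(nrow(tr))) {
      pid <- tr$patient_id[i]
      if (is.na(tr$line[i]) || tr$line[i] < 1 ||
          is.na(tr$modification[i]) || tr$modification[i] < 1) {
        issues <- .add_issue(issues, pid, i, "bad_index",
                             "line and modification must be positive integers")
        bad[i] <- TRUE
        next
      }
      if (!tr$setting[i] %in% .settings) {
        issues <- .add_issue(issues, pid, i, "unknown_setting",
                             paste0("unknown setting token: ", tr$setting[i]))
        bad[i] <- TRUE
        next
      }
      if (is.na(tr$start[i])) {
        issues <- .add_issue(issues, pid, i, "bad_date",
                             paste0("unparseable start date: ", start_raw[i]))
        bad[i] <- TRUE
        next
      }
      if (!is.na(stop_raw[i]) && trimws(stop_raw[i]) != "" && is.na(tr$stop[i])) {
        issues <- .add_issue(issues, pid, i, "bad_date",
                             paste0("unparseable stop date: ", stop_raw[i]))
        bad[i] <- TRUE
        next
      }
      if (!is.na(tr$stop[i]) && tr$start[i] > tr$stop[i]) {
        issues <- .add_issue(issues, pid, i, "start_after_stop",
                             "start after stop")
        bad[i] <- TRUE
      }
    }
    key <- paste(tr$patient_id, tr$line, tr$modification, sep = "\r")
    dup <- duplicated(key) & !bad
    for (i in which(dup)) {
      issues <- .add_issue(issues, tr$patient_id[i], i, "duplicate_key",
                           "duplicate (patient, line, modification)")
    }
    tr <- tr[!(bad | dup), , drop = FALSE]
    rownames(tr) <- NULL
  } else {
    tr$start <- as.Date(character()); tr$stop <- as.Date(character())
    tr$line <- integer(); tr$modification <- integer()
  }

  rs <- utils::read.csv(responses_path, colClasses = "character",
                        check.names = FALSE)
  need_r <- c("patient_id", "line", "date", "label")
  miss <- setdiff(need_r, names(rs))
  if (length(miss) > 0)
    stop("responses table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rs) > 0) {
    rs$line <- suppressWarnings(as.integer(rs$line))
    date_raw <- rs$date
    rs$date <- parse_mixed_date(date_raw)
    bad <- rep(FALSE, nrow(rs))
    for (i in seq_len(nrow(rs))) {
      if (!rs$label[i] %in% .response_labels) {
        issues <- .add_issue(issues, rs$patient_id[i], i, "unknown_label",
                             paste0("unknown response label: ", rs$label[i]))
        bad[i] <- TRUE
      } else if (is.na(rs$date[i])) {
        issues <- .add_issue(issues, rs$patient_id[i], i, "bad_date",
                             paste0("unparseable assessment date: ", date_raw[i]))
        bad[i] <- TRUE
      } else if (is.na(rs$line[i]) || rs$line[i] < 1) {
        issues <- .add_issue(issues, rs$patient_id[i], i, "bad_index",
                             "response line must be a positive integer")
        bad[i] <- TRUE
      }
    }
    rs <- rs[!bad, , drop = FALSE]
    rownames(rs) <- NULL
  } else {
    rs$date <- as.Date(character()); rs$line <- integer()
  }

  pt <- utils::read.csv(patients_path, colClasses = "character",
                        check.names = FALSE)
  need_p <- c("patient_id", "sex", "birth_date", "death_date",
              "last_followup_date")
  miss <- setdiff(need_p, names(pt))
  if (length(miss) > 0)
    stop("patients table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(pt) > 0) {
    pt$sex <- ifelse(pt$sex %in% c("M", "F"), pt$sex, "other/unknown")
    pt$birth_date <- parse_mixed_date(pt$birth_date)
    pt$death_date <- parse_mixed_date(pt$death_date)
    pt$last_followup_date <- parse_mixed_date(pt$last_followup_date)
    bad <- rep(FALSE, nrow(pt))
    for (i in seq_len(nrow(pt))) {
      # at least one of death date / last follow-up must be present
      if (is.na(pt$death_date[i]) && is.na(pt$last_followup_date[i])) {
        issues <- .add_issue(issues, pt$patient_id[i], i, "no_followup",
                             "neither death date nor last follow-up present")
        bad[i] <- TRUE
      }
    }
    dup <- duplicated(pt$patient_id) & !bad
    for (i in which(dup)) {
      issues <- .add_issue(issues, pt$patient_id[i], i, "duplicate_patient",
                           "duplicate patient_id in patient table")
    }
    pt <- pt[!(bad | dup), , drop = FALSE]
    rownames(pt) <- NULL
  } else {
    pt$birth_date <- as.Date(character())
    pt$death_date <- as.Date(character())
    pt$last_followup_date <- as.Date(character())
  }

  structure(list(treatments = tr, responses = rs, patients = pt,
                 issues = issues),
            class = "treatment_tables")
}

#' Write a validation report as JSON lines
#'
#' One JSON object per issue: `{patient_id, row, rule, message}`.
#'
#' @param issues the `issues` data frame from [read_tables()] or
#'   [build_event_log()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_validation_report <- function(issues, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(issues) > 0) {
    for (i in seq_len(nrow(issues))) {
      writeLines(jsonlite::toJSON(as.list(issues[i, , drop = FALSE][1, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Merge within-line treatment modifications into single events
#'
#' A treatment line may comprise several "modifications" (within-line drug
#' changes that do not open a new line, e.g. maintenance after induction or a
#' switch within the same treatment class). Each (patient, line) group is
#' collapsed to one event retaining the first start date and the latest stop
#' date. If any modification is ongoing (missing stop), the merged event is
#' ongoing. The merged event's treatment type is that of the first
#' modification — the line keeps its induction identity when a maintenance
#' modification has a different type.
#'
#' @param records data frame of validated treatment rows as returned in
#'   `read_tables()$treatments`.
#' @return data frame with one row per (patient, line):
#'   `patient_id, line, type, setting, start, stop, label`. The label is the
#'   treatment type for advanced lines and `adj:<type>` for adjuvant lines.
#' @examples
#' tab <- data.frame(
#'   patient_id = "1234", line = 2L, modification = 1:2,
#'   treatment = c("Ipilimumab+Nivolumab", "Nivolumab"),
#'   type = c("CTLA4+PD1", "PD1"),
#'   start = as.Date(c("2017-01-01", "2017-03-15")),
#'   stop  = as.Date(c("2017-03-01", "2017-12-31")),
#'   setting = "advanced")
#' merge_modifications(tab)  # one event, CTLA4+PD1, 2017-01-01..2017-12-31
#' @export
merge_modifications <- function(records) {
  empty <- data.frame(patient_id = character(), line = integer(),
                      type = character(), setting = character(),
                      start = as.Date(character()), stop = as.Date(character()),
                      label = character(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  key <- paste(records$patient_id, records$line, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    g <- records[idx, , drop = FALSE]
    if (length(unique(g$setting)) > 1) {
      stop("conflicting setting flags within patient ", g$patient_id[1],
           " line ", g$line[1])
    }
    first <- which.min(g$modification)
    stop_date <- if (anyNA(g$stop)) as.Date(NA) else max(g$stop)
    data.frame(patient_id = g$patient_id[1], line = g$line[1],
               type = g$type[first], setting = g$setting[1],
               start = min(g$start), stop = stop_date,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$patient_id, ev$line), , drop = FALSE]
  ev$label <- event_label(ev$type, ev$setting)
  rownames(ev) <- NULL
  ev
}

#' Compose a node/event label from treatment type and setting
#'
#' Adjuvant lines get a distinct label (`adj:<type>`) so that e.g. adjuvant
#' PD1 and first-line advanced PD1 occupy different tree nodes.
#'
#' @param type treatment type token(s).
#' @param setting `"advanced"` or `"adjuvant"`.
#' @return character label(s).
#' @export
event_label <- function(type, setting) {
  ifelse(setting == "adjuvant", paste0("adj:", type), type)
}

#' Assemble the per-patient event log
#'
#' Cross-references merged treatment events, the patient index and the
#' response table, orders each patient's events by line, and screens out
#' patients failing hard invariants (unknown patient id; line order
#' inconsistent with start-date order), recording a per-patient reason.
#' Patients with no treatment rows remain in the log with an empty sequence.
#' Responses referring to treatment lines absent from the treatment table are
#' kept but flagged with a warning-level issue.
#'
#' @param events merged events from [merge_modifications()].
#' @param patients patient data frame (`read_tables()$patients`).
#' @param responses response data frame (`read_tables()$responses`).
#' @return an object of class `event_log`: list with `events` (ordered data
#'   frame), `patients`, `responses`, `issues`.
#' @export
build_event_log <- function(events, patients, responses) {
  issues <- .new_issues()
  if (nrow(events) > 0) {
    unknown <- !(events$patient_id %in% patients$patient_id)
    for (pid in unique(events$patient_id[unknown])) {
      issues <- .add_issue(issues, pid, NA_integer_, "unknown_patient",
                           "treatment event references patient absent from patient table")
    }
    events <- events[!unknown, , drop = FALSE]
  }
  # order by (patient, line); screen patients whose date order contradicts
  # line order
  if (nrow(events) > 0) {
    events <- events[order(events$patient_id, events$line), , drop = FALSE]
    drop_pat <- character()
    for (pid in unique(events$patient_id)) {
      g <- events[events$patient_id == pid, , drop = FALSE]
      if (is.unsorted(g$start, strictly = FALSE)) {
        issues <- .add_issue(issues, pid, NA_integer_, "line_date_disorder",
                             paste0("patient ", pid,
                                    ": start dates not ordered by line"))
        drop_pat <- c(drop_pat, pid)
      } else if (nrow(g) > 1) {
        # overlapping consecutive lines: warn, keep (ambiguity is real in RWD)
        st <- g$stop[-nrow(g)]; nx <- g$start[-1]
        ov <- which(!is.na(st) & nx < st)
        for (k in ov) {
          issues <- .add_issue(issues, pid, NA_integer_, "line_overlap",
                               paste0("patient ", pid, ": line ",
                                      g$line[k + 1], " starts before line ",
                                      g$line[k], " stops"))
        }
      }
    }
    events <- events[!(events$patient_id %in% drop_pat), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (nrow(responses) > 0 && nrow(events) >= 0) {
    ev_key <- paste(events$patient_id, events$line, sep = "\r")
    rs_key <- paste(responses$patient_id, responses$line, sep = "\r")
    orphan <- !(rs_key %in% ev_key)
    for (i in which(orphan)) {
      issues <- .add_issue(issues, responses$patient_id[i], i,
                           "response_without_line",
                           "response refers to a treatment line absent from the log")
    }
    # recurrence labels are only defined for adjuvant lines
    if (any(!orphan)) {
      adj_key <- ev_key[events$setting == "adjuvant"]
      mis <- which(!orphan & responses$label %in% c("RE", "NR") &
                     !(rs_key %in% adj_key))
      for (i in mis) {
        issues <- .add_issue(issues, responses$patient_id[i], i,
                             "recurrence_label_on_advanced_line",
                             "RE/NR label on a non-adjuvant line")
      }
    }
  }
  structure(list(events = events, patients = patients,
                 responses = responses, issues = issues),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> ", nrow(x$patients), " patients, ",
      nrow(x$events), " treatment-line events, ",
      nrow(x$responses), " response assessments\n", sep = "")
  if (nrow(x$issues) > 0)
    cat("  validation issues: ", nrow(x$issues), "\n", sep = "")
  invisible(x)
}

#' Per-patient label sequences
#'
#' @param log an `event_log`.
#' @return named list mapping every patient id (including patients with no
#'   events) to the ordered character vector of event labels.
#' @export
patient_sequences <- function(log) {
  pids <- as.character(log$patients$patient_id)
  seqs <- rep(list(character(0)), length(pids))
  names(seqs) <- pids
  if (nrow(log$events) > 0) {
    sp <- split(log$events$label, log$events$patient_id)
    seqs[names(sp)] <- sp
  }
  seqs
}

#' Drop treatment types from an event log
#'
#' Removes events whose treatment type is in `exclude`; e.g. chemotherapy
#' lines can be neglected when only the sequence of ICI and targeted
#' treatments matters. Remaining events keep their original line indices and
#' no patient is ever removed (a patient may end with an empty sequence).
#'
#' @param log an `event_log`.
#' @param exclude character vector of treatment-type tokens to drop.
#' @return a new `event_log`.
#' @export
filter_event_types <- function(log, exclude) {
  stopifnot(inherits(log, "event_log"))
  if (length(exclude) == 0) return(log)
  known <- unique(log$events$type)
  unknown <- setdiff(exclude, known)
  if (length(unknown) > 0 && nrow(log$events) > 0) {
    stop("unknown treatment type token(s): ", paste(unknown, collapse = ", "))
  }
  keep <- !(log$events$type %in% exclude)
  log$events <- log$events[keep, , drop = FALSE]
  rownames(log$events) <- NULL
  log
}

#' Map raw treatment-type tokens to canonical ones
#'
#' The raw tables may print site-specific variants (e.g. `BRAFi+TT_MEKi`)
#' which a canonical vocabulary groups (`BRAFi+MEKi`); a mapping table can
#' also group classes for sequence analyses (e.g. all BRAFi-based treatments
#' as `TT`, all PD1-based as `ICI`). Unmapped tokens pass through with a
#' warning.
#'
#' @param types character vector of raw type tokens.
#' @param map named character vector: `names(map)` are raw tokens, values are
#'   canonical ones. Defaults to [default_type_map()].
#' @return canonical token vector of the same length.
#' @export
map_treatment_type <- function(types, map = default_type_map()) {
  if (length(map) == 0) return(types)
  hit <- types %in% names(map)
  # tokens already canonical pass silently; genuinely unknown ones warn
  known <- c(unname(map), .canonical_types)
  novel <- setdiff(unique(types[!hit]), known)
  if (length(novel) > 0) {
    warning("unmapped treatment type token(s) passed through: ",
            paste(novel, collapse = ", "), call. = FALSE)
  }
  out <- types
  out[hit] <- unname(map[types[hit]])
  out
}

#' Default raw-to-canonical treatment-type map
#'
#' Groups site-specific spellings of the BRAF/MEK inhibitor combination.
#'
#' @return named character vector.
#' @export
default_type_map <- function() {
  c("BRAFi+TT_MEKi" = "BRAFi+MEKi",
    "TT_MEKi" = "MEKi")
}

#' Apply a treatment-type map to a whole log
#'
#' Rewrites `type` and recomputes labels; a grouping map (several raw types
#' to one canonical type) can merge adjacent identical labels into distinct
#' consecutive events only in the sense of labels — events themselves are
#' kept one per line.
#'
#' @param log an `event_log`.
#' @inheritParams map_treatment_type
#' @return a new `event_log` with mapped types/labels.
#' @export
map_log_types <- function(log, map = default_type_map()) {
  stopifnot(inherits(log, "event_log"))
  if (nrow(log$events) > 0) {
    log$events$type <- map_treatment_type(log$events$type, map)
    log$events$label <- event_label(log$events$type, log$events$setting)
  }
  log
}
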
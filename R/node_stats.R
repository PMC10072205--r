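# Per-node outcome statistics: best-overall-response distributions
# (recurrence status for adjuvant nodes) and Kaplan-Meier overall survival
# anchored at the node's treatment start.

.bor_order <- c(PD = 1, SD = 2, PR = 3, CR = 4)

#' Best overall response of a treatment line
#'
#' The best label achieved among the line's assessments under the RECIST-like
#' ordering CR > PR > SD > PD; `NE` (not evaluable) when no assessment
#' exists. Adjuvant lines are scored with [recurrence_status()] instead.
#'
#' @param patient_id patient identifier.
#' @param line treatment-line index.
#' @param responses response data frame (`patient_id, line, date, label`).
#' @param adjuvant is the line adjuvant? (contract check)
#' @return one of `"CR","PR","SD","PD","NE"`.
#' @export
best_overall_response <- function(patient_id, line, responses,
                                  adjuvant = FALSE) {
  if (isTRUE(adjuvant))
    stop("best_overall_response is for non-adjuvant lines; use recurrence_status()")
  labs <- responses$label[responses$patient_id == patient_id &
                            responses$line == line &
                            responses$label %in% names(.bor_order)]
  if (length(labs) == 0) return("NE")
  names(.bor_order)[max(.bor_order[labs])]
}

#' Recurrence status of an adjuvant treatment line
#'
#' `RE` if any recurrence label was recorded, else `NR` if a no-recurrence
#' label exists, else `NE`.
#'
#' @inheritParams best_overall_response
#' @return one of `"RE","NR","NE"`.
#' @export
recurrence_status <- function(patient_id, line, responses, adjuvant = TRUE) {
  if (!isTRUE(adjuvant))
    stop("recurrence_status is for adjuvant lines; use best_overall_response()")
  labs <- responses$label[responses$patient_id == patient_id &
                            responses$line == line]
  if (any(labs == "RE")) return("RE")
  if (any(labs == "NR")) return("NR")
  "NE"
}

#' Best-overall-response distribution of a tree node
#'
#' Tallies the BOR of the node's treatment line over the node's patients.
#' Advanced nodes use the `CR/PR/SD/PD/NE` vocabulary; adjuvant nodes use the
#' two-color recurrence vocabulary `RE/NR/NE`.
#'
#' @param tree a `treatment_tree`.
#' @param node_id a non-root node id.
#' @param log the `event_log` the tree was discovered from.
#' @return object of class `bor_distribution`: list with `counts` (named
#'   integer vector), `n_total`, `adjuvant` flag.
#' @export
node_bor <- function(tree, node_id, log) {
  nd <- tree$nodes[[node_id]]
  if (nd$depth == 0) stop("node_bor is undefined for the root")
  adj <- identical(nd$setting, "adjuvant")
  vocab <- if (adj) c("RE", "NR", "NE") else c("CR", "PR", "SD", "PD", "NE")
  counts <- stats::setNames(integer(length(vocab)), vocab)
  for (pid in nd$patients) {
    line <- .node_line(log, pid, nd$depth)
    lab <- if (adj) recurrence_status(pid, line, log$responses)
    else best_overall_response(pid, line, log$responses)
    counts[lab] <- counts[lab] + 1L
  }
  structure(list(counts = counts, n_total = length(nd$patients),
                 adjuvant = adj),
            class = "bor_distribution")
}

# line number of the depth-th event of a patient (events are line-ordered)
.node_line <- function(log, patient_id, depth) {
  lines <- log$events$line[log$events$patient_id == patient_id]
  lines[depth]
}

#' @export
print.bor_distribution <- function(x, ...) {
  kind <- if (x$adjuvant) "recurrence" else "best overall response"
  cat("<bor_distribution> ", kind, ", n=", x$n_total, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Objective response rate from a BOR distribution
#'
#' Percentage of patients with a partial or complete response. By default
#' the denominator is the evaluable patients (NE excluded); set
#' `evaluable_only = FALSE` to divide by all patients.
#'
#' @param bor a `bor_distribution` (advanced vocabulary).
#' @param evaluable_only exclude NE from the denominator?
#' @return fraction in `[0, 1]` (`NaN` if the denominator is empty).
#' @export
objective_response_rate <- function(bor, evaluable_only = TRUE) {
  if (bor$adjuvant) stop("ORR is undefined for adjuvant (recurrence) nodes")
  num <- sum(bor$counts[c("CR", "PR")])
  den <- if (evaluable_only) bor$n_total - bor$counts[["NE"]] else bor$n_total
  unname(num / den)
}

#' Overall-survival times anchored at given dates
#'
#' For each patient: time from its anchor date to death (event) or to the
#' last follow-up date (censored). A death date always counts as an event
#' even without a recorded progression. Patients whose anchor falls after
#' their last follow-up with no death date cannot contribute and are dropped
#' with a warning.
#'
#' @param anchors named `Date` vector (names = patient ids).
#' @param patients patient data frame.
#' @return data frame `patient_id, time, event` (time in days).
#' @export
os_times <- function(anchors, patients) {
  idx <- match(names(anchors), patients$patient_id)
  if (anyNA(idx)) stop("anchor for unknown patient: ",
                       paste(names(anchors)[is.na(idx)], collapse = ", "))
  death <- patients$death_date[idx]
  fup <- patients$last_followup_date[idx]
  end <- ifelse(!is.na(death), as.numeric(death), as.numeric(fup))
  time <- end - as.numeric(anchors)
  event <- as.integer(!is.na(death))
  bad <- is.na(time) | (time < 0 & event == 0)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " patient(s) with anchor after last follow-up and no death",
            call. = FALSE)
  }
  out <- data.frame(patient_id = names(anchors), time = time, event = event,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  out$time <- pmax(out$time, 0)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier OS curve of a tree node
#'
#' Product-limit estimate of overall survival for the node's patients, with
#' time zero at each patient's start of the node's treatment line. The full
#' follow-up enters the estimator; `horizon_days` only truncates the
#' returned curve for display (five years by default).
#'
#' @param tree a `treatment_tree`.
#' @param node_id a non-root node id.
#' @param log the `event_log`.
#' @param horizon_days display truncation in days (default 5 years).
#' @return a `survival_curve` (see [km_estimate()]).
#' @export
node_os_curve <- function(tree, node_id, log, horizon_days = 1826) {
  nd <- tree$nodes[[node_id]]
  if (nd$depth == 0) stop("node_os_curve is undefined for the root")
  d <- os_times(nd$anchors, log$patients)
  curve <- km_estimate(d$time, d$event)
  truncate_curve(curve, horizon_days)
}

#' Truncate a survival curve for display
#'
#' @param curve a `survival_curve`.
#' @param horizon_days right limit in days.
#' @return a `survival_curve` restricted to `[0, horizon_days]`.
#' @export
truncate_curve <- function(curve, horizon_days) {
  keep <- curve$times <= horizon_days
  curve$times <- curve$times[keep]
  curve$survival <- curve$survival[keep]
  curve$at_risk <- curve$at_risk[keep]
  if (!is.null(curve$lower)) {
    curve$lower <- curve$lower[keep]
    curve$upper <- curve$upper[keep]
  }
  curve$censor_times <- curve$censor_times[curve$censor_times <= horizon_days]
  curve
}
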
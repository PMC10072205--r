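# Synthetic real-world-data generator: Markov-style treatment paths over a
# melanoma-flavoured vocabulary, per-line response labels, exponential
# survival with per-first-line hazards and optional multiplicative effects,
# administrative and random censoring, and a ground-truth export. Output
# tables use exactly the CSV dialects the event-log reader consumes.

.default_labels <- c("adj:PD1", "PD1", "CTLA4", "CTLA4+PD1",
                     "BRAFi+MEKi", "chemo")

.drug_names <- c("adj:PD1" = "Pembrolizumab", "PD1" = "Nivolumab",
                 "CTLA4" = "Ipilimumab", "CTLA4+PD1" = "Ipilimumab+Nivolumab",
                 "BRAFi+MEKi" = "Dabrafenib+Trametinib",
                 "chemo" = "Dacarbazine")

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate an advanced-melanoma real-world cohort: a first-line mix
#' dominated by PD1 and CTLA4+PD1 with a sizeable adjuvant-PD1 entry,
#' first-order transitions between lines with a per-label stop probability,
#' response mixes roughly reflecting published objective response rates of
#' each class, and exponential overall survival with a per-first-line hazard
#' (medians from roughly 10 months for chemotherapy to several years for the
#' ICI combination). All values are illustrative, not estimates of any
#' specific cohort.
#'
#' @param n_patients cohort size.
#' @param seed integer RNG seed; replaying it reproduces every file
#'   bit-for-bit.
#' @param labels treatment labels (adjuvant labels carry the `adj:` prefix).
#' @param init named first-line probability vector over `labels`.
#' @param next_probs named list: label -> probability vector over
#'   `c(labels, "stop")` entries (missing entries are 0).
#' @param response_mix named list: label -> probability vector over
#'   `CR/PR/SD/PD` (advanced) or `RE/NR` (adjuvant).
#' @param duration_meanlog,duration_sdlog named log-normal parameters of line
#'   duration (days) per label.
#' @param os_hazard named daily exponential death hazard per first-line
#'   label.
#' @param hr_map optional named multiplicative hazard effects applied when a
#'   label occurs anywhere in the path.
#' @param censor_rate probability of random early censoring.
#' @param followup_horizon administrative follow-up horizon (days from first
#'   treatment).
#' @param entry_window days over which study entry dates are spread.
#' @param max_lines cap on lines per patient.
#' @param modification_split_prob fraction of lines split into 2-3
#'   modification rows (to exercise modification merging).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 150,
                             seed = 1,
                             labels = .default_labels,
                             init = c("adj:PD1" = 0.20, "PD1" = 0.28,
                                      "CTLA4+PD1" = 0.24, "BRAFi+MEKi" = 0.16,
                                      "CTLA4" = 0.08, "chemo" = 0.04),
                             next_probs = list(
                               "adj:PD1" = c(stop = 0.60, "CTLA4+PD1" = 0.14,
                                             "PD1" = 0.10, "BRAFi+MEKi" = 0.10,
                                             "CTLA4" = 0.03, "chemo" = 0.03),
                               "PD1" = c(stop = 0.45, "CTLA4+PD1" = 0.20,
                                         "BRAFi+MEKi" = 0.18, "CTLA4" = 0.07,
                                         "chemo" = 0.06, "PD1" = 0.04),
                               "CTLA4+PD1" = c(stop = 0.50, "BRAFi+MEKi" = 0.22,
                                               "PD1" = 0.14, "chemo" = 0.08,
                                               "CTLA4" = 0.06),
                               "BRAFi+MEKi" = c(stop = 0.45, "CTLA4+PD1" = 0.25,
                                                "PD1" = 0.18, "chemo" = 0.07,
                                                "CTLA4" = 0.05),
                               "CTLA4" = c(stop = 0.40, "PD1" = 0.28,
                                           "CTLA4+PD1" = 0.14,
                                           "BRAFi+MEKi" = 0.12,
                                           "chemo" = 0.06),
                               "chemo" = c(stop = 0.55, "PD1" = 0.20,
                                           "CTLA4+PD1" = 0.10,
                                           "BRAFi+MEKi" = 0.10,
                                           "CTLA4" = 0.05)),
                             response_mix = list(
                               "adj:PD1" = c(RE = 0.23, NR = 0.77),
                               "PD1" = c(CR = 0.12, PR = 0.30, SD = 0.20,
                                         PD = 0.38),
                               "CTLA4+PD1" = c(CR = 0.17, PR = 0.36,
                                               SD = 0.15, PD = 0.32),
                               "CTLA4" = c(CR = 0.03, PR = 0.19, SD = 0.20,
                                           PD = 0.58),
                               "BRAFi+MEKi" = c(CR = 0.15, PR = 0.45,
                                                SD = 0.20, PD = 0.20),
                               "chemo" = c(CR = 0.02, PR = 0.08, SD = 0.20,
                                           PD = 0.70)),
                             duration_meanlog = c("adj:PD1" = log(270),
                                                  "PD1" = log(240),
                                                  "CTLA4" = log(120),
                                                  "CTLA4+PD1" = log(240),
                                                  "BRAFi+MEKi" = log(210),
                                                  "chemo" = log(90)),
                             duration_sdlog = 0.5,
                             os_hazard = log(2) / c("adj:PD1" = 2400,
                                                    "PD1" = 1200,
                                                    "CTLA4" = 600,
                                                    "CTLA4+PD1" = 1800,
                                                    "BRAFi+MEKi" = 750,
                                                    "chemo" = 300),
                             hr_map = NULL,
                             censor_rate = 0.15,
                             followup_horizon = 2200,
                             entry_window = 1825,
                             max_lines = 5,
                             modification_split_prob = 0.15) {
  cfg <- list(n_patients = n_patients, seed = seed, labels = labels,
              init = init, next_probs = next_probs,
              response_mix = response_mix,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              os_hazard = os_hazard, hr_map = hr_map,
              censor_rate = censor_rate,
              followup_horizon = followup_horizon,
              entry_window = entry_window, max_lines = max_lines,
              modification_split_prob = modification_split_prob)
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Every probability vector must sum to 1 within 1e-9, hazards must be
#' positive, and the censoring rate must lie in `[0, 1]`.
#'
#' @param config a `generator_config`.
#' @return the config, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  stopifnot(config$n_patients >= 0)
  if (abs(sum(config$init) - 1) > 1e-9)
    stop("first-line probabilities must sum to 1")
  if (!all(names(config$init) %in% config$labels))
    stop("init refers to labels outside the vocabulary")
  for (lab in names(config$next_probs)) {
    p <- config$next_probs[[lab]]
    if (abs(sum(p) - 1) > 1e-9)
      stop("transition probabilities from '", lab, "' must sum to 1")
    if (!all(names(p) %in% c(config$labels, "stop")))
      stop("transitions from '", lab, "' refer to unknown labels")
  }
  for (lab in names(config$response_mix)) {
    if (abs(sum(config$response_mix[[lab]]) - 1) > 1e-9)
      stop("response mix for '", lab, "' must sum to 1")
  }
  if (any(config$os_hazard <= 0)) stop("hazards must be positive")
  if (config$censor_rate < 0 || config$censor_rate > 1)
    stop("censor_rate must lie in [0, 1]")
  invisible(config)
}

.split_label <- function(label) {
  adj <- startsWith(label, "adj:")
  list(type = sub("^adj:", "", label),
       setting = ifelse(adj, "adjuvant", "advanced"))
}

.fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%d.%m.%Y"))

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-patient treatment paths from the first-order transition
#' structure, line intervals from log-normal durations with inter-line gaps,
#' response assessments from the per-label mixes (with a terminal
#' progression/recurrence assessment before every switch to a next line, so
#' tree transitions are response-consistent), and death times from the
#' exponential hazard of the first-line label times any `hr_map` effects of
#' labels in the path. Follow-up is administratively censored at the horizon
#' and, with probability `censor_rate`, randomly before it; lines that would
#' start after death or censoring are not observed, and the truth export
#' records the realized path.
#'
#' @param config a `generator_config`.
#' @return list of class `synthetic_cohort` with `treatments`, `responses`,
#'   `patients` (data frames with `Date` columns, in the event-log dialects)
#'   and `truth` (list: `config`, `paths` data frame with per-patient
#'   realized path / OS time / event, `lines` data frame with per-line true
#'   response labels).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  origin <- as.Date("2015-01-01")
  tr_rows <- list(); rs_rows <- list(); pt_rows <- list()
  truth_path <- list(); truth_lines <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    sex <- sample(c("M", "F"), 1, prob = c(0.6, 0.4))
    birth <- origin - sample(365 * 35:80, 1)
    braf <- sample(c("V600", "WT"), 1, prob = c(0.5, 0.5))
    entry <- origin + sample.int(config$entry_window, 1) - 1L

    # treatment path
    path <- sample(names(config$init), 1, prob = config$init)
    while (length(path) < config$max_lines) {
      p <- config$next_probs[[path[length(path)]]]
      if (is.null(p)) break
      nxt <- sample(names(p), 1, prob = p)
      if (nxt == "stop") break
      path <- c(path, nxt)
    }

    # survival: hazard of the first-line label times path-label effects
    rate <- config$os_hazard[[path[1]]]
    if (!is.null(config$hr_map)) {
      for (lab in unique(path)) {
        if (lab %in% names(config$hr_map)) rate <- rate * config$hr_map[[lab]]
      }
    }
    death_day <- stats::rexp(1, rate)
    censor_day <- if (stats::runif(1) < config$censor_rate)
      stats::runif(1, 0, config$followup_horizon) else config$followup_horizon
    os_day <- min(death_day, censor_day)
    died <- death_day <= censor_day

    # line intervals
    day <- 0
    kept <- character(0)
    starts <- numeric(0); stops <- numeric(0); ongoing <- logical(0)
    for (k in seq_along(path)) {
      if (day >= os_day) break
      dur <- stats::rlnorm(1, config$duration_meanlog[[path[k]]],
                           config$duration_sdlog)
      stop_day <- day + max(round(dur), 7)
      kept <- c(kept, path[k])
      starts <- c(starts, day)
      open <- stop_day >= os_day
      # death closes the line; censoring leaves it ongoing
      stops <- c(stops, if (open && died) floor(os_day) else stop_day)
      ongoing <- c(ongoing, open && !died)
      day <- stop_day + sample(14:60, 1)
    }
    if (length(kept) == 0) { # death/censoring before any treatment started
      kept <- path[1]; starts <- 0
      stops <- floor(os_day); ongoing <- !died
    }

    for (k in seq_along(kept)) {
      sl <- .split_label(kept[k])
      tr_rows[[length(tr_rows) + 1]] <- data.frame(
        patient_id = pid, line = k, modification = 1L,
        treatment = unname(.drug_names[kept[k]]), type = sl$type,
        start = entry + starts[k],
        stop = if (ongoing[k]) as.Date(NA) else entry + stops[k],
        setting = sl$setting, stringsAsFactors = FALSE)

      mix <- config$response_mix[[kept[k]]]
      lab <- sample(names(mix), 1, prob = mix)
      truth_lines[[length(truth_lines) + 1]] <- data.frame(
        patient_id = pid, line = k, label = kept[k], response = lab,
        stringsAsFactors = FALSE)
      obs_stop <- min(stops[k], floor(os_day))  # nothing after follow-up
      span <- max(obs_stop - starts[k], 1)
      assess_day <- starts[k] + sample.int(span, 1)
      rs_rows[[length(rs_rows) + 1]] <- data.frame(
        patient_id = pid, line = k, date = entry + min(assess_day, obs_stop),
        label = lab, stringsAsFactors = FALSE)
      # progression/recurrence recorded before every switch to a next line
      prog <- if (sl$setting == "adjuvant") "RE" else "PD"
      if (k < length(kept) && lab != prog) {
        rs_rows[[length(rs_rows) + 1]] <- data.frame(
          patient_id = pid, line = k, date = entry + stops[k],
          label = prog, stringsAsFactors = FALSE)
      }
    }

    death_date <- if (died) entry + floor(os_day) else as.Date(NA)
    pt_rows[[length(pt_rows) + 1]] <- data.frame(
      patient_id = pid, sex = sex, birth_date = birth,
      death_date = death_date, last_followup_date = entry + floor(os_day),
      braf_status = braf, stringsAsFactors = FALSE)
    truth_path[[length(truth_path) + 1]] <- data.frame(
      patient_id = pid, path = paste(kept, collapse = ">"),
      planned_path = paste(path, collapse = ">"),
      n_lines = length(kept), os_days = floor(os_day),
      os_event = as.integer(died), first_label = path[1],
      stringsAsFactors = FALSE)
  }

  treatments <- if (length(tr_rows) > 0) do.call(rbind, tr_rows) else
    data.frame(patient_id = character(), line = integer(),
               modification = integer(), treatment = character(),
               type = character(), start = as.Date(character()),
               stop = as.Date(character()), setting = character())
  if (config$modification_split_prob > 0 && nrow(treatments) > 0) {
    treatments <- inject_modifications(treatments,
                                       config$modification_split_prob,
                                       seed = config$seed + 1L)
  }
  responses <- if (length(rs_rows) > 0) do.call(rbind, rs_rows) else
    data.frame(patient_id = character(), line = integer(),
               date = as.Date(character()), label = character())
  patients <- if (length(pt_rows) > 0) do.call(rbind, pt_rows) else
    data.frame(patient_id = character(), sex = character(),
               birth_date = as.Date(character()),
               death_date = as.Date(character()),
               last_followup_date = as.Date(character()),
               braf_status = character())
  truth <- list(config = config,
                paths = if (length(truth_path) > 0)
                  do.call(rbind, truth_path) else NULL,
                lines = if (length(truth_lines) > 0)
                  do.call(rbind, truth_lines) else NULL)
  structure(list(treatments = treatments, responses = responses,
                 patients = patients, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$treatments), " treatment rows, ", nrow(x$responses),
      " responses (seed ", x$truth$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Split treatment lines into modification rows
#'
#' Randomly selected closed lines are split into 2-3 consecutive
#' modification rows covering the same interval (same treatment type), so
#' that merging modifications recovers the original line exactly.
#'
#' @param treatments treatment table (internal representation, `Date`
#'   columns).
#' @param split_prob probability of splitting each eligible line.
#' @param seed RNG seed.
#' @return the expanded treatment table.
#' @export
inject_modifications <- function(treatments, split_prob, seed = 1) {
  stopifnot(split_prob >= 0, split_prob <= 1)
  if (split_prob == 0 || nrow(treatments) == 0) return(treatments)
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(treatments))) {
    row <- treatments[i, , drop = FALSE]
    span <- if (is.na(row$stop)) 0 else as.numeric(row$stop - row$start)
    if (span >= 30 && stats::runif(1) < split_prob) {
      k <- sample(2:3, 1)
      cuts <- sort(sample.int(span - 1, k - 1))
      bounds <- c(0, cuts, span)
      for (m in seq_len(k)) {
        piece <- row
        piece$modification <- m
        piece$start <- row$start + bounds[m]
        piece$stop <- row$start + bounds[m + 1]
        out[[length(out) + 1]] <- piece
      }
    } else {
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic cohort to CSV/JSON files
#'
#' Writes `treatments.csv`, `responses.csv`, `patients.csv` in the event-log
#' input dialects (dates as DD.MM.YYYY, blank setting = advanced, blank stop
#' = ongoing) and `truth.json` with the ground truth and the config used.
#'
#' @param sim a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- sim$treatments
  tr$start <- .fmt_date(tr$start); tr$stop <- .fmt_date(tr$stop)
  tr$setting <- ifelse(tr$setting == "advanced", "", tr$setting)
  rs <- sim$responses
  rs$date <- .fmt_date(rs$date)
  pt <- sim$patients
  for (col in c("birth_date", "death_date", "last_followup_date"))
    pt[[col]] <- .fmt_date(pt[[col]])
  paths <- c(treatments = file.path(dir, "treatments.csv"),
             responses = file.path(dir, "responses.csv"),
             patients = file.path(dir, "patients.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(tr, paths[["treatments"]], row.names = FALSE)
  utils::write.csv(rs, paths[["responses"]], row.names = FALSE)
  utils::write.csv(pt, paths[["patients"]], row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}

#' Simulate two exponential survival arms with a known hazard ratio
#'
#' A minimal parameter-recovery harness: arm A has constant daily hazard
#' `base_rate`, arm B has `base_rate * hr`; both are administratively
#' censored at `censor_time` and optionally randomly before it.
#'
#' @param n_per_arm subjects per arm.
#' @param hr true hazard ratio (B vs A).
#' @param base_rate daily hazard of arm A (default: median one year).
#' @param censor_time administrative censoring time (days).
#' @param censor_rate probability of random early censoring.
#' @param seed optional RNG seed.
#' @return list `group_a`, `group_b`: data frames with `time`, `event`.
#' @export
simulate_two_arm <- function(n_per_arm, hr, base_rate = log(2) / 365,
                             censor_time = 1095, censor_rate = 0.1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(rate) {
    t <- stats::rexp(n_per_arm, rate)
    cens <- ifelse(stats::runif(n_per_arm) < censor_rate,
                   stats::runif(n_per_arm, 0, censor_time), censor_time)
    data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
  }
  list(group_a = draw(base_rate), group_b = draw(base_rate * hr))
}

#' Event log directly from a synthetic cohort
#'
#' Convenience wrapper: merges modifications and assembles the event log
#' from in-memory synthetic tables (no round trip through CSV files).
#'
#' @param sim a `synthetic_cohort`.
#' @return an `event_log`.
#' @export
log_from_cohort <- function(sim) {
  build_event_log(merge_modifications(sim$treatments), sim$patients,
                  sim$responses)
}
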
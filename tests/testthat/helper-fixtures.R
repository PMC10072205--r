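# Fixtures built in code: the printed worked-example tables, small in-memory
# event logs, and random-log generators for property tests.

# the five-row worked-example treatment table (one patient, three lines)
table1_treatment_rows <- function() {
  paste(
    "patient_id,line,modification,treatment,type,start,stop,setting",
    "1234,1,1,Pembrolizumab,PD1,01.07.2016,15.12.2016,adjuvant",
    "1234,2,1,Ipilimumab+Nivolumab,CTLA4+PD1,01.01.2017,01.03.2017,",
    "1234,2,2,Nivolumab,PD1,15.03.2017,31.12.2017,",
    "1234,3,1,Dabrafenib+Trametinib,BRAFi+TT_MEKi,15.01.2018,15.02.2018,",
    "1234,3,2,Vemurafenib+Cobimetinib,BRAFi+TT_MEKi,01.03.2018,31.12.2018,",
    sep = "\n")
}

table1_files <- function(dir = tempfile("tab1_")) {
  dir.create(dir, showWarnings = FALSE)
  tp <- file.path(dir, "treatments.csv")
  writeLines(table1_treatment_rows(), tp)
  rp <- file.path(dir, "responses.csv")
  writeLines("patient_id,line,date,label", rp)
  pp <- file.path(dir, "patients.csv")
  writeLines(c("patient_id,sex,birth_date,death_date,last_followup_date",
               "1234,M,01.01.1955,,01.06.2021"), pp)
  list(treatments = tp, responses = rp, patients = pp, dir = dir)
}

empty_responses <- function() {
  data.frame(patient_id = character(), line = integer(),
             date = as.Date(character()), label = character(),
             stringsAsFactors = FALSE)
}

# build an event_log straight from named label sequences; "adj:" prefixes
# mark adjuvant lines; all patients alive at a common follow-up date
log_from_seqs <- function(seqs, responses = empty_responses(),
                          followup = as.Date("2023-01-01")) {
  rows <- list()
  for (pid in names(seqs)) {
    labs <- seqs[[pid]]
    if (length(labs) == 0) next
    start <- as.Date("2018-01-01") + (seq_along(labs) - 1) * 200
    rows[[pid]] <- data.frame(
      patient_id = pid, line = seq_along(labs),
      type = sub("^adj:", "", labs),
      setting = ifelse(startsWith(labs, "adj:"), "adjuvant", "advanced"),
      start = start, stop = start + 150, label = labs,
      stringsAsFactors = FALSE)
  }
  events <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(), line = integer(),
               type = character(), setting = character(),
               start = as.Date(character()), stop = as.Date(character()),
               label = character(), stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = names(seqs), sex = rep(c("M", "F"),
                                        length.out = length(seqs)),
    birth_date = as.Date("1960-06-15"), death_date = as.Date(NA),
    last_followup_date = followup, stringsAsFactors = FALSE)
  build_event_log(events, patients, responses)
}

# random sequences over a small vocabulary, including empty sequences
random_seqs <- function(n_patients, labels = c("A", "B", "C", "D", "E"),
                        max_len = 4) {
  seqs <- lapply(seq_len(n_patients), function(i) {
    len <- sample(0:max_len, 1)
    if (len == 0) character(0) else sample(labels, len, replace = TRUE)
  })
  names(seqs) <- sprintf("S%03d", seq_len(n_patients))
  seqs
}

random_log <- function(n_patients, labels = c("A", "B", "C", "D", "E"),
                       max_len = 4) {
  log_from_seqs(random_seqs(n_patients, labels, max_len))
}
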
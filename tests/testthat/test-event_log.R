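# Parsing, validation and modification merging of the treatment-line tables.

test_that("the worked-example table parses into five records and merges into three lines", {
  f <- table1_files()
  tabs <- read_tables(f$treatments, f$responses, f$patients)
  expect_equal(nrow(tabs$issues), 0)
  expect_equal(nrow(tabs$treatments), 5)
  expect_equal(tabs$treatments$line, c(1L, 2L, 2L, 3L, 3L))
  expect_equal(tabs$treatments$setting,
               c("adjuvant", rep("advanced", 4)))
  expect_equal(tabs$treatments$start[1], as.Date("2016-07-01"))

  ev <- merge_modifications(tabs$treatments)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$line, 1:3)
  # line 1 keeps its adjuvant flag and label
  expect_equal(ev$setting[1], "adjuvant")
  expect_equal(ev$label[1], "adj:PD1")
  # line 2: first start, latest stop; induction type wins over maintenance
  expect_equal(ev$start[2], as.Date("2017-01-01"))
  expect_equal(ev$stop[2], as.Date("2017-12-31"))
  expect_equal(ev$type[2], "CTLA4+PD1")
  # line 3: two modifications of the same targeted-therapy type
  expect_equal(ev$start[3], as.Date("2018-01-15"))
  expect_equal(ev$stop[3], as.Date("2018-12-31"))
  expect_equal(ev$type[3], "BRAFi+TT_MEKi")
})

test_that("dates parse from both the dotted and ISO dialects", {
  expect_equal(parse_mixed_date(c("01.07.2016", "2016-07-01")),
               rep(as.Date("2016-07-01"), 2))
  expect_true(is.na(parse_mixed_date("")))
  expect_true(is.na(parse_mixed_date("July 1, 2016")))
})

test_that("invalid rows are reported and dropped, empty tables pass through", {
  d <- tempfile("val_"); dir.create(d)
  writeLines(c("patient_id,line,modification,treatment,type,start,stop,setting",
               "p1,1,1,DrugA,PD1,15.03.2017,01.01.2017,",
               "p1,2,1,DrugB,chemo,01.05.2017,01.06.2017,",
               "p2,0,1,DrugC,PD1,01.01.2018,,",
               "p3,1,1,DrugD,PD1,garbage,,"),
             file.path(d, "treatments.csv"))
  writeLines(c("patient_id,line,date,label", "p1,2,15.05.2017,XX"),
             file.path(d, "responses.csv"))
  writeLines(c("patient_id,sex,birth_date,death_date,last_followup_date",
               "p1,M,,,01.01.2020", "p2,F,,,", "p3,M,,,01.01.2020"),
             file.path(d, "patients.csv"))
  tabs <- read_tables(file.path(d, "treatments.csv"),
                      file.path(d, "responses.csv"),
                      file.path(d, "patients.csv"))
  expect_setequal(tabs$issues$rule,
                  c("start_after_stop", "bad_index", "bad_date",
                    "unknown_label", "no_followup"))
  expect_match(tabs$issues$message[tabs$issues$rule == "start_after_stop"],
               "start after stop")
  # only the one clean treatment row survives
  expect_equal(nrow(tabs$treatments), 1)
  expect_equal(nrow(tabs$responses), 0)
  expect_equal(nrow(tabs$patients), 2)

  # header-only files: empty tables, empty report
  writeLines("patient_id,line,modification,treatment,type,start,stop,setting",
             file.path(d, "empty_t.csv"))
  writeLines("patient_id,line,date,label", file.path(d, "empty_r.csv"))
  writeLines("patient_id,sex,birth_date,death_date,last_followup_date",
             file.path(d, "empty_p.csv"))
  tabs0 <- read_tables(file.path(d, "empty_t.csv"),
                       file.path(d, "empty_r.csv"),
                       file.path(d, "empty_p.csv"))
  expect_equal(nrow(tabs0$treatments), 0)
  expect_equal(nrow(tabs0$issues), 0)
  expect_error(read_tables(file.path(d, "absent.csv"),
                           file.path(d, "empty_r.csv"),
                           file.path(d, "empty_p.csv")),
               "cannot read")
})

test_that("merging is idempotent, conserves lines, and matches a brute-force scan", {
  f <- table1_files()
  tabs <- read_tables(f$treatments, f$responses, f$patients)
  ev <- merge_modifications(tabs$treatments)

  # idempotence: re-merge the merged events viewed as single-modification rows
  again <- ev
  again$modification <- 1L
  again$treatment <- "x"
  expect_equal(merge_modifications(again)[, names(ev)], ev)

  # randomized groups: min/max by brute force, count conservation
  set.seed(11)
  for (rep in 1:20) {
    n_lines <- sample(1:4, 1)
    rows <- list()
    for (ln in seq_len(n_lines)) {
      k <- sample(1:3, 1)
      starts <- as.Date("2019-01-01") + sample(0:400, k)
      rows[[ln]] <- data.frame(
        patient_id = "pX", line = ln, modification = sample(seq_len(k)),
        treatment = "t", type = sample(c("PD1", "chemo"), k, replace = TRUE),
        start = starts, stop = starts + sample(10:100, k),
        setting = "advanced", stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, rows)
    recs <- recs[sample(nrow(recs)), , drop = FALSE]  # shuffled order
    ev <- merge_modifications(recs)
    expect_equal(nrow(ev), length(unique(paste(recs$patient_id, recs$line))))
    for (ln in unique(recs$line)) {
      g <- recs[recs$line == ln, ]
      expect_equal(ev$start[ev$line == ln], min(g$start))
      expect_equal(ev$stop[ev$line == ln], max(g$stop))
      expect_equal(ev$type[ev$line == ln],
                   g$type[which.min(g$modification)])
    }
  }

  # ongoing modification makes the merged line ongoing
  recs <- data.frame(patient_id = "p", line = 1L, modification = 1:2,
                     treatment = "t", type = "PD1",
                     start = as.Date(c("2020-01-01", "2020-03-01")),
                     stop = as.Date(c("2020-02-01", NA)),
                     setting = "advanced")
  expect_true(is.na(merge_modifications(recs)$stop))

  # conflicting setting flags within a line are an error
  recs$setting <- c("advanced", "adjuvant")
  expect_error(merge_modifications(recs), "conflicting setting")
})

test_that("event-log assembly enforces cross-references and orderings", {
  events <- data.frame(
    patient_id = c("a", "a", "ghost", "b"), line = c(2L, 1L, 1L, 1L),
    type = "PD1", setting = "advanced",
    start = as.Date(c("2020-06-01", "2020-01-01", "2020-01-01",
                      "2020-01-01")),
    stop = as.Date("2021-01-01"), label = "PD1", stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = c("a", "b", "c"), sex = "F",
                         birth_date = as.Date("1950-01-01"),
                         death_date = as.Date(NA),
                         last_followup_date = as.Date("2022-01-01"))
  log <- build_event_log(events, patients, empty_responses())
  expect_true("unknown_patient" %in% log$issues$rule)
  expect_false("ghost" %in% log$events$patient_id)
  # per-patient events ordered by line
  expect_equal(log$events$line[log$events$patient_id == "a"], 1:2)
  # patient with no rows is present with an empty sequence
  expect_equal(patient_sequences(log)[["c"]], character(0))

  # date order contradicting line order excludes the patient with a reason
  bad <- events[events$patient_id == "a", ]
  bad$start <- rev(bad$start)
  log2 <- build_event_log(rbind(bad), patients, empty_responses())
  expect_true("line_date_disorder" %in% log2$issues$rule)
  expect_match(log2$issues$message[log2$issues$rule == "line_date_disorder"],
               "a")
  expect_false("a" %in% log2$events$patient_id)
})

test_that("type filtering drops events but never patients", {
  log <- log_from_seqs(list(p1 = c("PD1", "chemo", "BRAFi+MEKi"),
                            p2 = c("chemo")))
  out <- filter_event_types(log, "chemo")
  expect_equal(patient_sequences(out)$p1, c("PD1", "BRAFi+MEKi"))
  expect_equal(patient_sequences(out)$p2, character(0))
  # remaining events keep their original line indices
  expect_equal(out$events$line[out$events$patient_id == "p1"], c(1L, 3L))
  # identity and degenerate cases
  expect_identical(filter_event_types(log, character(0)), log)
  all_gone <- filter_event_types(log, c("PD1", "chemo", "BRAFi+MEKi"))
  expect_equal(nrow(all_gone$events), 0)
  tree <- discover_tree(all_gone, 0)
  expect_equal(length(tree$nodes), 1)  # root only
  expect_error(filter_event_types(log, "nonsense"), "unknown treatment type")
})

test_that("treatment-type mapping canonicalizes, groups, and passes unknowns through", {
  expect_equal(map_treatment_type("BRAFi+TT_MEKi"), "BRAFi+MEKi")
  expect_equal(map_treatment_type("PD1"), "PD1")
  expect_warning(out <- map_treatment_type("mystery_drug"), "unmapped")
  expect_equal(out, "mystery_drug")

  # DREAMseq-style grouping: only TT and ICI labels remain
  grouping <- c("BRAFi" = "TT", "BRAFi+MEKi" = "TT", "MEKi" = "TT",
                "PD1" = "ICI", "CTLA4" = "ICI", "CTLA4+PD1" = "ICI")
  log <- log_from_seqs(list(p1 = c("PD1", "BRAFi+MEKi"),
                            p2 = c("CTLA4+PD1", "BRAFi"),
                            p3 = c("BRAFi+MEKi", "PD1")))
  mapped <- map_log_types(log, grouping)
  expect_setequal(unique(mapped$events$label), c("TT", "ICI"))
})
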
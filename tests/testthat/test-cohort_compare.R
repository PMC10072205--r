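# Cohort algebra, the expression mini-language, and the survival statistics
# against independent oracles.

test_that("cohort set algebra over nodes matches hand arithmetic", {
  log <- log_from_seqs(list(A = "PD1", B = c("PD1", "BRAFi+MEKi")))
  tree <- discover_tree(log, 0)

  co <- cohort_from_nodes(tree, list("PD1"),
                          list(c("PD1", "BRAFi+MEKi")))
  expect_equal(co$members, "A")
  expect_equal(unname(co$anchors[["A"]]), as.Date("2018-01-01"))

  # A \ A = empty
  both <- cohort_from_nodes(tree, list("PD1"), list("PD1"))
  expect_equal(length(both$members), 0)

  # disjoint union adds sizes; union is commutative on membership
  log2 <- log_from_seqs(list(A = "PD1", B = "PD1", C = "CTLA4", D = "chemo"))
  tree2 <- discover_tree(log2, 0)
  u1 <- cohort_from_nodes(tree2, list("PD1", "CTLA4"))
  u2 <- cohort_from_nodes(tree2, list("CTLA4", "PD1"))
  expect_equal(length(u1$members), 3)
  expect_setequal(u1$members, u2$members)

  # provenance replay reproduces the members
  replay <- cohort_from_nodes(tree,
                              lapply(co$provenance$path[co$provenance$op == "add"],
                                     function(p) strsplit(p, ">")[[1]]),
                              lapply(co$provenance$path[co$provenance$op == "subtract"],
                                     function(p) strsplit(p, ">")[[1]]))
  expect_setequal(replay$members, co$members)

  # multi-membership anchors at the shallowest node, with a warning
  expect_warning(
    multi <- cohort_from_nodes(tree, list(c("PD1", "BRAFi+MEKi"), "PD1")),
    "shallowest")
  expect_equal(unname(multi$anchors[["B"]]), as.Date("2018-01-01"))
  expect_error(cohort_from_nodes(tree, list("nonexistent")), "no node")
})

test_that("the cohort expression mini-language parses unions and subtractions", {
  p <- parse_cohort_expression("PD1>CTLA4+PD1 + PD1>PD1 - adj:PD1")
  expect_equal(p$add, list(c("PD1", "CTLA4+PD1"), c("PD1", "PD1")))
  expect_equal(p$subtract, list("adj:PD1"))
  expect_equal(parse_cohort_expression("BRAFi+MEKi")$add,
               list("BRAFi+MEKi"))  # '+' inside a label is not an operator
  expect_error(parse_cohort_expression("  "), "empty")

  log <- log_from_seqs(list(A = "PD1", B = c("PD1", "BRAFi+MEKi")))
  tree <- discover_tree(log, 0)
  co <- cohort_from_expression(tree, "PD1 - PD1>BRAFi+MEKi")
  expect_equal(co$members, "A")
})

test_that("PFS takes the earliest of progression and death, else censors", {
  events <- data.frame(patient_id = "p", line = 1L, type = "PD1",
                       setting = "advanced", start = as.Date("2019-01-01"),
                       stop = as.Date("2019-06-01"), label = "PD1")
  mk <- function(death = NA, fup = "2020-02-05", rs = empty_responses()) {
    patients <- data.frame(patient_id = "p", sex = "F",
                           birth_date = as.Date("1960-01-01"),
                           death_date = as.Date(death),
                           last_followup_date = as.Date(fup))
    build_event_log(events, patients, rs)
  }
  pd90 <- data.frame(patient_id = "p", line = 1L,
                     date = as.Date("2019-01-01") + 90, label = "PD")
  # PD at day 90 precedes death at day 200
  expect_equal(pfs_time("p", 1L, mk(death = "2019-07-20", rs = pd90)),
               list(time = 90, event = 1L))
  # death without recorded PD still counts as the event
  expect_equal(pfs_time("p", 1L, mk(death = "2019-05-31")),
               list(time = 150, event = 1L))
  # alive, no PD: censored at last follow-up (day 400)
  expect_equal(pfs_time("p", 1L, mk()), list(time = 400, event = 0L))
  # a PD on a later line counts against the anchoring line
  pd_l2 <- data.frame(patient_id = "p", line = 2L,
                      date = as.Date("2019-01-01") + 120, label = "PD")
  expect_equal(pfs_time("p", 1L, mk(rs = pd_l2))$time, 120)
  expect_error(pfs_time("p", 7L, mk()), "no line")
})

test_that("the product-limit estimate matches hand computation and an oracle", {
  # one censor between two events: S = 1, 2/3 on [10,30), 0 after 30
  cv <- km_estimate(c(10, 20, 30), c(1, 0, 1))
  expect_equal(survival_rate_at(cv, 9)$rate, 1)
  expect_equal(survival_rate_at(cv, 15)$rate, 2 / 3)
  expect_equal(survival_rate_at(cv, 29.9)$rate, 2 / 3)
  expect_equal(survival_rate_at(cv, 30)$rate, 0)
  expect_equal(survival_rate_at(cv, 0)$rate, 1)
  expect_equal(cv$censor_times, 20)
  expect_warning(survival_rate_at(cv, 1e5), "beyond")

  # against the first-principles product-limit on random censored fixtures
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    time <- round(rexp(n, 1 / 100)) + 1
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    cv <- km_estimate(time, event)
    oracle <- km_oracle(time, event)
    got <- vapply(oracle$times, function(t)
      survival_rate_at(cv, t, warn_extrapolation = FALSE)$rate, 0)
    expect_equal(got, oracle$surv, tolerance = 1e-10)
  }
  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
})

test_that("without censoring the estimate is the empirical survival function", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    time <- sample(1:500, n, replace = TRUE)
    cv <- km_estimate(time, rep(1, n))
    ts <- sort(unique(time))
    emp <- vapply(ts, function(t) mean(time > t), 0)
    got <- vapply(ts, function(t)
      survival_rate_at(cv, t, warn_extrapolation = FALSE)$rate, 0)
    expect_equal(got, emp, tolerance = 1e-12)
  }
})

test_that("survival rates are non-increasing with confidence bounds around them", {
  set.seed(43)
  d <- simulate_two_arm(40, 1)$group_a
  cv <- km_estimate(d$time, d$event)
  ts <- seq(0, max(d$time), length.out = 50)
  rates <- vapply(ts, function(t)
    survival_rate_at(cv, t, warn_extrapolation = FALSE)$rate, 0)
  expect_false(is.unsorted(rev(rates)))
  r <- survival_rate_at(cv, 300)
  expect_lte(r$ci_low, r$rate)
  expect_gte(r$ci_high, r$rate)
})

test_that("the log-rank test degenerates correctly and matches a permutation null", {
  a <- data.frame(time = c(5, 10, 20, 30), event = c(1, 1, 0, 1))
  lr0 <- logrank_test(a, a)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  none <- data.frame(time = c(10, 20), event = c(0, 0))
  expect_equal(logrank_test(none, none), list(statistic = 0, p_value = 1))

  set.seed(44)
  arms <- simulate_two_arm(20, 1.8, seed = 77)
  lr <- logrank_test(arms$group_a, arms$group_b)
  time <- c(arms$group_a$time, arms$group_b$time)
  event <- c(arms$group_a$event, arms$group_b$event)
  grp <- rep(0:1, each = 20)
  # same statistic as the first-principles computation
  expect_equal(lr$statistic, logrank_stat_oracle(time, event, grp),
               tolerance = 1e-8)
  p_perm <- logrank_perm_p(time, event, grp, n_perm = 4000)
  expect_lt(abs(lr$p_value - p_perm), 0.03)
})

test_that("the Cox fit matches a partial-likelihood grid search and handles edge cases", {
  a <- data.frame(time = c(5, 8, 12, 20), event = c(1, 1, 0, 1))
  cx1 <- cox_hazard_ratio(a, a)
  expect_equal(cx1$hr, 1, tolerance = 1e-6)
  expect_lte(cx1$ci_low, cx1$hr)
  expect_gte(cx1$ci_high, cx1$hr)

  # <= 8 subjects, including a tie, against the Efron grid oracle
  fixtures <- list(
    list(a = data.frame(time = c(4, 7, 7, 15), event = c(1, 1, 1, 0)),
         b = data.frame(time = c(9, 14, 22, 30), event = c(1, 0, 1, 1))),
    list(a = data.frame(time = c(3, 6, 14), event = c(1, 1, 1)),
         b = data.frame(time = c(5, 12, 25), event = c(1, 1, 0))),
    list(a = data.frame(time = c(2, 5, 5, 9), event = c(1, 0, 1, 1)),
         b = data.frame(time = c(4, 8, 8), event = c(1, 1, 1))))
  for (fx in fixtures) {
    cx <- cox_hazard_ratio(fx$a, fx$b)
    beta_grid <- cox_grid_oracle(c(fx$a$time, fx$b$time),
                                 c(fx$a$event, fx$b$event),
                                 rep(0:1, c(nrow(fx$a), nrow(fx$b))))
    expect_equal(cx$coef, beta_grid, tolerance = 1e-4)
  }

  expect_error(cox_hazard_ratio(data.frame(time = 5, event = 0),
                                data.frame(time = 7, event = 0)),
               "zero events")
  # complete separation reports an infinite-bound CI
  sep <- cox_hazard_ratio(data.frame(time = c(50, 60), event = c(0, 0)),
                          data.frame(time = c(1, 2), event = c(1, 1)))
  expect_true(is.infinite(sep$ci_high) || is.na(sep$ci_low))
})

test_that("cohort comparison assembles curves, tests, landmarks and summaries", {
  sim <- generate_cohort(generator_config(n_patients = 200, seed = 21))
  log <- log_from_cohort(sim)
  tree <- discover_tree(log, 0)
  coA <- cohort_from_expression(tree, "PD1", name = "PD1")
  coB <- cohort_from_expression(tree, "CTLA4+PD1", name = "CTLA4+PD1")
  res <- compare_cohorts(coA, coB, "OS", log)
  expect_s3_class(res, "cohort_comparison")
  expect_lte(res$hr_ci_low, res$hazard_ratio)
  expect_gte(res$hr_ci_high, res$hazard_ratio)
  expect_gte(res$logrank_p, 0); expect_lte(res$logrank_p, 1)
  expect_equal(res$summaries$PD1$n, length(coA$members))
  expect_equal(res$summaries$`CTLA4+PD1`$n, length(coB$members))
  expect_equal(sum(res$summaries$PD1$bor), length(coA$members))
  expect_equal(sum(res$summaries$PD1$sex_ratio), length(coA$members))
  lmA <- res$landmark_estimates$PD1
  expect_gte(lmA[["rate"]], 0); expect_lte(lmA[["rate"]], 1)

  # PFS endpoint runs on the anchoring line
  res_pfs <- compare_cohorts(coA, coB, "PFS", log)
  expect_gt(res_pfs$curves$PD1$n_events, 0)

  # A vs itself: HR 1, log-rank p 1, and an overlap warning
  expect_warning(same <- compare_cohorts(coA, coA, "OS", log), "overlap")
  expect_equal(same$hazard_ratio, 1, tolerance = 1e-6)
  expect_equal(same$logrank_p, 1, tolerance = 1e-9)

  out <- tempfile("cmp_"); dir.create(out)
  files <- comparison_to_csv(res, out)
  stats_df <- read.csv(file.path(out, "comparison_stats.csv"))
  expect_equal(nrow(stats_df), 2)
  expect_equal(stats_df$hazard_ratio[1], res$hazard_ratio)
  curves_df <- read.csv(file.path(out, "comparison_curves.csv"))
  expect_setequal(unique(curves_df$cohort), c("PD1", "CTLA4+PD1"))
})
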
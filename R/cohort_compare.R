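# Cohort algebra over tree nodes (the drag-and-drop operation, scripted) and
# anchored survival comparison: KM curves, log-rank test, Cox hazard ratio,
# landmark rates and per-group summaries. The survival machinery is routed
# through the survival package (product-limit, Efron ties).

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` with a Greenwood-variance log-log confidence
#' band. The returned curve starts at S(0) = 1.
#'
#' @param durations non-negative times (days).
#' @param event_flags 1 = event, 0 = censored.
#' @param conf_level confidence level for the band.
#' @return object of class `survival_curve`: list with `times` (increasing,
#'   starting at 0), `survival`, `at_risk`, `lower`, `upper`,
#'   `censor_times`, `n`, `n_events`.
#' @export
km_estimate <- function(durations, event_flags, conf_level = 0.95) {
  if (length(durations) == 0) stop("km_estimate requires at least one subject")
  stopifnot(length(durations) == length(event_flags), all(durations >= 0))
  fit <- survival::survfit(
    survival::Surv(durations, event_flags) ~ 1,
    conf.type = "log-log", conf.int = conf_level)
  structure(list(times = c(0, fit$time),
                 survival = c(1, fit$surv),
                 at_risk = c(length(durations), fit$n.risk),
                 lower = c(1, fit$lower),
                 upper = c(1, fit$upper),
                 censor_times = fit$time[fit$n.censor > 0],
                 n = length(durations),
                 n_events = sum(event_flags)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  med <- survival_median(x)
  cat("<survival_curve> n=", x$n, ", events=", x$n_events,
      ", median=", ifelse(is.na(med), "not reached", paste0(med, " days")),
      "\n", sep = "")
  invisible(x)
}

#' Median survival time of a curve
#'
#' First time at which the estimate drops to 0.5 or below; `NA` if the curve
#' never does (median not reached).
#'
#' @param curve a `survival_curve`.
#' @return days, or `NA`.
#' @export
survival_median <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (length(idx) == 0) return(NA_real_)
  curve$times[idx[1]]
}

#' Survival rate at a landmark time
#'
#' Step-function value of the KM estimate at `t`, with the Greenwood log-log
#' confidence interval read from the curve's band. Asking beyond the last
#' observed time returns the last value with an extrapolation warning.
#'
#' @param curve a `survival_curve`.
#' @param t landmark time (days), `>= 0`.
#' @param warn_extrapolation warn when `t` exceeds the last observed time?
#' @return list `rate, ci_low, ci_high`.
#' @export
survival_rate_at <- function(curve, t, warn_extrapolation = TRUE) {
  stopifnot(t >= 0)
  last_t <- max(curve$times)
  if (t > last_t && warn_extrapolation) {
    warning("landmark time ", t, " beyond last observed time ", last_t,
            "; returning the last estimate", call. = FALSE)
  }
  idx <- max(which(curve$times <= t))
  list(rate = curve$survival[idx],
       ci_low = curve$lower[idx],
       ci_high = curve$upper[idx])
}

#' Two-group log-rank test
#'
#' Chi-square statistic on 1 degree of freedom comparing the survival
#' distributions of two groups.
#'
#' @param group_a,group_b data frames with columns `time`, `event`.
#' @return list `statistic`, `p_value`.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  if (sum(group_a$event) + sum(group_b$event) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  grp <- factor(rep(c("A", "B"), c(nrow(group_a), nrow(group_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p_value = unname(stats::pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Cox proportional-hazards ratio of group B versus group A
#'
#' Single binary covariate fit (Efron tie handling) with a Wald 95%
#' confidence interval. Complete separation (a group with no events after
#' all events of the other) yields an infinite bound.
#'
#' @param group_a,group_b data frames with columns `time`, `event`.
#' @param conf_level confidence level.
#' @return list `hr, ci_low, ci_high, coef, se`.
#' @export
cox_hazard_ratio <- function(group_a, group_b, conf_level = 0.95) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  n_events <- sum(group_a$event) + sum(group_b$event)
  if (n_events == 0) stop("cannot fit a hazard ratio with zero events")
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  grp <- factor(rep(c("A", "B"), c(nrow(group_a), nrow(group_b))),
                levels = c("A", "B"))
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ grp, ties = "efron"))
  beta <- unname(stats::coef(fit)[1])
  se <- unname(sqrt(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!is.finite(beta) || se > 100) {
    # separation: report the direction with an infinite bound
    hr <- exp(beta)
    return(list(hr = hr, ci_low = if (hr > 1) NA_real_ else 0,
                ci_high = if (hr > 1) Inf else NA_real_,
                coef = beta, se = se))
  }
  list(hr = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se), coef = beta, se = se)
}

#' Build a cohort by set algebra over tree nodes
#'
#' The scripted equivalent of drag-and-dropping treatment boxes: members are
#' the union of the added nodes' patients minus the union of the subtracted
#' nodes' patients (pure set difference — a subtracted node removes a
#' patient no matter which added node contributed it). Each member's anchor
#' is the start date of the treatment line of the node that contributed it;
#' a patient entering via several added nodes takes the anchor of the
#' shallowest one, with a warning.
#'
#' @param tree a `treatment_tree`.
#' @param add_paths list of label paths (character vectors) to add; a single
#'   path may be given directly.
#' @param subtract_paths list of label paths to subtract.
#' @param name cohort name.
#' @return object of class `cohort`: list with `name`, `members`, `anchors`
#'   (named `Date`), `anchor_depths` (named integer), `provenance`.
#' @export
cohort_from_nodes <- function(tree, add_paths, subtract_paths = list(),
                              name = "cohort") {
  norm <- function(p) if (is.character(p)) list(p) else p
  if (is.character(add_paths)) add_paths <- list(add_paths)
  if (is.character(subtract_paths)) subtract_paths <- list(subtract_paths)
  add_ids <- vapply(add_paths, function(p) find_node(tree, p), 1L)
  sub_ids <- if (length(subtract_paths) > 0)
    vapply(subtract_paths, function(p) find_node(tree, p), 1L) else integer(0)

  anchors <- stats::setNames(as.Date(character()), character())
  depths <- stats::setNames(integer(0), character())
  multi <- character(0)
  # shallowest node wins: process added nodes in order of increasing depth
  ord <- order(vapply(add_ids, function(i) tree$nodes[[i]]$depth, 1L))
  for (i in add_ids[ord]) {
    nd <- tree$nodes[[i]]
    if (nd$depth == 0) stop("the root cannot anchor a cohort")
    new <- setdiff(nd$patients, names(anchors))
    multi <- union(multi, intersect(nd$patients, names(anchors)))
    if (length(new) > 0) {
      anchors <- c(anchors, nd$anchors[new])
      depths <- c(depths, stats::setNames(rep(nd$depth, length(new)), new))
    }
  }
  if (length(multi) > 0) {
    warning("patient(s) entering via several nodes anchored at the ",
            "shallowest node: ", paste(multi, collapse = ", "), call. = FALSE)
  }
  removed <- unique(unlist(lapply(sub_ids, function(i)
    tree$nodes[[i]]$patients)))
  keep <- setdiff(names(anchors), removed)
  prov <- rbind(
    data.frame(path = vapply(add_paths, paste, "", collapse = ">"),
               op = "add", stringsAsFactors = FALSE),
    if (length(subtract_paths) > 0)
      data.frame(path = vapply(subtract_paths, paste, "", collapse = ">"),
                 op = "subtract", stringsAsFactors = FALSE))
  structure(list(name = name, members = keep,
                 anchors = anchors[keep], anchor_depths = depths[keep],
                 provenance = prov),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$name, ": ", length(x$members), " patients\n", sep = "")
  for (i in seq_len(nrow(x$provenance))) {
    cat("  ", ifelse(x$provenance$op[i] == "add", "+", "-"), " ",
        x$provenance$path[i], "\n", sep = "")
  }
  invisible(x)
}

#' Parse a cohort expression
#'
#' Mini-language for scripted cohort building:
#' `"PD1>CTLA4+PD1 + PD1>PD1 - adj:PD1"` is the union of the two paths minus
#' the adjuvant-PD1 node. `>` separates line labels within a path; `+` / `-`
#' (surrounded by whitespace) add or subtract node paths; `adj:` marks an
#' adjuvant label.
#'
#' @param expr expression string.
#' @return list with `add` and `subtract`, each a list of label paths.
#' @export
parse_cohort_expression <- function(expr) {
  expr <- trimws(expr)
  if (expr == "") stop("empty cohort expression")
  terms <- strsplit(expr, "\\s+[+-]\\s+")[[1]]
  ops_m <- gregexpr("\\s+([+-])\\s+", expr)[[1]]
  ops <- if (ops_m[1] == -1) character(0)
  else vapply(regmatches(expr, gregexpr("\\s+([+-])\\s+", expr))[[1]],
              function(s) gsub("\\s", "", s), "")
  ops <- c("+", ops)
  if (length(ops) != length(terms)) stop("malformed cohort expression: ", expr)
  paths <- lapply(terms, function(t) trimws(strsplit(t, ">")[[1]]))
  list(add = paths[ops == "+"], subtract = paths[ops == "-"])
}

#' Build a cohort from an expression string
#'
#' @param tree a `treatment_tree`.
#' @param expr cohort expression (see [parse_cohort_expression()]).
#' @param name cohort name.
#' @return a `cohort`.
#' @export
cohort_from_expression <- function(tree, expr, name = expr) {
  parsed <- parse_cohort_expression(expr)
  cohort_from_nodes(tree, parsed$add, parsed$subtract, name = name)
}

#' Progression-free survival time of a treatment line
#'
#' Time from the line's start to the earliest of (a) the first progression
#' assessment (`PD`; recurrence `RE` for adjuvant lines) on that line or a
#' later one, and (b) death — either counts as the event. Otherwise censored
#' at the last follow-up date. Death counts as a progression event even
#' without a recorded PD: the standard oncology PFS convention.
#'
#' @param patient_id patient identifier.
#' @param line treatment-line number (the anchoring line).
#' @param log an `event_log`.
#' @return list `time` (days), `event` (0/1).
#' @export
pfs_time <- function(patient_id, line, log) {
  ev <- log$events[log$events$patient_id == patient_id &
                     log$events$line == line, , drop = FALSE]
  if (nrow(ev) == 0) stop("patient ", patient_id, " has no line ", line)
  anchor <- ev$start[1]
  pt <- log$patients[log$patients$patient_id == patient_id, , drop = FALSE]
  rs <- log$responses[log$responses$patient_id == patient_id &
                        log$responses$line >= line &
                        log$responses$label %in% c("PD", "RE") &
                        !is.na(log$responses$date) &
                        log$responses$date >= anchor, , drop = FALSE]
  cand <- numeric(0)
  if (nrow(rs) > 0) cand <- c(cand, as.numeric(min(rs$date) - anchor))
  if (nrow(pt) == 1 && !is.na(pt$death_date))
    cand <- c(cand, as.numeric(pt$death_date - anchor))
  if (length(cand) > 0) {
    return(list(time = max(min(cand), 0), event = 1L))
  }
  list(time = max(as.numeric(pt$last_followup_date - anchor), 0), event = 0L)
}

# survival data (time, event) for a cohort under a given endpoint
.cohort_endpoint <- function(cohort, endpoint, log) {
  if (endpoint == "OS") {
    d <- os_times(cohort$anchors, log$patients)
    return(d)
  }
  rows <- lapply(cohort$members, function(pid) {
    line <- .node_line(log, pid, cohort$anchor_depths[[pid]])
    p <- pfs_time(pid, line, log)
    data.frame(patient_id = pid, time = p$time, event = p$event,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-cohort clinical summary: n, median age at anchor, sex ratio, BOR tally
.cohort_summary <- function(cohort, log) {
  idx <- match(cohort$members, log$patients$patient_id)
  birth <- log$patients$birth_date[idx]
  age <- as.numeric(cohort$anchors[cohort$members] - birth) / 365.25
  sex <- log$patients$sex[idx]
  bor <- stats::setNames(integer(8),
                         c("CR", "PR", "SD", "PD", "NE", "RE", "NR", "NE_adj"))
  for (pid in cohort$members) {
    depth <- cohort$anchor_depths[[pid]]
    line <- .node_line(log, pid, depth)
    ev <- log$events[log$events$patient_id == pid &
                       log$events$line == line, , drop = FALSE]
    if (identical(ev$setting[1], "adjuvant")) {
      lab <- recurrence_status(pid, line, log$responses)
      if (lab == "NE") lab <- "NE_adj"
    } else {
      lab <- best_overall_response(pid, line, log$responses)
    }
    bor[lab] <- bor[lab] + 1L
  }
  list(n = length(cohort$members),
       median_age_at_anchor = stats::median(age, na.rm = TRUE),
       sex_ratio = c(M = sum(sex == "M"), F = sum(sex == "F")),
       bor = bor[bor > 0 | names(bor) %in% c("CR", "PR", "SD", "PD", "NE")])
}

#' Compare two cohorts on an anchored survival endpoint
#'
#' Computes per-cohort Kaplan-Meier curves of the chosen endpoint (time zero
#' at each patient's own anchor), the two-group log-rank test, the Cox
#' hazard ratio of the second cohort versus the first with its Wald 95% CI,
#' landmark survival rates, and per-cohort clinical summaries (n, median age
#' at anchor, sex ratio, best-overall-response tally). Overlapping
#' membership triggers a warning listing the shared patients.
#'
#' @param cohort_a,cohort_b `cohort` objects.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param log the `event_log`.
#' @param landmark_days landmark time for survival rates (default 2 years).
#' @return object of class `cohort_comparison`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, endpoint = c("OS", "PFS"),
                            log, landmark_days = 730) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(cohort_a$members) > 0, length(cohort_b$members) > 0)
  shared <- intersect(cohort_a$members, cohort_b$members)
  if (length(shared) > 0) {
    warning("cohorts overlap on ", length(shared), " patient(s): ",
            paste(utils::head(shared, 10), collapse = ", "), call. = FALSE)
  }
  da <- .cohort_endpoint(cohort_a, endpoint, log)
  db <- .cohort_endpoint(cohort_b, endpoint, log)
  curve_a <- km_estimate(da$time, da$event)
  curve_b <- km_estimate(db$time, db$event)
  lr <- logrank_test(da, db)
  cx <- cox_hazard_ratio(da, db)
  lm_a <- suppressWarnings(survival_rate_at(curve_a, landmark_days))
  lm_b <- suppressWarnings(survival_rate_at(curve_b, landmark_days))
  res <- list(endpoint = endpoint,
              names = c(cohort_a$name, cohort_b$name),
              curves = stats::setNames(list(curve_a, curve_b),
                                       c(cohort_a$name, cohort_b$name)),
              data = stats::setNames(list(da, db),
                                     c(cohort_a$name, cohort_b$name)),
              logrank_statistic = lr$statistic,
              logrank_p = lr$p_value,
              hazard_ratio = cx$hr, hr_ci_low = cx$ci_low,
              hr_ci_high = cx$ci_high,
              landmark_days = landmark_days,
              landmark_estimates = stats::setNames(
                list(c(time = landmark_days, rate = lm_a$rate,
                       ci_low = lm_a$ci_low, ci_high = lm_a$ci_high),
                     c(time = landmark_days, rate = lm_b$rate,
                       ci_low = lm_b$ci_low, ci_high = lm_b$ci_high)),
                c(cohort_a$name, cohort_b$name)),
              summaries = stats::setNames(
                list(.cohort_summary(cohort_a, log),
                     .cohort_summary(cohort_b, log)),
                c(cohort_a$name, cohort_b$name)))
  class(res) <- "cohort_comparison"
  res
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison> ", x$endpoint, ": ", x$names[2], " vs ",
      x$names[1], "\n", sep = "")
  for (nm in x$names) {
    s <- x$summaries[[nm]]
    med <- survival_median(x$curves[[nm]])
    cat(sprintf("  %-28s n=%3d  median %s=%s days\n", nm, s$n, x$endpoint,
                ifelse(is.na(med), "NR", format(med))))
  }
  cat(sprintf("  HR (%s vs %s): %.2f (95%% CI %.2f to %.2f)\n",
              x$names[2], x$names[1], x$hazard_ratio, x$hr_ci_low,
              x$hr_ci_high))
  cat(sprintf("  log-rank chi-square: %.2f, p = %.3g\n",
              x$logrank_statistic, x$logrank_p))
  for (nm in x$names) {
    l <- x$landmark_estimates[[nm]]
    cat(sprintf("  %s at %d days, %s: %.0f%% (95%% CI %.0f to %.0f)\n",
                x$endpoint, x$landmark_days, nm, 100 * l[["rate"]],
                100 * l[["ci_low"]], 100 * l[["ci_high"]]))
  }
  invisible(x)
}

#' Export a cohort comparison as CSV tables
#'
#' Writes `<prefix>_stats.csv` (test statistics, HR, landmark rates,
#' summaries) and `<prefix>_curves.csv` (both KM step curves, long format).
#'
#' @param result a `cohort_comparison`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return paths of the written files, invisibly.
#' @export
comparison_to_csv <- function(result, dir, prefix = "comparison") {
  stats_rows <- list()
  for (nm in result$names) {
    s <- result$summaries[[nm]]
    l <- result$landmark_estimates[[nm]]
    stats_rows[[nm]] <- data.frame(
      cohort = nm, n = s$n,
      n_events = result$curves[[nm]]$n_events,
      median_days = survival_median(result$curves[[nm]]),
      median_age_at_anchor = round(s$median_age_at_anchor, 1),
      n_male = s$sex_ratio[["M"]], n_female = s$sex_ratio[["F"]],
      landmark_days = result$landmark_days,
      landmark_rate = l[["rate"]], landmark_ci_low = l[["ci_low"]],
      landmark_ci_high = l[["ci_high"]],
      bor = paste(names(s$bor), s$bor, sep = "=", collapse = ";"),
      stringsAsFactors = FALSE)
  }
  stats_df <- do.call(rbind, stats_rows)
  stats_df$endpoint <- result$endpoint
  stats_df$hazard_ratio <- result$hazard_ratio
  stats_df$hr_ci_low <- result$hr_ci_low
  stats_df$hr_ci_high <- result$hr_ci_high
  stats_df$logrank_statistic <- result$logrank_statistic
  stats_df$logrank_p <- result$logrank_p
  p1 <- file.path(dir, paste0(prefix, "_stats.csv"))
  utils::write.csv(stats_df, p1, row.names = FALSE)

  curve_rows <- lapply(result$names, function(nm) {
    cv <- result$curves[[nm]]
    data.frame(cohort = nm, time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk, lower = cv$lower, upper = cv$upper,
               stringsAsFactors = FALSE)
  })
  p2 <- file.path(dir, paste0(prefix, "_curves.csv"))
  utils::write.csv(do.call(rbind, curve_rows), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Plot the KM curves of a cohort comparison
#'
#' Base-graphics step plot with censoring ticks and the HR / log-rank
#' annotation.
#'
#' @param x a `cohort_comparison`.
#' @param col two colors.
#' @param xmax right limit in days (default the landmark horizon times 2.5).
#' @param ... passed to `plot`.
#' @export
plot.cohort_comparison <- function(x, col = c("#D55E00", "#0072B2"),
                                   xmax = NULL, ...) {
  if (is.null(xmax)) xmax <- max(vapply(x$curves, function(cv)
    max(cv$times), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "days since anchor",
                 ylab = paste0(x$endpoint, " probability"), ...)
  for (i in 1:2) {
    cv <- x$curves[[x$names[i]]]
    graphics::lines(stats::stepfun(cv$times[-1], cv$survival), do.points = FALSE,
                    col = col[i], lwd = 2)
    if (length(cv$censor_times) > 0) {
      s <- vapply(cv$censor_times, function(t)
        survival_rate_at(cv, t, warn_extrapolation = FALSE)$rate, 0)
      graphics::points(cv$censor_times, s, pch = 3, col = col[i], cex = 0.7)
    }
  }
  graphics::legend("topright", legend = x$names, col = col, lwd = 2, bty = "n")
  graphics::mtext(sprintf("HR %.2f (%.2f-%.2f), log-rank p=%.3g",
                          x$hazard_ratio, x$hr_ci_low, x$hr_ci_high,
                          x$logrank_p), side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}
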
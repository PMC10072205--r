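# Independent oracles, deliberately separate from the package's code paths:
# exhaustive prefix enumeration, a hand-written product-limit estimator, a
# hand-written log-rank statistic with its permutation null, and brute-force
# maximization of the Efron partial likelihood over a parameter grid.

# exhaustive (path, count) enumeration over all non-empty sequence prefixes
enumerate_prefixes <- function(seqs) {
  paths <- unlist(lapply(seqs, function(s) {
    if (length(s) == 0) return(character(0))
    vapply(seq_along(s), function(k) paste(s[1:k], collapse = ">"), "")
  }), use.names = FALSE)
  if (length(paths) == 0)
    return(data.frame(path = character(), n = integer()))
  tab <- table(paths)
  df <- data.frame(path = names(tab), n = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(df$path), , drop = FALSE]
}

# product-limit estimator from first principles
km_oracle <- function(time, event) {
  ot <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ot))
  for (i in seq_along(ot)) {
    n_at_risk <- sum(time >= ot[i])
    d <- sum(time == ot[i] & event == 1)
    s <- s * (1 - d / n_at_risk)
    surv[i] <- s
  }
  list(times = ot, surv = surv)
}

# two-group log-rank chi-square from first principles
logrank_stat_oracle <- function(time, event, grp) {
  ot <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ot) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# permutation p-value for the log-rank statistic
logrank_perm_p <- function(time, event, grp, n_perm = 10000) {
  obs <- logrank_stat_oracle(time, event, grp)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (logrank_stat_oracle(time, event, sample(grp)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / n_perm
}

# Efron partial log-likelihood for a single binary covariate
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

# brute-force argmax of the partial likelihood: coarse grid, then a fine
# grid at 1e-5 resolution around the coarse optimum
cox_grid_oracle <- function(time, event, x) {
  coarse <- seq(-4, 4, by = 0.01)
  ll <- vapply(coarse, efron_loglik, 0, time = time, event = event, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, efron_loglik, 0, time = time, event = event, x = x)
  fine[which.max(llf)]
}
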
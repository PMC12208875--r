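# Independent brute-force oracles used to verify the analytical machinery.
# These deliberately use naive loops (or survival::survdiff) rather than the
# package's own vectorized implementations.

# two-group log-rank by explicit O-E/V tabulation over event times
oracle_logrank <- function(time, event, group1) {
  dt <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group1)
    dj <- sum(time == t & event)
    d1j <- sum(time == t & event & group1)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# pairwise-comparison AUC
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand product-limit estimator at event times
oracle_km <- function(time, event) {
  dt <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = dt, survival = NA_real_)
  for (i in seq_along(dt)) {
    n <- sum(time >= dt[i])
    d <- sum(time == dt[i] & event)
    s <- s * (1 - d / n)
    out$survival[i] <- s
  }
  out
}

# exhaustive single-threshold scan via survival::survdiff
oracle_best_single <- function(values, surv, candidates, min_group_size) {
  best <- list(p = Inf, thr = NA)
  for (t in sort(candidates)) {
    g <- values >= t
    if (sum(g) < min_group_size || sum(!g) < min_group_size) next
    sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
    p <- pchisq(sd$chisq, 1, lower.tail = FALSE)
    if (p < best$p) best <- list(p = p, thr = t)
  }
  best
}

# exhaustive pairwise scan: every threshold pair, every quadrant vs the rest
oracle_best_pair <- function(v1, v2, surv, c1, c2, min_group_size) {
  n <- length(v1)
  best <- list(p = Inf, t1 = NA, t2 = NA, q = NA)
  for (t1 in sort(c1)) for (t2 in sort(c2)) {
    a <- v1 >= t1; b <- v2 >= t2
    quads <- list(Q1 = a & !b, Q2 = a & b, Q3 = !a & !b, Q4 = !a & b)
    for (qn in names(quads)) {
      g <- quads[[qn]]
      if (sum(g) < min_group_size || n - sum(g) < min_group_size) next
      sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
      p <- pchisq(sd$chisq, 1, lower.tail = FALSE)
      if (p < best$p) best <- list(p = p, t1 = t1, t2 = t2, q = qn)
    }
  }
  best
}

# random survival fixture with both events and censoring
make_surv <- function(n, seed) {
  set.seed(seed)
  data.frame(time = sample(1:40, n, replace = TRUE),
             event = runif(n) < 0.7)
}

# minimal hand-built timeline satisfying every inclusion criterion
eligible_timeline <- function(pid, extra = NULL) {
  ev <- data.frame(
    patient_id = pid,
    day_offset = c(-400L, -200L, -20L, 0L, 90L, 365L),
    kind = c("pv_diagnosis", "lab", "lab", "hu_prescription",
             "hu_prescription", "lab"),
    analyte = c(NA, "HCT", "HCT", NA, NA, "HCT"),
    value = c(NA, 44, 44, NA, NA, 42),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) ev <- rbind(ev, extra)
  ev <- ev[order(ev$day_offset), ]
  rownames(ev) <- NULL
  ev
}

eligible_patient <- function(pid, age = 60) {
  data.frame(patient_id = pid, age_at_index = age, stringsAsFactors = FALSE)
}
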
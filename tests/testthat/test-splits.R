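surv_with_signal <- function(n, seed) {
  # survival fixture whose hazard depends on a continuous marker
  set.seed(seed)
  x <- rnorm(n, 10, 2)
  risk <- plogis((x - 10))
  event <- runif(n) < risk
  time <- ifelse(event, sample(180:270, n, TRUE), 365L)
  list(x = x, surv = data.frame(time = time, event = event))
}

test_that("a single-candidate grid returns that threshold", {
  f <- surv_with_signal(40, 1)
  s <- best_single_split(f$x, f$surv, candidates = 10)
  expect_equal(s$threshold, 10)
  expect_equal(sum(f$x >= 10), unname(s$group_sizes["above"]))
})

test_that("single-threshold scan equals an exhaustive survdiff scan", {
  for (seed in 1:4) {
    f <- surv_with_signal(50, seed)
    rule <- split_grid_rule(max_candidates = 1000L, min_group_size = 5L)
    s <- best_single_split(f$x, f$surv, rule)
    o <- oracle_best_single(f$x, f$surv, candidate_thresholds(f$x, rule), 5L)
    expect_equal(s$p_value, o$p, tolerance = 1e-10)
    expect_equal(s$threshold, o$thr)
  }
})

test_that("constant variables are rejected", {
  f <- surv_with_signal(30, 2)
  expect_error(best_single_split(rep(1, 30), f$surv), "constant")
  expect_error(best_pair_split(rep(1, 30), f$x, f$surv), "constant")
})

test_that("pairwise scan equals an exhaustive brute-force scan over pairs and quadrants", {
  for (seed in 1:3) {
    f <- surv_with_signal(30, 10 + seed)
    set.seed(1000 + seed)
    y <- rnorm(30, 5, 1)
    rule <- split_grid_rule(max_candidates = 8L, min_group_size = 3L)
    c1 <- candidate_thresholds(f$x, rule)
    c2 <- candidate_thresholds(y, rule)
    ps <- best_pair_split(f$x, y, f$surv, rule)
    o <- oracle_best_pair(f$x, y, f$surv, c1, c2, 3L)
    expect_equal(ps$p_value, o$p, tolerance = 1e-10)
    expect_equal(ps$t1, o$t1)
    expect_equal(ps$t2, o$t2)
    expect_equal(ps$quadrant, o$q)
  }
})

test_that("pairwise scan with a degenerate second grid reduces to the single scan", {
  f <- surv_with_signal(60, 5)
  set.seed(6); y <- rnorm(60)
  rule <- split_grid_rule(min_group_size = 5L)
  s <- best_single_split(f$x, f$surv, rule)
  # the only candidate for y is its minimum: every patient is "high" on y
  ps <- best_pair_split(f$x, y, f$surv, rule,
                        candidates1 = s$candidates, candidates2 = min(y))
  expect_equal(ps$p_value, s$p_value)
  expect_equal(ps$t1, s$threshold)
})

test_that("refining the candidate grid never increases the minimum p", {
  f <- surv_with_signal(80, 7)
  rule <- split_grid_rule(min_group_size = 5L)
  coarse <- candidate_thresholds(f$x, split_grid_rule(max_candidates = 6L))
  fine <- sort(unique(c(coarse, candidate_thresholds(f$x, rule))))
  p_coarse <- best_single_split(f$x, f$surv, rule, candidates = coarse)$p_value
  p_fine <- best_single_split(f$x, f$surv, rule, candidates = fine)$p_value
  expect_lte(p_fine, p_coarse)
})

test_that("the omnibus pair test matches a direct 4-group log-rank", {
  f <- surv_with_signal(60, 8)
  set.seed(9); y <- rnorm(60, 5, 1)
  t1 <- median(f$x); t2 <- median(y)
  ps <- best_pair_split(f$x, y, f$surv,
                        rule = split_grid_rule(min_group_size = 3L),
                        candidates1 = t1, candidates2 = t2, omnibus = TRUE)
  g <- factor(paste0(f$x >= t1, y >= t2))
  sd <- survival::survdiff(survival::Surv(f$surv$time, f$surv$event) ~ g)
  expect_equal(ps$statistic, sd$chisq, tolerance = 1e-10)
  expect_equal(ps$p_value, pchisq(sd$chisq, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(is.na(ps$quadrant))
})

test_that("synergy score follows its definition and domain", {
  expect_equal(synergy_score(0.2, 0.3, 0.06), 1)          # independence
  expect_equal(synergy_score(1e-3, 1e-2, 1e-6), 10)
  # identity: synergy * p12 == p1 * p2 at full floating precision
  p1 <- 2.74e-9; p2 <- 6.82e-3; p12 <- 4.67e-15
  expect_identical(synergy_score(p1, p2, p12) * p12, p1 * p2)
  expect_error(synergy_score(0, 0.5, 0.1), "0, 1")
  expect_error(synergy_score(0.5, 1.2, 0.1), "0, 1")
  expect_error(synergy_score(0.5, 0.5, -1), "0, 1")
})

test_that("quadrant enrichment counts, undefined quadrants and conservation", {
  # 10 patients, 5 resistant; Q1 (x high, y low) holds 2, both resistant
  x <- c(2, 2, 1, 1, 1, 1, 2, 2, 1, 1)
  y <- c(1, 1, 2, 2, 1, 1, 2, 2, 1, 2)
  r <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  e <- quadrant_enrichment(x, y, 2, 2, r)
  expect_equal(e$n, c(2L, 2L, 3L, 3L))
  expect_equal(e$enrichment[1], (2 / 2) / (5 / 10))
  # size-weighted mean of enrichments is exactly 1
  expect_equal(sum(e$n * e$enrichment) / sum(e$n), 1)

  # empty quadrant is undefined
  e2 <- quadrant_enrichment(c(1, 1, 2, 2), c(2, 2, 2, 2), 2, 2,
                            c(TRUE, FALSE, TRUE, FALSE))
  expect_true(is.na(e2$enrichment[e2$quadrant == "Q1"]))
  expect_error(quadrant_enrichment(x, y, 2, 2, rep(FALSE, 10)), "prevalence")
})

test_that("enrichment is ~1 everywhere when resistance ignores both variables", {
  set.seed(21)
  x <- rnorm(4000); y <- rnorm(4000); r <- runif(4000) < 0.5
  e <- quadrant_enrichment(x, y, 0, 0, r)
  expect_true(all(abs(e$enrichment - 1) < 0.1))
})

test_that("rank_pairs evaluates every pair and sorts coherently", {
  set.seed(31)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, paste0("v", 1:5))))
  surv <- data.frame(time = ifelse(runif(n) < 0.5, sample(180:270, n, TRUE), 365),
                     event = runif(n) < 0.5)
  rp <- rank_pairs(X, surv, single_rule = split_grid_rule(max_candidates = 10),
                   pair_rule = split_grid_rule(max_candidates = 6))
  expect_equal(nrow(rp), choose(5, 2))
  expect_true(all(diff(rp$synergy) <= 1e-12))
  expect_equal(rp$synergy * rp$p12, rp$p1 * rp$p2, tolerance = 1e-12)
  assoc <- attr(rp, "associations")
  expect_true(all(diff(assoc$p12) >= -1e-15))
  expect_true(attr(rp, "n_tests") > 0)
})
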
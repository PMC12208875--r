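#' Candidate-threshold rule for maximally selected log-rank scans
#'
#' The default candidate grid for a variable is the set of its unique
#' observed values clipped to the 10th-90th percentile range; to keep the
#' two-dimensional pair scan tractable the grid is thinned to at most
#' `max_candidates` quantile-spaced values (the thinning is inactive on the
#' small cohorts used for oracle checks). Splits leaving fewer than
#' `min_group_size` patients on either side are not evaluated.
#'
#' @param clip numeric length-2: percentile range of candidate thresholds.
#' @param max_candidates maximum number of candidate thresholds per variable.
#' @param min_group_size minimum patients on each side of a split.
#' @return list of class `grid_rule`.
#' @export
split_grid_rule <- function(clip = c(0.1, 0.9), max_candidates = 50L,
                            min_group_size = 10L) {
  stopifnot(length(clip) == 2L, clip[1] >= 0, clip[2] <= 1, clip[1] < clip[2],
            max_candidates >= 1L, min_group_size >= 1L)
  structure(list(clip = clip, max_candidates = as.integer(max_candidates),
                 min_group_size = as.integer(min_group_size)),
            class = "grid_rule")
}

#' @rdname split_grid_rule
#' @param x numeric vector of observed values.
#' @param rule a `grid_rule`.
#' @export
candidate_thresholds <- function(x, rule = split_grid_rule()) {
  v <- sort(unique(x[is.finite(x)]))
  if (length(v) < 2L)
    stop("no valid split: variable is constant", call. = FALSE)
  q <- quantile(x, rule$clip, na.rm = TRUE, names = FALSE)
  vc <- v[v >= q[1] & v <= q[2]]
  if (length(vc) == 0L) vc <- v  # clipping removed everything: tiny samples
  if (length(vc) > rule$max_candidates)
    vc <- vc[unique(round(seq(1, length(vc), length.out = rule$max_candidates)))]
  vc
}

check_survival <- function(survival, n) {
  if (!is.data.frame(survival) || !all(c("time", "event") %in% names(survival)))
    stop("survival needs columns 'time' and 'event'", call. = FALSE)
  if (nrow(survival) != n)
    stop("survival and variable lengths differ", call. = FALSE)
  if (any(survival$time <= 0))
    stop("survival times must be positive", call. = FALSE)
  invisible(survival)
}

#' Best single-variable threshold by maximal log-rank significance
#'
#' Evaluates the two-group log-rank test at every candidate threshold
#' (patients with `value >= threshold` versus the rest) and returns the
#' threshold minimizing the p-value, i.e. the maximally selected cutpoint.
#' Ties are broken toward the smaller threshold.
#'
#' @param values numeric vector, one value per patient; `NA` patients are
#'   dropped from this scan.
#' @param survival data.frame with `time` and `event` per patient.
#' @param rule a [split_grid_rule()].
#' @param candidates optional explicit candidate thresholds, overriding the
#'   rule's grid.
#' @return object of class `split_result`: `threshold`, `p_value`,
#'   `statistic`, `group_sizes` (above/below), `candidates`.
#' @export
best_single_split <- function(values, survival, rule = split_grid_rule(),
                              candidates = NULL) {
  check_survival(survival, length(values))
  ok <- !is.na(values)
  values <- values[ok]
  survival <- survival[ok, , drop = FALSE]
  cand <- if (is.null(candidates)) candidate_thresholds(values, rule)
          else sort(unique(candidates))
  if (length(unique(values)) < 2L)
    stop("no valid split: variable is constant", call. = FALSE)
  G <- outer(values, cand, ">=")
  nA <- colSums(G)
  valid <- nA >= rule$min_group_size & (length(values) - nA) >= rule$min_group_size
  if (length(cand) == 1L) valid <- nA >= 1 & (length(values) - nA) >= 1
  if (!any(valid))
    stop("no valid split: all candidate thresholds leave a group below min_group_size",
         call. = FALSE)
  r <- batch_logrank(survival$time, survival$event, G[, valid, drop = FALSE])
  best <- which.min(r$p_value)             # first minimum = smallest threshold
  thr <- cand[valid][best]
  structure(list(threshold = thr,
                 p_value = r$p_value[best],
                 statistic = r$statistic[best],
                 group_sizes = c(above = unname(r$nA[best]),
                                 below = length(values) - unname(r$nA[best])),
                 candidates = cand),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Best split: value >= %g  (log-rank p = %.3g, %d vs %d patients)\n",
              x$threshold, x$p_value, x$group_sizes["above"], x$group_sizes["below"]))
  invisible(x)
}

quadrant_names <- c("Q1", "Q2", "Q3", "Q4")  # Q1 hi/lo, Q2 hi/hi, Q3 lo/lo, Q4 lo/hi

# indicator matrix (n x 4) of the four threshold quadrants; "high" = >= t
quadrant_matrix <- function(v1, v2, t1, t2) {
  a <- v1 >= t1
  b <- v2 >= t2
  cbind(Q1 = a & !b, Q2 = a & b, Q3 = !a & !b, Q4 = !a & b)
}

#' Best pairwise threshold split
#'
#' Scans the two-dimensional grid of threshold pairs. For every pair the four
#' quadrants ("high" = value >= threshold) are formed and each sufficiently
#' populated quadrant is compared against the remaining patients with a
#' two-group log-rank test; the overall best pairwise split is the
#' (threshold pair, quadrant) combination with the smallest p-value.
#' Ties are broken deterministically: smaller first threshold, then smaller
#' second threshold, then quadrant order Q1 < Q2 < Q3 < Q4 (Q1 =
#' var1-high/var2-low, Q2 = both high, Q3 = both low, Q4 = var1-low/var2-high).
#'
#' @param values1,values2 numeric vectors, one value per patient; patients
#'   with `NA` in either are dropped.
#' @param survival data.frame with `time` and `event` per patient.
#' @param rule a [split_grid_rule()]; the default pair rule thins each axis
#'   to at most 20 candidates.
#' @param candidates1,candidates2 optional explicit grids.
#' @param omnibus if `TRUE`, use a 4-group omnibus log-rank test (3 degrees
#'   of freedom, all populated quadrants jointly) at each threshold pair
#'   instead of the default quadrant-vs-rest contrast; the returned
#'   `quadrant` is then `NA`.
#' @return object of class `pair_split`: `t1`, `t2`, `p_value`, `statistic`,
#'   `quadrant` (which quadrant achieved the minimum), `group_sizes`,
#'   `candidates1`, `candidates2`, `n_tests`.
#' @export
best_pair_split <- function(values1, values2, survival,
                            rule = split_grid_rule(max_candidates = 20L),
                            candidates1 = NULL, candidates2 = NULL,
                            omnibus = FALSE) {
  check_survival(survival, length(values1))
  if (length(values1) != length(values2))
    stop("values1 and values2 lengths differ", call. = FALSE)
  ok <- !is.na(values1) & !is.na(values2)
  values1 <- values1[ok]; values2 <- values2[ok]
  survival <- survival[ok, , drop = FALSE]
  n <- length(values1)
  for (v in list(values1, values2))
    if (length(unique(v)) < 2L)
      stop("no valid split: variable is constant", call. = FALSE)
  c1 <- if (is.null(candidates1)) candidate_thresholds(values1, rule)
        else sort(unique(candidates1))
  c2 <- if (is.null(candidates2)) candidate_thresholds(values2, rule)
        else sort(unique(candidates2))
  B <- outer(values2, c2, ">=")
  mgs <- rule$min_group_size

  if (omnibus)
    return(pair_split_omnibus(values1, values2, survival, c1, c2, mgs))

  best <- list(p = Inf, stat = NA_real_, t1 = NA_real_, t2 = NA_real_,
               q = NA_integer_, nA = NA_integer_)
  n_tests <- 0L
  for (i in seq_along(c1)) {
    a <- values1 >= c1[i]
    ## columns ordered (quadrant within t2) so index -> (t2, quadrant)
    G <- matrix(FALSE, n, 4L * length(c2))
    for (j in seq_along(c2)) {
      b <- B[, j]
      G[, 4L * (j - 1L) + 1L] <- a & !b
      G[, 4L * (j - 1L) + 2L] <- a & b
      G[, 4L * (j - 1L) + 3L] <- !a & !b
      G[, 4L * (j - 1L) + 4L] <- !a & b
    }
    sz <- colSums(G)
    valid <- sz >= mgs & (n - sz) >= mgs
    if (!any(valid)) next
    r <- batch_logrank(survival$time, survival$event, G[, valid, drop = FALSE])
    n_tests <- n_tests + sum(valid)
    p <- rep(Inf, ncol(G)); p[valid] <- r$p_value
    st <- rep(NA_real_, ncol(G)); st[valid] <- r$statistic
    k <- which.min(p)                      # first = smallest t2, then Q order
    if (p[k] < best$p) {
      best <- list(p = p[k], stat = st[k], t1 = c1[i],
                   t2 = c2[(k - 1L) %/% 4L + 1L],
                   q = (k - 1L) %% 4L + 1L, nA = sz[k])
    }
  }
  if (!is.finite(best$p))
    stop("no valid pairwise split: every quadrant is below min_group_size",
         call. = FALSE)
  structure(list(t1 = best$t1, t2 = best$t2,
                 p_value = best$p, statistic = best$stat,
                 quadrant = quadrant_names[best$q],
                 group_sizes = c(quadrant = unname(best$nA),
                                 rest = n - unname(best$nA)),
                 candidates1 = c1, candidates2 = c2, n_tests = n_tests),
            class = "pair_split")
}

# omnibus variant: all populated quadrants compared jointly per threshold
# pair (chi-square with populated-quadrants - 1 df, via survival::survdiff)
pair_split_omnibus <- function(values1, values2, survival, c1, c2, mgs) {
  n <- length(values1)
  best <- list(p = Inf, stat = NA_real_, t1 = NA_real_, t2 = NA_real_,
               nA = NA_integer_)
  n_tests <- 0L
  for (t1 in c1) for (t2 in c2) {
    Q <- quadrant_matrix(values1, values2, t1, t2)
    sz <- colSums(Q)
    pop <- sz > 0
    if (sum(pop) < 2L || any(sz[pop] < mgs)) next
    g <- factor(Q %*% (1:4), levels = which(pop))
    sd <- survival::survdiff(
      survival::Surv(survival$time, survival$event) ~ g)
    p <- pchisq(sd$chisq, df = sum(pop) - 1L, lower.tail = FALSE)
    n_tests <- n_tests + 1L
    if (p < best$p)
      best <- list(p = p, stat = sd$chisq, t1 = t1, t2 = t2, nA = max(sz))
  }
  if (!is.finite(best$p))
    stop("no valid pairwise split: every quadrant is below min_group_size",
         call. = FALSE)
  structure(list(t1 = best$t1, t2 = best$t2,
                 p_value = best$p, statistic = best$stat,
                 quadrant = NA_character_,
                 group_sizes = c(quadrant = unname(best$nA),
                                 rest = n - unname(best$nA)),
                 candidates1 = c1, candidates2 = c2, n_tests = n_tests),
            class = "pair_split")
}

#' @export
print.pair_split <- function(x, ...) {
  cat(sprintf("Best pairwise split: t1 = %g, t2 = %g, quadrant %s (log-rank p = %.3g)\n",
              x$t1, x$t2, x$quadrant, x$p_value))
  invisible(x)
}

#' Multiplicative synergy score of a variable pair
#'
#' `synergy_score(p1, p2, p12)` returns `(p1 * p2) / p12`: the ratio of the
#' expected combined significance under independence (the product of the two
#' best single-variable log-rank p-values) to the observed best pairwise
#' p-value. Values above 1 indicate super-multiplicative, synergistic
#' significance of the pair.
#'
#' @param p1,p2 best single-split p-values of the two variables, in `(0, 1]`.
#' @param p12 best pairwise-split p-value, in `(0, 1]`.
#' @return numeric synergy score.
#' @examples
#' synergy_score(2.74e-9, 6.82e-3, 4.67e-15)  # ~ 4001
#' @export
synergy_score <- function(p1, p2, p12) {
  for (p in list(p1 = p1, p2 = p2, p12 = p12))
    if (!is.numeric(p) || any(p <= 0) || any(p > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
  (p1 * p2) / p12
}

#' Quadrant enrichment of resistant patients
#'
#' For the four quadrants defined by two thresholds ("high" = value >=
#' threshold), the enrichment of a quadrant is the resistant-patient
#' proportion inside the quadrant divided by the cohort-wide proportion.
#' Empty quadrants have undefined (`NA`) enrichment. When all quadrants are
#' non-empty the size-weighted mean of the enrichments is exactly 1.
#'
#' @param values1,values2 numeric vectors per patient.
#' @param t1,t2 thresholds for `values1` and `values2`.
#' @param resistant logical vector per patient; must contain at least one
#'   `TRUE` (otherwise the cohort prevalence is zero and enrichment is
#'   undefined everywhere).
#' @return data.frame with one row per quadrant (`Q1` var1-high/var2-low,
#'   `Q2` both-high, `Q3` both-low, `Q4` var1-low/var2-high): `n`,
#'   `n_resistant`, `enrichment`.
#' @export
quadrant_enrichment <- function(values1, values2, t1, t2, resistant) {
  stopifnot(length(values1) == length(values2),
            length(values1) == length(resistant))
  resistant <- as.logical(resistant)
  prev <- mean(resistant)
  if (!any(resistant))
    stop("no resistant patients: enrichment undefined (prevalence zero)",
         call. = FALSE)
  Q <- quadrant_matrix(values1, values2, t1, t2)
  nq <- colSums(Q)
  rq <- colSums(Q & resistant)
  data.frame(quadrant = quadrant_names,
             n = as.integer(nq),
             n_resistant = as.integer(rq),
             enrichment = ifelse(nq > 0, (rq / nq) / prev, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan all pairs of top-ranked variables for synergistic threshold splits
#'
#' Computes the best single-variable split for each feature once, then for
#' every unordered pair the best pairwise split, the synergy score
#' \eqn{S_{ab} = (P_a P_b) / P_{ab}}, and the quadrant enrichment of
#' resistant patients at the best thresholds.
#'
#' @param feature_table data.frame of numeric feature columns (one row per
#'   patient).
#' @param survival data.frame with `time` and `event` per patient; `event`
#'   doubles as the resistance flag for enrichment.
#' @param features character vector of feature columns to scan (>= 2);
#'   default: all numeric columns.
#' @param single_rule,pair_rule grid rules for the single and pairwise scans.
#' @return object of class `synergy_table`: a data.frame of pairs sorted by
#'   synergy (descending) with columns `var1`, `var2`, `p1`, `p2`,
#'   `expected_p`, `p12`, `synergy`, `t1`, `t2`, `quadrant`,
#'   `enrichment_Q1..Q4`; attributes `singles` (per-variable best splits) and
#'   `associations` (pairs sorted by `p12`, the pair-association table) and
#'   `n_tests` (total log-rank evaluations, for post-hoc multiplicity
#'   adjustment).
#' @export
rank_pairs <- function(feature_table, survival,
                       features = NULL,
                       single_rule = split_grid_rule(),
                       pair_rule = split_grid_rule(max_candidates = 20L)) {
  if (is.null(features))
    features <- names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  if (length(features) < 2L)
    stop("need at least two features to scan pairs", call. = FALSE)
  check_survival(survival, nrow(feature_table))

  singles <- list()
  for (f in features) {
    s <- tryCatch(best_single_split(feature_table[[f]], survival, single_rule),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning("feature '", f, "' has no valid split; dropped from pair scan",
              call. = FALSE)
    } else singles[[f]] <- s
  }
  feats <- names(singles)
  if (length(feats) < 2L)
    stop("fewer than two features admit a valid split", call. = FALSE)

  combos <- utils::combn(feats, 2L)
  n_tests <- sum(vapply(singles, function(s) length(s$candidates), integer(1)))
  rows <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    f1 <- combos[1L, k]; f2 <- combos[2L, k]
    ps <- best_pair_split(feature_table[[f1]], feature_table[[f2]], survival,
                          rule = pair_rule)
    n_tests <- n_tests + ps$n_tests
    enr <- quadrant_enrichment(feature_table[[f1]], feature_table[[f2]],
                               ps$t1, ps$t2, as.logical(survival$event))
    p1 <- singles[[f1]]$p_value
    p2 <- singles[[f2]]$p_value
    rows[[k]] <- data.frame(
      var1 = f1, var2 = f2, p1 = p1, p2 = p2,
      expected_p = p1 * p2, p12 = ps$p_value,
      synergy = synergy_score(p1, p2, ps$p_value),
      t1 = ps$t1, t2 = ps$t2, quadrant = ps$quadrant,
      enrichment_Q1 = enr$enrichment[1], enrichment_Q2 = enr$enrichment[2],
      enrichment_Q3 = enr$enrichment[3], enrichment_Q4 = enr$enrichment[4],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$synergy, out$var1, out$var2), ]
  rownames(out) <- NULL
  singles_df <- data.frame(
    variable = feats,
    threshold = vapply(singles, function(s) s$threshold, numeric(1)),
    p_value = vapply(singles, function(s) s$p_value, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  singles_df <- singles_df[order(singles_df$p_value), ]
  rownames(singles_df) <- NULL
  assoc <- out[order(out$p12), c("var1", "var2", "p12", "t1", "t2")]
  rownames(assoc) <- NULL
  structure(out, singles = singles_df, associations = assoc,
            n_tests = n_tests, class = c("synergy_table", "data.frame"))
}

#' @export
print.synergy_table <- function(x, n = 10L, ...) {
  cat(sprintf("Pairwise synergy scan: %d pairs (%d log-rank tests performed)\n",
              nrow(x), attr(x, "n_tests")))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("var1", "var2", "p12", "synergy", "t1", "t2", "quadrant")]
  df$p12 <- signif(df$p12, 3)
  df$synergy <- signif(df$synergy, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
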
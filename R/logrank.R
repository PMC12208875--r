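## Batch two-group log-rank engine.
##
## The maximally selected threshold scans below evaluate the log-rank
## statistic for thousands of candidate dichotomizations of the same cohort.
## All of them share the event-time tabulation, so the O-E/V quantities are
## computed for many group-indicator columns at once with two matrix
## products. Cross-checked in the test suite against survival::survdiff and
## a loop-based tabulation oracle.

# time, event: per-patient follow-up; G: n x K matrix (group-A indicators).
# Returns list(statistic, p_value, nA): vectors of length K.
batch_logrank <- function(time, event, G) {
  G <- as.matrix(G) * 1
  n <- length(time)
  stopifnot(nrow(G) == n, length(event) == n)
  dt <- sort(unique(time[event > 0]))
  if (length(dt) == 0L) stop("no events: log-rank undefined", call. = FALSE)
  Y <- outer(dt, time, "<=") * 1          # at risk just before each event time
  D <- outer(dt, time, "==") * matrix(event * 1, length(dt), n, byrow = TRUE)
  nj <- rowSums(Y)
  dj <- rowSums(D)
  n1 <- Y %*% G
  d1 <- D %*% G
  O <- colSums(d1)
  E <- colSums(n1 * (dj / nj))
  hyper <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
  frac <- n1 / nj
  V <- colSums(hyper * frac * (1 - frac))
  chisq <- ifelse(V > 0, (O - E)^2 / V, 0)
  list(statistic = as.numeric(chisq),
       p_value = pchisq(as.numeric(chisq), df = 1, lower.tail = FALSE),
       nA = colSums(G))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 degree of freedom) comparing the
#' time-to-event distributions of two groups, with the p-value from the
#' upper chi-square tail. Symmetric in group order.
#'
#' @param groupA,groupB data.frames with numeric column `time` (> 0, days to
#'   event or censoring) and logical/0-1 column `event`.
#' @return list with `statistic` (chi-square) and `p_value`.
#' @examples
#' a <- data.frame(time = c(2, 4, 6, 8), event = c(TRUE, TRUE, FALSE, TRUE))
#' b <- data.frame(time = c(5, 7, 9, 11), event = c(TRUE, FALSE, TRUE, TRUE))
#' logrank_test(a, b)
#' @export
logrank_test <- function(groupA, groupB) {
  for (g in list(groupA, groupB)) {
    if (!is.data.frame(g) || !all(c("time", "event") %in% names(g)))
      stop("each group needs columns 'time' and 'event'", call. = FALSE)
    if (nrow(g) == 0L) stop("empty group: log-rank undefined", call. = FALSE)
    if (any(g$time <= 0)) stop("survival times must be positive", call. = FALSE)
  }
  time <- c(groupA$time, groupB$time)
  event <- c(as.logical(groupA$event), as.logical(groupB$event))
  if (!any(event)) stop("no events: log-rank undefined", call. = FALSE)
  G <- matrix(rep(c(1, 0), c(nrow(groupA), nrow(groupB))), ncol = 1)
  r <- batch_logrank(time, event, G)
  list(statistic = r$statistic[1], p_value = r$p_value[1])
}
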
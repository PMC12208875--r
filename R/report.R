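#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the probability of remaining free of
#' hydroxyurea resistance, via [survival::survfit()]. With censored-only
#' data the curve is constant at 1.
#'
#' @param survival data.frame with `time` (> 0) and `event` per patient.
#' @return object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `survival` (starts at 1, non-increasing).
#' @export
km_curve <- function(survival) {
  if (is.null(survival) || nrow(survival) == 0L)
    stop("empty survival data", call. = FALSE)
  if (any(survival$time <= 0))
    stop("survival times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, as.logical(event)) ~ 1,
                           data = survival)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, final S(t) = %.3f\n",
              nrow(x), x$survival[nrow(x)]))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
                 xlab = "days since index", ylab = "resistance-free probability",
                 ylim = c(0, 1), main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Two-threshold RDW/HGB risk rule
#'
#' The fixed two-level decision rule distilled from the pairwise synergy
#' analysis: red cell distribution width (RDW, %) and hemoglobin (HGB, g/dL)
#' thresholds partition patients into four quadrants; the high-RDW /
#' low-HGB quadrant carries the highest risk of hydroxyurea resistance and
#' the low-RDW / low-HGB quadrant the lowest.
#'
#' @param rdw_threshold RDW threshold in % (default 17).
#' @param hgb_threshold HGB threshold in g/dL (default 15.5).
#' @return object of class `risk_rule`.
#' @export
risk_rule <- function(rdw_threshold = 17, hgb_threshold = 15.5) {
  if (rdw_threshold <= 0 || hgb_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(rdw_threshold = rdw_threshold, hgb_threshold = hgb_threshold,
                 risk = c(Q1 = "high", Q2 = "intermediate",
                          Q3 = "lowest", Q4 = "intermediate")),
            class = "risk_rule")
}

#' Classify a patient into an RDW/HGB risk quadrant
#'
#' Quadrants ("high" = value at or above its threshold): Q1 = high RDW, low
#' HGB (highest risk); Q2 = both high; Q3 = both low (lowest risk);
#' Q4 = low RDW, high HGB. Vectorized.
#'
#' @param rdw red cell distribution width, % (> 0).
#' @param hgb hemoglobin, g/dL (> 0).
#' @param rule a [risk_rule()].
#' @return data.frame with `quadrant` and `risk` per patient.
#' @examples
#' classify_quadrant(c(18, 16.9, 17), c(15.0, 15.0, 15.5))
#' @export
classify_quadrant <- function(rdw, hgb, rule = risk_rule()) {
  if (any(!is.finite(rdw)) || any(!is.finite(hgb)) || any(rdw <= 0) || any(hgb <= 0))
    stop("RDW and HGB must be finite and positive", call. = FALSE)
  hi_rdw <- rdw >= rule$rdw_threshold
  hi_hgb <- hgb >= rule$hgb_threshold
  quadrant <- ifelse(hi_rdw, ifelse(hi_hgb, "Q2", "Q1"),
                             ifelse(hi_hgb, "Q4", "Q3"))
  data.frame(quadrant = quadrant, risk = unname(rule$risk[quadrant]),
             stringsAsFactors = FALSE)
}

#' Compare laboratory profiles between threshold-defined groups
#'
#' Splits the cohort at `threshold` on `variable` ("high" = value at or
#' above) and compares every other numeric feature between the high and low
#' groups with a two-sided Mann-Whitney rank-sum test (group medians
#' reported), plus the ratio of resistance proportions with a two-proportion
#' chi-square test (no continuity correction).
#'
#' @param features data.frame of per-patient features.
#' @param resistant logical outcome vector.
#' @param variable name of the grouping column.
#' @param threshold numeric threshold on `variable`.
#' @param compare columns to compare; default: all numeric columns except
#'   `variable`.
#' @return object of class `group_comparison`: `table` (per-variable medians
#'   and rank-sum p), `n_high`, `n_low`, `prop_high`, `prop_low`,
#'   `proportion_ratio`, `proportion_p`.
#' @export
compare_groups <- function(features, resistant, variable, threshold,
                           compare = NULL) {
  resistant <- as.logical(resistant)
  hi <- features[[variable]] >= threshold
  if (!any(hi, na.rm = TRUE) || !any(!hi, na.rm = TRUE))
    stop("both groups must be non-empty", call. = FALSE)
  if (is.null(compare)) {
    compare <- names(features)[vapply(features, is.numeric, logical(1))]
    compare <- setdiff(compare, variable)
  }
  tab <- do.call(rbind, lapply(compare, function(v) {
    a <- features[[v]][hi]; b <- features[[v]][!hi]
    p <- if (all(is.na(a)) || all(is.na(b))) NA_real_ else
      suppressWarnings(wilcox.test(a, b)$p.value)
    data.frame(variable = v,
               median_high = median(a, na.rm = TRUE),
               median_low = median(b, na.rm = TRUE),
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  ph <- mean(resistant[hi]); pl <- mean(resistant[!hi])
  pt <- suppressWarnings(
    prop.test(c(sum(resistant[hi]), sum(resistant[!hi])),
              c(sum(hi), sum(!hi)), correct = FALSE))
  structure(list(table = tab, n_high = sum(hi), n_low = sum(!hi),
                 prop_high = ph, prop_low = pl,
                 proportion_ratio = ph / pl, proportion_p = pt$p.value,
                 variable = variable, threshold = threshold),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s >= %g: n = %d high vs %d low\n", x$variable, x$threshold,
              x$n_high, x$n_low))
  cat(sprintf("Resistance: %.1f%% vs %.1f%% (ratio %.2f, p = %.3g)\n",
              100 * x$prop_high, 100 * x$prop_low, x$proportion_ratio,
              x$proportion_p))
  tab <- x$table
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Half-width of a normal-approximation confidence interval for a proportion
#'
#' `z * sqrt(p (1 - p) / n)` with `z` the standard-normal quantile for the
#' requested confidence level; the precision measure used to size a
#' single-arm trial around an expected response proportion.
#'
#' @param p expected proportion in `[0, 1]`.
#' @param n sample size (> 0).
#' @param level confidence level in `(0, 1)`; default 0.95.
#' @return half-width of the confidence interval.
#' @examples
#' ci_halfwidth(0.80, 120, 0.95)  # ~ 0.072
#' @export
ci_halfwidth <- function(p, n, level = 0.95) {
  if (!is.numeric(p) || any(p < 0 | p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (!is.numeric(level) || any(level <= 0 | level >= 1))
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n)
}

#' Scatter of the cohort in the RDW/HGB plane
#'
#' Resistant and non-resistant patients with the risk-rule thresholds drawn
#' as quadrant lines.
#'
#' @param rdw,hgb per-patient values.
#' @param resistant logical outcome vector.
#' @param rule a [risk_rule()].
#' @export
plot_quadrant_scatter <- function(rdw, hgb, resistant, rule = risk_rule()) {
  resistant <- as.logical(resistant)
  graphics::plot(rdw, hgb, col = ifelse(resistant, "firebrick", "steelblue"),
                 pch = ifelse(resistant, 17, 1), cex = 0.6,
                 xlab = "RDW (%)", ylab = "HGB (g/dL)",
                 main = "RDW/HGB quadrants")
  graphics::abline(v = rule$rdw_threshold, h = rule$hgb_threshold, lty = 2)
  graphics::legend("topright", legend = c("resistant", "non-resistant"),
                   col = c("firebrick", "steelblue"), pch = c(17, 1), bty = "n")
  invisible(NULL)
}

#' Kaplan-Meier curves by stratum
#'
#' @param survival data.frame with `time` and `event`.
#' @param group factor/character stratum per patient.
#' @export
plot_km_strata <- function(survival, group) {
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, as.logical(event)) ~ group,
                           data = cbind(survival, group = group))
  graphics::plot(fit, col = seq_len(nlevels(group)),
                 xlab = "days since index",
                 ylab = "resistance-free probability")
  graphics::legend("bottomleft", legend = levels(group),
                   col = seq_len(nlevels(group)), lty = 1, bty = "n")
  invisible(NULL)
}
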
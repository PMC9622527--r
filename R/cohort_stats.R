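# Group comparison and reporting: mean +/- SD summaries, a Shapiro-Wilk
# normality gate choosing between Student's t-test and the Mann-Whitney
# U-test, and the derived percentage / fold-change statistics. Two-sided
# tests throughout; raw p-values (no multiplicity correction).

#' Assemble a per-subject metric table
#'
#' One row per subject x segment x metric, the long-format input to the
#' cohort comparison layer.
#'
#' @param subject_id,group_label,segment,metric,value,units vectors of
#'   equal length (units may be a single string per call)
#' @return a `metric_table` data frame
#' @export
metric_table <- function(subject_id, group_label, segment, metric, value,
                         units = NA_character_) {
  out <- data.frame(subject_id = as.character(subject_id),
                    group_label = as.character(group_label),
                    segment = as.character(segment),
                    metric = as.character(metric),
                    value = as.numeric(value),
                    units = as.character(units),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("subject_id", "segment", "metric")])
  if (any(dup))
    stop("duplicate subject x segment x metric rows in the metric table")
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Group mean and standard deviation of a metric
#'
#' Arithmetic mean and sample SD (n - 1 denominator) per group for one
#' metric in one segment.
#'
#' @param table a `metric_table` (or equivalent data frame)
#' @param metric metric name
#' @param segment segment label
#' @return data frame with columns `group`, `n`, `mean`, `sd`
#' @export
group_summary <- function(table, metric, segment) {
  rows <- table$metric == metric & table$segment == segment
  if (!any(rows)) stop(sprintf("no rows for metric '%s' in segment '%s'",
                               metric, segment))
  sub <- table[rows, ]
  groups <- sort(unique(sub$group_label))
  if (length(groups) < 2L)
    stop("a two-group summary needs subjects from two groups")
  out <- do.call(rbind, lapply(groups, function(gr) {
    v <- sub$value[sub$group_label == gr]
    if (length(v) < 2L)
      stop(sprintf("group '%s' has fewer than 2 subjects", gr))
    data.frame(group = gr, n = length(v), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Shapiro-Wilk normality gate
#'
#' Tests a sample for normality; a metric passes the gate when the
#' Shapiro-Wilk p-value is at least `alpha`. A degenerate (constant)
#' sample is flagged non-normal with `p = NA` rather than raising an
#' error.
#'
#' @param values numeric sample (n >= 3)
#' @param alpha gate level (default 0.05)
#' @return list `is_normal` (logical), `p` (Shapiro-Wilk p-value)
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("the Shapiro-Wilk test needs at least 3 observations")
  if (stats::sd(values) == 0)
    return(list(is_normal = FALSE, p = NA_real_))
  p <- stats::shapiro.test(values)$p.value
  list(is_normal = p >= alpha, p = p)
}

#' Compare two groups with a normality-gated test
#'
#' Both groups are screened with the Shapiro-Wilk test; when both pass at
#' `alpha` the comparison uses the two-sided Student's t-test, otherwise
#' the two-sided Mann-Whitney U-test (exact for small samples without
#' ties). Both normality p-values and the test used are recorded.
#'
#' @param a,b numeric samples
#' @param alpha normality gate level
#' @param var_equal passed to [stats::t.test()] (default `TRUE`, the
#'   classical Student test)
#' @return object of class `group_comparison`
#' @export
compare_groups <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  ga <- normality_gate(a, alpha)
  gb <- normality_gate(b, alpha)
  use_t <- isTRUE(ga$is_normal) && isTRUE(gb$is_normal)
  p <- if (use_t) stats::t.test(a, b, var.equal = var_equal)$p.value
  else suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
  structure(list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                 test_used = if (use_t) "t-test" else "Mann-Whitney",
                 p_value = p, normality_p_a = ga$p, normality_p_b = gb$p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d): %s p = %.4g\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
              x$test_used, x$p_value))
  invisible(x)
}

#' Signed percentage difference relative to a reference
#'
#' `100 * (other - reference) / reference`.
#'
#' @param reference reference value (non-zero)
#' @param other comparison value
#' @return signed percentage
#' @export
#' @examples
#' percent_difference(91.1, 154.6)  # +69.7
percent_difference <- function(reference, other) {
  if (any(reference == 0)) stop("reference value must be non-zero")
  100 * (other - reference) / reference
}

#' Fold change relative to a reference
#'
#' `other / reference`; consistent with [percent_difference()] through
#' `fold = 1 + pct / 100`.
#'
#' @param reference reference value (> 0)
#' @param other comparison value
#' @return ratio
#' @export
fold_change <- function(reference, other) {
  if (any(reference <= 0)) stop("reference value must be positive")
  other / reference
}

#' Render per-segment comparison tables
#'
#' Builds the standard cohort report: one row per metric x segment with
#' group `mean +/- SD` columns, the gated test and its p-value. Metrics or
#' segments with missing data are rendered as explicit `NA` rows rather
#' than dropped.
#'
#' @param table a `metric_table`
#' @param groups the two group labels to compare, in (reference, other)
#'   order; defaults to the sorted unique labels
#' @param alpha normality gate level
#' @return data frame with columns `metric`, `segment`, `units`,
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `test`, `p_value`
#' @export
render_tables <- function(table, groups = NULL, alpha = 0.05) {
  if (is.null(groups)) groups <- sort(unique(table$group_label))
  if (length(groups) != 2L) stop("exactly two group labels are required")
  combos <- unique(table[, c("metric", "segment", "units")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    m <- combos$metric[i]; sgm <- combos$segment[i]
    va <- table$value[table$metric == m & table$segment == sgm &
                        table$group_label == groups[1]]
    vb <- table$value[table$metric == m & table$segment == sgm &
                        table$group_label == groups[2]]
    row <- data.frame(metric = m, segment = sgm, units = combos$units[i],
                      mean_a = NA_real_, sd_a = NA_real_, n_a = length(va),
                      mean_b = NA_real_, sd_b = NA_real_, n_b = length(vb),
                      test = NA_character_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(va) >= 2L) { row$mean_a <- mean(va); row$sd_a <- stats::sd(va) }
    if (length(vb) >= 2L) { row$mean_b <- mean(vb); row$sd_b <- stats::sd(vb) }
    if (length(va) >= 3L && length(vb) >= 3L) {
      cmpr <- compare_groups(va, vb, alpha)
      row$test <- cmpr$test_used
      row$p_value <- cmpr$p_value
    }
    row
  }))
  attr(out, "groups") <- groups
  out
}
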
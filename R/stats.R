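#' Two-tailed Wilcoxon Mann-Whitney test
#'
#' U statistic for `sample_a` (number of (a, b) pairs with a > b, ties
#' counting one half) with a two-tailed p-value: exact by enumeration of the
#' rank distribution when `n_a * n_b <= 400` and there are no ties, and the
#' normal approximation with tie and continuity corrections otherwise.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List: `U`, `p_value`, `exact` (logical), `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_value  # 2/70
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (!is.numeric(sample_a) || length(sample_a) == 0 ||
      !is.numeric(sample_b) || length(sample_b) == 0) {
    stop("validation error: both samples must be non-empty numeric vectors",
         call. = FALSE)
  }
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("validation error: both samples must contain non-missing values",
         call. = FALSE)
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- !ties && length(sample_a) * length(sample_b) <= 400
  wt <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = exact,
                                     correct = TRUE,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact,
       n_a = length(sample_a), n_b = length(sample_b))
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, else `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Compare conditions against a control
#'
#' For each non-control group, records a variance-ratio F test (descriptive
#' screen only; it never switches the main test) and the two-tailed
#' Mann-Whitney p-value versus the control, with significance stars at
#' 0.05 / 0.01 / 0.001. No multiple-testing correction is applied by
#' default; `adjust = "holm"` is available.
#'
#' @param data Data frame of per-trajectory or per-FoV metrics.
#' @param metric Name of the numeric metric column.
#' @param group_col Name of the grouping column.
#' @param control Label of the control group (default: first group in the
#'   data).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame, one row per comparison: `metric`, `group`,
#'   `control`, `n_group`, `n_control`, `median_group`, `median_control`,
#'   `f_statistic`, `f_p_value`, `U`, `p_value`, `stars`.
#' @export
compare_conditions <- function(data, metric, group_col = "condition",
                               control = NULL, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!group_col %in% names(data)) {
    stop("validation error: unknown group column: ", group_col, call. = FALSE)
  }
  if (!metric %in% names(data)) {
    stop("validation error: unknown metric column: ", metric, call. = FALSE)
  }
  groups <- unique(as.character(data[[group_col]]))
  if (length(groups) < 2) {
    stop("validation error: need >= 2 groups to compare", call. = FALSE)
  }
  control <- control %||% groups[1]
  if (!control %in% groups) {
    stop("validation error: control group not present: ", control,
         call. = FALSE)
  }
  ctrl_vals <- data[[metric]][data[[group_col]] == control]
  ctrl_vals <- ctrl_vals[!is.na(ctrl_vals)]
  rows <- lapply(setdiff(groups, control), function(grp) {
    vals <- data[[metric]][data[[group_col]] == grp]
    vals <- vals[!is.na(vals)]
    ft <- tryCatch(var.test(vals, ctrl_vals),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    mw <- mann_whitney_u(vals, ctrl_vals)
    data.frame(metric = metric, group = grp, control = control,
               n_group = length(vals), n_control = length(ctrl_vals),
               median_group = median(vals), median_control = median(ctrl_vals),
               f_statistic = unname(ft$statistic), f_p_value = ft$p.value,
               U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_value_adj <- stats::p.adjust(out$p_value, "holm")
  out$stars <- significance_stars(if (adjust == "holm") out$p_value_adj else
    out$p_value)
  rownames(out) <- NULL
  out
}
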
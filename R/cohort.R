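# Cohort-level statistics: category proportions, percentage-point deltas,
# chi-square comparison of proportions, Kruskal-Wallis on ROI means.

marker_categories <- list(
  ndufb8 = c("very_low", "low", "normal", "high"),
  mtco1 = c("very_low", "low", "normal", "high"),
  tomm20 = c("low", "normal", "high"))

#' Category counts, percentages and mean Z-scores per grouping cell
#'
#' Pools cells within each grouping cell (e.g. per group, per patient or
#' per ROI) and reports, per marker, the count and percentage of cells in
#' each abundance category plus the mean z. Cells flagged `invalid` are
#' excluded. Percentages within a grouping cell and marker sum to 100.
#'
#' @param z_records classified records from [classify_cells()].
#' @param grouping character vector of grouping columns (e.g. `"group"`,
#'   `c("group", "patient_id")`, `"roi_id"`).
#' @param epithelial_only drop non-epithelial cells first (default `TRUE`
#'   when a `tissue_class` column is present).
#' @return Long data frame: grouping columns, `marker`, `category`,
#'   `count`, `n_cells`, `percentage`, `mean_z`. Empty grouping cells are
#'   omitted.
#' @export
category_proportions <- function(z_records, grouping = "group",
                                 epithelial_only =
                                   "tissue_class" %in% names(z_records)) {
  stopifnot(all(grouping %in% names(z_records)))
  d <- z_records
  if (epithelial_only && "tissue_class" %in% names(d))
    d <- d[!is.na(d$tissue_class) & d$tissue_class == "epithelial", ,
           drop = FALSE]
  if ("invalid" %in% names(d)) d <- d[!d$invalid, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no valid cells to summarise")
    return(data.frame())
  }
  key <- interaction(d[grouping], drop = TRUE, sep = "\r")
  out <- list()
  for (k in levels(key)) {
    dk <- d[key == k, , drop = FALSE]
    keys <- dk[1, grouping, drop = FALSE]
    for (m in names(marker_categories)) {
      cats <- marker_categories[[m]]
      cc <- factor(dk[[paste0("cat_", m)]], levels = cats)
      counts <- table(cc)
      mz <- mean(dk[[paste0("z_", m)]])
      for (cat in cats) {
        out[[length(out) + 1L]] <- cbind(
          keys,
          data.frame(marker = m, category = cat,
                     count = as.integer(counts[[cat]]),
                     n_cells = nrow(dk),
                     percentage = 100 * counts[[cat]] / nrow(dk),
                     mean_z = mz, stringsAsFactors = FALSE),
          row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percentage-point difference between two printed proportions
#'
#' @param p_a,p_b percentages in `[0, 100]`.
#' @return `p_a - p_b`, reported to 2 decimal places.
#' @examples
#' proportion_delta(4.52, 1.38)   # 3.14
#' proportion_delta(15.68, 0.61)  # 15.07
#' @export
proportion_delta <- function(p_a, p_b) {
  if (any(!is.finite(c(p_a, p_b))) || p_a < 0 || p_a > 100 ||
      p_b < 0 || p_b > 100)
    stop("proportions must lie in [0, 100]")
  round(p_a - p_b, 2)
}

#' Pearson chi-square test on a contingency table of cell counts
#'
#' No continuity correction; df = (rows-1)(cols-1); p from the upper tail
#' of the chi-square distribution. Any expected count below 5 sets the
#' `low_expected` flag.
#'
#' @param count_table numeric matrix of counts (typically 2 x k:
#'   deficient vs not, by group); all row and column totals must be
#'   positive.
#' @return A list of class `comparison_result` with `test_name`
#'   (`"chi-square"`), `chi2_stat`, `df`, `p_value`, `expected`,
#'   `low_expected`.
#' @export
chisq_proportions <- function(count_table) {
  O <- as.matrix(count_table)
  if (any(O < 0) || any(!is.finite(O))) stop("counts must be nonnegative")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal total in the contingency table")
  N <- sum(O)
  E <- outer(rs, cs) / N
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  res <- list(test_name = "chi-square", chi2_stat = stat, df = df,
              p_value = pchisq(stat, df, lower.tail = FALSE),
              expected = E, low_expected = any(E < 5))
  class(res) <- "comparison_result"
  res
}

#' Compare a category's proportion between two groups
#'
#' Builds the 2 x 2 table (in category vs not, group A vs group B) from
#' classified records and applies [chisq_proportions()]; reports both
#' percentages and their percentage-point difference.
#'
#' @param z_records classified records from [classify_cells()].
#' @param marker `"ndufb8"`, `"mtco1"` or `"tomm20"`.
#' @param category a category label, or `"deficient"` for the z < -3 rule
#'   (NDUFB8/MTCO1 only).
#' @param group_a,group_b values of `group_col` to contrast.
#' @param group_col grouping column (default `"group"`; use `"region"` for
#'   tumour vs benign-adjacent contrasts).
#' @param epithelial_only drop non-epithelial cells first.
#' @return A `comparison_result` with `contrast`, `marker`, `category`,
#'   `p_a`, `p_b`, `delta_pp` added.
#' @export
compare_proportions <- function(z_records, marker, category,
                                group_a, group_b, group_col = "group",
                                epithelial_only =
                                  "tissue_class" %in% names(z_records)) {
  d <- z_records
  if (epithelial_only && "tissue_class" %in% names(d))
    d <- d[!is.na(d$tissue_class) & d$tissue_class == "epithelial", ,
           drop = FALSE]
  if ("invalid" %in% names(d)) d <- d[!d$invalid, , drop = FALSE]
  in_cat <- if (category == "deficient") {
    if (!marker %in% c("ndufb8", "mtco1"))
      stop("'deficient' applies to ndufb8 and mtco1 only")
    d[[paste0("deficient_", marker)]]
  } else {
    d[[paste0("cat_", marker)]] == category
  }
  sel_a <- d[[group_col]] == group_a
  sel_b <- d[[group_col]] == group_b
  tab <- rbind(c(sum(in_cat & sel_a), sum(!in_cat & sel_a)),
               c(sum(in_cat & sel_b), sum(!in_cat & sel_b)))
  res <- chisq_proportions(tab)
  res$contrast <- sprintf("%s vs %s", group_a, group_b)
  res$marker <- marker
  res$category <- category
  res$p_a <- 100 * tab[1, 1] / sum(tab[1, ])
  res$p_b <- 100 * tab[2, 1] / sum(tab[2, ])
  res$delta_pp <- res$p_a - res$p_b
  res
}

#' Kruskal-Wallis rank test across groups of ROI-level means
#'
#' H statistic with tie correction; p from the chi-square approximation
#' with k-1 degrees of freedom.
#'
#' @param values_by_group named list of numeric vectors, one per group
#'   (at least two groups, each non-empty).
#' @return A `comparison_result` with `test_name` (`"kruskal-wallis"`),
#'   `chi2_stat` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values_by_group) {
  values_by_group <- values_by_group[lengths(values_by_group) > 0]
  k <- length(values_by_group)
  if (k < 2) stop("kruskal_wallis needs at least two non-empty groups")
  x <- unlist(values_by_group, use.names = FALSE)
  g <- rep(seq_len(k), lengths(values_by_group))
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rbar^2 / lengths(values_by_group)) -
    3 * (N + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr > 0) H <- H / tie_corr
  res <- list(test_name = "kruskal-wallis", chi2_stat = H, df = k - 1L,
              p_value = pchisq(H, k - 1L, lower.tail = FALSE),
              groups = names(values_by_group))
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: stat = %.4f, df = %d, p = %.3g\n", x$test_name,
              x$chi2_stat, x$df, x$p_value))
  if (!is.null(x$delta_pp))
    cat(sprintf("  %s/%s %s: %.2f%% vs %.2f%% (delta %.2f pp)\n",
                x$marker, x$category, x$contrast, x$p_a, x$p_b, x$delta_pp))
  invisible(x)
}

#' Mean Z-score per ROI for each marker
#'
#' The unweighted mean z of (valid, epithelial) cells per ROI — the unit
#' of analysis for the ROI-level rank comparisons and heatmaps.
#'
#' @param z_records classified records.
#' @param extra_cols grouping columns carried through (first value per
#'   ROI), e.g. `c("group", "patient_id", "region")`.
#' @return Data frame with `roi_id`, the carried columns, `n_cells`, and
#'   `mean_z_ndufb8`, `mean_z_mtco1`, `mean_z_tomm20`.
#' @export
roi_mean_z <- function(z_records,
                       extra_cols = intersect(c("group", "patient_id",
                                                "region"),
                                              names(z_records))) {
  d <- z_records
  if ("tissue_class" %in% names(d))
    d <- d[!is.na(d$tissue_class) & d$tissue_class == "epithelial", ,
           drop = FALSE]
  if ("invalid" %in% names(d)) d <- d[!d$invalid, , drop = FALSE]
  rois <- unique(d$roi_id)
  out <- lapply(rois, function(r) {
    dr <- d[d$roi_id == r, , drop = FALSE]
    cbind(data.frame(roi_id = r, stringsAsFactors = FALSE),
          dr[1, extra_cols, drop = FALSE],
          data.frame(n_cells = nrow(dr),
                     mean_z_ndufb8 = mean(dr$z_ndufb8),
                     mean_z_mtco1 = mean(dr$z_mtco1),
                     mean_z_tomm20 = mean(dr$z_tomm20)),
          row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
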
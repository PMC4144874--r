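#' Two-sample two-tailed t-test
#'
#' Pooled-variance Student t-test (default) with `df = n1 + n2 - 2`, as used
#' for all nodal and global between-group comparisons; the statistic is
#' oriented `mean(x) - mean(y)`. A Welch option is available.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param var_equal Pooled-variance test if `TRUE` (default); Welch
#'   otherwise.
#' @return A list with `statistic` (T), `p` (two-tailed), `df`, `mean_x`,
#'   `mean_y`.
#' @export
#' @examples
#' two_sample_ttest(rnorm(16, 1), rnorm(16))$df  # 30
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y))
  if (pooled <= 0)
    stop("zero pooled variance: samples are constant", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_x = mean(x), mean_y = mean(y))
}

#' @noRd
.comparison_row <- function(feature, node, g1, g2, var_equal) {
  ok <- length(g1) >= 2 && length(g2) >= 2 &&
    ((length(g1) - 1) * stats::var(g1) + (length(g2) - 1) * stats::var(g2)) > 0
  if (ok) {
    tt <- two_sample_ttest(g1, g2, var_equal = var_equal)
    data.frame(feature = feature, node = node, mean_g1 = tt$mean_x,
               mean_g2 = tt$mean_y, T = tt$statistic, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature = feature, node = node, mean_g1 = mean(g1),
               mean_g2 = mean(g2), T = NA_real_, df = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  }
}

#' Compare nodal network metrics between two groups
#'
#' Runs one two-sample two-tailed t-test per (metric, node) pair across
#' subjects. P-values are reported uncorrected by default (the comparisons
#' are exploratory); Benjamini-Hochberg adjustment is available.
#'
#' @param tables List (one per subject) of nodal metric data.frames as
#'   produced by [nodal_metrics()], with consistent node labels.
#' @param groups Factor or character vector of group labels, one per
#'   subject; the first factor level is group 1 (the `T` statistic is
#'   oriented group 1 minus group 2).
#' @param metrics Which metric columns to compare (default all five).
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @param p_adjust Multiple-testing adjustment method: `"none"` (default)
#'   or any method of [stats::p.adjust()]; adds a `p_adj` column.
#' @return A data.frame of class `network_comparison` with columns
#'   `feature`, `node`, `mean_g1`, `mean_g2`, `T`, `df`, `p`. Features with
#'   zero pooled variance get `NA` statistics.
#' @export
compare_nodal_metrics <- function(tables, groups,
                                  metrics = c("degree", "strength",
                                              "clustering",
                                              "mean_path_length",
                                              "betweenness"),
                                  var_equal = TRUE, p_adjust = "none") {
  if (!is.list(tables) || !length(tables))
    stop("`tables` must be a non-empty list of nodal metric tables",
         call. = FALSE)
  for (s in seq_along(tables))
    if (!is.data.frame(tables[[s]]) || is.null(tables[[s]]$label))
      stop(sprintf("missing or malformed metric table for subject %d", s),
           call. = FALSE)
  if (length(groups) != length(tables))
    stop("`groups` must have one label per subject", call. = FALSE)
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 subjects", call. = FALSE)
  labs <- tables[[1]]$label
  for (s in seq_along(tables))
    if (!identical(tables[[s]]$label, labs))
      stop(sprintf("node labels of subject %d do not match subject 1", s),
           call. = FALSE)
  g1 <- groups == levels(groups)[1]
  rows <- vector("list", length(metrics) * length(labs))
  r <- 0L
  for (met in metrics) {
    vals <- vapply(tables, function(tb) tb[[met]], numeric(length(labs)))
    for (v in seq_along(labs)) {
      r <- r + 1L
      rows[[r]] <- .comparison_row(met, labs[v], vals[v, g1], vals[v, !g1],
                                   var_equal)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  attr(out, "group_levels") <- levels(groups)
  class(out) <- c("network_comparison", "data.frame")
  out
}

#' Compare global network features between two groups
#'
#' One two-sample t-test per global feature (network clustering,
#' characteristic path length, global/local efficiency and, when supplied,
#' the small-world efficiency ratios).
#'
#' @param globals List (one per subject) of named lists or vectors of global
#'   features, e.g. [global_metrics()] output, optionally extended with
#'   `eloc_ratio` / `eglob_ratio` from [small_world_assessment()].
#' @inheritParams compare_nodal_metrics
#' @return A data.frame of class `network_comparison` (node column `NA`).
#' @export
compare_global_metrics <- function(globals, groups, var_equal = TRUE,
                                   p_adjust = "none") {
  if (!is.list(globals) || !length(globals))
    stop("`globals` must be a non-empty list", call. = FALSE)
  if (length(groups) != length(globals))
    stop("`groups` must have one label per subject", call. = FALSE)
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 subjects", call. = FALSE)
  feats <- names(globals[[1]])
  for (s in seq_along(globals))
    if (!all(feats %in% names(globals[[s]])))
      stop(sprintf("missing global features for subject %d", s),
           call. = FALSE)
  g1 <- groups == levels(groups)[1]
  rows <- lapply(feats, function(f) {
    vals <- vapply(globals, function(gl) as.numeric(gl[[f]]), 0)
    .comparison_row(f, NA_character_, vals[g1], vals[!g1], var_equal)
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  attr(out, "group_levels") <- levels(groups)
  class(out) <- c("network_comparison", "data.frame")
  out
}

#' @export
print.network_comparison <- function(x, digits_T = 2, sig_p = 3,
                                     alpha = 0.05, ...) {
  gl <- attr(x, "group_levels")
  cat(sprintf("Group comparison (%s vs %s), %d features\n",
              gl[1], gl[2], nrow(x)))
  sig <- !is.na(x$p) & x$p < alpha
  if (any(sig)) {
    cat(sprintf("Features with p < %.3g (uncorrected):\n", alpha))
    sh <- x[sig, , drop = FALSE]
    sh$T <- round(sh$T, digits_T)
    sh$p <- signif(sh$p, sig_p)
    print.data.frame(sh[order(sh$p), ], row.names = FALSE)
  } else {
    cat(sprintf("No feature reaches p < %.3g.\n", alpha))
  }
  invisible(x)
}

#' Correlate a network feature with musical-training onset age
#'
#' Pearson correlation with a two-sided test, applied within the trained
#' group between a nodal/global feature and the age at which training
#' began.
#'
#' @param feature Numeric feature values, one per subject.
#' @param onset_age Numeric onset ages, same length.
#' @return A list with `r`, `p`, `n`.
#' @export
correlate_onset <- function(feature, onset_age) {
  feature <- as.numeric(feature)
  onset_age <- as.numeric(onset_age)
  keep <- is.finite(feature) & is.finite(onset_age)
  feature <- feature[keep]
  onset_age <- onset_age[keep]
  if (length(feature) < 3L)
    stop("at least 3 paired values are required", call. = FALSE)
  if (stats::var(feature) == 0 || stats::var(onset_age) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(feature, onset_age, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(feature))
}
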
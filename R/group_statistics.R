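#' One-way ANOVA F-test p-value
#'
#' Classical one-way fixed-effects ANOVA across k groups: F with (k-1, N-k)
#' degrees of freedom. Returns NA (undefined) when both the between- and
#' within-group variation are zero, i.e. all values identical.
#'
#' @param groups list of >= 2 numeric samples (NAs dropped); each needs >= 2
#'   non-missing values.
#' @return Two-sided p-value, or NA if undefined.
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least 2 samples")
  groups <- lapply(groups, function(x) as.numeric(x[!is.na(x)]))
  if (any(vapply(groups, length, integer(1)) < 2L))
    return(NA_real_)
  values <- unlist(groups)
  if (stats::var(values) == 0) return(NA_real_)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  stats::oneway.test(values ~ g, var.equal = TRUE)$p.value
}

#' Mann-Whitney-Wilcoxon rank-sum test p-value (two-sided)
#'
#' Exact p-value (over the full distribution of rank assignments) when the
#' combined sample size is at most 12 and there are no ties; the normal
#' approximation with tie and continuity corrections otherwise. The exact
#' small-sample branch matters because this test is the workhorse pairwise
#' comparison at modest cohort sizes.
#'
#' @param x,y numeric samples, each with >= 1 non-missing value.
#' @return Two-sided p-value.
#' @export
mww <- function(x, y) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must have at least one value")
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(x) + length(y) <= 12L && !ties)
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  else
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Bonferroni correction
#'
#' Family-wise error rate control: `adjusted = min(1, m * p)` with m the
#' family size. Missing p-values stay missing and do not count toward m.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @param alpha significance level (default 0.05).
#' @return List with `p_adjusted` and logical `significant`
#'   (`adjusted < alpha`; NA p-values are never significant).
#' @export
bonferroni <- function(p, alpha = 0.05) {
  adjust_family(p, alpha, method = "bonferroni")
}

#' Benjamini-Hochberg correction
#'
#' False-discovery-rate control by the step-up procedure: sort p ascending,
#' `adjusted_(k) = min_{j >= k} min(1, m p_(j) / j)`, mapped back to input
#' order.
#'
#' @inheritParams bonferroni
#' @return List with `p_adjusted` and logical `significant`.
#' @export
bh <- function(p, alpha = 0.05) {
  adjust_family(p, alpha, method = "BH")
}

adjust_family <- function(p, alpha, method) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = method)
  sig <- !is.na(adj) & adj < alpha
  list(p_adjusted = adj, significant = sig)
}

#' Evaluate per-feature group differences across a cohort
#'
#' For every (ROI, feature) the feature values are compared across groups
#' with a one-way ANOVA F-test, and between each pair of groups with the
#' two-sided Mann-Whitney-Wilcoxon test. Bonferroni and Benjamini-Hochberg
#' corrections are then applied within each correction family. The default
#' family (`"per_roi"`) is all features of one ROI for one comparison — the
#' per-ROI significance counts this produces are directly comparable across
#' ROIs; `"global"` pools every test into a single family.
#'
#' Rows with missing feature values are dropped per test; a group left with
#' fewer than 2 usable values makes that test missing (NA), never
#' significant.
#'
#' @param table feature table (see [read_feature_table()]).
#' @param alpha significance level (default 0.05).
#' @param family correction family: "per_roi" or "global".
#' @return An object of class `cohort_result`: list with `results` (one row
#'   per ROI x feature x comparison: raw, Bonferroni- and BH-adjusted
#'   p-values with significance flags), `summary` (significance counts per
#'   ROI x comparison under each correction), `alpha`, `family` and
#'   `groups`.
#' @export
evaluate_cohort <- function(table, alpha = 0.05,
                            family = c("per_roi", "global")) {
  family <- match.arg(family)
  table <- validate_feature_table(table)
  grps <- sort(unique(as.character(table$group)))
  if (length(grps) < 2L)
    stop("need at least 2 groups, found ", length(grps))
  pairs <- utils::combn(grps, 2, simplify = FALSE)
  comparisons <- c("ANOVA",
                   vapply(pairs, function(pr) paste(pr, collapse = "-vs-"),
                          character(1)))
  rois <- unique(table$roi_id)
  feats <- feature_names()

  res <- do.call(rbind, lapply(rois, function(roi) {
    sub <- table[table$roi_id == roi, , drop = FALSE]
    do.call(rbind, lapply(feats, function(fn) {
      vals <- split(sub[[fn]], as.character(sub$group))
      usable <- lapply(grps, function(g) {
        v <- vals[[g]]
        if (is.null(v)) numeric(0) else v[!is.na(v)]
      })
      names(usable) <- grps
      p_an <- if (all(vapply(usable, length, integer(1)) >= 2L))
        anova_f(usable) else NA_real_
      p_pw <- vapply(pairs, function(pr) {
        a <- usable[[pr[1]]]; b <- usable[[pr[2]]]
        if (length(a) < 2L || length(b) < 2L) return(NA_real_)
        if (length(unique(c(a, b))) == 1L) return(NA_real_)
        mww(a, b)
      }, numeric(1))
      data.frame(roi_id = roi, feature = fn,
                 comparison = comparisons,
                 p = c(p_an, p_pw),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL

  fam_id <- if (family == "per_roi")
    paste(res$roi_id, res$comparison, sep = "|") else rep("all", nrow(res))
  res$p_bonferroni <- NA_real_
  res$p_bh <- NA_real_
  for (f in unique(fam_id)) {
    sel <- fam_id == f
    res$p_bonferroni[sel] <- bonferroni(res$p[sel], alpha)$p_adjusted
    res$p_bh[sel] <- bh(res$p[sel], alpha)$p_adjusted
  }
  res$sig_raw <- !is.na(res$p) & res$p < alpha
  res$sig_bh <- !is.na(res$p_bh) & res$p_bh < alpha
  res$sig_bonferroni <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha

  summary <- stats::aggregate(
    cbind(n_sig_raw = res$sig_raw, n_sig_bh = res$sig_bh,
          n_sig_bonferroni = res$sig_bonferroni),
    by = list(roi_id = res$roi_id, comparison = res$comparison), FUN = sum)
  summary <- summary[order(summary$roi_id, summary$comparison), ]
  rownames(summary) <- NULL

  structure(list(results = res, summary = summary, alpha = alpha,
                 family = family, groups = grps),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", length(unique(x$results$roi_id)), " ROIs, groups: ",
      paste(x$groups, collapse = ", "), ", alpha = ", x$alpha,
      ", family = ", x$family, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write cohort evaluation results to CSV
#'
#' Writes the per-test results table and the significance-count summary.
#'
#' @param result a [evaluate_cohort()] result.
#' @param results_path,summary_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_result <- function(result, results_path, summary_path) {
  stopifnot(inherits(result, "cohort_result"))
  utils::write.csv(result$results, results_path, row.names = FALSE, na = "NA")
  utils::write.csv(result$summary, summary_path, row.names = FALSE, na = "NA")
  invisible(c(results_path, summary_path))
}
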
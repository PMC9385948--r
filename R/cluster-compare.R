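#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the standard tie correction;
#' p-values are two-sided normal tail probabilities, adjusted with
#' `p.adjust`.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param p_adjust Adjustment method (default `"bonferroni"`, the usual
#'   convention for Dunn's procedure).
#' @return Data frame of pairwise comparisons with `z` and `p_value`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  ng <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt(s2 * (1 / ng[p[1]] + 1 / ng[p[2]]))
  })
  p <- stats::p.adjust(2 * pnorm(-abs(z)), method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p_value = pmin(as.numeric(p), 1), row.names = NULL)
}

#' Normality-gated comparison of a feature across groups
#'
#' The distribution of each group is assessed with the Shapiro-Wilk test
#' at `alpha_normality`; when every group passes, the parametric branch is
#' used (unpaired t-test for two groups, one-way ANOVA with Tukey post-hoc
#' for more), otherwise the nonparametric branch (Mann-Whitney for two
#' groups, Kruskal-Wallis with Dunn's post-hoc for more). Groups with
#' fewer than 3 values force the nonparametric branch with a warning.
#'
#' @param values Numeric response (one feature).
#' @param group_labels Group membership vector, >= 2 groups.
#' @param alpha_normality Shapiro-Wilk significance gate.
#' @param var_equal Use the equal-variance t-test (classical unpaired t).
#' @return A list of class `"group_comparison"`: `feature` test name,
#'   `branch`, `statistic`, `p_value`, `posthoc` (pairwise data frame or
#'   `NULL`), `normality` flags per group.
#' @export
compare_feature_across_groups <- function(values, group_labels,
                                          alpha_normality = 0.05,
                                          var_equal = TRUE) {
  groups <- factor(group_labels)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  ng <- table(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  small <- ng < 3
  normality <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(x) < 3 || length(unique(x)) == 1) return(NA)
    shapiro.test(x)$p.value >= alpha_normality
  }, logical(1))
  if (any(small)) {
    warning("group(s) with fewer than 3 values: nonparametric branch forced")
  }
  parametric <- !any(small) && all(normality, na.rm = FALSE) &&
    !anyNA(normality)
  posthoc <- NULL
  if (nlevels(groups) == 2) {
    if (parametric) {
      fit <- t.test(values ~ groups, var.equal = var_equal)
      test <- "t"; statistic <- unname(fit$statistic); p <- fit$p.value
    } else {
      fit <- suppressWarnings(wilcox.test(values ~ groups))
      test <- "mann_whitney"; statistic <- unname(fit$statistic)
      p <- fit$p.value
    }
  } else {
    if (parametric) {
      fit <- aov(values ~ groups)
      an <- summary(fit)[[1]]
      test <- "anova"; statistic <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      tk <- TukeyHSD(fit)$groups
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      posthoc <- data.frame(group1 = vapply(nm, `[`, "", 1),
                            group2 = vapply(nm, `[`, "", 2),
                            diff = tk[, "diff"], p_value = tk[, "p adj"],
                            row.names = NULL)
    } else {
      fit <- kruskal.test(values, groups)
      test <- "kruskal_wallis"; statistic <- unname(fit$statistic)
      p <- fit$p.value
      posthoc <- dunn_posthoc(values, groups)
    }
  }
  structure(
    list(test = test, branch = if (parametric) "parametric" else "nonparametric",
         statistic = statistic, p_value = p, posthoc = posthoc,
         normality = normality, group_sizes = as.integer(ng)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): statistic = %.4g, p = %.4g\n",
              x$test, x$branch, x$statistic, x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson statistic without continuity correction;
#' `df = (r - 1)(c - 1)`.
#'
#' @param contingency A two-way count table (matrix), entries >= 0.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
composition_chi_square <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0)) stop("counts must be non-negative")
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero marginal in contingency table")
  }
  fit <- suppressWarnings(chisq.test(contingency, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Exact binomial enrichment test per cluster
#'
#' For each cluster, the exact binomial tail probability of observing a
#' target-population count at least as extreme as the cluster's, under
#' the cohort-wide base proportion. One-sided toward enrichment by
#' default.
#'
#' @param cluster_labels Cluster membership per neuron.
#' @param population_labels Population per neuron.
#' @param target Population tested for enrichment.
#' @param base_proportion Baseline proportion of the target population;
#'   must lie strictly inside (0, 1). Default: its cohort-wide frequency.
#' @param alternative `"greater"` (enrichment), `"less"` (depletion), or
#'   `"two.sided"`.
#' @return Data frame with one row per cluster: `cluster`, `n`,
#'   `n_target`, `proportion`, `p_value`.
#' @export
cluster_enrichment_binomial <- function(cluster_labels, population_labels,
                                        target = "Shox2",
                                        base_proportion = NULL,
                                        alternative = c("greater", "less",
                                                        "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(cluster_labels) != length(population_labels)) {
    stop("label vectors must have the same length")
  }
  if (is.null(base_proportion)) {
    base_proportion <- mean(population_labels == target)
  }
  if (!(base_proportion > 0 && base_proportion < 1)) {
    stop("base_proportion must lie strictly inside (0, 1)")
  }
  clusters <- sort(unique(cluster_labels))
  rows <- lapply(clusters, function(cl) {
    in_cl <- cluster_labels == cl
    n <- sum(in_cl)
    if (n == 0) {
      warning("empty cluster skipped: ", cl)
      return(NULL)
    }
    x <- sum(population_labels[in_cl] == target)
    p <- switch(alternative,
      greater = pbinom(x - 1, n, base_proportion, lower.tail = FALSE),
      less = pbinom(x, n, base_proportion),
      two.sided = stats::binom.test(x, n, base_proportion)$p.value
    )
    data.frame(cluster = cl, n = n, n_target = x, proportion = x / n,
               p_value = p)
  })
  do.call(rbind, rows)
}

#' Correspondence between two cluster partitions
#'
#' Cross-tabulates the two labelings and reports, for every non-empty
#' cell, the overlap percentage `100 * count / min(size_A, size_B)` — the
#' "maximum percentage of appearance" convention under which 100% is
#' attainable for unequal cluster sizes. Cells above `threshold` are
#' flagged and the fraction of all neurons falling in flagged cells is
#' reported.
#'
#' @param labels_a,labels_b Partition labels over the same neurons.
#' @param threshold High-overlap flag threshold, percent (published
#'   convention: 80).
#' @param denominator `"min"` (default) or `"row"` (size of the
#'   `labels_a` cluster).
#' @return A list of class `"correspondence_result"`: `contingency`,
#'   `overlap` (data frame of non-empty cells with `overlap_pct` and
#'   `high_overlap`), `n_combinations`, `high_overlap_fraction`.
#' @export
cluster_correspondence <- function(labels_a, labels_b, threshold = 80,
                                   denominator = c("min", "row")) {
  denominator <- match.arg(denominator)
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have the same length")
  }
  tab <- table(a = labels_a, b = labels_b)
  sizes_a <- rowSums(tab)
  sizes_b <- colSums(tab)
  cells <- which(tab > 0, arr.ind = TRUE)
  overlap <- data.frame(
    cluster_a = rownames(tab)[cells[, 1]],
    cluster_b = colnames(tab)[cells[, 2]],
    count = tab[cells],
    overlap_pct = 100 * tab[cells] /
      if (denominator == "min") {
        pmin(sizes_a[cells[, 1]], sizes_b[cells[, 2]])
      } else sizes_a[cells[, 1]],
    row.names = NULL
  )
  overlap$high_overlap <- overlap$overlap_pct > threshold
  ord <- order(overlap$cluster_a, overlap$cluster_b)
  overlap <- overlap[ord, , drop = FALSE]
  structure(
    list(contingency = tab, overlap = overlap,
         n_combinations = nrow(overlap),
         high_overlap_fraction = sum(overlap$count[overlap$high_overlap]) /
           length(labels_a),
         threshold = threshold, denominator = denominator),
    class = "correspondence_result"
  )
}

#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf("<correspondence_result> %d combinations, %d above %g%% (%.0f%% of neurons)\n",
              x$n_combinations, sum(x$overlap$high_overlap), x$threshold,
              100 * x$high_overlap_fraction))
  print(x$contingency)
  invisible(x)
}
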
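# Metadata columns of a feature table that are never treated as features.
META_COLUMNS <- c("neuron_id", "population", "cluster", "firing_type",
                  "qc_pass")

#' Numeric feature matrix of a feature table
#'
#' @param table A feature table (`data.frame`).
#' @param features Which feature columns to use; default all non-metadata
#'   numeric columns.
#' @return A numeric matrix with neuron ids as row names.
#' @export
feature_matrix <- function(table, features = NULL) {
  if (is.matrix(table)) return(table)
  if (is.null(features)) {
    features <- setdiff(names(table), META_COLUMNS)
    features <- features[vapply(table[features], is.numeric, logical(1))]
  }
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(table[features])
  if (!is.null(table$neuron_id)) rownames(m) <- table$neuron_id
  m
}

# Pearson r and two-sided p for all feature pairs (direct t-distribution
# p-values, as in the classical correlation test).
pearson_matrix <- function(X) {
  n <- nrow(X)
  r <- cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.finite(p)] <- 0 # |r| = 1 pairs
  diag(p) <- NA
  diag(r) <- NA
  list(r = r, p = p)
}

#' Pearson correlation screen for redundant properties
#'
#' Computes all pairwise Pearson correlations with two-sided p-values and
#' iteratively removes features until no retained pair is correlated at
#' `alpha`: at each step the pair with the smallest p-value is taken and
#' its lower-priority member dropped. The default keep-priority ranks the
#' six non-redundant properties (resting potential, capacitance, fAHP
#' duration, fAHP amplitude, PIC onset, F/I slope) above all others, which
#' makes the published reduction reproducible; passing
#' `keep_priority = NULL` gives a priority-free greedy screen in which the
#' member with the larger mean |r| against the remaining features is
#' dropped.
#'
#' @param table A feature table (or numeric matrix), >= 4 rows.
#' @param alpha Significance threshold for "highly correlated". The
#'   default 0.001 matches the shading convention of the published
#'   correlation matrix; 0.01 (the accompanying text's threshold) is
#'   available here.
#' @param keep_priority Ordered character vector; earlier features are
#'   kept preferentially. Features not listed rank below all listed ones.
#' @param features Optional explicit feature set.
#' @return A list of class `"correlation_screen"` with `r_matrix`,
#'   `p_matrix`, `retained`, `removed`, `alpha`.
#' @export
correlation_screen <- function(table, alpha = 0.001,
                               keep_priority = RETAINED_FEATURES,
                               features = NULL) {
  X <- feature_matrix(table, features)
  if (ncol(X) < 2) stop("need at least 2 features")
  if (nrow(X) < 4) stop("need at least 4 rows")
  const <- apply(X, 2, function(x) sd(x) == 0 || !all(is.finite(x)))
  excluded <- colnames(X)[const]
  if (length(excluded) > 0) {
    warning("constant or non-finite columns excluded from screen: ",
            paste(excluded, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  pm <- pearson_matrix(X)
  feats <- colnames(X)
  prio <- function(f) {
    i <- match(f, keep_priority)
    ifelse(is.na(i), Inf, i)
  }
  active <- feats
  removed <- character(0)
  repeat {
    sub <- pm$p[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    if (all(is.na(sub)) || min(sub, na.rm = TRUE) >= alpha) break
    idx <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- c(active[idx[1]], active[idx[2]])
    ranks <- prio(pair)
    drop <- if (ranks[1] < ranks[2]) pair[2]
    else if (ranks[2] < ranks[1]) pair[1]
    else { # tie: drop the member more correlated with everything else
      others <- setdiff(active, pair)
      if (length(others) == 0) pair[2] else {
        mr <- vapply(pair, function(f) mean(abs(pm$r[f, others])), numeric(1))
        pair[which.max(mr)]
      }
    }
    removed <- c(removed, drop)
    active <- setdiff(active, drop)
    if (length(active) < 2) break
  }
  structure(
    list(r_matrix = pm$r, p_matrix = pm$p, retained = active,
         removed = c(removed, excluded), alpha = alpha),
    class = "correlation_screen"
  )
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> alpha = %g: %d retained, %d removed\n",
              x$alpha, length(x$retained), length(x$removed)))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Z-standardize the feature columns of a table
#'
#' Sets each feature column to mean 0 and SD 1 (sample SD, n-1, by
#' default), storing the original means and SDs in the
#' `"standardization"` attribute for the inverse transform.
#'
#' @param table A feature table.
#' @param features Optional explicit feature set.
#' @param population_sd Use the population (1/n) SD convention instead of
#'   the sample SD.
#' @return The table with standardized feature columns.
#' @export
standardize_features <- function(table, features = NULL,
                                 population_sd = FALSE) {
  X <- feature_matrix(table, features)
  if (nrow(X) < 2) stop("cannot standardize a single-row table")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (population_sd) sdev <- sdev * sqrt((nrow(X) - 1) / nrow(X))
  if (any(sdev == 0)) {
    stop("constant column(s): ",
         paste(colnames(X)[sdev == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  out <- table
  if (is.matrix(table)) out <- Z else out[colnames(Z)] <- as.data.frame(Z)
  attr(out, "standardization") <- list(mean = mu, sd = sdev,
                                       population_sd = population_sd)
  out
}

#' Principal component analysis of a standardized feature table
#'
#' @param ztable A standardized feature table (see
#'   [standardize_features()]).
#' @param groups Optional grouping vector (e.g. population or firing
#'   type); per-group ellipsoid summaries (mean and SD of the first three
#'   PC scores) are reported for it.
#' @param features Optional explicit feature set.
#' @return A list of class `"pca_result"` with `loadings`, `scores`,
#'   `variance_fraction`, `rank_deficient` flags, and `ellipsoids`.
#' @export
run_pca <- function(ztable, groups = NULL, features = NULL) {
  X <- feature_matrix(ztable, features)
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  rank_def <- vf < 1e-12
  ell <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    npc <- min(3, ncol(fit$x))
    ell <- do.call(rbind, lapply(unique(groups), function(g) {
      sc <- fit$x[groups == g, seq_len(npc), drop = FALSE]
      data.frame(group = g, component = colnames(sc),
                 center = colMeans(sc), semi_axis = apply(sc, 2, sd),
                 row.names = NULL)
    }))
  }
  structure(
    list(loadings = fit$rotation, scores = fit$x, variance_fraction = vf,
         rank_deficient = rank_def, center = fit$center, ellipsoids = ell),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$scores), "components; variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(min(3, length(x$variance_fraction)))]),
            collapse = ", "), "...\n")
  invisible(x)
}
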
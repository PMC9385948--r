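# One run of Lloyd's algorithm with given initial centers; records the
# within-cluster sum of squares after every update so the monotone
# descent of the objective can be verified.
lloyd_kmeans <- function(X, centers, max_iter = 100) {
  k <- nrow(centers)
  n <- nrow(X)
  labels <- integer(n)
  wss_trace <- numeric(0)
  xsq <- rowSums(X^2)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster with the point farthest from its center,
    # drawing only from clusters that can spare a member
    repeat {
      empties <- setdiff(seq_len(k), unique(new_labels))
      if (length(empties) == 0) break
      sizes <- tabulate(new_labels, k)
      eligible <- which(sizes[new_labels] > 1)
      far <- eligible[which.max(d2[cbind(eligible, new_labels[eligible])])]
      new_labels[far] <- empties[1]
    }
    for (c in seq_len(k)) {
      centers[c, ] <- colMeans(X[new_labels == c, , drop = FALSE])
    }
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    wss_trace <- c(wss_trace, sum(pmax(d2[cbind(seq_len(n), new_labels)], 0)))
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  list(labels = labels, centers = centers, wss = wss_trace[length(wss_trace)],
       wss_trace = wss_trace, iterations = it)
}

#' Silhouette values of a partition
#'
#' The standard silhouette `s(i) = (b - a) / max(a, b)`, where `a` is the
#' mean distance of neuron `i` to the other members of its cluster and `b`
#' the smallest mean distance to another cluster. Members of singleton
#' clusters get `s = 0` (documented convention).
#'
#' @param X A numeric matrix (rows = neurons), or a precomputed distance
#'   matrix passed as `dist_matrix`.
#' @param labels Integer/character cluster labels; at least two clusters,
#'   all non-empty.
#' @param metric Distance metric when computing from `X` (`"euclidean"`,
#'   `"cosine"`, `"correlation"`, `"cityblock"`).
#' @param dist_matrix Optional `n x n` distance matrix (overrides `X`).
#' @return Numeric vector of per-neuron silhouette values in `[-1, 1]`.
#' @export
silhouette_values <- function(X, labels, metric = "euclidean",
                              dist_matrix = NULL) {
  D <- if (is.null(dist_matrix)) {
    as.matrix(pairwise_distances(X, metric))
  } else as.matrix(dist_matrix)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least 2 clusters")
  n <- nrow(D)
  sums <- t(rowsum(D, labels))          # n x k: total distance to each cluster
  sizes <- tabulate(labels, k)
  a <- sums[cbind(seq_len(n), labels)] / pmax(sizes[labels] - 1, 1)
  mean_to <- sweep(sums, 2, sizes, "/")
  mean_to[cbind(seq_len(n), labels)] <- Inf
  b <- apply(mean_to, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  s[!is.finite(s)] <- 0
  unname(s)
}

#' Best-of-restarts k-means
#'
#' Runs Lloyd's algorithm `restarts` times with initial centers drawn
#' uniformly from the data points without replacement, and returns the
#' restart whose partition maximizes the mean silhouette. Deterministic
#' given `seed`.
#'
#' @param X Standardized feature table or numeric matrix.
#' @param k Number of clusters (2 <= k < n).
#' @param restarts Number of random restarts.
#' @param seed Integer seed governing the whole restart sequence.
#' @param dist_matrix Optional precomputed Euclidean distance matrix for
#'   the silhouette (saves recomputation across calls).
#' @param features Optional explicit feature set.
#' @return A list of class `"cluster_assignment"` with `method =
#'   "kmeans"`, `labels`, `k`, `silhouette` (per neuron),
#'   `mean_silhouette`, `centroids`, `wss`, `wss_trace`, `seed`,
#'   `restarts`.
#' @export
kmeans_best_of_restarts <- function(X, k, restarts = 100, seed = 1L,
                                    dist_matrix = NULL, features = NULL) {
  X <- feature_matrix(X, features)
  n <- nrow(X)
  if (k < 2) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of neurons")
  if (restarts < 1) stop("restarts must be >= 1")
  if (is.null(dist_matrix)) dist_matrix <- as.matrix(dist(X))
  best <- NULL
  best_sil <- -Inf
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- X[sample.int(n, k), , drop = FALSE]
      fit <- lloyd_kmeans(X, init)
      s <- silhouette_values(X, fit$labels, dist_matrix = dist_matrix)
      ms <- mean(s)
      if (ms > best_sil) {
        best_sil <- ms
        best <- c(fit, list(silhouette = s))
      }
    }
  })
  structure(
    list(method = "kmeans", labels = best$labels, k = k,
         silhouette = best$silhouette, mean_silhouette = best_sil,
         centroids = best$centers, wss = best$wss,
         wss_trace = best$wss_trace, seed = seed, restarts = restarts),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s, k = %d, sizes: %s, mean silhouette %.3f\n",
              x$method, x$k,
              paste(tabulate(as.integer(factor(x$labels)), x$k), collapse = "/"),
              mean(x$silhouette)))
  invisible(x)
}

#' Select the number of k-means clusters by the silhouette elbow
#'
#' For each `k` in `k_range` the best-of-restarts mean silhouette is
#' recorded; the chosen `k` is the smallest one after which no larger `k`
#' improves the best silhouette by at least `eps` (the plateau reading of
#' the elbow rule).
#'
#' @param X Standardized feature table or matrix.
#' @param k_range Candidate cluster numbers (2-8 convention).
#' @param restarts Restarts per `k`.
#' @param seed Integer seed.
#' @param eps Plateau tolerance (absolute, on the mean silhouette).
#' @param features Optional explicit feature set.
#' @return A list of class `"k_selection_curve"` with `k`,
#'   `best_silhouette`, `chosen_k`, and the `assignments` per `k`.
#' @export
select_k_by_silhouette_elbow <- function(X, k_range = 2:8, restarts = 100,
                                         seed = 1L, eps = 0.01,
                                         features = NULL) {
  if (length(k_range) == 0) stop("empty k range")
  X <- feature_matrix(X, features)
  if (any(k_range < 2) || any(k_range >= nrow(X))) {
    stop("k_range must lie within [2, n)")
  }
  D <- as.matrix(dist(X))
  fits <- lapply(seq_along(k_range), function(i) {
    kmeans_best_of_restarts(X, k_range[i], restarts = restarts,
                            seed = seed + i - 1L, dist_matrix = D)
  })
  best <- vapply(fits, function(f) f$mean_silhouette, numeric(1))
  chosen <- k_range[length(k_range)]
  for (i in seq_along(k_range)) {
    later <- best[seq_along(k_range) > i]
    if (all(later - best[i] < eps)) { chosen <- k_range[i]; break }
  }
  structure(
    list(k = k_range, best_silhouette = best, chosen_k = chosen,
         eps = eps, assignments = fits),
    class = "k_selection_curve"
  )
}

#' @export
print.k_selection_curve <- function(x, ...) {
  cat("<k_selection_curve> chosen k =", x$chosen_k, "\n")
  print(setNames(round(x$best_silhouette, 3), paste0("k", x$k)))
  invisible(x)
}

#' Pairwise distances under the candidate metrics
#'
#' @param X Numeric matrix, rows = observations.
#' @param metric `"euclidean"`, `"cosine"`, `"correlation"`, or
#'   `"cityblock"`.
#' @return A `dist` object.
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "cosine",
                                             "correlation", "cityblock")) {
  metric <- match.arg(metric)
  switch(metric,
    euclidean = dist(X),
    cityblock = dist(X, method = "manhattan"),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      zero <- which(nrm == 0)
      if (length(zero) > 0) {
        stop("cosine distance undefined for zero-vector row(s): ",
             paste(zero, collapse = ", "))
      }
      S <- (X / nrm) %*% t(X / nrm)
      as.dist(pmin(pmax(1 - S, 0), 2))
    },
    correlation = as.dist(1 - cor(t(X)))
  )
}

#' Hierarchical clustering with data-driven metric/linkage selection
#'
#' Builds a dendrogram for every valid (metric, linkage) combination in
#' the candidate grid and returns the one with the highest cophenetic
#' correlation coefficient (the correlation between the original pairwise
#' distances and the dendrogram's merge heights), the model-selection
#' criterion that picked the cosine/average combination in the published
#' analysis.
#'
#' @param X Feature table or numeric matrix (standardized upstream).
#' @param metrics,linkages Candidate grids. `"weighted"` is the WPGMA
#'   linkage (`hclust` method `"mcquitty"`).
#' @param features Optional explicit feature set.
#' @return A list of class `"linkage_tree"` with the `hclust` fit,
#'   `metric`, `linkage`, `cophenetic_coefficient`, the full `grid`
#'   (data.frame of all combinations), and the `distances` used.
#' @export
fit_dendrogram <- function(X, metrics = c("euclidean", "cosine",
                                          "correlation", "cityblock"),
                           linkages = c("average", "complete", "single",
                                        "weighted"),
                           features = NULL) {
  X <- feature_matrix(X, features)
  if (nrow(X) < 3) stop("need at least 3 observations")
  hclust_method <- c(average = "average", complete = "complete",
                     single = "single", weighted = "mcquitty")
  grid <- expand.grid(metric = metrics, linkage = linkages,
                      stringsAsFactors = FALSE)
  grid$cophenetic <- NA_real_
  fits <- vector("list", nrow(grid))
  dists <- lapply(setNames(metrics, metrics),
                  function(m) pairwise_distances(X, m))
  for (i in seq_len(nrow(grid))) {
    d <- dists[[grid$metric[i]]]
    hc <- hclust(d, method = hclust_method[[grid$linkage[i]]])
    grid$cophenetic[i] <- suppressWarnings(cor(d, cophenetic(hc)))
    fits[[i]] <- hc
  }
  # degenerate inputs (all distances equal) leave the coefficient undefined
  win <- if (all(is.na(grid$cophenetic))) 1L else which.max(grid$cophenetic)
  structure(
    list(hclust = fits[[win]], merge = fits[[win]]$merge,
         height = fits[[win]]$height, metric = grid$metric[win],
         linkage = grid$linkage[win],
         cophenetic_coefficient = grid$cophenetic[win], grid = grid,
         distances = dists[[grid$metric[win]]]),
    class = "linkage_tree"
  )
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %s distance, %s linkage, cophenetic r = %.4f (%d leaves)\n",
              x$metric, x$linkage, x$cophenetic_coefficient,
              length(x$height) + 1L))
  invisible(x)
}

#' Inconsistency coefficient of each dendrogram link
#'
#' For each non-leaf link, the links within `depth` levels below it
#' (including itself) are collected; the inconsistency is the link's
#' height minus the mean of those heights, divided by their standard
#' deviation (0 when the SD is 0).
#'
#' @param tree A `linkage_tree` or `hclust` object.
#' @param depth Comparison depth (conventional default 2).
#' @return A data.frame with `mean_height`, `sd_height`, `n_links`,
#'   `inconsistency`, one row per link in merge order.
#' @export
inconsistency_coefficients <- function(tree, depth = 2) {
  if (depth < 1) stop("depth must be >= 1")
  hc <- if (inherits(tree, "linkage_tree")) tree$hclust else tree
  m <- hc$merge
  h <- hc$height
  n_links <- nrow(m)
  out <- data.frame(mean_height = numeric(n_links),
                    sd_height = numeric(n_links),
                    n_links = integer(n_links),
                    inconsistency = numeric(n_links))
  for (i in seq_len(n_links)) {
    frontier <- i
    set <- i
    for (d in seq_len(depth - 1)) {
      kids <- m[frontier, , drop = FALSE]
      frontier <- kids[kids > 0]
      if (length(frontier) == 0) break
      set <- c(set, frontier)
    }
    hh <- h[set]
    mu <- mean(hh)
    s <- if (length(hh) > 1) sd(hh) else 0
    out$mean_height[i] <- mu
    out$sd_height[i] <- s
    out$n_links[i] <- length(hh)
    out$inconsistency[i] <- if (s == 0) 0 else (h[i] - mu) / s
  }
  out
}

#' Cut a dendrogram just below its maximum inconsistency
#'
#' The cut threshold is `max(inconsistency) * (1 - 1e-6)`; a link whose
#' inconsistency is below the threshold (and all of whose descendant links
#' are too) keeps its leaves merged, while links at or above it are cut.
#' When no link is inconsistent (maximum <= 0) the tree stays whole: one
#' cluster.
#'
#' @param tree A `linkage_tree` (as from [fit_dendrogram()]).
#' @param depth Inconsistency depth (see [inconsistency_coefficients()]).
#' @param cutoff Optional explicit inconsistency cutoff overriding the
#'   just-below-maximum construction.
#' @return A `"cluster_assignment"` with `method = "hierarchical"`;
#'   silhouettes are computed with the tree's own distances when the cut
#'   yields >= 2 clusters (otherwise `NA`).
#' @export
cut_by_inconsistency <- function(tree, depth = 2, cutoff = NULL) {
  hc <- if (inherits(tree, "linkage_tree")) tree$hclust else tree
  m <- hc$merge
  n <- nrow(m) + 1L
  inc <- inconsistency_coefficients(hc, depth)$inconsistency
  if (is.null(cutoff)) {
    if (max(inc) <= 0) cutoff <- Inf else cutoff <- max(inc) * (1 - 1e-6)
  }
  consistent <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    kids <- m[i, ]
    kids_ok <- all(vapply(kids, function(kk) kk < 0 || consistent[kk],
                          logical(1)))
    consistent[i] <- inc[i] < cutoff && kids_ok
  }
  labels <- integer(n)
  next_id <- 0L
  assign_leaves <- function(node, id) {
    stack <- node
    while (length(stack) > 0) {
      nd <- stack[[1]]; stack <- stack[-1]
      if (nd < 0) labels[-nd] <<- id else stack <- c(stack, m[nd, ])
    }
  }
  walk <- list(nrow(m))
  while (length(walk) > 0) {
    nd <- walk[[1]]; walk <- walk[-1]
    if (nd < 0 || consistent[nd]) {
      next_id <- next_id + 1L
      assign_leaves(nd, next_id)
    } else {
      walk <- c(walk, m[nd, ])
    }
  }
  k <- next_id
  sil <- rep(NA_real_, n)
  if (k >= 2 && inherits(tree, "linkage_tree")) {
    sil <- silhouette_values(NULL, labels, dist_matrix = tree$distances)
  }
  structure(
    list(method = "hierarchical", labels = labels, k = k, silhouette = sil,
         depth = depth, cutoff = cutoff,
         metric = if (inherits(tree, "linkage_tree")) tree$metric else NA,
         linkage = if (inherits(tree, "linkage_tree")) tree$linkage else NA),
    class = "cluster_assignment"
  )
}

#' Export a dendrogram in Newick format
#'
#' @param tree A `linkage_tree` or `hclust`.
#' @return A single Newick string with branch lengths derived from merge
#'   heights.
#' @export
as_newick <- function(tree) {
  hc <- if (inherits(tree, "linkage_tree")) tree$hclust else tree
  lab <- if (is.null(hc$labels)) as.character(seq_len(nrow(hc$merge) + 1L)) else hc$labels
  node_str <- function(nd, parent_h) {
    if (nd < 0) {
      sprintf("%s:%.6g", lab[-nd], parent_h)
    } else {
      kids <- hc$merge[nd, ]
      sprintf("(%s,%s):%.6g",
              node_str(kids[1], hc$height[nd] / 2),
              node_str(kids[2], hc$height[nd] / 2),
              parent_h - hc$height[nd] / 2)
    }
  }
  root <- nrow(hc$merge)
  kids <- hc$merge[root, ]
  h <- hc$height[root]
  paste0("(", node_str(kids[1], h / 2), ",", node_str(kids[2], h / 2), ");")
}
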
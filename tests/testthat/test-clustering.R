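test_that("the k-means objective never increases and seeds fix the outcome", {
  withr::with_seed(5, {
    for (i in 1:10) {
      X <- matrix(rnorm(60 * 3), 60, 3)
      km <- kmeans_best_of_restarts(X, k = sample(2:5, 1), restarts = 5,
                                    seed = i)
      expect_true(all(diff(km$wss_trace) <= 1e-9))
    }
  })
  X <- matrix(rnorm(80 * 4), 80, 4)
  a <- kmeans_best_of_restarts(X, 3, restarts = 20, seed = 123)
  b <- kmeans_best_of_restarts(X, 3, restarts = 20, seed = 123)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
  expect_error(kmeans_best_of_restarts(X, 80, seed = 1), "smaller")
  # agreement with the reference Lloyd implementation on an easy instance
  Y <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 5, 0.2), 20, 2))
  km <- kmeans_best_of_restarts(Y, 2, restarts = 5, seed = 2)
  ref <- kmeans(Y, 2, algorithm = "Lloyd", nstart = 5)
  expect_true(same_partition(km$labels, ref$cluster))
})

test_that("k-means separates point masses and matches exhaustive enumeration", {
  X <- rbind(matrix(0, 2, 2), matrix(10, 2, 2))
  km <- kmeans_best_of_restarts(X, 2, restarts = 3, seed = 1)
  expect_equal(sort(unname(tabulate(km$labels))), c(2, 2))
  expect_true(all(km$silhouette == 1))
  # two tight triads: recovered split equals the brute-force WSS optimum
  withr::with_seed(6, {
    Y <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2),
               matrix(rnorm(6, 8, 0.1), 3, 2))
    km2 <- kmeans_best_of_restarts(Y, 2, restarts = 10, seed = 3)
    brute <- brute_best_2partition(Y)
    expect_true(same_partition(km2$labels, brute$labels))
    # stability: 1 restart and many restarts agree on this easy case
    km_one <- kmeans_best_of_restarts(Y, 2, restarts = 1, seed = 11)
    km_many <- kmeans_best_of_restarts(Y, 2, restarts = 1000, seed = 11)
    expect_true(same_partition(km_one$labels, km_many$labels))
  })
})

test_that("silhouette values match brute force and the cluster package", {
  # closed-form 1-D case: two tight pairs
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  s <- silhouette_values(X, c(1, 1, 2, 2))
  expect_true(all(s > 0.9))
  # a point equidistant from both clusters scores 0
  X2 <- matrix(c(0, 2, 4), 3, 1)
  expect_equal(silhouette_values(X2, c(1, 1, 2))[2], 0)
  expect_error(silhouette_values(X2, c(1, 1, 1)), "2 clusters")
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(10:50, 1)
      k <- sample(2:4, 1)
      X <- matrix(rnorm(n * 3), n, 3)
      lab <- sample(rep(1:k, length.out = n))
      D <- as.matrix(dist(X))
      s <- silhouette_values(X, lab)
      expect_equal(s, brute_silhouette(D, lab), tolerance = 1e-12)
      ref <- cluster::silhouette(lab, dist(X))[, "sil_width"]
      expect_equal(s, unname(ref), tolerance = 1e-12)
    }
  })
})

test_that("the silhouette elbow finds obvious cluster counts", {
  # two point masses
  X <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) + rnorm(20, 0, 1e-3)
  sel <- select_k_by_silhouette_elbow(X, k_range = 2:5, restarts = 5,
                                      seed = 1)
  expect_equal(sel$chosen_k, 2)
  # four well-separated Gaussians
  withr::with_seed(9, {
    mu <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
    X4 <- do.call(rbind, lapply(1:4, function(i) {
      cbind(rnorm(15, mu[i, 1], 0.4), rnorm(15, mu[i, 2], 0.4))
    }))
    sel4 <- select_k_by_silhouette_elbow(X4, k_range = 2:8, restarts = 20,
                                         seed = 2)
    expect_equal(sel4$chosen_k, 4)
    # single blob: low flat-ish curve; the plateau rule lands on the
    # smallest k within eps of everything later (documented degenerate
    # behavior)
    X1 <- matrix(rnorm(120 * 2), 120, 2)
    sel1 <- select_k_by_silhouette_elbow(X1, k_range = 2:6, restarts = 10,
                                         seed = 3)
    expect_lt(max(sel1$best_silhouette), 0.5)
    i <- match(sel1$chosen_k, sel1$k)
    expect_true(all(sel1$best_silhouette[-seq_len(i)] -
                      sel1$best_silhouette[i] < sel1$eps))
  })
  expect_error(select_k_by_silhouette_elbow(X, k_range = integer(0)),
               "empty")
})

test_that("dendrogram selection maximizes the cophenetic coefficient", {
  # ultrametric configuration: two tight pairs with all cross-pair
  # distances equal -> cophenetic correlation exactly 1
  X <- rbind(c(-0.5, 0, 0), c(0.5, 0, 0), c(0, -0.5, 5), c(0, 0.5, 5))
  tree <- fit_dendrogram(X, metrics = "euclidean",
                         linkages = c("average", "complete", "single"))
  expect_equal(tree$cophenetic_coefficient, 1, tolerance = 1e-12)
  expect_equal(nrow(tree$grid), 3)
  # full grid on the reference cohort: winner reported with a complete grid
  tab <- standardize_features(simulate_reference_cohort(
    generator_config(seed = 5), features = "retained"))
  full <- fit_dendrogram(feature_matrix(tab))
  expect_equal(nrow(full$grid), 16)
  expect_equal(full$cophenetic_coefficient, max(full$grid$cophenetic))
  expect_true(full$metric %in% c("euclidean", "cosine", "correlation",
                                 "cityblock"))
  # brute-force cophenetic correlation agreement on random instances
  withr::with_seed(10, {
    for (i in 1:5) {
      Y <- matrix(rnorm(20 * 3), 20, 3)
      tr <- fit_dendrogram(Y, metrics = "euclidean", linkages = "average")
      expect_equal(tr$cophenetic_coefficient,
                   brute_cophenetic_cor(dist(Y), tr$hclust),
                   tolerance = 1e-10)
    }
  })
  # cosine metric rejects zero rows
  Z <- rbind(c(0, 0), c(1, 2), c(3, 1))
  expect_error(fit_dendrogram(Z, metrics = "cosine", linkages = "average"),
               "zero-vector")
})

test_that("inconsistency coefficients match brute force and cut sensibly", {
  # two tight pairs joined by one long link -> 2 clusters
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  tree <- fit_dendrogram(X, metrics = "euclidean", linkages = "average")
  inc <- inconsistency_coefficients(tree, depth = 2)
  expect_equal(inc$inconsistency[1:2], c(0, 0))
  expect_gt(inc$inconsistency[3], 0)
  cut <- cut_by_inconsistency(tree)
  expect_equal(cut$k, 2)
  expect_true(same_partition(cut$labels, c(1, 1, 2, 2)))
  expect_error(inconsistency_coefficients(tree, depth = 0), "depth")
  # all pairwise distances equal (regular simplex): no inconsistent link,
  # one cluster
  simplex <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(0, 0, 0))
  stree <- fit_dendrogram(simplex, metrics = "euclidean",
                          linkages = "average")
  scut <- cut_by_inconsistency(stree)
  expect_equal(scut$k, 1)
  # oracle equivalence on random trees
  withr::with_seed(11, {
    for (i in 1:5) {
      Y <- matrix(rnorm(20 * 2), 20, 2)
      tr <- fit_dendrogram(Y, metrics = "euclidean", linkages = "average")
      for (d in 1:3) {
        expect_equal(inconsistency_coefficients(tr, d)$inconsistency,
                     brute_inconsistency(tr$merge, tr$height, d),
                     tolerance = 1e-10)
      }
      # any cut yields a valid partition with 1..n clusters
      cc <- cut_by_inconsistency(tr, depth = sample(1:3, 1))
      expect_true(cc$k >= 1 && cc$k <= 20)
      expect_equal(sort(unique(cc$labels)), seq_len(cc$k))
    }
  })
})

test_that("label recovery on the 4-component reference mixture meets the stated bounds", {
  retained <- reference_cohort()$retained_features
  ari <- function(sd_scale, seeds) {
    vapply(seeds, function(s) {
      tab <- sample_feature_table(pooled_cluster_specs(),
                                  generator_config(seed = s,
                                                   sd_scale = sd_scale))
      z <- standardize_features(tab, features = retained)
      km <- kmeans_best_of_restarts(feature_matrix(z, retained), 4,
                                    restarts = 20, seed = s)
      mclust::adjustedRandIndex(km$labels, tab$cluster)
    }, numeric(1))
  }
  # clearly separated mixture (SDs halved): near-perfect recovery
  expect_gte(median(ari(0.5, 1:10)), 0.9)
  # unscaled SDs: clusters overlap; the documented looser bound holds
  expect_gte(median(ari(1, 1:20)), 0.4)
})

test_that("dendrograms serialize to parseable Newick with heights", {
  X <- matrix(rnorm(12 * 2), 12, 2)
  tree <- fit_dendrogram(X, metrics = "euclidean", linkages = "average")
  nwk <- as_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_equal(length(phy$tip.label), 12)
})
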
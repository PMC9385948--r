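#' Published reference-cohort parameters
#'
#' Loads the packaged description of the reference cohort of 171 adult lumbar
#' spinal interneurons (143 Shox2, 28 Chx10): group compositions (firing
#' types, k-means clusters, hierarchical clusters) and the per-subgroup
#' mean/SD of the 12 electrophysiological properties. These parameters drive
#' [sample_feature_table()] and [simulate_reference_cohort()].
#'
#' @return A list with elements `cohort`, `features`, `retained_features`,
#'   `firing_type_counts`, `kmeans_cluster_counts`,
#'   `hierarchical_cluster_counts`, and `cluster_specs` (a list of
#'   [cluster_spec()] objects, one per cluster-by-population subgroup).
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.json",
                      package = "ephysclust", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw$cluster_specs, function(s) {
    cluster_spec(
      name = s$cluster,
      population = s$population,
      n = s$n,
      mean = unlist(s$mean),
      sd = unlist(s$sd)
    )
  })
  counts_df <- function(x) {
    pops <- names(x)
    groups <- names(x[[1]])
    m <- sapply(pops, function(p) unlist(x[[p]])[groups])
    rownames(m) <- groups
    m
  }
  list(
    cohort = unlist(raw$cohort),
    features = unlist(raw$features),
    retained_features = unlist(raw$retained_features),
    firing_type_counts = counts_df(raw$firing_type_counts),
    kmeans_cluster_counts = counts_df(raw$kmeans_cluster_counts),
    hierarchical_cluster_counts = counts_df(raw$hierarchical_cluster_counts),
    cluster_specs = specs
  )
}

#' Per-subgroup feature distribution specification
#'
#' A cluster spec names one generative subgroup (a cluster by population
#' cell) and carries the mean and SD of each of the 12 properties for that
#' subgroup, plus how many neurons it contributes.
#'
#' @param name Cluster label (e.g. `"k1"`).
#' @param population `"Shox2"` or `"Chx10"`.
#' @param n Number of neurons to draw from this subgroup (count >= 0).
#' @param mean,sd Named numeric vectors over the feature columns; `sd` must
#'   be non-negative. Names must match between `mean` and `sd`.
#' @return An object of class `"cluster_spec"`.
#' @export
cluster_spec <- function(name, population = c("Shox2", "Chx10"), n, mean, sd) {
  population <- match.arg(population)
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (is.null(names(mean)) || is.null(names(sd)) ||
      !identical(sort(names(mean)), sort(names(sd)))) {
    stop("`mean` and `sd` must be named numeric vectors over the same features")
  }
  sd <- sd[names(mean)]
  if (any(sd < 0)) stop("all SDs must be >= 0")
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("`n` must be a non-negative count")
  structure(
    list(name = as.character(name), population = population, n = n,
         mean = mean, sd = sd),
    class = "cluster_spec"
  )
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat(sprintf("<cluster_spec> %s / %s, n = %d, %d features\n",
              x$name, x$population, x$n, length(x$mean)))
  invisible(x)
}
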
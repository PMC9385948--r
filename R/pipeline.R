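#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pipeline()]. Every stage parameter
#' has the analysis-convention default; ranges are checked before any
#' computation.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param alpha Correlation-screen significance threshold.
#' @param keep_priority Keep-priority of the screen (see
#'   [correlation_screen()]).
#' @param k_range Candidate k-means cluster numbers.
#' @param restarts k-means restarts per k.
#' @param elbow_eps Plateau tolerance of the silhouette elbow.
#' @param metrics,linkages Hierarchical candidate grids.
#' @param depth Inconsistency depth for the dendrogram cut.
#' @param overlap_threshold High-overlap flag threshold, percent.
#' @param qc Apply the QC exclusions (drop rows with `qc_pass == FALSE`).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.001,
                            keep_priority = RETAINED_FEATURES,
                            k_range = 2:8, restarts = 100,
                            elbow_eps = 0.01,
                            metrics = c("euclidean", "cosine",
                                        "correlation", "cityblock"),
                            linkages = c("average", "complete", "single",
                                         "weighted"),
                            depth = 2, overlap_threshold = 80, qc = TRUE) {
  if (length(k_range) < 1 || any(diff(k_range) <= 0)) {
    stop("k_range must be strictly increasing")
  }
  if (any(k_range < 2)) stop("k_range must start at 2 or above")
  if (restarts < 1) stop("restarts must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (depth < 1) stop("depth must be >= 1")
  structure(
    list(seed = as.integer(seed), alpha = alpha,
         keep_priority = keep_priority, k_range = k_range,
         restarts = restarts, elbow_eps = elbow_eps, metrics = metrics,
         linkages = linkages, depth = depth,
         overlap_threshold = overlap_threshold, qc = isTRUE(qc)),
    class = "pipeline_config"
  )
}

#' Run the full classification pipeline on a feature table
#'
#' Executes QC filtering, the correlation screen, z-standardization, PCA,
#' silhouette-elbow k-means, hierarchical clustering with cophenetic
#' metric/linkage selection and inconsistency cutting, per-feature
#' cluster statistics, population-enrichment binomial tests, and the
#' k-by-H correspondence. Fully deterministic given the seed in the
#' config.
#'
#' @param table A feature table (`data.frame`) or path to one.
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory; when given, each stage's result
#'   is written there as JSON/delimited text.
#' @return A list of class `"run_report"` holding the config echo, QC
#'   exclusions, and every stage's result object.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config")
  }
  if (is.character(table)) table <- read_feature_table(table)
  report <- list(config = unclass(config), exclusions = list())

  # QC exclusions, each with a reason string
  if (config$qc && "qc_pass" %in% names(table)) {
    bad <- which(!table$qc_pass)
    report$exclusions <- lapply(bad, function(i) {
      list(neuron_id = table$neuron_id[i], reason = "failed QC")
    })
    if (length(bad) > 0) table <- table[-bad, , drop = FALSE]
  }
  feats <- intersect(EPHYS_FEATURES, names(table))
  inc <- complete.cases(table[feats])
  if (any(!inc)) {
    report$exclusions <- c(report$exclusions,
      lapply(which(!inc), function(i) {
        list(neuron_id = table$neuron_id[i],
             reason = "missing clustering feature(s)")
      }))
    table <- table[inc, , drop = FALSE]
  }
  report$n_neurons <- nrow(table)

  screen <- correlation_screen(table, alpha = config$alpha,
                               keep_priority = config$keep_priority,
                               features = feats)
  report$screen <- screen

  ztab <- standardize_features(table, features = screen$retained)
  report$standardization <- attr(ztab, "standardization")

  report$pca <- run_pca(ztab, groups = table$population,
                        features = screen$retained)

  Z <- feature_matrix(ztab, screen$retained)
  sel <- select_k_by_silhouette_elbow(Z, k_range = config$k_range,
                                      restarts = config$restarts,
                                      seed = config$seed,
                                      eps = config$elbow_eps)
  report$k_selection <- sel
  km <- sel$assignments[[match(sel$chosen_k, sel$k)]]
  report$kmeans <- km

  tree <- fit_dendrogram(Z, metrics = config$metrics,
                         linkages = config$linkages)
  report$dendrogram <- tree
  hier <- cut_by_inconsistency(tree, depth = config$depth)
  report$hierarchical <- hier

  report$cluster_stats <- lapply(setNames(feats, feats), function(f) {
    tryCatch(compare_feature_across_groups(table[[f]], km$labels),
             error = function(e) conditionMessage(e))
  })
  if (!is.null(table$population) && length(unique(table$population)) > 1) {
    report$enrichment <- cluster_enrichment_binomial(
      km$labels, table$population)
    report$composition_chi_square <- tryCatch(
      composition_chi_square(table(table$population, km$labels)),
      error = function(e) conditionMessage(e))
  }
  report$correspondence <- cluster_correspondence(
    km$labels, hier$labels, threshold = config$overlap_threshold)

  report <- structure(report, class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, table, out_dir)
  report
}

write_run_report <- function(report, table, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jw <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  jw(report$config, "config.json")
  jw(list(n_neurons = report$n_neurons, exclusions = report$exclusions),
     "qc.json")
  jw(list(retained = report$screen$retained,
          removed = report$screen$removed, alpha = report$screen$alpha),
     "screen.json")
  jw(list(variance_fraction = report$pca$variance_fraction), "pca.json")
  jw(list(k = report$k_selection$k,
          best_silhouette = report$k_selection$best_silhouette,
          chosen_k = report$k_selection$chosen_k), "k_selection.json")
  jw(list(metric = report$dendrogram$metric,
          linkage = report$dendrogram$linkage,
          cophenetic = report$dendrogram$cophenetic_coefficient,
          grid = report$dendrogram$grid), "dendrogram.json")
  assign_df <- data.frame(neuron_id = table$neuron_id,
                          kmeans = report$kmeans$labels,
                          hierarchical = report$hierarchical$labels,
                          silhouette_kmeans = report$kmeans$silhouette)
  write.table(assign_df, file.path(out_dir, "assignments.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jw(report$correspondence$overlap, "correspondence.json")
  writeLines(as_newick(report$dendrogram),
             file.path(out_dir, "dendrogram.nwk"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  neurons: %d (%d excluded)\n", x$n_neurons,
              length(x$exclusions)))
  cat(sprintf("  screen: %d retained (%s)\n", length(x$screen$retained),
              paste(x$screen$retained, collapse = ", ")))
  cat(sprintf("  k-means: chosen k = %d\n", x$k_selection$chosen_k))
  cat(sprintf("  hierarchical: %s/%s, %d clusters\n", x$dendrogram$metric,
              x$dendrogram$linkage, x$hierarchical$k))
  cat(sprintf("  correspondence: %d combinations, %.0f%% of neurons in high-overlap cells\n",
              x$correspondence$n_combinations,
              100 * x$correspondence$high_overlap_fraction))
  invisible(x)
}
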
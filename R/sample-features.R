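#' Configuration for the synthetic feature-table generator
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed and configuration (identical calls are bit-identical).
#' @param sd_scale Positive multiplier applied to every within-subgroup SD.
#'   `sd_scale = 0` collapses each subgroup onto its mean vector.
#' @param dependency_structure If `TRUE`, the six redundant properties
#'   (input resistance, time constant, rheobase, AP threshold, AP half
#'   width, sAHP duration) are generated as noisy functions of the retained
#'   properties instead of independently, reproducing the redundancy that
#'   the correlation screen is designed to remove (see
#'   [correlation_screen()]).
#' @param truncate If `TRUE`, Gaussian draws are truncated at physical
#'   bounds (positive resistances, durations and capacitances; normalized
#'   fAHP amplitude in \[0, 1\]) via inverse-CDF sampling. The default
#'   `FALSE` matches the published first and second moments exactly.
#' @param positive_model `"gaussian"` (default) or `"lognormal"`: how
#'   strictly positive, unbounded-above features are drawn. The lognormal
#'   option matches the published mean and SD while keeping heavy-tailed
#'   features (e.g. sAHP duration, capacitance) strictly positive, which
#'   the redundancy formulas of `dependency_structure` rely on.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, sd_scale = 1, dependency_structure = FALSE,
                             truncate = FALSE,
                             positive_model = c("gaussian", "lognormal")) {
  if (!is.numeric(sd_scale) || sd_scale < 0) stop("`sd_scale` must be >= 0")
  structure(
    list(seed = as.integer(seed), sd_scale = sd_scale,
         dependency_structure = isTRUE(dependency_structure),
         truncate = isTRUE(truncate),
         positive_model = match.arg(positive_model)),
    class = "generator_config"
  )
}

# Physical lower/upper bounds used when truncate = TRUE.
feature_bounds <- function(feature) {
  lower <- c(rin_mohm = 0, tau_ms = 0, cm_pf = 0, rheobase_pa = 0,
             ap_halfwidth_ms = 0, fahp_duration_ms = 0, sahp_duration_ms = 0,
             fahp_amplitude_norm = 0, fi_slope_hz_per_pa = 0)
  upper <- c(fahp_amplitude_norm = 1)
  c(lower = unname(lower[feature])[1], upper = unname(upper[feature])[1])
}

# Gaussian draw, optionally truncated to [a, b] by inverse-CDF sampling.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  if (is.na(lower)) lower <- -Inf
  if (is.na(upper)) upper <- Inf
  if (!is.finite(lower) && !is.finite(upper)) return(rnorm(n, mean, sd))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Coefficients of the built-in redundancy structure: each redundant
# property is a noisy function of retained properties (lognormal noise for
# strictly positive quantities, additive Gaussian otherwise). Rin scales as
# an imperfect inverse of cell size (Cm^-0.6), so the time constant
# tau = Rin x Cm inherits a Cm^0.4 dependence and stays correlated with
# capacitance. Noise magnitudes give pairwise correlation p-values far
# below 1e-4 at n = 171.
DEPENDENCY_COEFS <- list(
  rin_kappa = 8700,        # Rin = kappa / Cm^gamma * lognormal (MOhm)
  rin_gamma = 0.6,
  rin_lsd = 0.15,          # sd of log-noise on Rin
  rheo_scale = 0.5,        # rheobase = scale * (thr - vhold)/Rin * 1e3 * lognormal
  rheo_lsd = 0.20,
  thr_offset = 12,         # AP threshold = PIC_on + offset + N(0, thr_sd)
  thr_sd = 2,
  hw_beta = 0.22,          # half width = beta * fAHP duration + N(0, hw_sd)
  hw_sd = 0.08,
  sahp_g0 = 110,           # sAHP duration = g0 - g1 * F/I slope + N(0, sahp_sd)
  sahp_g1 = 100,
  sahp_sd = 15,
  vhold = -70              # holding potential for step protocols (mV)
)

draw_subgroup <- function(spec, config) {
  n <- spec$n
  feats <- names(spec$mean)
  out <- matrix(NA_real_, nrow = n, ncol = length(feats),
                dimnames = list(NULL, feats))
  draw_one <- function(f) {
    m <- spec$mean[[f]]
    s <- config$sd_scale * spec$sd[[f]]
    b <- feature_bounds(f)
    if (config$positive_model == "lognormal" &&
        identical(b[["lower"]], 0) && !is.finite(b[["upper"]]) &&
        m > 0 && s > 0) {
      # lognormal with the same first two moments
      lv <- log(1 + (s / m)^2)
      return(rlnorm(n, log(m) - lv / 2, sqrt(lv)))
    }
    if (!config$truncate) b <- c(lower = -Inf, upper = Inf)
    rnorm_trunc(n, m, s, b[["lower"]], b[["upper"]])
  }
  if (!config$dependency_structure) {
    for (f in feats) out[, f] <- draw_one(f)
    return(out)
  }
  # retained features drawn independently from the spec ...
  for (f in intersect(RETAINED_FEATURES, feats)) out[, f] <- draw_one(f)
  # ... redundant features derived from them
  cf <- DEPENDENCY_COEFS
  ln <- function(lsd) exp(rnorm(n, 0, lsd))
  out[, "rin_mohm"] <- cf$rin_kappa / out[, "cm_pf"]^cf$rin_gamma *
    ln(cf$rin_lsd)
  out[, "tau_ms"] <- out[, "rin_mohm"] * out[, "cm_pf"] / 1000
  out[, "ap_threshold_mv"] <- out[, "pic_on_mv"] + cf$thr_offset +
    rnorm(n, 0, cf$thr_sd)
  out[, "rheobase_pa"] <- cf$rheo_scale *
    (out[, "ap_threshold_mv"] - cf$vhold) / out[, "rin_mohm"] * 1000 *
    ln(cf$rheo_lsd)
  out[, "ap_halfwidth_ms"] <- cf$hw_beta * out[, "fahp_duration_ms"] +
    rnorm(n, 0, cf$hw_sd)
  out[, "sahp_duration_ms"] <- cf$sahp_g0 -
    cf$sahp_g1 * out[, "fi_slope_hz_per_pa"] + rnorm(n, 0, cf$sahp_sd)
  out
}

#' Sample a synthetic feature table from per-subgroup Gaussians
#'
#' Each neuron is drawn from a diagonal (independent-feature) Gaussian with
#' its subgroup's means and `sd_scale` x SDs. Rows carry the population
#' label and the generative cluster label, so label recovery by the
#' clustering stage can be measured. With `dependency_structure` on, the
#' six redundant properties are generated as noisy functions of the
#' retained six (see [generator_config()]).
#'
#' @param specs A list of [cluster_spec()] objects (at least one).
#' @param config A [generator_config()].
#' @return A `data.frame` with columns `neuron_id`, `population`, `cluster`
#'   and one column per feature in the specs.
#' @export
sample_feature_table <- function(specs, config = generator_config()) {
  if (inherits(specs, "cluster_spec")) specs <- list(specs)
  if (length(specs) < 1) stop("need at least one cluster_spec")
  ok <- vapply(specs, inherits, logical(1), "cluster_spec")
  if (!all(ok)) stop("`specs` must be a list of cluster_spec objects")
  withr::with_seed(config$seed, {
    blocks <- lapply(specs, function(s) {
      m <- draw_subgroup(s, config)
      data.frame(population = rep(s$population, s$n),
                 cluster = rep(s$name, s$n), m,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
  })
  out <- cbind(neuron_id = sprintf("n%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

pool_specs <- function(specs, name, n = NULL) {
  w <- vapply(specs, function(s) s$n, numeric(1))
  if (is.null(n)) n <- sum(w)
  w <- w / sum(w)
  feats <- names(specs[[1]]$mean)
  mu <- sapply(feats, function(f) {
    sum(w * vapply(specs, function(s) s$mean[[f]], numeric(1)))
  })
  vv <- sapply(feats, function(f) {
    m <- vapply(specs, function(s) s$mean[[f]], numeric(1))
    s2 <- vapply(specs, function(s) s$sd[[f]]^2, numeric(1))
    sum(w * s2) + sum(w * (m - mu[[f]])^2)
  })
  cluster_spec(name = name, population = specs[[1]]$population, n = n,
               mean = mu, sd = sqrt(vv))
}

#' Pooled cohort-level feature distribution
#'
#' Collapses the per-subgroup published means/SDs into a single
#' cohort-level spec via the law of total variance (between-subgroup
#' spread plus weighted within-subgroup variance).
#'
#' @param n Number of neurons the pooled spec should draw (default: the
#'   full cohort, 171).
#' @return A [cluster_spec()] named `"cohort"`.
#' @export
pooled_cohort_spec <- function(n = NULL) {
  pool_specs(reference_cohort()$cluster_specs, "cohort", n)
}

#' Four-component per-cluster feature distributions
#'
#' One pooled spec per published k-means cluster (populations within a
#' cluster collapsed by the law of total variance), giving the
#' 4-component diagonal-Gaussian mixture used for label-recovery
#' benchmarking.
#'
#' @return A list of four [cluster_spec()] objects (k1-k4, n = 23, 11,
#'   68, 69).
#' @export
pooled_cluster_specs <- function() {
  specs <- reference_cohort()$cluster_specs
  clusters <- unique(vapply(specs, `[[`, "", "name"))
  lapply(clusters, function(cl) {
    pool_specs(Filter(function(s) s$name == cl, specs), cl)
  })
}

#' Canonical dependency-structured 12-feature fixture
#'
#' A 171-neuron table in which the six retained properties are drawn
#' independently from the pooled cohort-level distribution (positive
#' features lognormally, so the redundancy formulas stay well-behaved) and
#' the six redundant properties are noisy functions of them. This is the
#' fixture on which the correlation screen reproduces the published
#' six-variable reduction deterministically.
#'
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param sd_scale Multiplier on the pooled SDs.
#' @return A `data.frame` as in [sample_feature_table()].
#' @export
dependency_fixture <- function(n = 171, seed = 1L, sd_scale = 1) {
  sample_feature_table(
    pooled_cohort_spec(n),
    generator_config(seed = seed, sd_scale = sd_scale,
                     dependency_structure = TRUE,
                     positive_model = "lognormal")
  )
}

#' Simulate the published-composition cohort
#'
#' Emits a 171-row synthetic feature table with the published composition:
#' 143 Shox2 neurons (23 in k1, 7 in k2, 56 in k3, 57 in k4) and 28 Chx10
#' neurons (0, 4, 12, 12), each subgroup drawn from its published
#' mean/SD column (see [reference_cohort()]).
#'
#' @param config A [generator_config()].
#' @param features `"all"` (the 12 properties) or `"retained"` (the six
#'   properties kept by the correlation screen, as used by the clustering
#'   stage).
#' @return A `data.frame` as in [sample_feature_table()].
#' @export
simulate_reference_cohort <- function(config = generator_config(),
                                      features = c("all", "retained")) {
  features <- match.arg(features)
  ref <- reference_cohort()
  tab <- sample_feature_table(ref$cluster_specs, config)
  if (features == "retained") {
    tab <- tab[, c("neuron_id", "population", "cluster", ref$retained_features)]
  }
  tab
}
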
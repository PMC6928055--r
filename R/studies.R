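# Canonical synthetic study designs. Each function freezes the conditions of
# one planted-truth experiment: the same designs drive the examples, the
# test suite and the acceptance script, so "what the generator emulates" is
# defined in exactly one place.

#' Canonical synthetic study designs
#'
#' Frozen study conditions for the planted-truth experiments the package is
#' validated on. Every design uses two cohorts of 75 (TR) and 80 (UR)
#' samples (except the enterotype design, 75 + 75) and sequencing depths
#' uniform in 10,000-60,000 reads.
#'
#' * `sim_study_diversity()`: one shared community component; the TR
#'   cohort's concentrations are flattened with [diversity_gap_spec()]
#'   (scale 5), giving TR higher expected Shannon/Simpson/Chao1.
#' * `sim_study_ordination()`: each cohort drawn from its own dominant
#'   component, so samples separate into two clusters in JSD space.
#' * `sim_study_enterotype(k)`: one cohort-agnostic mixture of `k`
#'   well-separated components (default 3) over 100 features, mixed
#'   uniformly; ground truth assignments in `$truth`.
#' * `sim_study_effects()`: 200 features with a capped rank-abundance
#'   profile (offset 20) at total concentration 300; 8-fold effects planted
#'   on five mid-abundance features (abundance ranks 70-110; three enriched
#'   in TR, two in UR). The planted ids are in
#'   `attr(spec, "planted_features")`.
#' * `sim_study_cores()`: five features planted as core in both cohorts and
#'   three TR-only (prevalence 0.9 at 1% abundance), plus three sporadic
#'   features (prevalence 0.4) that must not reach the core score;
#'   ids in `attr(spec, "planted")`.
#'
#' @param seed integer seed; the single source of randomness.
#' @param k number of mixture components for the enterotype design.
#' @return a [cohort_spec()], with design-specific attributes as noted.
#' @name sim_studies
NULL

#' @rdname sim_studies
#' @export
sim_study_diversity <- function(seed = 1L) {
  base <- cohort_spec(n_samples = c(TR = 75, UR = 80), n_features = 200,
                      seed = seed)
  diversity_gap_spec(base, "TR", 5)
}

#' @rdname sim_studies
#' @export
sim_study_ordination <- function(seed = 1L) {
  comps <- default_components(120, k = 2, concentration = 60, seed = 1001L)
  cohort_spec(n_samples = c(TR = 75, UR = 80), n_features = 120,
              components = comps,
              component_weights = list(TR = c(1, 0), UR = c(0, 1)),
              seed = seed)
}

#' @rdname sim_studies
#' @export
sim_study_enterotype <- function(seed = 1L, k = 3) {
  comps <- default_components(100, k = k, concentration = 50, seed = 1002L)
  cohort_spec(n_samples = c(TR = 75, UR = 75), n_features = 100,
              components = comps,
              component_weights = list(TR = rep(1 / k, k),
                                       UR = rep(1 / k, k)),
              seed = seed)
}

#' @rdname sim_studies
#' @export
sim_study_effects <- function(seed = 1L) {
  comps <- default_components(200, k = 1, concentration = 300,
                              zipf_offset = 20, seed = 1003L)
  a <- comps[[1]]$alpha
  feats <- order(a, decreasing = TRUE)[c(70, 80, 90, 100, 110)]
  spec <- cohort_spec(
    n_samples = c(TR = 75, UR = 80), n_features = 200, components = comps,
    planted_effects = tibble::tibble(
      feature = feats, cohort = c("TR", "TR", "TR", "UR", "UR"), fold = 8),
    seed = seed)
  attr(spec, "planted_features") <- sprintf("OTU_%03d", feats)
  spec
}

#' @rdname sim_studies
#' @export
sim_study_cores <- function(seed = 1L) {
  shared <- 1:5; tr_only <- 6:8; sporadic <- 9:11
  pc <- dplyr::bind_rows(
    tibble::tibble(feature = shared, prevalence = 0.9, abundance = 0.01,
                   cohort = "both"),
    tibble::tibble(feature = tr_only, prevalence = 0.9, abundance = 0.01,
                   cohort = "TR"),
    # the TR-exclusive features stay sporadic in UR (well below the 70%
    # prevalence rule), rather than at their baseline Dirichlet abundance
    tibble::tibble(feature = tr_only, prevalence = 0.3, abundance = 0.01,
                   cohort = "UR"),
    tibble::tibble(feature = sporadic, prevalence = 0.4, abundance = 0.01,
                   cohort = "both"))
  spec <- cohort_spec(n_samples = c(TR = 75, UR = 80), n_features = 100,
                      planted_core = pc, seed = seed)
  attr(spec, "planted") <- list(
    shared = sprintf("OTU_%03d", shared),
    tr_only = sprintf("OTU_%03d", tr_only),
    sporadic = sprintf("OTU_%03d", sporadic))
  spec
}
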
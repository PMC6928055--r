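#' Dirichlet mixture component
#'
#' One compositional state of the community: a vector of positive Dirichlet
#' concentration parameters, one per feature.
#'
#' @param alpha positive numeric vector.
#' @param label component name.
#' @return a `dirichlet_component` object.
#' @export
dirichlet_component <- function(alpha, label = "component") {
  if (any(alpha <= 0)) rlang::abort("all Dirichlet alpha must be > 0")
  structure(list(alpha = as.numeric(alpha), label = label),
            class = "dirichlet_component")
}

#' Default community components
#'
#' Builds `k` Dirichlet components over `n_features` features. Each component
#' has a Zipf-like abundance profile (a few dominant taxa, a long tail, the
#' usual shape of gut 16S profiles) with its own dominant features, so
#' components are compositionally well separated.
#'
#' @param n_features number of features.
#' @param k number of components.
#' @param concentration total Dirichlet mass per component; larger values
#'   give less sample-to-sample scatter around the component profile.
#' @param zipf_exponent decay exponent of the rank-abundance profile
#'   (`abundance ~ (rank + zipf_offset)^-exponent`); 1 gives a strongly
#'   dominated community, smaller values a flatter one.
#' @param zipf_offset rank offset; positive values cap how dominant the top
#'   taxa are while keeping the long tail.
#' @param seed integer seed (controls which features dominate each component).
#' @return list of [dirichlet_component()]s.
#' @export
default_components <- function(n_features, k = 1, concentration = 50,
                               zipf_exponent = 1, zipf_offset = 0,
                               seed = 1L) {
  base <- (seq_len(n_features) + zipf_offset)^(-zipf_exponent)
  base <- base / sum(base)
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      prof <- base[sample.int(n_features)]
      dirichlet_component(concentration * prof, label = sprintf("C%d", i))
    })
  })
}

#' Specification of a two-cohort synthetic study
#'
#' Describes everything the generator needs: per-cohort sample sizes and
#' mixture weights over shared Dirichlet components, sequencing depth range,
#' planted core features (present at a target prevalence and mean relative
#' abundance), planted differentially abundant features (fold change on the
#' enriched cohort's components), and monotone links between features and
#' metadata covariates.
#'
#' @param n_samples named integer vector, samples per cohort
#'   (default `c(TR = 75, UR = 80)`).
#' @param n_features number of features.
#' @param depth_range min/max reads per sample (drawn uniformly).
#' @param components list of [dirichlet_component()] shared by both cohorts,
#'   or a named list of such lists (one per cohort). Default: one Zipf
#'   component per cohort via [default_components()].
#' @param component_weights named list of per-cohort probability vectors over
#'   components (each sums to 1). Default: uniform.
#' @param planted_core data frame with columns `feature` (index), `prevalence`
#'   (0-1), `abundance` (0-1, mean relative abundance when present), and
#'   optionally `cohort` (a cohort name or `"both"`, the default).
#' @param planted_effects data frame with columns `feature`, `cohort`
#'   (enriched cohort) and `fold` (> 0; multiplies that feature's alpha in
#'   the enriched cohort's components).
#' @param metadata_links data frame with columns `feature`, `covariate`
#'   (`"age"` or `"bmi"`), `direction` (`"increasing"`/`"decreasing"`) and
#'   optionally `rho` (target Spearman magnitude, default 0.5).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_samples = c(TR = 75, UR = 80),
                        n_features = 200,
                        depth_range = c(10000, 60000),
                        components = NULL,
                        component_weights = NULL,
                        planted_core = NULL,
                        planted_effects = NULL,
                        metadata_links = NULL,
                        seed = 1L) {
  stopifnot(length(n_samples) == 2, !is.null(names(n_samples)))
  cohorts <- names(n_samples)
  if (is.null(components))
    components <- default_components(n_features, k = 1, seed = seed)
  if (!is.null(names(components)) &&
      all(cohorts %in% names(components))) {
    comp <- components[cohorts]
  } else {
    comp <- stats::setNames(list(components, components), cohorts)
  }
  for (cl in comp) for (cc in cl) {
    stopifnot(inherits(cc, "dirichlet_component"))
    if (length(cc$alpha) != n_features)
      rlang::abort("component alpha length does not match n_features")
  }
  k <- length(comp[[1]])
  if (is.null(component_weights))
    component_weights <- stats::setNames(
      list(rep(1 / k, k), rep(1 / k, k)), cohorts)
  for (w in component_weights)
    if (abs(sum(w) - 1) > 1e-12)
      rlang::abort("component_weights must sum to 1 per cohort")
  norm_df <- function(x, cols) {
    if (is.null(x)) return(NULL)
    x <- tibble::as_tibble(x)
    stopifnot(all(cols %in% names(x)))
    x
  }
  planted_core <- norm_df(planted_core, c("feature", "prevalence", "abundance"))
  if (!is.null(planted_core)) {
    if (!"cohort" %in% names(planted_core)) planted_core$cohort <- "both"
    stopifnot(all(planted_core$prevalence >= 0 & planted_core$prevalence <= 1),
              all(planted_core$abundance > 0 & planted_core$abundance < 1))
  }
  planted_effects <- norm_df(planted_effects, c("feature", "cohort", "fold"))
  if (!is.null(planted_effects)) stopifnot(all(planted_effects$fold > 0))
  metadata_links <- norm_df(metadata_links, c("feature", "covariate",
                                              "direction"))
  if (!is.null(metadata_links) && !"rho" %in% names(metadata_links))
    metadata_links$rho <- 0.5
  structure(list(n_samples = n_samples, n_features = n_features,
                 depth_range = depth_range, components = comp,
                 component_weights = component_weights,
                 planted_core = planted_core,
                 planted_effects = planted_effects,
                 metadata_links = metadata_links,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Raise one cohort's expected diversity
#'
#' Rescales the concentration parameters of `hi_cohort`'s components toward
#' uniformity with a geometric-mean-preserving power map
#' `alpha' = gm^(1 - 1/s) * alpha^(1/s)`: the log-spread of alpha shrinks by
#' `1/s`, flattening the expected profile (higher evenness and richness)
#' while leaving the other cohort untouched. The map composes:
#' applying scale `s` then `t` equals applying `s * t`.
#'
#' @param base a [cohort_spec()].
#' @param hi_cohort name of the cohort to enrich.
#' @param concentration_scale scale `s >= 1`; `1` is the identity.
#' @return a modified `cohort_spec`.
#' @export
diversity_gap_spec <- function(base, hi_cohort, concentration_scale) {
  stopifnot(inherits(base, "cohort_spec"), concentration_scale >= 1)
  if (!hi_cohort %in% names(base$n_samples))
    rlang::abort(sprintf("unknown cohort '%s'", hi_cohort))
  s <- concentration_scale
  base$components[[hi_cohort]] <- lapply(
    base$components[[hi_cohort]], function(cc) {
      gm <- exp(mean(log(cc$alpha)))
      dirichlet_component(gm^(1 - 1 / s) * cc$alpha^(1 / s), cc$label)
    })
  base
}

# Per-cohort component alphas after applying planted effects.
.cohort_alphas <- function(spec, cohort) {
  alphas <- lapply(spec$components[[cohort]], `[[`, "alpha")
  pe <- spec$planted_effects
  if (!is.null(pe)) {
    pe <- pe[pe$cohort == cohort, , drop = FALSE]
    for (i in seq_len(nrow(pe)))
      alphas <- lapply(alphas, function(a) {
        a[pe$feature[i]] <- a[pe$feature[i]] * pe$fold[i]
        a
      })
  }
  alphas
}

.synthetic_taxonomy <- function(n_features, features_per_genus = 4) {
  genus <- (seq_len(n_features) - 1) %/% features_per_genus + 1
  phylum <- (genus - 1) %% 4 + 1
  tibble::tibble(
    feature_id = sprintf("OTU_%03d", seq_len(n_features)),
    lineage = sprintf("k__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%03d;g__Genus%03d",
                      phylum, phylum, phylum, genus, genus))
}

#' Generate a two-cohort synthetic study
#'
#' Draws, per sample: a mixture component from the cohort's weights,
#' community proportions from that component's Dirichlet (fold-change
#' adjusted for planted effects), a sequencing depth uniform in
#' `depth_range`, and counts from a multinomial at that depth. Planted core
#' features override their proportion with a Bernoulli(prevalence) presence
#' indicator times a concentrated Beta around the target mean abundance, so
#' their observed prevalence and abundance track the requested targets.
#' Metadata (age,
#' BMI, sex, diet, region) is drawn per sample; covariates named in
#' `metadata_links` are coupled to their feature's relative abundance
#' through a Gaussian copula at the requested Spearman strength.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort_sim` with elements `table` (counts
#'   [abundance_table()] with synthetic taxonomy), `metadata` (tibble:
#'   `sample_id`, `cohort`, `region`, `sex`, `diet`, `age`, `bmi`) and
#'   `truth` (tibble: `sample_id`, `component` — the generator's ground
#'   truth component assignment).
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, .generate_cohorts_impl(spec))
}

.generate_cohorts_impl <- function(spec) {
  cohorts <- names(spec$n_samples)
  tribal_regions <- c("Andhra", "Assam", "Manipur", "Sikkim")
  counts <- NULL; meta <- list(); truth <- list()
  for (ci in seq_along(cohorts)) {
    ch <- cohorts[ci]
    n <- spec$n_samples[[ch]]
    alphas <- .cohort_alphas(spec, ch)
    w <- spec$component_weights[[ch]]
    comp_labels <- vapply(spec$components[[ch]], `[[`, "", "label")
    z <- sample.int(length(alphas), n, replace = TRUE, prob = w)
    pc <- spec$planted_core
    if (!is.null(pc))
      pc <- pc[pc$cohort %in% c("both", ch), , drop = FALSE]
    x <- matrix(0L, nrow = spec$n_features, ncol = n)
    for (i in seq_len(n)) {
      p <- as.vector(rdirichlet(1, alphas[[z[i]]]))
      if (!is.null(pc) && nrow(pc) > 0) {
        on <- stats::runif(nrow(pc)) < pc$prevalence
        # concentrated Beta around the target mean: shape1 fixed at 20
        core_p <- ifelse(on,
                         stats::rbeta(nrow(pc), 20, 20 * (1 - pc$abundance) /
                                        pc$abundance),
                         0)
        if (sum(core_p) >= 1) core_p <- core_p / (sum(core_p) + 1e-6)
        p[pc$feature] <- 0
        p <- p / sum(p) * (1 - sum(core_p))
        p[pc$feature] <- core_p
      }
      depth <- floor(stats::runif(1, spec$depth_range[1],
                                  spec$depth_range[2] + 1))
      x[, i] <- stats::rmultinom(1, depth, p)
    }
    ids <- sprintf("%s_%03d", ch, seq_len(n))
    colnames(x) <- ids
    counts <- cbind(counts, x)
    region <- if (ch == "TR") sample(tribal_regions, n, replace = TRUE)
              else rep("Ahmedabad", n)
    meta[[ch]] <- tibble::tibble(
      sample_id = ids, cohort = ch, region = region,
      sex = sample(c("M", "F"), n, replace = TRUE),
      diet = sample(c("vegetarian", "non-vegetarian"), n, replace = TRUE),
      age = stats::runif(n, 18, 60),
      bmi = stats::runif(n, 15, 35))
    truth[[ch]] <- tibble::tibble(sample_id = ids,
                                  component = comp_labels[z])
  }
  rownames(counts) <- sprintf("OTU_%03d", seq_len(spec$n_features))
  metadata <- dplyr::bind_rows(meta)
  # couple linked covariates to feature abundances via a Gaussian copula
  ml <- spec$metadata_links
  if (!is.null(ml)) {
    rel <- sweep(counts, 2, colSums(counts), "/")
    for (i in seq_len(nrow(ml))) {
      x_f <- rel[ml$feature[i], ]
      nall <- length(x_f)
      rho_p <- 2 * sin(pi * ml$rho[i] / 6)  # Spearman -> Pearson on normals
      zx <- stats::qnorm((rank(x_f, ties.method = "average") - 0.5) / nall)
      t <- rho_p * zx + sqrt(1 - rho_p^2) * stats::rnorm(nall)
      if (ml$direction[i] == "decreasing") t <- -t
      cv <- ml$covariate[i]
      metadata[[cv]] <- sort(metadata[[cv]])[rank(t, ties.method = "first")]
    }
  }
  tab <- abundance_table(counts, kind = "counts",
                         taxonomy = .synthetic_taxonomy(spec$n_features))
  structure(list(table = tab, metadata = metadata,
                 truth = dplyr::bind_rows(truth)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim: %d features x %d samples (%s)>\n",
              nrow(x$table$values), ncol(x$table$values),
              paste(sprintf("%s=%d", names(table(x$metadata$cohort)),
                            as.integer(table(x$metadata$cohort))),
                    collapse = ", ")))
  invisible(x)
}
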
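#' Features qualifying as core in a cohort
#'
#' A feature is core-qualified when it is present at a minimum relative
#' abundance (default 0.1%) in at least a minimum fraction of the cohort's
#' samples (default 70%).
#'
#' @param table a relative [abundance_table()] restricted to one cohort.
#' @param min_prevalence fraction of samples; default 0.70.
#' @param min_abund minimum relative abundance; default 0.001.
#' @return character vector of qualifying feature ids.
#' @export
core_qualifies <- function(table, min_prevalence = 0.70, min_abund = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (ncol(v) == 0) rlang::abort("empty cohort")
  prev <- rowMeans(v >= min_abund)
  rownames(v)[prev >= min_prevalence]
}

#' Bootstrap stability scores for core features
#'
#' Resamples the cohort `iterations` times (by default a standard bootstrap:
#' `subset_size = n`, with replacement), recomputes the core-qualifying set
#' on each resample, and scores every feature by its frequency of appearance,
#' scaled to 0-100. A feature is flagged core when its score reaches
#' `score_cutoff` (default 80). Deterministic given `seed`.
#'
#' @inheritParams core_qualifies
#' @param iterations number of resamples; default 1000.
#' @param subset_size samples drawn per resample; default `ncol(table)`.
#' @param replace draw with replacement; default `TRUE`.
#' @param seed integer seed.
#' @param score_cutoff score (0-100) required for the core flag; default 80.
#' @return a `core_report` tibble: `feature_id`, `prevalence` (fraction of
#'   samples at `>= min_abund`), `median_abundance`, `bootstrap_score`,
#'   `is_core`.
#' @export
bootstrap_core <- function(table, iterations = 1000, subset_size = NULL,
                           replace = TRUE, seed = 1L, score_cutoff = 80,
                           min_prevalence = 0.70, min_abund = 0.001) {
  stopifnot(inherits(table, "abundance_table"), iterations >= 1)
  v <- table$values
  n <- ncol(v)
  if (is.null(subset_size)) subset_size <- n
  if (subset_size < 2) rlang::abort("subset_size must be >= 2")
  if (subset_size > n) rlang::abort("subset_size exceeds the cohort size")
  qual <- v >= min_abund
  hits <- numeric(nrow(v))
  with_seed(seed, {
    for (b in seq_len(iterations)) {
      idx <- sample.int(n, subset_size, replace = replace)
      hits <- hits + (rowSums(qual[, idx, drop = FALSE]) >=
                        min_prevalence * subset_size)
    }
  })
  score <- 100 * hits / iterations
  out <- tibble::tibble(
    feature_id = rownames(v),
    prevalence = unname(rowMeans(qual)),
    median_abundance = unname(apply(v, 1, stats::median)),
    bootstrap_score = unname(score),
    is_core = unname(score >= score_cutoff))
  class(out) <- c("core_report", class(out))
  out
}

#' Compare core reports of two cohorts
#'
#' Splits the combined core candidate list into shared and cohort-exclusive
#' sets. Median abundances are reported per cohort, with `NA` where the
#' feature did not cross the bootstrap score cutoff in that cohort.
#'
#' @param report_a,report_b [bootstrap_core()] reports over a common feature
#'   universe.
#' @param labels names of the two cohorts, used as column suffixes.
#' @return tibble: `feature_id`, `status` (`"shared"`, `"<a>_only"`,
#'   `"<b>_only"`), per-cohort `score_` and `median_` columns.
#' @export
compare_cores <- function(report_a, report_b, labels = c("TR", "UR")) {
  common <- intersect(report_a$feature_id, report_b$feature_id)
  if (length(common) == 0) rlang::abort("reports share no features")
  a <- report_a[match(common, report_a$feature_id), ]
  b <- report_b[match(common, report_b$feature_id), ]
  status <- dplyr::case_when(
    a$is_core & b$is_core ~ "shared",
    a$is_core ~ paste0(labels[1], "_only"),
    b$is_core ~ paste0(labels[2], "_only"),
    TRUE ~ "none")
  out <- tibble::tibble(
    feature_id = common,
    status = status,
    score_a = a$bootstrap_score,
    score_b = b$bootstrap_score,
    median_a = ifelse(a$is_core, a$median_abundance, NA_real_),
    median_b = ifelse(b$is_core, b$median_abundance, NA_real_))
  names(out)[3:6] <- c(paste0("score_", labels), paste0("median_", labels))
  out[out$status != "none", , drop = FALSE]
}

#' @describeIn bootstrap_core bootstrap score against prevalence, cutoff
#'   marked.
#' @param object a `core_report`.
#' @param ... unused.
#' @export
autoplot.core_report <- function(object, score_cutoff = 80, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$prevalence,
                               y = .data$bootstrap_score,
                               colour = .data$is_core)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = score_cutoff, linetype = 2) +
    ggplot2::labs(x = "prevalence at minimum abundance",
                  y = "bootstrap score (0-100)") +
    ggplot2::theme_minimal()
}
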
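#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the non-zero proportions of a sample,
#' natural log by default (the vegan convention).
#'
#' @param x non-negative counts or proportions for one sample.
#' @param base logarithm base; default `exp(1)` (nats).
#' @return Shannon index, in `[0, log(S_obs)]`.
#' @export
shannon <- function(x, base = exp(1)) {
  if (all(x == 0)) rlang::abort("all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p)) / log(base)
}

#' Gini-Simpson diversity index
#'
#' `D = 1 - sum(p_i^2)`: the probability that two reads drawn at random
#' belong to different features; accounts for both richness and evenness.
#'
#' @param x non-negative counts or proportions for one sample.
#' @return index in `[0, 1 - 1/S_obs]`.
#' @export
simpson <- function(x) {
  if (all(x == 0)) rlang::abort("all-zero sample")
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Bias-corrected Chao1 richness estimator
#'
#' `C = S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1` singletons and
#' `F2` doubletons. The bias-corrected form is defined even when no
#' doubletons are observed.
#'
#' @param x integer counts for one sample.
#' @return estimated richness, `>= S_obs`.
#' @export
chao1 <- function(x) {
  if (any(x != round(x))) rlang::abort("chao1() needs integer counts")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity
#'
#' Computes Shannon, Gini-Simpson and bias-corrected Chao1 for every sample
#' of a counts table (Chao1 needs integer counts, so rarefied counts are the
#' intended input).
#'
#' @param table a counts [abundance_table()].
#' @param metadata optional metadata tibble with `sample_id`; its columns are
#'   joined onto the result for downstream grouping.
#' @return a `diversity_result` tibble: `sample_id`, `shannon`, `simpson`,
#'   `chao1`, plus any metadata columns.
#' @export
alpha_diversity <- function(table, metadata = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  out <- tibble::tibble(
    sample_id = colnames(v),
    shannon = apply(v, 2, shannon),
    simpson = apply(v, 2, simpson),
    chao1 = if (table$kind == "counts") apply(v, 2, chao1) else NA_real_)
  if (!is.null(metadata))
    out <- dplyr::left_join(out, metadata, by = "sample_id")
  class(out) <- c("diversity_result", class(out))
  out
}

#' Compare diversity between groups
#'
#' Two-sided Wilcoxon rank-sum tests of each diversity metric between groups,
#' with Benjamini-Hochberg correction applied across the whole family of
#' comparisons emitted together (all metrics x all group pairs). With
#' `pairwise = TRUE` every pair of group levels is tested (the design used
#' when contrasting each tribal region against the urban cohort and regions
#' against each other); otherwise the grouping must have exactly two levels.
#'
#' @param div a [alpha_diversity()] result (or any tibble of per-sample
#'   metric columns).
#' @param group name of the grouping column in `div`.
#' @param metrics metric columns to test.
#' @param pairwise test all pairs of group levels.
#' @return tibble: `metric`, `group1`, `group2`, `statistic` (rank-sum W),
#'   `p_value`, `p_bh`.
#' @export
compare_groups <- function(div, group = "cohort",
                           metrics = c("shannon", "simpson", "chao1"),
                           pairwise = FALSE) {
  stopifnot(group %in% names(div))
  g <- as.factor(div[[group]])
  lv <- levels(g)
  if (length(lv) < 2) rlang::abort("need at least two groups")
  if (!pairwise && length(lv) != 2)
    rlang::abort("more than two groups: use pairwise = TRUE")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(metrics, function(m) {
      x <- div[[m]][g == pr[1]]
      y <- div[[m]][g == pr[2]]
      if (length(x) < 2 || length(y) < 2)
        rlang::abort(sprintf("group '%s' or '%s' has fewer than 2 samples",
                             pr[1], pr[2]))
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                                correct = TRUE))
      tibble::tibble(metric = m, group1 = pr[1], group2 = pr[2],
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    })
  })
  rows$p_bh <- stats::p.adjust(rows$p_value, method = "BH")
  rows
}

#' @describeIn alpha_diversity boxplots of each metric by group.
#' @param object a `diversity_result`.
#' @param group grouping column for the x axis.
#' @param ... unused.
#' @export
autoplot.diversity_result <- function(object, group = "cohort", ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("sample_id", group, "shannon", "simpson",
                                  "chao1")],
    cols = c("shannon", "simpson", "chao1"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "index value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
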
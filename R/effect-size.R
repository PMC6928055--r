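# LEfSe-style differential abundance: a Kruskal-Wallis screen per feature,
# then a bootstrapped linear-discriminant effect size on the survivors.

#' Kruskal-Wallis screen of per-feature class differences
#'
#' Raw (uncorrected) Kruskal-Wallis p-value per feature. For two classes
#' the screen is the two-sided Wilcoxon rank-sum test (exact where ties
#' permit), the distribution the Kruskal-Wallis statistic reduces to.
#' Constant features get `p = 1` by convention. No FDR correction,
#' matching the LEfSe convention; apply [stats::p.adjust()] downstream if
#' wanted.
#'
#' @param table an [abundance_table()].
#' @param classes factor/character class labels, named by sample id or in
#'   column order.
#' @param alpha screen threshold; default 0.05.
#' @return tibble: `feature_id`, `kw_p`, `passed_screen`.
#' @export
kw_screen <- function(table, classes, alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!is.null(names(classes))) classes <- classes[colnames(v)]
  classes <- as.factor(classes)
  if (any(table(classes) < 3))
    rlang::abort("each class needs at least 3 samples")
  two <- nlevels(classes) == 2
  p <- apply(v, 1, function(x) {
    if (length(unique(x)) == 1) return(1)
    if (two) {
      suppressWarnings(stats::wilcox.test(
        x[classes == levels(classes)[1]],
        x[classes == levels(classes)[2]])$p.value)
    } else {
      stats::kruskal.test(x, classes)$p.value
    }
  })
  tibble::tibble(feature_id = rownames(v), kw_p = unname(p),
                 passed_screen = unname(p) < alpha)
}

# per-class subsample whose RNG substream is keyed on the class's sample
# *set* (not its label), so relabelling classes permutes nothing
.class_subsample <- function(ids_by_class, frac, seed, boot) {
  lapply(ids_by_class, function(ids) {
    m <- max(2, ceiling(frac * length(ids)))
    sub_seed <- str_seed(paste(sort(ids), collapse = ","),
                         seed + 7919 * boot)
    with_seed(sub_seed, sample(ids, m))
  })
}

#' Bootstrapped LDA effect size
#'
#' Samples are first scaled to a fixed total (default 1e6, the LEfSe
#' convention), so the score does not depend on sequencing depth. On each of
#' `boots` bootstrap rounds a fraction of each class is subsampled and a
#' two-class linear discriminant is fitted with a ridge-regularised pooled
#' within-class covariance. The per-feature effect on one round averages the
#' feature's share of the class separation along the discriminant with its
#' raw class-mean difference; the reported score is
#' `sign(mean difference) * log10(1 + mean effect over rounds)`. Positive
#' scores mean enrichment in the first factor level (the reference class).
#' Swapping the class labels flips every score's sign exactly.
#'
#' @inheritParams kw_screen
#' @param boots bootstrap rounds; default 30.
#' @param subsample_frac fraction of each class per round; default 2/3.
#' @param seed integer seed.
#' @param scale_total per-sample total after scaling; default 1e6.
#' @param totals per-sample totals used as the scaling denominator; default
#'   the table's own column sums. Pass the full table's sums when scoring a
#'   feature subset, so shares stay shares of the whole community.
#' @param ridge ridge added to the within-class covariance diagonal,
#'   as a fraction of the mean within-class variance; default 1e-2.
#'   The scale-free form keeps scores invariant to the scaling total;
#'   the magnitude tames the noisy discriminant weights a
#'   more-features-than-samples fit otherwise produces.
#' @return tibble: `feature_id`, `delta` (class-mean difference on the
#'   scaled data, reference minus other), `lda_score`, `enriched_class`.
#' @export
lda_effect <- function(table, classes, boots = 30, subsample_frac = 2 / 3,
                       seed = 1L, scale_total = 1e6, ridge = 1e-2,
                       totals = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!is.null(names(classes))) classes <- classes[colnames(v)]
  classes <- as.factor(classes)
  if (nlevels(classes) != 2) rlang::abort("lda_effect() needs two classes")
  lv <- levels(classes)
  if (is.null(totals)) totals <- colSums(v)
  if (!is.null(names(totals))) totals <- totals[colnames(v)]
  x <- t(sweep(v, 2, totals, "/") * scale_total)  # samples x features
  ids_by_class <- split(colnames(v), classes)

  m_full <- lapply(ids_by_class, function(ids)
    colMeans(x[ids, , drop = FALSE]))
  delta_full <- m_full[[lv[1]]] - m_full[[lv[2]]]

  nf <- ncol(x)
  eff_sum <- numeric(nf)
  for (b in seq_len(boots)) {
    sub <- .class_subsample(ids_by_class, subsample_frac, seed, b)
    if (any(lengths(sub) == 0)) next
    m1 <- colMeans(x[sub[[lv[1]]], , drop = FALSE])
    m2 <- colMeans(x[sub[[lv[2]]], , drop = FALSE])
    cent <- rbind(sweep(x[sub[[lv[1]]], , drop = FALSE], 2, m1),
                  sweep(x[sub[[lv[2]]], , drop = FALSE], 2, m2))
    sw <- crossprod(cent) / (nrow(cent) - 2)
    # ridge scaled by the mean within-class variance: compositional data are
    # rank-deficient by construction, and a scale-free ridge preserves the
    # invariance of scores to the per-sample scaling total
    diag(sw) <- diag(sw) + ridge * mean(diag(sw)) + 1e-12
    dm <- m1 - m2
    w <- solve(sw, dm)
    w_unit <- w / sqrt(sum(w^2))
    sep <- sum(w_unit * dm)  # invariant under joint sign flip of classes
    eff_sum <- eff_sum + (abs(w_unit * sep) + abs(dm)) / 2
  }
  eff <- eff_sum / boots
  tibble::tibble(
    feature_id = colnames(x),
    delta = unname(delta_full),
    lda_score = unname(sign(delta_full) * log10(1 + eff)),
    enriched_class = unname(ifelse(delta_full >= 0, lv[1], lv[2])))
}

#' LEfSe-style differential abundance analysis
#'
#' Composition of [kw_screen()] and [lda_effect()]: features passing the
#' Kruskal-Wallis screen get a bootstrapped LDA effect size; a feature is
#' called differential (`passed`) when `kw_p < alpha` and
#' `|lda_score| > lda_cutoff`. The conventional cutoffs are 4 for
#' taxa (genera/OTUs, with alpha 0.05 or 0.01) and 2.5 for functional
#' pathways (with alpha 0.001). Inputs are expected to be prevalence
#' filtered first (see [prevalence_filter()]).
#'
#' @inheritParams lda_effect
#' @param alpha Kruskal-Wallis screen threshold; default 0.05.
#' @param lda_cutoff absolute LDA score threshold; default 4.
#' @return an `effect_size_result` tibble sorted by `|lda_score|`:
#'   `feature_id`, `kw_p`, `lda_score`, `enriched_class`, `passed`.
#' @export
lefse <- function(table, classes, alpha = 0.05, lda_cutoff = 4, boots = 30,
                  subsample_frac = 2 / 3, seed = 1L, ridge = 1e-2) {
  screen <- kw_screen(table, classes, alpha = alpha)
  keep <- screen$feature_id[screen$passed_screen]
  out <- screen[, c("feature_id", "kw_p")]
  out$lda_score <- NA_real_
  out$enriched_class <- NA_character_
  if (length(keep) > 0) {
    eff <- lda_effect(subset_table(table, features = keep), classes,
                      boots = boots, subsample_frac = subsample_frac,
                      seed = seed, ridge = ridge,
                      totals = colSums(table$values))
    idx <- match(eff$feature_id, out$feature_id)
    out$lda_score[idx] <- eff$lda_score
    out$enriched_class[idx] <- eff$enriched_class
  }
  out$passed <- !is.na(out$lda_score) & out$kw_p < alpha &
    abs(out$lda_score) > lda_cutoff
  out <- out[order(-abs(out$lda_score %ifna% 0)), ]
  class(out) <- c("effect_size_result", class(out))
  out
}

#' Per-rank LEfSe rollup along the taxonomy
#'
#' Re-runs [lefse()] on the table cumulated at each requested taxonomic
#' rank (plus the original features), for cladogram-style exports.
#'
#' @inheritParams lefse
#' @param ranks taxonomy ranks to cumulate to.
#' @return tibble of [lefse()] rows with a leading `level` column.
#' @export
lefse_clades <- function(table, classes, ranks = c("phylum", "family",
                                                   "genus"), ...) {
  if (is.null(table$taxonomy)) rlang::abort("lefse_clades() needs taxonomy")
  levels <- c(stats::setNames(lapply(ranks, function(r)
    collapse_taxa(table, r)), ranks), list(feature = table))
  purrr::imap_dfr(levels, function(tab, lev)
    dplyr::mutate(tibble::as_tibble(lefse(tab, classes, ...)),
                  level = lev, .before = 1))
}

#' @describeIn lefse horizontal bar plot of passing features, signed by
#'   enriched class.
#' @param object an `effect_size_result`.
#' @param ... unused.
#' @export
autoplot.effect_size_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$passed, ]
  df$feature_id <- stats::reorder(df$feature_id, df$lda_score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lda_score, y = .data$feature_id,
                                   fill = .data$enriched_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "LDA score (log10)", y = NULL, fill = "enriched in") +
    ggplot2::theme_minimal()
}
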
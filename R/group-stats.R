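# Metadata association statistics: binning, two-group and multi-group
# non-parametric tests, and ordered-bin trend summaries.

#' Bin age and BMI metadata into discrete groups
#'
#' Age is cut into six contiguous 5-year bins `[a, a+5)` starting at
#' `age_start` (default: the observed minimum floored to a multiple of 5);
#' the last bin is closed. BMI uses the WHO cuts: underweight `< 18.5`,
#' normal `[18.5, 25)`, obese `>= 25`. Samples whose age falls outside the
#' 6-bin span are flagged (`NA` bin) and reported.
#'
#' @param meta metadata tibble with `sample_id` and numeric `age`/`bmi`.
#' @param age_start left edge of the first age bin, or `NULL` for the
#'   default anchor.
#' @param bmi_cuts two cut points; default `c(18.5, 25)`.
#' @return `meta` with added ordered factors `age_bin` and `bmi_bin`;
#'   out-of-span sample ids in `attr(, "out_of_range")`.
#' @export
bin_metadata <- function(meta, age_start = NULL, bmi_cuts = c(18.5, 25)) {
  stopifnot(all(c("age", "bmi") %in% names(meta)))
  if (is.null(age_start)) age_start <- 5 * floor(min(meta$age, na.rm = TRUE) / 5)
  edges <- age_start + 5 * (0:6)
  lab <- sprintf("[%d,%d%s", edges[-7], edges[-1],
                 c(rep(")", 5), "]"))
  idx <- findInterval(meta$age, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > 6] <- NA
  out_of_range <- meta$sample_id[!is.na(meta$age) & is.na(idx)]
  if (length(out_of_range) > 0)
    rlang::warn(paste0("age outside the 6-bin span for: ",
                       paste(out_of_range, collapse = ", ")))
  meta$age_bin <- factor(lab[idx], levels = lab, ordered = TRUE)
  bmi_lab <- c("underweight", "normal", "obese")
  bidx <- findInterval(meta$bmi, bmi_cuts) + 1L
  meta$bmi_bin <- factor(bmi_lab[bidx], levels = bmi_lab, ordered = TRUE)
  attr(meta, "out_of_range") <- out_of_range
  meta
}

#' Two-group comparison of a feature
#'
#' `method = "wilcoxon"`: two-sided rank-sum test. `method = "whites"`: a
#' seeded permutation test of the difference in group means (two-sided,
#' default 1000 permutations) with a bootstrap percentile 95% CI of the mean
#' difference — the usual non-parametric two-group procedure for abundance
#' data. Permutation p-values are bounded below by `1/(permutations + 1)`.
#'
#' @param values numeric feature values.
#' @param labels two-level grouping.
#' @param method `"wilcoxon"` or `"whites"`.
#' @param permutations,boots resampling sizes for `"whites"`.
#' @param seed integer seed.
#' @return one-row tibble: `method`, `statistic`, `p_value`, `estimate`
#'   (mean difference, group1 - group2), `conf_low`, `conf_high`.
#' @export
two_group_test <- function(values, labels, method = c("wilcoxon", "whites"),
                           permutations = 1000, boots = 1000, seed = 1L) {
  method <- match.arg(method)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) rlang::abort("need exactly two groups")
  if (any(table(labels) < 3)) rlang::abort("each group needs >= 3 values")
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  est <- mean(x) - mean(y)
  if (method == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(x, y, conf.int = TRUE))
    return(tibble::tibble(method = method, statistic = unname(wt$statistic),
                          p_value = wt$p.value, estimate = est,
                          conf_low = wt$conf.int[1],
                          conf_high = wt$conf.int[2]))
  }
  n1 <- length(x)
  pooled <- c(x, y)
  res <- with_seed(seed, {
    perm <- replicate(permutations, {
      idx <- sample.int(length(pooled), n1)
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    boot <- replicate(boots, {
      mean(sample(x, n1, replace = TRUE)) -
        mean(sample(y, length(y), replace = TRUE))
    })
    list(perm = perm, boot = boot)
  })
  p <- (1 + sum(abs(res$perm) >= abs(est) - 1e-12)) / (permutations + 1)
  ci <- stats::quantile(res$boot, c(0.025, 0.975), names = FALSE)
  tibble::tibble(method = method, statistic = est, p_value = p,
                 estimate = est, conf_low = ci[1], conf_high = ci[2])
}

#' Multi-group comparison with effect size and post hoc contrasts
#'
#' Kruskal-Wallis across `>= 3` groups, with eta-squared effect size
#' `(H - k + 1) / (n - k)` and Tukey-Kramer post hoc contrasts on the rank
#' means (unequal-n standard errors, studentised-range reference
#' distribution).
#'
#' @param values numeric feature values.
#' @param bins grouping with at least 3 levels.
#' @param conf_level confidence level for the post hoc test; default 0.95.
#' @return list with `test` (one-row tibble: `statistic`, `p_value`,
#'   `eta_squared`) and `posthoc` (tibble of pairwise rank-mean contrasts:
#'   `group1`, `group2`, `diff_rank_mean`, `q`, `p_value`, `significant`).
#' @export
multi_group_test <- function(values, bins, conf_level = 0.95) {
  bins <- droplevels(as.factor(bins))
  keep <- !is.na(values) & !is.na(bins)
  values <- values[keep]; bins <- droplevels(bins[keep])
  k <- nlevels(bins)
  if (k < 3) rlang::abort("need at least 3 groups")
  if (any(table(bins) < 2)) rlang::abort("each group needs >= 2 values")
  n <- length(values)
  kw <- stats::kruskal.test(values, bins)
  h <- unname(kw$statistic)
  eta2 <- (h - k + 1) / (n - k)
  r <- rank(values)
  rk_mean <- tapply(r, bins, mean)
  ns <- tapply(r, bins, length)
  s2 <- stats::var(r)  # N(N+1)/12 without ties; tie-corrected with mid-ranks
  pairs <- utils::combn(levels(bins), 2, simplify = FALSE)
  posthoc <- purrr::map_dfr(pairs, function(pr) {
    d <- rk_mean[pr[1]] - rk_mean[pr[2]]
    se <- sqrt(s2 / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   diff_rank_mean = unname(d), q = unname(q),
                   p_value = unname(p),
                   significant = unname(p) < 1 - conf_level)
  })
  list(test = tibble::tibble(statistic = h, p_value = kw$p.value,
                             eta_squared = eta2),
       posthoc = posthoc)
}

#' Monotone trend of features across ordered bins
#'
#' Spearman rank correlation of each feature's abundance against the ordinal
#' bin index, BH-corrected across the feature family, with a direction label
#' (`increasing` / `decreasing` / `none`; `none` for constant features or
#' BH p above `alpha`). This formalises qualitative "abundance declines with
#' age"-style statements as a rank-trend test.
#'
#' @param table an [abundance_table()].
#' @param bins ordered factor, one level order per sample (named by sample
#'   id or in column order).
#' @param alpha significance level for the direction call; default 0.05.
#' @return tibble: `feature_id`, `rho`, `p_value`, `p_bh`, `direction`.
#' @export
trend_summary <- function(table, bins, alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!is.null(names(bins))) bins <- bins[colnames(v)]
  if (!is.ordered(bins)) bins <- factor(bins, ordered = TRUE)
  if (nlevels(droplevels(bins)) < 3)
    rlang::abort("need at least 3 ordered bins")
  idx <- as.integer(bins)
  keep <- !is.na(idx)
  res <- purrr::map_dfr(rownames(v), function(f) {
    x <- v[f, keep]
    if (length(unique(x)) == 1)
      return(tibble::tibble(feature_id = f, rho = NA_real_,
                            p_value = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, idx[keep], method = "spearman",
                                           exact = FALSE))
    tibble::tibble(feature_id = f, rho = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$direction <- dplyr::case_when(
    is.na(res$rho) | res$p_bh >= alpha ~ "none",
    res$rho > 0 ~ "increasing",
    TRUE ~ "decreasing")
  res
}
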
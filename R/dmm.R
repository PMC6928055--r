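#' Fit a Dirichlet-multinomial mixture (enterotype model)
#'
#' Models sample count profiles as a K-component mixture of
#' Dirichlet-multinomials, the standard probabilistic formulation of
#' enterotypes. Fitting is EM: the E-step computes component
#' responsibilities from the Dirichlet-multinomial likelihoods, the M-step
#' re-estimates mixture weights from responsibility means and each
#' component's concentration vector by responsibility-weighted Minka
#' fixed-point updates (an MM step, so the log-likelihood trace is
#' monotone). The best of `restarts` random initialisations is kept.
#'
#' Model evidence is approximated by Laplace's method in the
#' unconstrained `log(alpha)` parametrisation, with the observed
#' information taken block-diagonal per component and a weak
#' `N(0, sigma^2)` prior on each `log(alpha)` entry (default `sigma = 3`)
#' supplying the prior normalisation and curvature the approximation
#' needs to stay defined when a component's responsibility mass vanishes.
#' The returned `laplace` score is the negative approximate log-evidence
#' (lower is better), the quantity minimised when choosing K.
#'
#' By default the fit uses the `top_features` most abundant features
#' (tractability on large OTU tables); pass `top_features = Inf` for the
#' full table.
#'
#' @param table a counts [abundance_table()].
#' @param k number of components (`>= 1`).
#' @param seed integer seed for the random restarts.
#' @param restarts number of random initialisations; default 5.
#' @param tol relative log-likelihood convergence tolerance; default 1e-6.
#' @param max_iter maximum EM iterations; default 1000.
#' @param top_features cap on features, most-abundant first; default 500.
#' @param prior_sigma standard deviation of the `N(0, sigma^2)` evidence
#'   prior on `log(alpha)`; default 3.
#' @return a `dmm_fit` object: `k`, `alpha` (K x features), `pi`,
#'   `responsibilities` (samples x K, rows sum to 1), `assignment` (hard
#'   labels), `log_likelihood`, `trace`, `laplace`, `converged`.
#' @export
fit_dmm <- function(table, k, seed = 1L, restarts = 5, tol = 1e-6,
                    max_iter = 1000, top_features = 500, prior_sigma = 3) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "counts") rlang::abort("fit_dmm() needs counts")
  v <- table$values
  if (any(v != round(v))) rlang::abort("fit_dmm() needs integer counts")
  if (any(colSums(v) == 0)) rlang::abort("empty sample in table")
  if (k > ncol(v)) rlang::abort("k exceeds the number of samples")
  if (nrow(v) > top_features) {
    keep <- order(rowSums(v), decreasing = TRUE)[seq_len(top_features)]
    v <- v[sort(keep), , drop = FALSE]
  }
  x <- t(v)  # samples x features
  n <- nrow(x); nf <- ncol(x)
  prop <- x / rowSums(x)

  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(seed * 1000L + r, {
      lab <- sample.int(k, n, replace = TRUE)
      # guarantee every component at least one sample
      lab[sample.int(n, k)] <- seq_len(k)
      alpha0 <- t(vapply(seq_len(k), function(kk) {
        m <- colMeans(prop[lab == kk, , drop = FALSE])
        (m + 1e-6) / sum(m + 1e-6) * 10
      }, numeric(nf)))
      list(alpha = alpha0, pi = as.numeric(table(factor(lab, seq_len(k)))) / n)
    })
    fit <- dmm_em_cpp(x, init$alpha, init$pi, tol, max_iter, 3L)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  alpha <- best$alpha
  dimnames(alpha) <- list(paste0("ET_", seq_len(k)), colnames(x))
  resp <- best$resp
  dimnames(resp) <- list(rownames(x), rownames(alpha))
  # negative approximate log-evidence: the N(0, sigma2) prior on log(alpha)
  # contributes its normalisation (cancelling the alpha-block 2*pi volume),
  # its value at the mode, and 1/sigma2 curvature inside the determinant;
  # the mixture-weight block keeps the generic Laplace form.
  sigma2 <- prior_sigma^2
  logdet <- dmm_logdet_cpp(x, best$alpha, best$resp, sigma2)
  if (k > 1) {
    wts <- as.numeric(best$pi)
    logdet <- logdet + sum(log(n / wts[-k])) - log(wts[k])
  }
  prior_quad <- sum(log(pmax(best$alpha, 1e-12))^2) / (2 * sigma2)
  laplace <- -best$loglik + (k * nf / 2) * log(sigma2) + prior_quad -
    ((k - 1) / 2) * log(2 * pi) + 0.5 * logdet
  structure(list(
    k = k, alpha = alpha, pi = as.numeric(best$pi),
    responsibilities = resp,
    assignment = stats::setNames(max.col(resp), rownames(x)),
    log_likelihood = best$loglik, trace = as.numeric(best$trace),
    laplace = laplace, converged = best$converged),
    class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("<dmm_fit: k = %d, logLik = %.2f, Laplace = %.2f%s>\n",
              x$k, x$log_likelihood, x$laplace,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Choose the number of enterotypes by Laplace evidence
#'
#' Fits a Dirichlet-multinomial mixture for every `k` in `k_range` and keeps
#' the model with the minimum Laplace score (negative approximate
#' log-evidence). Also reports each component's top contributing features by
#' expected relative abundance (`alpha / sum(alpha)`).
#'
#' @inheritParams fit_dmm
#' @param k_range candidate component counts; default `1:7`.
#' @param top_m how many top features to report per component; default 20.
#' @param ... passed to [fit_dmm()].
#' @return list with `best` (the winning `dmm_fit`), `k_best`, `profile`
#'   (tibble `k`, `laplace`, `log_likelihood`, `converged`) and
#'   `top_features` (tibble `component`, `rank`, `feature_id`, `weight`).
#' @export
select_k_dmm <- function(table, k_range = 1:7, seed = 1L, top_m = 20, ...) {
  stopifnot(length(k_range) >= 1)
  fits <- lapply(k_range, function(k)
    fit_dmm(table, k, seed = seed + k, ...))
  profile <- tibble::tibble(
    k = k_range,
    laplace = vapply(fits, `[[`, 0, "laplace"),
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  best <- fits[[which.min(profile$laplace)]]
  top <- purrr::map_dfr(seq_len(best$k), function(kk) {
    w <- best$alpha[kk, ] / sum(best$alpha[kk, ])
    ord <- order(w, decreasing = TRUE)[seq_len(min(top_m, length(w)))]
    tibble::tibble(component = rownames(best$alpha)[kk],
                   rank = seq_along(ord),
                   feature_id = colnames(best$alpha)[ord],
                   weight = unname(w[ord]))
  })
  list(best = best, k_best = best$k, profile = profile, top_features = top)
}

#' @export
tidy.dmm_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(kk) {
    a <- x$alpha[kk, ]
    tibble::tibble(component = rownames(x$alpha)[kk],
                   feature_id = names(a),
                   alpha = unname(a),
                   expected_abundance = unname(a / sum(a)))
  })
}

#' @export
glance.dmm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, log_likelihood = x$log_likelihood,
                 laplace = x$laplace, converged = x$converged,
                 n_iter = length(x$trace))
}

#' Laplace score profile plot
#'
#' @param selection a [select_k_dmm()] result.
#' @return a ggplot of Laplace score against k, minimum marked.
#' @export
plot_laplace_profile <- function(selection) {
  prof <- selection$profile
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$k, y = .data$laplace)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = prof[which.min(prof$laplace), ],
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = prof$k) +
    ggplot2::labs(x = "number of Dirichlet components (k)",
                  y = "Laplace score (lower is better)") +
    ggplot2::theme_minimal()
}
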
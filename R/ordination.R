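#' Jensen-Shannon distance between community profiles
#'
#' For each pair of samples with proportion profiles P, Q:
#' `JSD(P, Q) = 0.5 KL(P || M) + 0.5 KL(Q || M)` with `M = (P + Q) / 2`,
#' natural log. The returned distance is `sqrt(JSD)` by default, which is a
#' true metric (the usual enterotyping convention); set `sqrt = FALSE` for
#' raw JSD. Zeros are replaced by a pseudocount and columns renormalised
#' before the divergence is computed.
#'
#' @param table a relative [abundance_table()] (columns sum to 1).
#' @param pseudocount value substituted for zeros; default `1e-6`.
#' @param sqrt take the square root of JSD (metric form); default `TRUE`.
#' @return a symmetric `n x n` distance matrix with zero diagonal and the
#'   sample ids as dimnames.
#' @export
jsd_distance <- function(table, pseudocount = 1e-6, sqrt = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "relative")
    rlang::abort("jsd_distance() needs relative abundances; see to_relative()")
  p <- table$values
  if (pseudocount > 0) {
    p[p == 0] <- pseudocount
    p <- sweep(p, 2, colSums(p), "/")
  }
  n <- ncol(p)
  # entropy decomposition: JSD(P,Q) = H(M) - (H(P) + H(Q))/2
  hcol <- -colSums(p * ifelse(p > 0, log(p), 0))
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1)) {
    m <- (p[, i] + p[, (i + 1):n, drop = FALSE]) / 2
    hm <- -colSums(m * ifelse(m > 0, log(m), 0))
    jsd <- hm - (hcol[i] + hcol[(i + 1):n]) / 2
    jsd[jsd < 0] <- 0  # guard tiny negative round-off
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- if (sqrt) base::sqrt(jsd) else jsd
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix and eigendecomposes it.
#' Negative eigenvalues (possible for non-Euclidean distances) are reported,
#' not silently dropped; coordinates are returned for positive axes only.
#'
#' @param dist symmetric distance matrix.
#' @return list with `points` (samples x axes, ordered by eigenvalue),
#'   `eigenvalues` (all of them, including negatives) and
#'   `prop_explained` (positive eigenvalues / their sum).
#' @export
pcoa <- function(dist) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8))
    rlang::abort("distance matrix must be symmetric")
  n <- nrow(dist)
  # cmdscale warns when some requested axes have non-positive eigenvalues;
  # that situation is expected here and reported through `eigenvalues`
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dist), k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > 1e-8 * max(abs(eig)))
  pts <- sc$points[, seq_along(pos), drop = FALSE]
  rownames(pts) <- rownames(dist)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = eig,
       prop_explained = eig[pos] / sum(eig[pos]))
}

#' Partitioning around medoids on a distance matrix
#'
#' k-medoids clustering. Instances small enough to enumerate (`n <= 10`)
#' are solved exactly over all medoid subsets; larger ones use the
#' BUILD + SWAP heuristic. Assignment ties between equidistant medoids are
#' broken toward the lowest medoid index, so the result is deterministic.
#'
#' @param dist symmetric distance matrix.
#' @param k number of clusters, `2 <= k < n` (`k = n` returns each sample as
#'   its own medoid at zero cost).
#' @return list with `k`, `medoids` (sample ids), `assignment` (integer
#'   cluster per sample, named), `cost` (sum of distances to assigned
#'   medoids).
#' @export
pam_jsd <- function(dist, k) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k < 2 || k > n) rlang::abort("k must be in [2, n]")
  if (k == n) {
    return(list(k = k, medoids = rownames(dist),
                assignment = stats::setNames(seq_len(n), rownames(dist)),
                cost = 0))
  }
  if (n <= 10) {
    best <- NULL; best_cost <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
      cost <- sum(apply(dist[, med, drop = FALSE], 1, min))
      if (cost < best_cost - 1e-12) {
        best <- med; best_cost <- cost
      }
    }
    med_idx <- best
  } else {
    fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE,
                        variant = "original")
    med_idx <- match(fit$medoids, rownames(dist))
  }
  # re-derive assignment with explicit lowest-index tie break
  dmed <- dist[, med_idx, drop = FALSE]
  assignment <- apply(dmed, 1, which.min)
  cost <- sum(dmed[cbind(seq_len(n), assignment)])
  list(k = k, medoids = rownames(dist)[med_idx],
       assignment = stats::setNames(as.integer(assignment), rownames(dist)),
       cost = cost)
}

#' Calinski-Harabasz index
#'
#' `CH = [SS_B / (k - 1)] / [SS_W / (n - k)]` computed on a Euclidean
#' embedding (for JSD-space clusterings, the PCoA axes with positive
#' eigenvalues — CH needs centroids, which the distance space itself lacks).
#'
#' @param embedding samples x axes coordinate matrix.
#' @param assignment integer cluster labels per sample.
#' @return the CH index (larger = better separated).
#' @export
ch_index <- function(embedding, assignment) {
  embedding <- as.matrix(embedding)
  assignment <- as.integer(as.factor(assignment))
  n <- nrow(embedding)
  k <- length(unique(assignment))
  if (k < 2) rlang::abort("CH index needs at least two clusters")
  grand <- colMeans(embedding)
  ss_b <- 0; ss_w <- 0
  for (cl in unique(assignment)) {
    sub <- embedding[assignment == cl, , drop = FALSE]
    cen <- colMeans(sub)
    ss_b <- ss_b + nrow(sub) * sum((cen - grand)^2)
    ss_w <- ss_w + sum(sweep(sub, 2, cen)^2)
  }
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Optimal cluster number by the CH index
#'
#' Runs PAM for each `k` in `2..k_max` on the distance matrix, scores each
#' clustering with the CH index on the positive-eigenvalue PCoA embedding,
#' and returns the argmax.
#'
#' @param dist symmetric distance matrix.
#' @param k_max largest k to try (`< n`).
#' @return list with `k_best`, `profile` (tibble `k`, `ch`, `cost`) and
#'   `clustering` (the [pam_jsd()] result at `k_best`).
#' @export
optimal_k <- function(dist, k_max = 7) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k_max >= n) rlang::abort("k_max must be < number of samples")
  emb <- pcoa(dist)$points
  fits <- lapply(2:k_max, function(k) pam_jsd(dist, k))
  profile <- tibble::tibble(
    k = 2:k_max,
    ch = vapply(fits, function(f) ch_index(emb, f$assignment), 0),
    cost = vapply(fits, `[[`, 0, "cost"))
  best <- which.max(profile$ch)
  list(k_best = profile$k[best], profile = profile,
       clustering = fits[[best]])
}

#' Ordination scatter plot
#'
#' @param ord a [pcoa()] result.
#' @param groups optional group labels per sample for colouring.
#' @return a ggplot.
#' @export
plot_ordination <- function(ord, groups = NULL) {
  df <- tibble::tibble(sample_id = rownames(ord$points),
                       PCo1 = ord$points[, 1],
                       PCo2 = ord$points[, 2])
  pe <- round(100 * ord$prop_explained[1:2], 1)
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}
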
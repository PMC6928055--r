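# Spearman co-occurrence networks with a pair-swap randomization null and
# a critical-r edge rule.

#' Pairwise Spearman correlation with BH correction
#'
#' Rows of `x` are variables (taxa, functions, diversity indices, numeric
#' metadata), columns are samples. Mid-ranks handle ties; p-values use the
#' t approximation and are BH-corrected across all emitted pairs. Constant
#' rows give `NA`. With `groups`, one matrix set per group of samples
#' (e.g. separate cohort networks).
#'
#' @param x numeric matrix, variables x samples, with rownames.
#' @param groups optional group label per sample.
#' @return list with `r`, `p`, `p_bh` (symmetric matrices), or a named list
#'   of such lists when `groups` is given.
#' @export
spearman_matrix <- function(x, groups = NULL) {
  x <- as.matrix(x)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    return(lapply(stats::setNames(nm = levels(groups)), function(g)
      spearman_matrix(x[, groups == g, drop = FALSE])))
  }
  n <- ncol(x)
  if (n < 4) rlang::abort("need at least 4 samples")
  const <- apply(x, 1, function(v) length(unique(v)) == 1)
  r <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  r[const, ] <- NA; r[, const] <- NA
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[which(abs(r) == 1)] <- 0
  diag(p) <- NA
  ut <- upper.tri(p)
  p_bh <- p
  p_bh[ut] <- stats::p.adjust(p[ut], method = "BH")
  p_bh[lower.tri(p_bh)] <- t(p_bh)[lower.tri(p_bh)]
  list(r = r, p = p, p_bh = p_bh)
}

#' Pair-swap randomization null for correlation networks
#'
#' Builds an empirical null distribution of pairwise Spearman correlations
#' by repeatedly swapping the abundances of a randomly chosen pair of
#' samples independently within every variable row, recomputing all pairwise
#' correlations after each step, and pooling them. The default `"walk"` mode
#' accumulates swaps (a randomization walk whose stationary law is an
#' independent per-row permutation of samples — the exact permutation null);
#' `"fresh"` restarts from the observed table at every step. The observed
#' table is never mutated.
#'
#' @param x numeric matrix, variables x samples.
#' @param steps randomization steps; default 10000.
#' @param seed integer seed.
#' @param mode `"walk"` (accumulating swaps) or `"fresh"`.
#' @return list of class `swap_null`: `null_r` (pooled correlations, length
#'   `steps * choose(nrow, 2)`), `expectancy` (their mean, the expectancy
#'   value), `steps`, `mode`.
#' @export
swap_null <- function(x, steps = 10000, seed = 1L,
                      mode = c("walk", "fresh")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  nf <- nrow(x); n <- ncol(x)
  if (steps < 1) rlang::abort("steps must be >= 1")
  if (nf < 2 || n < 3) rlang::abort("need >= 2 variables and >= 3 samples")
  # standardised mid-ranks: correlations are then plain inner products, and
  # a value swap in x is the same swap in z
  z <- t(apply(x, 1, rank, ties.method = "average"))
  z <- sweep(z, 1, rowMeans(z))
  zsd <- sqrt(rowSums(z^2) / (n - 1))
  zsd[zsd == 0] <- Inf  # constant rows contribute NA downstream; here 0
  z <- sweep(z, 1, zsd, "/")
  ut <- upper.tri(matrix(0, nf, nf))
  npair <- sum(ut)
  out <- numeric(steps * npair)
  with_seed(seed, {
    zc <- z
    for (s in seq_len(steps)) {
      if (mode == "fresh") zc <- z
      j1 <- sample.int(n, nf, replace = TRUE)
      j2 <- 1L + (j1 - 1L + sample.int(n - 1L, nf, replace = TRUE)) %% n
      i1 <- cbind(seq_len(nf), j1); i2 <- cbind(seq_len(nf), j2)
      tmp <- zc[i1]; zc[i1] <- zc[i2]; zc[i2] <- tmp
      rr <- tcrossprod(zc) / (n - 1)
      out[((s - 1) * npair + 1):(s * npair)] <- rr[ut]
    }
  })
  structure(list(null_r = out, expectancy = mean(out), steps = steps,
                 mode = mode), class = "swap_null")
}

#' Critical correlation threshold from a randomization null
#'
#' The `confidence` quantile (linear interpolation, type 7) of the absolute
#' null correlations: correlations between `critical_r` and 1 count as
#' positive associations, between -1 and `-critical_r` as negative, and
#' anything in between as insignificant.
#'
#' @param null a [swap_null()] result or a numeric vector of null r values.
#' @param confidence confidence level in (0, 1); default 0.99.
#' @return positive scalar threshold.
#' @export
critical_r <- function(null, confidence = 0.99) {
  if (inherits(null, "swap_null")) null <- null$null_r
  if (length(null) == 0) rlang::abort("empty null distribution")
  if (confidence <= 0 || confidence >= 1)
    rlang::abort("confidence must be in (0, 1)")
  stats::quantile(abs(null), confidence, type = 7, names = FALSE)
}

#' Build a correlation network from thresholded matrices
#'
#' Edges connect variable pairs with `|r| > critical_r` and BH-corrected
#' p below `p_cutoff`; the edge sign is the sign of the observed r. The
#' network is undirected with no self edges.
#'
#' @param corr a [spearman_matrix()] result.
#' @param critical_r positive threshold, from [critical_r()].
#' @param p_cutoff BH-corrected p threshold; default 0.01.
#' @param kinds optional named character vector of node kinds (`"taxon"`,
#'   `"function"`, `"diversity"`, `"metadata"`, ...).
#' @param confidence the confidence level the threshold was computed at
#'   (recorded in the object).
#' @param null_summary optional [swap_null()] result or summary, recorded.
#' @return a `correlation_network`: `nodes` (tibble `id`, `kind`), `edges`
#'   (tibble `from`, `to`, `r`, `sign`, `p_bh`), `critical_r`, `confidence`,
#'   `null_summary`.
#' @export
build_network <- function(corr, critical_r, p_cutoff = 0.01, kinds = NULL,
                          confidence = 0.99, null_summary = NULL) {
  r <- corr$r; p_bh <- corr$p_bh
  stopifnot(nrow(r) == ncol(r), all(dim(r) == dim(p_bh)))
  ids <- rownames(r)
  nodes <- tibble::tibble(
    id = ids,
    kind = if (is.null(kinds)) "taxon" else unname(kinds[ids] %ifna% "taxon"))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  keep <- !is.na(r[ut]) & abs(r[ut]) > critical_r &
    !is.na(p_bh[ut]) & p_bh[ut] < p_cutoff
  ut <- ut[keep, , drop = FALSE]
  r_edge <- r[ut]
  edges <- tibble::tibble(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    r = r_edge, sign = ifelse(r_edge > 0, "pos", "neg"),
    p_bh = p_bh[ut])
  if (inherits(null_summary, "swap_null"))
    null_summary <- tibble::tibble(
      expectancy = null_summary$expectancy,
      q50 = stats::median(null_summary$null_r),
      q99_abs = stats::quantile(abs(null_summary$null_r), 0.99, names = FALSE),
      steps = null_summary$steps, mode = null_summary$mode)
  structure(list(nodes = nodes, edges = edges, critical_r = critical_r,
                 confidence = confidence, null_summary = null_summary),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network: %d nodes, %d edges, critical r = %.4f (%.0f%% confidence)>\n",
              nrow(x$nodes), nrow(x$edges), x$critical_r,
              100 * x$confidence))
  invisible(x)
}

#' @export
tidy.correlation_network <- function(x, ...) x$edges

#' Export a correlation network
#'
#' `"sif"`: Cytoscape simple interaction format, one `source TAB sign TAB
#' target` line per edge. `"graphml"`: GraphML with `r` and `sign` edge
#' attributes (via igraph). `"tsv"`: the edge tibble as TSV.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$sign,
                     net$edges$to)
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("from", "to", "r", "sign")],
      directed = FALSE,
      vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Parse a SIF file back into an edge tibble
#'
#' @param path a SIF file written by [export_network()].
#' @return tibble: `from`, `sign`, `to`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(from = vapply(parts, `[`, "", 1),
                 sign = vapply(parts, `[`, "", 2),
                 to = vapply(parts, `[`, "", 3))
}
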
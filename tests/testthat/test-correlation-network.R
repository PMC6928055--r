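node_matrix <- function(nf, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nf * n), nf, n,
         dimnames = list(sprintf("F%02d", seq_len(nf)),
                         sprintf("S%02d", seq_len(n))))
}

test_that("spearman matrices reproduce hand-ranked values", {
  x <- rbind(a = 1:5, b = 2 * (1:5) + 1, c = -(1:5), d = c(2, 1, 4, 3, 5))
  colnames(x) <- sprintf("s%d", 1:5)
  sm <- spearman_matrix(x)
  expect_equal(sm$r["a", "b"], 1)
  expect_equal(sm$r["a", "c"], -1)
  expect_equal(sm$r["a", "d"], 0.8, tolerance = 1e-12)
  expect_equal(sm$p["a", "b"], 0)

  x2 <- rbind(x, e = rep(3, 5))
  sm2 <- spearman_matrix(x2)
  expect_true(all(is.na(sm2$r["e", ])))
  expect_error(spearman_matrix(x[, 1:3]), "4 samples")

  # cohort-wise mode returns one matrix set per group
  g <- c("u", "u", "u", "t", "t")
  expect_error(spearman_matrix(x, groups = g), "4 samples")
  smg <- spearman_matrix(cbind(x, x), groups = rep(c("u", "t"), each = 5))
  expect_setequal(names(smg), c("t", "u"))
})

test_that("the swap null is seeded, leaves the input intact, and is centred", {
  x <- node_matrix(10, 20, seed = 3)
  x_copy <- x + 0
  n1 <- swap_null(x, steps = 50, seed = 4)
  n2 <- swap_null(x, steps = 50, seed = 4)
  expect_identical(n1$null_r, n2$null_r)
  expect_identical(x, x_copy)
  expect_equal(length(n1$null_r), 50 * choose(10, 2))

  big <- swap_null(x, steps = 2000, seed = 5)
  expect_lt(abs(big$expectancy), 0.01)
  expect_error(swap_null(x, steps = 0), "steps")
})

test_that("independent per-row swaps break a perfect rank correlation", {
  x <- rbind(a = 1:6, b = (1:6) * 10)
  colnames(x) <- sprintf("s%d", 1:6)
  nl <- swap_null(x, steps = 200, seed = 2)
  expect_lt(min(nl$null_r), 1 - 1e-9)
  expect_lt(mean(nl$null_r == 1), 0.5)
  # an identical-index swap applied to both rows keeps r at exactly 1:
  # swapping the same two columns of both rows is a relabeling of samples
  swapped <- x[, c(2, 1, 3:6)]
  expect_equal(cor(swapped[1, ], swapped[2, ], method = "spearman"), 1)
})

test_that("critical r follows the quantile rule and its limits", {
  null <- seq(-0.5, 0.5, length.out = 1001)
  expect_equal(critical_r(null, 0.99),
               stats::quantile(abs(null), 0.99, type = 7, names = FALSE))
  expect_equal(critical_r(null, 0.999999), max(abs(null)), tolerance = 1e-4)
  expect_gte(critical_r(null, 0.99), critical_r(null, 0.95))
  expect_error(critical_r(null, 1.2), "confidence")
  expect_error(critical_r(numeric(0)), "empty")
})

test_that("network building applies both gates and stays symmetric in meaning", {
  x <- node_matrix(12, 40, seed = 6)
  x["F02", ] <- 0.9 * x["F01", ] + sqrt(0.19) * rnorm(40)
  sm <- spearman_matrix(x)
  net <- build_network(sm, critical_r = 0.5, p_cutoff = 0.01)
  expect_true(nrow(net$edges) >= 1)
  expect_true(all(abs(net$edges$r) > 0.5))
  expect_true(all(net$edges$p_bh < 0.01))
  expect_true(all(net$edges$from != net$edges$to))
  # critical_r = 1 silences everything
  empty <- build_network(sm, critical_r = 1)
  expect_equal(nrow(empty$edges), 0)
  # raising confidence never adds edges
  nl <- swap_null(x, steps = 500, seed = 1)
  n95 <- build_network(sm, critical_r(nl, 0.95))
  n99 <- build_network(sm, critical_r(nl, 0.99))
  expect_lte(nrow(n99$edges), nrow(n95$edges))
})

test_that("under independence about 1% of null pairs exceed the 99% critical r", {
  x <- node_matrix(40, 60, seed = 9)
  nl <- swap_null(x, steps = 3000, seed = 2)
  cr <- critical_r(nl, 0.99)
  sm <- spearman_matrix(x)
  frac <- mean(abs(sm$r[upper.tri(sm$r)]) > cr)
  npair <- choose(40, 2)
  se <- sqrt(0.01 * 0.99 / npair)
  expect_lt(frac, 0.01 + 3 * se)
})

test_that("exports round-trip through SIF and parse as GraphML", {
  x <- node_matrix(8, 30, seed = 12)
  x["F05", ] <- x["F04", ] + rnorm(30, 0, 0.1)
  net <- build_network(spearman_matrix(x), critical_r = 0.6,
                       p_cutoff = 0.05,
                       kinds = c(F01 = "taxon", F05 = "function"))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  back <- read_sif(sif)
  expect_equal(back$from, net$edges$from)
  expect_equal(back$to, net$edges$to)
  expect_equal(back$sign, net$edges$sign)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)),
               nrow(net$edges))
})
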
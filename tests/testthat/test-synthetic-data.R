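test_that("generated counts respect the requested depth range and are seed-deterministic", {
  sp <- cohort_spec(n_samples = c(TR = 8, UR = 9), n_features = 30,
                    depth_range = c(2000, 5000), seed = 11)
  sim <- generate_cohorts(sp)
  cs <- colSums(sim$table$values)
  expect_true(all(cs >= 2000 & cs <= 5000))
  expect_equal(ncol(sim$table$values), 17)
  expect_equal(sim$metadata$sample_id, colnames(sim$table$values))

  sim2 <- generate_cohorts(sp)
  expect_identical(sim$table$values, sim2$table$values)
  expect_identical(sim$metadata, sim2$metadata)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(component_weights = list(c(0.5, 0.4), c(1, 0)),
                           components = default_components(200, k = 2)),
               "sum to 1")
  expect_error(dirichlet_component(c(1, 0, 2)), "> 0")
  comps <- default_components(10, k = 1)
  expect_error(cohort_spec(n_features = 20, components = comps),
               "n_features")
})

test_that("component assignment frequencies match the mixture weights", {
  comps <- default_components(20, k = 3, concentration = 30, seed = 2)
  w <- c(0.5, 0.3, 0.2)
  sp <- cohort_spec(n_samples = c(TR = 1000, UR = 2), n_features = 20,
                    depth_range = c(50, 100), components = comps,
                    component_weights = list(TR = w, UR = w), seed = 3)
  sim <- generate_cohorts(sp)
  tr <- sim$truth[startsWith(sim$truth$sample_id, "TR"), ]
  freq <- as.numeric(table(factor(tr$component, paste0("C", 1:3)))) / 1000
  se <- sqrt(w * (1 - w) / 1000)
  expect_true(all(abs(freq - w) <= 3 * se))
})

test_that("planted core features hit their target prevalence and abundance", {
  pc <- tibble::tibble(feature = c(3, 7), prevalence = c(0.9, 0.5),
                       abundance = 0.01, cohort = "both")
  sp <- cohort_spec(n_samples = c(TR = 100, UR = 2), n_features = 50,
                    planted_core = pc, seed = 5)
  sim <- generate_cohorts(sp)
  rel <- to_relative(sim$table)
  tr <- rel$values[, startsWith(colnames(rel$values), "TR")]
  prev <- rowMeans(tr[c(3, 7), ] >= 0.001)
  expect_true(all(abs(prev - c(0.9, 0.5)) <= 0.10))
  present <- tr[3, tr[3, ] > 0]
  expect_equal(mean(present), 0.01, tolerance = 0.15)
})

test_that("a planted fold change raises the enriched cohort's mean abundance", {
  gaps <- vapply(1:20, function(s) {
    pe <- tibble::tibble(feature = 5, cohort = "TR", fold = 8)
    sp <- cohort_spec(n_samples = c(TR = 12, UR = 12), n_features = 30,
                      depth_range = c(2000, 4000), planted_effects = pe,
                      seed = s)
    sim <- generate_cohorts(sp)
    rel <- to_relative(sim$table)
    ch <- startsWith(colnames(rel$values), "TR")
    mean(rel$values[5, ch]) - mean(rel$values[5, !ch])
  }, 0)
  expect_gt(mean(gaps > 0), 0.9)
  expect_gt(mean(gaps), 0)
})

test_that("diversity_gap_spec is an identity at scale 1 and composes multiplicatively", {
  base <- cohort_spec(n_samples = c(TR = 5, UR = 5), n_features = 40, seed = 1)
  same <- diversity_gap_spec(base, "TR", 1)
  expect_equal(same$components$TR[[1]]$alpha, base$components$TR[[1]]$alpha)

  twice <- diversity_gap_spec(diversity_gap_spec(base, "TR", 5), "TR", 5)
  once <- diversity_gap_spec(base, "TR", 25)
  expect_equal(twice$components$TR[[1]]$alpha, once$components$TR[[1]]$alpha,
               tolerance = 1e-12)
  expect_equal(twice$components$UR[[1]]$alpha, base$components$UR[[1]]$alpha)
  expect_error(diversity_gap_spec(base, "XX", 2), "unknown cohort")
})

test_that("the diversity gap raises expected Shannon of the scaled cohort", {
  base <- cohort_spec(n_samples = c(TR = 50, UR = 50), n_features = 60,
                      depth_range = c(3000, 6000), seed = 8)
  sim <- generate_cohorts(diversity_gap_spec(base, "TR", 5))
  div <- alpha_diversity(rarefy(sim$table, seed = 2), sim$metadata)
  expect_gt(mean(div$shannon[div$cohort == "TR"]),
            mean(div$shannon[div$cohort == "UR"]))
})

test_that("metadata links induce the requested monotone association", {
  ml <- tibble::tibble(feature = 2, covariate = c("age"),
                       direction = "decreasing", rho = 0.5)
  sp <- cohort_spec(n_samples = c(TR = 60, UR = 60), n_features = 30,
                    metadata_links = ml, seed = 13)
  sim <- generate_cohorts(sp)
  rel <- to_relative(sim$table)
  rho <- cor(rel$values[2, ], sim$metadata$age, method = "spearman")
  expect_lt(rho, -0.3)
  expect_true(all(sim$metadata$age >= 18 & sim$metadata$age <= 60))
  expect_true(all(sim$metadata$bmi >= 15 & sim$metadata$bmi <= 35))
})
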
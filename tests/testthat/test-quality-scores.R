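test_that("tie-averaged percentiles match the definitional examples", {
  expect_equal(percentile_rank(c(10, 20, 20, 40), better = "lower"),
               c(100, 62.5, 62.5, 25))
  expect_equal(percentile_rank(5, better = "lower"), 100)
  expect_equal(percentile_rank(rep(7, 4), better = "lower"), rep(62.5, 4))
  expect_equal(percentile_rank(c(10, 20, 20, 40), better = "higher"),
               c(25, 62.5, 62.5, 100))
  expect_error(percentile_rank(numeric(0)), "empty")
  expect_error(percentile_rank(c(1, NA)), "missing")
})

test_that("percentile law holds on generated populations", {
  set.seed(11)
  for (n in c(1, 2, 17, 500, 2000)) {
    # heavy ties: values drawn from a small support
    v <- sample(1:5, n, replace = TRUE)
    p <- percentile_rank(v, better = "lower")
    expect_true(all(p > 0 & p <= 100))
    expect_equal(mean(p), 100 * (n + 1) / (2 * n))
    # tied inputs share percentiles
    expect_equal(length(unique(p)), length(unique(v)))
    # brute-force oracle equivalence
    expect_equal(p, oracle_percentile(v, "lower"))
    expect_equal(percentile_rank(v, "higher"), oracle_percentile(v, "higher"))
  }
})

test_that("midpoint convention shifts percentiles by half a rank", {
  v <- c(3, 1, 2)
  expect_equal(percentile_rank(v, "higher", convention = "midpoint"),
               c(2.5, 0.5, 1.5) / 3 * 100)
})

test_that("geometry PCA matches a direct eigendecomposition", {
  d <- make_varied_deposits(100, seed = 13)
  model <- fit_geometry_pca(d)

  g <- as.matrix(d[, c("clashscore", "rama_outliers", "rota_outliers")])
  z <- scale(g)
  eig <- eigen(stats::cov(z), symmetric = TRUE)
  expect_equal(model$explained_variance, eig$values / sum(eig$values),
               tolerance = 1e-10)
  for (k in 1:3) {
    expect_equal(abs(model$loadings[, k]), abs(eig$vectors[, k]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_true(all(model$loadings[, 1] >= 0))
  expect_true(all(diff(model$explained_variance) <= 1e-12))
})

test_that("three collinear geometry columns load PC1 at 1/sqrt(3) each", {
  base <- c(1, 2, 3, 4, 5, 6)
  d <- make_deposits(6, clashscore = base, rama_outliers = base / 2,
                     rota_outliers = base * 0.8)
  model <- fit_geometry_pca(d)
  expect_equal(model$explained_variance[1], 1)
  expect_equal(unname(model$loadings[, 1]), rep(1 / sqrt(3), 3), tolerance = 1e-10)
})

test_that("geometry outliers are excluded from fitting but still scored", {
  d <- make_varied_deposits(80, seed = 14)
  d$clashscore[1] <- 300            # beyond the Clashscore > 250 threshold
  model <- fit_geometry_pca(d)
  expect_identical(model$outlier_ids, d$pdb_id[1])
  expect_equal(model$n_fit, 79)
  # standardization parameters come from the clean subset only
  expect_equal(model$means[["clashscore"]], mean(d$clashscore[-1]))
  # the outlier still receives a score, and the worst geometry scores highest
  sc <- score_geometry(model, d)
  expect_equal(length(sc), 80)
  expect_equal(which.max(sc), 1L)
})

test_that("geometry scoring is centered, monotone, and protein-only", {
  d <- make_varied_deposits(60, seed = 15)
  model <- fit_geometry_pca(d)
  at_mean <- make_deposits(1, clashscore = model$means[["clashscore"]],
                           rama_outliers = model$means[["rama_outliers"]],
                           rota_outliers = model$means[["rota_outliers"]])
  expect_equal(score_geometry(model, at_mean), 0, tolerance = 1e-12)
  worse <- at_mean
  worse$clashscore <- worse$clashscore * 2
  expect_gt(score_geometry(model, worse), 0)
  nuc <- make_deposits(1, molecule_class = "nucleic_acid")
  expect_error(score_geometry(model, nuc), "inapplicable")
})

test_that("composite identities hold: equal components, min <= mean", {
  d <- make_varied_deposits(500, seed = 16, nucleic_fraction = 0.15)
  sc <- compute_q1(d, fit_geometry_pca(d))
  expect_equal(sc$q1, (sc$p_rfree + sc$p_rsrz + sc$p_geom) / 3)
  expect_true(all(sc$q1_min <= sc$q1 + 1e-12))
  expect_equal(sc$q1_min, pmin(sc$p_rfree, sc$p_rsrz, sc$p_geom))
  # a deposit with all three components equal has q1 = q1_min = component
  tied <- abs(sc$p_rfree - sc$p_rsrz) < 1e-9 & abs(sc$p_rsrz - sc$p_geom) < 1e-9
  expect_equal(sc$q1[tied], sc$p_rfree[tied])
  # percentile invariants per molecule group
  for (g in unique(sc$group)) {
    n <- sum(sc$group == g)
    expect_equal(mean(sc$p_q1[sc$group == g]), 100 * (n + 1) / (2 * n))
  }
})

test_that("protein and nucleic populations are scored separately", {
  d <- make_varied_deposits(400, seed = 17, nucleic_fraction = 0.25)
  sc <- compute_q1(d, fit_geometry_pca(d))
  nuc <- sc$group == "nucleic"
  # nucleic component percentiles depend only on the nucleic subpopulation
  expect_equal(sc$p_rfree[nuc],
               percentile_rank(d$r_free[nuc], "lower"))
  # nucleic geometry component is the Clashscore percentile
  expect_equal(sc$p_geom[nuc],
               percentile_rank(d$clashscore[nuc], "lower"))
  # complexes join the protein group
  d2 <- make_varied_deposits(100, seed = 18)
  d2$molecule_class[1:10] <- "complex"
  sc2 <- compute_q1(d2, fit_geometry_pca(d2))
  expect_true(all(sc2$group[1:10] == "protein"))
})

test_that("improving a single metric never lowers the composite rank", {
  d <- make_varied_deposits(200, seed = 19)
  sc <- compute_q1(d, fit_geometry_pca(d))
  d2 <- d
  mid <- 100
  d2$r_free[mid] <- d2$r_free[mid] * 0.5   # strictly better R-free
  sc2 <- compute_q1(d2, fit_geometry_pca(d))
  expect_gte(sc2$q1[mid], sc$q1[mid])
  expect_gte(sc2$p_q1[mid], sc$p_q1[mid])
})

test_that("the PCA-free approximation matches its formula and the exact score", {
  expect_equal(q1p_approx(60, 60, 60, 60, 60), 60)
  expect_equal(q1p_approx(100, 100, 0, 0, 0), 200 / 3)
  expect_error(q1p_approx(101, 50, 50, 50, 50), "percentiles")

  # correlated protein data from the generator (independent geometry
  # metrics would make PC1 an arbitrary rotation)
  d <- generate_deposits(synthetic_config(n_deposits = 2000, seed = 20,
                                          nucleic_fraction = 0))
  d <- impute_constant(d, "mean")$completed
  sc <- compute_q1(d, fit_geometry_pca(d))
  approx <- q1p_approx(sc$p_rfree, sc$p_rsrz,
                       percentile_rank(d$clashscore, "lower"),
                       percentile_rank(d$rama_outliers, "lower"),
                       percentile_rank(d$rota_outliers, "lower"))
  rho <- cor(approx, sc$q1, method = "spearman")
  expect_gt(rho, 0.95)
})
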
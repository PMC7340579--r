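test_that("resolution means match direct formulas and the power-mean inequality", {
  expect_equal(resolution_means(c(2, 2)),
               c(mean = 2, g_mean = 2, v_mean = 2))
  expect_equal(resolution_means(c(1, 4))[["g_mean"]], 2)
  expect_equal(resolution_means(c(1, 2))[["v_mean"]],
               ((1 + 1 / 8) / 2)^(-1 / 3))
  expect_equal(resolution_means(c(1, 2))[["v_mean"]], 1.2114, tolerance = 1e-4)
  set.seed(26)
  for (i in 1:20) {
    r <- exp(rnorm(sample(2:50, 1), log(2), 0.5))
    m <- resolution_means(r)
    expect_lte(m[["v_mean"]], m[["g_mean"]] + 1e-12)
    expect_lte(m[["g_mean"]], m[["mean"]] + 1e-12)
  }
  expect_error(resolution_means(numeric(0)), "empty")
  expect_error(resolution_means(c(1, -1)), "positive")
})

# Two-journal fixture with known scores; Welch statistic computed by its
# closed form in the test as the oracle.
make_scored_journals <- function(scores_a, scores_b, journal_b = "J BETA") {
  n <- length(scores_a) + length(scores_b)
  d <- make_deposits(n, journal_raw = c(rep("J ALPHA", length(scores_a)),
                                        rep(journal_b, length(scores_b))),
                     resolution = rep(2, n))
  d <- clean_journal_names(d)
  tp <- tibble::tibble(pdb_id = d$pdb_id, p_q1_td = c(scores_a, scores_b))
  list(deposits = d, temporal = tp)
}

test_that("journal means and Welch tests match hand computation", {
  a <- c(60, 70, 80, 75, 65)
  b <- c(40, 50, 60, 55, 45, 50)
  fx <- make_scored_journals(a, b)
  rk <- rank_journals(fx$temporal, fx$deposits, min_count = 5)
  expect_equal(rk$journal, c("J ALPHA", "J BETA"))
  expect_equal(rk$mean_score, c(mean(a), mean(b)))
  expect_equal(rk$rank, c(1L, 2L))

  # Welch t and Satterthwaite df by the closed form
  welch_p <- function(x, y) {
    t_stat <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
    df <- (var(x) / length(x) + var(y) / length(y))^2 /
      ((var(x) / length(x))^2 / (length(x) - 1) +
       (var(y) / length(y))^2 / (length(y) - 1))
    2 * pt(-abs(t_stat), df)
  }
  expect_equal(rk$p_value[1], welch_p(a, b), tolerance = 1e-12)
  expect_equal(rk$p_value[2], welch_p(b, a), tolerance = 1e-12)
})

test_that("identical journal and complement scores give p = 1", {
  fx <- make_scored_journals(c(50, 60, 70), c(50, 60, 70))
  rk <- rank_journals(fx$temporal, fx$deposits, min_count = 3)
  expect_equal(rk$p_value, c(1, 1))
  expect_false(any(rk$significant))
})

test_that("the structure-count threshold excludes small journals without side effects", {
  a <- rnorm(120, 60, 5); b <- rnorm(99, 55, 5); c <- rnorm(150, 50, 5)
  fx <- make_scored_journals(c(a, b), c, journal_b = "J GAMMA")
  fx$deposits$journal[seq_len(120)] <- "J ALPHA"
  fx$deposits$journal[120 + seq_along(b)] <- "J BETA"
  rk <- rank_journals(fx$temporal, fx$deposits, min_count = 100)
  expect_false("J BETA" %in% rk$journal)   # 99 < 100
  expect_equal(sort(rk$journal), c("J ALPHA", "J GAMMA"))

  # adding a below-threshold journal leaves other journals' rows unchanged
  rk_all <- rank_journals(fx$temporal, fx$deposits, min_count = 1)
  keep <- rk_all$journal %in% rk$journal
  expect_equal(rk_all$mean_score[keep][order(rk_all$journal[keep])],
               rk$mean_score[order(rk$journal)])
  # no journal meets the bar: empty table with a warning
  expect_warning(empty <- rank_journals(fx$temporal, fx$deposits, min_count = 1000),
                 "minimum")
  expect_equal(nrow(empty), 0)
})

test_that("a date cutoff reproduces the retrospective ranking", {
  d <- make_varied_deposits(800, seed = 27)
  d$journal_raw <- sample(c("J OLD", "J NEW"), 800, replace = TRUE)
  d <- clean_journal_names(d)
  sc <- compute_q1(d, fit_geometry_pca(d))
  tp <- temporal_percentile(sc, d)

  cutoff <- as.Date("2007-01-01")
  rk_cut <- rank_journals(tp, d, min_count = 10, date_cutoff = cutoff)
  keep <- d$deposition_date < cutoff
  rk_sub <- rank_journals(tp[match(d$pdb_id[keep], tp$pdb_id), ], d[keep, ],
                          min_count = 10)
  expect_equal(rk_cut$mean_score, rk_sub$mean_score)
  expect_equal(rk_cut$n_structures, rk_sub$n_structures)
  # and no cutoff equals the all-time table
  expect_identical(rank_journals(tp, d, min_count = 10),
                   rank_journals(tp, d, min_count = 10, date_cutoff = NULL))
})

test_that("windowed rankings respect the in-window threshold and anchoring", {
  d <- make_varied_deposits(500, seed = 28)
  d$journal_raw <- rep(c("J BIG", "J SMALL"), c(470, 30))
  # J SMALL: 29 deposits in the last window, 1 much earlier
  d$deposition_date[471:499] <- as.Date("2018-06-01")
  d$deposition_date[500] <- as.Date("1996-01-01")
  d$deposition_year <- as.integer(format(d$deposition_date, "%Y"))
  d <- clean_journal_names(d)
  sc <- compute_q1(d, fit_geometry_pca(d))
  tp <- temporal_percentile(sc, d)

  w <- windowed_ranking(tp, d, window_years = 5, min_count = 30)
  last_year <- max(d$deposition_year)
  expect_true(all(w$window_end <= last_year))
  expect_true(all(w$window_end - w$window_start == 4))
  expect_equal(max(w$window_end), last_year)
  # J SMALL has 29 < 30 in its window: absent everywhere
  expect_false("J SMALL" %in% w$journal)
  # single eligible journal per window ranks 1
  expect_true(all(w$rank[w$journal == "J BIG"] == 1))
})

test_that("impact correlation recovers monotone and degenerate cases", {
  n_j <- 8
  d <- make_deposits(n_j * 6,
                     journal_raw = rep(sprintf("J%02d", 1:n_j), each = 6),
                     issn = rep(sprintf("%04d-000%d", 1:n_j, 1:n_j %% 10), each = 6),
                     date = rep(as.Date("2005-06-01"), n_j * 6))
  d$deposition_year <- 2005L
  d <- clean_journal_names(d)
  # journal j scores exactly j; impact exactly j: rho = 1
  tp <- tibble::tibble(pdb_id = d$pdb_id,
                       p_q1_td = rep(seq_len(n_j) * 10, each = 6))
  biblio <- tibble::tibble(issn = sprintf("%04d-000%d", 1:n_j, 1:n_j %% 10),
                           year = 2005L, ipp = as.numeric(1:n_j),
                           snip = as.numeric(n_j:1))
  ic <- correlate_impact(tp, d, biblio, min_deposits = 5)
  expect_equal(ic$rho_ipp, 1)
  expect_equal(ic$rho_snip, -1)
  expect_equal(ic$n_journals, n_j)

  # fewer than 3 journal points: correlation reported absent
  ic2 <- correlate_impact(tp, d, biblio[1:2, ], min_deposits = 5)
  expect_true(is.na(ic2$rho_ipp))

  # journal-years below the deposit minimum contribute no point
  ic3 <- correlate_impact(tp, d, biblio, min_deposits = 7)
  expect_equal(nrow(ic3), 0)
})
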
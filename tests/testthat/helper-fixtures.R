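# Small hand-built deposit tables used across tests. All fixtures are
# constructed in code; values are chosen so that expected results can be
# verified by hand or by a brute-force oracle in the test itself.

make_deposits <- function(n,
                          pdb_id = sprintf("%04d", seq_len(n)),
                          date = as.Date("2000-01-01") + seq_len(n) - 1,
                          resolution = rep(2.0, n),
                          molecule_class = rep("protein", n),
                          journal_raw = rep("J Test", n),
                          issn = rep(NA_character_, n),
                          clashscore = rep(5, n),
                          rama_outliers = rep(0.5, n),
                          rota_outliers = rep(2, n),
                          rsrz_outliers = rep(3, n),
                          r_free = rep(22, n),
                          r_work = rep(19, n)) {
  d <- tibble::tibble(
    pdb_id = pdb_id,
    deposition_date = date,
    deposition_year = as.integer(format(date, "%Y")),
    resolution = resolution,
    molecule_class = molecule_class,
    structural_genomics = rep(FALSE, n),
    journal_raw = journal_raw,
    issn = issn,
    clashscore = clashscore,
    rama_outliers = rama_outliers,
    rota_outliers = rota_outliers,
    rsrz_outliers = rsrz_outliers,
    r_free = r_free,
    r_work = r_work)
  d$rama_outliers[d$molecule_class == "nucleic_acid"] <- NA_real_
  d$rota_outliers[d$molecule_class == "nucleic_acid"] <- NA_real_
  d
}

# Deposit table with enough smooth variation for PCA / scoring tests.
make_varied_deposits <- function(n, seed = 42, nucleic_fraction = 0) {
  set.seed(seed)
  d <- make_deposits(
    n,
    date = as.Date("1995-01-01") + sort(sample.int(9000, n, replace = TRUE)),
    resolution = exp(rnorm(n, log(2), 0.2)),
    molecule_class = ifelse(runif(n) < nucleic_fraction, "nucleic_acid", "protein"),
    clashscore = rlnorm(n, 1.5, 0.8),
    rama_outliers = rlnorm(n, -1.5, 1),
    rota_outliers = rlnorm(n, 0.8, 0.7),
    rsrz_outliers = rlnorm(n, 1, 0.8),
    r_free = pmin(rnorm(n, 23, 3.5), 45),
    r_work = pmin(rnorm(n, 19, 3), 40))
  d$r_free <- pmax(d$r_free, 5)
  d$r_work <- pmax(d$r_work, 4)
  d
}

# Brute-force tie-averaged percentile of each element, by definition:
# rank from worst to best, ties get the average rank of their group.
oracle_percentile <- function(values, better = "lower") {
  n <- length(values)
  vapply(seq_len(n), function(i) {
    if (better == "lower") {
      worse <- sum(values > values[i])   # strictly worse quality
      tied <- sum(values == values[i])
    } else {
      worse <- sum(values < values[i])
      tied <- sum(values == values[i])
    }
    ranks <- worse + seq_len(tied)
    100 * mean(ranks) / n
  }, numeric(1))
}

# Brute-force temporal percentile: re-rank each deposit within its full
# reference population (same stratum, strictly earlier date, plus self).
oracle_temporal <- function(q1, date, stratum) {
  n <- length(q1)
  vapply(seq_len(n), function(i) {
    ref <- which(stratum == stratum[i] & date < date[i])
    pop <- c(q1[ref], q1[i])
    pcts <- oracle_percentile(pop, better = "higher")
    pcts[length(pop)]
  }, numeric(1))
}
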
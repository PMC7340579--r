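#' Configuration for the synthetic deposit generator
#'
#' Bundles the parameters of the synthetic archive emulator. Defaults
#' reproduce the published marginal means/SDs and per-metric missing-value
#' fractions of the X-ray archive (Clashscore 8.05/9.11, Ramachandran
#' outliers 0.49/1.26, Rotamer outliers 3.26/3.65, RSRZ outliers
#' 4.05/4.06, R-free 23.35/3.82, R 19.31/3.25; missing fractions 0.10\%,
#' 1.69\%, 1.72\%, 9.56\%, 4.29\%, 2.39\%), a strong R/R-free correlation,
#' quality improvement over deposition year, and quality dependence on
#' resolution.
#'
#' @param n_deposits Number of deposits to generate.
#' @param seed Integer seed; same seed + config gives identical output.
#' @param year_range Two-element integer vector, first and last deposition
#'   year.
#' @param metric_marginals Named list of `c(mean, sd)` per metric.
#' @param missing_fractions Named per-metric missingness probabilities.
#' @param r_rfree_correlation Correlation between R and R-free in `(0,1)`.
#' @param year_quality_slope Latent-quality drift per year, in latent SD
#'   units (positive = newer deposits better).
#' @param resolution_effect Latent-quality worsening per Angstrom of
#'   resolution, in latent SD units.
#' @param n_journals Number of synthetic journals.
#' @param journal_effect_sd SD of per-journal latent-quality offsets.
#' @param nucleic_fraction Share of nucleic-acid-only deposits.
#' @param complex_fraction Share of protein-nucleic-acid complexes.
#' @param tbp_fraction Share of deposits with no primary citation
#'   ("To be published").
#' @param sg_fraction Share of structural-genomics deposits.
#' @param copula_strengths Named per-metric correlation between the latent
#'   quality and the metric's Gaussian copula latent.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_deposits = 10000,
                             seed = 1,
                             year_range = c(1972, 2019),
                             metric_marginals = list(
                               clashscore    = c(8.05, 9.11),
                               rama_outliers = c(0.49, 1.26),
                               rota_outliers = c(3.26, 3.65),
                               rsrz_outliers = c(4.05, 4.06),
                               r_free        = c(23.35, 3.82),
                               r_work        = c(19.31, 3.25)),
                             missing_fractions = c(
                               clashscore = 0.0010, rama_outliers = 0.0169,
                               rota_outliers = 0.0172, rsrz_outliers = 0.0956,
                               r_free = 0.0429, r_work = 0.0239),
                             r_rfree_correlation = 0.9,
                             year_quality_slope = 0.045,
                             resolution_effect = 0.8,
                             n_journals = 40,
                             journal_effect_sd = 0.3,
                             nucleic_fraction = 0.07,
                             complex_fraction = 0.07,
                             tbp_fraction = 0.16,
                             sg_fraction = 0.09,
                             copula_strengths = c(
                               clashscore = 0.65, rama_outliers = 0.5,
                               rota_outliers = 0.55, rsrz_outliers = 0.5,
                               r_free = 0.6)) {
  stopifnot(n_deposits >= 0,
            all(missing_fractions >= 0 & missing_fractions <= 1),
            r_rfree_correlation > 0 && r_rfree_correlation < 1,
            nucleic_fraction >= 0 && nucleic_fraction <= 1,
            tbp_fraction >= 0 && tbp_fraction <= 1,
            all(vapply(metric_marginals, function(m) m[2] >= 0, logical(1))))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic deposit table
#'
#' Draws deposits from a latent-quality Gaussian copula model. Each
#' deposit gets a latent quality that improves with deposition year,
#' worsens with resolution, and carries a per-journal offset plus noise;
#' each badness metric is then mapped through a right-skewed (lognormal)
#' marginal matching the configured mean/SD via the copula, while R-free
#' and R are drawn jointly Gaussian at the configured correlation.
#' Missingness is applied per metric at the configured rates, with RSRZ
#' missingness concentrated in early years (the metric did not exist for
#' early depositions); all values are clipped to legal ranges.
#'
#' @param config A [synthetic_config()].
#' @param journal_effects Optional tibble (`journal`, `offset`) of extra
#'   latent-quality offsets, used by [inject_journal_effects()].
#' @return A deposit tibble in the same schema as [read_deposit_table()]
#'   output, with the config and the realized journal offsets attached as
#'   attributes `synthetic_config` and `journal_effects`.
#' @export
generate_deposits <- function(config = synthetic_config(), journal_effects = NULL) {
  cfg <- config
  n <- cfg$n_deposits
  empty <- parse_deposits(tibble::tibble(
    pdb_id = character(), deposition_date = character(), resolution = character(),
    molecule_class = character(), structural_genomics = character(),
    journal_raw = character(), issn = character(),
    clashscore = character(), rama_outliers = character(),
    rota_outliers = character(), rsrz_outliers = character(),
    r_free = character(), r_work = character()))
  if (n == 0) return(empty)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(cfg$seed)
    code
  }
  withr_seed({
    y0 <- cfg$year_range[1]; y1 <- cfg$year_range[2]
    ## archive growth: newer years hold exponentially more deposits
    years <- y0:y1
    year <- sample(years, n, replace = TRUE, prob = exp(0.10 * (years - y0)))
    day <- sample.int(365, n, replace = TRUE)
    date <- as.Date(paste0(year, "-01-01")) + (day - 1)

    ## resolution: lognormal around ~2.1 A with a mild improvement by year
    meanlog <- log(2.08) - 0.0015 * (year - mean(year))
    resolution <- rlnorm(n, meanlog = meanlog, sdlog = 0.25)
    resolution <- pmax(resolution, 0.5)

    u <- runif(n)
    molecule_class <- ifelse(u < cfg$nucleic_fraction, "nucleic_acid",
                      ifelse(u < cfg$nucleic_fraction + cfg$complex_fraction,
                             "complex", "protein"))
    structural_genomics <- rbinom(n, 1, cfg$sg_fraction) == 1

    ## journals: Zipf-like popularity, Gaussian quality offsets
    j_names <- sprintf("J SYNTH %02d", seq_len(cfg$n_journals))
    j_issn <- sprintf("%04d-%04d", seq_len(cfg$n_journals), 1000 + seq_len(cfg$n_journals))
    j_offset <- rnorm(cfg$n_journals, 0, cfg$journal_effect_sd)
    base_effects <- tibble::tibble(journal = c(j_names, TO_BE_PUBLISHED),
                                   offset = c(j_offset, 0))
    if (!is.null(journal_effects)) {
      extra <- match(journal_effects$journal, base_effects$journal)
      if (anyNA(extra)) {
        stop("unknown journal(s) in effect table: ",
             paste(journal_effects$journal[is.na(extra)], collapse = ", "))
      }
      base_effects$offset[extra] <- base_effects$offset[extra] + journal_effects$offset
    }
    is_tbp <- runif(n) < cfg$tbp_fraction
    j_idx <- sample.int(cfg$n_journals, n, replace = TRUE,
                        prob = 1 / seq_len(cfg$n_journals)^0.8)
    journal_raw <- ifelse(is_tbp, TO_BE_PUBLISHED, j_names[j_idx])
    issn <- ifelse(is_tbp, NA_character_, j_issn[j_idx])
    offset <- base_effects$offset[match(journal_raw, base_effects$journal)]

    ## latent quality: higher = better
    z <- cfg$year_quality_slope * (year - mean(years)) -
      cfg$resolution_effect * (resolution - exp(log(2.08) + 0.25^2 / 2)) +
      offset + rnorm(n)
    ## normal-scores transform: keeps the quality ranking induced by year,
    ## resolution and journal, but gives the copula an exactly Gaussian
    ## latent so the configured marginals are preserved
    zc <- stats::qnorm((rank(z, ties.method = "first") - 0.5) / n)

    ## copula draw per badness metric: latent correlated with -quality
    latent <- function(rho) rho * (-zc) + sqrt(1 - rho^2) * rnorm(n)
    skewed <- function(metric) {
      m <- cfg$metric_marginals[[metric]][1]; s <- cfg$metric_marginals[[metric]][2]
      sig2 <- log(1 + (s / m)^2)
      qlnorm(pnorm(latent(cfg$copula_strengths[[metric]])),
             meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
    }
    clashscore <- clip_to_range(skewed("clashscore"), "clashscore")
    rama <- clip_to_range(skewed("rama_outliers"), "rama_outliers")
    rota <- clip_to_range(skewed("rota_outliers"), "rota_outliers")
    rsrz <- clip_to_range(skewed("rsrz_outliers"), "rsrz_outliers")

    ## R-free Gaussian in the copula; R jointly Gaussian with it
    l_rfree <- latent(cfg$copula_strengths[["r_free"]])
    rho_rr <- cfg$r_rfree_correlation
    l_r <- rho_rr * l_rfree + sqrt(1 - rho_rr^2) * rnorm(n)
    mm <- cfg$metric_marginals
    r_free <- clip_to_range(mm$r_free[1] + mm$r_free[2] * l_rfree, "r_free")
    r_work <- clip_to_range(mm$r_work[1] + mm$r_work[2] * l_r, "r_work")
    r_free <- pmax(r_free, 0.01); r_work <- pmax(r_work, 0.01)

    res <- tibble::tibble(
      pdb_id = sprintf("%04X", seq_len(n) - 1L + 4096L),
      deposition_date = date,
      deposition_year = as.integer(year),
      resolution = resolution,
      molecule_class = molecule_class,
      structural_genomics = structural_genomics,
      journal_raw = journal_raw,
      issn = issn,
      clashscore = clashscore,
      rama_outliers = rama,
      rota_outliers = rota,
      rsrz_outliers = rsrz,
      r_free = r_free,
      r_work = r_work)

    ## missingness: independent Bernoulli per metric; RSRZ concentrated in
    ## early years (two rescale passes keep the average at the target)
    fr <- cfg$missing_fractions
    for (m in names(fr)) {
      if (fr[[m]] <= 0) next
      p <- rep(fr[[m]], n)
      if (m == "rsrz_outliers") {
        w <- exp(-0.12 * (year - y0))
        p <- fr[[m]] * w / mean(w)
        for (k in 1:2) {
          capped <- pmin(p, 0.95)
          p <- pmin(p * fr[[m]] / mean(capped), 0.95)
        }
      }
      hide <- runif(n) < p
      res[[m]][hide] <- NA_real_
    }
    ## Rama/Rota inapplicable for nucleic-only deposits
    na_rows <- res$molecule_class == "nucleic_acid"
    res$rama_outliers[na_rows] <- NA_real_
    res$rota_outliers[na_rows] <- NA_real_

    attr(res, "synthetic_config") <- cfg
    attr(res, "journal_effects") <- base_effects
    res
  })
}

#' Add journal quality offsets and regenerate metrics
#'
#' Re-draws a synthetic deposit table with additional per-journal latent
#' quality offsets applied before the copula metric mapping, using the
#' same seed and configuration the table was generated with. Used for
#' parameter-recovery tests of the journal ranking: a journal given a
#' positive offset should surface at the top of the ranking.
#'
#' @param records A tibble produced by [generate_deposits()].
#' @param effect_table Tibble with columns `journal` and `offset` (latent
#'   SD units); every journal must exist in `records`.
#' @return A regenerated deposit tibble.
#' @export
inject_journal_effects <- function(records, effect_table) {
  cfg <- attr(records, "synthetic_config")
  if (is.null(cfg)) stop("records lack a synthetic_config attribute")
  known <- attr(records, "journal_effects")$journal
  if (!all(effect_table$journal %in% known)) {
    stop("unknown journal(s): ",
         paste(setdiff(effect_table$journal, known), collapse = ", "))
  }
  generate_deposits(cfg, journal_effects = effect_table)
}

#' Write a synthetic config as YAML
#' @param config A [synthetic_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  ## yaml drops names of named atomic vectors; store them as maps
  yamlable <- lapply(unclass(config), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(yamlable, path)
  invisible(path)
}

#' Read a synthetic config from YAML
#' @param path YAML path written by [write_synthetic_config()] (missing
#'   fields fall back to defaults).
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(synthetic_config)))
  vals <- vals[keep]
  for (nm in c("missing_fractions", "copula_strengths")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  if (!is.null(vals$metric_marginals)) {
    vals$metric_marginals <- lapply(vals$metric_marginals, unlist)
  }
  do.call(synthetic_config, vals)
}
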
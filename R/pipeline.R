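#' Default pipeline configuration
#'
#' @param deposits Path to a deposit CSV/TSV, or `NULL` to generate
#'   synthetic deposits from `synthetic`.
#' @param synthetic A [synthetic_config()] used when `deposits` is `NULL`.
#' @param schema Optional column-name mapping for [read_deposit_table()].
#' @param alias_map Optional path to a journal alias CSV.
#' @param bibliometrics Optional path to an IPP/SNIP CSV.
#' @param imputation_method `"mean"`, `"median"`, or `"mice"`.
#' @param imputation_iterations Chained-equations cycles.
#' @param seed Root seed; each stage derives its own from it.
#' @param variant Composite variant for the final percentile,
#'   `"averaging"` or `"minimum"`.
#' @param convention Percentile convention, see [percentile_rank()].
#' @param min_journal_count All-time ranking threshold (default 100).
#' @param window_years,window_min_count Windowed-ranking parameters.
#' @param alpha Welch/Bonferroni family-wise significance level.
#' @param date_cutoff Optional retrospective cutoff date.
#' @param out_dir Output directory for tables and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(deposits = NULL,
                            synthetic = synthetic_config(),
                            schema = NULL,
                            alias_map = NULL,
                            bibliometrics = NULL,
                            imputation_method = "mice",
                            imputation_iterations = 10,
                            seed = 1,
                            variant = "averaging",
                            convention = "inclusive",
                            min_journal_count = 100,
                            window_years = 5,
                            window_min_count = 30,
                            alpha = 0.001,
                            date_cutoff = NULL,
                            out_dir = tempfile("pdbqual_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields
#'   (the `synthetic` field, if present, is passed to
#'   [synthetic_config()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  vals <- vals[keep]
  if (!is.null(vals$synthetic)) {
    vals$synthetic <- do.call(synthetic_config, vals$synthetic)
  }
  do.call(pipeline_config, vals)
}

#' Run the full quality-analysis pipeline
#'
#' Executes ingest (or synthetic generation), journal-name cleaning,
#' imputation, geometry PCA, composite scoring, temporal percentiles, and
#' journal analytics in order, writing each stage's table to
#' `config$out_dir` together with a JSON run manifest (seeds, input
#' checksums, and per-stage row counts) that makes re-runs reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage outputs (`deposits`,
#'   `imputation`, `pca`, `scores`, `temporal`, `ranking`, `windowed`,
#'   `impact`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  for (p in c(cfg$deposits, cfg$alias_map, cfg$bibliometrics)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("pdbqual")),
                   seed = cfg$seed, stages = list())
  stage <- function(name, n_rows, extra = list()) {
    manifest$stages[[name]] <<- c(list(rows = n_rows), extra)
  }

  ## ingest or generate
  if (!is.null(cfg$deposits)) {
    deposits <- read_deposit_table(cfg$deposits, cfg$schema)
    stage("ingest", nrow(deposits),
          list(input_md5 = unname(tools::md5sum(cfg$deposits)),
               rejected = nrow(attr(deposits, "rejected"))))
  } else {
    syn <- cfg$synthetic
    syn$seed <- syn$seed + cfg$seed
    deposits <- generate_deposits(syn)
    stage("synthetic", nrow(deposits), list(generator_seed = syn$seed))
  }

  alias <- if (!is.null(cfg$alias_map)) read_alias_map(cfg$alias_map) else NULL
  deposits <- clean_journal_names(deposits, alias)
  stage("clean_journals", nrow(deposits),
        list(unique_journals = length(unique(deposits$journal))))
  write_deposit_table(deposits, file.path(cfg$out_dir, "deposits.csv"))

  imput <- impute_deposits(deposits, cfg$imputation_method,
                           iterations = cfg$imputation_iterations,
                           seed = cfg$seed + 1)
  completed <- imput$completed
  stage("impute", nrow(completed),
        list(method = imput$method, iterations = imput$n_iterations,
             imputed_cells = sum(as.matrix(
               imput$provenance[, .imputable_cols]) == "imputed")))
  readr::write_csv(imput$provenance, file.path(cfg$out_dir, "provenance.csv"))
  write_deposit_table(completed, file.path(cfg$out_dir, "completed.csv"))

  has_protein <- any(molecule_group(completed$molecule_class) == "protein")
  pca <- if (has_protein) fit_geometry_pca(completed) else NULL
  if (!is.null(pca)) {
    stage("geometry_pca", pca$n_fit,
          list(explained_variance = round(pca$explained_variance, 4),
               pc1_loadings = round(unname(pca$loadings[, 1]), 4),
               outliers_excluded = length(pca$outlier_ids)))
  }

  scores <- compute_q1(completed, pca, variant = cfg$variant,
                       convention = cfg$convention)
  stage("scores", nrow(scores))
  readr::write_csv(scores, file.path(cfg$out_dir, "scores.csv"))

  temporal <- temporal_percentile(scores, completed, conditioning = "both",
                                  convention = cfg$convention)
  stage("temporal", nrow(temporal))
  readr::write_csv(temporal, file.path(cfg$out_dir, "temporal.csv"))

  ranking <- rank_journals(temporal, completed,
                           min_count = cfg$min_journal_count,
                           date_cutoff = cfg$date_cutoff, alpha = cfg$alpha)
  stage("rank_journals", nrow(ranking))
  readr::write_csv(ranking, file.path(cfg$out_dir, "ranking.csv"))

  windowed <- windowed_ranking(temporal, completed,
                               window_years = cfg$window_years,
                               min_count = cfg$window_min_count)
  stage("windowed_ranking", nrow(windowed))
  readr::write_csv(windowed, file.path(cfg$out_dir, "windowed.csv"))

  impact <- NULL
  if (!is.null(cfg$bibliometrics)) {
    biblio <- read_bibliometrics(cfg$bibliometrics)
    impact <- correlate_impact(temporal, completed, biblio)
    stage("impact_correlation", nrow(impact))
    readr::write_csv(impact, file.path(cfg$out_dir, "impact.csv"))
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(deposits = deposits, imputation = imput, pca = pca,
                 scores = scores, temporal = temporal, ranking = ranking,
                 windowed = windowed, impact = impact, manifest = manifest,
                 out_dir = cfg$out_dir))
}
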